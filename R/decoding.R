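# Time-resolved multivariate decoding of workload states: per-time-point
# shrinkage LDA (Ledoit-Wolf), repeated stratified cross-validation,
# stratified dummy baselines, bootstrap-CI inference with a minimum-duration
# criterion, and Haufe activation-pattern transformation.

#' Downsample an epoch set
#'
#' Polyphase rational-rate resampling (anti-alias FIR) per trial and
#' channel; times are rescaled so the first sample time is preserved.
#'
#' @param epochs An [eeg_epochs].
#' @param target_fs Target rate in Hz (default 100); must not exceed the
#'   current rate.
#' @return An [eeg_epochs] at `target_fs`.
#' @export
downsample_epochs <- function(epochs, target_fs = 100) {
  fs <- epochs$fs
  if (target_fs > fs) stop("target_fs must not exceed the sampling rate")
  if (target_fs == fs) return(epochs)
  frac <- .as_fraction(target_fs / fs)
  d <- epochs$data
  dm <- dim(d)
  nout <- ceiling(dm[3] * frac[1] / frac[2])
  rs <- .resample_operator(dm[3], frac[1], frac[2])
  flat <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  res <- rs %*% flat
  out <- aperm(array(res, dim = c(nout, dm[1], dm[2])), c(2, 3, 1))
  epochs$data <- out
  epochs$times <- epochs$times[1] + (seq_len(nout) - 1) / target_fs
  epochs$fs <- target_fs
  epochs$history <- c(epochs$history, sprintf("downsampled_%gHz", target_fs))
  epochs
}

.as_fraction <- function(x, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("rate ratio is not a small rational")
}

# Rational-rate resampling as a linear operator: replicate-pad the edges,
# zero-stuff by p, zero-phase FIR low-pass at the tighter of the two
# Nyquists (filtfilt, so no group delay), keep every q-th sample of the
# unpadded region. Returns a ceiling(n p / q) x n matrix.
.resample_operator <- function(n, p, q) {
  ord <- 10 * max(p, q)
  npad <- min(2 * ord, n - 1)
  npd <- n + 2 * npad
  P <- matrix(0, npd, n)                  # edge-replication padding
  P[cbind(seq_len(npd),
          pmin(pmax(seq_len(npd) - npad, 1), n))] <- 1
  nup <- npd * p
  cutoff <- 1 / max(p, q)                 # relative to upsampled Nyquist
  fir <- signal::fir1(min(ord, floor((nup - 1) / 3) * 2), cutoff)
  U <- matrix(0, nup, npd)                # zero-stuffing
  U[cbind(seq(1, nup, by = p), seq_len(npd))] <- 1
  UP <- U %*% P
  Fw <- apply(UP, 2, function(col) signal::filtfilt(fir, col)) * p
  nout <- ceiling(n * p / q)
  keep <- npad * p + 1 + (seq_len(nout) - 1) * q
  Fw[keep, , drop = FALSE]
}

#' Ledoit-Wolf shrunk covariance
#'
#' Analytic optimal shrinkage towards the scaled identity:
#' `Sigma* = (1 - rho) S + rho (tr(S)/p) I`, with `S` the maximum-likelihood
#' sample covariance (denominator `n`) and `rho` the Ledoit-Wolf intensity
#' estimate. The result is positive definite for any `rho > 0`.
#'
#' @param X Numeric samples x features matrix.
#' @param center If `TRUE` (default), column-center `X` first. Pass
#'   `FALSE` for data already centred (e.g. pooled within-class residuals).
#' @return List with `cov` (p x p), `shrinkage` (rho), `mu` (tr(S)/p).
#' @export
ledoit_wolf_cov <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  if (center) X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < 1e-300) {
    return(list(cov = S, shrinkage = 0, mu = mu))
  }
  norms2 <- rowSums(X^2)
  b2bar <- (sum(norms2^2) - n * sum(S^2)) / (p * n^2)
  b2 <- min(max(b2bar, 0), d2)
  rho <- b2 / d2
  list(cov = (1 - rho) * S + diag(rho * mu, p), shrinkage = rho, mu = mu)
}

#' Fit a shrinkage LDA classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance
#' replaced by its Ledoit-Wolf shrunk estimate. For two classes the
#' discriminant is `w = Sigma*^-1 (mu_2 - mu_1)` with a bias from the class
#' means and empirical priors; with more classes one multiclass model is
#' fitted (per-class linear discriminant scores, softmax-comparable).
#'
#' @param X Numeric samples x features matrix.
#' @param y Class labels (coerced to factor); all classes must be present.
#' @param shrinkage If `FALSE`, use the unshrunk pooled covariance.
#' @return An object of class `lda_model` with elements `classes`, `means`,
#'   `W` (features x classes discriminant weights), `b` (per-class bias),
#'   `w`, `bias` (binary convenience: contrast second vs first class),
#'   `shrinkage`.
#' @export
lda_fit <- function(X, y, shrinkage = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  k <- length(classes)
  if (k < 2 || any(table(y) == 0)) stop("all classes must be present")
  p <- ncol(X)
  M <- matrix(0, k, p)
  Xc <- X
  for (i in seq_len(k)) {
    sel <- y == classes[i]
    M[i, ] <- colMeans(X[sel, , drop = FALSE])
    Xc[sel, ] <- sweep(X[sel, , drop = FALSE], 2, M[i, ])
  }
  lw <- ledoit_wolf_cov(Xc, center = FALSE)
  S <- if (shrinkage) lw$cov else crossprod(Xc) / nrow(Xc)
  pri <- as.vector(table(y)) / length(y)
  W <- solve(S, t(M))                       # p x k
  b <- -0.5 * colSums(t(M) * W) + log(pri)
  w <- W[, k] - W[, 1]
  bias <- b[k] - b[1]
  structure(list(classes = classes, means = M, W = W, b = b, w = w,
                 bias = bias, cov = S,
                 shrinkage = if (shrinkage) lw$shrinkage else 0),
            class = "lda_model")
}

#' Predict from a shrinkage LDA model
#'
#' @param object An `lda_model`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return List with `scores` (n x k per-class discriminants), `decision`
#'   (n; binary contrast score `w . x + bias`), `class` (predicted labels).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  sc <- sweep(X %*% object$W, 2, object$b, "+")
  cls <- object$classes[max.col(sc, ties.method = "first")]
  list(scores = sc, decision = as.vector(X %*% object$w) + object$bias,
       class = cls)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a positive-class score exceeds a
#' negative-class score, counting ties as one half.
#'
#' @param scores Numeric decision values.
#' @param labels Binary labels; the second factor level (or the larger of
#'   two unique values) is the positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes present")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Support-weighted F1 score
#'
#' Mean of per-class F1 scores weighted by true class support. A class with
#' zero precision+recall contributes 0.
#'
#' @param predictions Predicted labels.
#' @param labels True labels (defines the class set and supports).
#' @return Weighted F1 in \[0, 1\].
#' @export
weighted_f1 <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length")
  }
  labels <- factor(labels)
  predictions <- factor(predictions, levels = levels(labels))
  f1 <- vapply(levels(labels), function(cl) {
    tp <- sum(predictions == cl & labels == cl)
    fp <- sum(predictions == cl & labels != cl)
    fn <- sum(predictions != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  support <- as.vector(table(labels)) / length(labels)
  sum(f1 * support)
}

#' Repeated stratified k-fold assignments
#'
#' Within each repeat, each class's trials are shuffled and dealt
#' round-robin across folds, so fold class proportions match the overall
#' ratio within one trial.
#'
#' @param y Class labels.
#' @param n_splits Folds per repeat (default 5).
#' @param n_repeats Repeats (default 20).
#' @param seed RNG seed.
#' @return List of `n_splits * n_repeats` elements, each
#'   `list(train, test)` index vectors.
#' @export
stratified_folds <- function(y, n_splits = 5, n_repeats = 20, seed = 1) {
  y <- factor(y)
  if (any(table(y) < n_splits)) {
    stop("every class needs at least n_splits trials")
  }
  n <- length(y)
  with_seed(seed, {
    out <- vector("list", n_splits * n_repeats)
    fi <- 1
    for (r in seq_len(n_repeats)) {
      assign_fold <- integer(n)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        assign_fold[idx] <- rep_len(seq_len(n_splits), length(idx))
      }
      for (f in seq_len(n_splits)) {
        test <- which(assign_fold == f)
        out[[fi]] <- list(train = setdiff(seq_len(n), test), test = test)
        fi <- fi + 1
      }
    }
    out
  })
}

#' Haufe transformation of decoder weights into activation patterns
#'
#' Converts backward-model weights `W` into forward-model activation
#' patterns `A = Sigma_X W Sigma_s^-1`, where `Sigma_X` is the feature
#' covariance and `Sigma_s` the covariance of the decision scores
#' `s = X_c W`. For a single discriminant this reduces to
#' `Cov(x, s) / Var(s)` per feature.
#'
#' @param weights Features x classes matrix (or vector).
#' @param X Samples x features data the model was trained on.
#' @param scores Optional samples x classes decision scores; when `NULL`
#'   (default) they are computed as `X_c %*% weights`. Supplying them
#'   reduces the transform to `Cov(X, scores) Sigma_s^-1`.
#' @return Features x classes activation pattern matrix.
#' @export
haufe_patterns <- function(weights, X, scores = NULL) {
  W <- as.matrix(weights)
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  s <- if (is.null(scores)) Xc %*% W else as.matrix(scores)
  sc <- sweep(s, 2, colMeans(s))
  Ss <- crossprod(sc) / (n - 1)
  if (rcond(Ss) < 1e-12) stop("singular decision-score covariance")
  (crossprod(Xc, sc) / (n - 1)) %*% solve(Ss)
}

#' Time-resolved cross-validated decoding
#'
#' For every time point, fits a shrinkage LDA on the training trials of each
#' stratified fold (features = channels) and scores the held-out trials:
#' AUC for two classes, support-weighted F1 (multiclass LDA predictions) for
#' three or more. Fold assignments are shared across time points.
#'
#' @param epochs_by_condition Named list of [eeg_epochs], one per condition
#'   (same channels and time axes).
#' @param contrast Character vector of 2+ condition names to decode.
#' @param n_splits,n_repeats Cross-validation scheme (default 5 x 20 = 100
#'   folds per time point).
#' @param seed RNG seed for fold assignment.
#' @param patterns If `TRUE` (default), also return Haufe activation
#'   patterns computed per fold on the training data and averaged across
#'   folds (classes x channels x time; one "class" for binary contrasts).
#' @return A `decoding_result`: `scores` (folds x time), `times`,
#'   `contrast`, `metric`, `patterns`, `fold_sizes`.
#' @export
sliding_decode <- function(epochs_by_condition, contrast,
                           n_splits = 5, n_repeats = 20, seed = 1,
                           patterns = TRUE) {
  if (!all(contrast %in% names(epochs_by_condition))) {
    stop("contrast conditions missing from epochs_by_condition")
  }
  eps <- epochs_by_condition[contrast]
  X <- do.call(function(...) abind3(...), lapply(eps, function(e) e$data))
  y <- factor(rep(contrast, vapply(eps, n_trials, 1L)), levels = contrast)
  times <- eps[[1]]$times
  binary <- length(contrast) == 2
  folds <- stratified_folds(y, n_splits, n_repeats, seed)
  nf <- length(folds)
  nt <- length(times)
  p <- dim(X)[2]
  k_pat <- if (binary) 1 else length(contrast)
  scores <- matrix(NA_real_, nf, nt)
  pat <- if (patterns) array(0, dim = c(k_pat, p, nt)) else NULL
  for (ti in seq_len(nt)) {
    Xt <- X[, , ti]
    for (fi in seq_len(nf)) {
      tr <- folds[[fi]]$train; te <- folds[[fi]]$test
      fit <- lda_fit(Xt[tr, , drop = FALSE], y[tr])
      pr <- predict(fit, Xt[te, , drop = FALSE])
      scores[fi, ti] <- if (binary) {
        roc_auc(pr$decision, y[te])
      } else {
        weighted_f1(pr$class, y[te])
      }
      if (patterns) {
        Wf <- if (binary) matrix(fit$w, ncol = 1) else fit$W
        pat[, , ti] <- pat[, , ti] +
          t(haufe_patterns(Wf, Xt[tr, , drop = FALSE])) / nf
      }
    }
  }
  structure(list(scores = scores, times = times, contrast = contrast,
                 metric = if (binary) "auc" else "weighted_f1",
                 patterns = pat, channels = eps[[1]]$channels,
                 n_splits = n_splits, n_repeats = n_repeats),
            class = "decoding_result")
}

# bind 3d arrays along the first (trial) dimension
abind3 <- function(...) {
  args <- list(...)
  dm <- dim(args[[1]])
  nt <- sum(vapply(args, function(a) dim(a)[1], 1L))
  out <- array(0, dim = c(nt, dm[2], dm[3]))
  at <- 0
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Stratified dummy-classifier baseline scores
#'
#' Empirical chance level: per fold, test-set predictions are drawn i.i.d.
#' from the training labels' empirical distribution and scored exactly like
#' the decoder (AUC with the sampled labels as scores, or weighted F1). The
#' time axis is replicated, since the dummy ignores the data.
#'
#' @param y Class labels (as used for [sliding_decode()]).
#' @param n_times Number of time points to replicate over.
#' @param n_splits,n_repeats Cross-validation scheme.
#' @param seed RNG seed (independent of the decoder's CV seed).
#' @return Folds x time score matrix.
#' @export
dummy_scores <- function(y, n_times, n_splits = 5, n_repeats = 20,
                         seed = 2) {
  y <- factor(y)
  binary <- nlevels(y) == 2
  folds <- stratified_folds(y, n_splits, n_repeats, seed)
  sc <- with_seed(derive_seed(seed, 97), {
    vapply(folds, function(f) {
      prob <- as.vector(table(y[f$train])) / length(f$train)
      pred <- sample(levels(y), length(f$test), replace = TRUE, prob = prob)
      if (binary) {
        roc_auc(as.numeric(factor(pred, levels = levels(y))), y[f$test])
      } else {
        weighted_f1(pred, y[f$test])
      }
    }, 1.0)
  })
  matrix(sc, nrow = length(sc), ncol = n_times)
}

#' Bootstrap mean and percentile confidence interval per time point
#'
#' Resamples the fold scores with replacement (`n_boot` Monte Carlo
#' replicates), takes the mean of each replicate, and returns the replicate
#' mean and the percentile interval at the requested level.
#'
#' @param scores Folds x time matrix (or a vector, treated as one time
#'   point).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return A `boot_ci` list with numeric vectors `mean`, `lo`, `hi`.
#' @export
bootstrap_ci <- function(scores, n_boot = 5000, level = 0.95, seed = 3) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  nf <- nrow(scores)
  if (nf < 2) stop("need at least 2 scores per time point")
  alpha <- (1 - level) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(nf, n_boot * nf, replace = TRUE), n_boot, nf)
    nt <- ncol(scores)
    m <- lo <- hi <- numeric(nt)
    for (ti in seq_len(nt)) {
      bm <- rowMeans(matrix(scores[idx, ti], n_boot, nf))
      m[ti] <- mean(bm)
      q <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
      lo[ti] <- q[1]; hi[ti] <- q[2]
    }
    structure(list(mean = m, lo = lo, hi = hi, level = level,
                   n_boot = n_boot), class = "boot_ci")
  })
}

#' Significant decoding intervals
#'
#' Maximal runs of time points where the decoder's lower confidence bound
#' exceeds the dummy's upper bound; runs shorter than `min_duration` are
#' discarded. A run of `m` points at step `1/fs` counts as `m / fs` seconds
#' (closed count: 20 points at 100 Hz meet the 200 ms criterion).
#'
#' @param lda_ci,dummy_ci `boot_ci` objects on aligned time axes.
#' @param times Time axis (s).
#' @param min_duration Minimum duration in seconds (default 0.200).
#' @return Matrix with columns `start`, `end` (s) and attribute
#'   `"indices"` (list of index vectors); zero rows when nothing qualifies.
#' @export
significant_intervals <- function(lda_ci, dummy_ci, times,
                                  min_duration = 0.200) {
  if (length(lda_ci$lo) != length(dummy_ci$hi) ||
      length(lda_ci$lo) != length(times)) {
    stop("time axes are not aligned")
  }
  ok <- lda_ci$lo > dummy_ci$hi
  step <- stats::median(diff(times))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * step >= min_duration - 1e-9)
  out <- cbind(start = times[starts[keep]], end = times[ends[keep]])
  attr(out, "indices") <- lapply(which(keep), function(i)
    seq(starts[i], ends[i]))
  out
}

#' Univariate bootstrap-CI spatiotemporal mask
#'
#' Marks the (channel, time) points where at least one condition's bootstrap
#' CI of the subject-mean evoked response is disjoint from the CIs of every
#' other condition -- the sensor regions where one workload state's evoked
#' response separates from the rest.
#'
#' @param evoked_by_condition Named list (>= 3 conditions) of subjects x
#'   channels x time arrays.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Boolean channels x time matrix.
#' @export
univariate_ci_mask <- function(evoked_by_condition, n_boot = 5000,
                               level = 0.95, seed = 4) {
  k <- length(evoked_by_condition)
  if (k < 3) stop("need at least 3 conditions")
  dm <- dim(evoked_by_condition[[1]])
  if (dm[1] < 2) stop("need at least 2 subjects")
  alpha <- (1 - level) / 2
  cis <- lapply(seq_len(k), function(ci_i) {
    ev <- evoked_by_condition[[ci_i]]
    n <- dim(ev)[1]
    flat <- matrix(ev, nrow = n)                      # n x (ch*time)
    with_seed(derive_seed(seed, ci_i), {
      idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
      bm <- matrix(0, n_boot, ncol(flat))
      for (s in seq_len(n)) bm <- bm + flat[idx[, s], ]
      bm <- bm / n
      lo <- apply(bm, 2, stats::quantile, probs = alpha, names = FALSE)
      hi <- apply(bm, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
      list(lo = matrix(lo, dm[2], dm[3]), hi = matrix(hi, dm[2], dm[3]))
    })
  })
  mask <- matrix(FALSE, dm[2], dm[3])
  for (a in seq_len(k)) {
    sep <- matrix(TRUE, dm[2], dm[3])
    for (b in seq_len(k)) {
      if (b == a) next
      disjoint <- cis[[a]]$lo > cis[[b]]$hi | cis[[a]]$hi < cis[[b]]$lo
      sep <- sep & disjoint
    }
    mask <- mask | sep
  }
  mask
}

#' Peak-performance summary of a decoding result
#'
#' Locates the time of maximal bootstrap-mean decoding score within the
#' significant intervals and extracts the activation-pattern slice and the
#' per-condition bootstrap CIs of the evoked response in the masked sensor
#' region at that time.
#'
#' @param boot A `boot_ci` for the decoder scores.
#' @param intervals Output of [significant_intervals()].
#' @param times Time axis (s).
#' @param patterns Optional classes x channels x time pattern array.
#' @param evoked_by_condition Optional named list of subjects x channels x
#'   time arrays for the region CIs.
#' @param mask Optional boolean channels x time mask selecting the region.
#' @param n_boot,seed Bootstrap settings for the region CIs.
#' @return List with `peak_time`, `peak_score`, `peak_patterns`,
#'   `region_channels`, `region_ci` (per condition mean/lo/hi), or
#'   `peak_time = NA` when no interval is significant.
#' @export
peak_summary <- function(boot, intervals, times, patterns = NULL,
                         evoked_by_condition = NULL, mask = NULL,
                         n_boot = 2000, seed = 5) {
  idx <- unlist(attr(intervals, "indices"))
  if (!length(idx)) {
    return(list(peak_time = NA_real_, peak_score = NA_real_,
                peak_patterns = NULL, region_channels = integer(0),
                region_ci = NULL))
  }
  pk <- idx[which.max(boot$mean[idx])]
  out <- list(peak_time = times[pk], peak_score = boot$mean[pk])
  out$peak_patterns <- if (!is.null(patterns)) patterns[, , pk, drop = TRUE]
  region <- if (!is.null(mask)) which(mask[, pk]) else integer(0)
  out$region_channels <- region
  if (!is.null(evoked_by_condition) && length(region)) {
    out$region_ci <- lapply(evoked_by_condition, function(ev) {
      v <- apply(ev[, region, pk, drop = FALSE], 1, mean)
      ci <- bootstrap_ci(v, n_boot = n_boot, seed = seed)
      c(mean = ci$mean, lo = ci$lo, hi = ci$hi)
    })
  }
  out
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s (%s), %d folds x %d time points\n",
              paste(x$contrast, collapse = " vs "), x$metric,
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
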