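# Time-resolved decoding: resampling, shrinkage LDA, metrics,
# cross-validation bookkeeping, bootstrap inference, Haufe patterns.

test_that("downsampling to 100 Hz keeps counts, DC and tones", {
  tt <- (0:299) / 250 - 0.2
  sine <- sin(2 * pi * 5 * (tt + 0.2))
  ep <- new_eeg_epochs(array(rep(sine, each = 2), c(2, 1, 300)), tt, 250,
                       "c1")
  ds <- downsample_epochs(ep, 100)
  expect_equal(dim(ds$data)[3], 120)            # 1.2 s x 100 Hz
  expect_equal(ds$fs, 100)
  expect_equal(ds$times[1], -0.2)
  # amplitude of a 5 Hz tone preserved within 2% (RMS, interior)
  ref <- sin(2 * pi * 5 * (ds$times + 0.2))
  r_in <- 10:110
  expect_equal(sqrt(mean(ds$data[1, 1, r_in]^2)),
               sqrt(mean(ref[r_in]^2)), tolerance = 0.02)
  # DC unchanged
  dc <- new_eeg_epochs(array(2.5, c(1, 1, 300)), tt, 250, "c1")
  expect_equal(as.vector(downsample_epochs(dc, 100)$data),
               rep(2.5, 120), tolerance = 0.01)
  expect_error(downsample_epochs(ds, 250), "exceed")
})

test_that("Ledoit-Wolf covariance matches the direct formula", {
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  lw <- ledoit_wolf_cov(X)
  # independently coded double-loop oracle
  Xc <- sweep(X, 2, colMeans(X)); n <- 20; p <- 5
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  b2b <- 0
  for (i in seq_len(n)) b2b <- b2b + sum((tcrossprod(Xc[i, ]) - S)^2)
  rho <- min(b2b / (n^2 * p), d2) / d2
  expect_equal(lw$shrinkage, rho, tolerance = 1e-10)
  expect_equal(lw$cov, (1 - rho) * S + diag(rho * mu, p),
               tolerance = 1e-10)
  expect_true(all(eigen(lw$cov, only.values = TRUE)$values > 0))
  # spherical input: target equals S, shrinkage is a no-op on the estimate
  sph <- diag(3)[rep(1:3, 10), ] * 2
  lws <- ledoit_wolf_cov(sph)
  Ssph <- crossprod(sweep(sph, 2, colMeans(sph))) / 30
  expect_equal(lws$cov, (1 - lws$shrinkage) * Ssph +
                 diag(lws$shrinkage * mean(diag(Ssph)), 3),
               tolerance = 1e-9)
  # consistency: n >> p leaves a well-conditioned S nearly untouched
  set.seed(4)
  big <- matrix(rnorm(1e4 * 5), 1e4, 5) %*% diag(sqrt(1:5))
  lwb <- ledoit_wolf_cov(big)
  Sb <- crossprod(sweep(big, 2, colMeans(big))) / 1e4
  expect_lt(norm(lwb$cov - Sb, "F") / norm(Sb, "F"), 0.05)
  expect_error(ledoit_wolf_cov(matrix(c(1, NA), 1)), "finite|2 samples")
})

test_that("shrinkage LDA recovers the closed-form discriminant", {
  set.seed(5)
  Sig <- matrix(c(2, 0.8, 0.8, 1), 2)
  R <- chol(Sig)
  n <- 1e4
  X <- rbind(matrix(rnorm(n * 2), n, 2) %*% R,
             sweep(matrix(rnorm(n * 2), n, 2) %*% R, 2, c(1.5, 0.5), "+"))
  y <- rep(0:1, each = n)
  fit <- lda_fit(X, y)
  w_true <- solve(Sig, c(1.5, 0.5))
  cosine <- sum(fit$w * w_true) / sqrt(sum(fit$w^2) * sum(w_true^2))
  expect_gte(cosine, 0.999)
  # whitened data: w parallel to the mean difference
  Xw <- rbind(matrix(rnorm(2000), 1000, 2),
              sweep(matrix(rnorm(2000), 1000, 2), 2, c(2, 0), "+"))
  fw <- lda_fit(Xw, rep(0:1, each = 1000))
  expect_gt(abs(fw$w[1]) / (abs(fw$w[2]) + 1e-12), 10)
  # equal class means: w ~ 0 relative to scale
  Xe <- matrix(rnorm(4000), 2000, 2)
  fe <- lda_fit(Xe, rep(0:1, 1000))
  expect_lt(sqrt(sum(fe$w^2)), 0.2)
  expect_error(lda_fit(Xe, rep(0, 2000)), "classes")
})

test_that("AUC equals the Mann-Whitney pair count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  # label swap: 1 - AUC
  sc <- rnorm(40); lb <- rep(0:1, 20)
  expect_equal(roc_auc(sc, lb), 1 - roc_auc(sc, 1 - lb))
  # ties counted half
  expect_equal(roc_auc(c(1, 1), c(0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "two classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:5) {
    sc <- rnorm(60)
    lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("weighted F1 matches hand-computed confusion arithmetic", {
  expect_equal(weighted_f1(c("a", "b"), c("a", "b")), 1.0)
  # confusion [[2,1,0],[0,2,1],[0,0,3]] by true class rows
  pred <- c("a", "a", "b", "b", "b", "c", "c", "c", "c")
  lab <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  f1a <- 2 * 2 / (2 * 2 + 0 + 1)
  f1b <- 2 * 2 / (2 * 2 + 1 + 1)
  f1c <- 2 * 3 / (2 * 3 + 1 + 0)
  expect_equal(weighted_f1(pred, lab), mean(c(f1a, f1b, f1c)))
  # constant predictor on balanced 3-class labels scores below 1/2
  expect_lt(weighted_f1(rep("a", 9), lab), 0.5)
  expect_error(weighted_f1("a", c("a", "b")), "equal length")
})

test_that("stratified folds preserve class ratios and the 100-fold scheme", {
  y <- rep(c("u", "f"), each = 30)
  folds <- stratified_folds(y, n_splits = 5, n_repeats = 20, seed = 2)
  expect_length(folds, 100)
  for (f in folds[seq(1, 100, by = 7)]) {
    expect_length(f$test, 12)
    expect_equal(sum(y[f$test] == "u"), 6)      # exact stratification
    expect_length(intersect(f$train, f$test), 0)
  }
  # every repeat partitions all trials
  first_rep <- folds[1:5]
  expect_setequal(unlist(lapply(first_rep, `[[`, "test")), seq_along(y))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 50)), 5, 1), "n_splits")
})

test_that("sliding decoding finds effects only where they exist", {
  # two classes separated only inside 0.3-0.6 s
  set.seed(8)
  n <- 40; nt <- 60; p <- 6
  times <- seq(0, 1.18, by = 0.02)[1:nt]
  eff <- as.numeric(times > 0.3 & times < 0.6)
  mk <- function(shift) {
    arr <- array(rnorm(n * p * nt), c(n, p, nt))
    for (ti in which(eff == 1)) arr[, 1:2, ti] <- arr[, 1:2, ti] + shift
    new_eeg_epochs(arr, times, 50, paste0("ch", 1:p))
  }
  eps <- list(a = mk(0), b = mk(1.2))
  res <- sliding_decode(eps, c("a", "b"), n_splits = 5, n_repeats = 4,
                        seed = 1)
  expect_equal(dim(res$scores), c(20, nt))
  in_auc <- mean(res$scores[, eff == 1])
  out_auc <- mean(res$scores[, eff == 0])
  expect_gt(in_auc, 0.75)
  expect_lt(abs(out_auc - 0.5), 0.06)
  # patterns at effect times point to the loaded channels
  pat <- apply(abs(res$patterns[1, , eff == 1]), 1, mean)
  expect_gt(min(pat[1:2]), max(pat[3:p]))
})

test_that("shuffled labels decode at chance", {
  set.seed(9)
  n <- 40; nt <- 12; p <- 6
  aucs <- replicate(10, {
    arr <- array(rnorm(2 * n * p * nt), c(2 * n, p, nt))
    arr[(n + 1):(2 * n), 1:2, ] <- arr[(n + 1):(2 * n), 1:2, ] + 1
    y <- sample(rep(c("a", "b"), each = n))     # labels shuffled
    eps <- list(a = new_eeg_epochs(arr[y == "a", , ], (1:nt) / 50, 50,
                                   paste0("ch", 1:p)),
                b = new_eeg_epochs(arr[y == "b", , ], (1:nt) / 50, 50,
                                   paste0("ch", 1:p)))
    mean(sliding_decode(eps, c("a", "b"), n_repeats = 2, seed = 1,
                        patterns = FALSE)$scores)
  })
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("stratified dummy scores sit at their theoretical chance levels", {
  y2 <- rep(c("a", "b"), each = 40)
  d2 <- dummy_scores(y2, n_times = 3, n_splits = 5, n_repeats = 40,
                     seed = 3)
  expect_equal(dim(d2), c(200, 3))
  expect_equal(d2[, 1], d2[, 2])                # time axis replicated
  expect_equal(mean(d2), 0.5, tolerance = 0.02)
  y3 <- rep(c("a", "b", "c"), each = 30)
  d3 <- dummy_scores(y3, n_times = 1, n_splits = 5, n_repeats = 40,
                     seed = 4)
  expect_equal(mean(d3), 1 / 3, tolerance = 0.03)
  expect_identical(dummy_scores(y2, 2, seed = 5),
                   dummy_scores(y2, 2, seed = 5))
})

test_that("bootstrap CIs behave like the analytic standard error", {
  # constant scores: degenerate interval
  cst <- bootstrap_ci(rep(0.7, 30), n_boot = 200, seed = 1)
  expect_equal(c(cst$mean, cst$lo, cst$hi), rep(0.7, 3))
  # gaussian scores: half-width within 15% of 1.96 sd/sqrt(n)
  set.seed(10)
  x <- rnorm(100, 0.6, 0.1)
  ci <- bootstrap_ci(x, n_boot = 5000, seed = 2)
  half <- (ci$hi - ci$lo) / 2
  expect_equal(half, 1.96 * sd(x) / 10, tolerance = 0.15)
  expect_lte(ci$lo, ci$mean)
  expect_gte(ci$hi, ci$mean)
  # matrix input: per-time ordering always holds
  m <- matrix(rnorm(50 * 7), 50, 7)
  cim <- bootstrap_ci(m, n_boot = 500, seed = 3)
  expect_true(all(cim$lo <= cim$mean & cim$mean <= cim$hi))
  expect_error(bootstrap_ci(0.5), "at least 2")
})

test_that("the 200 ms duration criterion counts points inclusively", {
  nt <- 60
  times <- (seq_len(nt) - 1) / 100
  mk_ci <- function(lo) structure(list(mean = lo + 0.02, lo = lo,
                                       hi = lo + 0.04), class = "boot_ci")
  dummy <- structure(list(mean = rep(0.5, nt), lo = rep(0.48, nt),
                          hi = rep(0.52, nt)), class = "boot_ci")
  # 19 qualifying points: below 200 ms at 100 Hz -> nothing
  lo19 <- rep(0.4, nt); lo19[10:28] <- 0.6
  expect_equal(nrow(significant_intervals(mk_ci(lo19), dummy, times)), 0)
  # 20 points: exactly 200 ms -> one interval
  lo20 <- rep(0.4, nt); lo20[10:29] <- 0.6
  iv <- significant_intervals(mk_ci(lo20), dummy, times)
  expect_equal(nrow(iv), 1)
  expect_equal(unname(iv[1, ]), c(times[10], times[29]))
  # two runs separated by one failing point stay separate
  lo2 <- rep(0.4, nt); lo2[5:29] <- 0.6; lo2[31:55] <- 0.6
  iv2 <- significant_intervals(mk_ci(lo2), dummy, times)
  expect_equal(nrow(iv2), 2)
  # nothing qualifies
  expect_equal(nrow(significant_intervals(mk_ci(rep(0.4, nt)), dummy,
                                          times)), 0)
  expect_error(significant_intervals(mk_ci(lo20), dummy, times[-1]),
               "aligned")
})

test_that("Haufe patterns invert the backward model", {
  set.seed(12)
  # whitened features: pattern proportional to the weights
  Xw <- matrix(rnorm(5000 * 4), 5000, 4)
  w <- c(1, -2, 0.5, 0)
  Aw <- haufe_patterns(w, Xw)
  expect_equal(as.vector(Aw) / sqrt(sum(Aw^2)), w / sqrt(sum(w^2)),
               tolerance = 0.05)
  # forward model x = a s + noise: pattern recovers a
  a <- c(2, -1, 0.5, 0, 1)
  s <- rnorm(2000)
  X <- outer(s, a) + matrix(rnorm(2000 * 5), 2000, 5)
  fit <- lda_fit(X, s > 0)
  A <- haufe_patterns(fit$w, X)
  expect_gte(abs(cor(as.vector(A), a)), 0.95)
  # equals the regression form Cov(x, s_hat)/Var(s_hat), and scales
  # linearly with the data
  sh <- sweep(X, 2, colMeans(X)) %*% fit$w
  reg <- as.vector(cov(X, sh) / as.vector(var(sh)))
  expect_equal(as.vector(A), reg, tolerance = 1e-10)
  # scaling the data while holding the scores fixed scales A by c
  A3 <- haufe_patterns(fit$w, 3 * X, scores = sh)
  expect_equal(as.vector(A3), 3 * as.vector(A), tolerance = 1e-10)
  # scaling both (scores recomputed) leaves A invariant: c^2 / c^2
  expect_equal(as.vector(haufe_patterns(fit$w, 3 * X)), as.vector(A),
               tolerance = 1e-10)
  expect_error(haufe_patterns(c(0, 0, 0, 0, 0), X), "singular")
})

test_that("the univariate CI mask isolates separated condition cells", {
  set.seed(13)
  n_sub <- 10; p <- 4; nt <- 8
  mk <- function(off = NULL) {
    arr <- array(rnorm(n_sub * p * nt), c(n_sub, p, nt))
    if (!is.null(off)) arr[, off[1], off[2]] <- arr[, off[1], off[2]] + 10
    arr
  }
  # one condition offset by 10 SD at a single (channel, time)
  evs <- list(a = mk(), b = mk(), c = mk(c(2, 5)))
  mask <- univariate_ci_mask(evs, n_boot = 800, seed = 1)
  expect_true(mask[2, 5])
  expect_lte(mean(mask[-2, -5]), 0.08)
  # identical distributions: mask mostly empty over seeds
  rates <- vapply(1:5, function(sd) {
    m0 <- univariate_ci_mask(list(a = mk(), b = mk(), c = mk()),
                             n_boot = 400, seed = sd)
    mean(m0)
  }, 1.0)
  expect_lte(mean(rates), 0.07)
  # common rescaling leaves the mask unchanged
  sc <- lapply(evs, function(e) e * 3.7)
  expect_identical(univariate_ci_mask(sc, n_boot = 800, seed = 1), mask)
  expect_error(univariate_ci_mask(evs[1:2]), "3 conditions")
})

test_that("peak summaries locate the maximum inside significant windows", {
  nt <- 50
  times <- (seq_len(nt) - 1) / 100
  mean_curve <- 0.5 + 0.3 * exp(-(times - 0.25)^2 / (2 * 0.05^2))
  boot <- structure(list(mean = mean_curve, lo = mean_curve - 0.02,
                         hi = mean_curve + 0.02), class = "boot_ci")
  dummy <- structure(list(mean = rep(0.5, nt), lo = rep(0.49, nt),
                          hi = rep(0.51, nt)), class = "boot_ci")
  iv <- significant_intervals(boot, dummy, times)
  pats <- array(rnorm(2 * 3 * nt), c(2, 3, nt))
  pk <- peak_summary(boot, iv, times, patterns = pats)
  expect_equal(pk$peak_time, 0.25, tolerance = 0.011)
  expect_equal(pk$peak_score, max(boot$mean[unlist(attr(iv, "indices"))]))
  expect_equal(pk$peak_patterns,
               pats[, , which.min(abs(times - pk$peak_time))])
  # no significant interval: peak undefined but reported
  none <- significant_intervals(dummy, boot, times)
  pk0 <- peak_summary(dummy, none, times)
  expect_true(is.na(pk0$peak_time))
})
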