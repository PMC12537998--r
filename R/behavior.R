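# Behavioral and subjective statistics: relative game score, oddball count
# error, two-factor within-subject ANOVA with Greenhouse-Geisser correction
# and partial eta squared, and Tukey HSD post hocs on the within-subject
# error term.

#' Relative game score
#'
#' Performance in the primary task as the fraction of points won:
#' `p_won / (p_won + p_lost)`, bounded in \[0, 1\]. With no points at all the
#' score is defined as 0.5 (chance) with a warning.
#'
#' @param points_won,points_lost Non-negative counts.
#' @return Fraction in \[0, 1\].
#' @export
relative_game_score <- function(points_won, points_lost) {
  if (any(points_won < 0) || any(points_lost < 0)) {
    stop("point counts must be non-negative")
  }
  tot <- points_won + points_lost
  out <- ifelse(tot > 0, points_won / tot, 0.5)
  if (any(tot == 0)) warning("zero total points: score defined as 0.5")
  out
}

#' Relative oddball counting error
#'
#' Secondary-task performance: the signed relative difference between the
#' reported and the true number of oddballs, `(counted - true) / true`.
#'
#' @param counted Reported count.
#' @param true True count (> 0).
#' @return Signed fraction (0 = perfect, negative = undercount).
#' @export
oddball_count_error <- function(counted, true) {
  if (any(true <= 0)) stop("true count must be positive")
  (counted - true) / true
}

#' Greenhouse-Geisser sphericity epsilon
#'
#' Computed from the double-centered covariance of the effect's repeated
#' measures: with eigenvalues `lambda` of `C S C` (`C = I - J/k`),
#' `epsilon = (sum lambda)^2 / ((k-1) sum lambda^2)`. Bounded in
#' `[1/(k-1), 1]`; equals 1 under compound symmetry and is forced to 1 for
#' `k = 2`.
#'
#' @param S k x k covariance matrix of the repeated measures.
#' @return Scalar epsilon.
#' @export
greenhouse_geisser_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) stop("S must be k x k with k >= 2")
  if (k == 2) return(1)
  C <- diag(k) - 1 / k
  V <- C %*% S %*% C
  tr <- sum(diag(V))
  tr2 <- sum(V * t(V))
  if (tr2 < 1e-300) stop("degenerate covariance")
  max(1 / (k - 1), min(1, tr^2 / ((k - 1) * tr2)))
}

# Orthonormal polynomial-free contrast basis spanning the centered space of
# a k-level factor (k x (k-1), columns orthonormal, orthogonal to 1).
.centering_contrasts <- function(k) {
  C <- matrix(0, k, k - 1)
  for (j in seq_len(k - 1)) {
    C[seq_len(j), j] <- 1
    C[j + 1, j] <- -j
    C[, j] <- C[, j] / sqrt(j * (j + 1))
  }
  C
}

#' Two-factor within-subject ANOVA with Greenhouse-Geisser correction
#'
#' Full within-subject sums-of-squares decomposition for a subjects x A x B
#' complete balanced design (e.g. difficulty x ergonomic position); each
#' effect is tested against its own subject-interaction error term. For each
#' effect the Greenhouse-Geisser epsilon is estimated from the covariance of
#' the effect's orthonormal contrast scores, the corrected p-value uses
#' `F` at `(eps df1, eps df2)`, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table Long `data.frame` with columns `subject`, `difficulty`,
#'   `position`, `measure`, `value` (as produced by [simulate_behavior()]),
#'   or already-filtered rows of one measure.
#' @param measure Which measure to analyze (ignored when `table` has no
#'   `measure` column).
#' @return `data.frame` with one row per effect (`difficulty`, `position`,
#'   `difficulty:position`) and columns `F`, `df1`, `df2`, `epsilon`,
#'   `p_gg`, `p_uncorrected`, `pes`.
#' @export
rm_anova_2x3 <- function(table, measure = NULL) {
  if ("measure" %in% names(table) && !is.null(measure)) {
    table <- table[table$measure == measure, ]
  }
  need <- c("subject", "difficulty", "position", "value")
  if (!all(need %in% names(table))) {
    stop("table must have subject, difficulty, position, value columns")
  }
  table$subject <- factor(table$subject)
  table$difficulty <- factor(table$difficulty)
  table$position <- factor(table$position)
  n <- nlevels(table$subject)
  a <- nlevels(table$difficulty)
  b <- nlevels(table$position)
  if (nrow(table) != n * a * b) stop("design must be complete and balanced")
  # cell array y[s, a, b]
  y <- array(NA_real_, c(n, a, b))
  y[cbind(as.integer(table$subject), as.integer(table$difficulty),
          as.integer(table$position))] <- table$value
  if (anyNA(y)) stop("design must be complete and balanced")
  maps <- pointwise_rm_anova2(array(y, c(n, a, b, 1, 1)))
  # epsilon per effect from the subject x cell matrix and contrast bases
  cells <- matrix(y, n, a * b)                    # cells vary a fastest
  Ca <- .centering_contrasts(a)
  Cb <- .centering_contrasts(b)
  one_a <- matrix(1 / sqrt(a), a, 1)
  one_b <- matrix(1 / sqrt(b), b, 1)
  eff_eps <- function(Cmat) {
    Z <- cells %*% Cmat                  # orthonormal contrast scores
    df <- ncol(Z)
    if (df == 1) return(1)
    V <- stats::cov(Z)
    tr <- sum(diag(V))
    tr2 <- sum(V^2)
    max(1 / df, min(1, tr^2 / (df * tr2)))
  }
  kron <- function(Bm, Am) kronecker(Bm, Am)      # cells ordered a fastest
  eps <- c(difficulty = eff_eps(kron(one_b, Ca)),
           position = eff_eps(kron(Cb, one_a)),
           `difficulty:position` = eff_eps(kron(Cb, Ca)))
  effs <- list(difficulty = maps$A, position = maps$B,
               `difficulty:position` = maps$AB)
  out <- do.call(rbind, lapply(names(effs), function(nm) {
    sm <- effs[[nm]]
    f <- sm$values[1, 1]
    df1 <- sm$df[1]; df2 <- sm$df[2]
    e <- eps[[nm]]
    data.frame(effect = nm, F = f, df1 = df1, df2 = df2, epsilon = e,
               p_gg = stats::pf(f, e * df1, e * df2, lower.tail = FALSE),
               p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
               pes = f * df1 / (f * df1 + df2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p-values for all pairwise differences of
#' `k` cell means sharing an error mean square. On within-subject factors,
#' pass the effect's own error term (`MS_error` with
#' `df = (k-1)(n-1)`).
#'
#' @param means Named vector of cell means.
#' @param ms_error Error mean square.
#' @param df_error Error degrees of freedom.
#' @param n Observations per cell mean.
#' @param alpha Family-wise significance level for flagging (default 0.05).
#' @return `data.frame` with one row per pair: `diff`, `q`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(means, ms_error, df_error, n, alpha = 0.05) {
  if (ms_error <= 0) stop("ms_error must be positive")
  k <- length(means)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  se <- sqrt(ms_error / n)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    i1 <- pairs[1, i]; i2 <- pairs[2, i]
    d <- means[i2] - means[i1]
    q <- abs(d) / se
    p <- stats::ptukey(q, k, df_error, lower.tail = FALSE)
    data.frame(pair = paste(names(means)[i2], "-", names(means)[i1]),
               diff = unname(d), q = unname(q), p_adj = unname(p),
               significant = unname(p < alpha), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Behavioral statistics report for one measure
#'
#' Runs the two-factor within-subject ANOVA with Greenhouse-Geisser
#' correction and, when the difficulty effect is significant, Tukey HSD post
#' hocs on the difficulty cell means using the difficulty x subject error
#' term.
#'
#' @param table Long behavioral table (see [rm_anova_2x3()]).
#' @param measure Measure name.
#' @param alpha Significance level.
#' @return List with `anova` (effect table) and `posthoc` (Tukey table or
#'   `NULL`).
#' @export
behavior_stats <- function(table, measure, alpha = 0.05) {
  sub <- table[table$measure == measure, ]
  an <- rm_anova_2x3(sub)
  post <- NULL
  dif <- an[an$effect == "difficulty", ]
  if (is.finite(dif$p_gg) && dif$p_gg < alpha) {
    sub$subject <- factor(sub$subject)
    n <- nlevels(sub$subject)
    b <- length(unique(sub$position))
    cellm <- tapply(sub$value, sub$difficulty, mean)
    # reconstruct MS_error(difficulty x subject) from the F statistic:
    # F = MS_A / MS_AS; MS_A = n*b*var-like term. Compute directly instead.
    sm <- tapply(sub$value, list(sub$subject, sub$difficulty), mean)
    a <- ncol(sm)
    g <- mean(sm)
    ss_a <- n * sum((colMeans(sm) - g)^2)
    ss_s <- a * sum((rowMeans(sm) - g)^2)
    ss_as <- sum((sm - outer(rowMeans(sm), colMeans(sm), "+") + g)^2)
    # ms_as is on the scale of subject x difficulty means (averaged over
    # the b positions), so each difficulty mean averages n such values
    ms_as <- ss_as / ((a - 1) * (n - 1))
    post <- tukey_hsd(cellm, ms_error = ms_as, df_error = (a - 1) * (n - 1),
                      n = n, alpha = alpha)
  }
  list(anova = an, posthoc = post)
}

#' Write a behavioral statistics report as JSON
#'
#' @param stats_list Named list of [behavior_stats()] outputs per measure.
#' @param path Output file.
#' @export
write_behavior_json <- function(stats_list, path) {
  jsonlite::write_json(stats_list, path, digits = NA, auto_unbox = TRUE,
                       null = "null", dataframe = "rows")
  invisible(path)
}
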