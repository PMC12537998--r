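# Mass-univariate spatiotemporal cluster permutation statistics in the
# Maris & Oostenveld style: pointwise repeated-measures F or paired-t maps,
# adjacency-based cluster formation, and a max-cluster-mass permutation null
# built from within-subject relabeling (F) or sign flips (t).

#' Pointwise one-way repeated-measures F map
#'
#' For every (channel, time) point, the one-way within-subject F statistic
#' for the condition factor, with the subject effect partialled out:
#' `F = MS_condition / MS_(condition x subject)`, df `(k-1, (k-1)(n-1))`.
#'
#' @param data Numeric subjects x conditions x channels x time array
#'   (balanced design).
#' @return A `stat_map`: list with `values` (channels x time), `kind = "F"`,
#'   `df`.
#' @export
pointwise_rm_anova <- function(data) {
  dm <- dim(data)
  if (length(dm) != 4) stop("data must be subjects x conditions x ch x time")
  n <- dm[1]; k <- dm[2]
  if (k < 2 || n < 3) stop("need >= 2 conditions and >= 3 subjects")
  P <- dm[3] * dm[4]
  y <- array(data, dim = c(n, k, P))
  m_c <- colMeans(y)                                   # k x P
  m_s <- colMeans(aperm(y, c(2, 1, 3)))                # n x P
  g <- colMeans(m_c)                                   # P
  ss_a <- n * colSums(sweep(m_c, 2, g)^2)
  ss_s <- k * colSums(sweep(m_s, 2, g)^2)
  ss_tot <- colSums(matrix(y, n * k, P)^2) - n * k * g^2
  ss_as <- pmax(ss_tot - ss_a - ss_s, 0)
  ms_a <- ss_a / (k - 1)
  ms_as <- ss_as / ((k - 1) * (n - 1))
  f <- ifelse(ss_a <= 1e-300, 0, ms_a / pmax(ms_as, 1e-300))
  structure(list(values = matrix(f, dm[3], dm[4]), kind = "F",
                 df = c(k - 1, (k - 1) * (n - 1))),
            class = "stat_map")
}

#' Pointwise two-way repeated-measures F maps
#'
#' Full within-subject two-factor decomposition per (channel, time) point;
#' each effect is tested against its own subject-interaction error term.
#'
#' @param data Numeric subjects x A-levels x B-levels x channels x time
#'   array.
#' @return List of three `stat_map`s: `A`, `B`, `AB`.
#' @export
pointwise_rm_anova2 <- function(data) {
  dm <- dim(data)
  if (length(dm) != 5) stop("data must be subjects x A x B x ch x time")
  n <- dm[1]; a <- dm[2]; b <- dm[3]
  P <- dm[4] * dm[5]
  y <- array(data, dim = c(n, a, b, P))
  m_ab <- apply(y, c(2, 3, 4), mean)                   # a x b x P
  m_a <- apply(m_ab, c(1, 3), mean)                    # a x P
  m_b <- apply(m_ab, c(2, 3), mean)                    # b x P
  m_sa <- apply(y, c(1, 2, 4), mean)                   # n x a x P
  m_sb <- apply(y, c(1, 3, 4), mean)                   # n x b x P
  m_s <- apply(y, c(1, 4), mean)                       # n x P
  g <- colMeans(m_a)                                   # P
  ss_a <- n * b * colSums(sweep(m_a, 2, g)^2)
  ss_b <- n * a * colSums(sweep(m_b, 2, g)^2)
  dev_ab <- sweep(m_ab, c(1, 3), m_a) - rep(sweep(m_b, 2, g),
                                            each = a)
  ss_ab <- n * apply(dev_ab^2, 3, sum)
  dev_sa <- sweep(sweep(m_sa, c(2, 3), m_a), c(1, 3), sweep(m_s, 2, g))
  ss_as <- b * apply(dev_sa^2, 3, sum)
  dev_sb <- sweep(sweep(m_sb, c(2, 3), m_b), c(1, 3), sweep(m_s, 2, g))
  ss_bs <- a * apply(dev_sb^2, 3, sum)
  fmap <- function(ss_eff, df1, ss_err, df_err) {
    f <- ifelse(ss_eff <= 1e-300, 0,
                (ss_eff / df1) / pmax(ss_err / df_err, 1e-300))
    structure(list(values = matrix(f, dm[4], dm[5]), kind = "F",
                   df = c(df1, df_err)), class = "stat_map")
  }
  list(A = fmap(ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
       B = fmap(ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
       AB = {
         dfab <- (a - 1) * (b - 1)
         # ABS residual: y - m_ab - m_sa - m_sb + m_a + m_b + m_s - g
         res <- array(0, c(n, a, b, P))
         gm <- matrix(g, n, P, byrow = TRUE)
         for (ai in seq_len(a)) {
           mam <- matrix(m_a[ai, ], n, P, byrow = TRUE)
           for (bi in seq_len(b)) {
             res[, ai, bi, ] <- y[, ai, bi, ] -
               matrix(m_ab[ai, bi, ], n, P, byrow = TRUE) -
               m_sa[, ai, ] - m_sb[, bi, ] + mam +
               matrix(m_b[bi, ], n, P, byrow = TRUE) + m_s - gm
           }
         }
         ss_abs <- apply(res^2, 4, sum)
         fmap(ss_ab, dfab, pmax(ss_abs, 0), dfab * (n - 1))
       })
}

#' Pointwise paired-t map
#'
#' Paired t on the subject-wise condition differences per (channel, time)
#' point. Zero-variance points with a nonzero mean difference are clamped to
#' a large finite statistic with a warning.
#'
#' @param data Numeric subjects x 2 x channels x time array.
#' @return A `stat_map` with `kind = "t"`, df `n - 1`.
#' @export
pointwise_paired_t <- function(data) {
  dm <- dim(data)
  if (length(dm) != 4 || dm[2] != 2) {
    stop("data must be subjects x 2 x channels x time")
  }
  n <- dm[1]
  if (n < 3) stop("need >= 3 subjects")
  d <- data[, 1, , , drop = TRUE] - data[, 2, , , drop = TRUE]
  d <- array(d, dim = c(n, dm[3], dm[4]))
  m <- apply(d, c(2, 3), mean)
  s <- apply(d, c(2, 3), stats::sd)
  t <- m / (s / sqrt(n))
  zero <- s < 1e-300
  if (any(zero & m != 0)) {
    warning("zero-variance differences: t clamped to +/- 1e12")
    t[zero] <- sign(m[zero]) * 1e12
  }
  t[zero & m == 0] <- 0
  structure(list(values = t, kind = "t", df = n - 1), class = "stat_map")
}

#' Form spatiotemporal clusters from a statistic map
#'
#' Supra-threshold points are joined when adjacent in time on the same
#' channel, or simultaneous on spatially adjacent channels. For the
#' two-sided case, positive and negative exceedances form separate clusters
#' and masses keep their sign.
#'
#' @param map A `stat_map` (or bare channels x time matrix).
#' @param threshold Positive cluster-forming threshold on the statistic
#'   (applied to `|value|` for two-sided maps).
#' @param adjacency An `adjacency_graph` over the map's channels.
#' @param tail `"one"` (exceedances above `threshold`) or `"two"`.
#' @return List with `clusters` (list of two-column member matrices,
#'   channel/time indices) and `masses` (summed statistic per cluster).
#' @export
form_clusters <- function(map, threshold, adjacency, tail = c("one", "two")) {
  tail <- match.arg(tail)
  vals <- if (inherits(map, "stat_map")) map$values else as.matrix(map)
  if (threshold <= 0) stop("threshold must be positive")
  out <- list(clusters = list(), masses = numeric(0))
  polarities <- if (tail == "two") c(1, -1) else 1
  for (pol in polarities) {
    supra <- (pol * vals) > threshold
    cl <- .connected_components(supra, adjacency$matrix)
    for (members in cl) {
      out$clusters[[length(out$clusters) + 1]] <- members
      out$masses <- c(out$masses, sum(vals[members]))
    }
  }
  out
}

# Connected components of TRUE cells in a channels x time logical matrix
# under (c,t)~(c,t+/-1) and (c,t)~(c',t) for adjacent channels.
.connected_components <- function(supra, adj) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  nch <- nrow(supra); nt <- ncol(supra)
  id <- matrix(NA_integer_, nch, nt)
  id[idx] <- seq_along(idx)
  edges <- NULL
  if (nt > 1) {
    both <- supra[, -nt, drop = FALSE] & supra[, -1, drop = FALSE]
    w <- which(both, arr.ind = TRUE)
    if (nrow(w)) {
      edges <- cbind(id[cbind(w[, 1], w[, 2])], id[cbind(w[, 1], w[, 2] + 1)])
    }
  }
  pr <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(pr)) {
    both <- supra[pr[, 1], , drop = FALSE] & supra[pr[, 2], , drop = FALSE]
    w <- which(both, arr.ind = TRUE)
    if (nrow(w)) {
      edges <- rbind(edges,
                     cbind(id[cbind(pr[w[, 1], 1], w[, 2])],
                           id[cbind(pr[w[, 1], 2], w[, 2])]))
    }
  }
  comp <- .union_find(length(idx), edges)
  lapply(seq_len(max(comp)), function(ci) {
    members <- idx[comp == ci]
    cbind(channel = ((members - 1) %% nch) + 1,
          time = ((members - 1) %/% nch) + 1)
  })
}

# Union-find connected components; returns membership labels 1..ncomp.
.union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

.max_cluster_mass <- function(map_vals, threshold, adjacency, tail) {
  fc <- form_clusters(map_vals, threshold, adjacency, tail)
  if (!length(fc$masses)) 0 else max(abs(fc$masses))
}

#' Spatiotemporal cluster permutation test
#'
#' Nonparametric cluster-level inference: the null distribution is the
#' maximum cluster mass under within-subject exchange -- condition-label
#' permutation per subject for the repeated-measures F design, difference
#' sign-flips per subject for the paired-t design. Cluster
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` for Monte Carlo sampling;
#' when the exhaustive space is no larger than `n_perm` (sign-flip designs),
#' all relabelings are enumerated and p is the exact fraction.
#'
#' @param data Subjects x conditions x channels x time array (conditions = 2
#'   for the t design).
#' @param design `"F"` (rmANOVA map, one-sided) or `"t"` (paired t,
#'   two-sided).
#' @param n_perm Number of permutations (>= 100).
#' @param threshold Cluster-forming threshold; default is the parametric
#'   95th percentile of the pointwise statistic's null (F quantile, or
#'   two-sided |t| quantile).
#' @param adjacency An `adjacency_graph`.
#' @param seed RNG seed for Monte Carlo sampling.
#' @return A `cluster_result`: clusters, masses, `p_values`,
#'   `null_distribution`, `n_permutations`, `threshold`, `method`.
#' @export
permutation_cluster_test <- function(data, design = c("F", "t"),
                                     n_perm = 1024, threshold = NULL,
                                     adjacency, seed = 1) {
  design <- match.arg(design)
  if (n_perm < 100) stop("n_perm must be >= 100")
  dm <- dim(data)
  n <- dm[1]; k <- dm[2]
  if (design == "t") {
    if (k != 2) stop("t design needs exactly 2 conditions")
    if (is.null(threshold)) threshold <- stats::qt(0.975, n - 1)
    tail <- "two"
    d <- array(data[, 1, , ] - data[, 2, , ], dim = c(n, dm[3], dm[4]))
    tmap_from_diff <- function(dd) {
      m <- colMeans(dd)
      v <- (colSums(dd^2) - n * m^2) / (n - 1)
      t <- m / sqrt(pmax(v, 0) / n)
      t[!is.finite(t)] <- 0
      t
    }
    obs_map <- pointwise_paired_t(data)
    obs_map$values <- tmap_from_diff(d)   # identical numeric path as nulls
    exhaustive <- 2^n <= n_perm
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      nulls <- apply(signs, 1, function(sg) {
        .max_cluster_mass(tmap_from_diff(dd = dd_flip(d, sg)), threshold,
                          adjacency, tail)
      })
    } else {
      nulls <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          sg <- sample(c(1, -1), n, replace = TRUE)
          .max_cluster_mass(tmap_from_diff(dd_flip(d, sg)), threshold,
                            adjacency, tail)
        }, 1.0)
      })
    }
  } else {
    if (is.null(threshold)) {
      threshold <- stats::qf(0.95, k - 1, (k - 1) * (n - 1))
    }
    tail <- "one"
    obs_map <- pointwise_rm_anova(data)
    exhaustive <- FALSE
    nulls <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- data
        for (s in seq_len(n)) {
          perm[s, , , ] <- data[s, sample.int(k), , ]
        }
        .max_cluster_mass(pointwise_rm_anova(perm)$values, threshold,
                          adjacency, tail)
      }, 1.0)
    })
  }
  fc <- form_clusters(obs_map, threshold, adjacency, tail)
  # small tolerance guards floating-point ties at the identity relabeling
  p <- if (exhaustive) {
    vapply(fc$masses, function(m) mean(nulls >= abs(m) - 1e-9), 1.0)
  } else {
    vapply(fc$masses,
           function(m) (1 + sum(nulls >= abs(m) - 1e-9)) / (1 + n_perm),
           1.0)
  }
  structure(list(clusters = fc$clusters, masses = fc$masses, p_values = p,
                 null_distribution = nulls,
                 n_permutations = length(nulls), threshold = threshold,
                 design = design,
                 method = if (exhaustive) "exhaustive" else "montecarlo",
                 stat_map = obs_map),
            class = "cluster_result")
}

dd_flip <- function(d, sg) sweep(d, 1, sg, "*")

#' Restricted-permutation cluster test for a factor of a two-way design
#'
#' Tests one main effect of a subjects x A x B design by permuting the
#' tested factor's labels within each level of the other factor (and within
#' subject), so the nuisance factor's structure is preserved.
#'
#' @param data Subjects x A x B x channels x time array.
#' @param effect `"A"` or `"B"`.
#' @inheritParams permutation_cluster_test
#' @return A `cluster_result`.
#' @export
permutation_cluster_test_factorial <- function(data, effect = c("A", "B"),
                                               n_perm = 1024,
                                               threshold = NULL, adjacency,
                                               seed = 1) {
  effect <- match.arg(effect)
  dm <- dim(data)
  if (length(dm) != 5) stop("data must be subjects x A x B x ch x time")
  if (effect == "B") {
    data <- aperm(data, c(1, 3, 2, 4, 5))
    dm <- dim(data)
  }
  n <- dm[1]; a <- dm[2]; b <- dm[3]
  if (is.null(threshold)) threshold <- stats::qf(0.95, a - 1,
                                                 (a - 1) * (n - 1))
  fmap_a <- function(x) pointwise_rm_anova2(x)$A
  obs_map <- fmap_a(data)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- data
      for (s in seq_len(n)) {
        for (bb in seq_len(b)) {
          perm[s, , bb, , ] <- data[s, sample.int(a), bb, , ]
        }
      }
      .max_cluster_mass(fmap_a(perm)$values, threshold, adjacency, "one")
    }, 1.0)
  })
  fc <- form_clusters(obs_map, threshold, adjacency, "one")
  p <- vapply(fc$masses, function(m) (1 + sum(nulls >= abs(m))) /
                (1 + n_perm), 1.0)
  structure(list(clusters = fc$clusters, masses = fc$masses, p_values = p,
                 null_distribution = nulls, n_permutations = n_perm,
                 threshold = threshold, design = paste0("F-", effect),
                 method = "montecarlo", stat_map = obs_map),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s design, %d cluster(s), %d perms (%s)\n",
              x$design, length(x$clusters), x$n_permutations, x$method))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: %d points, mass %.2f, p = %.4g\n", i,
                  nrow(x$clusters[[i]]), x$masses[i], x$p_values[i]))
    }
  }
  invisible(x)
}

#' Serialize a cluster result to JSON
#'
#' @param result A `cluster_result`.
#' @param path Output file.
#' @export
write_cluster_json <- function(result, path) {
  jsonlite::write_json(list(
    design = result$design, threshold = result$threshold,
    n_permutations = result$n_permutations, method = result$method,
    clusters = lapply(seq_along(result$clusters), function(i) list(
      members = unname(result$clusters[[i]]),
      mass = result$masses[i], p = result$p_values[i])),
    null_summary = list(q95 = unname(stats::quantile(
      result$null_distribution, 0.95)),
      max = max(result$null_distribution))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
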