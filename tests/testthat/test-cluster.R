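# Spatiotemporal cluster permutation statistics.

test_that("pointwise rmANOVA F matches the sums-of-squares decomposition", {
  set.seed(7)
  y <- matrix(rnorm(18), 6, 3)                  # 6 subjects x 3 conditions
  sm <- pointwise_rm_anova(array(y, c(6, 3, 1, 1)))
  g <- mean(y)
  ss_a <- 6 * sum((colMeans(y) - g)^2)
  ss_s <- 3 * sum((rowMeans(y) - g)^2)
  ss_as <- sum((y - g)^2) - ss_a - ss_s
  f_oracle <- (ss_a / 2) / (ss_as / 10)
  expect_equal(sm$values[1, 1], f_oracle, tolerance = 1e-9)
  expect_identical(sm$df, c(2, 10))
  # df structure at the 13-subject, 3-condition design
  sm13 <- pointwise_rm_anova(array(rnorm(13 * 3 * 4), c(13, 3, 2, 2)))
  expect_identical(sm13$df, c(2, 24))
  # identical conditions per subject: F = 0 everywhere
  same <- array(rep(rnorm(5), 3 * 4), c(5, 3, 2, 2))
  expect_equal(max(pointwise_rm_anova(same)$values), 0)
  expect_error(pointwise_rm_anova(array(0, c(2, 3, 1, 1))), "3 subjects")
})

test_that("two-way rmANOVA maps match aov on a toy design", {
  set.seed(8)
  n <- 6; a <- 3; b <- 2
  y <- array(rnorm(n * a * b), c(n, a, b))
  y[, 2, ] <- y[, 2, ] + 1
  maps <- pointwise_rm_anova2(array(y, c(n, a, b, 1, 1)))
  df <- expand.grid(s = factor(1:n), A = factor(1:a), B = factor(1:b))
  df$v <- as.vector(y)
  av <- summary(aov(v ~ A * B + Error(s / (A * B)), df))
  f_aov <- c(av[["Error: s:A"]][[1]]["A", "F value"],
             av[["Error: s:B"]][[1]]["B", "F value"],
             av[["Error: s:A:B"]][[1]]["A:B", "F value"])
  expect_equal(c(maps$A$values[1, 1], maps$B$values[1, 1],
                 maps$AB$values[1, 1]), f_aov, tolerance = 1e-8)
  expect_identical(maps$A$df, c(2, 10))
  expect_identical(maps$AB$df, c(2, 10))
})

test_that("pointwise paired t matches the direct formula and is antisymmetric", {
  d5 <- c(0.3, -0.1, 0.4, 0.2, 0.25)
  dat <- array(0, c(5, 2, 1, 1)); dat[, 1, 1, 1] <- d5
  tm <- pointwise_paired_t(dat)
  expect_equal(tm$values[1, 1], mean(d5) / (sd(d5) / sqrt(5)),
               tolerance = 1e-12)
  expect_identical(tm$df, 4)
  # swapped conditions negate t
  swapped <- dat[, 2:1, , , drop = FALSE]
  expect_equal(pointwise_paired_t(swapped)$values, -tm$values)
  # identical conditions: t = 0
  same <- array(rep(rnorm(5), 2), c(5, 2, 1, 1))
  expect_equal(pointwise_paired_t(same)$values[1, 1], 0)
  # zero-variance nonzero differences clamp with a warning
  cst <- array(0, c(5, 2, 1, 1)); cst[, 1, 1, 1] <- 1
  expect_warning(tc <- pointwise_paired_t(cst), "clamped")
  expect_gt(tc$values[1, 1], 1e11)
})

test_that("cluster formation follows the space-time adjacency graph", {
  mon2 <- ring_montage(2, polar = 0.3)          # two nearby channels
  adj <- compute_adjacency(mon2, threshold = 1)
  expect_true(adj$matrix[1, 2])
  # L-shaped supra-threshold region: one cluster, hand-summed mass
  map <- rbind(c(3, 4, 0), c(0, 5, 0))
  fc <- form_clusters(map, 2, adj, "one")
  expect_length(fc$clusters, 1)
  expect_equal(fc$masses, 12)
  expect_equal(nrow(fc$clusters[[1]]), 3)
  # no supra-threshold points
  expect_length(form_clusters(map, 10, adj, "one")$clusters, 0)
  # two islands in non-adjacent channels at disjoint times
  far <- ring_montage(2, polar = 1.2)           # opposite sides
  adj_far <- compute_adjacency(far, threshold = 0.5)
  expect_false(adj_far$matrix[1, 2])
  map2 <- rbind(c(3, 0, 0), c(0, 0, 3))
  expect_length(form_clusters(map2, 2, adj_far, "one")$clusters, 2)
  # two-sided: polarities form separate signed clusters
  map3 <- rbind(c(3, -3, 0), c(0, -4, 0))
  fc3 <- form_clusters(map3, 2, adj, "two")
  expect_setequal(fc3$masses, c(3, -7))
})

test_that("exhaustive sign-flip permutation p equals brute-force enumeration", {
  set.seed(8)
  dat <- array(rnorm(5 * 2 * 1 * 4), c(5, 2, 1, 4))
  dat[, 1, , 3:4] <- dat[, 1, , 3:4] + 1.5
  adj <- compute_adjacency(mono_montage)
  res <- permutation_cluster_test(dat, "t", n_perm = 100, adjacency = adj,
                                  seed = 1)
  expect_identical(res$method, "exhaustive")
  expect_equal(res$n_permutations, 32)
  # independent brute-force oracle over all 2^5 sign patterns
  d <- array(dat[, 1, , ] - dat[, 2, , ], c(5, 1, 4))
  thr <- qt(0.975, 4)
  max_mass <- function(dd) {
    t <- apply(dd, c(2, 3), mean) / (apply(dd, c(2, 3), sd) / sqrt(5))
    v <- as.vector(t); s <- abs(v) > thr
    best <- 0; i <- 1
    while (i <= length(v)) {
      if (s[i]) {
        j <- i
        while (j < length(v) && s[j + 1] && sign(v[j + 1]) == sign(v[i]))
          j <- j + 1
        best <- max(best, abs(sum(v[i:j]))); i <- j + 1
      } else i <- i + 1
    }
    best
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  nulls <- apply(signs, 1, function(sg) max_mass(sweep(d, 1, sg, "*")))
  for (ci in seq_along(res$masses)) {
    expect_equal(res$p_values[ci], mean(nulls >= abs(res$masses[ci]) - 1e-9))
  }
})

test_that("p floor, determinism and channel-relabeling invariance hold", {
  set.seed(10)
  mon <- ring_montage(4)
  adj <- compute_adjacency(mon, threshold = 1.3)
  dat <- array(rnorm(8 * 3 * 4 * 10, sd = 0.1), c(8, 3, 4, 10))
  dat[, 1, , 4:7] <- dat[, 1, , 4:7] + 3        # strong effect
  res <- permutation_cluster_test(dat, "F", n_perm = 199, adjacency = adj,
                                  seed = 3)
  expect_equal(min(res$p_values), 1 / 200)      # observed beats all nulls
  expect_true(all(res$p_values >= 1 / 200 & res$p_values <= 1))
  res2 <- permutation_cluster_test(dat, "F", n_perm = 199, adjacency = adj,
                                   seed = 3)
  expect_identical(res2$p_values, res$p_values)
  # rotating the ring relabels channels but preserves the graph: p invariant
  rot <- c(2, 3, 4, 1)
  dat_r <- dat[, , rot, , drop = FALSE]
  res_r <- permutation_cluster_test(dat_r, "F", n_perm = 199,
                                    adjacency = adj, seed = 3)
  expect_equal(sort(res_r$p_values), sort(res$p_values))
})

test_that("effect scaling never raises the minimal cluster p", {
  set.seed(12)
  mon <- ring_montage(3)
  adj <- compute_adjacency(mon, threshold = 1.5)
  base <- array(rnorm(6 * 2 * 3 * 12, sd = 1), c(6, 2, 3, 12))
  minp <- vapply(c(0, 1.5, 4), function(delta) {
    d <- base
    d[, 1, , 5:9] <- d[, 1, , 5:9] + delta
    r <- permutation_cluster_test(d, "t", n_perm = 128, adjacency = adj,
                                  seed = 5)
    if (length(r$p_values)) min(r$p_values) else 1
  }, 1.0)
  expect_true(all(diff(minp) <= 1e-12))
})

test_that("restricted factorial permutation tests the right factor", {
  set.seed(14)
  mon <- ring_montage(3)
  adj <- compute_adjacency(mon, threshold = 1.5)
  # strong B effect, null A effect: A stays null under restricted perms
  dat <- array(rnorm(6 * 3 * 2 * 3 * 8, sd = 0.5), c(6, 3, 2, 3, 8))
  dat[, , 2, , ] <- dat[, , 2, , ] + 5
  resA <- permutation_cluster_test_factorial(dat, "A", n_perm = 150,
                                             adjacency = adj, seed = 2)
  expect_true(length(resA$p_values) == 0 || min(resA$p_values) > 0.05)
  resB <- permutation_cluster_test_factorial(dat, "B", n_perm = 150,
                                             adjacency = adj, seed = 2)
  expect_lt(min(resB$p_values), 0.05)
})

test_that("cluster results serialize to JSON", {
  set.seed(15)
  adj <- compute_adjacency(ring_montage(3), threshold = 1.5)
  dat <- array(rnorm(5 * 2 * 3 * 6), c(5, 2, 3, 6))
  dat[, 1, , 2:4] <- dat[, 1, , 2:4] + 2
  res <- permutation_cluster_test(dat, "t", n_perm = 128, adjacency = adj,
                                  seed = 1)
  jp <- withr::local_tempfile(fileext = ".json")
  write_cluster_json(res, jp)
  x <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(length(x$clusters$p), length(res$p_values))
  expect_equal(x$n_permutations, res$n_permutations)
})
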