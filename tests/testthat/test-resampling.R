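test_that("permutation reuses every pooled trial exactly once", {
  plan <- resampling_plan("permutation", n_iterations = 50, seed = 5)
  for (it in 1:20) {
    idx <- resample_indices(plan, 2, 2, it)
    expect_equal(sort(c(idx$idx1, idx$idx2)), 1:4)
  }
  plan2 <- resampling_plan("permutation", n_iterations = 50, seed = 5)
  for (it in c(7, 3, 19)) {
    # substreams: identical regardless of evaluation order
    expect_identical(resample_indices(plan2, 5, 4, it),
                     resample_indices(plan, 5, 4, it))
  }
})

test_that("index streams are reproducible and scheme-specific", {
  for (sch in c("permutation", "percentile_bootstrap", "bootstrap_t")) {
    p1 <- resampling_plan(sch, 100, seed = 9)
    p2 <- resampling_plan(sch, 100, seed = 9)
    expect_identical(resample_indices(p1, 6, 6, 42),
                     resample_indices(p2, 6, 6, 42))
    p3 <- resampling_plan(sch, 100, seed = 10)
    expect_false(identical(resample_indices(p1, 6, 6, 42),
                           resample_indices(p3, 6, 6, 42)))
  }
  # bootstrap indices stay within their condition
  pb <- resampling_plan("bootstrap_t", 100, seed = 2)
  idx <- resample_indices(pb, 4, 9, 1)
  expect_true(all(idx$idx1 <= 4) && all(idx$idx2 <= 9))
  pp <- resampling_plan("percentile_bootstrap", 100, seed = 2)
  idx2 <- resample_indices(pp, 4, 9, 1)
  expect_true(all(c(idx2$idx1, idx2$idx2) <= 13))
})

test_that("bootstrap draws follow the classical occupancy law", {
  plan <- resampling_plan("bootstrap_t", n_iterations = 2000, seed = 13)
  distinct <- vapply(1:2000, function(it)
    length(unique(resample_indices(plan, 10, 10, it)$idx1)), 1L)
  expected <- 10 * (1 - (9 / 10)^10)    # ~ 6.513
  se <- sd(distinct) / sqrt(length(distinct))
  expect_lt(abs(mean(distinct) - expected), 4 * se)
  expect_gte(min(distinct), 2)          # unconstrained draws can dip very low
})

test_that("min_unique redraws or fails with a scheme-naming error", {
  plan <- resampling_plan("percentile_bootstrap", 500, seed = 3,
                          min_unique = 8)
  distinct1 <- vapply(1:200, function(it) {
    idx <- resample_indices(plan, 10, 10, it)
    min(length(unique(idx$idx1)), length(unique(idx$idx2)))
  }, 1L)
  expect_gte(min(distinct1), 8)
  hard <- resampling_plan("bootstrap_t", 10, seed = 3, min_unique = 10)
  expect_error(resample_indices(hard, 10, 10, 1), "min_unique")
})

test_that("exhaustive permutation mode enumerates all distinct splits", {
  splits <- exhaustive_permutations(2, 2)
  expect_length(splits, choose(4, 2))
  keys <- vapply(splits, function(s) paste(sort(s$idx1), collapse = ","), "")
  expect_false(any(duplicated(keys)))
  expect_error(exhaustive_permutations(6, 6),
               class = "erpcluster_validation_error")
})

test_that("build_null matches a naive reimplementation for all three schemes", {
  set.seed(51)
  a <- array(rnorm(3 * 6 * 6, sd = 2), c(3, 6, 6))
  b <- array(rnorm(3 * 6 * 6, mean = 0.5, sd = 2), c(3, 6, 6))
  adj <- ring_adjacency(3)
  forming <- forming_threshold(0.2, 10)
  for (sch in c("permutation", "percentile_bootstrap", "bootstrap_t")) {
    plan <- resampling_plan(sch, n_iterations = 40, seed = 77)
    for (stat in c("mass", "extent", "height")) {
      got <- build_null(a, b, plan, stat, forming = forming, adjacency = adj)
      want <- naive_null_maxima(a, b, plan, forming$t_crit^2, adj, stat)
      expect_equal(got$maxima, want, tolerance = 1e-8)
    }
  }
})

test_that("bootstrap-t nulls are invariant to a condition-wide offset", {
  set.seed(52)
  a <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  b <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  adj <- ring_adjacency(3)
  plan <- resampling_plan("bootstrap_t", 60, seed = 8)
  forming <- forming_threshold(0.1, 14)
  n1 <- build_null(a, b, plan, "mass", forming = forming, adjacency = adj)
  n2 <- build_null(a + 7, b, plan, "mass", forming = forming, adjacency = adj)
  expect_equal(n2$maxima, n1$maxima, tolerance = 1e-7)
})

test_that("identical constant trials give all-zero maxima", {
  a <- array(3, c(2, 4, 5))
  adj <- build_adjacency(cbind(1, 2), n_channels = 2)
  for (sch in c("permutation", "percentile_bootstrap", "bootstrap_t")) {
    nd <- build_null(a, a, resampling_plan(sch, 30, seed = 1), "mass",
                     forming = forming_threshold(0.05, 8), adjacency = adj)
    expect_true(all(nd$maxima == 0))
  }
})

test_that("fwe_threshold applies the conservative rank rule", {
  expect_equal(fwe_threshold(1:1000, 0.05), 950)
  expect_equal(fwe_threshold(1:1000, 0.01), 990)
  expect_equal(fwe_threshold(rep(3.2, 77), 0.05), 3.2)
  expect_equal(fwe_threshold(rep(3.2, 77), 0.4), 3.2)
  set.seed(53)
  m <- rexp(500)
  expect_gte(fwe_threshold(m, 0.01), fwe_threshold(m, 0.05))
  expect_error(fwe_threshold(m, 0), class = "erpcluster_validation_error")
  expect_error(fwe_threshold(m, 1), class = "erpcluster_validation_error")
})

test_that("apply_correction keeps exactly the clusters beating the threshold", {
  # toy 1 x 6 map: t^2 clusters {9, 9} (mass 18) and {4} (mass 4)
  tvals <- matrix(c(3, 3, 0, 2, 0, 0), 1, 6)
  obs <- erpcluster:::new_stat_map(tvals, df = 10, squared = FALSE)
  adj <- build_adjacency(matrix(integer(0), ncol = 2), n_channels = 1)
  forming <- forming_threshold(0.2, 10)   # t_crit^2 ~ 1.88 < 4
  plan <- resampling_plan("permutation", 50, seed = 1)
  null <- structure(list(statistic = "mass", maxima = rep(10, 50),
                         plan = plan, forming = forming, tfce = NULL, df = 10),
                    class = "null_distribution")
  res <- apply_correction(obs, null, 0.05, adj)
  expect_equal(res$fwe_threshold, 10)
  expect_equal(nrow(res$surviving), 1)
  expect_equal(res$surviving$mass, 18)
  expect_equal(as.vector(res$mask), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  # all-zero null: any cluster with positive mass survives (strict >)
  null0 <- null; null0$maxima <- rep(0, 50)
  res0 <- apply_correction(obs, null0, 0.05, adj)
  expect_equal(nrow(res0$surviving), 2)

  # observed map with no suprathreshold point: empty mask
  flat <- erpcluster:::new_stat_map(matrix(0.1, 1, 6), df = 10, squared = FALSE)
  expect_equal(sum(apply_correction(flat, null, 0.05, adj)$mask), 0)

  # mismatched degrees of freedom is a configuration error
  obs2 <- erpcluster:::new_stat_map(tvals, df = 12, squared = FALSE)
  expect_error(apply_correction(obs2, null, 0.05, adj),
               class = "erpcluster_validation_error")
})

test_that("the full pipeline is deterministic given plan, data and parameters", {
  set.seed(54)
  a <- array(rnorm(4 * 8 * 10), c(4, 8, 10))
  b <- array(rnorm(4 * 8 * 10), c(4, 8, 10))
  adj <- ring_adjacency(4)
  f1 <- cluster_test(a, b, adj, scheme = "bootstrap_t", n_iterations = 80,
                     seed = 99)
  f2 <- cluster_test(a, b, adj, scheme = "bootstrap_t", n_iterations = 80,
                     seed = 99)
  expect_identical(f1$null$maxima, f2$null$maxima)
  expect_identical(f1$result$mask, f2$result$mask)
  expect_identical(glance(f1), glance(f2))
})

test_that("TFCE correction thresholds points, not clusters", {
  set.seed(55)
  a <- array(rnorm(4 * 8 * 12), c(4, 8, 12))
  b <- array(rnorm(4 * 8 * 12), c(4, 8, 12))
  b[2, 3:5, ] <- b[2, 3:5, ] + 6   # strong localised effect
  adj <- ring_adjacency(4)
  fit <- cluster_test(a, b, adj, statistic = "tfce", scheme = "permutation",
                      n_iterations = 120, seed = 3)
  expect_null(fit$result$surviving)
  expect_gt(sum(fit$result$mask), 0)
  tm <- tfce_transform(as_t2(fit$observed), adj, fit$null$tfce)
  expect_identical(fit$result$mask, tm$values > fit$result$fwe_threshold)
})
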