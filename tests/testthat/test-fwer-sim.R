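tiny_cfg <- fwer_config(sample_sizes = 50, n_mc = 100, schemes = "permutation",
                        statistics = "mass", forming_p = 0.05, alpha = 0.05,
                        n_iterations = 600, iteration_grid = c(200, 400, 600),
                        seed = 61)
tiny_pool <- generate_null_trials(synth_spec(n_channels = 4, n_timepoints = 20,
                                             n_trials = 120, seed = 62))
tiny_run <- run_fwer_experiment(tiny_pool, tiny_cfg)

test_that("permutation FWER is near nominal on a small null run", {
  fwer <- tiny_run$cells$fwer
  se <- sqrt(0.05 * 0.95 / tiny_cfg$n_mc)
  expect_lt(abs(fwer - 0.05), 3 * se)
  expect_equal(tiny_run$cells$n_reject, fwer * tiny_cfg$n_mc)  # integer count
})

test_that("convergence at the evaluation prefix equals the headline FWER", {
  conv <- convergence_curve(tiny_run)
  at_b <- conv$fwer[conv$iterations == tiny_cfg$eval_iterations]
  expect_equal(at_b, tiny_run$cells$fwer)
  expect_equal(sort(unique(conv$iterations)), c(200, 400, 600))
})

test_that("an alpha below 1/B thresholds at the null maximum: FWER near zero", {
  cfg <- fwer_config(sample_sizes = 30, n_mc = 60, schemes = "permutation",
                     statistics = "mass", forming_p = 0.05, alpha = 0.004,
                     n_iterations = 200, iteration_grid = 200, seed = 65)
  pool <- generate_null_trials(synth_spec(n_channels = 4, n_timepoints = 12,
                                          n_trials = 70, seed = 66))
  ex <- run_fwer_experiment(pool, cfg)
  # observed must beat every one of the 200 null maxima; under exchangeability
  # that has probability ~ 1/201 per replicate
  expect_lte(ex$cells$fwer, 0.05)
})

test_that("experiments are exactly reproducible from (pool, config, seed)", {
  again <- run_fwer_experiment(tiny_pool, tiny_cfg)
  expect_identical(again$cells, tiny_run$cells)
  expect_identical(again$replicates, tiny_run$replicates)
})

test_that("mask agreement metrics behave at the extremes", {
  m1 <- list(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2))
  expect_equal(mask_agreement(m1, m1)$prop_identical, 1)
  m2 <- lapply(m1, `!`)
  ag <- mask_agreement(m1, m2)
  expect_equal(ag$prop_identical, 0)
  expect_equal(ag$mean_pointwise, 0)
  expect_error(mask_agreement(m1, m1[1]), class = "erpcluster_validation_error")
})

test_that("scheme agreement compares full survivor sets per replicate", {
  cfg <- fwer_config(sample_sizes = c(20, 40), n_mc = 30,
                     schemes = c("permutation", "bootstrap_t"),
                     statistics = "mass", forming_p = 0.05, alpha = 0.05,
                     n_iterations = 200, iteration_grid = 200, seed = 63)
  pool <- generate_null_trials(synth_spec(n_channels = 4, n_timepoints = 15,
                                          n_trials = 90, seed = 64))
  ex <- run_fwer_experiment(pool, cfg)
  ag <- scheme_agreement(ex, "permutation", "bootstrap_t", by = "n")
  expect_equal(nrow(ag), 2)
  expect_true(all(ag$prop_identical >= 0 & ag$prop_identical <= 1))
  expect_equal(ag$n_compared, c(30L, 30L))
})

test_that("summaries use the stated trimming and bootstrap conventions", {
  s <- summarize_fwer(1:10, b_ci = 500)
  expect_equal(s$estimate[s$statistic == "trimmed_mean"], 5.5)  # mean of 3..8
  expect_equal(s$estimate[s$statistic == "mean"], 5.5)
  expect_equal(s$estimate[s$statistic == "median"], 5.5)

  sc <- summarize_fwer(rep(0.05, 6), b_ci = 200)
  expect_true(all(sc$estimate == 0.05))
  expect_true(all(sc$conf_low == 0.05 & sc$conf_high == 0.05))  # zero width

  # Bonferroni adjustment narrows the per-comparison level
  s7 <- summarize_fwer(rnorm(20), n_comparisons = 7, b_ci = 200)
  expect_equal(unique(s7$conf_level), 1 - 0.05 / 7)
  s7b <- summarize_fwer(rnorm(20), adjust = "sidak", n_comparisons = 7,
                        b_ci = 200)
  expect_equal(unique(s7b$conf_level), 0.95^(1 / 7))
  expect_error(summarize_fwer(0.05), class = "erpcluster_validation_error")
})

test_that("pairwise contrasts bootstrap the mean difference per cell", {
  df <- tibble::tibble(
    cell = rep(1:8, times = 2),
    scheme = rep(c("a", "b"), each = 8),
    fwer = c(0.05 + 0.001 * (1:8), 0.04 + 0.001 * (1:8)))
  pw <- fwer_pairwise(df, fwer, scheme, b_ci = 300)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$mean_difference, 0.01, tolerance = 1e-9)
  expect_lte(pw$conf_low, pw$mean_difference + 1e-12)
  expect_gte(pw$conf_high, pw$mean_difference - 1e-12)
})

test_that("configuration errors are caught up front", {
  expect_error(fwer_config(forming_p = c(0.05, 0.01), alpha = 0.05),
               class = "erpcluster_validation_error")
  expect_error(fwer_config(n_iterations = 400, iteration_grid = c(200, 800)),
               class = "erpcluster_validation_error")
  expect_error(fwer_config(n_iterations = 400, eval_iterations = 500),
               class = "erpcluster_validation_error")
  cfg <- fwer_config(sample_sizes = 100, n_mc = 5, n_iterations = 100,
                     iteration_grid = 100)
  small_pool <- generate_null_trials(synth_spec(n_channels = 4,
                                                n_timepoints = 10,
                                                n_trials = 50, seed = 1))
  expect_error(run_fwer_experiment(small_pool, cfg),
               class = "erpcluster_validation_error")
})

test_that("multi-dataset studies bind per-dataset tables reproducibly", {
  cfg <- fwer_config(sample_sizes = 20, n_mc = 10, schemes = "permutation",
                     statistics = "mass", forming_p = 0.05, alpha = 0.05,
                     n_iterations = 100, iteration_grid = 100, seed = 1)
  sp <- synth_spec(n_channels = 4, n_timepoints = 10, n_trials = 50, seed = 1)
  st1 <- run_fwer_study(sp, cfg, n_datasets = 2, seed = 3)
  st2 <- run_fwer_study(sp, cfg, n_datasets = 2, seed = 3)
  expect_identical(st1$cells, st2$cells)
  expect_equal(sort(unique(st1$cells$dataset)), 1:2)
  expect_equal(nrow(st1$replicates), 2 * 10)
})
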