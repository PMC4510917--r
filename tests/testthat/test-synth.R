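test_that("white-noise limits: no temporal or spatial correlation", {
  pool <- generate_null_trials(synth_spec(n_channels = 4, n_timepoints = 30,
                                          n_trials = 500, ar = 0,
                                          spatial_scale = 0, noise_sd = 10,
                                          seed = 71))
  x <- pool$epochs$data
  # lag-1 autocorrelation pooled over channels and trials
  lag1 <- cor(as.vector(x[, -30, ]), as.vector(x[, -1, ]))
  n_eff <- length(x[, -1, ])
  expect_lt(abs(lag1), 3 / sqrt(n_eff))
  # correlation between two different channels at the same time
  r12 <- cor(as.vector(x[1, , ]), as.vector(x[2, , ]))
  expect_lt(abs(r12), 3 / sqrt(length(x[1, , ])))
  # marginal scale
  expect_lt(abs(sd(x) - 10), 0.3)
})

test_that("temporal and spatial moments match the specified kernels", {
  spec <- synth_spec(n_channels = 9, n_timepoints = 40, n_trials = 1000,
                     ar = 0.8, spatial_scale = 1.5, noise_sd = 5, seed = 72)
  pool <- generate_null_trials(spec)
  x <- pool$epochs$data
  lag1 <- cor(as.vector(x[, -40, ]), as.vector(x[, -1, ]))
  expect_lt(abs(lag1 - 0.8), 0.02)
  # adjacent grid channels (distance 1): target exp(-1 / (2 * 1.5^2))
  r_adj <- cor(as.vector(x[1, , ]), as.vector(x[2, , ]))
  expect_lt(abs(r_adj - exp(-1 / 4.5)), 0.03)
  # distant channels are less correlated than neighbours
  r_far <- cor(as.vector(x[1, , ]), as.vector(x[9, , ]))
  expect_lt(r_far, r_adj)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- synth_spec(n_channels = 4, n_timepoints = 10, n_trials = 20, seed = 73)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  p1 <- generate_null_trials(spec)
  after <- rnorm(1)
  p2 <- generate_null_trials(spec)
  expect_identical(p1$epochs$data, p2$epochs$data)
  expect_equal(before, after)   # caller stream restored
})

test_that("null splits give pointwise rejection at the forming rate", {
  pool <- generate_null_trials(synth_spec(n_channels = 9, n_timepoints = 60,
                                          n_trials = 200, seed = 74))
  rates <- vapply(1:20, function(i) {
    prm <- erpcluster:::cpp_permute(100 + i, 1L, 200L)
    m <- two_sample_t(epochs_subset(pool$epochs, prm[1:100]),
                      epochs_subset(pool$epochs, prm[101:200]))
    crit <- forming_threshold(0.05, m$df)$t_crit
    mean(abs(m$values) > crit)
  }, 1)
  # correlated points inflate the variance of single-split rates; the mean
  # over independent splits settles near the nominal level
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("student-noise option keeps unit scaling", {
  pool <- generate_null_trials(synth_spec(n_channels = 4, n_timepoints = 20,
                                          n_trials = 400, ar = 0,
                                          spatial_scale = 0, noise_sd = 8,
                                          noise = "student", noise_df = 5,
                                          seed = 75))
  expect_lt(abs(sd(pool$epochs$data) - 8), 0.5)
})

test_that("effect injection is additive, windowed and validated", {
  spec <- synth_spec(n_channels = 9, n_timepoints = 50, n_trials = 10,
                     seed = 76)
  pool <- generate_null_trials(spec)
  e <- pool$epochs
  tms <- times_ms(e)

  expect_identical(inject_effects(e, 1:5, list()), e)  # empty list: unchanged

  win <- c(tms[10], tms[20])
  ef <- effect_spec(c(2, 3), win, amplitude = 4)
  mod <- inject_effects(e, 1:5, list(ef))
  sel <- tms >= win[1] & tms <= win[2]
  expect_equal(mod$data[2, sel, 1], e$data[2, sel, 1] + 4)
  expect_equal(mod$data[2, sel, 6], e$data[2, sel, 6])      # other trials
  expect_equal(mod$data[1, , 1], e$data[1, , 1])            # other channels
  expect_equal(mod$data[2, !sel, 1], e$data[2, !sel, 1])    # outside window

  # doubling the amplitude doubles the mean difference exactly
  mod2 <- inject_effects(e, 1:5, list(effect_spec(c(2, 3), win, 8)))
  d1 <- mod$data - e$data
  d2 <- mod2$data - e$data
  expect_equal(d2, 2 * d1)

  expect_error(inject_effects(e, 1:5, list(effect_spec(99, win, 1))),
               class = "erpcluster_validation_error")
  expect_error(
    inject_effects(e, 1:5, list(effect_spec(1, c(tms[1] - 50, tms[5]), 1))),
    class = "erpcluster_validation_error")
  expect_error(inject_effects(e, 40, list(ef)),
               class = "erpcluster_validation_error")
})

test_that("raised-cosine effects taper to zero at the window edges", {
  spec <- synth_spec(n_channels = 4, n_timepoints = 40, n_trials = 4, seed = 77)
  e <- generate_null_trials(spec)$epochs
  tms <- times_ms(e)
  win <- c(tms[5], tms[25])
  mod <- inject_effects(e, 1:2, list(effect_spec(1, win, 10,
                                                 shape = "raised_cosine")))
  d <- mod$data[1, , 1] - e$data[1, , 1]
  expect_equal(d[5], 0, tolerance = 1e-12)
  expect_equal(d[25], 0, tolerance = 1e-12)
  expect_equal(max(d), 10, tolerance = 1e-6)
})

test_that("the montage adjacency satisfies the graph invariants", {
  g <- montage_adjacency(16, k = 4)
  expect_s3_class(g, "adjacency_graph")
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  deg <- tabulate(g$edges, 16)
  expect_true(all(deg >= 4))   # symmetrisation can only add neighbours
})
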