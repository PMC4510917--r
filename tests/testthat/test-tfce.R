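adj1 <- build_adjacency(matrix(integer(0), ncol = 2), n_channels = 1)

test_that("TFCE of an all-zero map is zero and params validate", {
  expect_true(all(tfce_transform(matrix(0, 1, 4), adj1)$values == 0))
  expect_error(tfce_params(dh = 0), class = "erpcluster_validation_error")
  expect_error(tfce_params(e = -1), class = "erpcluster_validation_error")
  expect_error(tfce_transform(matrix(c(-1, 2), 1, 2),
                              build_adjacency(cbind(1, 2), n_channels = 2)),
               "t-squared", class = "erpcluster_validation_error")
})

test_that("an isolated point matches the closed-form integral", {
  # extent is always 1, so TFCE(4) ~ integral of h^2 dh from 0 to 4 = 64/3,
  # discretised as the Riemann sum over the dh grid
  got <- tfce_transform(matrix(c(0, 4, 0), 1, 3), adj1)$values[2]
  riemann <- sum(((1:40) * 0.1)^2 * 0.1)
  expect_equal(got, riemann, tolerance = 1e-9)
  expect_lt(abs(got - 64 / 3), 0.1 * 4^2 + 1e-9)  # O(dh) discretisation error
  # finer dh converges
  got2 <- tfce_transform(matrix(c(0, 4, 0), 1, 3), adj1,
                         tfce_params(dh = 0.01))$values[2]
  expect_lt(abs(got2 - 64 / 3), 0.01 * 4^2 + 1e-9)
})

test_that("E = 1, H = 0 recovers cluster mass above h0", {
  got <- tfce_transform(matrix(c(0, 3, 3, 0), 1, 4), adj1,
                        tfce_params(e = 1, h = 0))
  expect_equal(max(got$values), 6, tolerance = 1e-9)  # layer-cake identity
  # unimodal clusters never split at higher levels, so the peak's integral of
  # extents over levels is exactly the cluster mass (up to dh * extent);
  # random trains of unimodal bumps separated by zeros on one channel
  set.seed(41)
  for (i in 1:10) {
    bumps <- lapply(seq_len(sample(2:4, 1)), function(j) {
      up <- sort(round(rexp(sample(1:4, 1)) + 0.2, 1))
      c(0, up, rev(up) * sample(c(0.5, 1), 1))
    })
    x <- matrix(c(unlist(bumps), 0), 1)
    tf <- tfce_transform(x, adj1, tfce_params(e = 1, h = 0))
    labs <- label_clusters(x, 0, adj1)
    tab <- cluster_table(labs)
    for (l in seq_len(nrow(tab))) {
      peak <- max(tf$values[labs$labels == l])
      expect_lt(abs(peak - tab$mass[l]), 0.1 * tab$extent[l] + 1e-9)
    }
  }
  # in general the peak value never exceeds the mass (components at level h
  # are subsets of the cluster's points above h)
  set.seed(46)
  for (i in 1:10) {
    adj <- random_adjacency(5, 0.4)
    x <- matrix(round(rexp(5 * 8), 1), 5, 8)
    tf <- tfce_transform(x, adj, tfce_params(e = 1, h = 0))
    labs <- label_clusters(x, 0, adj)
    tab <- cluster_table(labs)
    for (l in seq_len(nrow(tab))) {
      peak <- max(tf$values[labs$labels == l])
      expect_lt(peak, tab$mass[l] + 0.1 * tab$extent[l] + 1e-9)
    }
  }
})

test_that("the sweep equals the naive per-level oracle for all parameter sets", {
  set.seed(42)
  param_sets <- list(c(0.5, 1), c(0.5, 2), c(1, 1), c(1, 2))
  for (i in 1:8) {
    nc <- sample(3:8, 1); nt <- sample(4:12, 1)
    adj <- random_adjacency(nc, 0.35)
    x <- matrix(rexp(nc * nt) * 2, nc, nt)
    x[sample(length(x), length(x) %/% 3)] <- 0
    for (ps in param_sets) {
      got <- tfce_transform(x, adj, tfce_params(ps[1], ps[2]))$values
      want <- naive_tfce(x, adj, ps[1], ps[2])
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("scaling the map up strictly increases nonzero TFCE values", {
  set.seed(43)
  adj <- random_adjacency(6, 0.3)
  x <- matrix(rexp(6 * 10) * 3, 6, 10)
  v1 <- tfce_transform(x, adj)$values
  v2 <- tfce_transform(1.5 * x, adj)$values
  nz <- v1 > 0
  expect_true(all(v2[nz] > v1[nz]))
})

test_that("TFCE is equivariant under channel relabelling", {
  set.seed(44)
  nc <- 6
  adj <- random_adjacency(nc, 0.4)
  x <- matrix(rexp(nc * 9) * 2, nc, 9)
  perm <- sample(nc)
  # relabel channels and the graph consistently
  inv <- order(perm)
  e2 <- matrix(inv[adj$edges], ncol = 2)
  adj2 <- build_adjacency(e2, n_channels = nc)
  v1 <- tfce_transform(x, adj)$values
  v2 <- tfce_transform(x[perm, , drop = FALSE], adj2)$values
  expect_equal(v2, v1[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("values are zero exactly at and below the integration start", {
  x <- matrix(c(0, 0.04, 0.5, 2), 1, 4)
  v <- tfce_transform(x, adj1)$values
  expect_equal(v[1], 0)
  expect_equal(v[2], 0)       # below the first grid level h0 + dh
  expect_true(all(v[3:4] > 0))
})
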