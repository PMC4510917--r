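# Independent oracles, deliberately naive: breadth-first flood fill for
# connected components, per-level re-clustering for TFCE, and a plain R loop
# for the resampling engines.  They share only the public index generator and
# grid conventions with the implementation under test.

# neighbour list (channel indices) from an adjacency_graph
nbr_list <- function(adj) {
  nl <- vector("list", adj$n_channels)
  for (i in seq_len(nrow(adj$edges))) {
    a <- adj$edges[i, 1]; b <- adj$edges[i, 2]
    nl[[a]] <- c(nl[[a]], b)
    nl[[b]] <- c(nl[[b]], a)
  }
  nl
}

# flood-fill labelling of {x > thr}; labels numbered by first-encountered
# point scanning channels in the outer loop, time in the inner loop
flood_fill_labels <- function(x, thr, adj) {
  nc <- nrow(x); nt <- ncol(x)
  nl <- nbr_list(adj)
  labels <- matrix(0L, nc, nt)
  lab <- 0L
  for (c0 in seq_len(nc)) for (t0 in seq_len(nt)) {
    if (x[c0, t0] <= thr || labels[c0, t0] != 0L) next
    lab <- lab + 1L
    queue <- list(c(c0, t0))
    labels[c0, t0] <- lab
    while (length(queue)) {
      pt <- queue[[1]]; queue <- queue[-1]
      cc <- pt[1]; tt <- pt[2]
      cand <- list()
      if (tt > 1) cand <- c(cand, list(c(cc, tt - 1)))
      if (tt < nt) cand <- c(cand, list(c(cc, tt + 1)))
      for (c2 in nl[[cc]]) cand <- c(cand, list(c(c2, tt)))
      for (q in cand) {
        if (x[q[1], q[2]] > thr && labels[q[1], q[2]] == 0L) {
          labels[q[1], q[2]] <- lab
          queue <- c(queue, list(q))
        }
      }
    }
  }
  list(labels = labels, n_clusters = lab)
}

# per-level TFCE oracle: rebuilds the component labelling at every grid level
naive_tfce <- function(x, adj, e, h, dh = 0.1, h0 = 0) {
  out <- matrix(0, nrow(x), ncol(x))
  vmax <- max(x)
  L <- floor((vmax - h0) / dh + 1e-6)
  if (L < 1) return(out)
  for (j in seq_len(L)) {
    lev <- h0 + j * dh
    member <- x >= lev - 1e-6 * dh
    ff <- flood_fill_labels(ifelse(member, 1, 0), 0.5, adj)
    if (ff$n_clusters == 0L) next
    sizes <- tabulate(ff$labels[ff$labels > 0], ff$n_clusters)
    inc <- ifelse(ff$labels > 0, sizes[pmax(ff$labels, 1L)]^e * lev^h * dh, 0)
    out <- out + inc
  }
  out
}

# plain-R reimplementation of one null-distribution loop, using the public
# per-iteration index generator plus naive t / clustering code
naive_null_maxima <- function(a_arr, b_arr, plan, forming_t2, adj,
                              statistic = "mass") {
  nc <- dim(a_arr)[1]; nt <- dim(a_arr)[2]
  n1 <- dim(a_arr)[3]; n2 <- dim(b_arr)[3]
  A <- matrix(a_arr, nc * nt, n1)
  B <- matrix(b_arr, nc * nt, n2)
  if (plan$scheme == "bootstrap_t") {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
  }
  pool <- cbind(A, B)
  vapply(seq_len(plan$n_iterations), function(it) {
    idx <- resample_indices(plan, n1, n2, it)
    if (plan$scheme == "bootstrap_t") {
      g1 <- A[, idx$idx1, drop = FALSE]
      g2 <- B[, idx$idx2, drop = FALSE]
    } else {
      g1 <- pool[, idx$idx1, drop = FALSE]
      g2 <- pool[, idx$idx2, drop = FALSE]
    }
    m1 <- rowMeans(g1); m2 <- rowMeans(g2)
    v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    den <- sp2 * (1 / n1 + 1 / n2)
    t2 <- ifelse(den > 0, (m1 - m2)^2 / den, ifelse(m1 == m2, 0, 1e12))
    ff <- flood_fill_labels(matrix(t2, nc, nt), forming_t2, adj)
    if (ff$n_clusters == 0L) return(0)
    vals <- matrix(t2, nc, nt)
    per <- vapply(seq_len(ff$n_clusters), function(l) {
      member <- ff$labels == l
      switch(statistic,
             mass = sum(vals[member]),
             extent = sum(member),
             height = max(vals[member]))
    }, 1)
    max(per)
  }, 1)
}

random_adjacency <- function(nc, p_edge = 0.3) {
  pairs <- t(utils::combn(nc, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  build_adjacency(pairs[keep, , drop = FALSE], n_channels = nc)
}

ring_adjacency <- function(nc) {
  build_adjacency(cbind(seq_len(nc), c(seq_len(nc - 1) + 1L, 1L)),
                  n_channels = nc)
}
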