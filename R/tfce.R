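#' TFCE parameter set
#'
#' Threshold-free cluster enhancement integrates, for every point, the quantity
#' extent(h)^E * h^H over all cluster-forming levels h from `h0` up to the
#' point's own value, approximated as a Riemann sum with step `dh`.  The
#' conventional defaults for non-negative (t-squared) maps are E = 0.5, H = 2,
#' dh = 0.1, h0 = 0; E = 1, H = 0 recovers the cluster-mass statistic above
#' `h0`.  `h0` is held at 0 rather than at the data minimum so that enhanced
#' values are comparable across resampling iterations.
#'
#' @param e extent exponent (>= 0).
#' @param h height exponent (>= 0).
#' @param dh integration step (> 0), on the scale of the map the transform is
#'   applied to (t-squared by default).
#' @param h0 integration start (default 0).
#' @return A `tfce_params` object.
#' @export
tfce_params <- function(e = 0.5, h = 2, dh = 0.1, h0 = 0) {
  check_scalar_number(e, "e", lower = 0)
  check_scalar_number(h, "h", lower = 0)
  check_scalar_number(dh, "dh", lower = 0, strict_lower = TRUE)
  check_scalar_number(h0, "h0")
  structure(list(e = e, h = h, dh = dh, h0 = h0), class = "tfce_params")
}

#' @export
print.tfce_params <- function(x, ...) {
  cat(sprintf("<tfce_params> E = %g, H = %g, dh = %g, h0 = %g\n",
              x$e, x$h, x$dh, x$h0))
  invisible(x)
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' For each point p, sums extent_h(p)^E * h^H * dh over the level grid
#' h = h0 + dh, h0 + 2 dh, ..., up to the largest grid level not exceeding the
#' map maximum, where extent_h(p) is the size of the connected component
#' containing p when the map is thresholded at level h (spatiotemporal
#' connectivity as in [label_clusters()]).  A point belongs to the level-h
#' component when its value is at least h.  The sweep is implemented once per
#' map with an incremental union-find over descending levels; it agrees exactly
#' with re-clustering at every level independently.
#'
#' @param map a `stat_map` in the t-squared view (see [as_t2()]) or a
#'   non-negative numeric matrix.
#' @param adjacency an [build_adjacency()] graph.
#' @param params a [tfce_params()] set.
#' @return A `tfce_map`: list with non-negative `values` (channels x time),
#'   the `params` used, and channel/time metadata.  Values are zero exactly at
#'   points at or below `h0 + dh` resolution of the input floor.
#' @export
#' @examples
#' adj <- build_adjacency(matrix(integer(0), ncol = 2), n_channels = 1)
#' m <- matrix(c(0, 4, 0), 1, 3)
#' tfce_transform(m, adj)$values
tfce_transform <- function(map, adjacency, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  if (inherits(map, "stat_map")) {
    if (!map$squared)
      stop_validation(
        "TFCE needs a non-negative map: square the t map first with as_t2()")
    vals <- map$values
    meta <- map[c("channel_ids", "times_ms")]
  } else if (is.matrix(map)) {
    vals <- map
    meta <- NULL
  } else {
    stop_validation("`map` must be a stat_map or a numeric matrix")
  }
  if (any(vals < 0))
    stop_validation(
      "negative input values: TFCE operates on the t-squared view (see as_t2())")
  edges <- edges_for_cpp(adjacency, nrow(vals))
  out <- cpp_tfce(vals, edges, params$e, params$h, params$dh, params$h0)[[1]]
  structure(list(values = out, params = params,
                 channel_ids = meta$channel_ids %||% sprintf("Ch%03d", seq_len(nrow(vals))),
                 times_ms = meta$times_ms %||% (seq_len(ncol(vals)) - 1)),
            class = "tfce_map")
}

#' @export
print.tfce_map <- function(x, ...) {
  cat(sprintf("<tfce_map> %d x %d, E = %g, H = %g, dh = %g, max = %.4g\n",
              nrow(x$values), ncol(x$values), x$params$e, x$params$h,
              x$params$dh, max(x$values)))
  invisible(x)
}

#' @method tidy tfce_map
#' @export
tidy.tfce_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    channel_id = rep(x$channel_ids, times = ncol(x$values)),
    time_ms = rep(x$times_ms, each = nrow(x$values)),
    value = as.vector(x$values))
}
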