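#' Spatiotemporal connected-component labelling of a suprathreshold map
#'
#' Partitions the points with `value > threshold` into maximal connected
#' components.  Two points are adjacent iff they share a channel and are one
#' time sample apart, or they are on neighbouring channels (per `adjacency`) at
#' the same time sample; diagonal channel-and-time moves are not connected.
#' Membership uses a strictly-greater comparison.  Clusters are numbered
#' 1..n_clusters by their first-encountered point scanning channels in the
#' outer loop and time in the inner loop, so labelling is deterministic.
#'
#' By default clustering is meant for the t-squared view, which merges adjacent
#' positive and negative deflections into one cluster; pass
#' `sign_split = TRUE` together with an *unsquared* map to cluster positive and
#' negative t values separately (labels are then assigned on the squared map
#' restricted to each sign).
#'
#' @param map a `stat_map` (squared or not) or a plain numeric matrix
#'   (channels x time).
#' @param threshold either a [forming_threshold()] object (its `t_crit^2` is
#'   applied to the t-squared map) or a single number on the scale of the map
#'   values as given.
#' @param adjacency an [build_adjacency()] graph with matching channel count.
#' @param sign_split cluster positive and negative deflections separately
#'   (default `FALSE`); requires an unsquared `stat_map`.
#' @return A `cluster_labels` object: list with `labels` (integer matrix, 0 =
#'   subthreshold), `n_clusters`, and the thresholded `map` used.
#' @export
#' @examples
#' adj <- build_adjacency(matrix(integer(0), ncol = 2), n_channels = 1)
#' m <- matrix(c(0, 9, 9, 0, 9), 1, 5)
#' label_clusters(m, 4, adj)$n_clusters
label_clusters <- function(map, threshold, adjacency, sign_split = FALSE) {
  if (inherits(map, "stat_map")) {
    if (inherits(threshold, "cluster_forming")) {
      thr <- threshold$t_crit^2
      m2 <- if (map$squared) map else as_t2(map)
    } else {
      thr <- check_scalar_number(threshold, "threshold")
      m2 <- map
    }
    vals <- m2$values
    raw_t <- if (!map$squared) map$values else NULL
  } else if (is.matrix(map)) {
    thr <- if (inherits(threshold, "cluster_forming")) threshold$t_crit^2
           else check_scalar_number(threshold, "threshold")
    vals <- map
    raw_t <- map
    m2 <- NULL
  } else {
    stop_validation("`map` must be a stat_map or a numeric matrix")
  }
  edges <- edges_for_cpp(adjacency, nrow(vals))

  if (sign_split) {
    if (is.null(raw_t))
      stop_validation("`sign_split` needs an unsquared map to recover the sign")
    pos <- vals * (raw_t > 0)
    neg <- vals * (raw_t < 0)
    lp <- cpp_label_clusters(pos, thr, edges)
    ln <- cpp_label_clusters(neg, thr, edges)
    labels <- lp$labels
    labels[ln$labels > 0] <- ln$labels[ln$labels > 0] + lp$n_clusters
    n <- lp$n_clusters + ln$n_clusters
  } else {
    res <- cpp_label_clusters(vals, thr, edges)
    labels <- res$labels
    n <- res$n_clusters
  }
  structure(list(labels = labels, n_clusters = n, values = vals,
                 threshold = thr,
                 channel_ids = if (!is.null(m2)) m2$channel_ids else NULL,
                 times_ms = if (!is.null(m2)) m2$times_ms else NULL),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %d cluster(s) above %.4g on a %d x %d map\n",
              x$n_clusters, x$threshold, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Cluster attributes: height, extent, mass
#'
#' One row per cluster: `height` is the maximum statistic value among members,
#' `extent` the number of member points, `mass` the sum of member values.  For
#' the non-negative t-squared maps used in two-sided inference,
#' `height <= mass <= height * extent` always holds.
#'
#' @param labels a [label_clusters()] result.
#' @param map optional map to take values from; defaults to the map the labels
#'   were computed on (must have the same geometry).
#' @return A tibble with columns `cluster_id`, `height`, `extent`, `mass`,
#'   `peak_channel`, `peak_time_ms`.
#' @export
cluster_table <- function(labels, map = NULL) {
  stopifnot(inherits(labels, "cluster_labels"))
  vals <- if (is.null(map)) labels$values
          else if (inherits(map, "stat_map")) map$values
          else map
  if (!identical(dim(vals), dim(labels$labels)))
    stop_validation("map geometry does not match the labels")
  if (labels$n_clusters == 0L)
    return(tibble::tibble(cluster_id = integer(0), height = numeric(0),
                          extent = integer(0), mass = numeric(0),
                          peak_channel = character(0), peak_time_ms = numeric(0)))
  st <- cpp_cluster_stats(vals, labels$labels, labels$n_clusters)
  nchan <- nrow(vals)
  pk <- st$peak - 1L
  pc <- pk %% nchan + 1L
  pt <- pk %/% nchan + 1L
  chan_ids <- labels$channel_ids %||% sprintf("Ch%03d", seq_len(nchan))
  times <- labels$times_ms %||% (seq_len(ncol(vals)) - 1)
  tibble::tibble(cluster_id = seq_len(labels$n_clusters),
                 height = st$height, extent = st$extent, mass = st$mass,
                 peak_channel = chan_ids[pc], peak_time_ms = times[pt])
}

#' Export a cluster table as CSV
#' @param x a tibble from [cluster_table()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
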