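#' Channel adjacency graph
#'
#' The spatial neighbour relation between channels that drives spatiotemporal
#' clustering.  Two points of a statistic map are adjacent iff they are on the
#' same channel at consecutive time points, or on neighbouring channels (per
#' this graph) at the same time point; there are no diagonal
#' channel-and-time moves.  The graph is stored by channel *index* (position in
#' the epochs' `channel_ids`), is symmetric, and carries no self-edges: any
#' asymmetric input is closed symmetrically and self-edges are dropped.
#'
#' @param spec either a two-column matrix/data frame of channel index pairs
#'   (one edge per row), or a square 0/1 adjacency matrix.
#' @param n_channels number of channels; required for an edge-list `spec`
#'   (for a square matrix it defaults to its dimension).
#'
#' @return An object of class `adjacency_graph` with fields `n_channels` and
#'   `edges` (a 2-column integer matrix with `edges[, 1] < edges[, 2]`, ordered
#'   lexicographically).
#' @export
#' @examples
#' build_adjacency(cbind(c(1, 2), c(2, 3)), n_channels = 3)
build_adjacency <- function(spec, n_channels = NULL) {
  if (is.data.frame(spec)) spec <- as.matrix(spec)
  if (!is.matrix(spec)) stop_validation("`spec` must be a matrix or data frame")
  if (ncol(spec) == 2L && (is.null(n_channels) || nrow(spec) != n_channels ||
                           ncol(spec) != n_channels)) {
    # edge list
    if (is.null(n_channels))
      stop_validation("`n_channels` is required with an edge-list `spec`")
    n_channels <- check_count(n_channels, "n_channels")
    edges <- matrix(as.integer(spec), ncol = 2L)
    if (nrow(edges) > 0L) {
      if (anyNA(edges) || any(edges < 1L) || any(edges > n_channels))
        stop_validation("edge index out of range 1..%d", n_channels)
    }
  } else {
    # square 0/1 matrix
    if (nrow(spec) != ncol(spec))
      stop_validation("adjacency matrix must be square (got %d x %d)",
                      nrow(spec), ncol(spec))
    n_channels <- n_channels %||% nrow(spec)
    if (n_channels != nrow(spec))
      stop_validation("`n_channels` disagrees with the matrix dimension")
    idx <- which(spec != 0, arr.ind = TRUE)
    edges <- matrix(as.integer(idx), ncol = 2L)
  }
  # symmetric closure, drop self-edges, dedupe
  if (nrow(edges) > 0L) {
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    keep <- a != b
    ord <- order(a[keep], b[keep])
    key <- paste(a[keep][ord], b[keep][ord])
    uni <- !duplicated(key)
    edges <- cbind(a[keep][ord][uni], b[keep][ord][uni])
  } else {
    edges <- matrix(integer(0), ncol = 2L)
  }
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("chan_a", "chan_b")
  structure(list(n_channels = n_channels, edges = edges),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d channels, %d edges\n",
              x$n_channels, nrow(x$edges)))
  invisible(x)
}

#' Edge list of an adjacency graph as a tibble
#' @param x an `adjacency_graph`.
#' @param channel_ids optional labels; when given, label columns are returned
#'   instead of indices.
#' @return tibble with columns `chan_a`, `chan_b`.
#' @export
adjacency_edges <- function(x, channel_ids = NULL) {
  stopifnot(inherits(x, "adjacency_graph"))
  e <- x$edges
  if (is.null(channel_ids))
    return(tibble::tibble(chan_a = e[, 1], chan_b = e[, 2]))
  if (length(channel_ids) != x$n_channels)
    stop_validation("`channel_ids` must have length %d", x$n_channels)
  tibble::tibble(chan_a = channel_ids[e[, 1]], chan_b = channel_ids[e[, 2]])
}

#' Write an adjacency graph as a CSV edge list
#'
#' Columns `chan_a,chan_b`, holding channel labels.
#' @inheritParams adjacency_edges
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(x, path, channel_ids = NULL) {
  channel_ids <- channel_ids %||% sprintf("Ch%03d", seq_len(x$n_channels))
  df <- adjacency_edges(x, channel_ids)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an adjacency specification from CSV
#'
#' Accepts either an edge list with header `chan_a,chan_b` (labels resolved
#' against `channel_ids`) or a square 0/1 matrix whose header row carries the
#' channel labels in order.
#'
#' @param path CSV file.
#' @param channel_ids channel labels fixing the index order.  Required for the
#'   edge-list form; for the matrix form it defaults to the file's header.
#' @return An [build_adjacency()] graph.
#' @export
read_adjacency <- function(path, channel_ids = NULL) {
  if (!file.exists(path)) stop_format("adjacency file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 2L && identical(names(df), c("chan_a", "chan_b"))) {
    if (is.null(channel_ids))
      stop_validation("`channel_ids` is required to read an edge-list CSV")
    a <- match(as.character(df$chan_a), channel_ids)
    b <- match(as.character(df$chan_b), channel_ids)
    if (anyNA(a) || anyNA(b))
      stop_validation("edge list refers to unknown channel labels")
    build_adjacency(cbind(a, b), n_channels = length(channel_ids))
  } else {
    m <- as.matrix(df)
    if (nrow(m) != ncol(m))
      stop_validation("adjacency matrix must be square (got %d x %d)",
                      nrow(m), ncol(m))
    build_adjacency(m)
  }
}

# 2-col 1-based integer edge matrix for the C++ layer
edges_for_cpp <- function(adjacency, n_channels) {
  if (!inherits(adjacency, "adjacency_graph"))
    stop_validation("`adjacency` must be an adjacency_graph")
  if (adjacency$n_channels != n_channels)
    stop_validation("adjacency has %d channels but the map has %d",
                    adjacency$n_channels, n_channels)
  e <- adjacency$edges
  if (nrow(e) == 0L) matrix(integer(0), ncol = 2L) else e
}
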