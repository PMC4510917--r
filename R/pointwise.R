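#' Mass-univariate two-sample Student's t map
#'
#' Computes the classical pooled-variance (equal-variance) two-sample Student's
#' t statistic at every channel x time point, comparing the trials of `a`
#' against the trials of `b`.  The pooled form is used deliberately: all three
#' resampling engines pool or centre trials across conditions, which is the
#' setting in which the pooled t is exchangeable under the null.
#'
#' Degenerate points (pooled variance exactly zero) yield t = 0 when the group
#' means are also equal, and are capped at `t_cap` otherwise, so non-finite
#' values never reach the clustering stage.
#'
#' @param a,b `epochs_set` objects (or plain channels x time x trials arrays)
#'   with identical channel and time geometry; each needs at least 2 trials.
#' @param t_cap replacement magnitude for infinite t at zero-variance points
#'   (default 1e6).
#' @return A `stat_map`: list with `values` (channels x time matrix of t),
#'   `df` = n1 + n2 - 2, `squared = FALSE`, plus channel/time metadata.
#' @seealso [as_t2()], [forming_threshold()], [label_clusters()]
#' @export
#' @examples
#' a <- array(rnorm(4 * 10 * 8), c(4, 10, 8))
#' b <- array(rnorm(4 * 10 * 8), c(4, 10, 8))
#' m <- two_sample_t(a, b)
#' range(m$values)
two_sample_t <- function(a, b, t_cap = 1e6) {
  ga <- as_trial_matrix(a)
  gb <- as_trial_matrix(b)
  if (!identical(ga$geom, gb$geom))
    stop_validation("groups have different channel x time geometry")
  n1 <- ncol(ga$mat); n2 <- ncol(gb$mat)
  if (n1 < 2 || n2 < 2)
    stop_validation("insufficient data: each group needs at least 2 trials (got %d and %d)",
                    n1, n2)
  check_scalar_number(t_cap, "t_cap", lower = 0, strict_lower = TRUE)
  t2 <- cpp_t2_map(ga$mat, gb$mat, t_cap)
  # recover the sign from the mean difference
  md <- rowMeans(ga$mat) - rowMeans(gb$mat)
  tval <- sign(md) * sqrt(t2)
  new_stat_map(matrix(tval, ga$geom[1], ga$geom[2]), df = n1 + n2 - 2,
               squared = FALSE, channel_ids = ga$channel_ids,
               times = ga$times)
}

new_stat_map <- function(values, df, squared, channel_ids = NULL, times = NULL) {
  structure(list(values = values, df = df, squared = squared,
                 channel_ids = channel_ids %||% sprintf("Ch%03d", seq_len(nrow(values))),
                 times_ms = times %||% seq_len(ncol(values)) - 1),
            class = "stat_map")
}

# accepts epochs_set or 3-D array; returns flattened points x trials matrix
as_trial_matrix <- function(x) {
  if (inherits(x, "epochs_set")) {
    d <- dim(x$data)
    list(mat = flatten_epochs(x), geom = d[1:2], channel_ids = x$channel_ids,
         times = times_ms(x))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    list(mat = matrix(x, d[1] * d[2], d[3]), geom = d[1:2],
         channel_ids = NULL, times = NULL)
  } else {
    stop_validation("expected an epochs_set or a channels x time x trials array")
  }
}

#' Squared (t-squared) view of a statistic map
#'
#' Two-sided inference is carried on the t-squared map, which merges positive
#' and negative deflections; clustering and TFCE both operate on this
#' non-negative view.
#'
#' @param map a `stat_map`.
#' @return The same map with `values` squared and `squared = TRUE`; squaring a
#'   squared map is an error.
#' @export
as_t2 <- function(map) {
  stopifnot(inherits(map, "stat_map"))
  if (map$squared) stop_validation("map is already in the t-squared view")
  out <- map
  out$values <- map$values^2
  out$squared <- TRUE
  out
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d x %d %s values, df = %d\n", nrow(x$values),
              ncol(x$values), if (x$squared) "t^2" else "t", x$df))
  invisible(x)
}

#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    channel_id = rep(x$channel_ids, times = ncol(x$values)),
    time_ms = rep(x$times_ms, each = nrow(x$values)),
    value = as.vector(x$values))
}

#' Cluster-forming threshold from a univariate probability level
#'
#' Converts a two-sided pointwise probability threshold into the positive
#' Student critical value at the map's degrees of freedom: the upper-tail
#' quantile at `p/2`.  Points enter clusters when `t^2 > t_crit^2`.
#'
#' @param p two-sided univariate probability threshold, in (0, 1); the
#'   conventional choices are 0.05 and 0.01.
#' @param df degrees of freedom (>= 1).
#' @return A `cluster_forming` object: list with fields `p`, `df`, `t_crit`.
#' @export
#' @examples
#' forming_threshold(0.05, df = 98)$t_crit
forming_threshold <- function(p, df) {
  check_scalar_number(p, "p", lower = 0, upper = 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  check_scalar_number(df, "df", lower = 1)
  structure(list(p = p, df = df, t_crit = stats::qt(1 - p / 2, df = df)),
            class = "cluster_forming")
}

#' @export
print.cluster_forming <- function(x, ...) {
  cat(sprintf("<cluster_forming> p = %g, df = %g, t_crit = %.4f\n",
              x$p, x$df, x$t_crit))
  invisible(x)
}

#' Export a statistic map as CSV plus JSON metadata
#'
#' Channels as rows, time points as columns; metadata (df, squared flag, and
#' optionally the forming threshold) in `<path>.json`.
#'
#' @param map a `stat_map` (or `tfce_map`).
#' @param path CSV path.
#' @param forming optional [forming_threshold()] to record alongside.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, forming = NULL) {
  vals <- map$values
  rownames(vals) <- map$channel_ids
  colnames(vals) <- sprintf("%g", map$times_ms)
  utils::write.csv(vals, path, row.names = TRUE)
  meta <- list(df = map$df, squared = isTRUE(map$squared))
  if (!is.null(map$params)) meta$params <- map$params
  if (!is.null(forming)) meta <- c(meta, list(p = forming$p, t_crit = forming$t_crit))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
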