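SCHEMES <- c(permutation = 0L, percentile_bootstrap = 1L, bootstrap_t = 2L)

#' Resampling plan
#'
#' Describes how the null distribution of the max statistic is estimated:
#'
#' * `permutation` — the trials of both conditions are pooled and randomly
#'   re-split without replacement into groups of the original sizes; exact
#'   under exchangeability.
#' * `percentile_bootstrap` — the pooled trials are sampled *with* replacement
#'   (n1 + n2 draws, the first n1 forming group 1).
#' * `bootstrap_t` — each condition is first mean-centred at every channel x
#'   time point, then its own trials are sampled with replacement.
#'
#' Randomness is driven by a named counter-based generator (SplitMix64) with
#' one substream per iteration, so iteration `i` yields the same indices
#' whether iterations are drawn in order, out of order, or in parallel.
#'
#' @param scheme one of `"permutation"`, `"percentile_bootstrap"`,
#'   `"bootstrap_t"`.
#' @param n_iterations number of resampling iterations B (default 1000).
#' @param seed integer seed.
#' @param min_unique optional minimum number of distinct trials per resampled
#'   group (bootstrap schemes only); iterations violating it are redrawn, and
#'   an error is raised after 100 failed redraws.  Default `NULL` leaves the
#'   bootstrap unconstrained.
#' @return A `resampling_plan` object.
#' @export
resampling_plan <- function(scheme = c("permutation", "percentile_bootstrap",
                                       "bootstrap_t"),
                            n_iterations = 1000, seed = 1, min_unique = NULL) {
  scheme <- match.arg(scheme)
  n_iterations <- check_count(n_iterations, "n_iterations")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.null(min_unique)) min_unique <- check_count(min_unique, "min_unique")
  structure(list(scheme = scheme, n_iterations = n_iterations, seed = seed,
                 min_unique = min_unique %||% 0L),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("<resampling_plan> %s, B = %d, seed = %d%s\n", x$scheme,
              x$n_iterations, x$seed,
              if (x$min_unique > 0) sprintf(", min_unique = %d", x$min_unique) else ""))
  invisible(x)
}

#' Trial-index assignment for one resampling iteration
#'
#' Deterministic given `(plan$seed, iteration)`.  For the pooled schemes the
#' returned indices refer to the pooled trials `1..n1+n2` (condition A first);
#' for `bootstrap_t` each group indexes its own condition's trials.
#'
#' @param plan a [resampling_plan()].
#' @param n1,n2 trials per group (each >= 2).
#' @param iteration iteration number, `1..plan$n_iterations`.
#' @return list with integer vectors `idx1` (length n1) and `idx2` (length n2).
#' @export
resample_indices <- function(plan, n1, n2, iteration) {
  stopifnot(inherits(plan, "resampling_plan"))
  n1 <- check_count(n1, "n1", min = 2L)
  n2 <- check_count(n2, "n2", min = 2L)
  iteration <- check_count(iteration, "iteration")
  cpp_resample_indices(plan$seed, iteration, SCHEMES[[plan$scheme]], n1, n2,
                       plan$min_unique)
}

#' All distinct permutation splits (exhaustive mode)
#'
#' Enumerates every way of choosing which pooled trials form group 1; intended
#' as a small-sample test oracle (n1 + n2 <= 10).
#'
#' @param n1,n2 group sizes.
#' @return list of `choose(n1+n2, n1)` index lists like [resample_indices()].
#' @export
exhaustive_permutations <- function(n1, n2) {
  N <- n1 + n2
  if (N > 10) stop_validation("exhaustive mode is limited to n1 + n2 <= 10")
  sets <- utils::combn(N, n1)
  lapply(seq_len(ncol(sets)), function(j) {
    i1 <- sets[, j]
    list(idx1 = i1, idx2 = setdiff(seq_len(N), i1))
  })
}

#' Null distribution of per-iteration maxima
#'
#' Runs the full resampling loop: for every iteration, trials are reassigned
#' according to the plan's scheme (with per-condition mean-centring first for
#' `bootstrap_t`), the pooled-variance t-squared map is recomputed, and the
#' maximum of the chosen statistic over the whole channel x time space is
#' recorded — the maximum cluster height / extent / mass over all clusters at
#' the forming threshold (0 when no point survives it), the maximum TFCE
#' value over all points, or the maximum pointwise t-squared.
#'
#' @param a,b `epochs_set` objects or channels x time x trials arrays, as in
#'   [two_sample_t()].
#' @param plan a [resampling_plan()].
#' @param statistic one of `"height"`, `"extent"`, `"mass"`, `"tfce"`,
#'   `"pointwise_t2"`.
#' @param forming a [forming_threshold()]; required for the cluster statistics
#'   (defaults to p = 0.05 at the data's df), ignored for TFCE.
#' @param tfce a [tfce_params()] set, used when `statistic = "tfce"`.
#' @param adjacency an [build_adjacency()] graph.
#' @param t_cap cap for degenerate-variance t values.
#' @return A `null_distribution`: list with `statistic`, `maxima` (length B,
#'   all >= 0), `plan`, `forming` (or `tfce`), `df`.
#' @export
build_null <- function(a, b, plan, statistic = c("mass", "height", "extent",
                                                 "tfce", "pointwise_t2"),
                       forming = NULL, tfce = tfce_params(), adjacency,
                       t_cap = 1e6) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(plan, "resampling_plan"))
  ga <- as_trial_matrix(a)
  gb <- as_trial_matrix(b)
  if (!identical(ga$geom, gb$geom))
    stop_validation("groups have different channel x time geometry")
  n1 <- ncol(ga$mat); n2 <- ncol(gb$mat)
  if (n1 < 2 || n2 < 2)
    stop_validation("insufficient data: each group needs at least 2 trials")
  df <- n1 + n2 - 2
  cluster_stat <- statistic %in% c("mass", "height", "extent")
  if (cluster_stat && is.null(forming)) forming <- forming_threshold(0.05, df)
  if (cluster_stat && abs(forming$df - df) > 1e-9)
    stop_validation("forming threshold was computed at df = %g but the data give df = %d",
                    forming$df, df)
  edges <- edges_for_cpp(adjacency, ga$geom[1])
  res <- cpp_null_maxima(
    ga$mat, gb$mat, SCHEMES[[plan$scheme]], plan$n_iterations, plan$seed,
    plan$min_unique,
    form_thr = if (cluster_stat) forming$t_crit^2 else numeric(0),
    want_cluster = cluster_stat,
    tfce_E = if (statistic == "tfce") tfce$e else numeric(0),
    tfce_H = if (statistic == "tfce") tfce$h else numeric(0),
    dh = tfce$dh, h0 = tfce$h0,
    edges = edges, nchan = ga$geom[1], ntime = ga$geom[2], t_cap = t_cap)
  maxima <- switch(statistic,
                   mass = res$mass[, 1], height = res$height[, 1],
                   extent = res$extent[, 1], tfce = res$tfce[, 1],
                   pointwise_t2 = res$max_t2)
  structure(list(statistic = statistic, maxima = as.numeric(maxima),
                 plan = plan,
                 forming = if (cluster_stat) forming else NULL,
                 tfce = if (statistic == "tfce") tfce else NULL,
                 df = df),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> max %s over B = %d %s iterations (df = %d)\n",
              x$statistic, length(x$maxima), x$plan$scheme, x$df))
  invisible(x)
}

#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$maxima), max_statistic = x$maxima)
}

#' Family-wise error threshold from a null distribution
#'
#' The empirical 100(1 - alpha) percentile of the per-iteration maxima, using
#' the conservative rank rule: the value at sorted rank `ceiling((1 - alpha) *
#' B)`.  Observed statistics must *exceed* this value (strict inequality) to
#' be declared significant, which guarantees FWER <= alpha conditionally on
#' the null sample.
#'
#' @param null a [build_null()] result, or a bare numeric vector of maxima.
#' @param alpha critical family-wise error rate in (0, 1).
#' @return The threshold (a single number).
#' @export
#' @examples
#' fwe_threshold(1:1000, alpha = 0.05)  # 950
fwe_threshold <- function(null, alpha) {
  maxima <- if (inherits(null, "null_distribution")) null$maxima else null
  if (!is.numeric(maxima) || length(maxima) < 1L)
    stop_validation("`null` must hold at least one maximum")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  b <- length(maxima)
  sort(maxima)[conservative_rank(b, alpha)]
}

#' Threshold an observed map against a null distribution
#'
#' Cluster statistics: observed clusters (formed at the same threshold as the
#' null) survive iff their attribute strictly exceeds the FWE threshold; the
#' mask covers exactly the member points of surviving clusters.  TFCE: points
#' survive iff their enhanced value strictly exceeds the FWE threshold.
#'
#' @param observed a `stat_map` from [two_sample_t()] (either view; the
#'   t-squared view is used internally).
#' @param null a [build_null()] result built with matching parameters.
#' @param alpha critical family-wise error rate.
#' @param adjacency the same adjacency graph used for the null.
#' @return A `significance_result`: list with logical `mask`,
#'   `fwe_threshold`, `alpha`, `statistic`, and `surviving` (a
#'   [cluster_table()] tibble restricted to surviving clusters; `NULL` for
#'   TFCE and pointwise statistics).
#' @export
apply_correction <- function(observed, null, alpha, adjacency) {
  stopifnot(inherits(observed, "stat_map"), inherits(null, "null_distribution"))
  if (abs(observed$df - null$df) > 1e-9)
    stop_validation("configuration error: observed df = %g but null df = %g",
                    observed$df, null$df)
  thr <- fwe_threshold(null, alpha)
  m2 <- if (observed$squared) observed else as_t2(observed)
  statistic <- null$statistic
  if (statistic %in% c("mass", "height", "extent")) {
    labs <- label_clusters(m2, null$forming, adjacency)
    tab <- cluster_table(labs)
    keep <- tab[[statistic]] > thr
    mask <- matrix(labs$labels %in% tab$cluster_id[keep],
                   nrow(m2$values), ncol(m2$values))
    surviving <- tab[keep, , drop = FALSE]
  } else if (statistic == "tfce") {
    tm <- tfce_transform(m2, adjacency, null$tfce)
    mask <- tm$values > thr
    surviving <- NULL
  } else {  # pointwise_t2
    mask <- m2$values > thr
    surviving <- NULL
  }
  structure(list(mask = mask, fwe_threshold = thr, alpha = alpha,
                 statistic = statistic, surviving = surviving,
                 channel_ids = m2$channel_ids, times_ms = m2$times_ms),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance_result> %s at FWE alpha = %g: threshold %.4g, %d significant point(s)%s\n",
    x$statistic, x$alpha, x$fwe_threshold, sum(x$mask),
    if (!is.null(x$surviving)) sprintf(" in %d cluster(s)", nrow(x$surviving)) else ""))
  invisible(x)
}

#' @method tidy significance_result
#' @export
tidy.significance_result <- function(x, ...) {
  if (!is.null(x$surviving)) return(x$surviving)
  tibble::tibble(
    channel = rep(seq_len(nrow(x$mask)), times = ncol(x$mask)),
    channel_id = rep(x$channel_ids, times = ncol(x$mask)),
    time_ms = rep(x$times_ms, each = nrow(x$mask)),
    significant = as.vector(x$mask))
}

#' Export a null distribution (CSV column + JSON metadata)
#' @param x a `null_distribution`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(x, path) {
  utils::write.csv(data.frame(max_statistic = x$maxima), path, row.names = FALSE)
  meta <- list(scheme = x$plan$scheme, n_iterations = x$plan$n_iterations,
               seed = x$plan$seed, statistic_kind = x$statistic, df = x$df)
  if (!is.null(x$forming)) meta <- c(meta, list(forming_p = x$forming$p,
                                                t_crit = x$forming$t_crit))
  if (!is.null(x$tfce)) meta <- c(meta, list(E = x$tfce$e, H = x$tfce$h,
                                             dh = x$tfce$dh, h0 = x$tfce$h0))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a significance result (0/1 mask CSV + summary JSON)
#' @param x a `significance_result`.
#' @param path CSV path for the mask; summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_significance <- function(x, path) {
  utils::write.csv(matrix(as.integer(x$mask), nrow(x$mask)), path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(alpha = x$alpha, fwe_threshold = x$fwe_threshold,
         statistic = x$statistic,
         n_surviving_clusters = if (!is.null(x$surviving)) nrow(x$surviving)
                                else NA,
         n_significant_points = sum(x$mask)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
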