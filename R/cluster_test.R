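#' Corrected two-sample test over the full channel x time space
#'
#' One-stop pipeline: pointwise pooled-variance t map, spatiotemporal
#' clustering (or TFCE), resampled null distribution of the chosen max
#' statistic, and max-statistic FWE thresholding.  Defaults follow common
#' practice for ERP cluster inference: B = 1000 iterations, cluster-forming
#' p = 0.05, critical FWE alpha = 0.05, TFCE E = 0.5 / H = 2 / dh = 0.1.
#'
#' @param a,b `epochs_set` objects or channels x time x trials arrays.
#' @param adjacency an [build_adjacency()] graph.
#' @param statistic `"mass"` (default), `"height"`, `"extent"`, `"tfce"`, or
#'   `"pointwise_t2"`.
#' @param scheme resampling scheme, see [resampling_plan()].
#' @param forming_p univariate two-sided cluster-forming probability.
#' @param alpha critical family-wise error rate.
#' @param n_iterations resampling iterations B.
#' @param tfce a [tfce_params()] set (used when `statistic = "tfce"`).
#' @param seed integer seed for the resampling generator.
#' @param min_unique optional bootstrap constraint, see [resampling_plan()].
#' @param t_cap cap for degenerate-variance t values.
#' @return A `cluster_test` object bundling the observed `stat_map`, the
#'   `null_distribution`, and the `significance_result`.
#' @export
#' @examples
#' set.seed(1)
#' a <- array(rnorm(4 * 15 * 20), c(4, 15, 20))
#' b <- array(rnorm(4 * 15 * 20), c(4, 15, 20))
#' adj <- build_adjacency(cbind(1:3, 2:4), n_channels = 4)
#' fit <- cluster_test(a, b, adj, n_iterations = 200)
#' glance(fit)
cluster_test <- function(a, b, adjacency,
                         statistic = c("mass", "height", "extent", "tfce",
                                       "pointwise_t2"),
                         scheme = c("permutation", "percentile_bootstrap",
                                    "bootstrap_t"),
                         forming_p = 0.05, alpha = 0.05, n_iterations = 1000,
                         tfce = tfce_params(), seed = 1, min_unique = NULL,
                         t_cap = 1e6) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  observed <- two_sample_t(a, b, t_cap = t_cap)
  plan <- resampling_plan(scheme, n_iterations = n_iterations, seed = seed,
                          min_unique = min_unique)
  forming <- if (statistic %in% c("mass", "height", "extent"))
    forming_threshold(forming_p, observed$df) else NULL
  null <- build_null(a, b, plan, statistic = statistic, forming = forming,
                     tfce = tfce, adjacency = adjacency, t_cap = t_cap)
  result <- apply_correction(observed, null, alpha, adjacency)
  structure(list(observed = observed, null = null, result = result,
                 plan = plan, alpha = alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  print(x$observed)
  print(x$null)
  print(x$result)
  invisible(x)
}

#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) {
  tidy(x$result)
}

#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$null$statistic,
    scheme = x$plan$scheme,
    df = x$observed$df,
    forming_p = if (!is.null(x$null$forming)) x$null$forming$p else NA_real_,
    alpha = x$alpha,
    n_iterations = x$plan$n_iterations,
    fwe_threshold = x$result$fwe_threshold,
    n_significant_points = sum(x$result$mask),
    n_surviving_clusters = if (!is.null(x$result$surviving))
      nrow(x$result$surviving) else NA_integer_)
}
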