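#' Configuration of a Monte-Carlo FWER experiment
#'
#' Describes the full validation design: for each Monte-Carlo replicate a null
#' trial pool is randomly split into two pseudo-conditions, the corrected test
#' is run for every combination of resampling scheme, statistic and
#' (forming p, critical alpha) level, and the realised family-wise error rate
#' is the proportion of replicates with at least one significant point.
#'
#' Sample sizes are drawn *by increment*: the trials used at size n are a
#' prefix of those used at the next size, mirroring the incremental design of
#' data-driven FWER simulations.  Convergence over the number of resampling
#' iterations reuses nested prefixes of a single iteration stream per
#' replicate, isolating the effect of B.
#'
#' `forming_p` and `alpha` are paired element-wise (forming p = 0.05 with
#' critical alpha = 0.05, and 0.01 with 0.01, by default).  TFCE needs no
#' forming threshold and is evaluated at every distinct `alpha`.
#'
#' @param sample_sizes trials per group (default the full incremental ladder
#'   10, 25, 50, 100, 300, 500, 900).
#' @param n_mc Monte-Carlo replicates (default 1000).
#' @param schemes subset of the three resampling schemes.
#' @param statistics subset of `"mass"`, `"height"`, `"extent"`, `"tfce"`.
#' @param forming_p,alpha paired vectors of cluster-forming probabilities and
#'   critical FWE rates (equal length).
#' @param tfce_param_sets list of [tfce_params()] (or `c(e, h)` pairs) when
#'   `"tfce"` is among the statistics.
#' @param n_iterations resampling iterations B per null distribution.
#' @param eval_iterations iteration count at which the headline FWER, masks
#'   and agreement are evaluated (a prefix of the stream; default
#'   `n_iterations`).
#' @param iteration_grid iteration counts for the convergence curve (default
#'   200 to `n_iterations` by 200); all values must be `<= n_iterations`.
#' @param seed integer seed governing splits and resampling.
#' @param t_cap degenerate-variance cap.
#' @return An `fwer_config` object.
#' @export
fwer_config <- function(sample_sizes = c(10, 25, 50, 100, 300, 500, 900),
                        n_mc = 1000,
                        schemes = c("permutation", "percentile_bootstrap",
                                    "bootstrap_t"),
                        statistics = "mass",
                        forming_p = c(0.05, 0.01), alpha = c(0.05, 0.01),
                        tfce_param_sets = list(tfce_params()),
                        n_iterations = 1000, eval_iterations = NULL,
                        iteration_grid = NULL, seed = 1, t_cap = 1e6) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  statistics <- match.arg(statistics, c("mass", "height", "extent", "tfce"),
                          several.ok = TRUE)
  sample_sizes <- sort(unique(vapply(sample_sizes, check_count, 1L,
                                     name = "sample_sizes", min = 2L)))
  n_mc <- check_count(n_mc, "n_mc")
  n_iterations <- check_count(n_iterations, "n_iterations")
  eval_iterations <- check_count(eval_iterations %||% n_iterations,
                                 "eval_iterations")
  if (eval_iterations > n_iterations)
    stop_validation("`eval_iterations` exceeds `n_iterations`")
  if (length(forming_p) != length(alpha))
    stop_validation("`forming_p` and `alpha` must be paired (equal length)")
  for (p in c(forming_p, alpha))
    check_scalar_number(p, "forming_p/alpha", lower = 0, upper = 1,
                        strict_lower = TRUE, strict_upper = TRUE)
  iteration_grid <- iteration_grid %||%
    unique(pmin(seq(200L, n_iterations, by = 200L), n_iterations))
  iteration_grid <- sort(unique(c(vapply(iteration_grid, check_count, 1L,
                                         name = "iteration_grid"),
                                  eval_iterations)))
  if (max(iteration_grid) > n_iterations)
    stop_validation("`iteration_grid` exceeds n_iterations = %d", n_iterations)
  tfce_param_sets <- lapply(tfce_param_sets, function(ps) {
    if (inherits(ps, "tfce_params")) ps else tfce_params(ps[[1]], ps[[2]])
  })
  structure(list(sample_sizes = sample_sizes, n_mc = n_mc, schemes = schemes,
                 statistics = statistics, forming_p = forming_p, alpha = alpha,
                 tfce_param_sets = tfce_param_sets,
                 n_iterations = n_iterations,
                 eval_iterations = eval_iterations,
                 iteration_grid = iteration_grid,
                 seed = check_count(seed, "seed", min = 0L), t_cap = t_cap),
            class = "fwer_config")
}

#' @export
print.fwer_config <- function(x, ...) {
  cat(sprintf(
    "<fwer_config> %d MC x sizes {%s} x schemes {%s} x stats {%s}, B = %d (eval %d)\n",
    x$n_mc, paste(x$sample_sizes, collapse = ", "),
    paste(x$schemes, collapse = ", "), paste(x$statistics, collapse = ", "),
    x$n_iterations, x$eval_iterations))
  invisible(x)
}

# one row per reported statistic-level combination
config_combos <- function(config) {
  rows <- list()
  cl <- setdiff(config$statistics, "tfce")
  for (s in cl) {
    for (f in seq_along(config$forming_p)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        statistic = s, kind = "cluster", forming_idx = f,
        forming_p = config$forming_p[f], alpha = config$alpha[f],
        tfce_idx = NA_integer_)
    }
  }
  if ("tfce" %in% config$statistics) {
    for (k in seq_along(config$tfce_param_sets)) {
      ps <- config$tfce_param_sets[[k]]
      for (a in unique(config$alpha)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          statistic = sprintf("tfce_e%g_h%g", ps$e, ps$h), kind = "tfce",
          forming_idx = NA_integer_, forming_p = NA_real_, alpha = a,
          tfce_idx = k)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# rank of the conservative empirical quantile; the epsilon guards against
# binary floating point pushing an exact product like 0.95 * k past its integer
conservative_rank <- function(k, alpha) ceiling((1 - alpha) * k - 1e-9)

#' Run a Monte-Carlo FWER experiment on a null trial pool
#'
#' For each replicate, `2 * max(sample_sizes)` trials are drawn from the pool
#' without replacement and split into two pseudo-conditions (smaller sizes use
#' nested prefixes).  Every configured correction is applied and the
#' significance decision recorded, along with the surviving-cluster sets (for
#' exact mask-agreement comparisons) and the decisions at every iteration
#' count in the convergence grid.
#'
#' @param pool an [epochs_set()] of exchangeable null trials, or the list
#'   returned by [generate_null_trials()].
#' @param config an [fwer_config()].
#' @param adjacency adjacency graph; defaults to the pool's own graph when
#'   `pool` comes from [generate_null_trials()].
#' @return An `fwer_experiment` with tibbles `cells` (per-cell FWER at
#'   `eval_iterations`), `convergence` (FWER per iteration count), and
#'   `replicates` (per-replicate decisions and surviving-cluster keys).
#' @export
run_fwer_experiment <- function(pool, config, adjacency = NULL) {
  if (is.list(pool) && !inherits(pool, "epochs_set") &&
      inherits(pool$epochs, "epochs_set")) {
    adjacency <- adjacency %||% pool$adjacency
    pool <- pool$epochs
  }
  stopifnot(inherits(pool, "epochs_set"), inherits(config, "fwer_config"))
  if (is.null(adjacency)) stop_validation("`adjacency` is required")
  d <- dim(pool$data)
  nchan <- d[1]; ntime <- d[2]; n_pool <- d[3]
  maxn <- max(config$sample_sizes)
  if (n_pool < 2 * maxn)
    stop_validation(
      "configuration error: pool has %d trials but 2 x %d are needed per replicate",
      n_pool, maxn)
  edges <- edges_for_cpp(adjacency, nchan)
  pm <- flatten_epochs(pool)
  combos <- config_combos(config)
  n_combo <- nrow(combos)
  cmb_kind <- combos$kind; cmb_stat <- combos$statistic
  cmb_fidx <- combos$forming_idx; cmb_fp <- combos$forming_p
  cmb_alpha <- combos$alpha; cmb_tidx <- combos$tfce_idx
  kgrid <- config$iteration_grid
  keval <- config$eval_iterations
  schemes <- config$schemes
  sizes <- config$sample_sizes
  any_cluster <- any(combos$kind == "cluster")
  tf_sets <- config$tfce_param_sets
  use_tfce <- any(combos$kind == "tfce")
  tf_e <- if (use_tfce) vapply(tf_sets, `[[`, 1, "e") else numeric(0)
  tf_h <- if (use_tfce) vapply(tf_sets, `[[`, 1, "h") else numeric(0)
  tf_dh <- if (use_tfce) tf_sets[[1]]$dh else 0.1
  tf_h0 <- if (use_tfce) tf_sets[[1]]$h0 else 0

  # derived seeds: one for the condition splits, one per (replicate, scheme)
  seeds <- with_local_seed(config$seed, {
    list(split = sample.int(.Machine$integer.max - 1L, 1L),
         plan = matrix(sample.int(.Machine$integer.max - 1L,
                                  config$n_mc * length(schemes)),
                       config$n_mc, length(schemes)))
  })

  n_rows <- config$n_mc * length(sizes) * length(schemes) * n_combo
  out_mc <- integer(n_rows); out_n <- integer(n_rows)
  out_scheme <- character(n_rows); out_stat <- character(n_rows)
  out_fp <- numeric(n_rows); out_alpha <- numeric(n_rows)
  out_obs <- numeric(n_rows); out_thr <- numeric(n_rows)
  out_rej <- logical(n_rows); out_surv <- character(n_rows)
  conv_rej <- array(0L, c(length(sizes), length(schemes), n_combo,
                          length(kgrid)))
  row <- 0L

  for (rep_i in seq_len(config$n_mc)) {
    prm <- cpp_permute(seeds$split, rep_i, n_pool)
    ia <- prm[seq_len(maxn)]
    ib <- prm[maxn + seq_len(maxn)]
    for (si in seq_along(sizes)) {
      n <- sizes[si]
      xa <- pm[, ia[seq_len(n)], drop = FALSE]
      xb <- pm[, ib[seq_len(n)], drop = FALSE]
      df <- 2L * n - 2L
      thr2 <- stats::qt(1 - config$forming_p / 2, df = df)^2
      t2 <- cpp_t2_map(xa, xb, config$t_cap)
      t2m <- matrix(t2, nchan, ntime)
      # observed cluster attributes per forming level
      obs_tab <- vector("list", length(thr2))
      if (any_cluster) {
        for (f in seq_along(thr2)) {
          lab <- cpp_label_clusters(t2m, thr2[f], edges)
          obs_tab[[f]] <- if (lab$n_clusters > 0)
            cpp_cluster_stats(t2m, lab$labels, lab$n_clusters)
          else list(height = numeric(0), extent = integer(0), mass = numeric(0))
        }
      }
      obs_tfce_max <- if (use_tfce) {
        maps <- cpp_tfce(t2m, edges, tf_e, tf_h, tf_dh, tf_h0)
        vapply(maps, max, 1)
      } else numeric(0)

      for (sc in seq_along(schemes)) {
        eng <- cpp_null_maxima(
          xa, xb, SCHEMES[[schemes[sc]]], config$n_iterations,
          seeds$plan[rep_i, sc], 0L,
          form_thr = if (any_cluster) thr2 else numeric(0),
          want_cluster = any_cluster, tfce_E = tf_e, tfce_H = tf_h,
          dh = tf_dh, h0 = tf_h0, edges = edges, nchan = nchan,
          ntime = ntime, t_cap = config$t_cap)
        for (ci in seq_len(n_combo)) {
          if (cmb_kind[ci] == "cluster") {
            maxima <- eng[[cmb_stat[ci]]][, cmb_fidx[ci]]
            attrs <- as.numeric(obs_tab[[cmb_fidx[ci]]][[cmb_stat[ci]]])
            obs_stat <- if (length(attrs)) max(attrs) else 0
          } else {
            maxima <- eng$tfce[, cmb_tidx[ci]]
            obs_stat <- obs_tfce_max[cmb_tidx[ci]]
            attrs <- NULL
          }
          thr_eval <- NA_real_
          for (ki in seq_along(kgrid)) {
            k <- kgrid[ki]
            thr_k <- sort(maxima[seq_len(k)])[conservative_rank(k, cmb_alpha[ci])]
            if (obs_stat > thr_k)
              conv_rej[si, sc, ci, ki] <- conv_rej[si, sc, ci, ki] + 1L
            if (k == keval) thr_eval <- thr_k
          }
          row <- row + 1L
          out_mc[row] <- rep_i; out_n[row] <- n
          out_scheme[row] <- schemes[sc]; out_stat[row] <- cmb_stat[ci]
          out_fp[row] <- cmb_fp[ci]; out_alpha[row] <- cmb_alpha[ci]
          out_obs[row] <- obs_stat; out_thr[row] <- thr_eval
          out_rej[row] <- obs_stat > thr_eval
          out_surv[row] <- if (!is.null(attrs))
            paste(which(attrs > thr_eval), collapse = ",") else NA_character_
        }
      }
    }
  }

  replicates <- tibble::tibble(
    mc = out_mc, n = out_n, scheme = out_scheme, statistic = out_stat,
    forming_p = out_fp, alpha = out_alpha, observed = out_obs,
    fwe_threshold = out_thr, reject = out_rej, survivors = out_surv)
  cells <- replicates |>
    dplyr::group_by(.data$scheme, .data$statistic, .data$forming_p,
                    .data$alpha, .data$n) |>
    dplyr::summarise(n_mc = dplyr::n(), n_reject = sum(.data$reject),
                     fwer = mean(.data$reject), .groups = "drop")
  conv <- expand.grid(si = seq_along(sizes), sc = seq_along(schemes),
                      ci = seq_len(n_combo), ki = seq_along(kgrid))
  convergence <- tibble::tibble(
    scheme = schemes[conv$sc],
    statistic = combos$statistic[conv$ci],
    forming_p = combos$forming_p[conv$ci],
    alpha = combos$alpha[conv$ci],
    n = sizes[conv$si],
    iterations = kgrid[conv$ki],
    n_mc = config$n_mc,
    n_reject = conv_rej[cbind(conv$si, conv$sc, conv$ci, conv$ki)],
    fwer = conv_rej[cbind(conv$si, conv$sc, conv$ci, conv$ki)] / config$n_mc) |>
    dplyr::arrange(.data$scheme, .data$statistic, .data$forming_p,
                   .data$alpha, .data$n, .data$iterations)
  structure(list(cells = cells, convergence = convergence,
                 replicates = replicates, config = config),
            class = "fwer_experiment")
}

#' @export
print.fwer_experiment <- function(x, ...) {
  cat(sprintf("<fwer_experiment> %d MC replicates, %d cells\n",
              x$config$n_mc, nrow(x$cells)))
  print(x$cells, n = 20)
  invisible(x)
}

#' @method tidy fwer_experiment
#' @export
tidy.fwer_experiment <- function(x, ...) x$cells

#' Convergence of the realised FWER over iteration counts
#'
#' Either extracts the convergence table from a fitted experiment, or runs the
#' experiment first.  FWER at iteration count k reuses the first k iterations
#' of each replicate's null stream (nested prefixes, not independent re-runs),
#' so the curve isolates the effect of B.  The value at `k = eval_iterations`
#' equals the headline FWER exactly.
#'
#' @param x an `fwer_experiment`, or a pool as in [run_fwer_experiment()].
#' @param ... passed to [run_fwer_experiment()] when `x` is a pool.
#' @return tibble with one row per (cell, iteration count).
#' @export
convergence_curve <- function(x, ...) {
  if (!inherits(x, "fwer_experiment")) x <- run_fwer_experiment(x, ...)
  x$convergence
}

#' Exact agreement between corrected masks of two schemes
#'
#' Two corrections "agree" on a replicate when their corrected masks are
#' identical — for cluster statistics, when exactly the same observed clusters
#' survive (under the null almost all masks are empty, so agreement is
#' typically very high).  Computed from the surviving-cluster keys stored per
#' replicate.
#'
#' @param x an `fwer_experiment` whose config includes both schemes.
#' @param scheme_a,scheme_b the two schemes to compare.
#' @param by optional grouping columns (e.g. `"n"`).
#' @return tibble with `n_compared` and `prop_identical` (plus `by` columns).
#' @export
scheme_agreement <- function(x, scheme_a, scheme_b, by = NULL) {
  stopifnot(inherits(x, "fwer_experiment"))
  r <- x$replicates |> dplyr::filter(!is.na(.data$survivors))
  a <- r |> dplyr::filter(.data$scheme == scheme_a)
  b <- r |> dplyr::filter(.data$scheme == scheme_b)
  keys <- c("mc", "n", "statistic", "forming_p", "alpha")
  j <- dplyr::inner_join(a, b, by = keys, suffix = c("_a", "_b"))
  if (nrow(j) == 0L) stop_validation("schemes not found in the experiment")
  j |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character(0)))) |>
    dplyr::summarise(
      n_compared = dplyr::n(),
      prop_identical = mean(.data$survivors_a == .data$survivors_b),
      .groups = "drop")
}

#' Exact and pointwise agreement between two mask streams
#'
#' The headline metric is the proportion of replicates on which the two masks
#' are identical; the mean pointwise agreement (fraction of matching points)
#' is returned alongside as a diagnostic.
#'
#' @param masks_a,masks_b lists of logical matrices of equal length and
#'   geometry.
#' @return list with `prop_identical` and `mean_pointwise`.
#' @export
mask_agreement <- function(masks_a, masks_b) {
  if (length(masks_a) != length(masks_b))
    stop_validation("mask streams have different lengths (%d vs %d)",
                    length(masks_a), length(masks_b))
  same <- vapply(seq_along(masks_a), function(i)
    identical(dim(masks_a[[i]]), dim(masks_b[[i]])) &&
      all(masks_a[[i]] == masks_b[[i]]), TRUE)
  pw <- vapply(seq_along(masks_a), function(i)
    mean(masks_a[[i]] == masks_b[[i]]), 1)
  list(prop_identical = mean(same), mean_pointwise = mean(pw))
}

trimmed_mean <- function(x, trim = 0.2) {
  g <- floor(trim * length(x))
  mean(sort(x)[(g + 1):(length(x) - g)])
}

#' Location summaries of FWER estimates with percentile-bootstrap CIs
#'
#' Mean, 20% trimmed mean (discarding `floor(0.2 n)` values at each end) and
#' median, each with a percentile-bootstrap confidence interval.  For
#' simultaneous coverage over several comparisons the per-comparison level is
#' adjusted by `n_comparisons` (Bonferroni by default; Šidák,
#' `1 - level^(1/m)`, as an alternative convention).
#'
#' @param data numeric vector of FWER estimates, or a data frame.
#' @param value column holding the estimates when `data` is a data frame.
#' @param ci_level simultaneous confidence level (default 0.95).
#' @param adjust `"bonferroni"`, `"sidak"` or `"none"`.
#' @param n_comparisons number of simultaneous comparisons (default 1).
#' @param b_ci bootstrap resamples for the CIs (default 2000).
#' @param trim trim fraction for the trimmed mean.
#' @param seed seed for the bootstrap.
#' @return tibble with columns `statistic`, `estimate`, `conf_low`,
#'   `conf_high`, `conf_level` (the per-comparison level used).
#' @export
#' @examples
#' summarize_fwer(c(0.048, 0.052, 0.05, 0.055, 0.047))
summarize_fwer <- function(data, value = NULL, ci_level = 0.95,
                           adjust = c("bonferroni", "sidak", "none"),
                           n_comparisons = 1, b_ci = 2000, trim = 0.2,
                           seed = 1) {
  adjust <- match.arg(adjust)
  x <- if (is.data.frame(data)) {
    dplyr::pull(data, {{ value }})
  } else {
    as.numeric(data)
  }
  if (length(x) < 2L)
    stop_validation("insufficient data: at least 2 values are needed")
  m <- check_count(n_comparisons, "n_comparisons")
  alpha <- switch(adjust,
                  bonferroni = (1 - ci_level) / m,
                  sidak = 1 - ci_level^(1 / m),
                  none = 1 - ci_level)
  stats_fns <- list(mean = mean, trimmed_mean = function(v) trimmed_mean(v, trim),
                    median = stats::median)
  boot <- with_local_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * b_ci, replace = TRUE),
                  ncol = b_ci)
    apply(idx, 2L, function(i) vapply(stats_fns, function(f) f(x[i]), 1))
  })
  purrr::map_dfr(seq_along(stats_fns), function(i) {
    ci <- stats::quantile(boot[i, ], c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tibble::tibble(statistic = names(stats_fns)[i],
                   estimate = stats_fns[[i]](x),
                   conf_low = ci[1], conf_high = ci[2],
                   conf_level = 1 - alpha)
  })
}

#' Pairwise differences between techniques with bootstrap CIs
#'
#' Reshapes a tidy FWER table so each cell (all columns other than `group` and
#' `value`) is one paired observation, then summarises the element-wise
#' difference between every pair of groups with a percentile bootstrap of the
#' mean difference.
#'
#' @param data tidy data frame of per-cell FWER values.
#' @param value column holding the values.
#' @param group column identifying the technique.
#' @inheritParams summarize_fwer
#' @return tibble with one row per ordered pair: `group_a`, `group_b`,
#'   `mean_difference`, `conf_low`, `conf_high`.
#' @export
fwer_pairwise <- function(data, value, group, ci_level = 0.95,
                          adjust = c("bonferroni", "sidak", "none"),
                          n_comparisons = NULL, b_ci = 2000, seed = 1) {
  adjust <- match.arg(adjust)
  groups <- unique(as.character(dplyr::pull(data, {{ group }})))
  wide <- tidyr::pivot_wider(data, names_from = {{ group }},
                             values_from = {{ value }})
  pairs <- utils::combn(groups, 2L)
  m <- n_comparisons %||% ncol(pairs)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    d <- wide[[pairs[1, j]]] - wide[[pairs[2, j]]]
    s <- summarize_fwer(d, ci_level = ci_level, adjust = adjust,
                        n_comparisons = m, b_ci = b_ci, seed = seed)
    s1 <- s[s$statistic == "mean", ]
    tibble::tibble(group_a = pairs[1, j], group_b = pairs[2, j],
                   mean_difference = s1$estimate, conf_low = s1$conf_low,
                   conf_high = s1$conf_high, conf_level = s1$conf_level)
  })
}

#' Multi-dataset FWER study
#'
#' Generates `n_datasets` independent synthetic null pools from `spec`
#' (fresh seed per dataset) and runs the configured experiment on each,
#' binding the per-dataset tables with a `dataset` column.  This is the
#' driver used to reproduce table-style summaries of the realised FWER
#' averaged across datasets.
#'
#' @param spec a [synth_spec()]; its seed field is re-derived per dataset.
#' @param config an [fwer_config()]; its seed is re-derived per dataset.
#' @param n_datasets number of synthetic datasets (default 5).
#' @param seed master seed for the per-dataset seeds.
#' @return An `fwer_study`: list of tibbles `cells`, `convergence`,
#'   `replicates` (each with a `dataset` column) plus the inputs.
#' @export
run_fwer_study <- function(spec, config, n_datasets = 5, seed = 1) {
  stopifnot(inherits(spec, "synth_spec"), inherits(config, "fwer_config"))
  n_datasets <- check_count(n_datasets, "n_datasets")
  ds_seeds <- with_local_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, 2L * n_datasets), ncol = 2L))
  runs <- lapply(seq_len(n_datasets), function(i) {
    sp <- spec; sp$seed <- ds_seeds[i, 1]
    cf <- config; cf$seed <- ds_seeds[i, 2]
    pool <- generate_null_trials(sp)
    run_fwer_experiment(pool, cf)
  })
  bind_with_ds <- function(field)
    dplyr::bind_rows(lapply(seq_along(runs), function(i)
      dplyr::mutate(runs[[i]][[field]], dataset = i, .before = 1L)))
  structure(list(cells = bind_with_ds("cells"),
                 convergence = bind_with_ds("convergence"),
                 replicates = bind_with_ds("replicates"),
                 spec = spec, config = config, n_datasets = n_datasets,
                 experiments = runs),
            class = "fwer_study")
}

#' @export
print.fwer_study <- function(x, ...) {
  cat(sprintf("<fwer_study> %d synthetic datasets\n", x$n_datasets))
  print(x$cells |>
          dplyr::group_by(.data$scheme, .data$statistic, .data$forming_p,
                          .data$alpha) |>
          dplyr::summarise(mean_fwer = mean(.data$fwer), .groups = "drop"))
  invisible(x)
}

#' @method tidy fwer_study
#' @export
tidy.fwer_study <- function(x, ...) x$cells

#' Export FWER results as tidy CSVs
#' @param x an `fwer_experiment` or `fwer_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fwer_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x$cells), file.path(dir, "fwer_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$convergence),
                   file.path(dir, "fwer_convergence.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_mc = x$config$n_mc %||% x$n_datasets,
         generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "fwer_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
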