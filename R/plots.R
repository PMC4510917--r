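# ggplot2 views of the result objects

raster_plot <- function(df, fill_lab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (ms)", y = "channel", fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, ...) {
  raster_plot(tidy(object), if (object$squared) "t^2" else "t")
}

#' @method autoplot tfce_map
#' @export
autoplot.tfce_map <- function(object, ...) {
  raster_plot(tidy(object),
              sprintf("TFCE (E=%g, H=%g)", object$params$e, object$params$h))
}

#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, alpha = 0.05, ...) {
  thr <- fwe_threshold(object, alpha)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$max_statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = sprintf("max %s per iteration", object$statistic),
                  y = "count",
                  title = sprintf("FWE threshold at alpha = %g: %.4g",
                                  alpha, thr)) +
    ggplot2::theme_minimal()
}

#' @method autoplot significance_result
#' @export
autoplot.significance_result <- function(object, ...) {
  df <- tibble::tibble(
    channel = rep(seq_len(nrow(object$mask)), times = ncol(object$mask)),
    time_ms = rep(object$times_ms, each = nrow(object$mask)),
    value = as.vector(object$mask))
  raster_plot(df, "significant")
}

#' Convergence curves of the realised FWER
#' @param object an `fwer_experiment` or `fwer_study`.
#' @param ... unused.
#' @method autoplot fwer_experiment
#' @export
autoplot.fwer_experiment <- function(object, ...) {
  df <- convergence_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iterations, y = .data$fwer,
                                   colour = factor(.data$n),
                                   linetype = .data$scheme)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        colour = "grey50", linetype = 3) +
    ggplot2::facet_grid(statistic ~ alpha, scales = "free_y") +
    ggplot2::labs(x = "resampling iterations", y = "type-1 FWER",
                  colour = "trials/group", linetype = "scheme") +
    ggplot2::theme_minimal()
}

#' @method autoplot fwer_study
#' @export
autoplot.fwer_study <- function(object, ...) {
  df <- object$cells
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$fwer,
                                   colour = .data$scheme)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        colour = "grey50", linetype = 3) +
    ggplot2::facet_grid(statistic ~ alpha, scales = "free_y") +
    ggplot2::labs(x = "trials per group", y = "type-1 FWER",
                  colour = "scheme") +
    ggplot2::theme_minimal()
}
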