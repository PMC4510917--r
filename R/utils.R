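# input checking helpers; all user-facing errors are classed so callers and
# the command-line wrapper can distinguish validation from format problems

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "erpcluster_validation_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "erpcluster_format_error")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("`%s` must be a single finite number", name)
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi)
    stop_validation("`%s` = %g is outside its valid range", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_validation("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
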