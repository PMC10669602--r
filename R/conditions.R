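# Classed conditions so callers (and the pipeline) can distinguish domain
# errors, data-validation errors, usage errors, and numerical failures.

oxex_stop <- function(message, class) {
  stop(structure(
    class = c(class, "oxex_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_domain <- function(message) oxex_stop(message, "oxex_domain_error")
stop_validation <- function(message) oxex_stop(message, "oxex_validation_error")
stop_usage <- function(message) oxex_stop(message, "oxex_usage_error")
stop_fit <- function(message) oxex_stop(message, "oxex_fit_error")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be a single non-missing number", name))
  }
  if (!allow_infinite && !is.finite(x)) {
    stop_domain(sprintf("`%s` must be finite", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}
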