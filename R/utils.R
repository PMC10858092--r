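abort_domain <- function(msg) {
  rlang::abort(msg, class = "endurofit_error_domain")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_positive_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_domain(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

check_nonnegative_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_domain(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

# log(exp(a) - exp(b)) for a > b, stable for large a, b
log_diff_exp <- function(a, b) {
  if (b >= a) abort_domain("log_diff_exp() requires a > b.")
  a + log1p(-exp(b - a))
}
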