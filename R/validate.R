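# Internal validation helpers. All user-facing validation errors carry the
# class "bim_validation_error"; violations of a numeric range additionally
# carry "bim_range_error", unknown parameter paths carry "bim_lookup_error".

abort_validation <- function(field, msg, class = character()) {
  rlang::abort(
    sprintf("Invalid value for `%s`: %s.", field, msg),
    class = c(class, "bim_validation_error")
  )
}

abort_range <- function(field, msg) {
  abort_validation(field, msg, class = "bim_range_error")
}

abort_lookup <- function(path) {
  rlang::abort(
    sprintf("Unknown parameter path `%s`.", path),
    class = "bim_lookup_error"
  )
}

check_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(field, "must be a single finite number")
  }
  invisible(x)
}

check_prob <- function(x, field) {
  check_scalar_number(x, field)
  if (x < 0 || x > 1) abort_range(field, "must lie in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  check_scalar_number(x, field)
  if (x < 0) abort_range(field, "must be >= 0")
  invisible(x)
}

check_min1 <- function(x, field) {
  check_scalar_number(x, field)
  if (x < 1) abort_range(field, "must be >= 1")
  invisible(x)
}
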