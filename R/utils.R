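# Internal validation helpers. Error conditions carry subclasses so callers
# (and tests) can distinguish invalid parameters from degenerate data.

stop_invalid <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_invalid_parameter", "bedsweep_error"))
}

stop_empty <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_empty_input", "bedsweep_error"))
}

stop_degenerate_labels <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_degenerate_labels", "bedsweep_error"))
}

stop_invalid_design <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_invalid_design", "bedsweep_error"))
}

stop_schema <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_schema_error", "bedsweep_error"))
}

stop_calibration <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_calibration_error", "bedsweep_error"))
}

stop_degenerate_outcome <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_degenerate_outcome", "bedsweep_error"))
}

stop_undefined_test <- function(msg) {
  rlang::abort(msg, class = c("bedsweep_undefined_test", "bedsweep_error"))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("`%s` must be finite and strictly positive.", name))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 1) || any(x != floor(x))) {
    stop_invalid(sprintf("`%s` must be a positive whole number.", name))
  }
  invisible(x)
}

# Coerce an outcome vector to logical; accepts logical or numeric 0/1.
as_binary_label <- function(labels, name = "labels") {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop_invalid(sprintf("`%s` must be logical or numeric 0/1.", name))
}
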