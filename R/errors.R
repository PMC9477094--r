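# Typed condition helpers. Every user-facing failure mode has its own
# condition class so callers (and the CLI) can branch on it instead of
# matching message text. Undefined ratios are errors, never Inf/NaN.

pgx_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pgxcea_error"), ...)
}

abort_validation <- function(message, ...) {
  pgx_abort(message, class = "pgxcea_validation_error", ...)
}

abort_undefined <- function(what, message) {
  # what: "nng", "cea" or "rrr"
  pgx_abort(message, class = paste0("pgxcea_undefined_", what))
}

abort_io <- function(message, ...) {
  pgx_abort(message, class = "pgxcea_io_error", ...)
}

abort_not_bracketed <- function(message) {
  pgx_abort(message, class = "pgxcea_not_bracketed_error")
}

check_number <- function(x, name, min = -Inf, max = Inf, len = 1L,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    abort_validation(sprintf("`%s` must be a non-missing numeric of length %d.",
                             name, len))
  }
  if (any(x < min) || any(x > max)) {
    abort_validation(sprintf("`%s` must lie in [%s, %s] (got %s).",
                             name, format(min), format(max),
                             paste(format(x), collapse = ", ")))
  }
  if (integerish && any(abs(x - round(x)) > 1e-8)) {
    abort_validation(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}
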