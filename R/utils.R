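# Internal helpers shared across modules.

# Categorized error conditions. Every user-facing failure carries both the
# generic class "mcml_error" and a category used by the CLI exit-status
# mapping: format, parameter, data, degenerate, lookup, domain.
abort_mcml <- function(message, category, ...) {
  abort(message,
        class = c(paste0("mcml_error_", category), "mcml_error"),
        ...)
}

warn_mcml <- function(message, category) {
  warn(message, class = c(paste0("mcml_warning_", category), "mcml_warning"))
}

# Extract a numeric value vector from either a series tibble (columns
# `date`, `value`) or a bare numeric vector.
series_values <- function(x, arg = "data") {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      abort_mcml(sprintf("`%s` must have a `value` column.", arg), "format")
    }
    as.numeric(x[["value"]])
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    abort_mcml(sprintf("`%s` must be a data frame or numeric vector.", arg),
               "parameter")
  }
}

series_dates <- function(x, n = NULL) {
  if (is.data.frame(x) && "date" %in% names(x)) {
    x[["date"]]
  } else {
    seq_len(if (is.null(n)) nrow_or_length(x) else n)
  }
}

nrow_or_length <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

# Rebuild an output in the shape of the input: tibble in -> tibble out,
# vector in -> vector out. `keep` gives the row indices of the input that
# the output values correspond to.
series_like <- function(template, values, keep = seq_along(values)) {
  if (is.data.frame(template)) {
    out <- tibble(date = series_dates(template)[keep], value = values)
    out
  } else {
    values
  }
}

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper &&
    (!integer || x == round(x))
  if (!ok) {
    abort_mcml(sprintf("`%s` must be a %s in %s%s, %s].",
                       arg, if (integer) "whole number" else "number",
                       if (strict_lower) "(" else "[",
                       format(lower), format(upper)),
               "parameter")
  }
  if (integer) as.integer(x) else x
}

# Map between 0-based internal offsets and the 1-based day index used in
# all public reports.
day_index <- function(offset0) offset0 + 1L
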