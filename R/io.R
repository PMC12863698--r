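#' Read a daily time series from CSV
#'
#' Reads either a plain two-column file (`date,value`, ISO-8601 dates) or an
#' OWID-style wide table (columns `date`, `location`,
#' `new_cases_smoothed_per_million`, other columns ignored) from which a
#' single location's normalized new-case series is extracted. The result is a
#' gap-free daily series: leading/trailing missing rows are dropped, interior
#' gaps up to `max_gap` days are filled by linear interpolation, and longer
#' gaps raise an error.
#'
#' @param path Path to a CSV file.
#' @param dialect `"simple"` for `date,value`; `"owid"` for the wide table.
#' @param location Location name, required for `dialect = "owid"`.
#' @param max_gap Longest interior gap (in days) that will be interpolated.
#' @param quiet Suppress the message reporting interpolated/dropped rows.
#' @return A tibble with columns `date` (Date) and `value` (double), carrying
#'   attributes `label`, `n_interpolated` and `n_dropped`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("date,value", "2021-01-01,5", "2021-01-03,7"), f)
#' read_series_csv(f, quiet = TRUE)
read_series_csv <- function(path, dialect = c("simple", "owid"),
                            location = NULL, max_gap = 14, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_mcml(sprintf("File not found: '%s'.", path), "data")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (dialect == "simple") {
    if (!all(c("date", "value") %in% names(raw))) {
      abort_mcml("Simple-dialect CSV must have columns `date` and `value`.",
                 "format")
    }
    label <- tools::file_path_sans_ext(basename(path))
    raw <- dplyr::select(raw, "date", "value")
  } else {
    needed <- c("date", "location", "new_cases_smoothed_per_million")
    if (!all(needed %in% names(raw))) {
      abort_mcml(paste0("OWID-dialect CSV must have columns ",
                        paste0("`", needed, "`", collapse = ", "), "."),
                 "format")
    }
    if (is.null(location)) {
      abort_mcml("`location` is required for the owid dialect.", "parameter")
    }
    if (!location %in% raw$location) {
      abort_mcml(sprintf("Location '%s' not present in '%s'.", location, path),
                 "lookup")
    }
    label <- location
    raw <- raw[raw$location == location,
               c("date", "new_cases_smoothed_per_million")]
    names(raw) <- c("date", "value")
  }

  raw$date <- as.Date(raw$date)
  raw$value <- as.numeric(raw$value)
  if (anyNA(raw$date)) {
    abort_mcml("Unparseable dates in input (ISO-8601 expected).", "format")
  }
  raw <- dplyr::arrange(raw, .data$date)
  if (anyDuplicated(raw$date)) {
    abort_mcml("Duplicate dates in input.", "format")
  }

  # Drop leading/trailing missing values, keep track for the log record.
  usable <- which(!is.na(raw$value))
  if (length(usable) < 2L) {
    abort_mcml("Fewer than 2 usable rows after dropping missing values.",
               "data")
  }
  n_dropped <- nrow(raw) - (max(usable) - min(usable) + 1L)
  raw <- raw[min(usable):max(usable), ]

  # Expand to a strict daily grid; interior absent dates count as gaps too.
  grid <- tibble(date = seq(raw$date[1], raw$date[nrow(raw)], by = "day"))
  full <- dplyr::left_join(grid, raw, by = "date")
  missing <- is.na(full$value)
  if (any(missing)) {
    runs <- rle(missing)
    if (max(runs$lengths[runs$values]) > max_gap) {
      abort_mcml(sprintf(
        "Interior gap longer than %d days; refusing to interpolate.", max_gap),
        "data")
    }
    filled <- approx(x = which(!missing), y = full$value[!missing],
                     xout = which(missing), method = "linear")$y
    full$value[missing] <- filled
  }
  n_interpolated <- sum(missing)
  if (!quiet) {
    inform(sprintf("read_series_csv: %d interpolated, %d dropped rows (%s).",
                   n_interpolated, n_dropped, label))
  }
  if (any(!is.finite(full$value))) {
    abort_mcml("Non-finite values in series.", "data")
  }

  structure(full, label = label, n_interpolated = n_interpolated,
            n_dropped = n_dropped)
}

#' Trailing 7-day moving average
#'
#' Replaces each value by the mean of the 7-day window ending on that day
#' (the convention used for published smoothed case counts). The first 6
#' days, where no full window exists, are dropped.
#'
#' @param data A series tibble (`date`, `value`) or numeric vector.
#' @return Same shape as the input, 6 elements shorter.
#' @export
moving_average_7 <- function(data) {
  x <- series_values(data)
  if (length(x) < 7L) {
    abort_mcml("Need at least 7 daily values for a 7-day moving average.",
               "data")
  }
  sm <- as.numeric(stats::filter(x, rep(1 / 7, 7), sides = 1))
  keep <- 7:length(x)
  series_like(data, sm[keep], keep)
}

#' Convert daily counts to rates per million inhabitants
#'
#' @param data A series tibble or numeric vector of daily counts.
#' @param population Population size (> 0).
#' @return Same shape as the input, values scaled by `1e6 / population`.
#' @export
per_million <- function(data, population) {
  population <- check_number(population, "population", lower = 0,
                             strict_lower = TRUE)
  x <- series_values(data)
  series_like(data, x * 1e6 / population)
}

#' Log transform with a small offset
#'
#' The working scale of the forecasting algorithm: `Y = log(Z + offset)`,
#' natural log, default offset 0.05. Compresses the scale of large case
#' counts while remaining defined at zero. Invertible via
#' `exp(Y) - offset`.
#'
#' @param data A series tibble or numeric vector of non-negative values.
#' @param offset Positive offset added before taking logs.
#' @return Same shape as the input; a tibble result carries an `offset`
#'   attribute.
#' @export
log_transform <- function(data, offset = 0.05) {
  offset <- check_number(offset, "offset", lower = 0, strict_lower = TRUE)
  z <- series_values(data)
  if (any(!is.finite(z)) || any(z + offset <= 0)) {
    abort_mcml("log_transform requires finite values with value + offset > 0.",
               "domain")
  }
  out <- series_like(data, log(z + offset))
  if (is.data.frame(out)) attr(out, "offset") <- offset
  out
}

#' One-day differences of a (log) series
#'
#' `D[i] = Y[i] - Y[i-1]`: positive for an increase, negative for a decrease,
#' zero for no change. The cumulative sum of the differences plus the first
#' value reconstructs the input exactly.
#'
#' @param data A series tibble or numeric vector, length >= 2.
#' @return Same shape as the input, one element shorter (dated by the later
#'   day of each pair).
#' @export
difference <- function(data) {
  y <- series_values(data)
  if (length(y) < 2L) {
    abort_mcml("Need at least 2 values to difference.", "data")
  }
  series_like(data, diff(y), keep = 2:length(y))
}
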