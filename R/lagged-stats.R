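#' Autocorrelation at a single lag
#'
#' The ratio of the lagged autocovariance to the variance,
#' `R_m = sum_{t=1}^{N-m} (x_t - xbar)(x_{t+m} - xbar) / sum_t (x_t - xbar)^2`,
#' with `xbar` the full-series mean. `R_0 = 1` exactly and `|R_m| <= 1` for
#' every lag.
#'
#' @param x Numeric vector, length > `lag`, non-constant.
#' @param lag Non-negative integer lag `m`.
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' autocorrelation(c(1, 2, 1, 2), 1)  # -0.75
autocorrelation <- function(x, lag) {
  x <- series_values(x, "x")
  n <- length(x)
  lag <- check_number(lag, "lag", lower = 0, integer = TRUE)
  if (lag >= n) {
    abort_mcml("`lag` must be smaller than the series length.", "parameter")
  }
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    abort_mcml("Autocorrelation is undefined for a constant series.",
               "degenerate")
  }
  if (lag == 0L) return(1)
  sum(xc[1:(n - lag)] * xc[(1 + lag):n]) / denom
}

#' Pearson correlation coefficient
#'
#' Sample correlation between two equal-length vectors: +1 means perfect
#' synchrony, -1 exact mirror images. Unlike [stats::cor()] this errors on
#' zero-variance input rather than returning `NA`, so callers (notably the
#' analog window search) must handle degenerate windows explicitly.
#'
#' @param x,y Numeric vectors of equal length >= 2 with positive variance.
#' @return A single number in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  x <- series_values(x, "x"); y <- series_values(y, "y")
  if (length(x) != length(y) || length(x) < 2L) {
    abort_mcml("`x` and `y` must have equal length >= 2.", "parameter")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort_mcml("Correlation is undefined when either input is constant.",
               "degenerate")
  }
  stats::cor(x, y)
}

bin_indices <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Average mutual information at one lag
#'
#' Binned estimator of the mutual information between a series and its
#' `lag`-shifted copy: `AMI(tau) = sum_ij p_ij log(p_ij / (p_i p_j))`, where
#' `p_i` is the probability that `x_t` falls in bin `i`, `p_j` that
#' `x_(t+tau)` falls in bin `j`, and `p_ij` the joint probability. Bins are
#' equal-width over the range of the full series and applied identically to
#' both pair members, so `AMI(0)` equals the entropy of the binned marginal.
#' Values are in nats by default; AMI is non-negative (it is the
#' Kullback-Leibler divergence of the joint from the product of marginals).
#'
#' @param x Numeric vector or series tibble.
#' @param lag Non-negative integer lag `tau`, smaller than the length.
#' @param bins Number of equal-width bins (>= 2), default 16.
#' @param normalize If `TRUE`, divide by the mean entropy of the two binned
#'   margins so the value lies in `[0, 1]`. Off by default.
#' @param units `"nats"` (natural log, default) or `"bits"` (display only).
#' @return An object of class `ami_estimate`: a list with elements `value`,
#'   `lag`, `bins`, `n_pairs`, `p_i`, `p_j`, `p_ij`, `normalized`, `units`.
#' @export
#' @examples
#' average_mutual_information(rep(c(0, 0, 1, 1), 10), lag = 4, bins = 2)$value
average_mutual_information <- function(x, lag, bins = 16, normalize = FALSE,
                                       units = c("nats", "bits")) {
  units <- match.arg(units)
  x <- series_values(x, "x")
  n <- length(x)
  lag <- check_number(lag, "lag", lower = 0, integer = TRUE)
  bins <- check_number(bins, "bins", lower = 2, integer = TRUE)
  if (lag >= n) {
    abort_mcml("`lag` must be smaller than the series length.", "parameter")
  }

  constant <- length(unique(x)) == 1L
  if (constant) {
    warn_mcml("Constant series: single occupied bin, AMI = 0.", "degenerate")
  }
  idx <- bin_indices(x, bins)
  n_pairs <- n - lag
  a <- idx[1:n_pairs]
  b <- idx[(1 + lag):n]
  joint <- matrix(0, bins, bins)
  for (k in seq_len(n_pairs)) joint[a[k], b[k]] <- joint[a[k], b[k]] + 1
  p_ij <- joint / n_pairs
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)

  occ <- which(p_ij > 0, arr.ind = TRUE)
  value <- sum(p_ij[occ] * log(p_ij[occ] / (p_i[occ[, 1]] * p_j[occ[, 2]])))
  value <- max(value, 0)  # guard tiny negative rounding

  if (normalize) {
    h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    mean_h <- (h(p_i) + h(p_j)) / 2
    value <- if (mean_h > 0) value / mean_h else 0
  } else if (units == "bits") {
    value <- value / log(2)
  }

  structure(list(value = value, lag = lag, bins = bins, n_pairs = n_pairs,
                 p_i = p_i, p_j = p_j, p_ij = p_ij,
                 normalized = normalize, units = units),
            class = "ami_estimate")
}

#' @export
print.ami_estimate <- function(x, ...) {
  cat(sprintf("AMI(lag = %d) = %.6g %s (%d bins, %d pairs)\n",
              x$lag, x$value,
              if (x$normalized) "(normalized)" else x$units,
              x$bins, x$n_pairs))
  invisible(x)
}

#' AMI profile over several lags
#'
#' Computes [average_mutual_information()] at each requested lag with the
#' same binning throughout.
#'
#' @inheritParams average_mutual_information
#' @param lags Vector of non-negative integer lags, all smaller than the
#'   series length.
#' @return A tibble with columns `lag`, `ami`, `n_pairs`.
#' @export
ami_profile <- function(x, lags, bins = 16, normalize = FALSE) {
  x <- series_values(x, "x")
  if (max(lags) >= length(x)) {
    abort_mcml("All lags must be smaller than the series length.", "parameter")
  }
  purrr::map_dfr(lags, function(l) {
    est <- average_mutual_information(x, l, bins = bins, normalize = normalize)
    tibble(lag = l, ami = est$value, n_pairs = est$n_pairs)
  })
}

#' Windowed AMI grid over lags and string lengths
#'
#' For every evaluation date, computes AMI over the trailing window of each
#' requested string length at each requested lag. The long-form result feeds
#' [sum_abs_ami()], which summarizes divergence of lagged information ahead
#' of epidemic peaks.
#'
#' @param data A series tibble (`date`, `value`) or numeric vector.
#' @param lags Integer lags (days), e.g. `seq(10, 90, 10)`.
#' @param string_lengths Trailing window lengths (days), e.g.
#'   `seq(100, 400, 50)`.
#' @param bins Bin count passed to [average_mutual_information()].
#' @param every Evaluate every `every`-th day (thins the grid for speed).
#' @return A tibble with columns `date`, `lag`, `string_length`, `ami`.
#' @export
ami_grid <- function(data, lags = seq(10, 90, 10),
                     string_lengths = seq(100, 400, 50), bins = 16,
                     every = 1) {
  x <- series_values(data)
  dates <- series_dates(data, length(x))
  if (max(lags) >= min(string_lengths)) {
    abort_mcml("Every lag must be smaller than every string length.",
               "parameter")
  }
  if (length(x) < max(string_lengths)) {
    abort_mcml("Series shorter than the largest string length.", "data")
  }
  purrr::map_dfr(string_lengths, function(wl) {
    ts <- seq(wl, length(x), by = every)
    purrr::map_dfr(ts, function(t) {
      win <- x[(t - wl + 1):t]
      prof <- suppressWarnings(ami_profile(win, lags, bins = bins))
      tibble(date = rep(dates[t], length(lags)), lag = prof$lag,
             string_length = wl, ami = prof$ami)
    })
  })
}

#' Sum of absolute AMI values over one grid axis
#'
#' Per-date sum of `|AMI|` across either all lags (at one fixed string
#' length) or all string lengths (at one fixed lag).
#'
#' @param grid Long-form tibble as produced by [ami_grid()].
#' @param axis `"lags"` to sum over lags, `"string_lengths"` to sum over
#'   string lengths.
#' @param at The fixed value of the other axis; may be omitted when the grid
#'   contains a single value for it.
#' @return A tibble with columns `date`, `sum_abs_ami`.
#' @export
sum_abs_ami <- function(grid, axis = c("lags", "string_lengths"), at = NULL) {
  axis <- match.arg(axis)
  needed <- c("date", "lag", "string_length", "ami")
  if (!all(needed %in% names(grid))) {
    abort_mcml("`grid` must have columns date, lag, string_length, ami.",
               "format")
  }
  fixed_col <- if (axis == "lags") "string_length" else "lag"
  sum_col <- if (axis == "lags") "lag" else "string_length"
  if (is.null(at)) {
    vals <- unique(grid[[fixed_col]])
    if (length(vals) != 1L) {
      abort_mcml(sprintf(
        "`at` must fix `%s` (grid holds %d distinct values).",
        fixed_col, length(vals)), "parameter")
    }
    at <- vals
  }
  sub <- grid[grid[[fixed_col]] == at, ]
  if (nrow(sub) == 0L) {
    abort_mcml(sprintf("No grid rows with %s = %s.", fixed_col, format(at)),
               "data")
  }
  expected <- length(unique(sub[[sum_col]]))
  counts <- table(sub$date)
  if (any(counts != expected)) {
    abort_mcml("Incomplete grid: some dates lack part of the summed axis.",
               "data")
  }
  out <- dplyr::summarise(dplyr::group_by(sub, .data$date),
                          sum_abs_ami = sum(abs(.data$ami)), .groups = "drop")
  dplyr::arrange(out, .data$date)
}
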