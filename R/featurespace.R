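#' Sliding-window feature series
#'
#' For every day `t` from `window` to the end of the series, computes the
#' autocorrelation and the average mutual information of the trailing
#' `window`-day stretch at the given `lag`, together with the window maximum
#' of the raw values. Because the window length stays constant and moves
#' with every new data point, all downstream scalings adjust day by day
#' (causal, real-time diagnostics).
#'
#' Days whose window is constant get `ac = NA` (autocorrelation undefined,
#' masked) and `ami = 0`.
#'
#' @param data A series tibble (`date`, `value`) or numeric vector of
#'   normalized new cases.
#' @param window Sliding window duration in days (default 150).
#' @param lag Time lag in days for both AC and AMI (default 15), `< window`.
#' @param bins Bin count for the AMI estimator (default 16).
#' @return A tibble with columns `date`, `nc`, `ac`, `ami`, `max_nc_wl` and
#'   attributes `window`, `lag`, `bins`. One row per evaluation day
#'   (`length - window + 1` rows).
#' @export
sliding_features <- function(data, window = 150, lag = 15, bins = 16) {
  x <- series_values(data)
  dates <- series_dates(data, length(x))
  window <- check_number(window, "window", lower = 2, integer = TRUE)
  lag <- check_number(lag, "lag", lower = 0, integer = TRUE)
  if (lag >= window) {
    abort_mcml("`lag` must be smaller than `window`.", "parameter")
  }
  if (length(x) < window) {
    abort_mcml(sprintf("Series shorter than the window (%d < %d).",
                       length(x), window), "data")
  }
  ts <- window:length(x)
  n_masked <- 0L
  rows <- lapply(ts, function(t) {
    win <- x[(t - window + 1L):t]
    constant <- length(unique(win)) == 1L
    ac <- if (constant) NA_real_ else autocorrelation(win, lag)
    ami <- if (constant) 0 else
      average_mutual_information(win, lag, bins = bins)$value
    if (constant) n_masked <<- n_masked + 1L
    list(ac = ac, ami = ami, mx = max(win))
  })
  if (n_masked > 0L) {
    inform(sprintf("sliding_features: %d constant windows masked.", n_masked))
  }
  out <- tibble(date = dates[ts], nc = x[ts],
                ac = vapply(rows, `[[`, numeric(1), "ac"),
                ami = vapply(rows, `[[`, numeric(1), "ami"),
                max_nc_wl = vapply(rows, `[[`, numeric(1), "mx"))
  attr(out, "window") <- window
  attr(out, "lag") <- lag
  attr(out, "bins") <- bins
  out
}

#' Dynamic half-maximum scaling of the feature axes
#'
#' Brings autocorrelation and AMI onto the scale of the new-cases axis by
#' multiplying with half the window maximum of new cases, day by day:
#' `ac_scaled = (AC + 1) * max_nc_wl / 2` (so `ac_scaled` lies in
#' `[0, max_nc_wl]`) and `ami_scaled = AMI * max_nc_wl / 2`. Optionally the
#' new-cases axis itself is divided by its window maximum
#' (`normalize_nc = TRUE`), which confines it to `[0, 1]` but compresses the
#' high end during upswings.
#'
#' @param features Output of [sliding_features()].
#' @param normalize_nc Divide `nc` by `max_nc_wl` (default `FALSE`).
#' @return The input tibble with added columns `ac_scaled`, `ami_scaled`,
#'   `nc_out`, and an `extra_factors` attribute (all 1 until
#'   [arbitrary_scale()] is applied). Days with `max_nc_wl = 0` are masked.
#' @export
dynamic_scale <- function(features, normalize_nc = FALSE) {
  needed <- c("nc", "ac", "ami", "max_nc_wl")
  if (!all(needed %in% names(features))) {
    abort_mcml("`features` must come from sliding_features().", "format")
  }
  half <- features$max_nc_wl / 2
  bad <- features$max_nc_wl <= 0
  half[bad] <- NA_real_
  out <- features
  out$ac_scaled <- (features$ac + 1) * half
  out$ami_scaled <- features$ami * half
  out$nc_out <- if (normalize_nc) {
    v <- features$nc / features$max_nc_wl
    v[bad] <- NA_real_
    v
  } else features$nc
  attr(out, "extra_factors") <- c(nc = 1, ac = 1, ami = 1)
  attr(out, "normalize_nc") <- normalize_nc
  for (a in c("window", "lag", "bins")) attr(out, a) <- attr(features, a)
  out
}

#' Additional constant rescaling of individual axes
#'
#' After dynamic scaling, individual axes may still sit on slightly
#' mismatched scales for a given data set; a per-axis constant factor
#' (chosen by the analyst, e.g. `ami = 2`) can be applied on top. Factors
#' are recorded in the output's `extra_factors` attribute for auditability.
#'
#' @param scaled Output of [dynamic_scale()].
#' @param nc,ac,ami Positive multiplicative constants (default 1).
#' @return The rescaled tibble with an updated `extra_factors` attribute.
#' @export
arbitrary_scale <- function(scaled, nc = 1, ac = 1, ami = 1) {
  if (!all(c("nc_out", "ac_scaled", "ami_scaled") %in% names(scaled))) {
    abort_mcml("`scaled` must come from dynamic_scale().", "format")
  }
  for (f in c(nc, ac, ami)) {
    check_number(f, "factor", lower = 0, strict_lower = TRUE)
  }
  out <- scaled
  out$nc_out <- scaled$nc_out * nc
  out$ac_scaled <- scaled$ac_scaled * ac
  out$ami_scaled <- scaled$ami_scaled * ami
  attr(out, "extra_factors") <- attr(scaled, "extra_factors") *
    c(nc = nc, ac = ac, ami = ami)
  out
}

#' Local Lyapunov exponent of two trajectories
#'
#' The one-step log ratio of gap sizes between two nearby trajectories,
#' `lambda_t = log(|x_{t+1} - y_{t+1}| / |x_t - y_t|)`: positive where the
#' gap grows (local instability), negative where it shrinks. Days where the
#' denominator gap is zero are masked (`NA`); a zero numerator over a
#' nonzero denominator would be `-Inf` and is masked with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A numeric vector of length `length(x) - 1`; element `t` describes
#'   the transition from `t` to `t + 1`.
#' @export
#' @examples
#' local_lyapunov_pair(c(0, 0, 0), c(1, 2, 2))  # log(2), 0
local_lyapunov_pair <- function(x, y) {
  x <- series_values(x, "x"); y <- series_values(y, "y")
  if (length(x) != length(y) || length(x) < 2L) {
    abort_mcml("`x` and `y` must have equal length >= 2.", "parameter")
  }
  gap <- abs(x - y)
  n <- length(gap)
  num <- gap[-1]
  den <- gap[-n]
  lam <- rep(NA_real_, n - 1L)
  ok <- !is.na(num) & !is.na(den) & den > 0
  zero_num <- ok & num == 0
  if (any(zero_num)) {
    warn_mcml(sprintf("%d steps with vanishing gap (lambda -> -Inf) masked.",
                      sum(zero_num)), "degenerate")
  }
  use <- ok & !zero_num
  lam[use] <- log(num[use] / den[use])
  lam
}

#' Maximum local Lyapunov exponent over the feature pairs
#'
#' Computes the local Lyapunov exponent for the three axis pairs of the
#' scaled feature space -- new cases vs scaled AC, scaled AC vs scaled AMI,
#' scaled AMI vs new cases -- and takes, per day, the largest defined value
#' (the MLE). Spikes in the MLE flag local instability of the feature-space
#' trajectory near infection peaks.
#'
#' @param scaled Output of [dynamic_scale()] (optionally after
#'   [arbitrary_scale()]).
#' @return A tibble with columns `date`, `lambda_nc_ac`, `lambda_ac_ami`,
#'   `lambda_ami_nc`, `mle`; each row describes the transition observed on
#'   that day (one fewer row than the input).
#' @export
max_lyapunov <- function(scaled) {
  if (!all(c("nc_out", "ac_scaled", "ami_scaled") %in% names(scaled))) {
    abort_mcml("`scaled` must come from dynamic_scale().", "format")
  }
  l1 <- suppressWarnings(local_lyapunov_pair(scaled$nc_out, scaled$ac_scaled))
  l2 <- suppressWarnings(local_lyapunov_pair(scaled$ac_scaled,
                                             scaled$ami_scaled))
  l3 <- suppressWarnings(local_lyapunov_pair(scaled$ami_scaled,
                                             scaled$nc_out))
  mle <- pmax(ifelse(is.na(l1), -Inf, l1),
              ifelse(is.na(l2), -Inf, l2),
              ifelse(is.na(l3), -Inf, l3))
  mle[is.na(l1) & is.na(l2) & is.na(l3)] <- NA_real_
  mle[is.infinite(mle) & mle < 0] <- NA_real_
  tibble(date = scaled$date[-1], lambda_nc_ac = l1, lambda_ac_ami = l2,
         lambda_ami_nc = l3, mle = mle)
}

#' First difference of a dated series
#'
#' Approximates a first derivative by the change between consecutive days:
#' `out[t] = in[t + 1] - in[t]`. The telescoping sum of the output equals
#' the last minus the first input value.
#'
#' @param data A series tibble or numeric vector, length >= 2.
#' @return Same shape as the input, one element shorter, dated by the
#'   earlier day of each pair.
#' @export
first_difference <- function(data) {
  x <- series_values(data)
  if (length(x) < 2L) {
    abort_mcml("Need at least 2 values to difference.", "data")
  }
  series_like(data, diff(x), keep = 1:(length(x) - 1L))
}

# Prominence-based local maxima. A peak's prominence is its height above
# the higher of the two lowest points one must descend to before reaching
# higher ground (or a series end) on each side. Peaks below min_prominence
# are dropped; among close peaks (< min_separation apart) the higher wins.
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  ok <- !is.na(x)
  cand <- which(vapply(seq_len(n), function(i) {
    if (!ok[i]) return(FALSE)
    left <- if (i > 1 && ok[i - 1]) x[i - 1] else -Inf
    right <- if (i < n && ok[i + 1]) x[i + 1] else -Inf
    x[i] > left && x[i] >= right && (i > 1 && i < n)
  }, logical(1)))
  if (length(cand) == 0L) return(integer(0))

  prom <- vapply(cand, function(i) {
    lmin <- Inf
    j <- i - 1L
    while (j >= 1L) {
      if (ok[j]) {
        if (x[j] > x[i]) break
        lmin <- min(lmin, x[j])
      }
      j <- j - 1L
    }
    rmin <- Inf
    j <- i + 1L
    while (j <= n) {
      if (ok[j]) {
        if (x[j] > x[i]) break
        rmin <- min(rmin, x[j])
      }
      j <- j + 1L
    }
    base <- max(min(lmin, x[i]), min(rmin, x[i]))
    x[i] - base
  }, numeric(1))

  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0L) return(integer(0))
  keep <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in keep) {
    if (all(abs(i - chosen) >= min_separation)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

#' Align new-case peaks with MLE spikes
#'
#' Detects local maxima of the new-case series and of the MLE series
#' (prominence at least `min_prominence_frac` times the series range,
#' separated by at least `min_separation_days`), then pairs each new-case
#' peak with an MLE spike within `max_lead_days` either way.
#' `lead_days > 0` means the spike preceded the peak -- the early-warning
#' configuration.
#'
#' Because the question of interest is whether a warning was available *at
#' or before* the peak, the default pairing (`prefer = "lead"`) takes the
#' nearest spike with non-negative lead when one exists inside the window
#' and only falls back to the nearest trailing spike otherwise;
#' `prefer = "nearest"` pairs with the closest spike regardless of sign.
#'
#' @param nc A dated series tibble (`date`, `value`) or the value column
#'   name may be `nc`; numeric vectors are indexed by day number.
#' @param mle A dated series of MLE values (e.g. `date` + `mle` columns from
#'   [max_lyapunov()]).
#' @param min_prominence_frac Peak prominence threshold as a fraction of the
#'   series range (default 0.1).
#' @param min_separation_days Minimum spacing between retained peaks
#'   (default 14).
#' @param max_lead_days Maximum |lead| allowed for a match (default 21).
#' @param prefer `"lead"` (default) or `"nearest"`; see Details.
#' @return A tibble with columns `nc_peak_day`, `mle_spike_day`,
#'   `lead_days` (possibly zero rows; unmatched peaks get `NA` spike day).
#' @export
peak_spike_alignment <- function(nc, mle, min_prominence_frac = 0.1,
                                 min_separation_days = 14,
                                 max_lead_days = 21,
                                 prefer = c("lead", "nearest")) {
  prefer <- match.arg(prefer)
  get_col <- function(d, prefer) {
    if (is.data.frame(d)) {
      col <- intersect(prefer, names(d))[1]
      if (is.na(col)) abort_mcml("Cannot find a value column.", "format")
      list(date = series_dates(d, nrow(d)), value = as.numeric(d[[col]]))
    } else {
      list(date = seq_along(d), value = as.numeric(d))
    }
  }
  a <- get_col(nc, c("value", "nc", "nc_out"))
  b <- get_col(mle, c("mle", "value"))

  common <- a$date[a$date %in% b$date]  # keeps the Date class intact
  if (length(common) < 3L) {
    abort_mcml("Date ranges of `nc` and `mle` do not overlap.", "data")
  }
  av <- a$value[match(common, a$date)]
  bv <- b$value[match(common, b$date)]
  dts <- a$date[match(common, a$date)]

  rng <- function(v) diff(range(v, na.rm = TRUE))
  pk_nc <- find_peaks(av, min_prominence = min_prominence_frac * rng(av),
                      min_separation = min_separation_days)
  pk_mle <- find_peaks(bv, min_prominence = min_prominence_frac * rng(bv),
                       min_separation = min_separation_days)
  if (length(pk_nc) == 0L) {
    return(tibble(nc_peak_day = dts[integer(0)],
                  mle_spike_day = dts[integer(0)],
                  lead_days = numeric(0)))
  }
  purrr::map_dfr(pk_nc, function(i) {
    if (length(pk_mle) == 0L) {
      return(tibble(nc_peak_day = dts[i], mle_spike_day = dts[NA_integer_],
                    lead_days = NA_real_))
    }
    gaps <- as.numeric(i - pk_mle)  # positive: spike earlier than peak
    in_win <- abs(gaps) <= max_lead_days
    j <- if (prefer == "lead" && any(in_win & gaps >= 0)) {
      cand <- which(in_win & gaps >= 0)
      cand[which.min(gaps[cand])]
    } else {
      which.min(abs(gaps))
    }
    if (abs(gaps[j]) > max_lead_days) {
      tibble(nc_peak_day = dts[i], mle_spike_day = dts[NA_integer_],
             lead_days = NA_real_)
    } else {
      tibble(nc_peak_day = dts[i], mle_spike_day = dts[pk_mle[j]],
             lead_days = gaps[j])
    }
  })
}

#' Pairwise feature-space plot
#'
#' Draws the trajectory of two scaled feature axes against each other over
#' time. Oscillatory epidemic dynamics trace a torus-like loop; rapid
#' monotone growth a near-straight line.
#'
#' @param scaled Output of [dynamic_scale()].
#' @param x,y Axis names among `"nc"`, `"ac"`, `"ami"`.
#' @return A ggplot object.
#' @export
plot_feature_space <- function(scaled, x = "nc", y = "ac") {
  cols <- c(nc = "nc_out", ac = "ac_scaled", ami = "ami_scaled")
  if (!x %in% names(cols) || !y %in% names(cols)) {
    abort_mcml("Axes must be among 'nc', 'ac', 'ami'.", "parameter")
  }
  df <- tibble(t = seq_len(nrow(scaled)),
               x = scaled[[cols[[x]]]], y = scaled[[cols[[y]]]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::scale_colour_viridis_c(name = "day") +
    ggplot2::labs(x = x, y = y, title = sprintf("Feature space: %s vs %s",
                                                y, x))
}

#' MLE spikes against normalized new cases over time
#'
#' @param lyap Output of [max_lyapunov()].
#' @param scaled The matching output of [dynamic_scale()] (for the new-case
#'   trace).
#' @return A ggplot object with MLE (blue) and rescaled new cases (red).
#' @export
plot_mle <- function(lyap, scaled) {
  nc <- scaled$nc_out[-1]
  nc_rs <- nc / max(nc, na.rm = TRUE) *
    max(abs(lyap$mle), na.rm = TRUE)
  df <- dplyr::bind_rows(
    tibble(date = lyap$date, value = lyap$mle, what = "MLE"),
    tibble(date = lyap$date, value = nc_rs, what = "new cases (rescaled)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value,
                                   colour = .data$what)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("MLE" = "blue",
                                            "new cases (rescaled)" = "red")) +
    ggplot2::labs(x = NULL, y = "local Lyapunov exponent", colour = NULL)
}
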