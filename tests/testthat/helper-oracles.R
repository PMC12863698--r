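# Independent oracles used to cross-check the implementation. These are
# deliberately written from the definitions (double loops, hand formulas,
# normal equations) and share no code with the package internals.

# Pearson correlation straight from the centered-sum formula.
oracle_pearson <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Autocorrelation as the ratio of lagged autocovariance to variance.
oracle_autocorrelation <- function(x, m) {
  n <- length(x)
  xc <- x - mean(x)
  sum(xc[seq_len(n - m)] * xc[seq_len(n - m) + m]) / sum(xc^2)
}

# Binned AMI by an explicit double loop over all cells, binning via cut().
oracle_ami <- function(x, lag, bins) {
  edges <- seq(min(x), max(x), length.out = bins + 1)
  bi <- as.integer(cut(x, edges, include.lowest = TRUE))
  a <- bi[seq_len(length(x) - lag)]
  b <- bi[seq_len(length(x) - lag) + lag]
  np <- length(a)
  total <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(a == i & b == j) / np
      if (pij > 0) {
        total <- total + pij * log(pij / ((sum(a == i) / np) *
                                            (sum(b == j) / np)))
      }
    }
  }
  total
}

# Exhaustive analog search: every anchor, correlation by the hand formula,
# ties resolved toward the most recent anchor.
oracle_window_search <- function(query, y, search_end) {
  p <- length(query)
  best_i <- NA_integer_
  best_rho <- -Inf
  for (i in (p + 2):search_end) {
    w <- y[(i - 2):(i - p - 1)]
    if (length(unique(w)) == 1L) next
    r <- oracle_pearson(query, w)
    if (r >= best_rho) {
      best_rho <- r
      best_i <- i
    }
  }
  list(i_star = best_i, rho = best_rho)
}

# OLS through the normal equations.
oracle_ols <- function(X, d) {
  as.numeric(solve(crossprod(X), crossprod(X, d)))
}

# A deterministic multi-pulse train (sum of Gaussians), used by the
# alignment tests.
pulse_train <- function(n, centers, width = 8, height = 1) {
  t <- seq_len(n)
  rowSums(vapply(centers, function(cc) height * exp(-(t - cc)^2 /
                                                      (2 * width^2)),
                 numeric(n)))
}
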