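#' Build the regression rows for a lagged linear model
#'
#' Stage 1 of the forecasting method regresses the one-day change
#' `D_i = Y_i - Y_{i-1}` on the `p` lagged values `(Y_{i-2}, ..., Y_{i-p-1})`
#' -- the candidate principal lags of day `i - 1`. The predictor vector never
#' contains `Y_i` or `Y_{i-1}`, so the response's own endpoints cannot leak
#' into the design.
#'
#' @param y Numeric vector of log-scale values (or a series tibble).
#' @param p Number of lags (>= 1).
#' @param m Number of regression rows.
#' @param rows `"aligned"` (default) uses the `m` most recent eligible rows
#'   `i = n - m + 1, ..., n`, so every `p` compared by BIC fits the identical
#'   response vector. `"literal"` uses rows `i = p + 2, ..., m + p + 1`
#'   anchored at the series start (different responses for different `p`);
#'   provided for compatibility.
#' @return A list with elements `response` (length `m`), `predictors`
#'   (`m x p` matrix, column `j` holding `Y_{i-j-1}`), and `rows` (the day
#'   indices `i`).
#' @export
build_lag_rows <- function(y, p, m, rows = c("aligned", "literal")) {
  rows <- match.arg(rows)
  y <- series_values(y, "y")
  n <- length(y)
  p <- check_number(p, "p", lower = 1, integer = TRUE)
  m <- check_number(m, "m", lower = 1, integer = TRUE)
  min_len <- m + p + 1L
  if (n < min_len) {
    abort_mcml(sprintf(
      "Series too short: need at least %d values for p = %d, m = %d (have %d).",
      min_len, p, m, n), "data")
  }
  i <- if (rows == "aligned") (n - m + 1L):n else (p + 2L):(m + p + 1L)
  predictors <- vapply(seq_len(p), function(j) y[i - j - 1L], numeric(m))
  predictors <- matrix(predictors, nrow = m, ncol = p,
                       dimnames = list(NULL, paste0("ylag", seq_len(p) + 1L)))
  list(response = y[i] - y[i - 1L], predictors = predictors, rows = i)
}

#' Fit one lagged linear model by ordinary least squares
#'
#' Fits `D_i = a_0 + a_1 Y_{i-2} + ... + a_p Y_{i-p-1} + eps_i` with an
#' intercept, storing the residual sum of squares, the error-variance
#' estimate `rss / m`, and the model's BIC.
#'
#' @param rows Row structure from [build_lag_rows()].
#' @return An object of class `lag_model_fit`: list with `p`, `m`,
#'   `coefficients` (`a_0 ... a_p`), `residuals`, `rss`, `sigma2`, `bic`,
#'   `perfect_fit`.
#' @export
fit_lag_model <- function(rows) {
  m <- length(rows$response)
  p <- ncol(rows$predictors)
  if (m <= p + 1L) {
    abort_mcml(sprintf("Need more rows (%d) than parameters (%d).",
                       m, p + 1L), "data")
  }
  X <- cbind(`(Intercept)` = 1, rows$predictors)
  fit <- lm.fit(X, rows$response)
  if (fit$rank < ncol(X)) {
    abort_mcml("Rank-deficient design (e.g. constant or duplicated lags).",
               "degenerate")
  }
  rss <- sum(fit$residuals^2)
  # A numerically perfect fit: rss at rounding-noise level relative to the
  # response scale. Such models win BIC selection by convention.
  perfect <- rss <= 1e-12 * max(sum(rows$response^2), 1e-300)
  out <- list(p = p, m = m, coefficients = fit$coefficients,
              residuals = fit$residuals, rss = rss, sigma2 = rss / m,
              perfect_fit = perfect)
  out$bic <- bic_of_fit(out)
  structure(out, class = "lag_model_fit")
}

#' BIC of a lagged linear model fit
#'
#' `BIC = m log(rss / m) + (p + 2) log(m)`, counting the intercept, the `p`
#' slopes and the error variance as parameters. The `+1` for the variance is
#' common to all `p`, so it never changes which `p` wins, but it is stated
#' for bit-exactness. Lower is better. A perfect fit (`rss = 0`) is assigned
#' `-Inf` and wins selection by convention.
#'
#' @param fit A `lag_model_fit`, or any list with elements `rss`, `m`, `p`.
#' @return A single number (possibly `-Inf`).
#' @export
bic_of_fit <- function(fit) {
  if (isTRUE(fit$perfect_fit) || fit$rss <= 0) return(-Inf)
  fit$m * log(fit$rss / fit$m) + (fit$p + 2) * log(fit$m)
}

#' Select the number of principal lags by BIC
#'
#' Fits lagged linear models for `p = 2, ..., q` and returns the full BIC
#' curve together with `p*`, the argmin. With the default `rows = "aligned"`
#' every model is fitted to the same `m` most recent response rows, so the
#' BIC values compare like with like; ties break toward smaller `p`
#' (parsimony). The selected lags `(Y_{i-2}, ..., Y_{i-p*-1})` are the
#' principal lags used by the analog forecaster.
#'
#' @inheritParams build_lag_rows
#' @param q Maximum number of lags considered (default 19).
#' @param m Number of regression rows; default `min(60, floor(n / 4))`.
#' @return An object of class `pl_selection`: list with `q`, `m`, `p_star`,
#'   `bic_curve` (tibble `p`, `bic`, `rss`), `best_fit`, `rows`.
#' @export
#' @examples
#' y <- cumsum(rnorm(200, sd = 0.1))
#' select_principal_lags(y, q = 8, m = 40)
select_principal_lags <- function(y, q = 19, m = NULL,
                                  rows = c("aligned", "literal")) {
  rows <- match.arg(rows)
  y <- series_values(y, "y")
  n <- length(y)
  q <- check_number(q, "q", lower = 2, integer = TRUE)
  if (is.null(m)) {
    m <- min(60L, floor(n / 4))
    if (m < q + 2L) {
      abort_mcml(sprintf(
        "Series too short for q = %d with the default m = floor(n/4): need at least %d values (have %d).",
        q, 4L * (q + 2L), n), "data")
    }
  }
  m <- check_number(m, "m", lower = q + 2, integer = TRUE)
  if (n < m + q + 1L) {
    abort_mcml(sprintf(
      "Series too short for q = %d, m = %d: need at least %d values (have %d).",
      q, m, m + q + 1L, n), "data")
  }

  ps <- 2:q
  fits <- lapply(ps, function(p) {
    tryCatch(fit_lag_model(build_lag_rows(y, p, m, rows = rows)),
             mcml_error_degenerate = function(e) NULL)
  })
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                numeric(1))
  rss <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rss,
                numeric(1))
  if (all(is.na(bic))) {
    abort_mcml("All candidate lag models were degenerate.", "degenerate")
  }
  best <- which.min(bic)  # first minimum: ties go to the smaller p
  structure(list(q = q, m = m, p_star = ps[best],
                 bic_curve = tibble(p = ps, bic = bic, rss = rss),
                 best_fit = fits[[best]], rows = rows),
            class = "pl_selection")
}

#' @export
print.pl_selection <- function(x, ...) {
  cat(sprintf("Principal-lag selection: p* = %d (q = %d, m = %d rows)\n",
              x$p_star, x$q, x$m))
  cat(sprintf("  BIC(p*) = %.4f\n",
              x$bic_curve$bic[x$bic_curve$p == x$p_star]))
  invisible(x)
}

#' @rdname select_principal_lags
#' @param x A `pl_selection` object.
#' @param ... Unused.
#' @export
tidy.pl_selection <- function(x, ...) x$bic_curve

#' @rdname select_principal_lags
#' @export
glance.pl_selection <- function(x, ...) {
  tibble(q = x$q, m = x$m, p_star = x$p_star,
         bic_min = min(x$bic_curve$bic, na.rm = TRUE))
}

#' @rdname select_principal_lags
#' @param object A `pl_selection` object.
#' @export
autoplot.pl_selection <- function(object, ...) {
  ggplot2::ggplot(object$bic_curve, ggplot2::aes(x = .data$p, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$bic_curve[
      object$bic_curve$p == object$p_star, ], colour = "red", size = 3) +
    ggplot2::labs(x = "number of lags p", y = "BIC",
                  title = sprintf("BIC lag selection (p* = %d)",
                                  object$p_star))
}
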