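#' Forecast accuracy metrics
#'
#' Mean absolute error, root mean square error and mean absolute percentage
#' error over the `M` evaluated points:
#' `MAE = mean(|e|)`, `RMSE = sqrt(mean(e^2))`,
#' `MAPE = mean(|e / y_true|)` over the points with `|y_true|` above the
#' zero guard (excluded points are counted, never silently dropped).
#' `MAE <= RMSE` always, with equality iff all absolute errors are equal.
#'
#' @param y_true,y_pred Numeric vectors (or series tibbles) of equal length.
#' @param zero_tol Points with `|y_true| <= zero_tol` are excluded from MAPE.
#' @return A one-row tibble with columns `mae`, `rmse`, `mape`,
#'   `n_evaluated`, `n_excluded_zero`. `mape` is `NA` when every point is
#'   excluded.
#' @export
#' @examples
#' evaluate_forecast(c(1, 2), c(2, 4))  # MAE 1.5, RMSE sqrt(2.5), MAPE 1
evaluate_forecast <- function(y_true, y_pred, zero_tol = 1e-8) {
  y_true <- series_values(y_true, "y_true")
  y_pred <- series_values(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) {
    abort_mcml("`y_true` and `y_pred` must have equal length.", "parameter")
  }
  if (length(y_true) < 1L) {
    abort_mcml("Need at least one point to evaluate.", "parameter")
  }
  e <- y_true - y_pred
  keep <- abs(y_true) > zero_tol
  mape <- if (any(keep)) mean(abs(e[keep] / y_true[keep])) else NA_real_
  if (!any(keep)) {
    warn_mcml("All points excluded from MAPE by the zero guard.", "degenerate")
  }
  tibble(mae = mean(abs(e)),
         rmse = sqrt(mean(e^2)),
         mape = mape,
         n_evaluated = length(e),
         n_excluded_zero = sum(!keep))
}
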