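#' Chronological train/test split
#'
#' Splits a series into the first `N = round(train_frac * n)` points
#' (training) and the remaining `M = n - N` points (testing), with no
#' shuffling, so the prediction never learns information from the future.
#'
#' @param data A series tibble or numeric vector.
#' @param train_frac Fraction of the data assigned to training, in (0, 1);
#'   default 0.8 (the customary 70-80% training share).
#' @return A list with elements `train` and `test`, each shaped like the
#'   input.
#' @export
train_test_split <- function(data, train_frac = 0.8) {
  train_frac <- check_number(train_frac, "train_frac", lower = 0, upper = 1,
                             strict_lower = TRUE)
  if (train_frac >= 1) {
    abort_mcml("`train_frac` must lie strictly inside (0, 1).", "parameter")
  }
  n <- nrow_or_length(data)
  N <- round(train_frac * n)
  if (N < 2L || n - N < 1L) {
    abort_mcml(sprintf("Degenerate split: N = %d, M = %d.", N, n - N),
               "parameter")
  }
  if (is.data.frame(data)) {
    list(train = data[1:N, ], test = data[(N + 1):n, ])
  } else {
    list(train = data[1:N], test = data[(N + 1):n])
  }
}

# Candidate analog library: for anchors i = p + 2, ..., search_end the
# window (Y_{i-2}, ..., Y_{i-p-1}) and the increment D_i = Y_i - Y_{i-1}
# that followed it. Centered rows are precomputed so repeated queries
# (multi-step forecasting) are cheap.
analog_library <- function(y, p, search_end) {
  n <- length(y)
  if (search_end > n) {
    abort_mcml("`search_end` beyond the end of the history.", "parameter")
  }
  if (search_end < p + 2L) {
    abort_mcml(sprintf(
      "No candidate anchors: need search_end >= %d (have %d).",
      p + 2L, search_end), "data")
  }
  anchors <- (p + 2L):search_end
  W <- vapply(seq_len(p), function(j) y[anchors - j - 1L],
              numeric(length(anchors)))
  W <- matrix(W, nrow = length(anchors), ncol = p)
  Wc <- W - rowMeans(W)
  rowss <- rowSums(Wc^2)
  list(anchors = anchors, Wc = Wc, rowss = rowss,
       d = y[anchors] - y[anchors - 1L])
}

match_in_library <- function(lib, query) {
  qc <- query - mean(query)
  qss <- sum(qc^2)
  if (qss == 0) {
    abort_mcml("Query window is constant: correlation undefined.",
               "degenerate")
  }
  valid <- lib$rowss > 0
  n_skipped <- sum(!valid)
  if (!any(valid)) {
    abort_mcml("All candidate windows were constant; no match possible.",
               "data")
  }
  rho <- rep(NA_real_, length(lib$anchors))
  rho[valid] <- (lib$Wc[valid, , drop = FALSE] %*% qc) /
    sqrt(lib$rowss[valid] * qss)
  mx <- max(rho[valid])
  hit <- which(!is.na(rho) & rho == mx)
  k <- hit[length(hit)]  # tie-break: most recent anchor wins
  structure(list(i_star = lib$anchors[k], rho = mx, d_pred = lib$d[k],
                 n_candidates = length(lib$anchors), n_skipped = n_skipped),
            class = "mcml_match")
}

#' @export
print.mcml_match <- function(x, ...) {
  cat(sprintf(
    "Analog match: anchor i* = %d, rho = %.6f, d_pred = %.6g (%d candidates, %d skipped)\n",
    x$i_star, x$rho, x$d_pred, x$n_candidates, x$n_skipped))
  invisible(x)
}

#' Most-correlated historical window
#'
#' Evaluates the Pearson correlation between the query principal-lag vector
#' and the vector `(Y_{i-2}, ..., Y_{i-p-1})` for every candidate anchor
#' `i = p + 2, ..., search_end`, and returns the argmax. The increment
#' `D_{i*} = Y_{i*} - Y_{i*-1}` that followed the winning window is the
#' analog prediction of the next change. Candidates with zero variance are
#' skipped (their correlation is undefined) and counted; exact ties break
#' toward the most recent anchor.
#'
#' @param query Numeric principal-lag vector, ordered most recent first
#'   (length `p* >= 2`), with positive variance.
#' @param history Numeric vector (or series tibble) of log-scale values.
#' @param search_end Last candidate anchor index (defaults to the end of the
#'   history).
#' @return An object of class `mcml_match`: list with `i_star`, `rho`,
#'   `d_pred`, `n_candidates`, `n_skipped`.
#' @export
most_correlated_window <- function(query, history, search_end = NULL) {
  history <- series_values(history, "history")
  query <- as.numeric(query)
  if (length(query) < 2L) {
    abort_mcml("`query` must have length >= 2.", "parameter")
  }
  search_end <- if (is.null(search_end)) length(history) else
    check_number(search_end, "search_end", lower = 1, integer = TRUE)
  lib <- analog_library(history, length(query), search_end)
  match_in_library(lib, query)
}

#' One-step-ahead analog forecast
#'
#' Predicts the value following the last observation: the query is the
#' principal-lag vector of the final day, `(Y_n-1, ..., Y_n-p*)`, the search
#' runs over all historical anchors, and the forecast is
#' `y_hat = Y_n + D_{i*}`.
#'
#' @param y Numeric vector (or series tibble) of log-scale values.
#' @param p_star Number of principal lags (>= 2), typically from
#'   [select_principal_lags()].
#' @return A list with elements `y_hat` and `match` (an `mcml_match`).
#' @export
one_step_forecast <- function(y, p_star) {
  y <- series_values(y, "y")
  p_star <- check_number(p_star, "p_star", lower = 2, integer = TRUE)
  n <- length(y)
  if (n < p_star + 2L) {
    abort_mcml(sprintf("Need at least %d values for p* = %d.",
                       p_star + 2L, p_star), "data")
  }
  query <- y[(n - 1L):(n - p_star)]
  match <- most_correlated_window(query, y, search_end = n)
  list(y_hat = y[n] + match$d_pred, match = match)
}

#' Iterative multi-step analog forecast
#'
#' Forecasts `M` steps beyond the training series. Step `k` predicts
#' `Y_{N+k}` using the query window of the `p*` values immediately preceding
#' day `N + k - 1` -- observed values for indices `<= N`, previously
#' predicted values beyond -- while the candidate search stays restricted to
#' training anchors (`i <= N`) at every step, so predicted values never
#' contaminate the analog library. Forecasts telescope:
#' `Yhat_{N+k} = Yhat_{N+k-1} + D_{i_k*}` with `Yhat_N = Y_N`, and every
#' predicted increment is a member of the training difference set.
#'
#' A step whose query window is constant falls back to a zero increment with
#' a warning.
#'
#' @param train Numeric vector (or series tibble) of log-scale training
#'   values, length `N >= p* + 3`.
#' @param M Number of steps to forecast (>= 1).
#' @param p_star Number of principal lags (>= 2).
#' @return An object of class `mcml_forecast`: list with `steps` (tibble
#'   `step`, `index`, `y_pred`, `i_star`, `rho`, `d_pred`, `n_skipped`),
#'   `y_pred`, `N`, `M`, `p_star`.
#' @export
multi_step_forecast <- function(train, M, p_star) {
  y <- series_values(train, "train")
  p_star <- check_number(p_star, "p_star", lower = 2, integer = TRUE)
  M <- check_number(M, "M", lower = 1, integer = TRUE)
  N <- length(y)
  if (N < p_star + 3L) {
    abort_mcml(sprintf("Need a training series of length >= %d for p* = %d.",
                       p_star + 3L, p_star), "data")
  }
  lib <- analog_library(y, p_star, search_end = N)
  ytil <- c(y, numeric(M))
  steps <- vector("list", M)
  for (k in seq_len(M)) {
    last <- N + k - 1L
    query <- ytil[(last - 1L):(last - p_star)]
    match <- tryCatch(match_in_library(lib, query),
                      mcml_error_degenerate = function(e) NULL)
    if (is.null(match)) {
      warn_mcml(sprintf(
        "Step %d: constant query window; falling back to a zero increment.",
        k), "degenerate")
      match <- list(i_star = NA_integer_, rho = NA_real_, d_pred = 0,
                    n_candidates = length(lib$anchors), n_skipped = NA_integer_)
    }
    ytil[N + k] <- ytil[N + k - 1L] + match$d_pred
    steps[[k]] <- tibble(step = k, index = N + k, y_pred = ytil[N + k],
                         i_star = match$i_star, rho = match$rho,
                         d_pred = match$d_pred, n_skipped = match$n_skipped)
  }
  structure(list(steps = dplyr::bind_rows(steps),
                 y_pred = ytil[(N + 1L):(N + M)],
                 N = N, M = M, p_star = p_star),
            class = "mcml_forecast")
}

#' @export
print.mcml_forecast <- function(x, ...) {
  cat(sprintf("MCML forecast: %d steps from N = %d training points (p* = %d)\n",
              x$M, x$N, x$p_star))
  print(utils::head(x$steps, 5))
  if (x$M > 5) cat(sprintf("# ... with %d more steps\n", x$M - 5))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, mcml_error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)),
          class = setdiff(class(e), c("rlang_error", "error", "condition")))
  })
}

#' Run the full maximum-correlation machine-learning pipeline
#'
#' End-to-end MCML on a raw daily series: log transform
#' (`Y = log(Z + offset)`), chronological train/test split, BIC selection of
#' the number of principal lags on the training portion only, iterative
#' multi-step analog forecasting over the whole test horizon, and
#' MAE/RMSE/MAPE evaluation against the held-out truth. Everything is
#' deterministic given the inputs.
#'
#' Metrics are computed on the log scale (the algorithm's working scale); a
#' second set on the back-transformed scale is included as `metrics_raw`.
#'
#' @param data A raw series tibble (`date`, `value`) or non-negative numeric
#'   vector.
#' @param train_frac Training fraction, see [train_test_split()].
#' @param q Maximum number of lags for selection (default 19).
#' @param m Regression sample size for selection; default
#'   `min(60, floor(N / 4))` computed on the training length.
#' @param offset Log-transform offset (default 0.05).
#' @param rows Row policy for BIC selection, see [select_principal_lags()].
#' @return An object of class `mcml_fit`: list with `predictions` (tibble
#'   `date`, `step`, `y_true`, `y_pred`, `i_star`, `rho`, `d_pred`),
#'   `selection`, `forecast`, `metrics` (log scale), `metrics_raw`,
#'   `N`, `M`, `p_star`, `offset`, `label`.
#' @export
#' @examples
#' series <- gen_periodic(n = 140, period = 28)
#' fit <- mcml_run(series, train_frac = 0.8, q = 5)
#' glance(fit)
mcml_run <- function(data, train_frac = 0.8, q = 19, m = NULL, offset = 0.05,
                     rows = c("aligned", "literal")) {
  rows <- match.arg(rows)
  z <- series_values(data)
  dates <- series_dates(data, length(z))
  label <- attr(data, "label", exact = TRUE) %||% "series"

  y <- with_stage("log_transform", log_transform(z, offset = offset))
  split <- with_stage("train_test_split", train_test_split(y, train_frac))
  N <- length(split$train)
  M <- length(split$test)
  selection <- with_stage("select_principal_lags",
                          select_principal_lags(split$train, q = q, m = m,
                                                rows = rows))
  p_star <- selection$p_star
  fc <- with_stage("multi_step_forecast",
                   multi_step_forecast(split$train, M = M, p_star = p_star))
  metrics <- with_stage("evaluate",
                        evaluate_forecast(split$test, fc$y_pred))
  metrics_raw <- with_stage("evaluate",
                            evaluate_forecast(z[(N + 1):(N + M)],
                                              exp(fc$y_pred) - offset))

  predictions <- tibble(date = dates[(N + 1):(N + M)],
                        step = fc$steps$step,
                        y_true = split$test,
                        y_pred = fc$y_pred,
                        i_star = fc$steps$i_star,
                        rho = fc$steps$rho,
                        d_pred = fc$steps$d_pred)
  structure(list(predictions = predictions, selection = selection,
                 forecast = fc, metrics = metrics, metrics_raw = metrics_raw,
                 N = N, M = M, p_star = p_star, offset = offset,
                 label = label,
                 train = tibble(date = dates[1:N], y = split$train)),
            class = "mcml_fit")
}

#' @export
print.mcml_fit <- function(x, ...) {
  cat(sprintf("MCML run on '%s': N = %d train, M = %d test, p* = %d\n",
              x$label, x$N, x$M, x$p_star))
  cat(sprintf("  log-scale MAE = %.4f, RMSE = %.4f, MAPE = %.4f\n",
              x$metrics$mae, x$metrics$rmse, x$metrics$mape))
  invisible(x)
}

#' @rdname mcml_run
#' @param x,object An `mcml_fit` object.
#' @param ... Unused.
#' @export
tidy.mcml_fit <- function(x, ...) x$predictions

#' @rdname mcml_run
#' @export
glance.mcml_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(label = x$label, N = x$N, M = x$M,
                          p_star = x$p_star), x$metrics)
}

#' @rdname mcml_run
#' @export
autoplot.mcml_fit <- function(object, ...) {
  train <- tibble(date = object$train$date, value = object$train$y,
                  what = "observed")
  truth <- tibble(date = object$predictions$date,
                  value = object$predictions$y_true, what = "observed")
  pred <- tibble(date = object$predictions$date,
                 value = object$predictions$y_pred, what = "predicted")
  df <- dplyr::bind_rows(train, truth, pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$predictions$date[1],
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(observed = "black",
                                            predicted = "red")) +
    ggplot2::labs(x = NULL, y = sprintf("log(value + %.2g)", object$offset),
                  colour = NULL,
                  title = sprintf("MCML forecast: %s (p* = %d)",
                                  object$label, object$p_star))
}
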