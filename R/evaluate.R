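#' Goodness-of-fit and predictive-accuracy metrics
#'
#' Compares predicted against measured SPAD values with the standard metric
#' set: `SSE`, `RMSE = sqrt(SSE / n)`, `R2 = 1 - SSE / SST`, adjusted
#' `R2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`, and the per-sample predictive
#' accuracy `(1 - |predicted - measured| / measured) * 100` (mean in percent;
#' its standard deviation reported on the fractional scale by default, or in
#' percent via `accuracy_scale`). An optional abnormal-point rule removes
#' pairs whose standardized residual exceeds `k` in absolute value before any
#' metric is computed; `n_removed` reports how many.
#'
#' @param predicted,measured equal-length numeric vectors (n >= 2).
#' @param n_params number of model parameters p entering the adjusted
#'   R-squared (excluding the intercept); `NA` adjusted R-squared is flagged
#'   when `n - p - 1 <= 0`.
#' @param outlier `"none"` (default) or `"abs_residual_z"`.
#' @param k standardized-residual cut for the abnormal rule.
#' @param accuracy compute the accuracy metrics (requires every retained
#'   measured value > 0; a zero measured value is an error).
#' @param accuracy_scale `"fraction"` or `"percent"` scale of the accuracy
#'   standard deviation.
#' @return A `spad_evaluation` list: `n`, `n_removed`, `sse`, `rmse`,
#'   `r_squared`, `adj_r_squared`, `accuracy_pct`, `accuracy_sd`,
#'   `accuracy_scale`.
#' @examples
#' evaluate_predictions(c(30, 20), c(25, 20), n_params = 1)
#' @export
evaluate_predictions <- function(predicted, measured, n_params = NA_integer_,
                                 outlier = c("none", "abs_residual_z"), k = 3,
                                 accuracy = TRUE,
                                 accuracy_scale = c("fraction", "percent")) {
  outlier <- match.arg(outlier)
  accuracy_scale <- match.arg(accuracy_scale)
  predicted <- as.numeric(predicted)
  measured <- as.numeric(measured)
  if (length(predicted) != length(measured) || length(measured) < 2L)
    stop("predicted and measured must be equal-length vectors, n >= 2",
         call. = FALSE)
  n_removed <- 0L
  if (outlier == "abs_residual_z") {
    r <- measured - predicted
    z <- (r - mean(r)) / stats::sd(r)
    drop <- is.finite(z) & abs(z) > k
    n_removed <- sum(drop)
    predicted <- predicted[!drop]
    measured <- measured[!drop]
  }
  n <- length(measured)
  sse <- sum((predicted - measured)^2)
  sst <- sum((measured - mean(measured))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (!is.na(n_params) && n - n_params - 1L > 0L && !is.na(r2))
    1 - (1 - r2) * (n - 1) / (n - n_params - 1) else NA_real_
  acc_mean <- acc_sd <- NA_real_
  if (accuracy) {
    if (any(measured == 0))
      stop("predictive accuracy undefined: a measured value is 0",
           call. = FALSE)
    acc <- (1 - abs(predicted - measured) / measured) * 100
    acc_mean <- mean(acc)
    acc_sd <- stats::sd(acc) / if (accuracy_scale == "fraction") 100 else 1
  }
  structure(list(n = n, n_removed = n_removed, sse = sse,
                 rmse = sqrt(sse / n), r_squared = r2, adj_r_squared = adj,
                 accuracy_pct = acc_mean, accuracy_sd = acc_sd,
                 accuracy_scale = accuracy_scale),
            class = "spad_evaluation")
}

#' @export
print.spad_evaluation <- function(x, ...) {
  cat("<spad_evaluation> n = ", x$n,
      if (x$n_removed > 0) paste0(" (", x$n_removed, " abnormal removed)"),
      "\n  SSE = ", signif(x$sse, 6), ", RMSE = ", signif(x$rmse, 6),
      "\n  R2 = ", signif(x$r_squared, 4), ", adjusted R2 = ",
      signif(x$adj_r_squared, 4), "\n", sep = "")
  if (!is.na(x$accuracy_pct))
    cat("  predictive accuracy = ", round(x$accuracy_pct, 2), "% (SD ",
        signif(x$accuracy_sd, 4), " on the ", x$accuracy_scale, " scale)\n",
        sep = "")
  invisible(x)
}
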