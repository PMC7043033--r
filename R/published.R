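#' Published SPAD association models F1-F4
#'
#' Returns one of the four published tobacco-leaf SPAD models as a ready-made
#' `spad_model` predictor:
#'
#' * `F1` (linear): `59.733 - 0.304 R_Mean`
#' * `F2` (stepwise linear): `76.134 - 0.441 R_Mean - 11.203 Y_Skewness -
#'   1.516 G_Kurtosis`
#' * `F3` (Fourier): `19.38 + 7.972 cos(1.314 R_Median) -
#'   6.747 sin(1.314 R_Median)` (arguments in radians)
#' * `F4` (polynomial surface in `R_Mean`, `R_Skewness`): nine-term cubic,
#'   see `coef(published_model("F4"))`.
#'
#' @param id one of `"F1"`, `"F2"`, `"F3"`, `"F4"`.
#' @return A `spad_model` usable with [predict.spad_model]; it carries no
#'   training data (`fitted`, `residuals`, `plot` are unavailable).
#' @examples
#' predict(published_model("F1"), data.frame(R_Mean = 98.64))  # ~29.75
#' @export
published_model <- function(id = c("F1", "F2", "F3", "F4")) {
  id <- match.arg(id)
  fit <- switch(id,
    F1 = list(family = "stepwise",
              coefficients = c(`(Intercept)` = 59.733, R_Mean = -0.304),
              selected = "R_Mean", n_params = 2L,
              predictors = "R_Mean"),
    F2 = list(family = "stepwise",
              coefficients = c(`(Intercept)` = 76.134, R_Mean = -0.441,
                               Y_Skewness = -11.203, G_Kurtosis = -1.516),
              selected = c("R_Mean", "Y_Skewness", "G_Kurtosis"),
              n_params = 4L,
              predictors = c("R_Mean", "Y_Skewness", "G_Kurtosis")),
    F3 = list(family = "fourier",
              coefficients = c(a0 = 19.38, a1 = 7.972, b1 = -6.747,
                               w = 1.314),
              n_params = 4L, predictors = "R_Median"),
    F4 = {
      powers <- surface_powers(3L, "exact")
      co <- c(0.3344,           # 1
              0.8709, -177.3,   # x1, x2
              -0.005536, 2.876, 8.515,        # x1^2, x1 x2, x2^2
              -0.01227, -0.1398, 7.301)       # x1^2 x2, x1 x2^2, x2^3
      ord <- order(powers$i + powers$j, powers$j)
      stopifnot(identical(ord, seq_len(nrow(powers))))
      names(co) <- ifelse(powers$i + powers$j == 0, "(Intercept)",
                          paste0("x1^", powers$i, ".x2^", powers$j))
      list(family = "surface", coefficients = co, powers = powers,
           degree = 3L, terms = "exact", n_params = 9L,
           predictors = c("R_Mean", "R_Skewness"))
    })
  fit$id <- id
  fit$response <- "SPAD"
  class(fit) <- c(paste0("spad_", fit$family), "spad_model")
  fit
}

#' Evaluate a published model on a feature record
#'
#' Convenience wrapper: `predict(published_model(id), record)`. The printed
#' formula is evaluated exactly; a missing required feature is an error
#' naming the feature.
#'
#' @param id `"F1"`, `"F2"`, `"F3"` or `"F4"`.
#' @param record data.frame of feature records (or a named list/vector with
#'   the required features).
#' @return Numeric vector of SPAD estimates.
#' @export
predict_published <- function(id, record) {
  if (!is.data.frame(record)) record <- as.data.frame(as.list(record))
  predict(published_model(id), record)
}

#' Published goodness-of-fit and prediction table
#'
#' The reported evaluation of the four published models: training R-squared,
#' adjusted R-squared, SSE and RMSE, plus prediction on an independent batch
#' (168 leaves after removal of abnormal readings): mean predictive accuracy
#' `(1 - |predicted - measured| / measured) * 100` and its standard deviation
#' on the fractional scale.
#'
#' @return data.frame with one row per model: `model`, `r_squared`,
#'   `adj_r_squared`, `sse`, `rmse`, `n_prediction`, `n_removed`,
#'   `accuracy_pct`, `accuracy_sd`.
#' @export
published_evaluation <- function() {
  data.frame(
    model = c("F1", "F2", "F3", "F4"),
    r_squared = c(0.583, 0.694, 0.648, 0.719),
    adj_r_squared = c(0.581, 0.689, 0.643, 0.705),
    sse = c(7168, 5260, 6048, 4870),
    rmse = c(6.017, 5.181, 5.555, 5.050),
    n_prediction = c(168L, 168L, 168L, 168L),
    n_removed = c(8L, 16L, 13L, 11L),
    accuracy_pct = c(78.17, 79.36, 64.42, 82.15),
    accuracy_sd = c(0.1832, 0.1976, 0.2320, 0.1732),
    stringsAsFactors = FALSE
  )
}
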