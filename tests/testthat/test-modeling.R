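test_that("stepwise selection finds a planted single predictor among noise", {
  set.seed(61)
  n <- 200
  X <- as.data.frame(matrix(rnorm(n * 20), n))
  names(X) <- paste0("x", 1:20)
  X$SPAD <- 2 * X$x1 + rnorm(n, 0, 0.1)
  fit <- spad_model(SPAD ~ ., X, family = "stepwise")
  # the planted predictor enters first; at p_enter = 0.05 classic stepwise
  # admits a spurious null candidate among 19 with probability ~0.6, so the
  # assertion is on the signal, not on an empty noise set
  expect_identical(fit$trace$variable[1], "x1")
  expect_true("x1" %in% fit$selected)
  expect_lte(length(fit$selected), 2L)
  se <- 0.1 / sqrt(sum((X$x1 - mean(X$x1))^2))
  expect_lt(abs(coef(fit)[["x1"]] - 2), 3 * se)
})

test_that("constant response yields the intercept-only model", {
  df <- data.frame(SPAD = rep(5, 30), x1 = rnorm(30), x2 = rnorm(30))
  fit <- spad_model(SPAD ~ ., df, family = "stepwise")
  expect_length(fit$selected, 0)
  expect_equal(unname(coef(fit)), 5)
  expect_equal(predict(fit, data.frame(x1 = 1, x2 = 2)), 5)
})

test_that("orthogonal planted predictors enter in two steps", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  df <- data.frame(x1 = x1, x2 = x2, SPAD = x1 + x2)
  fit <- spad_model(SPAD ~ x1 + x2, df, family = "stepwise")
  expect_setequal(fit$selected, c("x1", "x2"))
  expect_equal(nrow(fit$trace), 2L)
  expect_equal(coef(fit)[["x1"]], 1, tolerance = 1e-10)
  expect_equal(coef(fit)[["x2"]], 1, tolerance = 1e-10)
})

test_that("stepwise equals brute-force best subset under strong signal", {
  set.seed(62)
  for (rep in 1:5) {
    n <- 120
    X <- matrix(rnorm(n * 6), n)
    colnames(X) <- paste0("x", 1:6)
    truth <- sort(sample(1:6, sample(1:3, 1)))
    y <- X[, truth, drop = FALSE] %*% runif(length(truth), 2, 4) +
      rnorm(n, 0, 0.05)
    df <- cbind(data.frame(SPAD = as.numeric(y)), as.data.frame(X))
    fit <- spad_model(SPAD ~ ., df, family = "stepwise")
    # oracle: best subset by BIC over all 2^6 subsets
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
    bic <- apply(subsets, 1, function(s) {
      Z <- cbind(1, X[, as.logical(s), drop = FALSE])
      r <- stats::lm.fit(Z, as.numeric(y))$residuals
      n * log(mean(r^2)) + log(n) * ncol(Z)
    })
    best <- colnames(X)[as.logical(unlist(subsets[which.min(bic), ]))]
    expect_setequal(fit$selected, best)
  }
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(63)
  df <- data.frame(x1 = rnorm(50))
  df$x2 <- 2 * df$x1            # exact collinearity
  df$SPAD <- df$x1 + rnorm(50, 0, 0.01)
  expect_warning(fit <- spad_model(SPAD ~ x1 + x2, df, family = "stepwise"),
                 "collinear")
  expect_identical(fit$selected, "x1")
})

test_that("fourier fit recovers the published curve from noiseless data", {
  x <- seq(90, 160, length.out = 100)
  y <- 19.38 + 7.972 * cos(1.314 * x) - 6.747 * sin(1.314 * x)
  fit <- spad_model(SPAD ~ R_Median,
                    data.frame(R_Median = x, SPAD = y), family = "fourier")
  co <- coef(fit)
  expect_equal(co[["w"]], 1.314, tolerance = 1e-6)
  expect_equal(co[["a0"]], 19.38, tolerance = 1e-6)
  expect_equal(co[["a1"]], 7.972, tolerance = 1e-6)
  expect_equal(co[["b1"]], -6.747, tolerance = 1e-6)
})

test_that("fourier degenerate and fixed-frequency paths are exact", {
  df <- data.frame(x = seq(0, 10, length.out = 40), SPAD = 7)
  fit <- spad_model(SPAD ~ x, df, family = "fourier")
  expect_equal(coef(fit)[["a0"]], 7, tolerance = 1e-6)
  expect_equal(abs(coef(fit)[["a1"]]), 0, tolerance = 1e-6)
  expect_equal(abs(coef(fit)[["b1"]]), 0, tolerance = 1e-6)

  # fixed w reduces to linear least squares: match the normal equations
  set.seed(64)
  x <- runif(60, 0, 20)
  y <- 3 + 2 * cos(0.8 * x) - 1.5 * sin(0.8 * x) + rnorm(60, 0, 0.3)
  fit <- spad_model(SPAD ~ x, data.frame(x = x, SPAD = y),
                    family = "fourier", w = 0.8)
  Z <- cbind(1, cos(0.8 * x), sin(0.8 * x))
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  expect_equal(unname(coef(fit)[c("a0", "a1", "b1")]), as.numeric(beta),
               tolerance = 1e-10)
})

test_that("fourier SSE never exceeds the intercept-only SSE", {
  set.seed(65)
  for (rep in 1:5) {
    x <- runif(30, 0, 50)
    y <- rnorm(30, 20, 4)
    fit <- spad_model(SPAD ~ x, data.frame(x = x, SPAD = y),
                      family = "fourier")
    expect_lte(sum(residuals(fit)^2), sum((y - mean(y))^2) + 1e-8)
  }
})

test_that("surface fit recovers the published nine-term cubic exactly", {
  grid <- expand.grid(R_Mean = seq(90, 160, length.out = 20),
                      R_Skewness = seq(-0.8, 0.8, length.out = 20))
  grid$SPAD <- predict_published("F4", grid)
  fit <- spad_model(SPAD ~ R_Mean + R_Skewness, grid, family = "surface")
  expect_equal(coef(fit), coef(published_model("F4")), tolerance = 1e-6)
  expect_false("x1^3.x2^0" %in% names(coef(fit)))   # exact-terms layout
  full <- spad_model(SPAD ~ R_Mean + R_Skewness, grid, family = "surface",
                     terms = "full")
  expect_true("x1^3.x2^0" %in% names(coef(full)))
  expect_equal(length(coef(full)), 10L)
})

test_that("planar data yields only the planar surface term", {
  set.seed(66)
  df <- data.frame(x1 = runif(50, -2, 2), x2 = runif(50, -2, 2))
  df$SPAD <- df$x1
  fit <- spad_model(SPAD ~ x1 + x2, df, family = "surface")
  co <- coef(fit)
  expect_equal(co[["x1^1.x2^0"]], 1, tolerance = 1e-8)
  expect_lt(max(abs(co[setdiff(names(co), "x1^1.x2^0")])), 1e-8)
})

test_that("rank-deficient surface designs report the offending terms", {
  df <- data.frame(x1 = rep(1, 20), x2 = rnorm(20), SPAD = rnorm(20))
  expect_error(spad_model(SPAD ~ x1 + x2, df, family = "surface"),
               "offending term")
})

test_that("the cubic surface never fits worse than the linear model", {
  set.seed(67)
  for (rep in 1:5) {
    ds <- small_dataset(seed = 600 + rep, leaves_per_age = 3,
                        width = 36, height = 44)
    rec <- ds$records
    lin <- spad_model(SPAD ~ R_Mean, rec, family = "stepwise")
    # force R_Mean in even if stepwise would not enter it
    lin_sse <- sum(lm(SPAD ~ R_Mean, rec)$residuals^2)
    surf <- spad_model(SPAD ~ R_Mean + R_Skewness, rec, family = "surface",
                       terms = "full")
    sst <- sum((rec$SPAD - mean(rec$SPAD))^2)
    expect_gte(1 - sum(residuals(surf)^2) / sst, 1 - lin_sse / sst - 1e-10)
  }
})

test_that("published models evaluate their printed formulas exactly", {
  expect_equal(predict_published("F1", data.frame(R_Mean = 98.64)),
               59.733 - 0.304 * 98.64, tolerance = 1e-12)
  expect_equal(round(predict_published("F1", data.frame(R_Mean = 98.64)), 2),
               29.75)
  expect_equal(predict_published("F2", data.frame(R_Mean = 0, Y_Skewness = 0,
                                                  G_Kurtosis = 0)), 76.134)
  expect_equal(predict_published("F3", data.frame(R_Median = 0)),
               19.38 + 7.972)
  expect_equal(predict_published("F4", data.frame(R_Mean = 0,
                                                  R_Skewness = 0)), 0.3344)
  # radians: one full period of the F3 curve
  expect_equal(predict_published("F3", data.frame(R_Median = 2 * pi / 1.314)),
               19.38 + 7.972, tolerance = 1e-9)

  # statelessness: repeated evaluation is bit-identical
  rec <- data.frame(R_Mean = 121.78, R_Skewness = -0.19, R_Median = 123.68,
                    Y_Skewness = -0.2, G_Kurtosis = 0.06)
  for (id in c("F1", "F2", "F3", "F4"))
    expect_identical(predict_published(id, rec), predict_published(id, rec))

  expect_error(predict_published("F2", data.frame(R_Mean = 1)), "Y_Skewness")
})

test_that("model evaluation metrics match their defining formulas", {
  ev <- evaluate_predictions(c(10, 20, 30), c(10, 20, 30), n_params = 1)
  expect_equal(ev$sse, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$accuracy_pct, 100)

  ev2 <- evaluate_predictions(c(30, 20), c(25, 20), n_params = NA)
  expect_equal((1 - abs(30 - 25) / 25) * 100, 80)
  expect_equal(ev2$accuracy_pct, mean(c(80, 100)))

  # adjusted R2 hand check: R2 = 0.5, n = 12, p = 1 -> 0.45
  set.seed(68)
  meas <- rnorm(12, 20, 3)
  sst <- sum((meas - mean(meas))^2)
  # build predictions with SSE = sst / 2 by shrinking residuals
  pred <- meas - sqrt(0.5) * (meas - mean(meas))
  ev3 <- evaluate_predictions(pred, meas, n_params = 1)
  expect_equal(ev3$r_squared, 0.5, tolerance = 1e-12)
  expect_equal(ev3$adj_r_squared, 0.45, tolerance = 1e-12)

  expect_error(evaluate_predictions(c(1, 2), c(0, 2)), "measured value is 0")
})

test_that("the abnormal-residual rule removes gross outliers only", {
  set.seed(69)
  meas <- rnorm(60, 25, 1)
  pred <- meas + rnorm(60, 0, 0.5)
  pred[7] <- meas[7] + 30
  ev <- evaluate_predictions(pred, meas, outlier = "abs_residual_z", k = 3)
  expect_equal(ev$n_removed, 1L)
  expect_equal(ev$n, 59L)
  ev_none <- evaluate_predictions(pred, meas)
  expect_gt(ev_none$rmse, ev$rmse)

  # accuracy SD scale switch: percent = 100 x fraction
  evp <- evaluate_predictions(pred, meas, accuracy_scale = "percent")
  expect_equal(evp$accuracy_sd, ev_none$accuracy_sd * 100)
})

test_that("spad_model objects expose the standard S3 surface", {
  set.seed(70)
  df <- data.frame(x = runif(40, 0, 10))
  df$SPAD <- 30 - 2 * df$x + rnorm(40, 0, 0.5)
  fit <- spad_model(SPAD ~ x, df, family = "stepwise")
  expect_s3_class(fit, "spad_model")
  expect_equal(fitted(fit) + residuals(fit), df$SPAD, tolerance = 1e-12)
  expect_output(print(fit), "stepwise")
  expect_output(print(summary(fit)), "R2")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(40L, 3L))
  sims2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sims, sims2)
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()

  # JSON round trip preserves predictions
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  nd <- data.frame(x = c(0, 5, 10))
  expect_equal(predict(back, nd), predict(fit, nd), tolerance = 1e-12)
})
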