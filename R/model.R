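#' Fit a SPAD association model
#'
#' Fits one of the three model families relating SPAD chlorophyll readings to
#' leaf colour features:
#'
#' * `family = "stepwise"` — multivariate linear regression built by classic
#'   forward selection with backward elimination on partial-F p-values
#'   (enter at `p_enter`, remove at `p_remove`). All right-hand-side terms of
#'   the formula are candidates; `SPAD ~ .` uses every numeric feature column.
#' * `family = "fourier"` — single-term Fourier curve
#'   `y = a0 + a1 cos(w x) + b1 sin(w x)` on one predictor; the frequency `w`
#'   is found by a multistart grid search (linear least squares for
#'   `a0, a1, b1` at each `w`) followed by local refinement, or fixed via `w`.
#' * `family = "surface"` — bivariate polynomial surface on two predictors,
#'   all monomials `x1^i x2^j` with `i + j <= degree`. With
#'   `terms = "exact"` (default) the `x1^degree` pure term is dropped,
#'   matching the published nine-term cubic layout; `terms = "full"` keeps
#'   the complete set.
#'
#' @param formula model formula, e.g. `SPAD ~ .` (stepwise),
#'   `SPAD ~ R_Median` (fourier), `SPAD ~ R_Mean + R_Skewness` (surface).
#' @param data data.frame of feature records (see [extract_features]).
#' @param family model family.
#' @param p_enter,p_remove stepwise partial-F entry/removal thresholds.
#' @param w fixed Fourier angular frequency (radians per predictor unit);
#'   `NULL` (default) searches for it.
#' @param degree total polynomial degree of the surface.
#' @param terms `"exact"` or `"full"` surface term set.
#' @return An object of class `c("spad_<family>", "spad_model")` supporting
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`. Stepwise fits carry a `$trace` data.frame of enter/remove
#'   actions with their partial-F p-values.
#' @examples
#' ds <- generate_dataset(leaves_per_age = 5, seed = 42,
#'                        spec_template = leaf_spec(width = 60, height = 80))
#' fit <- spad_model(SPAD ~ R_Mean + R_Skewness, ds$records, family = "surface")
#' summary(fit)
#' @export
spad_model <- function(formula, data,
                       family = c("stepwise", "fourier", "surface"),
                       p_enter = 0.05, p_remove = 0.10,
                       w = NULL, degree = 3L, terms = c("exact", "full")) {
  family <- match.arg(family)
  terms <- match.arg(terms)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  yname <- all.vars(formula[[2L]])
  if (!yname %in% names(data)) stop("response ", yname, " not in data",
                                    call. = FALSE)
  rhs <- formula[[3L]]
  if (identical(rhs, as.name("."))) {
    num <- vapply(data, is.numeric, logical(1))
    xnames <- setdiff(names(data)[num], c(yname, "age", "n_pixels"))
  } else {
    xnames <- all.vars(rhs)
  }
  missing <- setdiff(xnames, names(data))
  if (length(missing)) stop("predictors not in data: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(data[c(yname, xnames)])
  y <- as.numeric(data[[yname]][keep])
  X <- as.matrix(data[keep, xnames, drop = FALSE])
  fit <- switch(family,
    stepwise = fit_stepwise(X, y, p_enter, p_remove),
    fourier = {
      if (ncol(X) != 1L) stop("fourier family needs exactly one predictor",
                              call. = FALSE)
      fit_fourier1(X[, 1L], y, w = w)
    },
    surface = {
      if (ncol(X) != 2L) stop("surface family needs exactly two predictors",
                              call. = FALSE)
      fit_poly_surface(X[, 1L], X[, 2L], y, degree = degree, terms = terms)
    })
  fit$response <- yname
  fit$predictors <- xnames
  fit$n <- length(y)
  fit$y <- y
  fit$fitted.values <- as.numeric(predict_core(fit, X))
  fit$residuals <- y - fit$fitted.values
  fit$sigma <- if (fit$n > fit$n_params)
    sqrt(sum(fit$residuals^2) / (fit$n - fit$n_params)) else 0
  fit$call <- match.call()
  class(fit) <- c(paste0("spad_", family), "spad_model")
  fit
}

## ---- stepwise -------------------------------------------------------------

fit_stepwise <- function(X, y, p_enter, p_remove) {
  n <- length(y)
  cand <- colnames(X)
  const <- apply(X, 2L, function(c) stats::sd(c) == 0)
  if (any(const)) {
    warning("dropping constant candidate(s): ",
            paste(cand[const], collapse = ", "))
    cand <- cand[!const]
  }
  tss <- sum((y - mean(y))^2)
  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  rss <- function(vars) {
    Z <- cbind(`(Intercept)` = 1, X[, vars, drop = FALSE])
    f <- stats::lm.fit(Z, y)
    if (f$rank < ncol(Z)) return(NA_real_)   # collinear set
    sum(f$residuals^2)
  }
  rss_cur <- tss
  repeat {
    if (step >= 100L) {
      warning("stepwise selection stopped after 100 actions")
      break
    }
    changed <- FALSE
    # forward: best entering candidate by partial-F p-value
    pool <- setdiff(cand, selected)
    if (length(pool) && n > length(selected) + 2L &&
        rss_cur > 1e-12 * max(tss, 1)) {
      p_in <- vapply(pool, function(v) {
        r1 <- rss(c(selected, v))
        if (is.na(r1)) return(NA_real_)      # collinear: skip
        df2 <- n - length(selected) - 2L
        f <- (rss_cur - r1) / (r1 / df2)
        if (!is.finite(f)) return(0)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (any(is.na(p_in)))
        warning("skipping collinear candidate(s): ",
                paste(pool[is.na(p_in)], collapse = ", "))
      ok <- which(!is.na(p_in))
      if (length(ok) && min(p_in[ok]) < p_enter) {
        best <- ok[which.min(p_in[ok])]      # ties: smallest p, first column
        selected <- c(selected, pool[best])
        rss_cur <- rss(selected)
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "enter",
                                         variable = pool[best],
                                         p_value = p_in[best]))
        changed <- TRUE
      }
    }
    # backward: remove the worst included variable above p_remove
    if (length(selected) > 0L) {
      p_out <- vapply(selected, function(v) {
        r0 <- rss(setdiff(selected, v))
        df2 <- n - length(selected) - 1L
        if (rss_cur <= 1e-12 * max(tss, 1))
          return(if (r0 > 1e-12 * max(tss, 1)) 0 else 1)
        f <- (r0 - rss_cur) / (rss_cur / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (max(p_out) > p_remove) {
        worst <- which.max(p_out)
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         variable = selected[worst],
                                         p_value = p_out[worst]))
        selected <- selected[-worst]
        rss_cur <- if (length(selected)) rss(selected) else tss
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Z <- cbind(`(Intercept)` = 1, X[, selected, drop = FALSE])
  beta <- qr.coef(qr(Z), y)
  list(family = "stepwise", coefficients = beta, selected = selected,
       trace = trace, n_params = length(beta),
       p_enter = p_enter, p_remove = p_remove)
}

## ---- fourier --------------------------------------------------------------

# linear subproblem at fixed frequency: returns (coef, sse)
fourier_ls <- function(x, y, w) {
  Z <- cbind(1, cos(w * x), sin(w * x))
  f <- stats::lm.fit(Z, y)
  co <- unname(f$coefficients)
  co[is.na(co)] <- 0
  list(coef = co, sse = sum(f$residuals^2))
}

fit_fourier1 <- function(x, y, w = NULL) {
  n <- length(y)
  if (n < 5L) stop("fourier fit needs n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("fourier fit needs a non-constant predictor",
                              call. = FALSE)
  if (is.null(w)) {
    rng <- diff(range(x))
    dx_min <- min(diff(sort(unique(x))))
    w_lo <- 0.5 * 2 * pi / rng
    w_hi <- 2 * pi / dx_min
    # grid fine enough to bracket every local SSE basin (~ period 2*pi/rng)
    step <- (2 * pi / rng) / 8
    grid <- seq(w_lo, w_hi, by = step)
    sses <- vapply(grid, function(wk) fourier_ls(x, y, wk)$sse, numeric(1))
    # refine every local basin of the SSE profile: equally spaced predictors
    # alias frequencies (w and 2*pi/dx - w fit identically), and the contract
    # is that exact ties resolve to the smallest frequency
    k <- length(sses)
    is_min <- sses <= c(Inf, sses[-k]) & sses <= c(sses[-1], Inf)
    cand <- which(is_min)
    refined <- lapply(cand, function(b) {
      stats::optimize(function(wk) fourier_ls(x, y, wk)$sse,
                      lower = grid[max(1L, b - 1L)],
                      upper = grid[min(k, b + 1L)], tol = 1e-12)
    })
    obj <- vapply(refined, `[[`, numeric(1), "objective")
    ws <- vapply(refined, `[[`, numeric(1), "minimum")
    sst <- sum((y - mean(y))^2)
    w <- min(ws[obj <= min(obj) + 1e-12 * max(sst, 1)])
    # polish around the winner
    opt2 <- stats::optimize(function(wk) fourier_ls(x, y, wk)$sse,
                            lower = w - step / 50, upper = w + step / 50,
                            tol = 1e-14)
    if (opt2$objective <= fourier_ls(x, y, w)$sse) w <- opt2$minimum
  }
  ls <- fourier_ls(x, y, w)
  if (!all(is.finite(ls$coef)))
    stop("fourier fit failed to converge for every frequency start",
         call. = FALSE)
  list(family = "fourier",
       coefficients = c(a0 = ls$coef[1L], a1 = ls$coef[2L], b1 = ls$coef[3L],
                        w = w),
       n_params = 4L)
}

## ---- polynomial surface ---------------------------------------------------

surface_powers <- function(degree, terms) {
  pw <- expand.grid(i = 0:degree, j = 0:degree)
  pw <- pw[pw$i + pw$j <= degree, ]
  if (terms == "exact") pw <- pw[!(pw$i == degree & pw$j == 0L), ]
  pw <- pw[order(pw$i + pw$j, pw$j), ]
  rownames(pw) <- NULL
  pw
}

surface_design <- function(x1, x2, powers) {
  Z <- mapply(function(i, j) x1^i * x2^j, powers$i, powers$j)
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = length(x1))
  colnames(Z) <- ifelse(powers$i + powers$j == 0, "(Intercept)",
                        paste0("x1^", powers$i, ".x2^", powers$j))
  Z
}

fit_poly_surface <- function(x1, x2, y, degree = 3L, terms = "exact") {
  powers <- surface_powers(degree, terms)
  if (length(y) < nrow(powers))
    stop("need at least ", nrow(powers), " observations for a degree-",
         degree, " surface", call. = FALSE)
  Z <- surface_design(x1, x2, powers)
  # scale columns for conditioning; report coefficients on the original scale
  sc <- apply(abs(Z), 2L, max)
  sc[sc == 0] <- 1
  Zs <- sweep(Z, 2L, sc, "/")
  dec <- qr(Zs)
  if (dec$rank < ncol(Zs)) {
    bad <- colnames(Zs)[dec$pivot[(dec$rank + 1L):ncol(Zs)]]
    stop("rank-deficient surface design; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(dec, y) / sc
  names(beta) <- colnames(Z)
  list(family = "surface", coefficients = beta, powers = powers,
       degree = degree, terms = terms, n_params = length(beta))
}

## ---- shared methods -------------------------------------------------------

predict_core <- function(object, X) {
  switch(object$family,
    stepwise = {
      co <- object$coefficients
      vars <- setdiff(names(co), "(Intercept)")
      out <- rep(co[["(Intercept)"]], nrow(X))
      if (length(vars)) out <- out + as.numeric(X[, vars, drop = FALSE] %*% co[vars])
      out
    },
    fourier = {
      co <- object$coefficients
      x <- X[, 1L]
      as.numeric(co[["a0"]] + co[["a1"]] * cos(co[["w"]] * x) +
                 co[["b1"]] * sin(co[["w"]] * x))
    },
    surface = {
      Z <- surface_design(X[, 1L], X[, 2L], object$powers)
      as.numeric(Z %*% object$coefficients)
    })
}

needed_columns <- function(object) {
  switch(object$family,
         stepwise = setdiff(names(object$coefficients), "(Intercept)"),
         object$predictors)
}

#' Predict SPAD from a fitted or published model
#'
#' @param object a `spad_model` (from [spad_model] or [published_model]).
#' @param newdata data.frame of feature records containing the model's
#'   predictor columns; omit to return the training fitted values. Fourier
#'   trigonometric arguments are in radians.
#' @param ... unused.
#' @return Numeric vector of SPAD estimates.
#' @export
predict.spad_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  need <- needed_columns(object)
  missing <- setdiff(need, names(newdata))
  if (length(missing))
    stop("newdata lacks required feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- if (object$family == "stepwise") need else object$predictors
  newdata <- as.data.frame(newdata)
  X <- as.matrix(newdata[, cols, drop = FALSE])
  if (!nrow(X)) X <- matrix(numeric(0), nrow = nrow(newdata), ncol = 0)
  predict_core(object, X)
}

#' @export
coef.spad_model <- function(object, ...) object$coefficients

#' @export
fitted.spad_model <- function(object, ...) object$fitted.values

#' @export
residuals.spad_model <- function(object, ...) object$residuals

#' @export
print.spad_model <- function(x, digits = 6, ...) {
  cat("<spad_model> family:", x$family,
      if (!is.null(x$id)) paste0("(published ", x$id, ")"), "\n")
  cat("  response:", x$response, " predictors:",
      paste(x$predictors, collapse = ", "), "\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.spad_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$y)) {
    out$evaluation <- evaluate_predictions(object$fitted.values, object$y,
                                           n_params = object$n_params - 1L,
                                           accuracy = !any(object$y <= 0))
  }
  class(out) <- "summary.spad_model"
  out
}

#' @export
print.summary.spad_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$trace) && nrow(x$model$trace)) {
    cat("stepwise trace:\n")
    print.data.frame(x$model$trace, row.names = FALSE)
  }
  if (!is.null(x$evaluation)) {
    cat("training fit:\n")
    print(x$evaluation)
  }
  invisible(x)
}

#' @export
plot.spad_model <- function(x, ...) {
  if (is.null(x$y)) stop("published models carry no training data to plot",
                         call. = FALSE)
  graphics::plot(x$fitted.values, x$y, xlab = "fitted SPAD",
                 ylab = "measured SPAD",
                 main = paste("SPAD model:", x$family), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate SPAD responses from a fitted model
#'
#' Draws `nsim` response vectors as model prediction plus Gaussian noise with
#' the fit's residual standard deviation (or `sigma`).
#'
#' @param object a `spad_model`.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param newdata feature records to predict at (default: training data fits).
#' @param sigma noise SD; defaults to the fit's residual SD.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated responses.
#' @export
simulate.spad_model <- function(object, nsim = 1, seed = NULL,
                                newdata = NULL, sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata)
  if (is.null(sigma)) sigma <- if (is.null(object$sigma)) 0 else object$sigma
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
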