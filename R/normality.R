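#' Jarque-Bera normality test
#'
#' Tests a gradation sample (or any numeric vector) against normality using
#' the biased sample skewness S and raw kurtosis K: the statistic is
#' `JB = (n / 6) * (S^2 + (K - 3)^2 / 4)`, asymptotically chi-squared with 2
#' degrees of freedom under the null. The asymptotic tail is adequate at
#' pixel-scale sample sizes; no small-sample table is used.
#'
#' @param sample a `pixel_sample` or numeric vector, n >= 8, nonzero variance.
#' @param alpha significance level for the reject decision.
#' @return A `normality_result`: list with `method = "jarque_bera"`,
#'   `statistic`, `p_value`, `reject` (`p_value < alpha`), `alpha`, `n`.
#' @export
jarque_bera <- function(sample, alpha = 0.05) {
  x <- normality_input(sample, min_n = 8L)
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0)
    stop("zero variance: Jarque-Bera statistic undefined", call. = FALSE)
  S <- mean(d^3) / m2^1.5
  K <- mean(d^4) / m2^2
  jb <- (n / 6) * (S^2 + (K - 3)^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  normality_result("jarque_bera", jb, p, alpha, n)
}

normality_input <- function(sample, min_n) {
  x <- if (inherits(sample, "pixel_sample")) as.numeric(sample$values)
       else as.numeric(sample)
  if (anyNA(x)) stop("sample contains missing values", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " observations", call. = FALSE)
  x
}

normality_result <- function(method, statistic, p, alpha, n) {
  structure(list(method = method, statistic = statistic, p_value = p,
                 reject = p < alpha, alpha = alpha, n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat("<normality_result> ", x$method, ": statistic = ",
      signif(x$statistic, 6), ", p = ", format(x$p_value),
      if (x$method == "lilliefors") " (clipped to [0.001, 0.5])",
      ", n = ", x$n, "\n  normality ",
      if (x$reject) "REJECTED" else "not rejected",
      " at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test against a normal law with mean and standard
#' deviation estimated from the sample:
#' `D = sup_x | F_n(x) - Phi((x - xbar) / s) |`. Because the parameters are
#' estimated, the usual KS null distribution does not apply; p-values are
#' interpolated from a Monte-Carlo-calibrated critical-value table (20,000
#' null replicates per sample-size grid point, fixed seed, shipped with the
#' package) and clipped to the conventional reporting range [0.001, 0.5].
#' For sample sizes above the table grid the critical values are carried over
#' by the asymptotic `1/sqrt(n)` scaling of the largest grid row.
#'
#' @param sample a `pixel_sample` or numeric vector, n >= 4, nonzero variance.
#' @param alpha significance level for the reject decision.
#' @return A `normality_result` with `method = "lilliefors"`; `p_value` is
#'   always in [0.001, 0.5].
#' @examples
#' set.seed(1)
#' lilliefors(rnorm(100))          # p near the 0.5 ceiling
#' lilliefors(rexp(1000))          # p at the 0.001 floor
#' @export
lilliefors <- function(sample, alpha = 0.05) {
  x <- normality_input(sample, min_n = 4L)
  n <- length(x)
  if (stats::sd(x) == 0)
    stop("zero variance: Lilliefors statistic undefined", call. = FALSE)
  D <- lilliefors_statistic(x)
  p <- lilliefors_pvalue(D, n)
  normality_result("lilliefors", D, p, alpha, n)
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort(stats::pnorm(x, mean(x), stats::sd(x)))
  i <- seq_len(n)
  max(pmax(abs(z - i / n), abs(z - (i - 1) / n)))
}

# reporting-range clip convention
LILLIEFORS_P_RANGE <- c(0.001, 0.5)

lilliefors_pvalue <- function(D, n) {
  tab <- lilliefors_table_cached()
  levels <- attr(tab, "levels")          # descending: 0.5 ... 0.001
  crit <- lilliefors_crit_at_n(tab, levels, n)
  if (D <= crit[1L]) return(LILLIEFORS_P_RANGE[2L])
  if (D >= crit[length(crit)]) return(LILLIEFORS_P_RANGE[1L])
  # log-linear interpolation of the tail probability in D
  p <- exp(stats::approx(crit, log(levels), xout = D, ties = "ordered")$y)
  min(max(p, LILLIEFORS_P_RANGE[1L]), LILLIEFORS_P_RANGE[2L])
}

lilliefors_crit_at_n <- function(tab, levels, n) {
  ns <- tab$n
  k <- length(levels)
  crit_cols <- as.matrix(tab[, -1L, drop = FALSE])
  if (n <= ns[1L]) return(crit_cols[1L, ])
  if (n >= ns[length(ns)]) {
    # asymptotic 1/sqrt(n) continuation of the largest calibrated row
    return(crit_cols[nrow(crit_cols), ] * sqrt(ns[length(ns)] / n))
  }
  # interpolate across the grid linearly in 1/sqrt(n), per level
  s <- 1 / sqrt(ns)
  vapply(seq_len(k), function(j)
    stats::approx(s, crit_cols[, j], xout = 1 / sqrt(n))$y, numeric(1))
}

lilliefors_env <- new.env(parent = emptyenv())

lilliefors_table_cached <- function() {
  if (is.null(lilliefors_env$tab)) {
    path <- system.file("extdata", "lilliefors_critical.csv",
                        package = "leafskew", mustWork = TRUE)
    tab <- utils::read.csv(path, check.names = FALSE)
    attr(tab, "levels") <- as.numeric(sub("^p", "", names(tab)[-1L]))
    lilliefors_env$tab <- tab
  }
  lilliefors_env$tab
}

#' Monte-Carlo calibration of Lilliefors critical values
#'
#' Simulates the null distribution of the Lilliefors statistic (standard
#' normal samples, mean and SD re-estimated per replicate) on a grid of
#' sample sizes and returns the upper-tail critical values at the requested
#' tail probabilities. This regenerates the table shipped in
#' `inst/extdata/lilliefors_critical.csv` (seed 20200226, 20,000 replicates).
#'
#' @param ns integer grid of sample sizes.
#' @param levels descending upper-tail probabilities (reported p-values).
#' @param nreps Monte-Carlo replicates per grid point (>= 10,000 recommended).
#' @param seed RNG seed.
#' @return data.frame with column `n` and one column `p<level>` per level.
#' @export
lilliefors_critical_table <- function(ns = c(4:10, 12L, 15L, 20L, 25L, 30L,
                                             40L, 50L, 75L, 100L, 150L, 200L,
                                             300L, 500L, 1000L),
                                      levels = c(0.5, 0.25, 0.15, 0.1, 0.05,
                                                 0.025, 0.01, 0.005, 0.001),
                                      nreps = 20000L, seed = 20200226L) {
  stopifnot(all(ns >= 4L), all(diff(ns) > 0), all(diff(levels) < 0))
  set.seed(seed)
  rows <- lapply(ns, function(n) {
    d <- vapply(seq_len(nreps),
                function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
    stats::quantile(d, probs = 1 - levels, names = FALSE, type = 8)
  })
  out <- data.frame(n = ns)
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("p", levels)
  cbind(out, as.data.frame(m))
}
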