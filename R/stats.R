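#' Pearson correlation of leaf features with SPAD
#'
#' Correlates every feature column of a record table with the measured SPAD
#' values: Pearson r, two-tailed p-value from the t distribution with n - 2
#' degrees of freedom, and significance stars (`*` at p < 0.05, `**` at
#' p < 0.01). Constant features get an `NA` correlation (flagged, not an
#' error). No multiple-testing correction is applied across features.
#'
#' @param records data.frame of feature records (see [extract_features]).
#' @param target name of the target column, default `"SPAD"`.
#' @param features character vector of feature columns; default every numeric
#'   column except the target, `age` and `n_pixels`.
#' @return A `data.frame` of class `spad_correlation` with columns `feature`,
#'   `r`, `p_value`, `stars`, `n`.
#' @export
correlate_spad <- function(records, target = "SPAD", features = NULL) {
  stopifnot(is.data.frame(records), target %in% names(records))
  y <- records[[target]]
  if (is.null(features)) {
    num <- vapply(records, is.numeric, logical(1))
    features <- setdiff(names(records)[num], c(target, "age", "n_pixels"))
  }
  rows <- lapply(features, function(f) {
    x <- records[[f]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L)
      stop("need at least 3 complete records to correlate ", f, call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(feature = f, r = NA_real_, p_value = NA_real_,
                        stars = "", n = n, stringsAsFactors = FALSE))
    r <- stats::cor(x[ok], y[ok])
    # exact |r| = 1 has zero residual: p = 0 by continuity
    p <- if (abs(r) >= 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    }
    data.frame(feature = f, r = r, p_value = p,
               stars = if (is.na(p)) "" else if (p < 0.01) "**"
                       else if (p < 0.05) "*" else "",
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spad_correlation", "data.frame")
  out
}

#' @export
print.spad_correlation <- function(x, digits = 3, ...) {
  df <- data.frame(feature = x$feature,
                   r = round(x$r, digits),
                   p = signif(x$p_value, digits),
                   sig = x$stars)
  print.data.frame(df, row.names = FALSE)
  cat("---\n* p < 0.05, ** p < 0.01 (two-tailed)\n")
  invisible(x)
}

#' Duncan multiple-range test with compact letter display
#'
#' One-way ANOVA followed by Duncan's multiple-range test: least significant
#' ranges come from studentized-range quantiles at the Duncan protection
#' level `1 - (1 - alpha)^(p - 1)` for a stretch of p ordered means, and the
#' compact letters are assigned by the insert-and-absorb procedure on means
#' sorted ascending (letter "a" attaches to the smallest mean). Groups that
#' share a letter are not significantly different at `alpha`. With unequal
#' group sizes the harmonic mean of the stretch's extreme group sizes enters
#' the range standard error.
#'
#' @param values numeric response (e.g. one feature, one value per leaf).
#' @param groups group labels of the same length (e.g. leaf age).
#' @param alpha significance level, default 0.05.
#' @return A `duncan_letters` object: data.frame with columns `group`, `n`,
#'   `mean`, `letters` (ascending means), plus attributes `MSE`, `df`,
#'   `anova_F`, `anova_p`, `alpha`.
#' @examples
#' set.seed(1)
#' duncan_letters(c(rnorm(10), rnorm(10, 8)), rep(c("young", "old"), each = 10))
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  values <- as.numeric(values)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ni <- tabulate(groups)
  if (any(ni < 2L)) stop("every group needs at least 2 observations",
                         call. = FALSE)
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  df <- an[["Df"]][2L]
  means <- tapply(values, groups, mean)
  ord <- order(means)
  m <- as.numeric(means)[ord]
  n_ord <- ni[ord]
  # stretch (i..j) homogeneous iff its extreme means differ by less than the
  # least significant range for span p = j - i + 1
  lsr <- function(p, nh) {
    prot <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - prot, nmeans = p, df = df) * sqrt(mse / nh)
  }
  homog <- function(i, j) {
    if (i == j) return(TRUE)
    nh <- 2 / (1 / n_ord[i] + 1 / n_ord[j])
    (m[j] - m[i]) <= lsr(j - i + 1L, nh)
  }
  # maximal homogeneous stretches -> letters (insert-and-absorb)
  stretches <- list()
  for (i in seq_len(k)) {
    js <- i
    for (j in seq(i, k)) if (homog(i, j)) js <- j
    stretches[[i]] <- c(i, js)
  }
  keep <- vapply(seq_len(k), function(a) {
    !any(vapply(seq_len(k)[-a], function(b)
      stretches[[b]][1L] <= stretches[[a]][1L] &&
      stretches[[b]][2L] >= stretches[[a]][2L] &&
      (stretches[[b]][2L] - stretches[[b]][1L]) >
        (stretches[[a]][2L] - stretches[[a]][1L]), logical(1)))
  }, logical(1))
  stretches <- unique(stretches[keep])
  lett <- character(k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    idx <- rng[1L]:rng[2L]
    lett[idx] <- paste0(lett[idx], letters[s])
  }
  out <- data.frame(group = levels(groups)[ord], n = n_ord, mean = m,
                    letters = lett, stringsAsFactors = FALSE)
  attr(out, "MSE") <- mse
  attr(out, "df") <- df
  attr(out, "anova_F") <- an[["F value"]][1L]
  attr(out, "anova_p") <- an[["Pr(>F)"]][1L]
  attr(out, "alpha") <- alpha
  class(out) <- c("duncan_letters", "data.frame")
  out
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat("Duncan multiple-range test (alpha = ", attr(x, "alpha"),
      ", MSE = ", signif(attr(x, "MSE"), 4),
      ", df = ", attr(x, "df"), ")\n", sep = "")
  print.data.frame(data.frame(group = x$group, n = x$n,
                              mean = round(x$mean, 3), letters = x$letters),
                   row.names = FALSE)
  cat("groups sharing a letter are not significantly different\n")
  invisible(x)
}
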