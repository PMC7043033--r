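#' Gradation-level histogram of a pixel sample
#'
#' Counts how many masked pixels fall on each of the 256 integer gradation
#' levels. The cumulative view (running sum across levels) is the display
#' used for colour cumulative frequency histograms.
#'
#' @param sample a `pixel_sample` from [channel_sample] or [to_gray], or a
#'   bare integer vector with values in 0..255.
#' @return A `channel_histogram`: list with `channel`, integer `counts`
#'   (length 256, level 0 first), `cumulative` (running sum) and total `n`.
#' @examples
#' h <- channel_histogram(c(0L, 0L, 255L))
#' h$counts[c(1, 256)]   # 2 pixels at level 0, 1 at level 255
#' @export
channel_histogram <- function(sample) {
  s <- as_pixel_values(sample)
  counts <- tabulate(s$values + 1L, nbins = 256L)
  structure(list(channel = s$channel, counts = counts,
                 cumulative = cumsum(counts), n = length(s$values)),
            class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  cat("<channel_histogram> channel ", x$channel, ", n = ", x$n,
      ", levels used: ", sum(x$counts > 0), "\n", sep = "")
  invisible(x)
}

#' Plot a cumulative gradation histogram
#'
#' @param x a `channel_histogram`.
#' @param cumulative plot the running sum (default) or the per-level counts.
#' @param ... passed to [graphics::plot].
#' @export
plot.channel_histogram <- function(x, cumulative = TRUE, ...) {
  y <- if (cumulative) x$cumulative else x$counts
  graphics::plot(0:255, y, type = "s", xlab = "gradation level",
                 ylab = if (cumulative) "cumulative frequency" else "frequency",
                 main = paste0("channel ", x$channel), ...)
  invisible(x)
}

as_pixel_values <- function(sample) {
  if (inherits(sample, "pixel_sample"))
    return(list(values = sample$values, channel = sample$channel))
  v <- as.integer(sample)
  if (length(v) < 1L || anyNA(v) || any(v < 0L) || any(v > 255L))
    stop("values must be integers in [0, 255] with n >= 1", call. = FALSE)
  list(values = v, channel = NA_character_)
}

#' Skewed-distribution parameters of a gradation sample
#'
#' The five-number description of one channel's histogram: mean, median, mode,
#' skewness and kurtosis. Skewness is the third standardized central moment
#' `g1 = m3 / m2^1.5` and kurtosis the fourth, `m4 / m2^2`, both with
#' population (biased) central moments `mk = sum((v - mean)^k) / n` and no
#' small-sample correction. Kurtosis is reported as excess (normal law -> 0)
#' by default; `kurtosis = "raw"` keeps the m4/m2^2 convention (normal -> 3).
#' The mode is the most frequent integer level, ties broken to the smallest
#' level; the median of an even-sized sample is the mean of the two central
#' order statistics.
#'
#' @param sample a `pixel_sample` or integer vector in 0..255.
#' @param kurtosis `"excess"` (default) or `"raw"`.
#' @return A `skewed_params` object: list with `channel`, `n`, `mean`,
#'   `median`, `mode`, `skewness`, `kurtosis`, `kurtosis_convention`.
#'   Skewness and kurtosis are `NA` (flagged, not an error) for zero-variance
#'   samples.
#' @examples
#' p <- skewed_params(1:5)
#' c(p$mean, p$median, p$mode, p$skewness, p$kurtosis)
#' @export
skewed_params <- function(sample, kurtosis = c("excess", "raw")) {
  kurtosis <- match.arg(kurtosis)
  s <- as_pixel_values(sample)
  v <- as.numeric(s$values)
  n <- length(v)
  mu <- mean(v)
  med <- stats::median(v)
  counts <- tabulate(s$values + 1L, nbins = 256L)
  mode <- which.max(counts) - 1L  # which.max returns the first (smallest) tie
  d <- v - mu
  m2 <- mean(d^2)
  if (n < 2L || m2 == 0) {
    sk <- ku <- NA_real_
  } else {
    sk <- mean(d^3) / m2^1.5
    ku <- mean(d^4) / m2^2
    if (kurtosis == "excess") ku <- ku - 3
  }
  structure(list(channel = s$channel, n = n, mean = mu, median = med,
                 mode = as.numeric(mode), skewness = sk, kurtosis = ku,
                 kurtosis_convention = kurtosis),
            class = "skewed_params")
}

#' @export
print.skewed_params <- function(x, ...) {
  cat("<skewed_params>", if (!is.na(x$channel)) paste0(" channel ", x$channel),
      " (n = ", x$n, ")\n", sep = "")
  print(round(c(mean = x$mean, median = x$median, mode = x$mode,
                skewness = x$skewness, kurtosis = x$kurtosis), 4))
  invisible(x)
}

#' Mean-based colour indices
#'
#' The thirteen chlorophyll-proxy quantities built from the three channel
#' means: the means themselves, their sum, the three ratios to the sum, the
#' three pairwise differences and the three pairwise sums.
#'
#' @param r_mean,g_mean,b_mean channel means (finite numbers).
#' @return Named numeric vector of length 13 with names `R_Mean`, `G_Mean`,
#'   `B_Mean`, `idx_RGB_sum`, `idx_R_ratio`, `idx_G_ratio`, `idx_B_ratio`,
#'   `idx_R_minus_G`, `idx_R_minus_B`, `idx_G_minus_B`, `idx_R_plus_G`,
#'   `idx_R_plus_B`, `idx_G_plus_B`. The ratio indices are `NA` (flagged)
#'   when the channel sum is zero.
#' @examples
#' color_indices(98.64, 126.58, 32.60)[["idx_G_ratio"]]  # ~0.4909
#' @export
color_indices <- function(r_mean, g_mean, b_mean) {
  m <- c(r_mean, g_mean, b_mean)
  if (length(m) != 3L || anyNA(m) || any(!is.finite(m)))
    stop("channel means must be three finite numbers", call. = FALSE)
  s <- r_mean + g_mean + b_mean
  ratios <- if (s > 0) m / s else rep(NA_real_, 3L)
  c(R_Mean = r_mean, G_Mean = g_mean, B_Mean = b_mean,
    idx_RGB_sum = s,
    idx_R_ratio = ratios[1L], idx_G_ratio = ratios[2L],
    idx_B_ratio = ratios[3L],
    idx_R_minus_G = r_mean - g_mean, idx_R_minus_B = r_mean - b_mean,
    idx_G_minus_B = g_mean - b_mean,
    idx_R_plus_G = r_mean + g_mean, idx_R_plus_B = r_mean + b_mean,
    idx_G_plus_B = g_mean + b_mean)
}

# canonical feature column order shared by extract_features / CSV IO / models
feature_param_names <- function() {
  as.vector(t(outer(c("R", "G", "B", "Y"),
                    c("Mean", "Median", "Mode", "Skewness", "Kurtosis"),
                    paste, sep = "_")))
}

index_names <- function() {
  c("idx_RGB_sum", "idx_R_ratio", "idx_G_ratio", "idx_B_ratio",
    "idx_R_minus_G", "idx_R_minus_B", "idx_G_minus_B",
    "idx_R_plus_G", "idx_R_plus_B", "idx_G_plus_B")
}

#' All skewed-distribution parameters and colour indices of one leaf
#'
#' Computes the 20-parameter set (mean, median, mode, skewness, kurtosis for
#' the R, G, B and gray channels) plus the 10 non-mean colour indices, as one
#' feature record. Deterministic: the same image always yields a bit-identical
#' record.
#'
#' @param image a [leaf_image].
#' @param id leaf identifier (any scalar; stored as character).
#' @param age leaf age in days (optional).
#' @param spad measured SPAD value (optional).
#' @param kurtosis kurtosis convention, see [skewed_params].
#' @return A one-row `data.frame` with columns `leaf_id`, `age`, `SPAD`,
#'   `n_pixels`, the 20 parameters `R_Mean` ... `Y_Kurtosis` and the 10
#'   indices `idx_*` (the 13 colour indices are these 10 plus the 3 means).
#' @export
extract_features <- function(image, id = "leaf", age = NA_real_,
                             spad = NA_real_, kurtosis = c("excess", "raw")) {
  kurtosis <- match.arg(kurtosis)
  stopifnot(inherits(image, "leaf_image"))
  samples <- list(R = channel_sample(image, "R"),
                  G = channel_sample(image, "G"),
                  B = channel_sample(image, "B"),
                  Y = to_gray(image))
  params <- lapply(samples, skewed_params, kurtosis = kurtosis)
  vals <- unlist(lapply(params, function(p)
    c(p$mean, p$median, p$mode, p$skewness, p$kurtosis)), use.names = FALSE)
  names(vals) <- feature_param_names()
  idx <- color_indices(vals[["R_Mean"]], vals[["G_Mean"]], vals[["B_Mean"]])
  rec <- data.frame(leaf_id = as.character(id), age = as.numeric(age),
                    SPAD = as.numeric(spad), n_pixels = samples$R$n,
                    stringsAsFactors = FALSE)
  rec[names(vals)] <- as.list(vals)
  rec[index_names()] <- as.list(idx[index_names()])
  rec
}

#' Write / read leaf feature records as CSV
#'
#' Column names are part of the public contract: `leaf_id`, `age`, `SPAD`,
#' `n_pixels`, `R_Mean` ... `Y_Kurtosis`, `idx_*`.
#'
#' @param records data.frame of feature records (rows = leaves).
#' @param path CSV path.
#' @return `path` invisibly (write); the records data.frame (read).
#' @export
write_features_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a histogram as a 256-row CSV
#'
#' @param hist a `channel_histogram`.
#' @param path CSV path; columns `level`, `count`, `cumulative`.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "channel_histogram"))
  utils::write.csv(data.frame(level = 0:255, count = hist$counts,
                              cumulative = hist$cumulative),
                   path, row.names = FALSE)
  invisible(path)
}
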