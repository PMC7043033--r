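#' Construct a masked leaf image
#'
#' A `leaf_image` bundles the three 8-bit colour rasters of a leaf photograph
#' with a logical mask marking which pixels belong to the leaf. All downstream
#' descriptors (histograms, skewed-distribution parameters, colour indices)
#' are computed over masked pixels only.
#'
#' @param red,green,blue integer matrices of identical dimensions with values
#'   in 0..255 (rows = image rows, columns = image columns).
#' @param mask logical matrix of the same dimensions; `TRUE` marks leaf pixels.
#' @return An object of class `leaf_image` with elements `red`, `green`,
#'   `blue` (integer matrices), `mask` (logical matrix), `width`, `height`.
#' @export
leaf_image <- function(red, green, blue, mask) {
  red <- as_raster255(red, "red")
  green <- as_raster255(green, "green")
  blue <- as_raster255(blue, "blue")
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  dims <- dim(red)
  if (!identical(dim(green), dims) || !identical(dim(blue), dims) ||
      !identical(dim(mask), dims))
    stop("red, green, blue and mask must share identical dimensions",
         call. = FALSE)
  structure(
    list(red = red, green = green, blue = blue, mask = mask,
         width = ncol(red), height = nrow(red)),
    class = "leaf_image"
  )
}

as_raster255 <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`", what, "` must be a numeric matrix", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 255) || any(x != round(x)))
    stop("`", what, "` must hold integers in [0, 255]", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

#' @export
print.leaf_image <- function(x, ...) {
  cat("<leaf_image> ", x$width, "x", x$height, " pixels, ",
      sum(x$mask), " masked leaf pixels (",
      round(100 * mean(x$mask), 1), "%)\n", sep = "")
  invisible(x)
}

#' Read a leaf photograph and derive its analysis mask
#'
#' Reads a PNG (RGBA or RGB) or JPEG (RGB) image and builds the leaf mask
#' either from the alpha channel (`background = "alpha"`: segmentation tools
#' that cut the leaf out typically export a transparent-background PNG, so
#' leaf pixels are those with alpha > 0) or by thresholding the gray level
#' (`background = "threshold"`: photographs on a bright white matte
#' countertop, background pixels are those with gray level >= `threshold`).
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @param background `"alpha"` (default, requires an alpha channel) or
#'   `"threshold"`.
#' @param threshold gray-level cut in 0..255 for `background = "threshold"`;
#'   pixels with BT.601 gray level strictly below it are kept as leaf.
#' @return A [leaf_image].
#' @examples
#' img <- generate_leaf(leaf_spec(seed = 1, width = 40, height = 50))
#' f <- tempfile(fileext = ".png")
#' write_leaf_png(img, f)
#' img2 <- load_leaf_image(f)
#' identical(img$red[img$mask], img2$red[img2$mask])
#' @export
load_leaf_image <- function(path, background = c("alpha", "threshold"),
                            threshold = 250) {
  background <- match.arg(background)
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (need PNG or JPEG)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  nchan <- dim(arr)[3L]
  to255 <- function(m) {
    m <- round(m * 255)
    storage.mode(m) <- "integer"
    m
  }
  if (nchan >= 3L) {
    red <- to255(arr[, , 1L]); green <- to255(arr[, , 2L]); blue <- to255(arr[, , 3L])
  } else {
    red <- green <- blue <- to255(arr[, , 1L])
  }
  if (background == "alpha") {
    if (nchan < 4L)
      stop("image has no alpha channel; use background = \"threshold\"",
           call. = FALSE)
    mask <- arr[, , 4L] > 0
  } else {
    gray <- bt601_gray(red, green, blue)
    mask <- gray < threshold
  }
  if (!any(mask))
    stop("mask is empty: no leaf pixel found (degenerate input)", call. = FALSE)
  leaf_image(red, green, blue, mask)
}

# BT.601 luma on integer rasters; round half away from zero so that equal
# channels map back to the common level for every value in 0..255.
bt601_gray <- function(r, g, b) {
  y <- 0.2989 * r + 0.5870 * g + 0.1140 * b
  y <- round_half_away(y)
  y[y < 0L] <- 0L
  y[y > 255L] <- 255L
  y
}

round_half_away <- function(x) {
  r <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(r) <- "integer"   # keeps dim attributes, unlike as.integer()
  r
}

#' Gray-channel pixel sample of a leaf image
#'
#' Converts the masked pixels to 8-bit gray levels with the BT.601 weights
#' `Y = round(0.2989 R + 0.5870 G + 0.1140 B)` (round half away from zero,
#' clamped to 0..255) and returns them as a pixel sample in row-major scan
#' order.
#'
#' @param image a [leaf_image].
#' @param weights length-3 numeric expert override of the gray weights.
#' @return A `pixel_sample` (see [channel_sample]) with `channel = "Y"`.
#' @export
to_gray <- function(image, weights = c(0.2989, 0.5870, 0.1140)) {
  stopifnot(inherits(image, "leaf_image"), length(weights) == 3L)
  y <- round_half_away(weights[1L] * image$red + weights[2L] * image$green +
                       weights[3L] * image$blue)
  y[y < 0L] <- 0L
  y[y > 255L] <- 255L
  dim(y) <- dim(image$red)
  pixel_sample(masked_values(y, image$mask), "Y")
}

#' Per-channel pixel sample of a leaf image
#'
#' Extracts the masked intensities of one colour channel in row-major scan
#' order (left to right within a row, rows top to bottom), so that repeated
#' extraction is bit-reproducible.
#'
#' @param image a [leaf_image].
#' @param channel `"R"`, `"G"` or `"B"` (use [to_gray] for `"Y"`).
#' @return A `pixel_sample`: list with `channel`, integer `values` and count
#'   `n` equal to the number of masked pixels.
#' @export
channel_sample <- function(image, channel = c("R", "G", "B")) {
  stopifnot(inherits(image, "leaf_image"))
  channel <- match.arg(channel)
  ras <- switch(channel, R = image$red, G = image$green, B = image$blue)
  pixel_sample(masked_values(ras, image$mask), channel)
}

# row-major: R matrices are column-major, so walk the transpose
masked_values <- function(raster, mask) {
  as.integer(t(raster))[as.logical(t(mask))]
}

pixel_sample <- function(values, channel) {
  if (length(values) < 1L)
    stop("empty mask: pixel sample needs at least one value", call. = FALSE)
  structure(list(channel = channel, values = as.integer(values),
                 n = length(values)),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat("<pixel_sample> channel ", x$channel, ", n = ", x$n,
      ", range [", min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' Write a leaf image as a transparent-background RGBA PNG
#'
#' Background (non-mask) pixels get alpha 0, leaf pixels alpha 1, so the file
#' round-trips through [load_leaf_image] with the default alpha rule.
#'
#' @param image a [leaf_image].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_leaf_png <- function(image, path) {
  stopifnot(inherits(image, "leaf_image"))
  arr <- array(0, c(nrow(image$red), ncol(image$red), 4L))
  arr[, , 1L] <- image$red / 255
  arr[, , 2L] <- image$green / 255
  arr[, , 3L] <- image$blue / 255
  arr[, , 4L] <- ifelse(image$mask, 1, 0)
  png::writePNG(arr, path)
  invisible(path)
}

#' Write the analysis mask as a black/white PNG
#'
#' @param image a [leaf_image].
#' @param path output `.png` path; leaf pixels are written white.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(image, path) {
  stopifnot(inherits(image, "leaf_image"))
  png::writePNG(ifelse(image$mask, 1, 0), path)
  invisible(path)
}

#' Nearest-neighbour resize of a leaf image
#'
#' Optional strict-replication step: nearest-neighbour resampling preserves
#' the set of gradation values (no interpolation creates new levels), at the
#' cost of repeating/dropping pixels. Off by default in every pipeline.
#'
#' @param image a [leaf_image].
#' @param width,height target size in pixels.
#' @return A resized [leaf_image].
#' @export
resize_nearest <- function(image, width = 1000L, height = 1330L) {
  stopifnot(inherits(image, "leaf_image"), width >= 1L, height >= 1L)
  ri <- pmin(nrow(image$red), floor((seq_len(height) - 0.5) / height * nrow(image$red)) + 1L)
  ci <- pmin(ncol(image$red), floor((seq_len(width) - 0.5) / width * ncol(image$red)) + 1L)
  leaf_image(image$red[ri, ci, drop = FALSE],
             image$green[ri, ci, drop = FALSE],
             image$blue[ri, ci, drop = FALSE],
             image$mask[ri, ci, drop = FALSE])
}
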