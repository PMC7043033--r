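#' Channel intensity laws for synthetic leaves
#'
#' Three families of per-channel pixel-intensity laws:
#' * `law_skew_normal(xi, omega, alpha)` — skew-normal with location `xi`,
#'   scale `omega` and shape `alpha` (skewness up to |0.9953|), matching the
#'   mildly skewed red/green/gray gradation histograms of real leaves;
#' * `law_beta(a, b, scale)` — beta law scaled to `[0, scale]`, for strongly
#'   right-skewed channels (skewness well above 1, as in the blue channel);
#' * `law_point(value)` — degenerate point mass, for exactness tests.
#'
#' Sampling draws the continuous law, rounds half away from zero to integer
#' gradation levels and clips to 0..255; laws should put essentially all mass
#' inside [0, 255] so the clipping bias is negligible (the generator warns
#' when more than 0.1 percent of draws land outside).
#'
#' @param xi,omega,alpha skew-normal location, scale (> 0) and shape.
#' @param a,b beta shape parameters (> 0).
#' @param scale upper end of the scaled beta support.
#' @param value integer gradation level of the point mass.
#' @return A `channel_law` object.
#' @export
law_skew_normal <- function(xi, omega, alpha) {
  stopifnot(is.finite(xi), omega > 0, is.finite(alpha))
  structure(list(family = "skew_normal", xi = xi, omega = omega,
                 alpha = alpha), class = "channel_law")
}

#' @rdname law_skew_normal
#' @export
law_beta <- function(a, b, scale = 255) {
  stopifnot(a > 0, b > 0, scale > 0)
  structure(list(family = "beta", a = a, b = b, scale = scale),
            class = "channel_law")
}

#' @rdname law_skew_normal
#' @export
law_point <- function(value) {
  stopifnot(value >= 0, value <= 255, value == round(value))
  structure(list(family = "point", value = as.integer(value)),
            class = "channel_law")
}

#' @export
print.channel_law <- function(x, ...) {
  cat("<channel_law>", x$family,
      switch(x$family,
             skew_normal = sprintf("(xi=%g, omega=%g, alpha=%g)",
                                   x$xi, x$omega, x$alpha),
             beta = sprintf("(a=%g, b=%g, scale=%g)", x$a, x$b, x$scale),
             point = sprintf("(value=%d)", x$value)), "\n")
  invisible(x)
}

#' Closed-form moments of a channel law
#'
#' Exact mean, standard deviation, skewness and excess kurtosis of the
#' continuous law, before discretization to integer levels. These are the
#' oracle targets for feature extraction on synthetic leaves: for laws whose
#' mass sits well inside [0, 255] and whose scale is at least ~10 levels, the
#' rounding/clipping bias in skewness is far below sampling noise at the
#' pixel counts of real images.
#'
#' @param law a `channel_law`.
#' @return list with `mean`, `sd`, `skewness`, `kurtosis` (excess); the two
#'   shape moments are `NA` for a point mass.
#' @examples
#' analytic_moments(law_skew_normal(100, 20, 5))$skewness  # 0.8510
#' analytic_moments(law_beta(2, 8))$skewness               # 0.8292
#' @export
analytic_moments <- function(law) {
  stopifnot(inherits(law, "channel_law"))
  switch(law$family,
    skew_normal = {
      delta <- law$alpha / sqrt(1 + law$alpha^2)
      muz <- delta * sqrt(2 / pi)
      g1 <- (4 - pi) / 2 * muz^3 / (1 - muz^2)^1.5
      g2 <- 2 * (pi - 3) * muz^4 / (1 - muz^2)^2
      list(mean = law$xi + law$omega * muz,
           sd = law$omega * sqrt(1 - muz^2),
           skewness = g1, kurtosis = g2)
    },
    beta = {
      a <- law$a; b <- law$b
      g1 <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
      g2 <- 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
        (a * b * (a + b + 2) * (a + b + 3))
      list(mean = law$scale * a / (a + b),
           sd = law$scale * sqrt(a * b / ((a + b)^2 * (a + b + 1))),
           skewness = g1, kurtosis = g2)
    },
    point = list(mean = as.numeric(law$value), sd = 0,
                 skewness = NA_real_, kurtosis = NA_real_)
  )
}

# skew-normal sampler: delta|u0| + sqrt(1-delta^2) u1 is SN(0, 1, alpha)
rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

draw_law <- function(law, n) {
  x <- switch(law$family,
    skew_normal = rskewnorm(n, law$xi, law$omega, law$alpha),
    beta = law$scale * stats::rbeta(n, law$a, law$b),
    point = rep(as.numeric(law$value), n))
  outside <- mean(x < -0.5 | x > 255.5)
  if (outside > 0.001)
    warning(sprintf("channel law puts %.2f%% of its mass outside [0, 255]; ",
                    100 * outside),
            "clipping will bias the sample moments")
  v <- round_half_away(x)
  v[v < 0L] <- 0L
  v[v > 255L] <- 255L
  v
}

#' Solve law parameters from target moments
#'
#' Inverts the closed-form moment maps: `skew_normal_from_moments` returns the
#' skew-normal law with given mean, SD and skewness (|skewness| < 0.9952);
#' `beta_from_moments` returns the scaled beta law with given mean and
#' (same-sign-as-`scale/2 - mean`) skewness. Used to plant age-dependent
#' channel distributions with known targets.
#'
#' @param mean,sd,skewness target moments.
#' @param scale beta support upper end.
#' @return A `channel_law`.
#' @export
skew_normal_from_moments <- function(mean, sd, skewness) {
  stopifnot(sd > 0, abs(skewness) < 0.9952)
  g <- abs(skewness)
  t <- if (g == 0) 0 else
    stats::uniroot(function(t) (4 - pi) / 2 * t^3 / (1 - t^2)^1.5 - g,
                   c(0, sqrt(2 / pi) - 1e-9), tol = 1e-12)$root
  t <- sign(skewness) * t
  delta <- t / sqrt(2 / pi)
  alpha <- delta / sqrt(1 - delta^2)
  omega <- sd / sqrt(1 - t^2)
  law_skew_normal(mean - omega * t, omega, alpha)
}

#' @rdname skew_normal_from_moments
#' @export
beta_from_moments <- function(mean, skewness, scale = 255) {
  m <- mean / scale
  stopifnot(m > 0, m < 1, skewness * (1 - 2 * m) > 0)
  # the two-point (s -> 0) limit bounds the attainable skewness at fixed mean
  gmax <- abs(1 - 2 * m) / sqrt(m * (1 - m))
  if (abs(skewness) >= gmax)
    stop(sprintf(paste("skewness %.3f is not attainable by a beta law with",
                       "mean %g on [0, %g]; the bound is %.3f"),
                 skewness, mean, scale, gmax), call. = FALSE)
  g1 <- function(s) {
    a <- m * s; b <- (1 - m) * s
    2 * (b - a) * sqrt(s + 1) / ((s + 2) * sqrt(a * b))
  }
  s <- stats::uniroot(function(s) g1(s) - skewness, c(1e-9, 1e9),
                      tol = 1e-10)$root
  law_beta(m * s, (1 - m) * s, scale)
}

#' Specification of one synthetic leaf image
#'
#' Describes a synthetic leaf: canvas size, elliptical leaf mask (semi-axes
#' as fractions of the half-canvas), one `channel_law` per colour channel,
#' and a mandatory RNG seed. Pixel intensities are drawn independently per
#' pixel and per channel: real leaves have spatial texture, but every
#' implemented descriptor is a marginal histogram statistic, for which only
#' the per-channel law matters.
#'
#' @param width,height canvas size in pixels.
#' @param axes length-2 semi-axis fractions in (0, 1].
#' @param laws named list with entries `R`, `G`, `B` of class `channel_law`.
#' @param seed integer RNG seed (mandatory).
#' @return A `leaf_spec` object.
#' @export
leaf_spec <- function(width = 500L, height = 665L, axes = c(0.9, 0.9),
                      laws = list(R = skew_normal_from_moments(98.64, 20, 0.46),
                                  G = skew_normal_from_moments(126.58, 18, 0.35),
                                  B = beta_from_moments(32.60, 1.83)),
                      seed = NULL) {
  if (is.null(seed)) stop("leaf_spec requires an explicit integer seed",
                          call. = FALSE)
  stopifnot(width >= 2L, height >= 2L, length(axes) == 2L,
            all(axes > 0), all(axes <= 1),
            setequal(names(laws), c("R", "G", "B")),
            all(vapply(laws, inherits, logical(1), "channel_law")))
  structure(list(width = as.integer(width), height = as.integer(height),
                 axes = axes, laws = laws, seed = as.integer(seed)),
            class = "leaf_spec")
}

#' Generate a synthetic leaf image
#'
#' Rasterizes an elliptical leaf mask on the canvas and fills each masked
#' pixel's channels with independent draws from the spec's channel laws
#' (rounded and clipped to integer gradation levels). Background pixels are
#' zero and unmasked. Fully reproducible: the same spec (including seed)
#' yields a bit-identical image.
#'
#' @param spec a [leaf_spec].
#' @return A [leaf_image].
#' @export
generate_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  set.seed(spec$seed)
  cx <- (spec$width + 1) / 2
  cy <- (spec$height + 1) / 2
  ax <- spec$axes[1L] * spec$width / 2
  ay <- spec$axes[2L] * spec$height / 2
  col_idx <- matrix(rep(seq_len(spec$width), each = spec$height),
                    nrow = spec$height)
  row_idx <- matrix(rep(seq_len(spec$height), times = spec$width),
                    nrow = spec$height)
  mask <- ((col_idx - cx) / ax)^2 + ((row_idx - cy) / ay)^2 <= 1
  n <- sum(mask)
  fill <- function(law) {
    m <- matrix(0L, spec$height, spec$width)
    m[mask] <- draw_law(law, n)
    m
  }
  leaf_image(fill(spec$laws$R), fill(spec$laws$G), fill(spec$laws$B), mask)
}

#' Age profile of channel laws and SPAD link
#'
#' Defines, for each leaf age, the channel laws of the synthetic leaves and
#' how SPAD is linked to the realized features. The default profile tracks
#' the aging trends observed on tobacco: channel means rising with age (the
#' leaf yellows), red/green/gray skewness falling from positive at 40 days to
#' negative at 65 days, and a strongly right-skewed blue channel throughout.
#' SPAD is generated as the prediction of a published model on the realized
#' leaf features plus Gaussian noise.
#'
#' @param ages leaf ages in days.
#' @param r_mean,r_skew,g_mean,g_skew per-age red/green targets (means and
#'   skewnesses); gray follows from the channels.
#' @param b_mean,b_skew per-age blue targets (beta laws).
#' @param r_sd,g_sd channel standard deviations in gradation levels.
#' @param spad_link published model id used as the SPAD-generating formula.
#' @param spad_sigma SD of the Gaussian SPAD noise, meter units.
#' @return An `age_profile` object: list of per-age law sets plus the link.
#' @export
age_profile <- function(ages = c(40, 50, 60, 65),
                        r_mean = c(98.64, 102.38, 121.78, 154.62),
                        r_skew = c(0.46, -0.04, -0.19, -0.59),
                        g_mean = c(126.58, 126.98, 138.96, 149.80),
                        g_skew = c(0.35, -0.29, -0.36, -0.59),
                        b_mean = c(32.60, 37.34, 39.65, 44.82),
                        b_skew = c(1.46, 1.18, 1.32, 1.68),
                        r_sd = 20, g_sd = 18,
                        spad_link = "F1", spad_sigma = 2.5) {
  k <- length(ages)
  stopifnot(k >= 1L, length(r_mean) == k, length(r_skew) == k,
            length(g_mean) == k, length(g_skew) == k,
            length(b_mean) == k, length(b_skew) == k, spad_sigma >= 0)
  per_age <- lapply(seq_len(k), function(i) list(
    age = ages[i],
    laws = list(R = skew_normal_from_moments(r_mean[i], r_sd, r_skew[i]),
                G = skew_normal_from_moments(g_mean[i], g_sd, g_skew[i]),
                B = beta_from_moments(b_mean[i], b_skew[i]))))
  structure(list(ages = ages, per_age = per_age, spad_link = spad_link,
                 spad_sigma = spad_sigma),
            class = "age_profile")
}

#' Generate a synthetic leaf dataset with SPAD values
#'
#' Emulates the sampling design of a leaf-aging study: `leaves_per_age`
#' leaves at each age of the profile, each leaf drawn from its age's channel
#' laws, features extracted with [extract_features], and SPAD generated as
#' the profile's published-model prediction on the realized features plus
#' Gaussian noise. Per-leaf sub-seeds are derived deterministically from the
#' master seed, so runs are bit-reproducible.
#'
#' @param profile an [age_profile].
#' @param leaves_per_age leaves per age group (50 emulates the field design).
#' @param seed master integer seed (mandatory).
#' @param spec_template [leaf_spec] providing canvas size and mask shape
#'   (its laws and seed are overridden per leaf).
#' @param keep_images also return the generated [leaf_image]s (memory-heavy).
#' @return list with `records` (feature data.frame, one row per leaf,
#'   including `age` and noisy `SPAD`) and, if requested, `images`.
#' @export
generate_dataset <- function(profile = age_profile(), leaves_per_age = 50L,
                             seed = NULL,
                             spec_template = leaf_spec(seed = 0L),
                             keep_images = FALSE) {
  stopifnot(inherits(profile, "age_profile"), leaves_per_age >= 1L)
  if (is.null(seed)) stop("generate_dataset requires an explicit seed",
                          call. = FALSE)
  n_total <- length(profile$per_age) * leaves_per_age
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total + 1L)
  noise_seed <- sub_seeds[n_total + 1L]
  records <- vector("list", n_total)
  images <- if (keep_images) vector("list", n_total) else NULL
  idx <- 0L
  for (agelaws in profile$per_age) {
    for (l in seq_len(leaves_per_age)) {
      idx <- idx + 1L
      sp <- leaf_spec(width = spec_template$width,
                      height = spec_template$height,
                      axes = spec_template$axes,
                      laws = agelaws$laws, seed = sub_seeds[idx])
      img <- generate_leaf(sp)
      records[[idx]] <- extract_features(
        img, id = sprintf("age%g_leaf%03d", agelaws$age, l),
        age = agelaws$age)
      if (keep_images) images[[idx]] <- img
    }
  }
  records <- do.call(rbind, records)
  mu <- predict_published(profile$spad_link, records)
  set.seed(noise_seed)
  records$SPAD <- mu + stats::rnorm(n_total, 0, profile$spad_sigma)
  out <- list(records = records)
  if (keep_images) out$images <- images
  out
}
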