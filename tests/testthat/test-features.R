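test_that("histograms count levels and conserve the pixel count", {
  h <- channel_histogram(c(0L, 0L, 255L))
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 1)
  expect_equal(sum(h$counts[2:255]), 0)
  expect_equal(h$cumulative[256], h$n)

  set.seed(4)
  for (i in 1:20) {
    v <- sample(0:255, sample(1:500, 1), replace = TRUE)
    h <- channel_histogram(v)
    expect_equal(sum(h$counts), length(v))
    expect_equal(h$cumulative[256], length(v))
  }
})

test_that("skewed params match hand arithmetic and the tie-break rules", {
  p <- skewed_params(1:5)
  expect_equal(p$mean, 3)
  expect_equal(p$median, 3)
  expect_equal(p$mode, 1)              # all tied: smallest level wins
  expect_equal(p$skewness, 0)
  expect_equal(p$kurtosis, -1.3)       # population m4/m2^2 - 3 = 6.8/4 - 3

  praw <- skewed_params(1:5, kurtosis = "raw")
  expect_equal(praw$kurtosis, 1.7)

  # even n: median is the mean of the two central order statistics
  expect_equal(skewed_params(c(1L, 2L, 10L, 11L))$median, 6)

  # symmetric sample: skewness 0 within numerical noise
  expect_lt(abs(skewed_params(c(10L, 20L, 30L, 40L, 50L))$skewness), 1e-12)

  # zero variance: shape moments flagged undefined, not an error
  p0 <- skewed_params(rep(7L, 10))
  expect_equal(c(p0$mean, p0$median, p0$mode), c(7, 7, 7))
  expect_true(is.na(p0$skewness) && is.na(p0$kurtosis))
})

test_that("median and mode agree with a brute-force oracle on random samples", {
  set.seed(99)
  for (i in 1:1000) {
    v <- sample(0:20, sample(1:30, 1), replace = TRUE)
    p <- skewed_params(v)
    sv <- sort(v)
    n <- length(v)
    med <- if (n %% 2 == 1) sv[(n + 1) / 2] else mean(sv[n / 2 + 0:1])
    counts <- table(v)
    mode <- min(as.integer(names(counts)[counts == max(counts)]))
    expect_identical(p$median, as.numeric(med))
    expect_identical(p$mode, as.numeric(mode))
  }
})

test_that("mean/median/mode are shift-equivariant, shape moments invariant", {
  set.seed(12)
  for (i in 1:25) {
    v <- sample(0:150, 200, replace = TRUE)
    c_ <- sample(1:100, 1)
    p0 <- skewed_params(v)
    p1 <- skewed_params(v + c_)
    expect_equal(p1$mean, p0$mean + c_)
    expect_equal(p1$median, p0$median + c_)
    expect_equal(p1$mode, p0$mode + c_)
    expect_equal(p1$skewness, p0$skewness, tolerance = 1e-12)
    expect_equal(p1$kurtosis, p0$kurtosis, tolerance = 1e-12)
  }
})

test_that("reflection v -> 255 - v negates skewness and keeps kurtosis", {
  set.seed(13)
  for (i in 1:25) {
    v <- sample(0:255, 300, replace = TRUE, prob = stats::dbeta((0:255 + 0.5) / 256, 2, 6))
    p <- skewed_params(v)
    pr <- skewed_params(255L - v)
    expect_equal(pr$skewness, -p$skewness, tolerance = 1e-12)
    expect_equal(pr$kurtosis, p$kurtosis, tolerance = 1e-12)
  }
})

test_that("colour indices reproduce hand arithmetic and their identities", {
  idx <- color_indices(98.64, 126.58, 32.60)
  expect_equal(idx[["idx_G_ratio"]], 126.58 / 257.82, tolerance = 1e-12)
  expect_equal(idx[["idx_G_ratio"]], 0.4909, tolerance = 2e-4)  # printed precision

  flat <- color_indices(1, 1, 1)
  expect_equal(unname(flat[c("idx_R_ratio", "idx_G_ratio", "idx_B_ratio")]),
               rep(1 / 3, 3))
  expect_equal(unname(flat[c("idx_R_minus_G", "idx_R_minus_B",
                             "idx_G_minus_B")]), rep(0, 3))

  set.seed(14)
  for (i in 1:50) {
    m <- runif(3, 1, 255)
    idx <- color_indices(m[1], m[2], m[3])
    expect_equal(idx[["idx_R_ratio"]] + idx[["idx_G_ratio"]] +
                   idx[["idx_B_ratio"]], 1, tolerance = 1e-12)
    expect_equal(idx[["idx_R_minus_B"]],
                 idx[["idx_R_plus_G"]] - idx[["idx_G_plus_B"]],
                 tolerance = 1e-10)
  }

  # zero channel sum: ratio indices flagged undefined
  z <- color_indices(0, 0, 0)
  expect_true(all(is.na(z[c("idx_R_ratio", "idx_G_ratio", "idx_B_ratio")])))
})

test_that("extract_features is deterministic and exact on flat leaves", {
  img <- flat_leaf(50, 120, 30)
  rec <- extract_features(img, id = "flat", age = 40)
  expect_equal(rec$G_Mean, 120)
  expect_equal(rec$G_Median, 120)
  expect_equal(rec$G_Mode, 120)
  expect_true(is.na(rec$G_Skewness))
  expect_equal(rec$n_pixels, 12L)
  expect_named(rec, c("leaf_id", "age", "SPAD", "n_pixels",
                      as.vector(t(outer(c("R", "G", "B", "Y"),
                                        c("Mean", "Median", "Mode",
                                          "Skewness", "Kurtosis"),
                                        paste, sep = "_"))),
                      paste0("idx_", c("RGB_sum", "R_ratio", "G_ratio",
                                       "B_ratio", "R_minus_G", "R_minus_B",
                                       "G_minus_B", "R_plus_G", "R_plus_B",
                                       "G_plus_B"))))

  img2 <- generate_leaf(leaf_spec(width = 40, height = 50, seed = 21))
  expect_identical(extract_features(img2, "a"), extract_features(img2, "a"))
})

test_that("feature records and histograms round-trip through CSV", {
  img <- generate_leaf(leaf_spec(width = 40, height = 50, seed = 22))
  rec <- extract_features(img, id = "x", age = 40, spad = 25)
  f <- tempfile(fileext = ".csv")
  write_features_csv(rec, f)
  back <- read_features_csv(f)
  expect_equal(back$R_Mean, rec$R_Mean)
  expect_equal(nrow(back), 1L)

  fh <- tempfile(fileext = ".csv")
  write_histogram_csv(channel_histogram(channel_sample(img, "G")), fh)
  h <- utils::read.csv(fh)
  expect_equal(nrow(h), 256L)
  expect_equal(sum(h$count), sum(img$mask))
})
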