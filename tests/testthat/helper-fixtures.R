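# tiny in-code fixtures shared across test files

# 2x2 leaf with hand-set channel values and a full mask
tiny_leaf <- function(mask = matrix(TRUE, 2, 2)) {
  leaf_image(red = matrix(c(255L, 0L, 100L, 10L), 2, 2),
             green = matrix(c(0L, 0L, 100L, 20L), 2, 2),
             blue = matrix(c(0L, 0L, 100L, 30L), 2, 2),
             mask = mask)
}

# constant-colour leaf on an n x m canvas, full mask
flat_leaf <- function(r, g, b, nrow = 3, ncol = 4) {
  leaf_image(matrix(as.integer(r), nrow, ncol),
             matrix(as.integer(g), nrow, ncol),
             matrix(as.integer(b), nrow, ncol),
             matrix(TRUE, nrow, ncol))
}

# biased sample skewness / raw kurtosis oracles (plain arithmetic)
oracle_g1 <- function(v) {
  d <- v - mean(v)
  mean(d^3) / mean(d^2)^1.5
}
oracle_kraw <- function(v) {
  d <- v - mean(v)
  mean(d^4) / mean(d^2)^2
}

# small fast synthetic dataset for model-level tests
small_dataset <- function(seed, leaves_per_age = 4, sigma = 2.5, link = "F1",
                          width = 50, height = 64) {
  generate_dataset(age_profile(spad_link = link, spad_sigma = sigma),
                   leaves_per_age = leaves_per_age, seed = seed,
                   spec_template = leaf_spec(width = width, height = height,
                                             seed = 0L))
}
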