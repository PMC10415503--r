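# Small in-code fixtures shared across test files.

random_shape <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(2 * n), ncol = 2L)
}

centred_unit <- function(coords) {
  c <- sweep(coords, 2L, colMeans(coords))
  c / sqrt(sum(c^2))
}

rotate2 <- function(coords, theta) {
  coords %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
}

# A wiggly but well-behaved trace for io/resampling tests.
wiggly_trace <- function(id = "w1", n = 40L, seed = 1L, ...) {
  set.seed(seed)
  x <- seq(0, 1, length.out = n)
  y <- 0.05 * sin(6 * pi * x) + cumsum(rnorm(n, 0, 0.002))
  raw_trace(id, cbind(x, y), ...)
}

random_cohort <- function(n_specimens = 3L, seed = 1L, with_meta = TRUE) {
  set.seed(seed)
  traces <- lapply(seq_len(n_specimens), function(i) {
    k <- sample(10:30, 1L)
    pts <- cbind(sort(runif(k)), rnorm(k, 0, 0.1))
    raw_trace(sprintf("sp%02d", i), pts,
              age = if (with_meta) round(runif(1, 8, 66), 1) else NA_real_,
              sex = if (with_meta) sample(c("male", "female"), 1L)
              else NA_character_)
  })
  suture_cohort(traces)
}
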