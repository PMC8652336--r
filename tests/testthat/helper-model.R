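# shared fixtures built in code

# absolute-difference comparison (expect_equal tolerances are relative)
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

# small random scored dataset with the five model columns, loosely shaped
# like the survey scales
random_scored <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n, 90, 13)
  m1 <- 25 + 0.16 * (x - 90) + rnorm(n, 0, 6)
  m2 <- 17 + 0.12 * (x - 90) + rnorm(n, 0, 3.5)
  m3 <- 16 + 0.08 * (x - 90) + rnorm(n, 0, 3)
  y <- 41 - 0.1 * (x - 90) - 0.25 * (m1 - 25) - 0.9 * (m2 - 17) -
    1.1 * (m3 - 16) - 0.013 * (x - 90) * (m1 - 25) +
    0.03 * (x - 90) * (m3 - 16) + rnorm(n, 0, 11)
  data.frame(Y = y, X = x, M1 = m1, M2 = m2, M3 = m3)
}

# a deliberately small, hand-checkable fitted model
toy_fit <- function(a1 = c(M1 = 0.2, M2 = 0.1, M3 = 0.05),
                    b1 = c(M1 = -0.3, M2 = -0.8, M3 = -1.0),
                    c1 = -0.1,
                    c2 = c(M1 = -0.01, M2 = 0, M3 = 0.02),
                    seed = 42, n = 5000) {
  spec <- synthetic_spec(n = n, a1 = a1, b1 = b1, c1 = c1, c2 = c2)
  fit_from_raw(simulate_raw(spec, seed = seed))
}

survey_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_from_moments(survey_moments())
    cache
  }
})
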