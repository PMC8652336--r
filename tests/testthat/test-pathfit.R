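test_that("compute_moments agrees with a brute-force summation oracle on a toy table", {
  toy <- data.frame(Y = c(30, 45, 28, 60, 41),
                    X = c(80, 95, 88, 102, 90),
                    M1 = c(20, 28, 24, 31, 22),
                    M2 = c(12, 19, 15, 22, 17),
                    M3 = c(10, 16, 12, 18, 14))
  m <- compute_moments(toy)
  # oracle: direct summation, no cor()/sd() shortcuts
  xc <- toy$X - sum(toy$X) / 5
  m1c <- toy$M1 - sum(toy$M1) / 5
  prod <- xc * m1c
  expect_equal(unname(m$means["XM1"]), sum(prod) / 5)
  expect_equal(unname(m$sds["Y"]),
               sqrt(sum((toy$Y - sum(toy$Y) / 5)^2) / 4))
  r_oracle <- (sum(xc * m1c) / 4) /
    (sqrt(sum(xc^2) / 4) * sqrt(sum(m1c^2) / 4))
  expect_equal(unname(m$corr["X", "M1"]), r_oracle)
  # product mean = covariance of the centered factors up to n vs n-1
  expect_equal(unname(m$means["XM1"]) * 5 / 4, sum(xc * m1c) / 4)
  expect_error(compute_moments(toy[1:2, ]), "at least 3 rows")
})

test_that("first-stage slopes from the survey moments equal the closed-form r*SD ratios", {
  m <- survey_moments()
  fit <- survey_fit()
  for (med in c("M1", "M2", "M3")) {
    expect_equal(unname(fit$a1[med]),
                 m$corr["X", med] * m$sds[[med]] / m$sds[["X"]],
                 tolerance = 1e-12)
  }
  expect_equal(unname(fit$a1_std), c(0.332, 0.435, 0.332), tolerance = 1e-12)
})

test_that("moment-route and raw-route fits are identical, and match lm()", {
  for (seed in 1:5) {
    d <- random_scored(60, seed)
    f_raw <- fit_from_raw(d)
    f_mom <- fit_from_moments(compute_moments(d))
    expect_equal(f_raw$b, f_mom$b, tolerance = 1e-12)
    expect_equal(f_raw$a1, f_mom$a1, tolerance = 1e-12)
    expect_equal(f_raw$b0, f_mom$b0, tolerance = 1e-12)
    # independent oracle: lm on the prepared frame
    pf <- prepare_model_frame(d)
    lm_fit <- lm(Y ~ Xc + M1c + M2c + M3c + XM1 + XM2 + XM3, data = pf)
    expect_equal(unname(f_raw$b), unname(coef(lm_fit)[-1]), tolerance = 1e-10)
    expect_equal(f_raw$b0, unname(coef(lm_fit)[1]), tolerance = 1e-10)
    expect_equal(unname(f_raw$b_se),
                 unname(summary(lm_fit)$coefficients[-1, "Std. Error"]),
                 tolerance = 1e-8)
  }
})

test_that("zero predictor-outcome correlations give zero slopes and a mean intercept", {
  cols <- c("Y", "X", "M1", "M2", "M3", "XM1", "XM2", "XM3")
  corr <- diag(8)
  m <- summary_moments(cols, means = c(40, 0, 0, 0, 0, 1, 2, 3),
                       sds = rep(1, 8), corr = corr, n = 100)
  fit <- fit_from_moments(m)
  expect_equal(unname(fit$b), rep(0, 7))
  expect_equal(fit$b0, 40)
  expect_equal(unname(fit$pseudo_r2), rep(0, 4))
})

test_that("standardization round-trips and uses the observed product SDs", {
  fit <- survey_fit()
  sds <- fit$sds
  pred <- c("X", "M1", "M2", "M3", "XM1", "XM2", "XM3")
  expect_equal(fit$b_std, fit$b * sds[pred] / sds[["Y"]], tolerance = 1e-12)
  expect_equal(fit$b, fit$b_std * sds[["Y"]] / sds[pred], tolerance = 1e-12)
  std <- standardized_coefficients(fit)
  expect_equal(std$a1_std, fit$moments$corr["X", c("M1", "M2", "M3")])
})

test_that("pseudo R2 reduces to the squared correlation for single-regressor equations", {
  fit <- survey_fit()
  r2 <- pseudo_r2(fit)
  expect_equal(unname(r2[c("M1", "M2", "M3")]),
               unname(fit$moments$corr["X", c("M1", "M2", "M3")]^2))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("a singular predictor submatrix is rejected with the condition number", {
  cols <- c("Y", "X", "M1", "M2", "M3", "XM1", "XM2", "XM3")
  corr <- diag(8)
  dimnames(corr) <- list(cols, cols)
  corr["M1", "M2"] <- corr["M2", "M1"] <- 1   # M2 duplicates M1
  m <- summary_moments(cols, means = rep(0, 8), sds = rep(1, 8),
                       corr = corr, n = 100)
  expect_error(fit_from_moments(m), "singular")
})

test_that("noise-free data reproduce the generating coefficients to machine precision", {
  set.seed(21)
  n <- 400
  x <- rnorm(n, 90, 13)
  xc <- x - mean(x)
  m1 <- 25 + 0.2 * xc + rnorm(n)   # mediator noise is fine: Y has none
  m2 <- 17 + 0.1 * xc + rnorm(n)
  m3 <- 16 + 0.05 * xc + rnorm(n)
  d <- data.frame(X = x, M1 = m1, M2 = m2, M3 = m3)
  pf <- prepare_model_frame(cbind(Y = 0, d))
  pf$Y <- 40 - 0.1 * pf$Xc - 0.3 * pf$M1c - 0.8 * pf$M2c - 1.1 * pf$M3c -
    0.01 * pf$XM1 + 0.002 * pf$XM2 + 0.03 * pf$XM3
  fit <- fit_from_raw(pf[, c("Y", "X", "M1", "M2", "M3")])
  expect_equal(unname(fit$b), c(-0.1, -0.3, -0.8, -1.1, -0.01, 0.002, 0.03),
               tolerance = 1e-10)
  expect_equal(fit$b0, 40, tolerance = 1e-8)
})
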