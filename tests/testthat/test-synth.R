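test_that("the packaged survey moments are internally consistent", {
  m <- survey_moments()
  expect_equal(m$n, 2133L)
  expect_equal(m$corr["Y", "X"], -0.343)
  ev <- eigen(m$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # mean of each product column equals r * SD(X) * SD(M) within 0.5%
  for (i in 1:3) {
    med <- paste0("M", i)
    expected <- m$corr["X", med] * m$sds[["X"]] * m$sds[[med]]
    expect_equal(unname(m$means[paste0("XM", i)]), expected,
                 tolerance = 0.005)
  }
  # moments JSON round-trips exactly
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_moments(m, tmp)
  m2 <- read_moments(tmp)
  expect_equal(m2$corr, m$corr)
  expect_equal(m2$means, m$means)
})

test_that("implied moments have the closed-form structure", {
  spec <- synthetic_spec(n = 1000)
  im <- implied_moments(spec)
  # implied X-mediator correlations are a1 * SD(X) / SD(M)
  for (i in 1:3) {
    med <- paste0("M", i)
    expect_equal(im$corr["X", med],
                 spec$a1[[med]] * spec$sd_x / spec$sd_m[[med]],
                 tolerance = 1e-12)
  }
  expect_equal(im$corr["X", "M2"], 0.434, tolerance = 0.001)
  # product-term variance: Var(X)Var(M) + Cov(X,M)^2
  expect_equal(unname(im$sds["XM1"]^2),
               spec$sd_x^2 * spec$sd_m[["M1"]]^2 +
                 (spec$a1[["M1"]] * spec$sd_x^2)^2,
               tolerance = 1e-8)
  # slopes all zero -> X independent of the mediators
  spec0 <- synthetic_spec(n = 1000, a1 = c(M1 = 0, M2 = 0, M3 = 0))
  im0 <- implied_moments(spec0)
  expect_equal(unname(im0$corr["X", c("M1", "M2", "M3")]), rep(0, 3))
  # infeasible targets are rejected
  expect_error(synthetic_spec(sd_m = c(M1 = 0.5, M2 = 3.746, M3 = 3.014)),
               "positive semi-definite")
  expect_error(synthetic_spec(sd_y = 2), "below the SD implied")
})

test_that("simulated sample moments converge to the implied moments", {
  spec <- synthetic_spec(n = 200000)
  d <- simulate_raw(spec, seed = 55)
  emp <- compute_moments(d)
  im <- implied_moments(spec)
  expect_equal(emp$corr, im$corr, tolerance = 0.02)
  expect_lt(max(abs(emp$corr - im$corr)), 0.02)
  # closed-form product variance vs empirical, within 1%
  expect_equal(unname(emp$sds["XM1"]^2), unname(im$sds["XM1"]^2),
               tolerance = 0.01)
  expect_equal(unname(emp$sds[c("Y", "X", "M1", "M2", "M3")]),
               unname(im$sds[c("Y", "X", "M1", "M2", "M3")]),
               tolerance = 0.01)
})

test_that("simulation is reproducible by seed and near-deterministic with zero residuals", {
  spec <- synthetic_spec(n = 200)
  d1 <- simulate_raw(spec, seed = 7)
  d2 <- simulate_raw(spec, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_raw(spec, seed = 8)
  expect_false(identical(d1$Y, d3$Y))

  # residual-free outcome: shrink SD(Y) to exactly the structural part
  base <- synthetic_spec(n = 3000)
  struct_sd <- sqrt(base$sd_y^2 - base$resid_var_y)
  pure <- synthetic_spec(n = 3000, sd_y = struct_sd)
  expect_equal(pure$resid_var_y, 0)
  d <- simulate_raw(pure, seed = 10)
  fit <- fit_from_raw(d)
  # the generator centers at the population means, the fit at the sample
  # means; the interaction terms absorb the difference, shifting the
  # lower-order coefficients by exactly c2 * (sample mean offset)
  xbar <- mean(d$X) - pure$mean_x
  mbar <- colMeans(d[, c("M1", "M2", "M3")]) - pure$mean_m
  expect_equal(unname(fit$b[c("XM1", "XM2", "XM3")]), unname(pure$c2),
               tolerance = 1e-10)
  expect_equal(unname(fit$b[c("M1", "M2", "M3")]),
               unname(pure$b1 + pure$c2 * xbar), tolerance = 1e-10)
  expect_equal(unname(fit$b["X"]),
               unname(pure$c1 + sum(pure$c2 * mbar)), tolerance = 1e-10)
  expect_equal(fit$pseudo_r2[["Y"]], 1, tolerance = 1e-10)
})

test_that("item compositions hit the score exactly, including the boundaries", {
  scores <- data.frame(Y = c(20, 100, 57), X = c(26, 130, 90),
                       M1 = c(8, 40, 25), M2 = c(5, 25, 17),
                       M3 = c(4, 20, 12))
  items <- simulate_items(scores, seed = 31)
  # boundary scores admit a unique composition
  expect_true(all(items[1, sprintf("iat_%02d", 1:20)] == 1))
  expect_true(all(items[2, sprintf("iat_%02d", 1:20)] == 5))
  # emotional adaptation items are all reverse-coded: a minimum adaptation
  # score is emitted as the all-5 response pattern
  expect_true(all(items[1, sprintf("emo_%02d", 1:8)] == 5))
  rescored <- score_instruments(items)
  expect_equal(rescored[, c("Y", "X", "M1", "M2", "M3")],
               scores, ignore_attr = TRUE)
  expect_error(modmedpath:::.sample_compositions(3, k = 4, points = 5),
               "feasible range")
  expect_error(modmedpath:::.sample_compositions(21, k = 4, points = 5),
               "feasible range")
})

test_that("composition sampling is uniform over the feasible set", {
  # k = 2 items on 5 points, score 6: five equally likely compositions
  set.seed(77)
  draws <- modmedpath:::.sample_compositions(rep(6, 5000), k = 2, points = 5)
  expect_true(all(rowSums(draws) == 6))
  freq <- table(draws[, 1])
  expect_equal(length(freq), 5L)
  expect_true(all(abs(freq / 5000 - 0.2) < 0.03))
})
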