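test_that("reverse coding maps endpoints symmetrically and is an involution", {
  m <- data.frame(a = c(1L, 3L, 5L), b = c(2L, 4L, 1L))
  r <- reverse_code(m, reversed = "a")
  expect_equal(r$a, c(5L, 3L, 1L))   # endpoint symmetry, midpoint fixed
  expect_equal(r$b, m$b)
  set.seed(11)
  big <- as.data.frame(matrix(sample(1:5, 200, TRUE), ncol = 4,
                              dimnames = list(NULL, letters[1:4])))
  twice <- reverse_code(reverse_code(big, c("a", "c")), c("a", "c"))
  expect_identical(twice, big)
  expect_error(reverse_code(data.frame(a = c(1L, 6L)), "a"),
               "out of range")
})

test_that("scoring sums recoded items within the declared range", {
  emo <- scale_def("emoada", paste0("i", 1:8), reversed = paste0("i", 1:8))
  lows <- as.data.frame(matrix(1L, 3, 8, dimnames = list(NULL, paste0("i", 1:8))))
  highs <- as.data.frame(matrix(5L, 3, 8, dimnames = list(NULL, paste0("i", 1:8))))
  expect_equal(score_scale(lows, emo), rep(8, 3))
  expect_equal(score_scale(highs, emo), rep(40, 3))
  iat <- scale_def("iat", paste0("q", 1:20))
  all5 <- as.data.frame(matrix(5L, 2, 20, dimnames = list(NULL, paste0("q", 1:20))))
  expect_equal(score_scale(all5, iat), rep(100, 2))
  expect_error(score_scale(lows[, 1:7], emo), "i8")
  expect_error(scale_def("bad", paste0("i", 1:8), range = c(5, 25)),
               "does not match")
})

test_that("reverse coding the complement set mirrors the score around (k+1)*n_items", {
  set.seed(5)
  items <- as.data.frame(matrix(sample(1:5, 160, TRUE), ncol = 8,
                                dimnames = list(NULL, paste0("i", 1:8))))
  rev_set <- c("i2", "i5")
  def <- scale_def("s", paste0("i", 1:8))
  s1 <- score_scale(reverse_code(items, rev_set), def)
  s2 <- score_scale(reverse_code(items, setdiff(names(items), rev_set)), def)
  expect_equal(s1 + s2, rep(6 * 8, nrow(items)))
})

test_that("Cronbach's alpha matches the covariance-formula oracle and its invariances", {
  # frozen oracle: 4 x 3 integer table, worked through the variance formula
  tab <- rbind(c(1, 2, 3), c(2, 4, 4), c(3, 3, 5), c(4, 5, 5))
  expect_equal(cronbach_alpha(tab), 0.916030534351145, tolerance = 1e-12)
  # two identical columns with positive variance -> perfect consistency
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))), 1)
  # invariant under adding a constant to any item
  expect_equal(cronbach_alpha(sweep(tab, 2, c(10, -3, 0), "+")),
               cronbach_alpha(tab))
  # independent items -> near zero shared variance at large n
  set.seed(9)
  indep <- cbind(rnorm(20000), rnorm(20000))
  expect_lt(abs(cronbach_alpha(indep)), 0.05)
  expect_warning(a <- cronbach_alpha(matrix(3, 5, 3)), "undefined")
  expect_true(is.na(a))
})

test_that("IAT severity bands partition the admissible score range", {
  expect_equal(as.character(grade_iat(c(45, 39, 60, 80))),
               c("mild", "none", "moderate", "severe"))
  g <- grade_iat(20:100)
  expect_false(anyNA(g))                       # every score categorised
  expect_equal(as.character(g[c(1, 21, 41, 61, 81)]),
               c("none", "mild", "moderate", "severe", "severe"))
  expect_error(grade_iat(19), "\\[20, 100\\]")
  expect_error(grade_iat(101), "\\[20, 100\\]")
})

test_that("grand-mean centering zeroes the mean and retains it", {
  x <- c(88, 92, 95, 86.456)
  cx <- center_grand_mean(x)
  expect_lt(abs(mean(cx)), 1e-10)
  expect_equal(attr(cx, "center"), mean(x))
  const <- center_grand_mean(rep(7.5, 10))
  expect_equal(as.numeric(const), rep(0, 10))
  expect_equal(attr(const, "center"), 7.5)
  again <- center_grand_mean(as.numeric(cx))   # idempotence
  expect_equal(as.numeric(again), as.numeric(cx))
})

test_that("instrument scoring applies listwise deletion and rejects duplicate ids", {
  set.seed(3)
  scores <- data.frame(Y = sample(20:100, 6), X = sample(26:130, 6),
                       M1 = sample(8:40, 6), M2 = sample(5:25, 6),
                       M3 = sample(4:20, 6))
  items <- simulate_items(scores, seed = 1)
  items$iat_01[2] <- NA
  out <- score_instruments(items)
  expect_equal(nrow(out), 5)
  items2 <- simulate_items(scores, seed = 1)
  items2$id <- c(1, 1, 2, 3, 4, 5)
  expect_error(score_instruments(items2), "duplicated")
  rel <- reliability_report(simulate_items(scores, seed = 2))
  expect_equal(rel$k, c(20, 26, 8, 5, 4))
  expect_equal(rel$scale, c("iat", "ppq", "emoada", "leaada", "intada"))
})
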