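test_that("range-normalised RMSE: arithmetic, shift invariance, degeneracy", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0, 100), c(10, 110)), 10)
  x <- runif(20, 0, 50); y <- x + rnorm(20)
  expect_equal(nrmse(x, y), nrmse(x + 7, y + 7))
  expect_error(nrmse(rep(1, 5), runif(5)), "zero reference range")
  expect_error(nrmse(1:3, 1:4))
})

test_that("linear fit reproduces closed forms and reports the origin variant", {
  x <- c(1, 2, 3, 4)
  f <- linear_fit(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope_origin, 2)
  # exact two-point-style solution with an intercept
  f2 <- linear_fit(c(0, 1, 2), c(1, 3, 5))
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1)
  # slope tends to 1 as noise vanishes
  set.seed(1)
  slopes <- vapply(c(1, 0.1, 0.001), function(s) {
    linear_fit(1:50, 1:50 + rnorm(50, 0, s))$slope
  }, numeric(1))
  expect_lt(abs(slopes[3] - 1), abs(slopes[1] - 1) + 0.01)
  expect_equal(slopes[3], 1, tolerance = 1e-3)
  expect_error(linear_fit(rep(2, 5), 1:5), "degenerate")
})

test_that("pearson correlation: bounds and null behaviour", {
  x <- runif(10)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(2)
  expect_lt(abs(pearson(rnorm(5000), rnorm(5000))), 0.1)
  expect_error(pearson(rep(1, 5), runif(5)), "variance")
})

test_that("Bland-Altman bias and limits of agreement", {
  a <- runif(10)
  ba <- bland_altman(a, a)
  expect_equal(ba$bias, 0); expect_equal(ba$loa, c(0, 0))
  # constant difference: zero SD, degenerate limits at the bias
  ba <- bland_altman(a + 3, a)
  expect_equal(ba$bias, 3); expect_equal(ba$loa, c(3, 3))
  # standard-normal differences: limits tend to +/- 1.96
  set.seed(3)
  d <- rnorm(2e5)
  ba <- bland_altman(d, rep(0, length(d)))
  expect_equal(ba$loa, c(-1.96, 1.96), tolerance = 0.02)
  # swapping the inputs negates the bias and mirrors the limits
  x <- runif(30); y <- x + rnorm(30, 0.5, 0.2)
  b1 <- bland_altman(x, y); b2 <- bland_altman(y, x)
  expect_equal(b1$bias, -b2$bias)
  expect_equal(b1$loa, -rev(b2$loa))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("method_agreement bundles fit, NRMSE and Bland-Altman coherently", {
  set.seed(4)
  ref <- runif(30, 100, 3000)
  cand <- 0.97 * ref + 20 + rnorm(30, 0, 15)
  ma <- method_agreement(ref, cand, labels = c("OLA", "VLA"))
  expect_s3_class(ma, "method_agreement")
  expect_equal(ma$slope, linear_fit(ref, cand)$slope)
  expect_equal(ma$nrmse_pct, nrmse(ref, cand))
  expect_equal(ma$bias, mean(cand - ref))
  expect_true(ma$loa_low <= ma$bias && ma$bias <= ma$loa_high)
  expect_lte(abs(ma$pearson_r), 1)
  expect_equal(unname(coef(ma)), c(ma$intercept, ma$slope))
  expect_equal(predict(ma, 1000), ma$intercept + ma$slope * 1000)
  expect_equal(residuals(ma), cand - predict(ma))
  expect_output(print(ma), "OLA")
  expect_equal(summary(ma)$nrmse_pct, ma$nrmse_pct)
})

test_that("CV tables use sample SD per group and pool the season row", {
  df <- data.frame(
    das = rep(c(100, 120, 140), each = 4),
    len = c(10, 12, 11, 13, 20, 22, 25, 19, 31, 35, 30, 28),
    thick = c(1, 3, 1, 3, 2, 2.5, 2, 2.5, 3, 3, 3.2, 3.2))
  tab <- cv_table(df, group = "das")
  # a constant group has CV zero
  dfc <- data.frame(g = rep(1:2, each = 3), v = c(5, 5, 5, 1, 2, 3))
  tabc <- cv_table(dfc, group = "g", dims = "v")
  expect_equal(tabc["1", "v"], 0)
  # two values {1, 3}: sample SD sqrt(2), CV = 70.71%
  df2 <- data.frame(g = c("a", "a"), v = c(1, 3))
  expect_equal(cv_table(df2, "g", "v")["a", "v"], 100 * sqrt(2) / 2,
               tolerance = 1e-9)
  # the season row pools raw data and so differs from the mean of group CVs
  pooled <- 100 * sd(df$len) / mean(df$len)
  expect_equal(tab["Season", "len"], pooled)
  expect_equal(tab["Mean", "len"],
               mean(tab[c("100", "120", "140"), "len"]))
  expect_false(isTRUE(all.equal(tab["Season", "len"], tab["Mean", "len"])))
  expect_true(all(tab >= 0))
  expect_error(cv_table(data.frame(g = 1:2, v = 1:2), "g"), "at least 2")
})

test_that("correlation matrix flags significance classes at the right rate", {
  set.seed(5)
  df <- data.frame(a = rnorm(50))
  df$b <- df$a + rnorm(50, 0, 0.01)  # near-duplicate column
  df$c <- rnorm(50)
  cm <- correlation_matrix(df)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_gt(cm$r["a", "b"], 0.999)
  expect_identical(cm$stars["a", "b"], "**")  # P < 0.001
  expect_error(correlation_matrix(data.frame(a = rep(1, 5), b = 1:5)),
               "constant")
  # type-I error rate of the 0.05 flag on independent columns
  set.seed(6)
  flagged <- 0; pairs <- 0
  for (rep in 1:5) {
    m <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
    cm <- correlation_matrix(m)
    up <- upper.tri(cm$p)
    flagged <- flagged + sum(cm$p[up] < 0.05)
    pairs <- pairs + sum(up)
  }
  expect_gt(flagged / pairs, 0.01)
  expect_lt(flagged / pairs, 0.12)
})
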