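test_that("water density interpolation matches an independent oracle and its invariants", {
  # independent closed-form oracle (Kell polynomial) at an off-grid point
  expect_equal(water_density(22), kell_density(22) / 1000, tolerance = 2e-6)
  expect_equal(water_density(21.75), kell_density(21.75) / 1000, tolerance = 2e-6)
  # monotone decreasing above 4 degC
  temps <- seq(15, 30, by = 0.25)
  expect_true(all(diff(water_density(temps)) < 0))
  expect_gt(water_density(21.5), water_density(23))
  # grid points are returned exactly
  expect_equal(water_density(22.5) * 1000, 0.9976558, tolerance = 1e-12)
  # physical range, no extrapolation
  expect_true(all(water_density(temps) * 1000 > 0.995 &
                    water_density(temps) * 1000 < 1.001))
  expect_error(water_density(14.9), "temperature")
  expect_error(water_density(30.1), "temperature")
})

test_that("retainer volume is linear in the reading and rejects non-positive input", {
  rho <- water_density(20)
  expect_equal(retainer_volume(1.000, 20), 1 / rho)
  expect_equal(retainer_volume(2.000, 20), 2 * retainer_volume(1.000, 20))
  expect_error(retainer_volume(0, 20), "positive")
})

test_that("suspension volumetry follows the displaced-water arithmetic", {
  rho <- water_density(22)
  # an empty retainer re-measured gives zero leaf volume
  rec <- suspension_record(dW_r = 1.996, dW_t = 1.996, temp = 22)
  expect_equal(leaf_volume_suspension(rec)$V_l, 0)
  # direct arithmetic: V_l = dW_t / rho - V_r
  rec <- suspension_record(dW_r = 2000 * rho, dW_t = 2500 * rho, temp = 22)
  expect_equal(leaf_volume_suspension(rec, V_r = 2000)$V_l, 500,
               tolerance = 1e-9)
  # round trip against the simulator
  rec <- simulate_suspension_weighing(800, temp = 22, seed = 4)
  expect_equal(leaf_volume_suspension(rec, V_r = 2000)$V_l, 800,
               tolerance = 0.502 / 800)
  # a grossly negative volume flags the bubble failure mode
  bad <- suspension_record(dW_r = 2.0, dW_t = 2.0, temp = 22)
  expect_error(leaf_volume_suspension(bad, V_r = 2100), "bubble")
  # record invariant: dW_t below dW_r is rejected at construction
  expect_error(suspension_record(dW_r = 2.0, dW_t = 1.9, temp = 22), "dW_t")
})

test_that("the two SGB formulas agree and invert the simulator on random consistent records", {
  set.seed(41)
  for (i in 1:50) {
    temp <- runif(1, 15.5, 29.5)
    rho <- water_density(temp)
    V <- runif(1, 50, 3000); V_r <- runif(1, 1000, 3000)
    W_dry <- runif(1, 0.1, 2); W_r1 <- runif(1, 10, 30)
    rec <- simulate_sgb_weighing(V, W_dry, temp = temp,
                                 retainer = list(W_r1 = W_r1, V_r = V_r),
                                 n_replicates = 1, resolution = 0)
    with_r2 <- leaf_volume_sgb(rec, V_r = V_r)$V_l
    rec_no_r2 <- rec; rec_no_r2$W_r2 <- NA_real_
    without_r2 <- leaf_volume_sgb(rec_no_r2, V_r = V_r)$V_l
    expect_equal(with_r2, without_r2, tolerance = 1e-9)
    expect_equal(with_r2, V, tolerance = 1e-9)
  }
  # neutrally buoyant pile: W_T2 = W_r2 implies V_l = W_l1 / rho
  rho <- water_density(22)
  rec <- sgb_record(W_r1 = 20, W_l1 = 0.7, W_T2 = 20 - 2000 * rho, temp = 22,
                    W_r2 = 20 - 2000 * rho)
  expect_equal(leaf_volume_sgb(rec, V_r = 2000)$V_l, 0.7 / rho)
  # inconsistent W_r2 violates the type invariant
  bad <- sgb_record(W_r1 = 20, W_l1 = 0.45, W_T2 = 17.95, temp = 22, W_r2 = 19)
  expect_error(leaf_volume_sgb(bad, V_r = 2000), "inconsistent")
  expect_error(sgb_record(W_r1 = 20, W_l1 = 0.45, W_T2 = 18, temp = 22,
                          W_r2 = 21), "buoyed")
})

test_that("midrib volume models: cylinder, cone, and input validation", {
  expect_equal(midrib_volume(100, 1, "cylinder"), 25 * pi)
  expect_equal(midrib_volume(100, 1, "cylinder"), 78.540, tolerance = 1e-4)
  expect_equal(midrib_volume(100, 1, "cone"), 25 * pi / 3)
  expect_error(midrib_volume(100, 0, "cylinder"), "positive")
  expect_error(midrib_volume(0, 1, "cone"), "positive")
  expect_error(midrib_volume(100, 1, "sphere"))
})

test_that("volumetric leaf area arithmetic, midrib share, and homogeneity", {
  expect_equal(volumetric_leaf_area(250, 0.25), 1000)
  # midrib at 4.5% of total volume
  expect_equal(volumetric_leaf_area(250, 0.25, V_m = 0.045 * 250), 955)
  # linear in V_l, inverse in T_l
  v <- runif(5, 100, 1000); t <- runif(5, 0.1, 0.5)
  expect_equal(volumetric_leaf_area(2 * v, t), 2 * volumetric_leaf_area(v, t))
  expect_equal(volumetric_leaf_area(v, 2 * t), volumetric_leaf_area(v, t) / 2)
  expect_error(volumetric_leaf_area(250, 0), "thickness")
  expect_error(volumetric_leaf_area(250, 0.25, V_m = 250), "V_m")
})

test_that("replicate aggregation discards bubble outliers", {
  expect_equal(aggregate_replicates(c(500, 500, 500)),
               list(estimate = 500, n_used = 3L, used = c(TRUE, TRUE, TRUE)))
  agg <- aggregate_replicates(c(500, 501, 950))
  expect_equal(agg$estimate, 500.5)
  expect_identical(agg$n_used, 2L)
  expect_identical(aggregate_replicates(731)$estimate, 731)
  expect_error(aggregate_replicates(numeric(0)), "replicate")
})

test_that("volume is conserved: a pile weighs as the sum of its members", {
  vols <- c(120, 450, 980, 60, 1500)
  singles <- vapply(vols, function(v) {
    rec <- simulate_suspension_weighing(v, temp = 22, seed = v)
    leaf_volume_suspension(rec, V_r = 2000)$V_l
  }, numeric(1))
  pile_rec <- simulate_suspension_weighing(sum(vols), temp = 22, seed = 77)
  pile <- leaf_volume_suspension(pile_rec, V_r = 2000)$V_l
  # tolerance: one rounding bound per weighing involved
  expect_equal(pile, sum(singles), tolerance = 6 * 0.502 / sum(vols))
})

test_that("median relative volume error stays below 0.5% under default noise", {
  set.seed(13)
  vols <- rlnorm_mean_cv(1000, mean = 600, cv = 0.8)
  vols <- pmax(vols, 100)
  err <- vapply(seq_along(vols), function(i) {
    rec <- simulate_suspension_weighing(vols[i], temp = 22, seed = i)
    abs(leaf_volume_suspension(rec, V_r = 2000)$V_l - vols[i]) / vols[i]
  }, numeric(1))
  expect_lt(median(err), 0.005)
})
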