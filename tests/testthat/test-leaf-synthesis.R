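test_that("closed-form areas and volumes are reproduced by the quadrature", {
  # rectangle: constant width profile
  rect <- rect_specimen(L = 100, W = 10, t = 0.25)
  expect_equal(true_area(rect), 1000, tolerance = 1e-8)
  # slab: volume = area x constant thickness (no midrib)
  expect_equal(true_volume(rect, include_midrib = FALSE), 250, tolerance = 1e-8)
  # triangular profile via a custom width function: area = L W / 2
  tri <- leaf_specimen(leaf_shape(100, 10, width_fun = function(x) 10 * (1 - x / 100),
                                  thickness = c(0.3, 0.25, 0.2)))
  expect_equal(true_area(tri), 500, tolerance = 1e-8)
  # midrib add-on is exactly the cylinder/cone model volume
  piece <- leaf_specimen(leaf_shape(100, 10), interval = c(20, 60), id = "p")
  d <- midrib_diameter_profile(piece$shape, 20)
  expect_equal(true_volume(piece) - true_volume(piece, include_midrib = FALSE),
               midrib_volume(40, d, "cylinder"))
  full <- lance_specimen()
  expect_equal(true_volume(full) - true_volume(full, include_midrib = FALSE),
               midrib_volume(150, full$shape$midrib[1], "cone"))
})

test_that("area and volume are additive over any partition of the leaf", {
  full <- lance_specimen(L = 137, W = 11.3)
  pieces <- cut_specimen(full, cuts = c(12.5, 30, 77.7, 120))
  expect_length(pieces, 5)
  expect_equal(sum(vapply(pieces, true_area, numeric(1))), true_area(full),
               tolerance = 1e-6)
  expect_equal(
    sum(vapply(pieces, function(p) true_volume(p, include_midrib = FALSE),
               numeric(1))),
    true_volume(full, include_midrib = FALSE), tolerance = 1e-6)
})

test_that("degenerate zero-CV population yields identical specimens, and draws are seed-deterministic", {
  p0 <- population_params(n = 5, cv = c(length = 0, width = 0, t_base = 0,
                                        t_middle = 0, t_tip = 0, m_base = 0,
                                        m_middle = 0, m_tip = 0), seed = 3)
  pop <- sample_population(p0)
  shapes <- lapply(pop, function(s) s$shape)
  for (i in 2:5) expect_identical(shapes[[i]], shapes[[1]])
  expect_identical(shapes[[1]]$length, 150)
  # determinism: identical parameter sets give byte-identical lists
  p <- population_params(n = 20, seed = 99)
  expect_identical(sample_population(p), sample_population(p))
  expect_false(identical(sample_population(population_params(n = 20, seed = 100)),
                         sample_population(p)))
  # invalid parameters are rejected
  expect_error(population_params(n = 0), "n must be")
  expect_error(population_params(mean = c(length = -5)), "positive")
  expect_error(population_params(cv = c(width = -0.1)), "non-negative")
})

test_that("population marginals reproduce the requested mean and CV at large n", {
  p <- population_params(n = 1000, cv = c(t_middle = 0.12), seed = 7)
  tm <- vapply(sample_population(p), function(s) s$shape$thickness[2], numeric(1))
  cv_hat <- 100 * sd(tm) / mean(tm)
  expect_gt(cv_hat, 10.2)
  expect_lt(cv_hat, 13.8)
  expect_equal(mean(tm), 0.25, tolerance = 0.02)
  # shape invariants survive the stochastic draw
  pop <- sample_population(population_params(n = 200, seed = 11))
  for (s in pop) {
    expect_gte(s$shape$thickness[1], s$shape$thickness[3])
    expect_gte(s$shape$midrib[1], s$shape$thickness[1])
  }
})

test_that("study-style piece sets hit their target areas and midrib shares", {
  sp <- sample_leaf_pieces(n = 14, area_range = c(60, 3500), seed = 5)
  areas <- vapply(sp, true_area, numeric(1))
  expect_true(all(areas >= 55 & areas <= 3600))
  expect_gt(diff(range(areas)), 500)  # spans a wide range
  truth <- specimen_truth(sp)
  share <- truth$midrib_volume_model /
    (truth$lamina_volume + truth$midrib_volume_model)
  expect_true(all(share >= 0.015 & share <= 0.095))
  expect_identical(sample_leaf_pieces(n = 14, seed = 5)[[3]]$shape,
                   sp[[3]]$shape)
})

test_that("mean thickness sampling follows the field schemes", {
  const <- rect_specimen(t = 0.31)
  for (sch in c("three_point", "every_2cm", "middle_only")) {
    expect_equal(mean_thickness(const, sch), 0.31)
  }
  # linear taper 0.3 -> 0.1 through middle 0.2: three-point mean is 0.2
  taper <- leaf_specimen(leaf_shape(100, 10, thickness = c(0.3, 0.2, 0.1),
                                    midrib = c(0.5, 0.4, 0.3)))
  expect_equal(mean_thickness(taper, "three_point"), 0.2)
  expect_equal(mean_thickness(taper, "middle_only"), 0.2)
  # a 10 mm piece gets exactly one (mid-piece) reading under every_2cm
  short <- leaf_specimen(taper$shape, interval = c(40, 50))
  expect_equal(mean_thickness(short, "every_2cm"),
               leaf_thickness_profile(taper$shape, 45))
  # reading noise is seed-deterministic and zero-mean-ish
  expect_identical(mean_thickness(taper, noise_sd = 0.01, seed = 2),
                   mean_thickness(taper, noise_sd = 0.01, seed = 2))
  expect_false(mean_thickness(taper, noise_sd = 0.01, seed = 2) ==
                 mean_thickness(taper, noise_sd = 0.01, seed = 3))
  expect_error(mean_thickness(taper, "weekly"))
})

test_that("rendering: aligned square pixel count, determinism, canvas guard", {
  sq <- rect_specimen(L = 25.4, W = 25.4, t = 0.25)
  sc <- render_scan(sq, dpi = 200, rotation = 0, offset = c(0, 0))
  expect_equal(sum(sc$pixels), 40000)
  expect_equal(pixels_to_area(segment_pixels(sc), 200), 25.4^2)
  # seed determinism of the full render
  s1 <- render_scan(sq, 200, seed = 42)
  s2 <- render_scan(sq, 200, seed = 42)
  expect_identical(s1$pixels, s2$pixels)
  # the fused count path matches the materialised mask
  leafy <- lance_specimen(L = 90, W = 9)
  expect_equal(optical_area(leafy, 300, seed = 8),
               pixels_to_area(segment_pixels(render_scan(leafy, 300, seed = 8)), 300))
  expect_error(render_scan(lance_specimen(L = 280, W = 20), 200, seed = 1,
                           rotation = pi / 4, canvas = c(210, 297)),
               "canvas")
  expect_error(render_scan(sq, dpi = 10), "dpi")
})

test_that("rasterised area converges to the true area as dpi grows", {
  s <- lance_specimen(L = 60, W = 8)
  a0 <- true_area(s)
  err <- sapply(c(200, 600, 1200), function(d) {
    mean(abs(vapply(1:50, function(i) optical_area(s, d, seed = i), numeric(1)) - a0))
  })
  expect_true(err[1] > err[2] && err[2] > err[3])
  expect_lt(err[3] / a0, 0.001)
})

test_that("weighing simulators invert exactly at zero noise", {
  rho22 <- water_density(22)
  # suspension: pre-rounding reading equals V * rho
  rec <- simulate_suspension_weighing(1000, temp = 22, retainer_volume = 0,
                                      n_replicates = 1, resolution = 0)
  expect_equal(rec$dW_t, 1000 * rho22)
  expect_equal(rec$dW_t, 0.998, tolerance = 1e-3)
  # with 0.001 g rounding, recovery is within the per-replicate bound
  rec <- simulate_suspension_weighing(800, temp = 22, retainer_volume = 2000,
                                      n_replicates = 3, seed = 1)
  got <- leaf_volume_suspension(rec, V_r = 2000)
  expect_equal(got$V_l, 800, tolerance = 0.502 / 800)
  # SGB: algebraic inverse is exact without rounding
  rec <- simulate_sgb_weighing(500, W_dry = 0.45, temp = 22,
                               retainer = list(W_r1 = 20, V_r = 2000),
                               n_replicates = 2, resolution = 0)
  expect_equal(leaf_volume_sgb(rec, V_r = 2000)$V_l, 500, tolerance = 1e-9)
  # neutral buoyancy: W_dry = V * rho implies W_T2 = W_r2
  vb <- 1200; wd <- vb * rho22
  recb <- simulate_sgb_weighing(vb, W_dry = wd, temp = 22,
                                retainer = list(W_r1 = 20, V_r = 2000),
                                n_replicates = 1, resolution = 0)
  expect_equal(recb$W_T2, recb$W_r2)
  # noise draws differ by seed and vanish at SD zero
  r1 <- simulate_suspension_weighing(500, noise_sd = 0.002, seed = 1)
  r2 <- simulate_suspension_weighing(500, noise_sd = 0.002, seed = 2)
  expect_false(identical(r1$dW_t, r2$dW_t))
  expect_identical(simulate_suspension_weighing(500, seed = 1)$dW_t,
                   simulate_suspension_weighing(500, seed = 2)$dW_t)
})
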