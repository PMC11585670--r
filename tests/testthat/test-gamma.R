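test_that("gamma closed forms: identity and uniform dose offsets", {
  ref <- dose_grid(array(10, c(8, 8, 8)))
  g0 <- gamma_map(ref, ref)
  expect_true(all(g0$gamma == 0))
  expect_equal(g0$pass_rate, 100)
  expect_equal(g0$n_evaluated, 512L)

  # 3% of 10 Gy = 0.3 Gy: a uniform 10.3 Gy field sits exactly at criterion
  g1 <- gamma_map(ref, dose_grid(array(10.3, c(8, 8, 8))))
  expect_equal(as.numeric(g1$gamma), rep(1, 512), tolerance = 1e-12)
  expect_equal(g1$pass_rate, 100)

  g2 <- gamma_map(ref, dose_grid(array(10.6, c(8, 8, 8))))
  expect_equal(as.numeric(g2$gamma), rep(2, 512), tolerance = 1e-12)
  expect_equal(g2$pass_rate, 0)
})

test_that("threshold mask follows the dose threshold convention", {
  ref <- dose_grid(array(10, c(5, 5, 5)))
  expect_true(all(threshold_mask(ref, 0)))
  expect_true(all(threshold_mask(ref, 0.2)))

  ramp <- dose_grid(array(rep(seq(0, 10, length.out = 50), 25), c(50, 5, 5)))
  m <- threshold_mask(ramp, 0.2)
  frac <- mean(m)
  expect_lt(abs(frac - 0.8), 1 / 50 + 1e-12)  # within one voxel layer
  # agrees with the direct comparison
  expect_equal(as.vector(m), as.vector(ramp$values >= 0.2 * 10))
})

test_that("pruned gamma equals the exhaustive oracle on random smooth grids", {
  for (s in 1:10) {
    ref <- smooth_random_grid(c(20, 20, 20), max_dose = 10, seed = s)
    ev <- smooth_random_grid(c(20, 20, 20), max_dose = 10, seed = s + 100)
    gm <- gamma_map(ref, ev)
    gb <- gamma_brute_force(ref, ev)
    expect_identical(is.na(gm$gamma), is.na(gb$gamma))
    expect_lt(max(abs(gm$gamma - gb$gamma), na.rm = TRUE), 1e-9)
    expect_identical(gm$n_evaluated, gb$n_evaluated)
    expect_identical(gm$pass_rate, gb$pass_rate)
  }
})

test_that("the C++ engine matches an independent pure-R gamma on a small case", {
  params <- gamma_params(distance_criterion = 2, search_radius_factor = 1,
                         evaluated_upsampling_step = 0.25)
  ref <- smooth_random_grid(c(6, 6, 6), max_dose = 10, sigma = 1.5, seed = 31)
  ev <- smooth_random_grid(c(6, 6, 6), max_dose = 10, sigma = 1.5, seed = 32)
  gm <- gamma_map(ref, ev, params)
  ora <- r_gamma_oracle(ref, ev, params)
  expect_equal(gm$gamma, ora, tolerance = 1e-9)
})

test_that("pass rate is monotone in the criteria", {
  ref <- smooth_random_grid(c(16, 16, 16), max_dose = 10, seed = 41)
  ev <- smooth_random_grid(c(16, 16, 16), max_dose = 10, seed = 42)
  p_base <- gamma_map(ref, ev, gamma_params())$pass_rate
  p_dose <- gamma_map(ref, ev, gamma_params(dose_criterion_fraction = 0.06))$pass_rate
  p_dist <- gamma_map(ref, ev, gamma_params(distance_criterion = 6))$pass_rate
  expect_gte(p_dose, p_base)
  expect_gte(p_dist, p_base)
})

test_that("a sub-criterion translation passes everywhere on the synthetic plan", {
  plan <- small_plan()
  ev <- translate_grid(plan$dose, c(2.7, 0, 0))  # 0.9 x the 3 mm DTA
  g <- gamma_map(plan$dose, ev)
  expect_equal(g$pass_rate, 100)
  # gamma never exceeds |t| / DTA plus the sub-grid discretisation error
  expect_lte(max(g$gamma, na.rm = TRUE), 2.7 / 3 + 0.01)
})

test_that("gamma is invariant under joint positive rescaling (global normalisation)", {
  ref <- smooth_random_grid(c(12, 12, 12), max_dose = 10, seed = 51)
  ev <- smooth_random_grid(c(12, 12, 12), max_dose = 10, seed = 52)
  g1 <- gamma_map(ref, ev)
  ref2 <- dose_grid(ref$values * 3.7, ref$origin, ref$spacing)
  ev2 <- dose_grid(ev$values * 3.7, ev$origin, ev$spacing)
  g2 <- gamma_map(ref2, ev2)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-12)
})

test_that("film-plane gamma confines candidates to the plane and passes for identity", {
  plan <- small_plan()
  curve <- calibration_curve(10, 25)
  scan <- simulate_film(plan$dose, "coronal", 0, curve)
  pl <- place_film_in_3d(od_to_dose(scan, curve), scan$pixel_spacing,
                         scan$origin2d, "coronal", 0,
                         valid = attr(scan, "valid"))
  g <- gamma_film(plan$dose, pl)
  expect_equal(g$pass_rate, 100)
  expect_lt(max(g$gamma, na.rm = TRUE), 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  ref <- dose_grid(array(10, c(4, 4, 4)))
  far <- dose_grid(array(10, c(4, 4, 4)), origin = c(1e3, 1e3, 1e3))
  expect_error(gamma_map(ref, far), "candidate")
  expect_error(gamma_map(dose_grid(array(0, c(4, 4, 4))), ref), "> 0")
})
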