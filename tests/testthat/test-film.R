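test_that("calibration fit recovers exact coefficients and enforces its preconditions", {
  b <- 10; cc <- 25; n <- 2.5
  od <- c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6)
  doses <- b * od + cc * od^n
  fit <- fit_calibration(od, doses)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$c, cc, tolerance = 1e-6)
  expect_equal(as.numeric(od_to_dose(0, fit)), 0)  # no constant term
  expect_lt(attr(fit, "rms_residual"), 1e-9)

  # duplicating a sample leaves the unweighted least-squares fit unchanged
  fit2 <- fit_calibration(c(od, od[3]), c(doses, doses[3]))
  expect_equal(c(fit2$b, fit2$c), c(fit$b, fit$c), tolerance = 1e-9)

  expect_error(fit_calibration(od[1:3], doses[1:3]), "four distinct")
  expect_error(fit_calibration(od, rev(doses)), "non-monotone")
})

test_that("optical density converts to dose pixel-wise and inverts to 1e-9", {
  curve <- calibration_curve(10, 25)
  od <- matrix(0.2, 3, 4)
  d <- od_to_dose(od, curve)
  expect_equal(d[1, 1], 10 * 0.2 + 25 * 0.2^2.5)
  expect_true(all(attr(d, "in_range")))
  expect_equal(as.numeric(od_to_dose(matrix(0, 2, 2), curve)),
               rep(0, 4))

  doses <- matrix(seq(0.01, 11.9, length.out = 64), 8, 8)
  round_trip <- od_to_dose(dose_to_od(doses, curve), curve)
  expect_lt(max(abs(round_trip - doses)), 1e-9)
})

test_that("marker registration recovers known rigid transforms exactly", {
  pts <- rbind(c(-40, -50, 0), c(40, -50, 0), c(40, 50, 0), c(-30, 40, 0))
  # already aligned -> identity, zero residual
  tf0 <- register_markers(film_pts = pts, mri_pts = pts)
  expect_lt(max(abs(tf0$translation)), 1e-9)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-9)
  expect_lt(attr(tf0, "rms_residual"), 1e-9)

  # 90 degrees about z plus (5, 0, 0)
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- sweep(pts %*% t(Rz), 2, c(5, 0, 0), "+")
  tf <- register_markers(film_pts = pts, mri_pts = moved)
  expect_lt(max(abs(tf$rotation - Rz)), 1e-9)
  expect_lt(max(abs(tf$translation - c(5, 0, 0))), 1e-9)

  expect_error(register_markers(film_pts = rbind(c(0, 0, 0), c(1, 0, 0),
                                                 c(2, 0, 0)),
                                mri_pts = rbind(c(0, 0, 0), c(1, 0, 0),
                                                c(2, 0, 0))),
               "collinear")
})

test_that("marker registration under jitter recovers translation within 0.2 mm (Monte Carlo)", {
  set.seed(101)
  pts <- rbind(c(-40, -50, 0), c(40, -50, 0), c(40, 50, 0),
               c(-40, 50, 0), c(0, -55, 0), c(5, 52, 0))  # n = 6
  t_true <- c(1.5, -0.8, 0.4)
  hits <- vapply(1:100, function(i) {
    jit <- pts + matrix(rnorm(18, sd = 0.1), 6, 3)
    tf <- register_markers(film_pts = jit,
                           mri_pts = sweep(pts, 2, t_true, "+"))
    all(abs(tf$translation - t_true) <= 0.2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("film placement positions pixels by the registration transform", {
  dplane <- matrix(1:12, 3, 4) * 1.0
  # identity, coronal plane at y = 0
  pl <- place_film_in_3d(dplane, c(1, 1), c(0, 0), "coronal", 0)
  expect_true(all(pl$coords[, 2] == 0))
  # pure translation moves the slice
  pl3 <- place_film_in_3d(dplane, c(1, 1), c(0, 0), "coronal", 0,
                          rigid_transform(c(0, 3, 0)))
  expect_true(all(pl3$coords[, 2] == 3))
  # consistency with a rotational marker registration
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  tf <- rigid_transform(c(5, 0, 0), Rz)
  plr <- place_film_in_3d(dplane, c(1, 1), c(0, 0), "coronal", 0, tf)
  u <- rep(0:2, times = 4); v <- rep(0:3, each = 3)
  direct <- apply_transform(tf, cbind(u, 0, v))
  expect_lt(max(abs(plr$coords - direct)), 1e-9)
})

test_that("the noiseless film chain reproduces the plane dose and is deterministic", {
  plan <- small_plan()
  curve <- calibration_curve(10, 25)
  scan <- simulate_film(plan$dose, "coronal", plane_offset = 0, curve = curve)
  d2 <- od_to_dose(scan, curve)
  pl <- place_film_in_3d(d2, scan$pixel_spacing, scan$origin2d, "coronal",
                         scan$plane_offset, register_markers(scan),
                         valid = attr(scan, "valid"))
  ref <- trilinear_sample(plan$dose, pl$coords)
  keep <- as.vector(pl$valid) & ref$inside
  expect_lt(max(abs(as.vector(pl$dose)[keep] - ref$values[keep])), 1e-6)

  # coronal and sagittal presets give orthogonal planes
  sag <- simulate_film(plan$dose, "sagittal", plane_offset = 0, curve = curve)
  pls <- place_film_in_3d(od_to_dose(sag, curve), sag$pixel_spacing,
                          sag$origin2d, "sagittal", 0)
  expect_true(all(pl$coords[, 2] == 0))   # coronal: fixed y
  expect_true(all(pls$coords[, 1] == 0))  # sagittal: fixed x

  scan2 <- simulate_film(plan$dose, "coronal", plane_offset = 0,
                         curve = curve, od_noise_sd = 0.01,
                         marker_jitter_sd = 0.1, seed = 7)
  scan3 <- simulate_film(plan$dose, "coronal", plane_offset = 0,
                         curve = curve, od_noise_sd = 0.01,
                         marker_jitter_sd = 0.1, seed = 7)
  expect_identical(serialize(scan2, NULL), serialize(scan3, NULL))
  expect_error(simulate_film(plan$dose, "coronal", plane_offset = 1e4,
                             curve = curve), "outside")
})
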