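test_that("correlation ratio detects functional dependence and independence", {
  plan <- small_plan()
  roi <- roi_from_boxes(plan$dose, ptv_roi_boxes(plan))
  x <- plan$dose$values[roi]
  expect_gte(correlation_ratio(x, x), 0.999)          # eta^2(X, X)
  expect_gte(correlation_ratio(x^2, x), 0.99)         # nonlinear dependence
  # affine rescaling of either argument leaves eta^2 (nearly) unchanged
  expect_equal(correlation_ratio(2 * x + 3, x), correlation_ratio(x, x),
               tolerance = 1e-6)

  set.seed(5)
  f <- runif(1e5); m <- runif(1e5)
  expect_lt(correlation_ratio(f, m), 0.01)            # independent inputs

  expect_equal(correlation_ratio(x, rep(1, length(x))), 0)
  expect_error(correlation_ratio(rep(1, 100), runif(100)), "constant")
})

test_that("Hooke-Jeeves converges on a convex quadratic and honours its contract", {
  target <- c(1.5, -2.25, 0.75)
  f <- function(v) sum((v - target)^2)
  res <- hooke_jeeves(f, c(0, 0, 0),
                      fit_settings(initial_step = 2,
                                   step_reduction_factor = 0.5,
                                   min_step = 0.01))
  expect_true(all(abs(res$par - target) <= 0.01))
  expect_true(res$converged)

  # constant objective: stays at the start, converges by step reduction
  resc <- hooke_jeeves(function(v) 1, c(0.3, -0.1, 0))
  expect_equal(resc$par, c(0.3, -0.1, 0))
  expect_true(resc$converged)

  # stationary start of a 1-D section
  res1 <- hooke_jeeves(function(v) -cos(v), 0,
                       fit_settings(search_bounds = 3))
  expect_equal(res1$par, 0)

  # monotone improvement: never returns a point worse than the start
  set.seed(9)
  for (i in 1:5) {
    start <- runif(3, -2, 2)
    g <- function(v) sin(3 * v[1]) + cos(2 * v[2]) * v[3]^2 + sum(v^2) / 10
    r <- hooke_jeeves(g, start)
    expect_lte(r$value, g(start))
  }

  # determinism
  ra <- hooke_jeeves(f, c(0, 0, 0))
  rb <- hooke_jeeves(f, c(0, 0, 0))
  expect_identical(ra, rb)
})

test_that("self-fit returns a shift no larger than the minimum step", {
  plan <- small_plan()
  fit <- fit_dose_to_readout(plan$dose, plan$dose, ptv_roi_boxes(plan))
  expect_lte(max(abs(fit$shift)), fit_settings()$min_step)
  expect_gte(fit$similarity, 0.999)
})

test_that("known rigid shifts are recovered to sub-resolution accuracy", {
  plan <- small_plan()
  roi <- ptv_roi_boxes(plan)
  for (t_true in list(c(1.0, -0.5, 2.0), c(-0.73, 1.31, -2.57))) {
    meas <- apply_known_shift(plan$dose, rigid_transform(t_true))
    fit <- fit_dose_to_readout(plan$dose, meas, roi)
    expect_true(all(abs(fit$shift - t_true) <= 0.05))
  }
})

test_that("the fit is invariant to affine intensity rescaling of the measurement", {
  plan <- small_plan()
  roi <- ptv_roi_boxes(plan)
  t_true <- c(1.0, -0.5, 2.0)
  meas <- apply_known_shift(plan$dose, rigid_transform(t_true))
  fit0 <- fit_dose_to_readout(plan$dose, meas, roi)
  scaled <- dose_grid(0.5 * meas$values + 1, meas$origin, meas$spacing,
                      meas$valid)
  fit1 <- fit_dose_to_readout(plan$dose, scaled, roi)
  expect_lte(max(abs(fit1$shift - fit0$shift)), fit_settings()$min_step)
})

test_that("the gel chain output yields the same recovery as the raw shifted dose", {
  plan <- small_plan()
  t_true <- c(1.0, -0.5, 2.0)
  meas <- apply_known_shift(plan$dose, rigid_transform(t_true))
  gel <- gel_to_dose(simulate_gel(meas, noise_sd = 0,
                                  readout_spacing = meas$spacing),
                     reference_max_dose = max(plan$dose$values),
                     output_spacing = meas$spacing)
  fit <- fit_dose_to_readout(plan$dose, gel, ptv_roi_boxes(plan))
  expect_true(all(abs(fit$shift - t_true) <= 0.05))
})

test_that("a frozen axis stays at its start (in-plane film fitting mode)", {
  plan <- small_plan()
  t_true <- c(1.0, 0, -1.5)
  meas <- apply_known_shift(plan$dose, rigid_transform(t_true))
  fit <- fit_dose_to_readout(plan$dose, meas, ptv_roi_boxes(plan),
                             free_axes = c(TRUE, FALSE, TRUE))
  expect_identical(fit$shift[2], 0)
  expect_true(all(abs(fit$shift[c(1, 3)] - t_true[c(1, 3)]) <= 0.05))
})

test_that("displacement vectors and session statistics are exact", {
  v <- displacement_vectors(c(0.1, 0.2, 0.2))
  expect_equal(as.numeric(v["v_3d"]), 0.3)
  expect_equal(as.numeric(displacement_vectors(c(0.3, 0, 0.4))["v_xz"]), 0.5)
  expect_equal(as.numeric(displacement_vectors(c(0, 0, 0))), rep(0, 4))

  s <- session_statistics(cbind(c(0.1, 0.2, 0.3), 0, 0))
  expect_equal(s$mean[s$quantity == "dx"], 0.2)
  expect_equal(s$sd[s$quantity == "dx"], 0.1)
  sid <- session_statistics(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(sid$sd == 0))
  s1 <- session_statistics(rbind(c(1, 2, 3)))
  expect_true(all(is.na(s1$sd)))

  # brute-force recomputation from simulated session ground truths
  plan <- small_plan()
  sess <- simulate_session(plan, 5, shift_sd = 0.3, seed = 17)
  shifts <- t(vapply(sess, function(m) m$true_transform$translation,
                     numeric(3)))
  st <- session_statistics(shifts)
  expect_equal(st$mean[1:3], colMeans(shifts))
  expect_equal(st$sd[1:3], apply(shifts, 2, sd))
  v3 <- sqrt(rowSums(shifts^2))
  expect_equal(st$mean[st$quantity == "v_3d"], mean(v3))
  expect_equal(st$sd[st$quantity == "v_3d"], sd(v3))
})
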