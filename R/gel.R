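#' Polymer-gel readout (R2 relaxation-rate map)
#'
#' Container for a gel dosimeter readout: a 3D map of the transverse
#' relaxation rate R2 (s^-1) on its own lattice, together with the linear
#' dose-response coefficients `R2 = intercept + slope * dose`. In polymer
#' gels R2 increases with dose, so the slope must be positive.
#'
#' @param r2 3D numeric array of R2 values (s^-1).
#' @param origin,spacing readout lattice geometry (mm), voxel-centre
#'   convention as in [dose_grid()].
#' @param slope dose sensitivity b (s^-1/Gy), > 0.
#' @param intercept baseline R2 a (s^-1) at zero dose.
#' @param valid optional logical array marking meaningful voxels.
#' @return An object of class `gel_readout`.
#' @export
gel_readout <- function(r2, origin, spacing, slope, intercept, valid = NULL) {
  stopifnot(is.array(r2), length(dim(r2)) == 3, slope > 0, all(spacing > 0))
  storage.mode(r2) <- "double"
  if (!is.null(valid)) stopifnot(identical(dim(valid), dim(r2)))
  keep <- if (is.null(valid)) TRUE else valid
  if (any(!is.finite(r2[keep]))) stop("R2 values must be finite on valid voxels")
  structure(list(r2 = r2, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), slope = slope,
                 intercept = intercept, valid = valid),
            class = "gel_readout")
}

#' Fit R2 maps from multi-echo signal amplitudes
#'
#' Per-voxel least-squares fit of the mono-exponential decay
#' `S(TE) = S0 exp(-R2 TE)` in log space: `log S = log S0 - R2 TE`. Exact for
#' noiseless mono-exponential input. Voxels with a non-positive signal at any
#' echo are flagged invalid (`NA` in the map).
#'
#' @param signals numeric array whose last dimension indexes echoes: either a
#'   4D array (3D volume x echo) or an n x n_echo matrix.
#' @param echo_times echo times TE (s), at least two distinct values.
#' @return list with `r2` (same spatial shape as the input, s^-1) and `valid`
#'   (logical).
#' @export
fit_r2_from_echoes <- function(signals, echo_times) {
  echo_times <- as.numeric(echo_times)
  ne <- length(echo_times)
  if (ne < 2 || length(unique(echo_times)) < 2)
    stop("at least two distinct echo times are required")
  d <- dim(signals)
  if (is.null(d)) stop("signals must be a matrix or 4D array")
  stopifnot(d[length(d)] == ne)
  spatial <- d[-length(d)]
  S <- matrix(signals, ncol = ne)
  valid <- rowSums(!is.finite(S) | S <= 0) == 0
  tc <- echo_times - mean(echo_times)
  w <- tc / sum(tc^2)
  r2 <- rep(NA_real_, nrow(S))
  if (any(valid)) r2[valid] <- -as.numeric(log(S[valid, , drop = FALSE]) %*% w)
  if (length(spatial) > 1) {
    r2 <- array(r2, spatial)
    valid <- array(valid, spatial)
  }
  list(r2 = r2, valid = valid)
}

#' Simulate a gel readout from a dose grid
#'
#' Resamples the dose onto the gel readout lattice (default the study's
#' 0.78 x 0.78 x 2.0 mm MRI protocol) and applies the linear dose response
#' `R2 = a + b * dose` plus optional Gaussian noise. Doses beyond 20 Gy are
#' outside the gel's linear range and trigger a warning.
#'
#' @param dose a [dose_grid()].
#' @param slope sensitivity b (s^-1/Gy), default 0.4.
#' @param intercept baseline a (s^-1), default 1.2.
#' @param noise_sd Gaussian R2 noise SD (s^-1), default 0.
#' @param readout_spacing gel lattice spacing (mm), default
#'   `c(0.78, 0.78, 2.0)`.
#' @param seed integer noise seed.
#' @return A [gel_readout()] covering the dose grid's extent.
#' @export
simulate_gel <- function(dose, slope = 0.4, intercept = 1.2, noise_sd = 0,
                         readout_spacing = c(0.78, 0.78, 2.0), seed = 1L) {
  if (max(dose$values) > 20)
    warning("dose exceeds 20 Gy: beyond the gel's linear response range")
  geom <- cover_geometry(dose, readout_spacing)
  res <- resample(dose, rigid_transform(), geom)
  r2 <- intercept + slope * res$values
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    r2 <- r2 + array(rnorm(length(r2), sd = noise_sd), dim(r2))
  }
  gel_readout(r2, geom$origin, geom$spacing, slope, intercept,
              valid = res$valid)
}

# smallest lattice at the requested spacing whose voxel-centre hull covers the
# grid's voxel-centre hull, centred on the same extent
cover_geometry <- function(grid, spacing) {
  spacing <- as.numeric(spacing)
  d <- dim(grid$values)
  extent <- (d - 1) * grid$spacing
  n <- pmax(1L, as.integer(ceiling(extent / spacing)) + 1L)
  centre <- grid$origin + extent / 2
  list(origin = centre - (n - 1) / 2 * spacing, spacing = spacing, dim = n)
}

#' Convert a gel readout to a normalised dose grid
#'
#' Subtracts the baseline R2, resamples the (dose-proportional) map onto an
#' isotropic output lattice, and rescales so its maximum equals the maximum
#' calculated (planned) dose -- the normalisation applied to gel readouts
#' before comparison. Negative values after scaling are clipped to 0.
#'
#' @param readout a [gel_readout()].
#' @param reference_max_dose the maximum calculated dose (Gy), > 0; the output
#'   maximum equals this exactly.
#' @param output_spacing isotropic output voxel size (mm), default
#'   `c(1, 1, 1)`.
#' @return A [dose_grid()] with validity mask.
#' @export
gel_to_dose <- function(readout, reference_max_dose,
                        output_spacing = c(1, 1, 1)) {
  stopifnot(reference_max_dose > 0)
  rel <- readout$r2 - readout$intercept
  keep <- if (is.null(readout$valid)) array(TRUE, dim(rel)) else readout$valid
  if (!any(keep)) stop("gel readout has no valid voxels")
  if (diff(range(rel[keep])) == 0)
    stop("constant R2 map: zero dynamic range, cannot normalise")
  rel[rel < 0] <- 0
  src <- dose_grid(rel, readout$origin, readout$spacing, valid = keep)
  geom <- cover_geometry(src, output_spacing)
  res <- resample(src, rigid_transform(), geom)
  v <- res$values
  mx <- max(v[res$valid])
  if (mx <= 0) stop("gel readout has no positive signal above baseline")
  v <- (v / mx) * reference_max_dose  # maximum maps to exactly 1 * reference
  v[v < 0] <- 0
  dose_grid(v, geom$origin, geom$spacing, valid = res$valid)
}
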