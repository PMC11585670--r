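#' Truncated-cone target specification
#'
#' One of the two cone-shaped planning target volumes (PTVs) of the dual-cone
#' head-phantom plan. The cone tapers linearly from `tip_diameter` at the apex
#' to `base_diameter` at axial distance `length` along `axis`. Defaults follow
#' the study geometry: tip 0.5 cm, base 3.0 cm, length 4.6 cm.
#'
#' @param tip_diameter,base_diameter cone diameters (mm),
#'   `0 < tip_diameter < base_diameter`.
#' @param length cone length (mm) along the axis.
#' @param axis direction of the cone axis (normalised internally).
#' @param apex world position (mm) of the tip centre.
#' @return An object of class `cone_spec`.
#' @export
cone_spec <- function(tip_diameter = 5, base_diameter = 30, length = 46,
                      axis = c(0, 1, 0), apex = c(0, -23, 20)) {
  stopifnot(tip_diameter > 0, tip_diameter < base_diameter, length > 0)
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  stopifnot(nrm > 0)
  structure(list(tip_diameter = tip_diameter, base_diameter = base_diameter,
                 length = length, axis = axis / nrm, apex = as.numeric(apex)),
            class = "cone_spec")
}

#' Voxel mask of a truncated cone
#'
#' True where the voxel centre lies inside the cone: axial coordinate
#' `s = (p - apex) . axis` in `[0, length]` and radial distance at most the
#' linearly interpolated radius `r(s) = r_tip + (r_base - r_tip) s / length`.
#'
#' @param spec a [cone_spec()].
#' @param grid a [dose_grid()] (geometry source).
#' @return Logical array of the grid's shape. Errors if no voxel centre falls
#'   inside the cone.
#' @export
cone_mask <- function(spec, grid) {
  p <- voxel_centers(grid)
  v <- sweep(p, 2, spec$apex, "-")
  s <- as.numeric(v %*% spec$axis)
  perp2 <- rowSums(v^2) - s^2
  r <- (spec$tip_diameter + (spec$base_diameter - spec$tip_diameter) *
          s / spec$length) / 2
  inside <- s >= 0 & s <= spec$length & perp2 <= r^2 + 1e-12
  if (!any(inside)) stop("cone lies outside the grid: empty mask")
  array(inside, dim(grid$values))
}

# axis-aligned bounding box (2 x 3 matrix, mm) of a truncated cone
cone_bounding_box <- function(spec) {
  rmax <- spec$base_diameter / 2
  ends <- rbind(spec$apex, spec$apex + spec$length * spec$axis)
  # pad the full base radius in every direction orthogonal-agnostically;
  # slightly generous for oblique axes, exact for axis-aligned cones
  pad <- rmax * sqrt(pmax(0, 1 - spec$axis^2))
  rbind(pmin(ends[1, ], ends[2, ]) - pad, pmax(ends[1, ], ends[2, ]) + pad)
}

#' Dual-cone phantom plan specification
#'
#' Parameters of the synthetic pre-treatment plan: two identical truncated
#' cones mirrored in z about `z = 0` (axes along y), a PTV maximum dose of
#' 11 Gy, a background plateau kept below the 6 Gy out-of-PTV cap, a Gaussian
#' penumbra, and per-voxel Gaussian statistical noise. The default lattice is
#' the 1.0 mm isotropic recalculation grid (120 x 120 x 160 voxels, centred on
#' the isocentre); `grid_preset = "online"` selects the coarser 3.0 mm online
#' dose grid.
#'
#' @param cone1,cone2 [cone_spec()] objects; defaults are the mirrored pair at
#'   z = -20 mm and z = +20 mm.
#' @param ptv_max_dose maximum dose over PTV voxels (Gy); the generated plan
#'   is rescaled so this holds exactly.
#' @param background_cap upper bound (Gy) for dose outside the (dilated)
#'   PTVs.
#' @param background_dose raw plateau level (Gy, pre-normalisation) of the
#'   head background; kept well below the cap so the cap holds after
#'   normalisation.
#' @param penumbra_sigma Gaussian penumbra width (mm).
#' @param noise_sd_fraction per-voxel Gaussian noise SD as a fraction of the
#'   maximum dose (default 0.001, the statistical level of the recalculated
#'   plan).
#' @param grid_preset `"recalculated"` (1 mm) or `"online"` (3 mm), or supply
#'   `origin`/`spacing`/`dim` explicitly.
#' @param origin,spacing,dim grid geometry overrides (mm / voxel counts).
#' @param seed integer seed driving all randomness of the generator.
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(cone1 = cone_spec(apex = c(0, -23, -20)),
                      cone2 = cone_spec(apex = c(0, -23, 20)),
                      ptv_max_dose = 11, background_cap = 6,
                      background_dose = 4, penumbra_sigma = 3,
                      noise_sd_fraction = 0.001,
                      grid_preset = c("recalculated", "online"),
                      origin = NULL, spacing = NULL, dim = NULL,
                      seed = 1L) {
  grid_preset <- match.arg(grid_preset)
  if (is.null(spacing))
    spacing <- if (grid_preset == "online") c(3, 3, 3) else c(1, 1, 1)
  if (is.null(dim))
    dim <- if (grid_preset == "online") c(40, 40, 54) else c(120, 120, 160)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  stopifnot(ptv_max_dose > background_cap, background_cap > 0,
            background_dose > 0, background_dose <= background_cap,
            penumbra_sigma > 0, noise_sd_fraction >= 0)
  spec <- structure(list(cone1 = cone1, cone2 = cone2,
                         ptv_max_dose = ptv_max_dose,
                         background_cap = background_cap,
                         background_dose = background_dose,
                         penumbra_sigma = penumbra_sigma,
                         noise_sd_fraction = noise_sd_fraction,
                         origin = as.numeric(origin),
                         spacing = as.numeric(spacing),
                         dim = as.integer(dim), seed = as.integer(seed)),
                    class = "plan_spec")
  spec
}

# separable 3D Gaussian blur; truncated kernels are renormalised per row so
# constant fields (and the mirror symmetry of symmetric inputs) are preserved
gaussian_blur3 <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    r <- max(1L, ceiling(4 * sigma_mm / spacing[ax]))
    k <- stats::dnorm((-r:r) * spacing[ax], sd = sigma_mm)
    n <- d[ax]
    B <- matrix(0, n, n)
    idx <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
    sel <- abs(idx) <= r
    B[sel] <- k[idx[sel] + r + 1]
    B <- B / rowSums(B)
    arr <- if (ax == 1) {
      array(B %*% matrix(arr, d[1]), d)
    } else if (ax == 2) {
      m <- aperm(arr, c(2, 1, 3))
      aperm(array(B %*% matrix(m, d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      m <- aperm(arr, c(3, 1, 2))
      aperm(array(B %*% matrix(m, d[3]), d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

#' Generate the dual-cone plan dose
#'
#' Builds a deterministic (per seed) synthetic plan dose: a background plateau
#' over the head region plus the two cone indicator fields, both blurred by
#' the Gaussian penumbra, with optional per-voxel Gaussian noise, rescaled so
#' the maximum over PTV voxels equals `ptv_max_dose` exactly, and clipped at
#' zero. The dose model is a geometric stand-in for a TPS dose: the
#' registration and gamma procedures only require realistic gradients.
#'
#' @param spec a [plan_spec()].
#' @return list with `dose` (a [dose_grid()]), `ptv1`, `ptv2` (logical masks),
#'   and `spec`.
#' @export
generate_plan_dose <- function(spec) {
  grid <- dose_grid(array(0, spec$dim), spec$origin, spec$spacing)
  m1 <- cone_mask(spec$cone1, grid)
  m2 <- cone_mask(spec$cone2, grid)
  if (any(m1 & m2)) stop("the two PTV cones overlap")
  for (cn in list(spec$cone1, spec$cone2)) {
    bb <- cone_bounding_box(cn)
    ax <- grid_axes(grid)
    lo <- vapply(1:3, function(a) min(ax[[a]]), 0)
    hi <- vapply(1:3, function(a) max(ax[[a]]), 0)
    if (any(bb[1, ] < lo - spec$spacing / 2) || any(bb[2, ] > hi + spec$spacing / 2))
      stop("a PTV cone exceeds the grid bounds")
  }
  head_box <- rbind(pmin(cone_bounding_box(spec$cone1)[1, ],
                         cone_bounding_box(spec$cone2)[1, ]) - 15,
                    pmax(cone_bounding_box(spec$cone1)[2, ],
                         cone_bounding_box(spec$cone2)[2, ]) + 15)
  head <- roi_from_boxes(grid, head_box)
  raw <- spec$background_dose * gaussian_blur3(array(as.numeric(head), spec$dim),
                                               spec$penumbra_sigma, spec$spacing) +
         spec$ptv_max_dose * gaussian_blur3(array(as.numeric(m1 | m2), spec$dim),
                                            spec$penumbra_sigma, spec$spacing)
  if (spec$noise_sd_fraction > 0) {
    set.seed(spec$seed)
    raw <- raw + rnorm(length(raw), sd = spec$noise_sd_fraction * max(raw))
  }
  ptv <- m1 | m2
  # divide-then-multiply so the PTV maximum equals ptv_max_dose exactly
  raw <- (raw / max(raw[ptv])) * spec$ptv_max_dose
  raw[raw < 0] <- 0
  list(dose = dose_grid(raw, spec$origin, spec$spacing),
       ptv1 = m1, ptv2 = m2, spec = spec)
}

#' ROI boxes encapsulating both PTVs
#'
#' Bounding boxes of the two cones expanded by a margin; the fit region used
#' by the registration, and convertible to a voxel mask with
#' [roi_from_boxes()].
#'
#' @param plan output of [generate_plan_dose()] (or a [plan_spec()]).
#' @param margin expansion (mm) on all faces, default 5.
#' @return list of two 2 x 3 corner matrices.
#' @export
ptv_roi_boxes <- function(plan, margin = 5) {
  spec <- if (inherits(plan, "plan_spec")) plan else plan$spec
  lapply(list(spec$cone1, spec$cone2), function(cn) {
    bb <- cone_bounding_box(cn)
    rbind(bb[1, ] - margin, bb[2, ] + margin)
  })
}

#' Apply a known rigid displacement plus readout noise
#'
#' Ground-truth generator for fit validation: resamples the dose through the
#' transform onto its own lattice, then adds independent Gaussian noise with
#' SD equal to `noise_sd_fraction` times the maximum dose (clipped at 0 Gy).
#' The ground-truth transform is recorded in the `"true_transform"` attribute.
#'
#' @param dose a [dose_grid()].
#' @param transform a [rigid_transform()]; the displacement that moves the
#'   dose distribution.
#' @param noise_sd_fraction Gaussian noise SD as a fraction of max dose.
#' @param seed integer seed for the noise (ignored when noise is 0).
#' @return A [dose_grid()] with validity mask and provenance attribute.
#' @export
apply_known_shift <- function(dose, transform, noise_sd_fraction = 0,
                              seed = 1L) {
  out <- resample(dose, transform, dose)
  if (noise_sd_fraction > 0) {
    set.seed(as.integer(seed))
    v <- out$values + rnorm(length(out$values),
                            sd = noise_sd_fraction * max(dose$values))
    v[v < 0] <- 0
    out <- dose_grid(array(v, dim(out$values)), out$origin, out$spacing,
                     out$valid)
  }
  attr(out, "true_transform") <- transform
  out
}

#' Simulate a measurement session of displaced, noisy dose deliveries
#'
#' Draws `n_measurements` independent rigid shifts (Gaussian per axis) and
#' produces the correspondingly displaced, noisy dose grids, each carrying its
#' ground-truth transform. All randomness flows from `seed`; the same seed
#' reproduces the session bit-identically.
#'
#' @param plan output of [generate_plan_dose()].
#' @param n_measurements number of measurements (default 5, one session).
#' @param shift_sd per-axis SD (mm) of the true shifts (default 0.2); use 0
#'   for identity ground truths.
#' @param noise_sd_fraction per-measurement readout noise fraction.
#' @param seed integer session seed.
#' @return list of lists with elements `dose` (a [dose_grid()]) and
#'   `true_transform` (a [rigid_transform()]).
#' @export
simulate_session <- function(plan, n_measurements = 5, shift_sd = 0.2,
                             noise_sd_fraction = 0, seed = 1L) {
  if (n_measurements < 1) stop("n_measurements must be >= 1")
  set.seed(as.integer(seed))
  shifts <- matrix(rnorm(3 * n_measurements, sd = shift_sd),
                   ncol = 3, byrow = TRUE)
  if (shift_sd == 0) shifts[] <- 0
  meas_seeds <- sample.int(.Machine$integer.max, n_measurements)
  lapply(seq_len(n_measurements), function(i) {
    tf <- rigid_transform(shifts[i, ])
    list(dose = apply_known_shift(plan$dose, tf, noise_sd_fraction,
                                  meas_seeds[i]),
         true_transform = tf)
  })
}
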