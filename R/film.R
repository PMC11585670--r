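#' Radiochromic-film calibration curve
#'
#' Net-optical-density-to-dose response of the form
#' `D(netOD) = b * netOD + c * netOD^n` with fixed exponent `n` (default 2.5),
#' the standard radiochromic-film parameterisation: zero net OD maps to zero
#' dose and the curve is strictly increasing over its valid range.
#'
#' @param b linear coefficient (Gy per unit net OD).
#' @param c power-term coefficient (Gy).
#' @param n fixed exponent, > 1.
#' @param dose_range valid dose range (Gy), default `c(0, 12)`.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(b, c, n = 2.5, dose_range = c(0, 12)) {
  stopifnot(is.finite(b), is.finite(c), n > 1, dose_range[2] > dose_range[1],
            dose_range[1] >= 0)
  curve <- structure(list(b = b, c = c, n = n,
                          dose_range = as.numeric(dose_range),
                          od_range = c(0, 0)),
                     class = "calibration_curve")
  od_hi <- dose_to_od_scalar(curve, dose_range[2])
  od <- seq(0, od_hi, length.out = 512)
  if (any(diff(b * od + c * od^n) <= 0))
    stop("calibration curve is not strictly monotone over the valid range")
  curve$od_range <- c(0, od_hi)
  curve
}

curve_eval <- function(curve, od) curve$b * od + curve$c * od^curve$n

# scalar monotone inverse by expanding bisection
dose_to_od_scalar <- function(curve, dose) {
  hi <- 1
  while (curve_eval(curve, hi) < dose && hi < 1e6) hi <- hi * 2
  lo <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (curve_eval(curve, mid) < dose) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit a film calibration curve from known doses
#'
#' Linear least-squares fit of `D = b * netOD + c * netOD^n` (fixed `n`) to
#' calibration films irradiated with known doses. At least four distinct dose
#' levels are required; the fitted curve must be strictly monotone over the
#' sampled range.
#'
#' @param net_od net optical densities of the calibration films.
#' @param doses matching known doses (Gy).
#' @param n fixed exponent, default 2.5.
#' @param dose_range valid range (Gy) recorded on the curve.
#' @return A [calibration_curve()] with the residuals in attribute
#'   `"residuals"` and their RMS in `"rms_residual"`.
#' @export
fit_calibration <- function(net_od, doses, n = 2.5, dose_range = c(0, 12)) {
  net_od <- as.numeric(net_od); doses <- as.numeric(doses)
  stopifnot(length(net_od) == length(doses), all(net_od >= 0))
  if (length(unique(doses)) < 4)
    stop("at least four distinct calibration dose levels are required")
  o <- order(net_od)
  if (any(diff(doses[o]) < -1e-9 * max(abs(doses))))
    stop("calibration data are non-monotone: dose decreases with net OD")
  X <- cbind(net_od, net_od^n)
  if (qr(X)$rank < 2) stop("rank-deficient calibration fit")
  beta <- as.numeric(qr.solve(X, doses))
  curve <- calibration_curve(beta[1], beta[2], n, dose_range)
  resid <- doses - curve_eval(curve, net_od)
  attr(curve, "residuals") <- resid
  attr(curve, "rms_residual") <- sqrt(mean(resid^2))
  curve
}

#' Convert net optical density to dose
#'
#' Pixel-wise evaluation of a calibration curve. Pixels converting outside
#' the curve's valid dose range are flagged in the `"in_range"` attribute.
#'
#' @param net_od numeric vector/matrix/array of net OD values (or a
#'   [film_scan()], whose `net_od` plane is used).
#' @param curve a [calibration_curve()].
#' @return Dose (Gy) with the shape of the input; logical attribute
#'   `"in_range"`.
#' @export
od_to_dose <- function(net_od, curve) {
  if (inherits(net_od, "film_scan")) net_od <- net_od$net_od
  dose <- curve_eval(curve, net_od)
  attr(dose, "in_range") <- dose >= curve$dose_range[1] &
    dose <= curve$dose_range[2]
  dose
}

#' Invert a calibration curve (dose to net optical density)
#'
#' Monotone numeric inverse by bisection, vectorised over the input; used by
#' the film simulator. Accurate to ~1e-12 in net OD.
#'
#' @param dose numeric dose values (Gy), >= 0.
#' @param curve a [calibration_curve()].
#' @return Net OD values with the shape of the input.
#' @export
dose_to_od <- function(dose, curve) {
  stopifnot(all(dose >= -1e-12))
  d <- pmax(as.numeric(dose), 0)
  hi0 <- dose_to_od_scalar(curve, max(d)) * 1.0000001
  lo <- numeric(length(d)); hi <- rep(hi0, length(d))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    below <- curve_eval(curve, mid) < d
    lo[below] <- mid[below]; hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  if (!is.null(dim(dose))) dim(out) <- dim(dose)
  out
}

#' Film scan with marker correspondences
#'
#' A 2D net-optical-density plane in film coordinates `(u, v)` plus the
#' point-matching marker correspondences used to register the film into the
#' 3D online-MRI frame: the centres of the circular cut-outs on the film and
#' the matching MR-visible marker positions in 3D.
#'
#' Film-plane convention (IEC 61217): a *coronal* film spans x (u) and z (v)
#' at fixed y; a *sagittal* film spans y (u) and z (v) at fixed x.
#'
#' @param net_od 2D numeric matrix of net OD (>= 0).
#' @param pixel_spacing length-2 pixel size (mm) along (u, v).
#' @param origin2d length-2 film coordinate (mm) of the first pixel centre.
#' @param plane `"coronal"` or `"sagittal"`.
#' @param plane_offset nominal world coordinate (mm) of the film plane along
#'   its normal (y for coronal, x for sagittal).
#' @param marker_points_film k x 2 matrix (k >= 3) of cut-out centres in film
#'   coordinates (mm).
#' @param marker_points_mri k x 3 matrix of matching MR marker positions (mm).
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(net_od, pixel_spacing, origin2d = c(0, 0),
                      plane = c("coronal", "sagittal"), plane_offset = 0,
                      marker_points_film, marker_points_mri) {
  plane <- match.arg(plane)
  net_od <- as.matrix(net_od)
  stopifnot(all(net_od >= 0), all(pixel_spacing > 0))
  marker_points_film <- as.matrix(marker_points_film)
  marker_points_mri <- as.matrix(marker_points_mri)
  stopifnot(nrow(marker_points_film) >= 3,
            nrow(marker_points_film) == nrow(marker_points_mri),
            ncol(marker_points_film) == 2, ncol(marker_points_mri) == 3)
  structure(list(net_od = net_od, pixel_spacing = as.numeric(pixel_spacing),
                 origin2d = as.numeric(origin2d), plane = plane,
                 plane_offset = plane_offset,
                 marker_points_film = marker_points_film,
                 marker_points_mri = marker_points_mri),
            class = "film_scan")
}

# lift film-plane 2D coordinates into 3D world coordinates at the nominal
# plane position
lift_film_points <- function(pts2d, plane, plane_offset) {
  pts2d <- as.matrix(pts2d)
  if (plane == "coronal") cbind(pts2d[, 1], plane_offset, pts2d[, 2])
  else cbind(plane_offset, pts2d[, 1], pts2d[, 2])
}

#' Rigid point-matching registration (orthogonal Procrustes)
#'
#' Closed-form least-squares rigid transform (Kabsch solution) mapping the
#' film cut-out centres, lifted to 3D in the nominal film plane, onto the MR
#' marker positions. At least three non-collinear correspondences are
#' required (collinearity tested on the second singular value of the centred
#' source points, tolerance 1e-6).
#'
#' @param scan a [film_scan()]; alternatively supply `film_pts` (k x 3) and
#'   `mri_pts` (k x 3) directly.
#' @param film_pts,mri_pts optional explicit 3D correspondences overriding
#'   `scan`.
#' @return A [rigid_transform()] mapping film points onto MRI points, with
#'   the RMS correspondence residual (mm) in attribute `"rms_residual"`.
#' @export
register_markers <- function(scan = NULL, film_pts = NULL, mri_pts = NULL) {
  if (is.null(film_pts)) {
    stopifnot(inherits(scan, "film_scan"))
    film_pts <- lift_film_points(scan$marker_points_film, scan$plane,
                                 scan$plane_offset)
    mri_pts <- scan$marker_points_mri
  }
  film_pts <- as_points3(film_pts); mri_pts <- as_points3(mri_pts)
  stopifnot(nrow(film_pts) >= 3, nrow(film_pts) == nrow(mri_pts))
  pc <- colMeans(film_pts); qc <- colMeans(mri_pts)
  P <- sweep(film_pts, 2, pc); Q <- sweep(mri_pts, 2, qc)
  if (svd(P)$d[2] < 1e-6)
    stop("marker points are collinear: rotation under-determined")
  H <- crossprod(P, Q)           # sum p_i q_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qc - as.numeric(R %*% pc)
  tf <- rigid_transform(t, R)
  resid <- mri_pts - apply_transform(tf, film_pts)
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' Place a film dose plane into the 3D frame
#'
#' Applies the film-to-MRI registration transform to every film pixel,
#' producing a one-pixel-thick planar dose object in world coordinates: pixel
#' values plus their exact transformed 3D positions and a validity mask
#' confined to the plane. Downstream registration fitting consumes it like a
#' single-slice grid.
#'
#' @param dose_plane 2D matrix of film dose (Gy) in film coordinates.
#' @param pixel_spacing length-2 pixel size (mm).
#' @param origin2d film coordinate (mm) of the first pixel centre.
#' @param plane `"coronal"` or `"sagittal"`.
#' @param plane_offset nominal plane position (mm) along the plane normal.
#' @param transform a [rigid_transform()] from [register_markers()] (default
#'   identity).
#' @param valid optional logical matrix of meaningful pixels.
#' @return An object of class `film_placement` with elements `dose`,
#'   `coords` (n x 3 world positions, pixel order column-major), `valid`,
#'   `plane`, `pixel_spacing`, `origin2d`, `plane_offset`, `transform`.
#' @export
place_film_in_3d <- function(dose_plane, pixel_spacing, origin2d = c(0, 0),
                             plane = c("coronal", "sagittal"),
                             plane_offset = 0,
                             transform = rigid_transform(), valid = NULL) {
  plane <- match.arg(plane)
  dose_plane <- as.matrix(dose_plane)
  d <- dim(dose_plane)
  u <- origin2d[1] + (seq_len(d[1]) - 1) * pixel_spacing[1]
  v <- origin2d[2] + (seq_len(d[2]) - 1) * pixel_spacing[2]
  pts2d <- cbind(rep(u, times = d[2]), rep(v, each = d[1]))
  coords <- apply_transform(transform,
                            lift_film_points(pts2d, plane, plane_offset))
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  structure(list(dose = dose_plane, coords = coords, valid = valid,
                 plane = plane, pixel_spacing = as.numeric(pixel_spacing),
                 origin2d = as.numeric(origin2d), plane_offset = plane_offset,
                 transform = transform),
            class = "film_placement")
}

#' Simulate a film measurement from a 3D dose grid
#'
#' Extracts the requested film plane from the dose by trilinear sampling,
#' converts dose to net optical density through the inverse calibration
#' curve, adds optional OD noise, and generates marker correspondences
#' (exact MR positions; film positions with optional Gaussian jitter).
#' Deterministic per seed.
#'
#' @param dose a [dose_grid()].
#' @param plane `"coronal"` or `"sagittal"`.
#' @param plane_offset plane position (mm) along its normal.
#' @param curve a [calibration_curve()].
#' @param pixel_spacing film pixel size (mm), default `c(1, 1)`.
#' @param od_noise_sd Gaussian net-OD noise SD, default 0.
#' @param marker_jitter_sd Gaussian jitter SD (mm) on the film-side marker
#'   coordinates, default 0.
#' @param marker_points_film k x 2 nominal marker positions in film
#'   coordinates; default four non-collinear points near the film corners.
#' @param seed integer seed.
#' @return A [film_scan()] (pixels outside the dose grid carry zero OD and
#'   are flagged in attribute `"valid"`).
#' @export
simulate_film <- function(dose, plane = c("coronal", "sagittal"),
                          plane_offset = 0, curve,
                          pixel_spacing = c(1, 1), od_noise_sd = 0,
                          marker_jitter_sd = 0, marker_points_film = NULL,
                          seed = 1L) {
  plane <- match.arg(plane)
  ax <- grid_axes(dose)
  inplane <- if (plane == "coronal") ax[c(1, 3)] else ax[c(2, 3)]
  normal_range <- if (plane == "coronal") range(ax[[2]]) else range(ax[[1]])
  if (plane_offset < normal_range[1] || plane_offset > normal_range[2])
    stop("film plane lies outside the dose grid")
  u <- seq(min(inplane[[1]]), max(inplane[[1]]), by = pixel_spacing[1])
  v <- seq(min(inplane[[2]]), max(inplane[[2]]), by = pixel_spacing[2])
  pts2d <- cbind(rep(u, times = length(v)), rep(v, each = length(u)))
  smp <- trilinear_sample(dose, lift_film_points(pts2d, plane, plane_offset))
  plane_dose <- matrix(ifelse(smp$inside, smp$values, 0),
                       length(u), length(v))
  od <- dose_to_od(pmin(plane_dose, curve$dose_range[2]), curve)
  set.seed(as.integer(seed))
  if (od_noise_sd > 0)
    od <- pmax(od + matrix(rnorm(length(od), sd = od_noise_sd), nrow(od)), 0)
  if (is.null(marker_points_film)) {
    ru <- range(u); rv <- range(v)
    mu <- 0.1 * diff(ru); mv <- 0.1 * diff(rv)
    marker_points_film <- rbind(c(ru[1] + mu, rv[1] + mv),
                                c(ru[2] - mu, rv[1] + mv),
                                c(ru[2] - mu, rv[2] - mv),
                                c(ru[1] + 2 * mu, rv[2] - 2 * mv))
  }
  mri_pts <- lift_film_points(marker_points_film, plane, plane_offset)
  film_pts <- marker_points_film
  if (marker_jitter_sd > 0)
    film_pts <- film_pts + matrix(rnorm(length(film_pts),
                                        sd = marker_jitter_sd),
                                  nrow(film_pts))
  scan <- film_scan(od, pixel_spacing, origin2d = c(min(u), min(v)),
                    plane = plane, plane_offset = plane_offset,
                    marker_points_film = film_pts,
                    marker_points_mri = mri_pts)
  attr(scan, "valid") <- matrix(smp$inside, length(u), length(v))
  scan
}
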