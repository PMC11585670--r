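#' Settings for the dose-to-readout registration fit
#'
#' Controls the Hooke-Jeeves pattern search and the correlation-ratio
#' similarity metric. Defaults: initial step 2.0 mm, geometric step reduction
#' 0.5, minimum step 0.01 mm (two orders of magnitude below the sub-millimetre
#' effects of interest), at most 200 iterations, 64 histogram bins, and a
#' +/- 10 mm search range per axis.
#'
#' @param initial_step starting exploratory step (mm).
#' @param step_reduction_factor step shrink factor in (0, 1) applied on a
#'   failed exploratory cycle.
#' @param min_step termination step (mm), < `initial_step`.
#' @param max_iterations iteration cap.
#' @param n_bins correlation-ratio histogram bins, >= 8.
#' @param search_bounds per-axis search half-range (mm) around the start.
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(initial_step = 2, step_reduction_factor = 0.5,
                         min_step = 0.01, max_iterations = 200,
                         n_bins = 64, search_bounds = c(10, 10, 10)) {
  stopifnot(initial_step > min_step, min_step > 0,
            step_reduction_factor > 0, step_reduction_factor < 1,
            n_bins >= 8, max_iterations >= 1, all(search_bounds > 0))
  structure(list(initial_step = initial_step,
                 step_reduction_factor = step_reduction_factor,
                 min_step = min_step,
                 max_iterations = as.integer(max_iterations),
                 n_bins = as.integer(n_bins),
                 search_bounds = rep_len(as.numeric(search_bounds), 3)),
            class = "fit_settings")
}

#' Correlation ratio between two aligned intensity sets
#'
#' The correlation ratio eta^2 measures how well `fixed` is predicted by an
#' arbitrary function of `moving`:
#' `eta^2 = 1 - E[Var(fixed | moving bin)] / Var(fixed)`, with `moving`
#' partitioned into `n_bins` equal-width bins over its range. It is 1 for a
#' perfect (possibly nonlinear) functional dependence, near 0 for independent
#' intensities, and invariant under affine rescaling of either input -- the
#' property that makes it suitable for registering a planned dose against a
#' linearly converted dosimeter readout.
#'
#' @param fixed numeric vector, the dependent intensities (already masked to
#'   the ROI).
#' @param moving numeric vector of equal length, the binning intensities.
#' @param n_bins number of equal-width bins, default 64. Empty bins
#'   contribute nothing.
#' @return eta^2 in `[0, 1]`. A constant `moving` returns 0; a constant
#'   `fixed` is an error (the metric is undefined).
#' @export
correlation_ratio <- function(fixed, moving, n_bins = 64) {
  stopifnot(length(fixed) == length(moving), length(fixed) > 1)
  n <- length(fixed)
  vf <- sum((fixed - mean(fixed))^2) / n
  if (vf == 0) stop("fixed intensities are constant: correlation ratio undefined")
  rng <- range(moving)
  if (rng[1] == rng[2]) return(0)
  w <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((moving - rng[1]) / w) + 1, n_bins)
  agg <- rowsum(cbind(1, fixed, fixed^2), idx)
  nj <- agg[, 1]
  within <- sum(agg[, 3] - agg[, 2]^2 / nj) / n
  min(max(1 - within / vf, 0), 1)
}

#' Hooke-Jeeves pattern-search minimisation
#'
#' Classic derivative-free pattern search: exploratory moves of +/- step along
#' each axis in fixed order (positive direction probed first, strict
#' improvement required); on an improved exploratory cycle a pattern move
#' doubles the successful displacement and exploration continues around the
#' pattern point; on failure the step is multiplied by the reduction factor.
#' Terminates when the step falls below `min_step` or the iteration cap is
#' reached. Fully deterministic; candidates outside the search bounds or with
#' non-finite objective are rejected. The returned point is never worse than
#' the start.
#'
#' @param objective function of a numeric vector returning a finite scalar to
#'   minimise.
#' @param start numeric start point (finite objective required there).
#' @param settings a [fit_settings()]; `search_bounds` is interpreted per
#'   axis around `start` (recycled to the dimension of `start`).
#' @return list with `par`, `value`, `iterations`, `converged` (step
#'   reduction completed), and `n_evaluations`.
#' @export
hooke_jeeves <- function(objective, start, settings = fit_settings()) {
  start <- as.numeric(start)
  k <- length(start)
  lower <- start - rep_len(settings$search_bounds, k)
  upper <- start + rep_len(settings$search_bounds, k)
  n_eval <- 0L
  fcall <- function(x) {
    n_eval <<- n_eval + 1L
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  f0 <- fcall(start)
  if (!is.finite(f0)) stop("objective is not finite at the start point")

  explore <- function(x, fx, step) {
    for (a in seq_len(k)) {
      for (s in c(step, -step)) {
        cand <- x
        cand[a] <- cand[a] + s
        if (cand[a] < lower[a] || cand[a] > upper[a]) next
        fc <- fcall(cand)
        if (fc < fx) { x <- cand; fx <- fc; break }
      }
    }
    list(x = x, f = fx)
  }

  base <- start; fb <- f0
  step <- settings$initial_step
  iter <- 0L
  while (step >= settings$min_step && iter < settings$max_iterations) {
    iter <- iter + 1L
    ex <- explore(base, fb, step)
    if (ex$f < fb) {
      # pattern moves: keep doubling the successful displacement while the
      # exploration around the pattern point keeps improving
      repeat {
        dir <- ex$x - base
        base <- ex$x; fb <- ex$f
        pat <- pmin(pmax(base + dir, lower), upper)
        px <- explore(pat, fcall(pat), step)
        if (px$f < fb && iter < settings$max_iterations) {
          iter <- iter + 1L
          ex <- px
        } else break
      }
    } else {
      step <- step * settings$step_reduction_factor
    }
  }
  list(par = base, value = fb, iterations = iter,
       converged = step < settings$min_step, n_evaluations = n_eval)
}

# extract (points, values) of the measured data restricted to the ROI and to
# valid voxels/pixels; roi may be a logical mask aligned with a dose_grid
# measurement, a list of world-space boxes, or NULL (everything valid)
measured_points <- function(measured, roi) {
  if (inherits(measured, "dose_grid")) {
    keep <- if (is.null(measured$valid)) array(TRUE, dim(measured$values))
            else measured$valid
    if (is.logical(roi)) {
      stopifnot(identical(dim(roi), dim(measured$values)))
      keep <- keep & roi
    }
    pts <- voxel_centers(measured)[as.vector(keep), , drop = FALSE]
    vals <- measured$values[keep]
  } else if (inherits(measured, "film_placement")) {
    keep <- as.vector(measured$valid)
    pts <- measured$coords[keep, , drop = FALSE]
    vals <- as.vector(measured$dose)[keep]
    if (is.logical(roi))
      stop("for film placements supply the ROI as world-space boxes")
  } else stop("measured must be a dose_grid or film_placement")
  if (is.list(roi) && !is.logical(roi)) {
    inroi <- rep(FALSE, nrow(pts))
    for (b in roi) {
      b <- as.matrix(b)
      inroi <- inroi | (pts[, 1] >= b[1, 1] & pts[, 1] <= b[2, 1] &
                        pts[, 2] >= b[1, 2] & pts[, 2] <= b[2, 2] &
                        pts[, 3] >= b[1, 3] & pts[, 3] <= b[2, 3])
    }
    pts <- pts[inroi, , drop = FALSE]
    vals <- vals[inroi]
  }
  if (nrow(pts) == 0) stop("no valid measured samples inside the ROI")
  list(points = pts, values = vals)
}

#' Fit the planned dose to a dosimeter readout
#'
#' The core estimator: recovers the rigid shift between the planned 3D dose
#' and a measured dose readout by maximising the correlation ratio (measured
#' dose as the dependent intensities, resampled planned dose defining the
#' bins) over translations with Hooke-Jeeves pattern search, restricted to a
#' region of interest encapsulating both PTVs. The returned shift is the
#' displacement that maps the planned dose onto the measured dose, reported
#' per axis in the IEC 61217 frame.
#'
#' Candidate shifts for which fewer than 50% of the ROI samples map inside
#' the planned grid are rejected; an error is raised if every candidate is
#' rejected.
#'
#' @param planned a [dose_grid()], the planned (TPS) dose.
#' @param measured a [dose_grid()] (gel chain output or shifted plan) or a
#'   [film_placement()].
#' @param roi fit region: a logical mask aligned with a `dose_grid`
#'   measurement, or a list of world-space boxes (see [ptv_roi_boxes()]),
#'   required for film placements.
#' @param settings a [fit_settings()].
#' @param start initial shift (mm), default `c(0, 0, 0)`.
#' @param free_axes logical length-3; axes set to `FALSE` are frozen at
#'   `start` (e.g. in-plane-only film fitting). Default all free (3-DOF).
#' @return list of class `fit_result` with `shift` (mm), `similarity` (the
#'   final correlation ratio), `iterations`, `converged`, `n_evaluations`.
#' @export
fit_dose_to_readout <- function(planned, measured, roi,
                                settings = fit_settings(),
                                start = c(0, 0, 0),
                                free_axes = c(TRUE, TRUE, TRUE)) {
  mp <- measured_points(measured, roi)
  n_roi <- nrow(mp$points)
  any_ok <- FALSE
  objective <- function(shift) {
    smp <- trilinear_sample(planned, sweep(mp$points, 2, shift, "-"))
    ok <- smp$inside
    if (mean(ok) < 0.5) return(Inf)
    any_ok <<- TRUE
    -correlation_ratio(mp$values[ok], smp$values[ok], settings$n_bins)
  }
  full_shift <- as.numeric(start)
  obj_free <- function(x) {
    s <- full_shift
    s[free_axes] <- x
    objective(s)
  }
  res <- tryCatch(
    hooke_jeeves(obj_free, start[free_axes], settings),
    error = function(e) {
      if (!any_ok)
        stop("all candidate shifts rejected: ROI coverage below 50%")
      stop(e)
    })
  if (!any_ok) stop("all candidate shifts rejected: ROI coverage below 50%")
  shift <- full_shift
  shift[free_axes] <- res$par
  structure(list(shift = shift, similarity = -res$value,
                 iterations = res$iterations, converged = res$converged,
                 n_evaluations = res$n_evaluations, n_roi_samples = n_roi),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: shift (%.3f, %.3f, %.3f) mm, eta^2 = %.5f (%d evaluations%s)\n",
              x$shift[1], x$shift[2], x$shift[3], x$similarity,
              x$n_evaluations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Planar and 3D displacement vectors from a per-axis shift
#'
#' Root-sum-square magnitudes of the shift projected into each coordinate
#' plane, plus the full 3D vector. Under IEC 61217 a coronal film plane spans
#' x-z (`v_xz`) and a sagittal plane spans y-z (`v_yz`); all three planar
#' projections are returned with explicit axis labels.
#'
#' @param shift numeric length-3 shift (dx, dy, dz) in mm.
#' @return named numeric vector `c(v_xy, v_xz, v_yz, v_3d)` in mm.
#' @export
displacement_vectors <- function(shift) {
  shift <- as.numeric(shift)
  stopifnot(length(shift) == 3)
  c(v_xy = sqrt(shift[1]^2 + shift[2]^2),
    v_xz = sqrt(shift[1]^2 + shift[3]^2),
    v_yz = sqrt(shift[2]^2 + shift[3]^2),
    v_3d = sqrt(sum(shift^2)))
}

#' Session reproducibility statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-measurement shifts and their planar/3D displacement vectors, the
#' reproducibility summary reported per measurement session.
#'
#' @param shifts n x 3 matrix (or list of length-3 vectors) of per-measurement
#'   shifts (mm).
#' @return data.frame with columns `quantity`, `mean`, `sd` for dx, dy, dz,
#'   v_xy, v_xz, v_yz, v_3d. With a single measurement the SD is `NA`.
#' @export
session_statistics <- function(shifts) {
  if (is.list(shifts)) shifts <- do.call(rbind, shifts)
  shifts <- as.matrix(shifts)
  stopifnot(ncol(shifts) == 3, nrow(shifts) >= 1)
  vecs <- t(apply(shifts, 1, displacement_vectors))
  m <- cbind(dx = shifts[, 1], dy = shifts[, 2], dz = shifts[, 3], vecs)
  data.frame(quantity = colnames(m),
             mean = colMeans(m),
             sd = if (nrow(m) >= 2) apply(m, 2, sd) else NA_real_,
             row.names = NULL)
}
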