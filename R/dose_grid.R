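#' Axis-aligned 3D dose grid
#'
#' The common volumetric container of the pipeline: a 3D scalar field of
#' absorbed dose (Gy) on an axis-aligned lattice in the IEC 61217 patient
#' frame (x lateral, y vertical, z longitudinal), with physical geometry given
#' by the world position of the *centre* of the first voxel (`origin`, mm) and
#' the per-axis voxel size (`spacing`, mm). An optional validity mask marks
#' voxels whose values are meaningful; resampling propagates validity and
#' downstream metrics exclude invalid voxels rather than zero-filling.
#'
#' @param values 3D numeric array of dose in Gy; all finite and >= 0.
#' @param origin numeric length-3, world coordinate (mm) of the first voxel
#'   centre.
#' @param spacing numeric length-3, voxel size (mm) per axis, all > 0.
#' @param valid optional logical array of the same shape; `NULL` means all
#'   voxels valid.
#' @return An object of class `dose_grid`.
#' @seealso [resample()], [trilinear_sample()], [roi_from_boxes()]
#' @examples
#' g <- dose_grid(array(1:8, c(2, 2, 2)), origin = c(0, 0, 0))
#' trilinear_sample(g, cbind(0.5, 0.5, 0.5))
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      valid = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3, all(dim(values) >= 1))
  storage.mode(values) <- "double"
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3, length(spacing) == 3,
            all(is.finite(origin)), all(spacing > 0))
  if (!is.null(valid)) {
    stopifnot(is.logical(valid), identical(dim(valid), dim(values)))
    if (any(!is.finite(values[valid])) || any(values[valid] < 0))
      stop("dose values must be finite and >= 0 on valid voxels")
    values[!valid] <- 0
  } else {
    if (any(!is.finite(values)) || any(values < 0))
      stop("dose values must be finite and >= 0")
  }
  structure(list(values = values, origin = origin, spacing = spacing,
                 valid = valid),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("dose_grid: ", paste(d, collapse = " x "), " voxels, spacing (",
      paste(format(x$spacing), collapse = ", "), ") mm, origin (",
      paste(format(x$origin), collapse = ", "), ") mm\n", sep = "")
  v <- if (is.null(x$valid)) x$values else x$values[x$valid]
  cat("  dose range [", format(min(v)), ", ", format(max(v)), "] Gy",
      if (!is.null(x$valid))
        sprintf("; %.1f%% voxels valid", 100 * mean(x$valid)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Grid dimensions
#' @param grid a [dose_grid()].
#' @return integer length-3 vector of voxel counts.
#' @export
grid_dim <- function(grid) dim(grid$values)

#' Voxel-centre coordinate vectors
#' @param grid a [dose_grid()].
#' @return list of three numeric vectors, the world coordinates (mm) of voxel
#'   centres along each axis.
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$spacing[a])
}

#' World coordinates of every voxel centre
#' @param grid a [dose_grid()].
#' @return n x 3 matrix in array (column-major) order.
#' @export
voxel_centers <- function(grid) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' Convert world coordinates to continuous (0-based) voxel indices
#'
#' Index 0 maps to `origin`; the inverse of [voxel_to_world()].
#'
#' @param grid a [dose_grid()].
#' @param points n x 3 matrix of world coordinates (mm); a length-3 vector is
#'   taken as one point.
#' @return n x 3 matrix of continuous voxel indices. Out-of-grid points give
#'   out-of-range indices; callers decide how to treat them.
#' @export
world_to_voxel <- function(grid, points) {
  points <- as_points3(points)
  sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Convert continuous voxel indices to world coordinates
#' @param grid a [dose_grid()].
#' @param index n x 3 matrix of 0-based continuous voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(grid, index) {
  index <- as_points3(index)
  sweep(sweep(index, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Trilinear dose sampling at world points
#'
#' Samples the grid by trilinear interpolation between the eight neighbouring
#' voxel centres. Values at voxel centres are reproduced exactly; points
#' outside the voxel-centre hull are flagged outside and return `NA` (no
#' extrapolation). Samples whose interpolation stencil touches an invalid
#' voxel are flagged outside as well.
#'
#' @param grid a [dose_grid()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return list with `values` (numeric, Gy, `NA` outside) and `inside`
#'   (logical).
#' @export
trilinear_sample <- function(grid, points) {
  points <- as_points3(points)
  has_valid <- !is.null(grid$valid)
  trilinear_sample_cpp(grid$values, dim(grid$values), grid$origin,
                       grid$spacing, points,
                       if (has_valid) grid$valid else logical(0), has_valid)
}

#' Resample a dose grid through a rigid transform onto a target lattice
#'
#' The transform maps the moving grid's content forward: the output value at a
#' target voxel centre `x` is the trilinear sample of `moving` at
#' `R^-1 (x - t)`. Target voxels mapping outside the moving grid (or onto its
#' invalid voxels) are marked invalid in the companion validity mask and set
#' to 0 Gy; downstream metrics exclude them.
#'
#' @param moving a [dose_grid()] to be resampled.
#' @param transform a [rigid_transform()] (default identity).
#' @param target a [dose_grid()] or a list with `origin`, `spacing`, `dim`
#'   giving the output geometry; default the geometry of `moving`.
#' @return A [dose_grid()] with the target geometry and a validity mask.
#' @export
resample <- function(moving, transform = rigid_transform(), target = moving) {
  geom <- target_geometry(target)
  if (prod(geom$dim) == 0) stop("target geometry is empty")
  has_valid <- !is.null(moving$valid)
  res <- resample_grid_cpp(moving$values, dim(moving$values), moving$origin,
                           moving$spacing,
                           if (has_valid) moving$valid else logical(0),
                           has_valid,
                           as.integer(geom$dim), geom$origin, geom$spacing,
                           t(transform$rotation), transform$translation)
  vals <- array(res$values, geom$dim)
  vals[vals < 0] <- 0  # guard FP round-off at zero-dose voxels
  dose_grid(vals, geom$origin, geom$spacing,
            valid = array(res$valid, geom$dim))
}

target_geometry <- function(target) {
  if (inherits(target, "dose_grid"))
    list(origin = target$origin, spacing = target$spacing,
         dim = dim(target$values))
  else {
    stopifnot(is.list(target), all(c("origin", "spacing", "dim") %in% names(target)))
    list(origin = as.numeric(target$origin),
         spacing = as.numeric(target$spacing), dim = as.integer(target$dim))
  }
}

#' Translate a dose grid geometrically
#'
#' Moves the whole dose distribution by shifting the grid origin; no
#' resampling and therefore no interpolation error. Useful for constructing
#' exactly-translated evaluation grids.
#'
#' @param grid a [dose_grid()].
#' @param translation numeric length-3 displacement (mm).
#' @return A [dose_grid()] with identical values and shifted origin.
#' @export
translate_grid <- function(grid, translation) {
  dose_grid(grid$values, grid$origin + as.numeric(translation), grid$spacing,
            grid$valid)
}

#' Region-of-interest mask from world-space boxes
#'
#' Marks voxels whose centres lie inside any of the supplied axis-aligned
#' boxes, each expanded by `margin` on all faces. Containment is inclusive of
#' the box faces.
#'
#' @param grid a [dose_grid()] supplying the lattice geometry.
#' @param boxes a single 2 x 3 matrix (rows: min and max corner, mm) or a list
#'   of such matrices.
#' @param margin non-negative expansion (mm) applied to every face.
#' @return A logical array of the grid's shape (an ROI mask).
#' @export
roi_from_boxes <- function(grid, boxes, margin = 0) {
  if (is.matrix(boxes)) boxes <- list(boxes)
  stopifnot(length(boxes) >= 1, margin >= 0)
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  mask <- array(FALSE, d)
  for (b in boxes) {
    b <- as.matrix(b)
    stopifnot(identical(dim(b), c(2L, 3L)))
    inx <- ax[[1]] >= b[1, 1] - margin & ax[[1]] <= b[2, 1] + margin
    iny <- ax[[2]] >= b[1, 2] - margin & ax[[2]] <= b[2, 2] + margin
    inz <- ax[[3]] >= b[1, 3] - margin & ax[[3]] <= b[2, 3] + margin
    mask <- mask | (array(inx, d) &
                    array(rep(iny, each = d[1]), d) &
                    array(rep(inz, each = d[1] * d[2]), d))
  }
  if (!any(mask)) stop("ROI mask is empty: no voxel centre falls in the boxes")
  mask
}

#' Write a dose grid to NIfTI
#'
#' Stores the dose array as float32 with the grid geometry in the NIfTI
#' transform (diagonal spacing, origin as offset). Read back with
#' [read_dose_nifti()]; the round trip is lossless for float32 payloads.
#' Validity masks are not stored.
#'
#' @param grid a [dose_grid()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dose_nifti <- function(grid, path) {
  arr <- grid$values
  attr(arr, "pixdim") <- grid$spacing
  img <- RNifti::asNifti(arr, datatype = "float")
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dose grid from NIfTI
#'
#' @param path a NIfTI file written by [write_dose_nifti()] (or any NIfTI
#'   volume with a diagonal, positive transform).
#' @return A [dose_grid()].
#' @export
read_dose_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- diag(aff)[1:3]
  if (any(spacing <= 0) || max(abs(aff[1:3, 1:3] - diag(spacing))) > 1e-6)
    stop("only axis-aligned NIfTI volumes with positive spacing are supported")
  dose_grid(array(as.numeric(img), dim(img)[1:3]),
            origin = aff[1:3, 4], spacing = spacing)
}
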