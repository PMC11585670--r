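#' Rigid transform in the IEC 61217 frame
#'
#' A rigid-body transform (proper rotation plus translation) acting on world
#' coordinates in mm. Dose-to-readout fitting uses translation-only transforms;
#' marker-based film registration also estimates a rotation.
#'
#' @param translation numeric length-3, (dx, dy, dz) in mm.
#' @param rotation 3x3 orthonormal matrix with determinant +1 (default
#'   identity). Orthonormality is checked to 1e-9.
#' @return An object of class `rigid_transform` with elements `translation`
#'   and `rotation`.
#' @examples
#' tf <- rigid_transform(c(1, -0.5, 2))
#' apply_transform(tf, cbind(0, 0, 0))
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3, all(is.finite(translation)))
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be a proper rotation (det +1)")
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: t = (",
      paste(format(x$translation, digits = 6), collapse = ", "), ") mm",
      if (max(abs(x$rotation - diag(3))) > 1e-12) " (with rotation)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' Maps points `p` to `R p + t`.
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(transform, points) {
  points <- as_points3(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(-as.numeric(Rt %*% transform$translation), Rt)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param first,second [rigid_transform()] objects.
#' @return A single `rigid_transform` with rotation
#'   `second$rotation %*% first$rotation`.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(
    as.numeric(second$rotation %*% first$translation) + second$translation,
    second$rotation %*% first$rotation
  )
}

# coerce to an n x 3 numeric matrix
as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}
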