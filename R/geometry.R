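#' Suprathreshold pixel coordinates and intensity weights
#'
#' Every voxel with intensity strictly above the threshold contributes its
#' excess `y - theta` as a raw weight; sub-threshold voxels are excluded
#' entirely. Weights are returned normalized to sum 1 (the weights are only
#' defined up to proportionality, so normalization just fixes the
#' representation). Coordinates are 0-based voxel centers multiplied
#' componentwise by the stack's voxel spacing.
#'
#' @param stack An [image_stack()].
#' @param theta Threshold intensity.
#' @return A list with `coords` (n x 3 matrix, columns z, y, x) and
#'   `weights` (length n, positive, summing to 1).
#' @export
compute_weights <- function(stack, theta) {
  stopifnot(inherits(stack, "ImageStack"), is.finite(theta))
  idx <- which(stack$data > theta)
  if (!length(idx))
    qc_stop("no suprathreshold pixels: cell rejected (QC failure)")
  ai <- arrayInd(idx, dim(stack$data))
  coords <- sweep(ai - 1, 2, stack$spacing, `*`)
  colnames(coords) <- c("z", "y", "x")
  w <- stack$data[idx] - theta
  list(coords = coords, weights = w / sum(w))
}

#' Intensity-weighted center of mass
#'
#' `c = sum_i w_i x_i / sum_i w_i` over the suprathreshold pixel centers;
#' the estimate of the cell center under the spherical approximation.
#'
#' @param coords n x 3 coordinate matrix.
#' @param weights Positive weights (normalized internally).
#' @return Length-3 numeric center (z, y, x).
#' @export
center_of_mass <- function(coords, weights) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty coordinate set")
  if (length(weights) != nrow(coords) || any(weights < 0))
    stop("weights must be non-negative, one per coordinate row")
  w <- weights / sum(weights)
  as.numeric(colSums(coords * w))
}

#' Euclidean distances from the cell center
#'
#' Distances are computed in the (spacing-scaled) coordinate space of
#' `coords`; anisotropic voxel spacing is therefore honored automatically
#' because [compute_weights()] already applies it.
#'
#' @param coords n x 3 coordinate matrix.
#' @param center Length-3 center.
#' @return Vector of n non-negative distances.
#' @export
center_distances <- function(coords, center) {
  coords <- as.matrix(coords)
  stopifnot(length(center) == ncol(coords), all(is.finite(center)))
  sqrt(rowSums(sweep(coords, 2, center)^2))
}

#' Intensity-weighted radius of gyration
#'
#' `R_g = sqrt( sum_i w_i ||x_i - c||^2 / sum_i w_i )`: the weighted RMS
#' distance of suprathreshold pixels from the center of mass, used as the
#' cell-size normalizer for scaled distance distributions.
#'
#' @param coords n x 3 coordinate matrix.
#' @param weights Positive weights (normalized internally).
#' @param center Optional center; computed with [center_of_mass()] if NULL.
#' @return Non-negative scalar; 0 iff all mass sits at one point.
#' @export
radius_of_gyration <- function(coords, weights, center = NULL) {
  coords <- as.matrix(coords)
  w <- weights / sum(weights)
  if (is.null(center)) center <- center_of_mass(coords, w)
  d <- center_distances(coords, center)
  sqrt(sum(w * d^2))
}

#' Full per-cell geometry from a thresholded stack
#'
#' Runs [compute_weights()], [center_of_mass()], [center_distances()] and
#' [radius_of_gyration()] and bundles the results. With `planar = TRUE`
#' distances (and hence the radius of gyration) use only the in-plane (y, x)
#' components — a per-layer 2D view for comparison with the full 3D default.
#'
#' @param stack An [image_stack()].
#' @param theta Threshold intensity.
#' @param planar Logical; ignore the z-component in distances.
#' @return An object of class `CellGeometry` with fields `coords`,
#'   `weights`, `center`, `distances`, `rg`, `theta`, `n`, `planar`,
#'   `cell_id`, `group`.
#' @export
cell_geometry <- function(stack, theta, planar = FALSE) {
  cw <- compute_weights(stack, theta)
  center <- center_of_mass(cw$coords, cw$weights)
  use <- if (planar) 2:3 else 1:3
  d <- center_distances(cw$coords[, use, drop = FALSE], center[use])
  rg <- sqrt(sum(cw$weights * d^2))
  structure(list(coords = cw$coords, weights = cw$weights, center = center,
                 distances = d, rg = rg, theta = theta,
                 n = nrow(cw$coords), planar = planar,
                 cell_id = stack$cell_id, group = stack$group),
            class = "CellGeometry")
}

#' @export
print.CellGeometry <- function(x, ...) {
  cat(sprintf("CellGeometry %s [%s]: %d suprathreshold pixels (theta = %.2f)\n",
              x$cell_id, x$group, x$n, x$theta))
  cat(sprintf("  center (z,y,x) = (%.2f, %.2f, %.2f), Rg = %.3f%s\n",
              x$center[1], x$center[2], x$center[3], x$rg,
              if (x$planar) " [planar]" else ""))
  invisible(x)
}
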