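#' Weighted distance distribution of one cell
#'
#' Histograms the center distances of suprathreshold pixels with their
#' intensity weights, density-normalized (the bin densities integrate to 1).
#' With `scaled = TRUE` the distances are divided by the cell's radius of
#' gyration, removing cell size and placing every cell on a fixed common
#' grid `[0, grid_max]` so populations are comparable; weighted mass beyond
#' `grid_max` accumulates in the last bin and is reported as
#' `overflow_fraction`. Unscaled histograms span `[0, max d]` by default.
#'
#' Bins are half-open `[e_b, e_{b+1})` with the last bin closed.
#'
#' @param geometry A [cell_geometry()] result.
#' @param bins Number of bins (default 100).
#' @param scaled Divide distances by `R_g` (default TRUE).
#' @param grid_max Upper edge; defaults to 2.5 for scaled histograms and to
#'   the maximum distance for unscaled ones.
#' @return An object of class `DistanceDistribution` with fields
#'   `bin_edges` (length bins + 1), `density`, `scaled`, `cell_id`, `group`,
#'   `rg`, `theta`, `overflow_fraction`, `n_pixels`.
#' @export
distance_distribution <- function(geometry, bins = 100L, scaled = TRUE,
                                  grid_max = NULL) {
  stopifnot(inherits(geometry, "CellGeometry"), bins >= 1L)
  d <- geometry$distances
  w <- geometry$weights
  if (scaled) {
    if (!is.finite(geometry$rg) || geometry$rg <= 0)
      qc_stop("scaled distribution requested but Rg = 0 (all mass at one point)")
    d <- d / geometry$rg
    if (is.null(grid_max)) grid_max <- 2.5
  } else if (is.null(grid_max)) {
    grid_max <- max(d)
    if (grid_max <= 0)
      qc_stop("unscaled distribution undefined: all suprathreshold mass at the center")
  }
  edges <- seq(0, grid_max, length.out = bins + 1L)
  overflow <- sum(w[d > grid_max])
  d <- pmin(d, grid_max)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  agg <- rowsum(w, bin)
  mass <- numeric(bins)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  density <- mass / diff(edges)
  structure(list(bin_edges = edges, density = density, scaled = scaled,
                 cell_id = geometry$cell_id, group = geometry$group,
                 rg = geometry$rg, theta = geometry$theta,
                 overflow_fraction = overflow, n_pixels = geometry$n),
            class = "DistanceDistribution")
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  cat(sprintf("DistanceDistribution %s [%s]: %d bins on [0, %g], %s, Rg = %.3f\n",
              x$cell_id, x$group, length(x$density), max(x$bin_edges),
              if (x$scaled) "scaled (d / Rg)" else "unscaled", x$rg))
  if (x$overflow_fraction > 0)
    cat(sprintf("  overflow beyond grid: %.3f%%\n", 100 * x$overflow_fraction))
  invisible(x)
}

#' @export
plot.DistanceDistribution <- function(x, ...) {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mid, x$density, type = "s",
                 xlab = if (x$scaled) "scaled distance d / Rg" else "distance (pixels)",
                 ylab = "density",
                 main = sprintf("%s [%s]", x$cell_id, x$group), ...)
  invisible(x)
}

#' Block-mean down-sampling of a stack
#'
#' Averages `factor x factor` tiles within each z-layer (z is untouched) and
#' multiplies the in-plane voxel spacing by `factor`, so physical distances
#' are preserved. Block averaging (rather than decimation) preserves
#' integrated intensity structure. Trailing rows/columns that do not fill a
#' complete tile are dropped with a warning.
#'
#' @param stack An [image_stack()].
#' @param factor Positive integer sampling rate (2 halves each layer side).
#' @return A down-sampled [image_stack()].
#' @export
downsample <- function(stack, factor = 2L) {
  stopifnot(inherits(stack, "ImageStack"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(stack)
  d <- dim(stack$data)
  ny2 <- d[2] %/% factor
  nx2 <- d[3] %/% factor
  if (ny2 * factor != d[2] || nx2 * factor != d[3])
    warning("factor does not divide y/x dimensions; trailing rows/columns dropped")
  if (ny2 < 1L || nx2 < 1L) stop("factor larger than image")
  out <- array(0, c(d[1], ny2, nx2))
  for (a in seq_len(factor)) {
    for (b in seq_len(factor)) {
      out <- out + stack$data[, seq(a, by = factor, length.out = ny2),
                              seq(b, by = factor, length.out = nx2),
                              drop = FALSE]
    }
  }
  image_stack(out / factor^2,
              spacing = stack$spacing * c(1, factor, factor),
              cell_id = stack$cell_id, group = stack$group,
              bit_depth = "float")
}

#' Mean z-projection of thresholded excess intensity
#'
#' Per (y, x) position, the mean over z of `max(y - theta, 0)`; the standard
#' QC view of where suprathreshold signal sits in the cell footprint.
#'
#' @param stack An [image_stack()].
#' @param theta Threshold intensity.
#' @return A `ny x nx` matrix.
#' @export
zproject_mean <- function(stack, theta) {
  stopifnot(inherits(stack, "ImageStack"), is.finite(theta))
  colMeans(pmax(stack$data - theta, 0))
}

#' Histogram of suprathreshold event intensities
#'
#' By default histograms the raw intensities of suprathreshold pixels. With
#' `per_event = TRUE`, 26-connected components of the suprathreshold mask
#' are labelled as discrete events and the histogram is over each event's
#' integrated excess intensity — the granularity at which STED imaging
#' resolves structures that confocal imaging merges into single blobs.
#'
#' @param stack An [image_stack()].
#' @param theta Threshold intensity.
#' @param bins Number of equal-width bins (default 64).
#' @param per_event Histogram per connected component instead of per pixel.
#' @return An object of class `IntensityDistribution` with fields
#'   `bin_edges`, `counts`, `density`, `values`, `per_event`, `n_events`.
#' @export
intensity_distribution <- function(stack, theta, bins = 64L, per_event = FALSE) {
  stopifnot(inherits(stack, "ImageStack"), is.finite(theta), bins >= 1L)
  mask <- stack$data > theta
  if (!any(mask)) qc_stop("no suprathreshold pixels")
  if (per_event) {
    lab <- label_components(mask)
    vals <- as.vector(rowsum((stack$data - theta)[mask], lab[mask]))
  } else {
    vals <- stack$data[mask]
  }
  rng <- range(vals)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(vals, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = bins)
  structure(list(bin_edges = edges, counts = counts,
                 density = counts / (sum(counts) * diff(edges)),
                 values = vals, per_event = per_event,
                 n_events = length(vals)),
            class = "IntensityDistribution")
}

#' Label 26-connected components of a 3D mask
#'
#' Iterative minimum-label propagation over the 26-neighborhood (all voxels
#' sharing a face, edge or corner), the standard connectivity for 3D puncta.
#' 2D masks are treated as single-layer stacks (8-connectivity).
#'
#' @param mask Logical array (3D) or matrix.
#' @return Integer array of the same shape: 0 for background, 1..k for the
#'   components; the number of components is attached as attribute `n`.
#' @export
label_components <- function(mask) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  rng <- function(n, o) {
    lo <- max(1L, 1L + o); hi <- min(n, n + o)
    if (lo > hi) integer(0) else lo:hi
  }
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      dz <- rng(d[1], o[1]); dy <- rng(d[2], o[2]); dx <- rng(d[3], o[3])
      if (!length(dz) || !length(dy) || !length(dx)) next
      a <- lab[dz, dy, dx, drop = FALSE]
      b <- lab[dz - o[1], dy - o[2], dx - o[3], drop = FALSE]
      upd <- b > 0L & a > 0L & b < a
      if (any(upd)) {
        a[upd] <- b[upd]
        lab[dz, dy, dx] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  attr(lab, "n") <- length(ids)
  lab
}
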