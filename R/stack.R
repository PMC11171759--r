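#' Construct an image stack
#'
#' The unit of analysis: one single-channel 3D fluorescence z-stack for one
#' cell. Data are stored as a numeric array indexed `[z, y, x]`. Voxel indices
#' are 0-based conceptually: the pixel center of voxel `(k, j, i)` sits at the
#' point `(k, j, i)` in index space, multiplied componentwise by `spacing` for
#' physical distances. With the default isotropic spacing of 1 all distances
#' come out in pixel units.
#'
#' @param data 3D numeric array `[z, y, x]` of finite, non-negative
#'   intensities. A matrix is promoted to a single-layer stack.
#' @param spacing Physical voxel size `(dz, dy, dx)`, strictly positive.
#' @param cell_id Identifier of the cell.
#' @param group Condition label (e.g. `"WT1"`, `"MUT2"`, `"RhoAII"`).
#' @param bit_depth Bits per sample for integer data (8, 16, 32) or the
#'   string `"float"` for real-valued data.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, spacing = c(1, 1, 1), cell_id = "", group = "",
                        bit_depth = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 8L || d[3] < 8L)
    stop("stack needs at least 1 z-layer and y/x dimensions of at least 8")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  if (min(data) < 0)
    stop("intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel sizes (dz, dy, dx)")
  if (is.null(bit_depth))
    bit_depth <- if (all(data == round(data)) && max(data) <= 65535) 16L else "float"
  structure(list(data = data, spacing = spacing,
                 cell_id = as.character(cell_id), group = as.character(group),
                 bit_depth = bit_depth),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack %s [%s]: %d x %d x %d (z,y,x), spacing (%g, %g, %g), %s\n",
              x$cell_id, x$group, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              if (identical(x$bit_depth, "float")) "float"
              else paste0(x$bit_depth, "-bit")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

is_integer_data <- function(stack) {
  !identical(stack$bit_depth, "float") && all(stack$data == round(stack$data))
}
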