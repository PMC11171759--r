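#' Read a single-channel TIFF / OME-TIFF z-stack
#'
#' Multi-page TIFFs are interpreted as z-layers; a 2D image becomes a
#' single-layer stack. Voxel spacing is taken, in order of precedence, from
#' the `spacing` argument, a JSON sidecar written by [write_stack()], OME
#' `PhysicalSize{X,Y,Z}` fields in the TIFF description, or the isotropic
#' default of 1 pixel (which reproduces distance computations in pixel
#' units when no metadata is available).
#'
#' @param path TIFF file path.
#' @param spacing Optional voxel sizes `(dz, dy, dx)`; overrides metadata.
#' @param group Condition label attached to the stack.
#' @param cell_id Cell identifier; defaults to the file name without extension.
#' @param channel For multi-channel files, the 1-based channel to extract.
#'   Multi-channel (including RGB) data without an explicit channel are
#'   rejected because the quantified signal would be ambiguous.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing = NULL, group = "", cell_id = NULL,
                       channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- tiff::readTIFF(path, payload = FALSE)
  is_float <- any(info$bits.per.sample >= 32)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)

  meta <- read_sidecar(path)
  desc <- attr(pages[[1]], "description")

  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel))
        stop("multi-channel TIFF (", dim(p)[3],
             " samples per pixel): supply `channel`; RGB signal is ambiguous")
      if (channel < 1L || channel > dim(p)[3]) stop("channel out of range")
      p <- p[, , channel]
    }
    p
  })
  d2 <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]]

  if (is_float && !is.null(meta$scale)) data <- data * meta$scale

  if (is.null(spacing)) {
    spacing <- meta$spacing %||% ome_spacing(desc) %||% c(1, 1, 1)
  }
  if (is.null(cell_id))
    cell_id <- meta$cell_id %||% sub("\\.[^.]*$", "", basename(path))
  if (!nzchar(group)) group <- meta$group %||% ""

  image_stack(data, spacing = spacing, cell_id = cell_id, group = group,
              bit_depth = if (is_float) "float" else 16L)
}

#' Write an image stack as a multi-page TIFF
#'
#' Integer data are stored as 16-bit samples (lossless round trip); float
#' data as 32-bit samples rescaled into `[0, 1]` with the scale factor
#' recorded in a JSON sidecar `<path>.json` alongside voxel spacing and
#' labels, so [read_stack()] restores the stack including metadata.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the parent directory must exist.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  d <- dim(stack$data)
  scale <- NULL
  if (is_integer_data(stack)) {
    if (max(stack$data) > 65535)
      stop("integer stack exceeds 16-bit range")
    pages <- lapply(seq_len(d[1]), function(k) stack$data[k, , ] / 65535)
    bits <- 16L
  } else {
    scale <- max(stack$data)
    if (scale <= 0) scale <- 1
    pages <- lapply(seq_len(d[1]), function(k) stack$data[k, , ] / scale)
    bits <- 32L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF: ", path)
  sidecar <- list(spacing = stack$spacing, cell_id = stack$cell_id,
                  group = stack$group,
                  bit_depth = if (is.null(scale)) 16 else "float")
  if (!is.null(scale)) sidecar$scale <- scale
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  out <- try(jsonlite::read_json(sp, simplifyVector = TRUE), silent = TRUE)
  if (inherits(out, "try-error")) list() else out
}

# Pull PhysicalSizeZ/Y/X (micrometres) out of an OME-XML TIFF description.
ome_spacing <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(NULL)
  grab <- function(axis) {
    m <- regmatches(desc, regexpr(sprintf('PhysicalSize%s="([0-9.eE+-]+)"', axis),
                                  desc))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(sprintf('PhysicalSize%s="', axis), "",
                   sub('"$', "", m)))
  }
  s <- c(grab("Z"), grab("Y"), grab("X"))
  if (anyNA(s)) NULL else s
}

#' Write records as a CSV table
#'
#' Deterministic column order, header row, floating point values rendered
#' with full precision (17 significant digits) so a parse-back recovers the
#' written numbers.
#'
#' @param records A data.frame, or a list of named rows with identical names.
#' @param path Output CSV path.
#' @export
write_table <- function(records, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  if (!is.data.frame(records)) {
    if (length(records) == 0L) stop("empty record list needs a data.frame with columns for a header")
    records <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
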