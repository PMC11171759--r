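#' Local maxima of a binned density curve
#'
#' Detects strict local maxima after a centered moving-average smoothing,
#' and scores each with its topographic prominence (height above the higher
#' of the two valley floors separating it from higher terrain). Used to
#' decide whether a scaled distance distribution is unimodal (homogeneous
#' vesicle dispersion) or bimodal (separate perinuclear and
#' plasma-membrane-adjacent populations).
#'
#' @param density Numeric vector of bin densities.
#' @param edges Optional bin edges (length `length(density) + 1`); peak
#'   locations are then reported as bin centers, otherwise as bin indices.
#' @param smooth Moving-average window in bins (default 3).
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   smoothed height (default 0: keep all).
#' @return A data.frame with columns `bin`, `location`, `height`,
#'   `prominence`, ordered by location.
#' @export
find_peaks <- function(density, edges = NULL, smooth = 3L, min_prominence = 0) {
  sm <- moving_average(density, smooth)
  n <- length(sm)
  locs <- if (is.null(edges)) seq_len(n) else (edges[-1] + edges[-(n + 1)]) / 2
  idx <- which(diff(sign(diff(sm))) == -2) + 1L  # strict interior maxima
  idx <- idx[sm[idx] > 0]
  if (!length(idx))
    return(data.frame(bin = integer(0), location = numeric(0),
                      height = numeric(0), prominence = numeric(0)))
  prominence <- vapply(idx, function(i) {
    h <- sm[i]
    base_side <- function(seqs) {
      vmin <- h
      for (j in seqs) {
        if (sm[j] > h) return(vmin)
        if (sm[j] < vmin) vmin <- sm[j]
      }
      vmin
    }
    left <- base_side(rev(seq_len(i - 1L)))
    right <- base_side(if (i < n) (i + 1L):n else integer(0))
    h - max(left, right)
  }, numeric(1))
  keep <- prominence >= min_prominence * max(sm)
  data.frame(bin = idx[keep], location = locs[idx[keep]],
             height = sm[idx[keep]], prominence = prominence[keep])
}

#' Location and mass of the outer (membrane-adjacent) peak
#'
#' Finds the most prominent local maximum beyond `search_min` on the scaled
#' distance axis and integrates the density over a window of half-width
#' `halfwidth` around it. When `center` is supplied the peak search is
#' skipped and the mass is integrated around that location instead — this
#' is how a treatment group is measured in the window defined by its
#' control group's outer peak.
#'
#' @param density Bin densities.
#' @param edges Bin edges.
#' @param search_min Lower bound of the peak search (default 0.8 scaled
#'   distance units, past the main body of a homogeneous distribution).
#' @param halfwidth Integration half-width (default 0.15).
#' @param smooth,min_prominence Passed to [find_peaks()].
#' @param center Optional fixed window center.
#' @return A list with `center` (NA if no outer peak) and `mass`.
#' @export
outer_peak_mass <- function(density, edges, search_min = 0.8,
                            halfwidth = 0.15, smooth = 3L,
                            min_prominence = 0.02, center = NULL) {
  if (!is.null(center) && is.na(center))
    return(list(center = NA_real_, mass = NA_real_))
  if (is.null(center)) {
    pk <- find_peaks(density, edges, smooth = smooth,
                     min_prominence = min_prominence)
    pk <- pk[pk$location > search_min, , drop = FALSE]
    if (!nrow(pk)) return(list(center = NA_real_, mass = 0))
    center <- pk$location[which.max(pk$height)]
  }
  list(center = center,
       mass = band_mass(density, edges, center - halfwidth, center + halfwidth))
}
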