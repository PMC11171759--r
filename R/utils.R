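#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Centered moving average with shrinking end windows
#'
#' @param x Numeric vector.
#' @param window Odd window width in samples; 1 returns `x` unchanged.
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  h <- window %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Signal a quality-control failure (degenerate cell) as a typed condition so
# pipeline drivers can separate QC exclusions from programming errors.
qc_stop <- function(msg) {
  stop(structure(class = c("vesdist_qc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Integrate a piecewise-constant density over an interval
#'
#' Treats `density` as constant within each histogram bin and integrates it
#' over `[lower, upper]`, handling partial bin overlap.
#'
#' @param density Bin densities (length B).
#' @param edges Bin edges (length B + 1, strictly increasing).
#' @param lower,upper Integration limits.
#' @return The integrated probability mass.
#' @export
band_mass <- function(density, edges, lower, upper) {
  stopifnot(length(edges) == length(density) + 1L, upper >= lower)
  left <- edges[-length(edges)]
  right <- edges[-1L]
  overlap <- pmin(right, upper) - pmax(left, lower)
  sum(density * pmax(overlap, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
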