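#' Stack per-cell scaled distributions into a population summary
#'
#' All distributions must be scaled and share the identical common grid.
#' Group mean curves are unweighted means of the per-cell densities (the
#' radius-of-gyration scaling has already removed cell size, so cells count
#' equally) and are themselves density-normalized by construction.
#'
#' @param distributions List of [distance_distribution()] results (scaled).
#' @return An object of class `PopulationSummary` with fields `grid` (bin
#'   edges), `matrix` (cells x bins densities), `labels` (group per cell),
#'   `cell_ids`, `rg`, `group_n`, `mean_curves` (named list), and empty PCA
#'   fields until [pca_distributions()] is applied.
#' @export
aggregate_distributions <- function(distributions) {
  if (!length(distributions)) stop("no distributions given")
  ok <- vapply(distributions, inherits, logical(1), "DistanceDistribution")
  if (!all(ok)) stop("all inputs must be DistanceDistribution objects")
  if (!all(vapply(distributions, `[[`, logical(1), "scaled")))
    stop("population aggregation needs scaled distributions (common grid)")
  grid <- distributions[[1]]$bin_edges
  same <- vapply(distributions, function(d)
    length(d$bin_edges) == length(grid) && max(abs(d$bin_edges - grid)) < 1e-12,
    logical(1))
  if (!all(same)) stop("mixed histogram grids: resample to a common grid first")
  mat <- do.call(rbind, lapply(distributions, `[[`, "density"))
  labels <- vapply(distributions, `[[`, character(1), "group")
  cell_ids <- vapply(distributions, `[[`, character(1), "cell_id")
  rownames(mat) <- cell_ids
  groups <- unique(labels)
  mean_curves <- lapply(groups, function(g)
    colMeans(mat[labels == g, , drop = FALSE]))
  names(mean_curves) <- groups
  structure(list(grid = grid, matrix = mat, labels = labels,
                 cell_ids = cell_ids,
                 rg = vapply(distributions, `[[`, numeric(1), "rg"),
                 group_n = table(labels)[groups],
                 mean_curves = mean_curves,
                 pca_scores = NULL, pca_loadings = NULL, pca_explained = NULL),
            class = "PopulationSummary")
}

#' @export
print.PopulationSummary <- function(x, ...) {
  cat(sprintf("PopulationSummary: %d cells x %d bins on [0, %g]\n",
              nrow(x$matrix), ncol(x$matrix), max(x$grid)))
  for (g in names(x$mean_curves))
    cat(sprintf("  %s: n = %d\n", g, sum(x$labels == g)))
  if (!is.null(x$pca_explained))
    cat(sprintf("  PCA: %s\n", paste(sprintf("PC%d %.1f%%",
      seq_along(x$pca_explained), 100 * x$pca_explained), collapse = ", ")))
  invisible(x)
}

#' Principal component analysis of binned distributions
#'
#' PCA on the density rows (column-mean centered, no variance scaling: the
#' bins share units). Components come from the singular value decomposition
#' with a deterministic sign convention — each component's entry of largest
#' absolute value is positive — so scores are reproducible across runs and
#' platforms.
#'
#' @param summary A [aggregate_distributions()] result.
#' @param n_components Number of components (default 2).
#' @return The summary with `pca_scores` (cells x k), `pca_loadings`
#'   (bins x k) and `pca_explained` (variance fractions) filled in.
#' @export
pca_distributions <- function(summary, n_components = 2L) {
  stopifnot(inherits(summary, "PopulationSummary"))
  X <- summary$matrix
  if (nrow(X) < 2L) stop("PCA needs at least 2 cells")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(X)))
    stop("n_components must be in 1..min(cells, bins)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  total <- sum(Xc^2)
  if (total < 1e-24)
    stop("degenerate population: all distributions identical, variance undefined")
  sv <- svd(Xc, nu = n_components, nv = n_components)
  V <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(scores) <- summary$cell_ids
  colnames(scores) <- paste0("PC", seq_len(n_components))
  colnames(V) <- colnames(scores)
  summary$pca_scores <- scores
  summary$pca_loadings <- V
  summary$pca_explained <- (sv$d[seq_len(n_components)]^2) / total
  summary
}

#' Membrane-adjacent mass of a scaled distance distribution
#'
#' The integrated density mass at scaled distances beyond `cutoff`. With the
#' default cutoff of 1 this is the weight sitting beyond the radius of
#' gyration — a per-cell statistic of the plasma-membrane-arrested vesicle
#' population that is elevated in the bimodal phenotype.
#'
#' @param distribution A scaled [distance_distribution()].
#' @param cutoff Scaled distance cutoff, inside the histogram grid.
#' @return A fraction in `[0, 1]`, monotone non-increasing in `cutoff`.
#' @export
membrane_fraction <- function(distribution, cutoff = 1.0) {
  stopifnot(inherits(distribution, "DistanceDistribution"))
  if (!distribution$scaled)
    stop("membrane_fraction is defined on scaled distributions")
  edges <- distribution$bin_edges
  if (cutoff < edges[1] || cutoff > edges[length(edges)])
    stop("cutoff outside the histogram grid")
  band_mass(distribution$density, edges, cutoff, edges[length(edges)])
}

# membrane fraction for one density row of a population matrix
row_membrane_fraction <- function(density, edges, cutoff) {
  band_mass(density, edges, cutoff, edges[length(edges)])
}

#' Descriptive comparison of two groups
#'
#' Emits the two group mean curves, their difference curve (`group_b` minus
#' `group_a`), per-group membrane fractions (mean +/- SEM), PC1 score
#' summaries when PCA has been run, and the outer-peak mass of both groups
#' measured in the window defined by `group_a`'s outer peak. Purely
#' descriptive: no hypothesis test is performed or implied.
#'
#' @param summary A [aggregate_distributions()] (optionally after
#'   [pca_distributions()]).
#' @param group_a,group_b Group labels present in the summary (>= 2 cells
#'   each). `group_a` is the reference (e.g. vehicle) group.
#' @param cutoff Membrane-fraction cutoff (default 1.0).
#' @param peak_search_min,peak_halfwidth Passed to [outer_peak_mass()].
#' @return An object of class `GroupComparison`.
#' @export
compare_groups <- function(summary, group_a, group_b, cutoff = 1.0,
                           peak_search_min = 0.8, peak_halfwidth = 0.15) {
  stopifnot(inherits(summary, "PopulationSummary"))
  for (g in c(group_a, group_b)) {
    if (!g %in% summary$labels) stop("unknown group label: ", g)
    if (sum(summary$labels == g) < 2L) stop("group ", g, " has fewer than 2 cells")
  }
  edges <- summary$grid
  mean_a <- summary$mean_curves[[group_a]]
  mean_b <- summary$mean_curves[[group_b]]
  mf <- function(g) {
    rows <- summary$matrix[summary$labels == g, , drop = FALSE]
    apply(rows, 1, row_membrane_fraction, edges = edges, cutoff = cutoff)
  }
  mfa <- mf(group_a); mfb <- mf(group_b)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  peak_a <- outer_peak_mass(mean_a, edges, search_min = peak_search_min,
                            halfwidth = peak_halfwidth)
  peak_b <- outer_peak_mass(mean_b, edges, center = peak_a$center,
                            halfwidth = peak_halfwidth)
  pc1 <- NULL
  if (!is.null(summary$pca_scores)) {
    s1 <- summary$pca_scores[, 1]
    pc1 <- list(a = c(mean = mean(s1[summary$labels == group_a]),
                      sem = sem(s1[summary$labels == group_a])),
                b = c(mean = mean(s1[summary$labels == group_b]),
                      sem = sem(s1[summary$labels == group_b])))
  }
  structure(list(group_a = group_a, group_b = group_b, grid = edges,
                 mean_a = mean_a, mean_b = mean_b,
                 difference = mean_b - mean_a,
                 membrane_fraction = list(
                   a = c(mean = mean(mfa), sem = sem(mfa), n = length(mfa)),
                   b = c(mean = mean(mfb), sem = sem(mfb), n = length(mfb)),
                   cutoff = cutoff, per_cell_a = mfa, per_cell_b = mfb),
                 outer_peak = list(center = peak_a$center,
                                   mass_a = peak_a$mass, mass_b = peak_b$mass,
                                   halfwidth = peak_halfwidth),
                 pc1 = pc1),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  m <- x$membrane_fraction
  cat(sprintf("GroupComparison: %s (n = %d) vs %s (n = %d)\n",
              x$group_a, m$a[["n"]], x$group_b, m$b[["n"]]))
  cat(sprintf("  membrane fraction (s > %g): %.3f +/- %.3f vs %.3f +/- %.3f\n",
              m$cutoff, m$a[["mean"]], m$a[["sem"]], m$b[["mean"]], m$b[["sem"]]))
  if (!is.na(x$outer_peak$center))
    cat(sprintf("  outer peak at s = %.2f: mass %.3f vs %.3f\n",
                x$outer_peak$center, x$outer_peak$mass_a, x$outer_peak$mass_b))
  if (!is.null(x$pc1))
    cat(sprintf("  PC1: %.3f +/- %.3f vs %.3f +/- %.3f\n",
                x$pc1$a[["mean"]], x$pc1$a[["sem"]],
                x$pc1$b[["mean"]], x$pc1$b[["sem"]]))
  invisible(x)
}

#' Overlay group mean curves
#'
#' @param summary A [aggregate_distributions()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_mean_curves <- function(summary, ...) {
  stopifnot(inherits(summary, "PopulationSummary"))
  mid <- (summary$grid[-1] + summary$grid[-length(summary$grid)]) / 2
  curves <- do.call(cbind, summary$mean_curves)
  graphics::matplot(mid, curves, type = "l", lty = 1,
                    xlab = "scaled distance d / Rg", ylab = "density", ...)
  graphics::legend("topright", legend = names(summary$mean_curves),
                   lty = 1, col = seq_along(summary$mean_curves), bty = "n")
  invisible(summary)
}
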