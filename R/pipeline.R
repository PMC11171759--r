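#' Pipeline configuration
#'
#' Bundles the adjustable parameters of the analysis pipeline. Defaults
#' mirror the confocal workflow: Gaussian-mode background fitting with
#' `n_sigma = 10`, a sampling rate of 2 for in-plane down-sampling, and
#' scaled histograms of 100 bins on `[0, 2.5]`. Set
#' `threshold_mode = "global_mean_std"` and `n_sigma = 1` for the STED
#' convention.
#'
#' @param ... Overrides of the default fields: `n_sigma`, `threshold_mode`
#'   (`"gaussian_mode"` or `"global_mean_std"`), `downsample_factor`,
#'   `bins`, `grid_max`, `histogram_bins`, `spacing` (NULL = from stack
#'   metadata), `cutoff`, `pca_components`, `seed`.
#' @return A named list of class `vesdist_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(n_sigma = 10, threshold_mode = "gaussian_mode",
              downsample_factor = 2L, bins = 100L, grid_max = 2.5,
              histogram_bins = 256L, spacing = NULL, cutoff = 1.0,
              pca_components = 2L, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!cfg$threshold_mode %in% c("gaussian_mode", "global_mean_std"))
    stop("threshold_mode must be 'gaussian_mode' or 'global_mean_std'")
  stopifnot(cfg$n_sigma >= 0, cfg$downsample_factor >= 1, cfg$bins >= 1,
            cfg$grid_max > 0, cfg$cutoff >= 0)
  class(cfg) <- "vesdist_config"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file; top-level keys override [pipeline_config()]
#'   defaults.
#' @return A `vesdist_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  groups <- raw$groups
  raw$groups <- NULL
  cfg <- do.call(pipeline_config, raw)
  attr(cfg, "groups") <- groups
  cfg
}

#' Simulate a synthetic dataset on disk
#'
#' Generates one population per group description, writes every stack as a
#' 16-bit TIFF with its metadata sidecar, the per-cell ground truth as CSV,
#' a manifest (`path`, `cell_id`, `group`) and a JSON record of all
#' parameters and seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param groups List of group descriptions; each a list with `name`,
#'   `n_cells`, and optional [synthetic_cell_spec()] field overrides
#'   (e.g. `spatial_model`, `membrane_weight`).
#' @param spec Template [synthetic_cell_spec()].
#' @param jitter Relative cell-size variation (default 0.2).
#' @param seed Master seed; group and cell seeds are derived from it.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(out_dir, groups, spec = synthetic_cell_spec(),
                         jitter = 0.2, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(groups)))
  manifest <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    stopifnot(!is.null(g$name), !is.null(g$n_cells))
    overrides <- g[setdiff(names(g), c("name", "n_cells"))]
    spec_fields <- spec[setdiff(names(spec), "dz")]
    spec_fields[names(overrides)] <- overrides
    spec_g <- do.call(synthetic_cell_spec, spec_fields)
    cells <- generate_population(spec_g, n_cells = g$n_cells, jitter = jitter,
                                 group = g$name, seed = gseeds[gi])
    for (cell in cells) {
      path <- file.path(out_dir, paste0(cell$stack$cell_id, ".tif"))
      write_stack(cell$stack, path)
      write_table(cell$ground_truth,
                  file.path(out_dir, paste0(cell$stack$cell_id, "_truth.csv")))
      manifest[[length(manifest) + 1L]] <-
        data.frame(path = path, cell_id = cell$stack$cell_id, group = g$name,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  write_table(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(
    list(seed = seed, jitter = jitter,
         groups = lapply(groups, function(g) g[c("name", "n_cells")]),
         spec = unclass(spec), version = as.character(utils::packageVersion("vesdist"))),
    file.path(out_dir, "simulate.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

analyze_one <- function(stack, config) {
  if (config$downsample_factor > 1L)
    stack <- downsample(stack, config$downsample_factor)
  if (config$threshold_mode == "gaussian_mode") {
    model <- background_model(stack, n_sigma = config$n_sigma,
                              histogram_bins = config$histogram_bins)
    theta <- model$theta
  } else {
    theta <- sted_threshold(stack, n_sigma = config$n_sigma)
    model <- list(mu = NA_real_, sigma = NA_real_, n_sigma = config$n_sigma,
                  theta = theta,
                  background_fraction = background_fraction(stack, theta))
  }
  geom <- cell_geometry(stack, theta)
  scaled <- distance_distribution(geom, bins = config$bins, scaled = TRUE,
                                  grid_max = config$grid_max)
  raw <- distance_distribution(geom, bins = config$bins, scaled = FALSE)
  list(stack = stack, model = model, geometry = geom,
       scaled = scaled, raw = raw)
}

hist_table <- function(dist) {
  data.frame(bin_left = dist$bin_edges[-length(dist$bin_edges)],
             bin_right = dist$bin_edges[-1],
             density = dist$density)
}

#' Analyze every stack in a manifest
#'
#' Per cell: background fit (or global mean/std threshold), optional
#' in-plane down-sampling, suprathreshold geometry, raw and scaled weighted
#' distance histograms, and a z-projection QC image. Cells failing QC (no
#' suprathreshold pixels, `Rg = 0`) or unreadable files are listed with
#' reasons in `exclusions.csv` and never silently dropped.
#'
#' @param manifest Data.frame with columns `path`, `cell_id`, `group`, or
#'   the path of a manifest CSV.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `results` (per-cell analyses), `geometry`
#'   (data.frame), `exclusions` (data.frame).
#' @export
run_analyze <- function(manifest, out_dir, config = pipeline_config()) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "cell_id", "group") %in% names(manifest)))
  if (anyDuplicated(manifest$cell_id)) stop("manifest cell_id values must be unique")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geometry_rows <- list(); exclusions <- list(); results <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- read_stack(row$path, spacing = config$spacing,
                          group = row$group, cell_id = row$cell_id)
      analyze_one(stack, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(cell_id = row$cell_id, group = row$group,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    id <- row$cell_id
    jsonlite::write_json(
      res$model[c("mu", "sigma", "n_sigma", "theta", "background_fraction")],
      file.path(out_dir, paste0(id, "_background.json")),
      auto_unbox = TRUE, digits = NA)
    for (kind in c("scaled", "raw")) {
      dist <- res[[kind]]
      write_table(hist_table(dist),
                  file.path(out_dir, sprintf("%s_hist_%s.csv", id, kind)))
      jsonlite::write_json(
        list(cell_id = dist$cell_id, group = dist$group, rg = dist$rg,
             theta = dist$theta, scaled = dist$scaled,
             overflow_fraction = dist$overflow_fraction,
             n_pixels = dist$n_pixels),
        file.path(out_dir, sprintf("%s_hist_%s.json", id, kind)),
        auto_unbox = TRUE, digits = NA)
    }
    zp <- zproject_mean(res$stack, res$model$theta)
    write_stack(image_stack(array(zp, c(1L, dim(zp))),
                            spacing = res$stack$spacing,
                            cell_id = paste0(id, "_zproj"), group = row$group),
                file.path(out_dir, paste0(id, "_zproj.tif")))
    g <- res$geometry
    geometry_rows[[length(geometry_rows) + 1L]] <-
      data.frame(cell_id = id, group = row$group, theta = g$theta,
                 n_suprathreshold = g$n, c_z = g$center[1], c_y = g$center[2],
                 c_x = g$center[3], rg = g$rg, stringsAsFactors = FALSE)
    results[[id]] <- res
  }
  geometry <- if (length(geometry_rows)) do.call(rbind, geometry_rows) else
    data.frame(cell_id = character(0), group = character(0), theta = numeric(0),
               n_suprathreshold = integer(0), c_z = numeric(0), c_y = numeric(0),
               c_x = numeric(0), rg = numeric(0))
  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(cell_id = character(0), group = character(0), reason = character(0))
  write_table(geometry, file.path(out_dir, "geometry.csv"))
  write_table(excl, file.path(out_dir, "exclusions.csv"))
  jsonlite::write_json(c(unclass(config)[!vapply(config, is.null, logical(1))],
                         list(n_analyzed = nrow(geometry), n_excluded = nrow(excl),
                              version = as.character(utils::packageVersion("vesdist")))),
                       file.path(out_dir, "analyze.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(geometry) == 0L) stop("all cells failed analysis")
  invisible(list(results = results, geometry = geometry, exclusions = excl))
}

read_distribution <- function(dir, cell_id, kind = "scaled") {
  tab <- utils::read.csv(file.path(dir, sprintf("%s_hist_%s.csv", cell_id, kind)))
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_hist_%s.json", cell_id, kind)),
                              simplifyVector = TRUE)
  structure(list(bin_edges = c(tab$bin_left, tab$bin_right[nrow(tab)]),
                 density = tab$density, scaled = meta$scaled,
                 cell_id = meta$cell_id, group = meta$group, rg = meta$rg,
                 theta = meta$theta, overflow_fraction = meta$overflow_fraction,
                 n_pixels = meta$n_pixels),
            class = "DistanceDistribution")
}

#' Group-level population report
#'
#' Reads the per-cell scaled histograms written by [run_analyze()],
#' aggregates them, runs PCA, and writes: `population.csv` (cell_id, group,
#' rg, membrane_fraction, PC scores), one mean-curve CSV per group, and a
#' JSON report with parameters and software version.
#'
#' @param analyze_dir Directory produced by [run_analyze()].
#' @param out_dir Output directory (defaults to `analyze_dir`).
#' @param config A [pipeline_config()].
#' @return The [aggregate_distributions()] summary (with PCA), invisibly.
#' @export
run_population <- function(analyze_dir, out_dir = analyze_dir,
                           config = pipeline_config()) {
  geometry <- utils::read.csv(file.path(analyze_dir, "geometry.csv"),
                              stringsAsFactors = FALSE)
  if (nrow(geometry) < 2L) stop("population summary needs at least 2 analyzed cells")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dists <- lapply(geometry$cell_id, function(id)
    read_distribution(analyze_dir, id, "scaled"))
  summary <- aggregate_distributions(dists)
  summary <- pca_distributions(summary,
                               min(config$pca_components, nrow(summary$matrix)))
  mf <- apply(summary$matrix, 1, row_membrane_fraction,
              edges = summary$grid, cutoff = config$cutoff)
  pop <- data.frame(cell_id = summary$cell_ids, group = summary$labels,
                    rg = summary$rg, membrane_fraction = mf,
                    stringsAsFactors = FALSE)
  pop <- cbind(pop, as.data.frame(summary$pca_scores))
  write_table(pop, file.path(out_dir, "population.csv"))
  for (g in names(summary$mean_curves)) {
    write_table(data.frame(bin_left = summary$grid[-length(summary$grid)],
                           bin_right = summary$grid[-1],
                           density = summary$mean_curves[[g]]),
                file.path(out_dir, sprintf("mean_curve_%s.csv", g)))
  }
  groups <- names(summary$mean_curves)
  jsonlite::write_json(
    list(groups = as.list(table(summary$labels)[groups]),
         cutoff = config$cutoff,
         membrane_fraction_mean = as.list(tapply(mf, summary$labels, mean)[groups]),
         pca_explained = summary$pca_explained,
         parameters = unclass(config)[!vapply(config, is.null, logical(1))],
         version = as.character(utils::packageVersion("vesdist"))),
    file.path(out_dir, "population.json"), auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
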