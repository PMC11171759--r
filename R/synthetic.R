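#' Specification of a synthetic single-cell z-stack
#'
#' Describes one simulated cell: an approximately spherical cell body,
#' squashed along the optical axis as adherent cells are, containing
#' diffraction-blurred fluorescent vesicles over a Gaussian camera
#' background. Three spatial models emulate the phenotypes of interest:
#'
#' * `uniform_ball` — vesicles uniform in the (squashed) cell volume: the
#'   homogeneous, WT-like disposition.
#' * `bimodal` — a mixture: with probability `membrane_weight` a vesicle is
#'   placed on the membrane shell, otherwise in a truncated-Gaussian
#'   perinuclear core. `membrane_weight = 0.5` emulates the mutant
#'   (membrane-arrested) phenotype, `0.1` a rescued intermediate, and `0`
#'   degenerates to the pure perinuclear core.
#' * `shell` — all vesicles on the membrane shell.
#'
#' The z direction is sampled coarsely, like a real confocal stack: the
#' generator picks a z-step `dz = 2 * axial_squash * cell_radius /
#' (0.9 * (nz - 1))` so the squashed cell spans 90% of the z range, and
#' records `(dz, 1, 1)` as the stack's voxel spacing. Geometry computations
#' honor that spacing, so distances live in the physically squashed frame.
#' Single-layer shapes (`nz = 1`) switch to a 2D in-plane model (a STED-like
#' ROI section).
#'
#' Membrane placement samples the direction uniformly on the unit sphere
#' *before* the axial squash, which concentrates membrane vesicles at the
#' lateral cell rim — where plasma-membrane-arrested endosomes appear in
#' z-projections — rather than on the flat top/bottom faces.
#'
#' Vesicles have a finite size: each is rendered as a separable
#' voxel-integrated Gaussian of width `sqrt(psf_sigma^2 + vesicle_sigma^2)`
#' (object size convolved with the microscope PSF), scaled so a perfectly
#' centered vesicle attains `vesicle_amplitude` (times a lognormal
#' per-vesicle jitter with unit mean) above background at its peak voxel.
#'
#' @param shape Stack dimensions (z, y, x); default `c(16, 256, 256)`.
#' @param cell_radius In-plane cell radius in pixels (default 80).
#' @param axial_squash Ratio of the axial to the in-plane semi-axis.
#'   The default of 1 is the spherical cell of the modelling approach
#'   itself (and the isotropic limit where closed-form ball/shell results
#'   apply); values below 1 emulate flattened adherent geometries.
#' @param n_vesicles Number of vesicles (default 150).
#' @param spatial_model One of `"uniform_ball"`, `"bimodal"`, `"shell"`.
#' @param membrane_weight Fraction of vesicles on the membrane shell for the
#'   bimodal model; defaults to 0.5 for `"bimodal"` and 0 otherwise.
#' @param shell_thickness Radial thickness of the membrane shell in pixels
#'   (default 4).
#' @param perinuclear_radius Gaussian scale of the perinuclear core
#'   (default `0.35 * cell_radius`).
#' @param psf_sigma PSF sigma in pixels: 2.5 confocal-like (default),
#'   0.6 STED-like.
#' @param vesicle_sigma Intrinsic vesicle size (Gaussian sigma, pixels);
#'   default 3.5, i.e. roughly a 0.8 um FWHM endosome at 0.1 um sampling.
#'   Vesicles are resolved-size objects — which is exactly why a STED-scale
#'   PSF separates neighbors that a confocal PSF merges.
#' @param vesicle_amplitude Mean peak intensity above background; default
#'   `60 * background_sigma`, bright puncta well clear of the conservative
#'   10-sigma threshold yet far from 16-bit saturation.
#' @param amplitude_jitter Lognormal sdlog of the per-vesicle amplitude
#'   (default 0.3).
#' @param background_mu,background_sigma Gaussian camera background
#'   parameters (defaults 1861.63 and 147.70).
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return An object of class `SyntheticCellSpec`.
#' @export
synthetic_cell_spec <- function(shape = c(16L, 256L, 256L),
                                cell_radius = 80,
                                axial_squash = 1,
                                n_vesicles = 150L,
                                spatial_model = c("uniform_ball", "bimodal", "shell"),
                                membrane_weight = NULL,
                                shell_thickness = 4,
                                perinuclear_radius = 0.35 * cell_radius,
                                psf_sigma = 2.5,
                                vesicle_sigma = 3.5,
                                vesicle_amplitude = 60 * background_sigma,
                                amplitude_jitter = 0.3,
                                background_mu = 1861.63,
                                background_sigma = 147.70,
                                seed = 1L) {
  spatial_model <- match.arg(spatial_model)
  if (is.null(membrane_weight))
    membrane_weight <- if (spatial_model == "bimodal") 0.5 else 0
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            cell_radius > 0, axial_squash > 0, axial_squash <= 1,
            n_vesicles >= 1L, membrane_weight >= 0, membrane_weight <= 1,
            shell_thickness > 0, perinuclear_radius > 0,
            psf_sigma > 0, vesicle_sigma >= 0, vesicle_amplitude > 0,
            amplitude_jitter >= 0, background_sigma > 0)
  if (cell_radius > (min(shape[2:3]) - 1) / 2)
    stop("cell does not fit inside the stack bounds in y/x")
  dz <- if (shape[1] > 1L)
    max(1, 2 * axial_squash * cell_radius / (0.9 * (shape[1] - 1))) else 1
  structure(list(shape = shape, cell_radius = cell_radius,
                 axial_squash = axial_squash, n_vesicles = as.integer(n_vesicles),
                 spatial_model = spatial_model, membrane_weight = membrane_weight,
                 shell_thickness = shell_thickness,
                 perinuclear_radius = perinuclear_radius,
                 psf_sigma = psf_sigma, vesicle_sigma = vesicle_sigma,
                 vesicle_amplitude = vesicle_amplitude,
                 amplitude_jitter = amplitude_jitter,
                 background_mu = background_mu,
                 background_sigma = background_sigma,
                 dz = dz, seed = as.integer(seed)),
            class = "SyntheticCellSpec")
}

# Sample vesicle positions in centered physical coordinates (z, y, x).
# 3D models sample the isotropic construction first, then squash z.
sample_positions <- function(spec) {
  n <- spec$n_vesicles
  R <- spec$cell_radius
  is2d <- spec$shape[1] == 1L
  unit_dir <- function(m, dims) {
    v <- matrix(stats::rnorm(m * dims), m, dims)
    v / sqrt(rowSums(v^2))
  }
  ball <- function(m) {
    if (is2d) {
      u <- unit_dir(m, 2L)
      r <- R * sqrt(stats::runif(m))
      cbind(0, r * u)
    } else {
      u <- unit_dir(m, 3L)
      r <- R * stats::runif(m)^(1 / 3)
      r * u
    }
  }
  shell <- function(m) {
    u <- unit_dir(m, if (is2d) 2L else 3L)
    r <- stats::runif(m, R - spec$shell_thickness, R)
    if (is2d) cbind(0, r * u) else r * u
  }
  core <- function(m) {
    dims <- if (is2d) 2L else 3L
    out <- matrix(0, m, dims)
    todo <- seq_len(m)
    for (it in 1:200) {
      if (!length(todo)) break
      cand <- matrix(stats::rnorm(length(todo) * dims, 0, spec$perinuclear_radius),
                     length(todo), dims)
      ok <- sqrt(rowSums(cand^2)) <= R
      out[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    if (is2d) cbind(0, out) else out
  }
  pos <- switch(spec$spatial_model,
    uniform_ball = list(xyz = ball(n), component = rep("ball", n)),
    shell = list(xyz = shell(n), component = rep("shell", n)),
    bimodal = {
      on_shell <- stats::runif(n) < spec$membrane_weight
      xyz <- matrix(0, n, 3L)
      if (any(on_shell)) xyz[on_shell, ] <- shell(sum(on_shell))
      if (any(!on_shell)) xyz[!on_shell, ] <- core(sum(!on_shell))
      list(xyz = xyz, component = ifelse(on_shell, "shell", "core"))
    })
  pos$xyz[, 1] <- pos$xyz[, 1] * spec$axial_squash
  colnames(pos$xyz) <- c("z", "y", "x")
  pos
}

#' Generate one synthetic cell stack with ground truth
#'
#' Samples vesicle positions per the spec's spatial model, renders each as a
#' voxel-integrated Gaussian spot, adds Gaussian camera background, clips at
#' zero and quantizes to 16 bits. Fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param cell_id,group Labels attached to the stack.
#' @return A list with `stack` (an [image_stack()]), `ground_truth`
#'   (data.frame with 0-based index-space vesicle centers `z`, `y`, `x`,
#'   the generating `component`, and the peak `amplitude`), and `spec`.
#' @export
generate_cell <- function(spec, cell_id = "cell", group = "synthetic") {
  stopifnot(inherits(spec, "SyntheticCellSpec"))
  with_seed(spec$seed, {
    d <- spec$shape
    dz <- spec$dz
    pos <- sample_positions(spec)
    n <- spec$n_vesicles
    amp <- spec$vesicle_amplitude *
      exp(stats::rnorm(n, 0, spec$amplitude_jitter) - spec$amplitude_jitter^2 / 2)

    data <- array(stats::rnorm(prod(d), spec$background_mu, spec$background_sigma), d)

    sig <- sqrt(spec$psf_sigma^2 + spec$vesicle_sigma^2)
    sig_idx <- c(sig / dz, sig, sig)              # per-axis sigma in index units
    f0 <- prod(stats::pnorm(0.5 / sig_idx) - stats::pnorm(-0.5 / sig_idx))
    ctr0 <- (d - 1) / 2                           # 0-based stack center
    centers <- sweep(pos$xyz, 2, c(dz, 1, 1), `/`)  # physical -> index offsets
    centers <- sweep(centers, 2, ctr0, `+`)

    axis_mass <- function(c_idx, sigma, nmax) {
      lo <- max(0L, floor(c_idx - 4 * sigma - 1))
      hi <- min(nmax - 1L, ceiling(c_idx + 4 * sigma + 1))
      if (lo > hi) return(NULL)
      k <- lo:hi
      list(idx = k + 1L,
           mass = stats::pnorm((k + 0.5 - c_idx) / sigma) -
                  stats::pnorm((k - 0.5 - c_idx) / sigma))
    }
    for (v in seq_len(n)) {
      mz <- axis_mass(centers[v, 1], sig_idx[1], d[1])
      my <- axis_mass(centers[v, 2], sig_idx[2], d[2])
      mx <- axis_mass(centers[v, 3], sig_idx[3], d[3])
      if (is.null(mz) || is.null(my) || is.null(mx)) next
      spot <- (amp[v] / f0) * ((mz$mass %o% my$mass) %o% mx$mass)
      data[mz$idx, my$idx, mx$idx] <-
        data[mz$idx, my$idx, mx$idx, drop = FALSE] + spot
    }
    data <- round(pmin(pmax(data, 0), 65535))
    stack <- image_stack(data, spacing = c(dz, 1, 1), cell_id = cell_id,
                         group = group, bit_depth = 16L)
    ground_truth <- data.frame(cell_id = cell_id,
                               z = centers[, 1], y = centers[, 2],
                               x = centers[, 3],
                               component = pos$component, amplitude = amp,
                               stringsAsFactors = FALSE)
    list(stack = stack, ground_truth = ground_truth, spec = spec)
  })
}

#' Generate a population of synthetic cells
#'
#' Cell radius and vesicle count are perturbed uniformly within
#' `+/- jitter` (relative), emulating the cell-size variation that
#' motivates the radius-of-gyration scaling; the perinuclear core scales
#' with the radius. Per-cell seeds are derived deterministically from the
#' population seed.
#'
#' @param spec Template [synthetic_cell_spec()].
#' @param n_cells Number of cells (>= 1).
#' @param jitter Relative variation of `cell_radius` and `n_vesicles`,
#'   in `[0, 0.5)` (default 0.2).
#' @param group Group label applied to every cell.
#' @param seed Population seed.
#' @return A list of `generate_cell()` results.
#' @export
generate_population <- function(spec, n_cells, jitter = 0.2,
                                group = "synthetic", seed = 1L) {
  stopifnot(inherits(spec, "SyntheticCellSpec"), n_cells >= 1L)
  if (jitter < 0 || jitter >= 0.5) stop("jitter must be in [0, 0.5)")
  pars <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_cells),
    rf = stats::runif(n_cells, 1 - jitter, 1 + jitter),
    vf = stats::runif(n_cells, 1 - jitter, 1 + jitter)))
  lapply(seq_len(n_cells), function(i) {
    spec_i <- synthetic_cell_spec(
      shape = spec$shape,
      cell_radius = spec$cell_radius * pars$rf[i],
      axial_squash = spec$axial_squash,
      n_vesicles = max(1L, as.integer(round(spec$n_vesicles * pars$vf[i]))),
      spatial_model = spec$spatial_model,
      membrane_weight = spec$membrane_weight,
      shell_thickness = spec$shell_thickness,
      perinuclear_radius = spec$perinuclear_radius * pars$rf[i],
      psf_sigma = spec$psf_sigma,
      vesicle_sigma = spec$vesicle_sigma,
      vesicle_amplitude = spec$vesicle_amplitude,
      amplitude_jitter = spec$amplitude_jitter,
      background_mu = spec$background_mu,
      background_sigma = spec$background_sigma,
      seed = pars$seeds[i])
    generate_cell(spec_i, cell_id = sprintf("%s_%03d", group, i), group = group)
  })
}

#' Noise-free geometric phantom stacks
#'
#' Analytic validation objects: a uniform (squashed) ball or a thin shell of
#' constant intensity `value` over a constant `background`, with no noise or
#' blur. In the isotropic limit these have closed-form second moments
#' (`Rg = R * sqrt(3/5)` for the solid ball, `Rg = R` for the thin shell),
#' which anchors the geometry tests.
#'
#' @param shape Stack dimensions (z, y, x).
#' @param radius Object radius in physical units.
#' @param model `"ball"` (solid) or `"shell"` (thin).
#' @param thickness Shell thickness (default 1).
#' @param axial_squash Axial semi-axis ratio (default 1, isotropic).
#' @param spacing Voxel spacing (dz, dy, dx).
#' @param value Intensity inside the object (default 2).
#' @param background Intensity outside (default 0).
#' @return An [image_stack()]; threshold at `background + value / 2` to get
#'   equal weights on every interior voxel.
#' @export
phantom_stack <- function(shape, radius, model = c("ball", "shell"),
                          thickness = 1, axial_squash = 1,
                          spacing = c(1, 1, 1), value = 2, background = 0) {
  model <- match.arg(model)
  shape <- as.integer(shape)
  ctr <- (shape - 1) / 2 * spacing
  az <- (((seq_len(shape[1]) - 1) * spacing[1] - ctr[1]) / axial_squash)^2
  ay <- ((seq_len(shape[2]) - 1) * spacing[2] - ctr[2])^2
  ax <- ((seq_len(shape[3]) - 1) * spacing[3] - ctr[3])^2
  rho <- sqrt(outer(outer(az, ay, `+`), ax, `+`))
  inside <- if (model == "ball") rho <= radius
            else rho <= radius & rho > radius - thickness
  image_stack(background + value * inside, spacing = spacing,
              cell_id = paste0("phantom_", model), group = "phantom",
              bit_depth = "float")
}
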