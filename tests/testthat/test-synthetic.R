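small_spec <- function(...) {
  synthetic_cell_spec(shape = c(8L, 96L, 96L), cell_radius = 30,
                      n_vesicles = 60, ...)
}

test_that("generation is bit-identical for a fixed seed", {
  a <- generate_cell(small_spec(seed = 41))
  b <- generate_cell(small_spec(seed = 41))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_cell(small_spec(seed = 42))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("bimodal mixture limits degenerate to core / shell models", {
  w0 <- generate_cell(small_spec(spatial_model = "bimodal",
                                 membrane_weight = 0, seed = 43))
  expect_true(all(w0$ground_truth$component == "core"))
  w1 <- generate_cell(small_spec(spatial_model = "bimodal",
                                 membrane_weight = 1, seed = 43))
  expect_true(all(w1$ground_truth$component == "shell"))
  ball <- generate_cell(small_spec(seed = 43))
  expect_true(all(ball$ground_truth$component == "ball"))
})

test_that("shell assignment tracks membrane_weight within binomial error", {
  n <- 400
  spec <- synthetic_cell_spec(shape = c(8L, 96L, 96L), cell_radius = 30,
                              n_vesicles = n, spatial_model = "bimodal",
                              membrane_weight = 0.5, seed = 44)
  gt <- generate_cell(spec)$ground_truth
  frac <- mean(gt$component == "shell")
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("vesicles stay inside the cell and the stack bounds", {
  cell <- generate_cell(small_spec(spatial_model = "bimodal", seed = 45))
  gt <- cell$ground_truth
  d <- dim(cell$stack$data)
  expect_true(all(gt$z >= 0 & gt$z <= d[1] - 1))
  expect_true(all(gt$y >= 0 & gt$y <= d[2] - 1))
  expect_true(all(gt$x >= 0 & gt$x <= d[3] - 1))
  # physical radial position within the cell radius (plus shell thickness slack)
  sp <- cell$stack$spacing
  ctr <- (d - 1) / 2
  r <- sqrt(((gt$z - ctr[1]) * sp[1])^2 + (gt$y - ctr[2])^2 + (gt$x - ctr[3])^2)
  expect_true(all(r <= cell$spec$cell_radius + 1e-9))
})

test_that("default stacks sit in the reported background regime", {
  for (seed in 46:47) {
    cell <- generate_cell(synthetic_cell_spec(seed = seed))
    bm <- background_model(cell$stack, n_sigma = 10)
    expect_gte(bm$background_fraction, 0.85)
    expect_lte(bm$background_fraction, 0.99)
  }
})

test_that("population jitter perturbs geometry; jitter 0 keeps it fixed", {
  spec <- small_spec()
  fixed <- generate_population(spec, 3, jitter = 0, seed = 48)
  radii <- vapply(fixed, function(c) c$spec$cell_radius, numeric(1))
  expect_true(all(radii == spec$cell_radius))
  expect_false(identical(fixed[[1]]$stack$data, fixed[[2]]$stack$data))

  jit <- generate_population(spec, 5, jitter = 0.3, seed = 48)
  radii_j <- vapply(jit, function(c) c$spec$cell_radius, numeric(1))
  expect_gt(diff(range(radii_j)), 0)
  expect_true(all(abs(radii_j / spec$cell_radius - 1) <= 0.3))
  expect_error(generate_population(spec, 2, jitter = 0.6), "jitter")
})

test_that("pipeline recovers the generating spatial model from one cell", {
  uni <- analyze_cell(generate_cell(synthetic_cell_spec(seed = 49)))
  pk_uni <- find_peaks(uni$density, uni$bin_edges, min_prominence = 0.1)
  expect_equal(nrow(pk_uni), 1L) # homogeneous: unimodal

  bi <- analyze_cell(generate_cell(synthetic_cell_spec(
    spatial_model = "bimodal", membrane_weight = 0.5, seed = 49)))
  pk_bi <- find_peaks(bi$density, bi$bin_edges, min_prominence = 0.1)
  expect_gte(nrow(pk_bi), 2L)
  outer <- max(pk_bi$location)
  expect_gte(outer, 0.9)
  expect_lte(outer, 1.6)
})

test_that("STED-scale rendering resolves at least as many events", {
  base <- list(shape = c(1L, 192L, 192L), cell_radius = 60, n_vesicles = 100,
               spatial_model = "bimodal", vesicle_sigma = 1.0, seed = 50)
  n_events <- function(psf) {
    cell <- generate_cell(do.call(synthetic_cell_spec, c(base, psf_sigma = psf)))
    bm <- background_model(cell$stack)
    attr(label_components(binarize(cell$stack, bm$theta)), "n")
  }
  expect_gte(n_events(0.6), n_events(2.5))
})

test_that("phantom stacks carve the expected voxel sets", {
  ball <- phantom_stack(c(32, 32, 32), 12, "ball", value = 2)
  n_in <- sum(ball$data > 1)
  expect_lt(abs(n_in - 4 / 3 * pi * 12^3) / n_in, 0.02)
  shell <- phantom_stack(c(32, 32, 32), 12, "shell", thickness = 2)
  rho <- cell_geometry(shell, 1)
  expect_true(all(rho$distances <= 12.1))
  # squashed ball respects the axial ratio
  sq <- phantom_stack(c(32, 64, 64), 20, "ball", axial_squash = 0.5)
  g <- cell_geometry(sq, 1)
  expect_lte(max(abs(g$coords[, "z"] - g$center[1])), 10 + 0.5)
})
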