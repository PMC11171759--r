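test_that("unscaled binning places mass in the expected bins", {
  # two equal-weight suprathreshold pixels: center sits midway between them
  d <- array(0, c(1, 9, 9))
  d[1, 5, 4] <- 10; d[1, 5, 8] <- 10
  geom <- cell_geometry(image_stack(d), 5)
  expect_equal(geom$distances, c(2, 2))

  # two equal weights at distances 1 and 3, 4 bins on [0, 3]
  g <- structure(list(distances = c(1, 3), weights = c(0.5, 0.5), rg = 1,
                      theta = 5, n = 2L, cell_id = "m", group = "g"),
                 class = "CellGeometry")
  dist <- distance_distribution(g, bins = 4, scaled = FALSE, grid_max = 3)
  mass <- dist$density * diff(dist$bin_edges)
  expect_equal(mass, c(0, 0.5, 0, 0.5)) # [0,.75) [.75,1.5) [1.5,2.25) [2.25,3]
})

test_that("histogram bin assignment matches the brute-force loop", {
  for (seed in 21:24) {
    rs <- random_stack(seed, d = c(4, 16, 16))
    theta <- as.numeric(quantile(rs$data, 0.85))
    geom <- cell_geometry(rs, theta)
    dist <- distance_distribution(geom, bins = 13, scaled = TRUE, grid_max = 2.5)
    ref <- oracle_hist_mass(pmin(geom$distances / geom$rg, 2.5), geom$weights,
                            dist$bin_edges)
    expect_equal(dist$density * diff(dist$bin_edges), ref, tolerance = 1e-12)
    expect_equal(band_mass(dist$density, dist$bin_edges, 0, 2.5), 1,
                 tolerance = 1e-9) # density normalization
  }
})

test_that("scaled distributions are invariant to uniform magnification", {
  rs <- random_stack(25, d = c(6, 16, 16))
  theta <- as.numeric(quantile(rs$data, 0.8))
  a <- cell_geometry(rs, theta)
  k <- 3.7
  mag <- image_stack(rs$data, spacing = rs$spacing * k)
  b <- cell_geometry(mag, theta)
  expect_equal(b$rg, k * a$rg, tolerance = 1e-9)
  da <- distance_distribution(a)
  db <- distance_distribution(b)
  expect_equal(db$density, da$density, tolerance = 1e-9)
})

test_that("analytic phantoms produce the closed-form scaled distributions", {
  shell <- cell_geometry(phantom_stack(c(64, 64, 64), 26, "shell"), 1)
  ds <- distance_distribution(shell)
  expect_gte(band_mass(ds$density, ds$bin_edges, 0.95, 1.05), 0.99)

  ball <- cell_geometry(phantom_stack(c(64, 64, 64), 26, "ball"), 1)
  db <- distance_distribution(ball)
  s_max <- sqrt(5 / 3)
  expect_gte(band_mass(db$density, db$bin_edges, 0, s_max + 0.05), 0.99)
  mean_s <- sum(ball$weights * ball$distances / ball$rg)
  expect_lt(abs(mean_s - 0.75 * s_max), 0.02)
})

test_that("overflow mass beyond the grid is tracked in the last bin", {
  g <- list(distances = c(0.5, 3.0), weights = c(0.75, 0.25), rg = 1,
            theta = 0, n = 2, cell_id = "o", group = "g")
  class(g) <- "CellGeometry"
  dist <- distance_distribution(g, bins = 10, scaled = TRUE, grid_max = 2.5)
  expect_equal(dist$overflow_fraction, 0.25)
  mass <- dist$density * diff(dist$bin_edges)
  expect_equal(mass[10], 0.25) # clipped into the closed last bin
  expect_equal(sum(mass), 1, tolerance = 1e-12)
})

test_that("block-mean down-sampling averages tiles and rescales spacing", {
  const <- image_stack(array(7, c(3, 16, 16)), spacing = c(1, 0.5, 0.5))
  ds <- downsample(const, 2)
  expect_identical(dim(ds$data), c(3L, 8L, 8L))
  expect_true(all(ds$data == 7))
  expect_equal(ds$spacing, c(1, 1, 1))

  d <- array(0, c(1, 16, 16))
  d[1, 1:2, 1:2] <- c(1, 5, 3, 7) # column-major tile: mean 4
  ds2 <- downsample(image_stack(d), 2)
  expect_equal(ds2$data[1, 1, 1], 4)

  odd <- image_stack(array(1, c(1, 17, 17)))
  expect_warning(downsample(odd, 2), "dropped")
  expect_identical(dim(suppressWarnings(downsample(odd, 2))$data), c(1L, 8L, 8L))
  expect_error(downsample(const, 0), "positive")
})

test_that("z-projection clips at zero and matches a naive loop", {
  st <- random_stack(26, d = c(4, 8, 8))
  theta <- as.numeric(quantile(st$data, 0.5))
  zp <- zproject_mean(st, theta)
  ref <- matrix(0, 8, 8)
  for (j in 1:8) for (i in 1:8)
    ref[j, i] <- mean(pmax(st$data[, j, i] - theta, 0))
  expect_equal(zp, ref, tolerance = 1e-12)
  expect_true(all(zproject_mean(st, max(st$data)) == 0))
  one <- image_stack(st$data[1, , , drop = FALSE])
  expect_equal(zproject_mean(one, theta), pmax(st$data[1, , ] - theta, 0))
})

test_that("event intensities integrate over 26-connected components", {
  d <- array(0, c(3, 12, 12))
  d[1, 2, 2] <- 5; d[2, 6, 6] <- 7; d[3, 10, 10] <- 9 # isolated events
  st <- image_stack(d)
  ev <- intensity_distribution(st, 1, per_event = TRUE)
  expect_equal(ev$n_events, 3L)
  expect_equal(sort(ev$values), c(4, 6, 8))

  d2 <- array(0, c(2, 12, 12))
  d2[1, 3, 3] <- 4; d2[2, 4, 4] <- 6 # corner-adjacent across z: one event
  ev2 <- intensity_distribution(image_stack(d2), 0, per_event = TRUE)
  expect_equal(ev2$n_events, 1L)
  expect_equal(ev2$values, 10)

  px <- intensity_distribution(st, 1, per_event = FALSE)
  expect_equal(sort(px$values), c(5, 7, 9)) # raw intensities per pixel
  expect_error(intensity_distribution(st, 100), class = "vesdist_qc_error")
})

test_that("component labelling matches connectivity expectations", {
  m <- array(FALSE, c(2, 8, 8))
  m[1, 1, 1] <- TRUE; m[1, 1, 2] <- TRUE  # face neighbors
  m[2, 2, 3] <- TRUE                      # corner neighbor of (1,1,2)
  m[1, 8, 8] <- TRUE                      # far away
  lab <- label_components(m)
  expect_equal(attr(lab, "n"), 2L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 3])
  expect_false(lab[1, 1, 1] == lab[1, 8, 8])

  flat <- matrix(FALSE, 6, 6); flat[1, 1] <- TRUE; flat[2, 2] <- TRUE
  flat[5, 5] <- TRUE
  expect_equal(attr(label_components(flat), "n"), 2L) # 8-connectivity in 2D
})
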