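two_group_summary <- function(n_a = 4, n_b = 3, bins = 20, seed = 31) {
  with_seed(seed, {
    dists <- c(
      lapply(seq_len(n_a), function(i)
        make_dist(dexp(seq(0, 2.4, length.out = bins)) + runif(bins, 0, 0.05),
                  edges = seq(0, 2.5, length.out = bins + 1),
                  cell_id = sprintf("a%d", i), group = "A")),
      lapply(seq_len(n_b), function(i)
        make_dist(dnorm(seq(0, 2.4, length.out = bins), 1.2, 0.3) +
                    runif(bins, 0, 0.05),
                  edges = seq(0, 2.5, length.out = bins + 1),
                  cell_id = sprintf("b%d", i), group = "B")))
    aggregate_distributions(dists)
  })
}

test_that("aggregation stacks rows, means groups, records cohort sizes", {
  d1 <- make_dist(c(1, 2, 3, 4), cell_id = "x", group = "G")
  d2 <- make_dist(c(1, 2, 3, 4), cell_id = "y", group = "G")
  s <- aggregate_distributions(list(d1, d2))
  expect_equal(s$mean_curves$G, d1$density)

  s2 <- two_group_summary(60, 56)
  expect_equal(unname(as.vector(s2$group_n)), c(60L, 56L))
  # group means equal brute-force column means
  for (g in c("A", "B")) {
    rows <- s2$matrix[s2$labels == g, ]
    ref <- apply(rows, 2, mean)
    expect_equal(s2$mean_curves[[g]], ref, tolerance = 1e-12)
    expect_equal(band_mass(s2$mean_curves[[g]], s2$grid, 0, 2.5), 1,
                 tolerance = 1e-9)
  }
})

test_that("aggregation rejects mixed grids and unscaled inputs", {
  d1 <- make_dist(1:4)
  d2 <- make_dist(1:5, edges = seq(0, 2.5, length.out = 6))
  expect_error(aggregate_distributions(list(d1, d2)), "grid")
  d3 <- make_dist(1:4); d3$scaled <- FALSE
  expect_error(aggregate_distributions(list(d1, d3)), "scaled")
})

test_that("aggregation is permutation-invariant within groups", {
  s <- two_group_summary(5, 5, seed = 32)
  dists <- lapply(seq_len(nrow(s$matrix)), function(i)
    make_dist(s$matrix[i, ], cell_id = s$cell_ids[i], group = s$labels[i]))
  perm <- with_seed(33, sample(length(dists)))
  s_perm <- aggregate_distributions(dists[perm])
  expect_equal(s_perm$mean_curves$A, s$mean_curves$A, tolerance = 1e-12)
  expect_equal(s_perm$mean_curves$B, s$mean_curves$B, tolerance = 1e-12)
})

test_that("PCA reproduces the covariance eigendecomposition", {
  s <- pca_distributions(two_group_summary(6, 6, seed = 34), n_components = 3)
  X <- scale(s$matrix, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(X), symmetric = TRUE)
  ref_scores <- X %*% eig$vectors[, 1:3]
  for (j in 1:3) { # compare up to sign with the deterministic convention
    expect_equal(abs(s$pca_scores[, j]), abs(ref_scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    i <- which.max(abs(s$pca_loadings[, j]))
    expect_gt(s$pca_loadings[i, j], 0)
  }
  expect_equal(s$pca_explained, eig$values[1:3] / sum(eig$values),
               tolerance = 1e-9)
  # explained fractions: non-increasing, in [0, 1]
  expect_true(all(diff(s$pca_explained) <= 1e-12))
  expect_true(all(s$pca_explained >= 0 & s$pca_explained <= 1))
  expect_lte(sum(s$pca_explained), 1 + 1e-9)
})

test_that("PCA of two distinct cells loads everything on PC1", {
  s <- aggregate_distributions(list(make_dist(c(4, 1, 1, 1), cell_id = "p"),
                                    make_dist(c(1, 1, 1, 4), cell_id = "q")))
  s <- pca_distributions(s, 1)
  expect_equal(s$pca_explained[1], 1, tolerance = 1e-9)
})

test_that("PCA rejects degenerate inputs", {
  same <- aggregate_distributions(list(make_dist(1:4, cell_id = "u"),
                                       make_dist(1:4, cell_id = "v")))
  expect_error(pca_distributions(same), "degenerate")
  one <- aggregate_distributions(list(make_dist(1:4)))
  expect_error(pca_distributions(one), "at least 2")
  expect_error(pca_distributions(two_group_summary(3, 3), n_components = 50),
               "n_components")
})

test_that("membrane fraction integrates scaled mass beyond the cutoff", {
  # thin shell at s = 1.2
  shell <- make_dist(c(rep(0, 47), 1, rep(0, 52))) # bin 48 of 100: [1.175,1.2)
  expect_equal(membrane_fraction(shell, 1.0), 1, tolerance = 1e-9)
  expect_equal(membrane_fraction(shell, 2.0), 0, tolerance = 1e-9)

  ball <- cell_geometry(phantom_stack(c(48, 48, 48), 20, "ball"), 1)
  db <- distance_distribution(ball)
  # support ends at s_max (up to voxel discretization of the ball boundary)
  expect_lt(membrane_fraction(db, sqrt(5 / 3) + 0.05), 0.005)
  expect_lt(membrane_fraction(db, sqrt(5 / 3)), 0.02)

  cuts <- seq(0, 2.5, by = 0.1)
  mf <- vapply(cuts, function(ct) membrane_fraction(db, ct), numeric(1))
  expect_true(all(diff(mf) <= 1e-12)) # monotone non-increasing
  expect_error(membrane_fraction(db, 3.0), "outside")
  raw <- distance_distribution(ball, scaled = FALSE)
  expect_error(membrane_fraction(raw), "scaled")
})

test_that("group comparison is descriptive and symmetric for identical groups", {
  d <- make_dist(dnorm(seq(0.1, 2.4, length.out = 25), 1, 0.4),
                 edges = seq(0, 2.5, length.out = 26))
  dists <- lapply(1:6, function(i) {
    out <- d; out$cell_id <- paste0("c", i)
    out$group <- if (i <= 3) "A" else "B"
    out
  })
  s <- aggregate_distributions(dists)
  cmp <- compare_groups(s, "A", "B")
  expect_equal(cmp$difference, rep(0, 25))
  expect_equal(cmp$membrane_fraction$a[["mean"]], cmp$membrane_fraction$b[["mean"]])
  expect_equal(cmp$membrane_fraction$a[["sem"]], 0)
  expect_error(compare_groups(s, "A", "nope"), "unknown group")
})

test_that("group SEM matches the textbook formula", {
  s <- two_group_summary(8, 5, seed = 35)
  cmp <- compare_groups(s, "A", "B", cutoff = 1.0)
  mfa <- apply(s$matrix[s$labels == "A", ], 1, function(r)
    band_mass(r, s$grid, 1.0, 2.5))
  expect_equal(cmp$membrane_fraction$a[["mean"]], mean(mfa), tolerance = 1e-12)
  expect_equal(cmp$membrane_fraction$a[["sem"]], sd(mfa) / sqrt(8),
               tolerance = 1e-12)
})

test_that("peak detection finds prominent local maxima only", {
  x <- dnorm(seq(0, 2.5, length.out = 100), 0.5, 0.15) +
       0.6 * dnorm(seq(0, 2.5, length.out = 100), 1.4, 0.12)
  pk <- find_peaks(x, seq(0, 2.5, length.out = 101), min_prominence = 0.05)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$location, c(0.5, 1.4), tolerance = 0.05)

  mono <- seq(0, 1, length.out = 50)^2 # monotone: no interior maximum
  expect_equal(nrow(find_peaks(mono)), 0L)
})

test_that("outer-peak mass integrates around the detected membrane peak", {
  edges <- seq(0, 2.5, length.out = 101)
  mids <- (edges[-1] + edges[-101]) / 2
  bi <- dnorm(mids, 0.5, 0.15) + 0.8 * dnorm(mids, 1.3, 0.1)
  bi <- bi / band_mass(bi, edges, 0, 2.5)
  op <- outer_peak_mass(bi, edges)
  expect_equal(op$center, 1.3, tolerance = 0.05)
  expect_equal(op$mass,
               band_mass(bi, edges, op$center - 0.15, op$center + 0.15))
  # fixed-center mode for measuring a comparison group in the same window
  op2 <- outer_peak_mass(bi, edges, center = 1.3)
  expect_equal(op2$center, 1.3)
})
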