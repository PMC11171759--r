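# Independent brute-force oracles: plain per-pixel loops, no shared code with
# the implementation under test.

random_stack <- function(seed, d = c(16L, 32L, 32L), spacing = c(1, 1, 1),
                         lo = 0, hi = 100) {
  with_seed(seed, image_stack(array(runif(prod(d), lo, hi), d),
                              spacing = spacing,
                              cell_id = paste0("rand", seed), group = "test"))
}

# loop over every voxel; returns 0-based spacing-scaled coords and raw excesses
oracle_suprathreshold <- function(stack, theta) {
  d <- dim(stack$data)
  sp <- stack$spacing
  rows <- list()
  w <- numeric(0)
  # column-major enumeration: z fastest, then y, then x (matches which())
  for (i in seq_len(d[3])) for (j in seq_len(d[2])) for (k in seq_len(d[1])) {
    y <- stack$data[k, j, i]
    if (y > theta) {
      rows[[length(rows) + 1L]] <-
        c((k - 1) * sp[1], (j - 1) * sp[2], (i - 1) * sp[3])
      w[length(w) + 1L] <- y - theta
    }
  }
  list(coords = do.call(rbind, rows), weights = w / sum(w))
}

oracle_binarize <- function(stack, theta) {
  d <- dim(stack$data)
  out <- array(FALSE, d)
  for (k in seq_len(d[1])) for (j in seq_len(d[2])) for (i in seq_len(d[3]))
    out[k, j, i] <- stack$data[k, j, i] > theta
  out
}

oracle_com <- function(coords, weights) {
  s <- c(0, 0, 0); tot <- 0
  for (r in seq_len(nrow(coords))) {
    s <- s + weights[r] * coords[r, ]
    tot <- tot + weights[r]
  }
  s / tot
}

oracle_rg <- function(coords, weights, center) {
  num <- 0; tot <- 0
  for (r in seq_len(nrow(coords))) {
    num <- num + weights[r] * sum((coords[r, ] - center)^2)
    tot <- tot + weights[r]
  }
  sqrt(num / tot)
}

# half-open bins [e_b, e_{b+1}), last bin closed
oracle_hist_mass <- function(values, weights, edges) {
  B <- length(edges) - 1L
  mass <- numeric(B)
  for (r in seq_along(values)) {
    v <- values[r]
    for (b in seq_len(B)) {
      if ((v >= edges[b] && v < edges[b + 1]) || (b == B && v == edges[B + 1])) {
        mass[b] <- mass[b] + weights[r]
        break
      }
    }
  }
  mass
}

l1_distance <- function(a, b) {
  stopifnot(max(abs(a$bin_edges - b$bin_edges)) < 1e-12)
  band_mass(abs(a$density - b$density), a$bin_edges, 0, max(a$bin_edges))
}

random_rotation <- function(seed) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# lightweight scaled distribution for population-level tests
make_dist <- function(density, edges = seq(0, 2.5, length.out = length(density) + 1),
                      cell_id = "c", group = "g", rg = 1) {
  mass <- density / sum(density * diff(edges)) # density-normalize
  structure(list(bin_edges = edges, density = mass, scaled = TRUE,
                 cell_id = cell_id, group = group, rg = rg, theta = 0,
                 overflow_fraction = 0, n_pixels = 100L),
            class = "DistanceDistribution")
}

# standard single-cell analysis used across phenotype tests
analyze_cell <- function(cell, n_sigma = 10, ds = 1L, bins = 100L) {
  st <- cell$stack
  if (ds > 1L) st <- downsample(st, ds)
  bm <- background_model(st, n_sigma = n_sigma)
  geom <- cell_geometry(st, bm$theta)
  distance_distribution(geom, bins = bins, scaled = TRUE)
}
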