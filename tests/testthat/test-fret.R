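# fret_av: accessible volume, Forster relations, shot-noise histograms

# minimal av_cloud built directly from positions (for closed-form checks)
point_cloud <- function(positions) {
  structure(list(positions = matrix(positions, ncol = 3),
                 mean_position = colMeans(matrix(positions, ncol = 3)),
                 spacing = 1, attachment = c(0, 0, 0),
                 geodesic = rep(0, nrow(matrix(positions, ncol = 3)))),
            class = "av_cloud")
}

test_that("Forster relations: midpoint, limits, round trip", {
  d <- point_cloud(c(0, 0, 0))
  a <- point_cloud(c(40, 0, 0))
  expect_equal(fret_efficiency(d, a, R0 = 40)$mean_E, 0.5, tolerance = 1e-12)

  near <- point_cloud(c(0.01, 0, 0))
  expect_gt(fret_efficiency(d, near, R0 = 40)$mean_E, 0.999)
  far <- point_cloud(c(120, 0, 0)) # r = 3 R0
  expect_equal(fret_efficiency(d, far, R0 = 40)$mean_E, 1 / 730,
               tolerance = 1e-9)

  expect_equal(distance_from_efficiency(0.5, 38), 38, tolerance = 1e-12)
  expect_equal(distance_from_efficiency(0.8, 40), 40 * 0.25^(1 / 6),
               tolerance = 1e-9)
  expect_equal(distance_from_efficiency(0.8, 40), 31.748, tolerance = 1e-3)
  for (E in c(0.1, 0.37, 0.9)) {
    expect_equal(efficiency_from_distance(distance_from_efficiency(E, 42), 42),
                 E, tolerance = 1e-10)
  }
  expect_error(distance_from_efficiency(1, 40), "strictly")
  expect_error(distance_from_efficiency(0, 40), "strictly")
})

test_that("accessible volume of an unobstructed dye is a spherical shell", {
  # single-atom "protein": clash radius = dye radius (vdW set to 0),
  # geodesic = Euclidean, so the cloud is the 3..10 A shell
  s <- bead_structure(matrix(0, 1, 3))
  dye <- dye_spec(1, atom = "CA", linker_length = 10, dye_radius = 3,
                  role = "donor")
  av <- accessible_volume(s, dye, spacing = 1.0, vdw_radii = c(C = 0))
  # oracle: enumerate the same grid with plain Euclidean distances
  ax <- seq(-10, 10, by = 1)
  grid <- as.matrix(expand.grid(ax, ax, ax))
  r <- sqrt(rowSums(grid^2))
  oracle_count <- sum(r <= 10 + 1e-9 & r >= 3)
  expect_lt(abs(nrow(av$positions) - oracle_count) / oracle_count, 0.05)
  # analytic shell volume as a sanity check on the oracle itself
  vol <- nrow(av$positions) * av$spacing^3
  expect_lt(abs(vol - 4 / 3 * pi * (10^3 - 3^3)) / (4 / 3 * pi * (10^3 - 3^3)),
            0.06)
  # every position obeys both constraints
  rr <- sqrt(rowSums(av$positions^2))
  expect_true(all(rr >= 3 - 1e-9))
  expect_true(all(av$geodesic <= 10 + 1e-9))
  # symmetric problem: mean position at the attachment
  expect_lt(sqrt(sum(av$mean_position^2)), 0.3)
})

test_that("a wall of atoms confines the cloud to the open half-space", {
  # wall beyond the attachment's covalent-neighbour radius so it is fully
  # opaque; too wide for the 12 A linker to reach around
  wall <- expand.grid(x = 5, y = seq(-25, 25, 1.5), z = seq(-25, 25, 1.5))
  xyz <- rbind(c(0, 0, 0), as.matrix(wall))
  s <- bead_structure(xyz)
  dye <- dye_spec(1, atom = "CA", linker_length = 12, dye_radius = 3,
                  role = "donor")
  av <- accessible_volume(s, dye, spacing = 1.0)
  expect_true(all(av$positions[, 1] < 5))
})

test_that("grid refinement moves the AV mean position by < 0.5 A", {
  xyz <- saxsens:::.chain_compact(12, seed = 3)
  s <- bead_structure(xyz)
  dye <- dye_spec(6, atom = "CA", linker_length = 8, dye_radius = 2.5,
                  role = "donor")
  av1 <- accessible_volume(s, dye, spacing = 1.0)
  av05 <- accessible_volume(s, dye, spacing = 0.5)
  expect_lt(sqrt(sum((av1$mean_position - av05$mean_position)^2)), 0.5)
})

test_that("sampled efficiency matches the exhaustive all-pairs oracle", {
  set.seed(31)
  dpos <- matrix(rnorm(30, 0, 2), 10, 3)
  apos <- matrix(rnorm(30, 35, 2), 10, 3)
  d <- point_cloud(dpos); a <- point_cloud(apos)
  exact <- fret_efficiency(d, a, R0 = 40, exact = TRUE)
  oracle <- {
    Es <- numeric(0)
    for (i in 1:10) for (j in 1:10) {
      r <- sqrt(sum((dpos[i, ] - apos[j, ])^2))
      Es <- c(Es, 1 / (1 + (r / 40)^6))
    }
    mean(Es)
  }
  expect_equal(exact$mean_E, oracle, tolerance = 1e-12)
  mc <- fret_efficiency(d, a, R0 = 40, n_samples = 20000, seed = 2)
  expect_lt(abs(mc$mean_E - oracle), 0.02)
})

test_that("efficiency decreases as clouds are rigidly separated", {
  base <- matrix(rnorm(60, 0, 3), 20, 3)
  d <- point_cloud(base)
  Es <- vapply(c(20, 30, 40, 55, 75), function(sep) {
    a <- point_cloud(sweep(base, 2, c(-sep, 0, 0)))
    fret_efficiency(d, a, R0 = 40, exact = TRUE)$mean_E
  }, numeric(1))
  expect_true(all(diff(Es) < 0))
})

test_that("ensemble histogram: shot-noise limit and bimodal mixtures", {
  # two rigid bead conformations with very different dye separations
  near <- rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0), c(24, 0, 0))
  far <- rbind(c(0, 0, 0), c(25, 0, 0), c(50, 0, 0), c(75, 0, 0))
  s_near <- bead_structure(near)
  s_far <- bead_structure(far)
  pair <- fret_pair(dye_spec(1, atom = "CA", linker_length = 5, dye_radius = 2,
                             role = "donor"),
                    dye_spec(4, atom = "CA", linker_length = 5, dye_radius = 2,
                             role = "acceptor"),
                    R0 = 45)

  # single structure, many photons: histogram collapses onto that E
  h1 <- ensemble_fret_histogram(list(s_near), 1, pair, photons = 10000,
                                n_events = 400, seed = 3)
  expect_lt(h1$sd, 0.02)
  expect_equal(h1$mean, h1$per_state_E[1], tolerance = 0.01)

  # equal mixture: bimodal, event efficiencies cluster at the two state Es
  h2 <- ensemble_fret_histogram(list(s_near, s_far), c(0.5, 0.5), pair,
                                photons = 5000, n_events = 600, seed = 4)
  E_lo <- min(h2$per_state_E); E_hi <- max(h2$per_state_E)
  expect_gt(E_hi - E_lo, 0.3)
  assign_lo <- abs(h2$efficiencies - E_lo) < abs(h2$efficiencies - E_hi)
  expect_equal(mean(h2$efficiencies[assign_lo]), E_lo, tolerance = 0.02)
  expect_equal(mean(h2$efficiencies[!assign_lo]), E_hi, tolerance = 0.02)
  expect_equal(mean(assign_lo), 0.5, tolerance = 0.1)

  # determinism
  h3 <- ensemble_fret_histogram(list(s_near, s_far), c(0.5, 0.5), pair,
                                photons = 5000, n_events = 600, seed = 4)
  expect_identical(h2$efficiencies, h3$efficiencies)
})
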