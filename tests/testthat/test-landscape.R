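test_that("binning spans the observed range and conserves particles", {
  pts <- tibble::tibble(q1 = c(0, 0, 1, 1), q2 = c(0, 1, 0, 1))
  g <- bin_particles(pts, c(2, 2))
  expect_equal(g$counts, matrix(1L, 2, 2))
  set.seed(1)
  pts2 <- tibble::tibble(q1 = runif(5000), q2 = rnorm(5000))
  g2 <- bin_particles(pts2, c(7, 13))
  expect_equal(sum(g2$counts), 5000)
  expect_equal(range(g2$bin_edges_q1), range(pts2$q1))
  expect_equal(range(g2$bin_edges_q2), range(pts2$q2))
  expect_error(bin_particles(tibble::tibble(q1 = rep(1, 5), q2 = 1:5)),
               "zero variance")
  expect_error(bin_particles(pts, c(1, 2)), "at least 2 bins")
})

test_that("Boltzmann inversion matches its closed form and masks empties", {
  g <- grid_from_energies(matrix(c(0, 0), 2, 1), scale = 1)
  g$counts <- matrix(c(1000L, 368L), 2, 1)
  g$empty_mask <- g$counts == 0L
  g <- boltzmann_invert(g)
  expect_equal(g$energies[1, 1], 0)
  expect_equal(g$energies[2, 1], -log(368 / 1000), tolerance = 1e-12)
  # a bin at exp(-5.6) relative occupancy sits 5.6 kT up
  g2 <- grid_from_energies(matrix(c(0, 0), 2, 1), scale = 1)
  g2$counts <- matrix(c(100000L, as.integer(round(100000 * exp(-5.6)))), 2, 1)
  g2$empty_mask <- g2$counts == 0L
  g2 <- boltzmann_invert(g2)
  expect_equal(g2$energies[2, 1], 5.6, tolerance = 1e-3)
  # uniform counts -> all zero; empty bins masked
  g3 <- grid_from_energies(matrix(0, 3, 3))
  expect_true(all(g3$energies == 0))
  g4 <- grid_from_energies(matrix(c(0, NA, 1, 2), 2, 2))
  expect_true(is.na(g4$energies[2, 1]))
  expect_true(g4$empty_mask[2, 1])
})

test_that("inversion is consistent with the forward populations", {
  surf <- two_basin_surface()
  pp <- sample_particles(surf, 2e4, seed = 2)
  g <- boltzmann_invert(bin_particles(pp, c(20, 20)))
  w <- exp(-g$energies)
  w[is.na(w)] <- 0
  expect_equal(w / sum(w), g$counts / sum(g$counts), tolerance = 1e-12)
})

test_that("watershed finds the constructed basins", {
  # single well
  E1 <- outer((1:9 - 5)^2, (1:9 - 5)^2, `+`) / 10
  g1 <- find_basins(grid_from_energies(E1), min_depth = 0)
  expect_equal(nrow(g1$basins), 1)
  expect_equal(g1$basins$fraction, 1)
  # two designed wells
  x <- seq(-1, 1, length.out = 21)
  E2 <- outer(x, x, function(a, b) (a^2 - 0.25)^2 * 8 + b^2)
  g2 <- find_basins(grid_from_energies(E2), min_depth = 0)
  expect_equal(nrow(g2$basins), 2)
  expect_equal(sort(abs(g2$basins$min_q1 - 10.5)), c(5, 5), tolerance = 1)
})

test_that("shallow noise catchments merge under the persistence threshold", {
  E <- outer((1:15 - 8)^2, (1:15 - 8)^2, `+`) / 8
  E[3, 3] <- min(E[2:4, 2:4][-5]) - 0.3  # a dimple much shallower than 1 kT
  g <- find_basins(grid_from_energies(E), min_depth = 1)
  expect_equal(nrow(g$basins), 1)
  g0 <- find_basins(grid_from_energies(E), min_depth = 0)
  expect_gt(nrow(g0$basins), 1)
})

test_that("minimax barrier matches the worked example and brute force", {
  E <- matrix(c(0, 9, 9, 3, 2, 4, 9, 9, 1), 3, 3)
  g <- find_basins(grid_from_energies(E), min_depth = 0)
  expect_equal(nrow(g$basins), 2)
  a <- g$basins$basin[g$basins$min_energy == 0]
  b <- setdiff(g$basins$basin, a)
  bar <- find_barrier(g, a, b)
  expect_equal(bar$saddle_energy, 2, tolerance = 1e-4)
  expect_equal(bar$barrier_from_a, 2, tolerance = 1e-4)
  expect_equal(bar$barrier_from_b, 1, tolerance = 1e-4)
  expect_equal(brute_minimax(E, c(1, 1), c(3, 3)), 2)
  # identical basins give zero
  expect_equal(find_barrier(g, a, a)$barrier_from_a, 0)
})

test_that("bottleneck search equals exhaustive path enumeration on small grids", {
  set.seed(99)
  for (n1 in 2:4) for (n2 in 2:4) for (rep in 1:4) {
    E <- matrix(round(runif(n1 * n2, 0, 10), 2), n1, n2)
    if (rep %% 2 == 0) E[sample(length(E), 1)] <- NA  # masked bin
    from <- c(1, 1); to <- c(n1, n2)
    if (is.na(E[1, 1]) || is.na(E[n1, n2])) next
    oracle <- brute_minimax(E, from, to)
    got <- corelandscape:::bottleneck_value(E, 1L, n1 * n2)$value
    expect_equal(got, oracle)
  }
})

test_that("barrier is shift-invariant and monotone in on-path energies", {
  set.seed(7)
  E <- matrix(runif(25, 0, 6), 5, 5)
  v0 <- corelandscape:::bottleneck_value(E, 1L, 25L)$value
  expect_equal(corelandscape:::bottleneck_value(E + 2.5, 1L, 25L)$value, v0 + 2.5)
  E2 <- E
  E2[3, 3] <- E2[3, 3] + 3
  expect_gte(corelandscape:::bottleneck_value(E2, 1L, 25L)$value, v0)
})

test_that("disconnected basins report an explicit lower bound", {
  E <- matrix(c(0, NA, NA, NA, NA, NA, NA, NA, 1), 3, 3)
  g <- find_basins(grid_from_energies(E), min_depth = 0)
  expect_equal(nrow(g$basins), 2)
  bar <- find_barrier(g, 1, 2)
  expect_true(bar$lower_bound)
  expect_equal(bar$barrier_from_a, max(E, na.rm = TRUE), tolerance = 1e-4)
})

test_that("state assignment inherits bin basins and flags compression", {
  surf <- two_basin_surface()
  pp <- sample_particles(surf, 3e4, seed = 8)
  g <- find_basins(boltzmann_invert(bin_particles(pp, c(30, 30))), min_depth = 1)
  asg <- assign_states(pp, g, compression_range = 12)
  fr <- state_fractions(asg)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  expect_true(any(fr$compressed))
  # labels agree with generator truth away from the saddle region
  core <- asg[pp$q2 < 4 | pp$q2 > 8, ]
  truth <- pp$basin[pp$q2 < 4 | pp$q2 > 8]
  map <- vapply(split(truth, core$basin), function(x)
    names(sort(-table(x)))[1], character(1))
  agree <- mean(map[as.character(core$basin)] == truth)
  expect_gt(agree, 0.99)
})
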