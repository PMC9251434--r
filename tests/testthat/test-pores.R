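# Pore-geometry tests run on a reduced barrel (30 A outer radius) so the
# voxel grids stay small; the wall construction and measurement regime are
# identical to the full-size assembly.

test_that("rasterization covers a probe-inflated ball around each bead", {
  one <- as_bead_model(tibble::tibble(
    bead_id = 1L, group = "cp_beta_1", x = 0, y = 0, z = 0,
    radius = 2.5, pseudo_residue = "A"))
  g <- rasterize_assembly(one, spacing = 0.5, probe_radius = 1.4)
  occ <- which(g$occupied)
  pts <- corelandscape:::voxel_centres(g, occ)
  r <- sqrt(rowSums(pts^2))
  expect_lte(max(r), 3.9 + 1e-9)
  # every voxel centre within one voxel of the surface is occupied
  expect_gte(max(r), 3.9 - 0.5 * sqrt(3))
  # empty structure -> all solvent
  g0 <- rasterize_assembly(one[0, ], spacing = 0.5)
  expect_false(any(g0$occupied))
  expect_error(rasterize_assembly(one, spacing = 6), "resolution")
})

test_that("a closed shell yields no pores and a drilled shell exactly one", {
  g_closed <- rasterize_assembly(build_assembly(mini_config()), spacing = 0.5)
  expect_equal(nrow(detect_pores(g_closed)), 0)

  m1 <- build_assembly(mini_config(pores = list(
    list(azimuth_deg = 0, z = 20, d_long = 10, d_short = 10))))
  p1 <- detect_pores(rasterize_assembly(m1, spacing = 0.5))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$d_min_A, 10, tolerance = 0.5)
  expect_equal(p1$d_max_A, 10, tolerance = 0.5)
})

test_that("elliptical constriction axes are recovered within one spacing", {
  m <- build_assembly(mini_config(pores = list(
    list(azimuth_deg = 120, z = 20, d_long = 11.3, d_short = 7.9))))
  p <- detect_pores(rasterize_assembly(m, spacing = 0.5))
  expect_equal(nrow(p), 1)
  expect_equal(p$d_min_A, 7.9, tolerance = 0.5)
  expect_equal(p$d_max_A, 11.3, tolerance = 0.5)
  expect_lte(p$d_min_A, p$d_max_A)
})

test_that("pore count equals drilled channel count for random layouts", {
  set.seed(17)
  for (k in c(3, 6)) {
    # channels at least 60 degrees apart so rim constructions never touch
    az <- sort(sample(seq(0, 300, by = 60), k))
    zs <- sample(c(14, 20, 26), k, replace = TRUE)
    pores <- purrr::map2(az, zs, function(a, z)
      list(azimuth_deg = a, z = z, d_long = 6, d_short = 6))
    m <- build_assembly(mini_config(pores = pores))
    p <- detect_pores(rasterize_assembly(m, spacing = 0.5))
    expect_equal(nrow(p), k)
    expect_true(all(abs(p$d_min_A - 6) < 0.5))
  }
})

test_that("measurements are invariant to an azimuthal rotation of the fixture", {
  base <- list(azimuth_deg = 0, z = 20, d_long = 11.3, d_short = 7.9)
  rot <- base; rot$azimuth_deg <- 77
  p1 <- detect_pores(rasterize_assembly(
    build_assembly(mini_config(pores = list(base))), spacing = 0.5))
  p2 <- detect_pores(rasterize_assembly(
    build_assembly(mini_config(pores = list(rot))), spacing = 0.5))
  expect_equal(p1$d_min_A, p2$d_min_A, tolerance = 0.5)
  expect_equal(p1$d_max_A, p2$d_max_A, tolerance = 0.5)
})

test_that("gate measurement brackets the pore-diameter regime endpoints", {
  expect_equal(measure_gate(build_assembly(mini_config())), 0)
  for (gd in c(4, 14, 17)) {
    m <- build_assembly(mini_config(gate_diameter = gd))
    expect_equal(measure_gate(m), gd, tolerance = 0.5)
  }
  m_norp <- build_assembly(mini_config())
  expect_error(measure_gate(m_norp[m_norp$group != "cp_alpha_distal", ]),
               "distal ring")
})

test_that("lining chemistry follows the Kyte-Doolittle scale and formal charges", {
  m <- build_assembly(mini_config(pores = list(
    list(azimuth_deg = 0, z = 20, d_long = 10, d_short = 10))))
  g <- rasterize_assembly(m, spacing = 0.5)
  p <- detect_pores(g)

  with_residue <- function(res) {
    m2 <- m
    m2$pseudo_residue <- res
    g2 <- g
    g2$structure <- m2
    characterize_pore(p, g2)
  }
  ile <- with_residue("I")
  expect_equal(ile$mean_hydropathy, 4.5)
  expect_equal(ile$class, "hydrophobic")
  ser <- with_residue("S")
  expect_equal(ser$mean_hydropathy, -0.8)
  expect_equal(ser$class, "hydrophilic")
  # alternating D/K lining cancels to zero net charge
  m3 <- m
  m3$pseudo_residue <- rep(c("D", "K"), length.out = nrow(m))
  g3 <- g
  g3$structure <- m3
  dk <- characterize_pore(p, g3)
  expect_lte(abs(dk$net_charge), 1)  # parity of the lining count
  expect_equal(dk$net_charge %% 2 == 0, dk$n_lining %% 2 == 0)
})

test_that("the release filter is strict at 7 A", {
  pores <- tibble::tibble(pore_id = 1:4, d_min_A = c(4, 7, 7.9, 10))
  kept <- filter_releasing(pores)
  expect_equal(kept$pore_id, c(3L, 4L))
  expect_equal(attr(kept, "n_releasing"), 2)
})

test_that("degenerate channels report zero width with a warning", {
  m <- build_assembly(mini_config())
  g <- rasterize_assembly(m, spacing = 0.8)
  # a fabricated "channel" buried inside the occupied wall
  wall_vox <- which(g$occupied)[1:10]
  fake <- list(voxels = wall_vox, entries = wall_vox[1], exits = wall_vox[10])
  expect_warning(res <- measure_pore(fake, g), "d_min reported as 0")
  expect_equal(res$d_min, 0)
})
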