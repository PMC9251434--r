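test_that("reference assembly satisfies its structural invariants", {
  m <- full_model()
  expect_true(all(m$radius > 0))
  expect_false(anyDuplicated(m$bead_id) > 0)
  expect_setequal(unique(m$group),
                  c("cp_alpha_proximal", "cp_beta_1", "cp_beta_2",
                    "cp_alpha_distal", "lid", "base_atpase", "rpn1",
                    "rpn11_marker"))
  # four core rings stacked along +z in order
  ring_z <- vapply(c("cp_alpha_proximal", "cp_beta_1", "cp_beta_2",
                     "cp_alpha_distal"),
                   function(g) mean(m$z[m$group == g]), numeric(1))
  expect_true(all(diff(ring_z) > 0))
  expect_true(all(m$pseudo_residue %in% names(corelandscape:::KD_HYDROPATHY)))
})

test_that("core rings have sevenfold point symmetry about the barrel axis", {
  m <- build_assembly(assembly_config(gate_diameter = 14))
  cp <- m[grepl("^cp_", m$group), ]
  R7 <- corelandscape:::rotation_matrix(c(0, 0, 1), 360 / 7)
  rot <- as.matrix(cp[, c("x", "y", "z")]) %*% t(R7)
  worst <- max(vapply(seq_len(nrow(rot)), function(i) {
    min(sqrt((cp$x - rot[i, 1])^2 + (cp$y - rot[i, 2])^2 +
               (cp$z - rot[i, 3])^2))
  }, numeric(1)))
  expect_lt(worst, 1e-6)
})

test_that("gate construction yields the requested opening by construction", {
  expect_equal(measure_gate(build_assembly(mini_config(gate_diameter = 0))), 0)
  for (g in c(4, 14, 17)) {
    m <- build_assembly(mini_config(gate_diameter = g))
    expect_equal(measure_gate(m), g, tolerance = 1e-6)
  }
})

test_that("drilled elliptical pores carry the requested construction axes", {
  pore <- list(azimuth_deg = 40, z = 20, d_long = 11.3, d_short = 7.9)
  m <- build_assembly(mini_config(pores = list(pore)))
  cfg <- attr(m, "config")
  expect_length(cfg$pores, 1)
  expect_equal(cfg$pores[[1]]$d_long, 11.3)
  expect_equal(cfg$pores[[1]]$d_short, 7.9)
  # drilling removed wall beads around the requested site
  m0 <- build_assembly(mini_config())
  expect_false(nrow(m) == nrow(m0))
})

test_that("closed shell has no solvent path between interior and exterior", {
  m <- build_assembly(mini_config())
  g <- rasterize_assembly(m, spacing = 0.8, probe_radius = 1.4)
  reach <- corelandscape:::flood_solvent(g, c(0, 0, 20))
  d <- dim(reach)
  hits_boundary <- any(reach[1, , ]) || any(reach[d[1], , ]) ||
    any(reach[, 1, ]) || any(reach[, d[2], ]) ||
    any(reach[, , 1]) || any(reach[, , d[3]])
  expect_false(hits_boundary)
})

test_that("non-physical geometry is rejected with a configuration error", {
  expect_error(assembly_config(wall_thickness = 3, bead_radius = 2.5),
               "thinner than one bead")
  expect_error(assembly_config(outer_radius = -5), "positive")
  expect_error(assembly_config(gate_diameter = 200), "lumen")
  expect_error(assembly_config(pores = list(list(azimuth_deg = 0, z = 10,
                                                 d_long = 4, d_short = 9))),
               "d_short <= d_long")
})
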