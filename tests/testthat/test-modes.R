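test_that("default catalogue contains the four documented modes", {
  modes <- define_modes(full_model())
  expect_equal(modes$name, c("lid_rotation", "lid_tilt", "cp_compression",
                             "rpn1_swing"))
  expect_equal(modes$range_min, c(0, 4, 0, 1))
  expect_equal(modes$range_max, c(35, 10, 12, 25))
  # lid rotation pivots at the RPN11 marker, about the barrel axis
  marker <- colMeans(as.matrix(full_model()[full_model()$group == "rpn11_marker",
                                            c("x", "y", "z")]))
  expect_equal(modes$pivot[[1]], unname(marker))
  expect_equal(modes$axis[[1]], c(0, 0, 1))
  expect_true(all(vapply(modes$axis, function(a) abs(sum(a^2) - 1) < 1e-9,
                         logical(1))))
})

test_that("empty and custom catalogues echo their configuration", {
  m <- full_model()
  expect_equal(nrow(define_modes(m, modes = list())), 0)
  custom <- define_modes(m, modes = list(
    list(name = "probe", kind = "rotation", groups = "lid",
         pivot = c(1, 2, 3), axis = c(1, 0, 0), range = c(0, 10))))
  expect_equal(custom$name, "probe")
  expect_equal(custom$pivot[[1]], c(1, 2, 3))
  expect_equal(custom$axis[[1]], c(1, 0, 0))
  expect_error(define_modes(m, modes = list(
    list(name = "bad", kind = "rotation", groups = "nonexistent",
         axis = c(1, 0, 0), range = c(0, 1)))), "unknown group")
})

test_that("zero amplitudes reproduce the reference bit-identically", {
  m <- full_model()
  modes <- define_modes(m)
  out <- apply_modes(m, modes, zero_amps(modes))
  expect_identical(out$x, m$x)
  expect_identical(out$y, m$y)
  expect_identical(out$z, m$z)
})

test_that("compression reduces the core axial extent by exactly its amplitude", {
  m <- full_model()
  modes <- define_modes(m)
  conf <- apply_modes(m, modes, one_mode_amps(modes, "cp_compression", 12))
  cp <- grepl("^cp_", m$group)
  expect_equal(diff(range(conf$z[cp])), diff(range(m$z[cp])) - 12,
               tolerance = 1e-12)
  # unaffected beads are bit-identical
  still <- !m$group %in% c("cp_alpha_distal", "cp_beta_2")
  expect_identical(conf$x[still], m$x[still])
  expect_identical(conf$z[still], m$z[still])
})

test_that("a rotation composed with its inverse recovers the reference", {
  m <- full_model()
  modes <- define_modes(m)
  fwd <- apply_modes(m, modes, one_mode_amps(modes, "lid_rotation", 35))
  # invert by rotating back about the same pivot/axis
  inv_modes <- define_modes(m, modes = list(
    list(name = "back", kind = "rotation", groups = "lid",
         pivot = modes$pivot[[1]], axis = modes$axis[[1]], range = c(-35, 0))))
  back <- apply_modes(fwd, inv_modes, c(back = -35))
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                      as.matrix(m[, c("x", "y", "z")]))), 1e-9)
})

test_that("rigid transforms preserve intra-group pairwise distances", {
  m <- full_model()
  modes <- define_modes(m)
  conf <- apply_modes(m, modes, c(lid_rotation = 20, lid_tilt = 7,
                                  cp_compression = 5, rpn1_swing = 10))
  for (g in c("lid", "rpn1", "cp_alpha_distal")) {
    before <- dist(as.matrix(m[m$group == g, c("x", "y", "z")][1:10, ]))
    after <- dist(as.matrix(conf[conf$group == g, c("x", "y", "z")][1:10, ]))
    expect_lt(max(abs(before - after)), 1e-9)
  }
})

test_that("amplitudes outside the mode range are rejected, zero is allowed", {
  m <- full_model()
  modes <- define_modes(m)
  expect_error(apply_modes(m, modes, one_mode_amps(modes, "lid_rotation", 40)),
               "outside range")
  expect_error(apply_modes(m, modes, one_mode_amps(modes, "lid_tilt", 2)),
               "outside range")
  expect_silent(apply_modes(m, modes, zero_amps(modes)))
})
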