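test_that("alignment removes global motion and keeps internal motion", {
  m <- full_model()
  modes <- define_modes(m)
  # identical copies -> identical rows
  al <- align_ensemble(list(m, m), m)
  expect_equal(al[1, ], al[2, ])
  # a globally rotated copy aligns back onto the reference
  R <- corelandscape:::rotation_matrix(c(1, 1, 0.5), 23)
  rot <- m
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(3, -4, 7), `+`)
  rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  al2 <- align_ensemble(list(rot), m)
  ref_flat <- as.vector(t(as.matrix(m[, c("x", "y", "z")])))
  expect_lt(max(abs(al2[1, ] - ref_flat)), 1e-6)
  # lid-only motion: anchor rings unmoved, lid moved
  conf <- apply_modes(m, modes, one_mode_amps(modes, "lid_rotation", 20))
  al3 <- align_ensemble(list(conf), m)
  dev <- matrix(al3[1, ] - ref_flat, ncol = 3, byrow = TRUE)
  anchor <- m$group %in% c("cp_alpha_proximal", "cp_beta_1")
  expect_lt(sqrt(mean(rowSums(dev[anchor, ]^2))), 1e-6)
  expect_gt(sqrt(mean(rowSums(dev[m$group == "lid", ]^2))), 1)
})

test_that("alignment rejects mismatched conformers", {
  m <- full_model()
  bad <- m[-1, ]
  expect_error(align_ensemble(list(bad), m), "do not match")
})

test_that("principal modes recover constructed variance structure", {
  m <- full_model()
  modes <- define_modes(m)
  # single translation mode -> essentially all variance on PC1
  amps <- seq(1, 25, length.out = 9)
  confs <- lapply(amps, function(a)
    apply_modes(m, modes, one_mode_amps(modes, "rpn1_swing", a)))
  pm <- principal_modes(align_ensemble(confs, m), k = 2)
  expect_gt(pm$all_variances[1] / pm$total_variance, 0.999)
  # two orthogonal translation modes of unequal amplitude, ordered
  confs2 <- list()
  for (a in c(0, 12.5, 25)) for (b in c(0, 3, 6)) {
    confs2[[length(confs2) + 1]] <- apply_modes(
      m, modes, c(lid_rotation = 0, lid_tilt = 0, cp_compression = b,
                  rpn1_swing = a))
  }
  pm2 <- principal_modes(align_ensemble(confs2, m), k = 3)
  expect_gt(pm2$all_variances[1], pm2$all_variances[2])
  expect_gt(pm2$all_variances[2], 10 * pm2$all_variances[3])
  # identical conformers -> zero variance
  pm0 <- principal_modes(align_ensemble(list(m, m, m), m), k = 2)
  expect_equal(pm0$total_variance, 0, tolerance = 1e-12)
  expect_error(principal_modes(align_ensemble(list(m), m), k = 1), "at least 2")
})

test_that("full-rank projections reconstruct the centred data", {
  m <- full_model()
  modes <- define_modes(m)
  confs <- lapply(1:5, function(i)
    apply_modes(m, modes, c(lid_rotation = 3 * i, lid_tilt = 0,
                            cp_compression = i, rpn1_swing = i)))
  al <- align_ensemble(confs, m)
  k <- nrow(al) - 1L
  pm <- principal_modes(al, k = k)
  recon <- pm$projections %*% t(pm$modes)
  centred <- sweep(al, 2, pm$center)
  expect_lt(max(abs(recon - centred)), 1e-6)
})

test_that("rigid decomposition recovers constructed motions exactly", {
  m <- full_model()
  modes <- define_modes(m)
  # identity
  d0 <- decompose_rigid_motion(m, m, "lid")
  expect_equal(d0$rotation_angle, 0)
  expect_equal(d0$max_displacement, 0)
  # 35 degree lid rotation about the construction pivot
  conf <- apply_modes(m, modes, one_mode_amps(modes, "lid_rotation", 35))
  d1 <- decompose_rigid_motion(m, conf, "lid")
  expect_equal(d1$rotation_angle, 35, tolerance = 1e-6)
  expect_equal(abs(d1$rotation_axis[[1]][3]), 1, tolerance = 1e-9)
  # pivot lies on the construction axis (x = y = 0)
  expect_lt(sqrt(sum(d1$pivot[[1]][1:2]^2)), 1e-6)
  # 25 A translation of RPN1
  conf2 <- apply_modes(m, modes, one_mode_amps(modes, "rpn1_swing", 25))
  d2 <- decompose_rigid_motion(m, conf2, "rpn1")
  expect_equal(d2$max_displacement, 25, tolerance = 1e-9)
  expect_equal(abs(d2$translation_along_axis), 25, tolerance = 1e-9)
})

test_that("decomposition round-trips random constructed screws", {
  m <- full_model()
  set.seed(123)
  for (i in 1:8) {
    axis <- corelandscape:::unit_vec(rnorm(3))
    pivot <- runif(3, -20, 20)
    angle <- runif(1, 2, 170)
    custom <- define_modes(m, modes = list(
      list(name = "probe", kind = "rotation", groups = "lid",
           pivot = pivot, axis = axis, range = c(0, 180))))
    conf <- apply_modes(m, custom, c(probe = angle))
    d <- decompose_rigid_motion(m, conf, "lid")
    expect_equal(d$rotation_angle, angle, tolerance = 1e-6)
    expect_equal(abs(sum(d$rotation_axis[[1]] * axis)), 1, tolerance = 1e-9)
  }
})

test_that("recovered angle is invariant under a shared global motion", {
  m <- full_model()
  modes <- define_modes(m)
  conf <- apply_modes(m, modes, one_mode_amps(modes, "lid_rotation", 17))
  R <- corelandscape:::rotation_matrix(c(0.3, -1, 0.2), 41)
  shift <- c(5, 6, -7)
  move <- function(mod) {
    xyz <- sweep(as.matrix(mod[, c("x", "y", "z")]) %*% t(R), 2, shift, `+`)
    mod$x <- xyz[, 1]; mod$y <- xyz[, 2]; mod$z <- xyz[, 3]
    mod
  }
  d <- decompose_rigid_motion(move(m), move(conf), "lid")
  expect_equal(d$rotation_angle, 17, tolerance = 1e-6)
})

test_that("degenerate groups are rejected", {
  m <- full_model()
  expect_error(decompose_rigid_motion(m, m, "rpn11_marker"), "degenerate")
  expect_error(decompose_rigid_motion(m, m, "no_such_group"), "not found")
})

test_that("mode taxonomy classifies the four archetypes", {
  m <- full_model()
  modes <- define_modes(m)
  classify_of <- function(name, amp, group) {
    conf <- apply_modes(m, modes, one_mode_amps(modes, name, amp))
    classify_mode(decompose_rigid_motion(m, conf, group))
  }
  expect_equal(classify_of("lid_rotation", 35, "lid"), "rotation")
  expect_equal(classify_of("lid_tilt", 10, "lid"), "tilt")
  expect_equal(classify_of("cp_compression", 12, "cp_alpha_distal"), "compression")
  expect_equal(classify_of("rpn1_swing", 25, "rpn1"), "translation")
  expect_equal(classify_mode(decompose_rigid_motion(m, m, "lid")), "none")
})
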