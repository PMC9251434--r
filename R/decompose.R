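#' Superpose an ensemble of conformers onto a reference
#'
#' Least-squares (Kabsch) superposition of each conformer onto the
#' reference using only the anchor group's beads, the usual prerequisite
#' for a principal-component analysis of the remaining motion. The default
#' anchor is the proximal half of the core barrel (the two rings closest
#' to the regulatory particle), so all reported motion is relative to that
#' anchor.
#'
#' @param conformers list of `bead_model`s sharing bead ids/groups with
#'   `reference`.
#' @param reference a `bead_model`.
#' @param anchor_group character; group label(s) used for the fit.
#' @return numeric matrix, one row per conformer, `3 * n_beads` columns
#'   (x1, y1, z1, x2, ...); bead ids stored in attribute `"bead_id"`.
#' @export
align_ensemble <- function(conformers, reference,
                           anchor_group = c("cp_alpha_proximal", "cp_beta_1")) {
  stopifnot(inherits(reference, "bead_model"), length(conformers) >= 1L)
  ref_xyz <- bead_coords(reference)
  anchor <- reference$group %in% anchor_group
  if (sum(anchor) < 3L) stop("anchor group has fewer than 3 beads", call. = FALSE)
  rows <- lapply(conformers, function(cf) {
    if (!identical(cf$bead_id, reference$bead_id) ||
        !identical(cf$group, reference$group)) {
      stop("conformer bead ids/groups do not match the reference", call. = FALSE)
    }
    xyz <- bead_coords(cf)
    fit <- kabsch(xyz[anchor, , drop = FALSE], ref_xyz[anchor, , drop = FALSE])
    aligned <- xyz %*% t(fit$R)
    aligned <- sweep(aligned, 2, fit$t, `+`)
    as.vector(t(aligned))
  })
  out <- do.call(rbind, rows)
  attr(out, "bead_id") <- reference$bead_id
  out
}

#' Principal modes of an aligned ensemble
#'
#' Mean-centred principal-component decomposition of the flattened
#' coordinate matrix (exact SVD; no randomised solver). Variances are
#' non-increasing and projections reproduce the centred data exactly at
#' full rank.
#'
#' @param aligned matrix from [align_ensemble()] (n conformers x 3m).
#' @param k number of components to keep.
#' @return object of class `principal_modes`: list with `modes` (3m x k),
#'   `variances` (length k), `projections` (n x k tibble-compatible
#'   matrix), `center`, `total_variance`.
#' @export
principal_modes <- function(aligned, k = 2L) {
  stopifnot(is.matrix(aligned))
  n <- nrow(aligned)
  if (n < 2L) stop("need at least 2 conformers for a decomposition", call. = FALSE)
  k <- as.integer(k)
  if (k > min(n - 1L, ncol(aligned))) stop("`k` exceeds the available rank", call. = FALSE)
  pc <- stats::prcomp(aligned, center = TRUE, scale. = FALSE)
  structure(
    list(modes = pc$rotation[, seq_len(k), drop = FALSE],
         variances = pc$sdev[seq_len(k)]^2,
         all_variances = pc$sdev^2,
         projections = pc$x[, seq_len(k), drop = FALSE],
         center = pc$center,
         total_variance = sum(pc$sdev^2)),
    class = "principal_modes"
  )
}

#' Decompose the motion of a group between two conformers
#'
#' Finds the optimal rigid transform carrying the group's beads in
#' `reference` onto those in `moved` (Kabsch), then expresses it as a
#' screw motion: rotation angle, rotation axis, translation along the
#' axis, and the pivot -- the point of the screw axis closest to the group
#' centroid, the unique stable representative of that line. Constructed
#' rigid motions are recovered exactly (to numerical precision).
#'
#' For (near-)pure translations the rotation axis is undefined; the
#' reported axis is then the direction of translation and
#' `translation_along_axis` its full magnitude.
#'
#' @param reference,moved `bead_model`s with identical bead ids.
#' @param group label of the group to analyse.
#' @return one-row tibble of class `rigid_motion`: `group`,
#'   `rotation_angle` (degrees, in \[0, 180\]), `rotation_axis` (list,
#'   unit 3-vector), `pivot` (list), `translation_along_axis` (A),
#'   `max_displacement` (A).
#' @export
decompose_rigid_motion <- function(reference, moved, group) {
  stopifnot(inherits(reference, "bead_model"), inherits(moved, "bead_model"))
  r <- reference[reference$group == group, ]
  m <- moved[moved$group == group, ]
  if (nrow(r) == 0L) stop(sprintf("group '%s' not found", group), call. = FALSE)
  if (!identical(r$bead_id, m$bead_id)) {
    stop("bead ids differ between reference and moved", call. = FALSE)
  }
  X0 <- as.matrix(r[, c("x", "y", "z")])
  X1 <- as.matrix(m[, c("x", "y", "z")])
  if (nrow(X0) >= 3L) {
    sv <- svd(sweep(X0, 2, colMeans(X0)))
    if (sum(sv$d > 1e-9 * max(sv$d)) < 2L) {
      stop("degenerate geometry: group beads are collinear", call. = FALSE)
    }
  } else {
    stop("degenerate geometry: group needs at least 3 non-collinear beads", call. = FALSE)
  }
  disp <- X1 - X0
  max_disp <- sqrt(max(rowSums(disp^2)))
  fit <- kabsch(X0, X1)      # X1 ~= X0 R^T + t
  aa <- rotation_axis_angle(fit$R)
  centroid <- colMeans(X0)
  if (aa$angle < 1e-4) {
    # numerically a pure translation: the screw axis degenerates to the
    # translation direction and the pivot to the group centroid
    tmag <- vec_norm(fit$t)
    axis <- if (tmag > 1e-12) unit_vec(fit$t) else c(0, 0, 1)
    return(new_rigid_motion(group, aa$angle, axis, centroid, tmag, max_disp))
  }
  u <- aa$axis
  d <- sum(u * fit$t)
  # pivot: least-squares solution of (I - R) p = t - d u in the plane
  # perpendicular to u (rank-2 system; solved via SVD pseudo-inverse)
  Amat <- diag(3) - fit$R
  rhs <- fit$t - d * u
  sv <- svd(Amat)
  inv_d <- ifelse(sv$d > 1e-8 * max(sv$d), 1 / sv$d, 0)
  p <- as.vector(sv$v %*% (inv_d * crossprod(sv$u, rhs)))
  # representative point on the axis line closest to the group centroid
  p <- p + sum((centroid - p) * u) * u
  new_rigid_motion(group, aa$angle, u, p, d, max_disp)
}

new_rigid_motion <- function(group, angle, axis, pivot, d, max_disp) {
  structure(
    tibble::tibble(
      group = group,
      rotation_angle = angle,
      rotation_axis = list(axis),
      pivot = list(pivot),
      translation_along_axis = d,
      max_displacement = max_disp
    ),
    class = c("rigid_motion", class(tibble::tibble()))
  )
}

#' Classify a motion descriptor
#'
#' Labels a rigid-motion descriptor using fixed taxonomy cut-offs:
#' rotations and tilts require at least 2 degrees of rotation, with the
#' axis within 15 degrees of the barrel axis (rotation) or at least 75
#' degrees away (tilt); a compression is a near-pure translation
#' anti-parallel (within 15 degrees) to the barrel axis acting on a core
#' ring group; any other motion of at least 0.5 A is a translation, or
#' mixed when rotation and off-axis translation combine. Sub-threshold
#' motion is labelled `"none"`.
#'
#' @param descriptor a `rigid_motion` (one row).
#' @param barrel_axis unit 3-vector (default +z).
#' @return character label: rotation, tilt, translation, compression,
#'   mixed, or none.
#' @export
classify_mode <- function(descriptor, barrel_axis = c(0, 0, 1)) {
  stopifnot(inherits(descriptor, "rigid_motion"), nrow(descriptor) == 1L)
  ang <- descriptor$rotation_angle
  axis <- descriptor$rotation_axis[[1]]
  d <- descriptor$translation_along_axis
  max_disp <- descriptor$max_displacement
  if (!all(is.finite(c(ang, axis, d, max_disp)))) stop("descriptor is not finite", call. = FALSE)
  if (ang >= 2) {
    ax_dev <- axis_angle_between(axis, barrel_axis)
    if (ax_dev <= 15) return("rotation")
    if (ax_dev >= 75) return("tilt")
    return("mixed")
  }
  # negligible rotation: translation-dominated motion
  if (max_disp < 0.5) return("none")
  tvec <- d * axis
  is_cp <- grepl("^cp_", descriptor$group)
  if (is_cp && vec_norm(tvec) >= 0.5 &&
      angle_between(tvec, -barrel_axis) <= 15) {
    return("compression")
  }
  "translation"
}
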