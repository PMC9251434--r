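# Internal linear-algebra helpers shared by the assembly builder and the
# rigid-motion decomposition. Vectors are plain numeric length-3; all
# lengths in Angstrom, all angles in degrees at the API surface.

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle_deg`
#' degrees about the (unit) `axis`.
#'
#' @param axis numeric length-3, need not be normalised.
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle (degrees, in [0, 180]) between two 3-vectors.
angle_between <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

# Undirected version: treats v and -v as the same axis; result in [0, 90].
axis_angle_between <- function(a, b) {
  ang <- angle_between(a, b)
  min(ang, 180 - ang)
}

# Kabsch: optimal proper rotation R and translation t such that
# moved ~= ref %*% t(R) + t (row-vector convention). Returns list(R, t).
kabsch <- function(ref, moved) {
  stopifnot(nrow(ref) == nrow(moved), ncol(ref) == 3L, ncol(moved) == 3L)
  c0 <- colMeans(ref)
  c1 <- colMeans(moved)
  H <- crossprod(sweep(ref, 2, c0), sweep(moved, 2, c1))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- c1 - as.vector(R %*% c0)
  list(R = R, t = t)
}

# Axis (unit vector) and angle (degrees) of a rotation matrix.
# For angles near 0 the axis is ill-defined; returns c(0,0,1) by convention.
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2)))
  if (ang < 1e-12) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(ang - pi) < 1e-6) {
    # near 180 degrees: axis from the eigenvector of eigenvalue +1
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, i])
    return(list(axis = unit_vec(ax), angle = rad2deg(ang)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  list(axis = unit_vec(ax), angle = rad2deg(ang))
}
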