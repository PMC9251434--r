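#' Configuration for the reference barrel assembly
#'
#' Collects the geometric parameters of the coarse-grained surrogate
#' assembly: a four-ring barrel core (two outer alpha rings, two inner beta
#' rings) closed by caps, an optional annular gate in the distal (non
#' regulatory-particle) cap, optional elliptical wall pores, and a
#' regulatory particle (lid, ATPase base, RPN1 cluster, RPN11 marker)
#' attached at the proximal face (low z). The barrel axis is +z.
#'
#' Defaults place the construction at a coarse-grained proteasome-like
#' scale: outer radius 55 A, ring spacing 15 A (barrel height 60 A), wall
#' thickness 10 A, bead radius 2.5 A. These produce gates and drilled
#' pores in the 4-17 A measurement regime of interest.
#'
#' @param outer_radius barrel outer radius in Angstrom.
#' @param ring_spacing axial height of each of the four core rings (A).
#' @param wall_thickness radial wall thickness (A), measured between the
#'   inner and outer bead surfaces.
#' @param bead_radius radius of every bead (A).
#' @param wall_bead_spacing lattice spacing of wall/cap beads (A). Must be
#'   small enough that the shell is watertight to a probe-inflated bead
#'   surface; values below `2 * (bead_radius + probe_radius) / sqrt(2)` are
#'   safe.
#' @param gate_diameter inner diameter (A) of the annular gate in the
#'   distal cap; 0 builds a fully closed cap.
#' @param pores list of wall-pore specifications, each a list with fields
#'   `azimuth_deg`, `z` (channel centre height, A), `d_long` and `d_short`
#'   (full ellipse axes of the free channel, A; equal values drill a
#'   circular channel). The long axis runs along the barrel axis.
#' @param probe_radius solvent probe radius (A) assumed when offsetting the
#'   free gate/pore boundary from bead centres; keep equal to the probe
#'   used at measurement time.
#' @param include_rp logical; attach the regulatory-particle groups (lid,
#'   base, RPN1, RPN11 marker) at the proximal face.
#' @param residue_seed integer seed for the deterministic pseudo-residue
#'   decoration.
#' @return a list of class `assembly_config`.
#' @export
#' @examples
#' cfg <- assembly_config(gate_diameter = 14)
#' model <- build_assembly(cfg)
#' dplyr::count(model, group)
assembly_config <- function(outer_radius = 55,
                            ring_spacing = 15,
                            wall_thickness = 10,
                            bead_radius = 2.5,
                            wall_bead_spacing = 2.5,
                            gate_diameter = 0,
                            pores = list(),
                            probe_radius = 1.4,
                            include_rp = TRUE,
                            residue_seed = 20220311) {
  cfg <- list(
    outer_radius = outer_radius, ring_spacing = ring_spacing,
    wall_thickness = wall_thickness, bead_radius = bead_radius,
    wall_bead_spacing = wall_bead_spacing, gate_diameter = gate_diameter,
    pores = pores, probe_radius = probe_radius, include_rp = include_rp,
    residue_seed = residue_seed
  )
  class(cfg) <- "assembly_config"
  problems <- validate_assembly_config(cfg)
  if (length(problems)) {
    stop("invalid assembly configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

validate_assembly_config <- function(cfg) {
  p <- character()
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      p <<- c(p, sprintf("`%s` must be a single positive number", field))
    }
  }
  for (f in c("outer_radius", "ring_spacing", "wall_thickness",
              "bead_radius", "wall_bead_spacing")) num_pos(f)
  for (f in c("gate_diameter", "probe_radius")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      p <- c(p, sprintf("`%s` must be a single non-negative number", f))
    }
  }
  if (is.numeric(cfg$wall_thickness) && is.numeric(cfg$bead_radius) &&
      length(cfg$wall_thickness) == 1L && length(cfg$bead_radius) == 1L &&
      cfg$wall_thickness < 2 * cfg$bead_radius) {
    p <- c(p, "non-physical geometry: `wall_thickness` thinner than one bead diameter")
  }
  if (is.numeric(cfg$outer_radius) && is.numeric(cfg$wall_thickness) &&
      is.numeric(cfg$gate_diameter) && length(cfg$gate_diameter) == 1L &&
      cfg$gate_diameter > 0 &&
      cfg$gate_diameter / 2 >= cfg$outer_radius - cfg$wall_thickness) {
    p <- c(p, "`gate_diameter` must fit inside the barrel lumen")
  }
  for (i in seq_along(cfg$pores)) {
    pr <- cfg$pores[[i]]
    need <- c("azimuth_deg", "z", "d_long", "d_short")
    if (!is.list(pr) || !all(need %in% names(pr))) {
      p <- c(p, sprintf("pore %d must list azimuth_deg, z, d_long, d_short", i))
      next
    }
    if (pr$d_long <= 0 || pr$d_short <= 0 || pr$d_short > pr$d_long) {
      p <- c(p, sprintf("pore %d: need 0 < d_short <= d_long", i))
    }
  }
  p
}

CP_GROUPS <- c("cp_alpha_proximal", "cp_beta_1", "cp_beta_2", "cp_alpha_distal")
ALL_GROUPS <- c(CP_GROUPS, "lid", "base_atpase", "rpn1", "rpn11_marker")

# A circle of beads at radius r, height z; bead count forced to a multiple
# of seven so each ring is invariant under a 2*pi/7 rotation.
ring_of_beads <- function(r, z, spacing, min_mult = 1L) {
  if (r < 1e-9) {
    return(data.frame(x = 0, y = 0, z = z))
  }
  n <- 7L * max(min_mult, as.integer(round(2 * pi * r / (7 * spacing))))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(x = r * cos(ang), y = r * sin(ang), z = z)
}

# Dense ring used for gate/pore rims: arc spacing `spacing`, still a
# multiple of seven beads.
dense_ring <- function(r, z, spacing = 1.2) {
  n <- 7L * max(1L, as.integer(ceiling(2 * pi * r / (7 * spacing))))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(x = r * cos(ang), y = r * sin(ang), z = z)
}

# Flat cap disc: concentric rings up to r_max (plus a centre bead).
cap_disc <- function(r_max, z, spacing) {
  radii <- seq(0, r_max, by = spacing)
  do.call(rbind, lapply(radii, ring_of_beads, z = z, spacing = spacing))
}

build_wall <- function(cfg) {
  H <- 4 * cfg$ring_spacing
  r_out_layer <- cfg$outer_radius - cfg$bead_radius
  r_in_layer <- cfg$outer_radius - cfg$wall_thickness + cfg$bead_radius
  nz <- as.integer(round(H / cfg$wall_bead_spacing)) + 1L
  zs <- seq(0, H, length.out = nz)
  rows <- lapply(zs, function(z) {
    rbind(ring_of_beads(r_in_layer, z, cfg$wall_bead_spacing),
          ring_of_beads(r_out_layer, z, cfg$wall_bead_spacing))
  })
  do.call(rbind, rows)
}

# Ring group of a core bead from its height (caps belong to their alpha ring).
cp_group_of_z <- function(z, ring_spacing) {
  H <- 4 * ring_spacing
  idx <- pmin(3L, pmax(0L, as.integer(floor(z / ring_spacing + 1e-9))))
  idx[z >= H - 1e-9] <- 3L
  CP_GROUPS[idx + 1L]
}

# Offset distance from a free opening boundary to the rim bead centres.
rim_offset <- function(cfg) cfg$bead_radius + cfg$probe_radius

drill_test <- function(xyz, pore, cfg) {
  # TRUE for beads inside the (slightly enlarged) elliptical prism of the
  # drilled channel; the prism axis is the radial ray at (azimuth, z).
  phi <- deg2rad(pore$azimuth_deg)
  off <- rim_offset(cfg)
  a <- pore$d_long / 2 + off   # semi-axis along the barrel axis
  b <- pore$d_short / 2 + off  # semi-axis along the tangential direction
  dz <- xyz[, 3] - pore$z
  dtan <- -xyz[, 1] * sin(phi) + xyz[, 2] * cos(phi)
  radial <- xyz[, 1] * cos(phi) + xyz[, 2] * sin(phi)
  inside <- (dz / (a + 1.2))^2 + (dtan / (b + 1.2))^2 < 1
  inside & radial > 0
}

pore_rim_beads <- function(pore, cfg) {
  phi <- deg2rad(pore$azimuth_deg)
  off <- rim_offset(cfg)
  a <- pore$d_long / 2 + off
  b <- pore$d_short / 2 + off
  # ellipse perimeter sampled at ~1.1 A arc spacing
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  n_psi <- max(12L, as.integer(ceiling(per / 1.1)))
  psi <- 2 * pi * (seq_len(n_psi) - 1L) / n_psi
  dz <- a * cos(psi)
  dtan <- b * sin(psi)
  r_in <- cfg$outer_radius - cfg$wall_thickness + 1
  r_out <- cfg$outer_radius - 1
  ts <- seq(r_in, r_out, length.out = max(2L, ceiling((r_out - r_in) / 1.5) + 1L))
  grid <- expand.grid(i = seq_len(n_psi), t = ts)
  data.frame(
    x = grid$t * cos(phi) - dtan[grid$i] * sin(phi),
    y = grid$t * sin(phi) + dtan[grid$i] * cos(phi),
    z = pore$z + dz[grid$i]
  )
}

build_rp <- function(cfg) {
  R <- cfg$outer_radius
  H <- 4 * cfg$ring_spacing
  s <- cfg$wall_bead_spacing
  base <- rbind(ring_of_beads(0.50 * R, -0.10 * H, s),
                ring_of_beads(0.46 * R, -0.18 * H, s))
  lid <- rbind(ring_of_beads(0.65 * R, -0.30 * H, s),
               ring_of_beads(0.40 * R, -0.37 * H, s),
               ring_of_beads(0.20 * R, -0.40 * H, s))
  marker <- data.frame(x = 0, y = 0, z = -0.33 * H)
  # small off-axis cluster, free to swing
  th <- seq(0, 2 * pi, length.out = 12L)[-12L]
  rpn1 <- data.frame(
    x = 0.90 * R + 4 * cos(th),
    y = 4 * sin(th) * 0.8,
    z = -0.25 * H + 3 * sin(2 * th)
  )
  rpn1 <- rbind(rpn1, data.frame(x = 0.90 * R, y = 0, z = -0.25 * H))
  list(base_atpase = base, lid = lid, rpn11_marker = marker, rpn1 = rpn1)
}

#' Build the reference coarse-grained assembly
#'
#' Constructs the bead model described by an [assembly_config()]: a closed
#' four-ring barrel wall with caps, an optional annular distal gate,
#' optional elliptical wall pores (each drilled as a prism through the wall
#' and lined with rim beads so the free channel has exactly the requested
#' axes), and the regulatory-particle groups. With no pores and gate
#' diameter 0 the shell has no solvent path between interior and exterior.
#'
#' @param config an [assembly_config()].
#' @return a tibble of class `bead_model` with columns `bead_id`, `group`,
#'   `x`, `y`, `z`, `radius`, `pseudo_residue`, carrying the configuration
#'   and the barrel axis as attributes.
#' @export
build_assembly <- function(config) {
  stopifnot(inherits(config, "assembly_config"))
  cfg <- config
  H <- 4 * cfg$ring_spacing

  wall <- build_wall(cfg)
  wall$group <- cp_group_of_z(wall$z, cfg$ring_spacing)

  cap_r_max <- cfg$outer_radius - cfg$wall_thickness
  prox_cap <- cap_disc(cap_r_max, 0, cfg$wall_bead_spacing)
  prox_cap$group <- "cp_alpha_proximal"
  dist_cap <- cap_disc(cap_r_max, H, cfg$wall_bead_spacing)
  dist_cap$group <- "cp_alpha_distal"

  if (cfg$gate_diameter > 0) {
    r_rim <- cfg$gate_diameter / 2 + rim_offset(cfg)
    keep <- sqrt(dist_cap$x^2 + dist_cap$y^2) >= r_rim - 1e-9
    dist_cap <- dist_cap[keep, , drop = FALSE]
    rim <- dense_ring(r_rim, H)
    rim$group <- "cp_alpha_distal"
    dist_cap <- rbind(dist_cap, rim)
  }

  core <- rbind(wall, prox_cap, dist_cap)

  for (pore in cfg$pores) {
    xyz <- as.matrix(core[, c("x", "y", "z")])
    core <- core[!drill_test(xyz, pore, cfg), , drop = FALSE]
    rimb <- pore_rim_beads(pore, cfg)
    rimb$group <- cp_group_of_z(rimb$z, cfg$ring_spacing)
    core <- rbind(core, rimb)
  }

  parts <- list(core = core)
  if (cfg$include_rp) {
    rp <- build_rp(cfg)
    for (g in names(rp)) {
      rp[[g]]$group <- g
    }
    parts <- c(parts, rp)
  }
  beads <- do.call(rbind, parts)

  beads <- tibble::tibble(
    bead_id = seq_len(nrow(beads)),
    group = beads$group,
    x = beads$x, y = beads$y, z = beads$z,
    radius = cfg$bead_radius,
    pseudo_residue = sample_pseudo_residues(nrow(beads), cfg$residue_seed)
  )
  new_bead_model(beads, cfg)
}

#' Coerce a bead table to a `bead_model`
#'
#' @param beads data frame with columns `bead_id`, `group`, `x`, `y`, `z`,
#'   `radius`, `pseudo_residue` (e.g. a conformer from [read_ensemble()]).
#' @param config optional `assembly_config` to attach.
#' @return a `bead_model` tibble.
#' @export
as_bead_model <- function(beads, config = NULL) {
  need <- c("bead_id", "group", "x", "y", "z", "radius", "pseudo_residue")
  if (!all(need %in% names(beads))) {
    stop("bead table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  new_bead_model(tibble::as_tibble(beads)[, need], config)
}

new_bead_model <- function(beads, cfg) {
  structure(
    tibble::as_tibble(beads),
    config = cfg,
    barrel_axis = c(0, 0, 1),
    class = c("bead_model", class(tibble::tibble()))
  )
}

#' @export
print.bead_model <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<bead_model> %d beads, %d groups, barrel axis +z\n",
              nrow(x), dplyr::n_distinct(x$group)))
  if (!is.null(cfg)) {
    cat(sprintf("  outer radius %.1f A, height %.1f A, gate %.1f A, %d wall pore(s)\n",
                cfg$outer_radius, 4 * cfg$ring_spacing, cfg$gate_diameter,
                length(cfg$pores)))
  }
  NextMethod()
}

bead_coords <- function(model, groups = NULL) {
  if (!is.null(groups)) model <- model[model$group %in% groups, ]
  as.matrix(model[, c("x", "y", "z")])
}

barrel_axis_of <- function(model) {
  ax <- attr(model, "barrel_axis")
  if (is.null(ax)) c(0, 0, 1) else ax
}
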