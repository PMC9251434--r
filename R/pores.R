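# Grid-based pore detection on a bead model. The reference assembly is a
# closed barrel whose wall pores are narrow channels; detection works on a
# probe-inflated occupancy grid, while diameters are refined against the
# exact bead geometry so they converge faster than the voxel size.

#' Rasterize a bead model onto an occupancy grid
#'
#' A voxel is occupied iff its centre lies within `bead radius +
#' probe_radius` of any bead centre. The grid is padded with at least two
#' voxels of solvent on every side.
#'
#' @param structure a `bead_model`.
#' @param spacing voxel edge length in Angstrom (default 0.5).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @return object of class `occupancy_grid`: list with `occupied` (3-D
#'   logical array), `origin` (coordinates of the first voxel centre),
#'   `spacing`, `probe_radius`, and the source `structure`.
#' @export
rasterize_assembly <- function(structure, spacing = 0.5, probe_radius = 1.4) {
  stopifnot(inherits(structure, "bead_model"))
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (probe_radius < 0) stop("`probe_radius` must be >= 0", call. = FALSE)
  if (nrow(structure) > 0 && spacing > 2 * max(structure$radius)) {
    stop("resolution error: `spacing` exceeds the bead diameter", call. = FALSE)
  }
  if (nrow(structure) == 0L) {
    occ <- array(FALSE, dim = c(4L, 4L, 4L))
    return(structure_grid(occ, c(0, 0, 0), spacing, probe_radius, structure))
  }
  xyz <- bead_coords(structure)
  r_eff <- structure$radius + probe_radius
  pad <- max(r_eff) + 3 * spacing
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  occ <- array(FALSE, dim = dims)
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  reach <- as.integer(ceiling(max(r_eff) / spacing))
  offs <- as.matrix(expand.grid(di = -reach:reach, dj = -reach:reach, dk = -reach:reach))
  offs <- offs[rowSums((offs * spacing)^2) <= (max(r_eff) + spacing)^2, , drop = FALSE]
  for (b in seq_len(nrow(xyz))) {
    ctr <- (xyz[b, ] - lo) / spacing + 1  # fractional voxel coordinate
    base <- round(ctr)
    vi <- base[1] + offs[, 1]; vj <- base[2] + offs[, 2]; vk <- base[3] + offs[, 3]
    ok <- vi >= 1L & vi <= dims[1] & vj >= 1L & vj <= dims[2] & vk >= 1L & vk <= dims[3]
    vi <- vi[ok]; vj <- vj[ok]; vk <- vk[ok]
    d2 <- ((vi - ctr[1])^2 + (vj - ctr[2])^2 + (vk - ctr[3])^2) * spacing^2
    hit <- d2 <= r_eff[b]^2
    if (any(hit)) {
      occ[vi[hit] + (vj[hit] - 1L) * n1 + (vk[hit] - 1L) * n12] <- TRUE
    }
  }
  structure_grid(occ, lo, spacing, probe_radius, structure)
}

structure_grid <- function(occ, origin, spacing, probe_radius, model) {
  structure(list(occupied = occ, origin = origin, spacing = spacing,
                 probe_radius = probe_radius, structure = model),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  d <- dim(x$occupied)
  cat(sprintf("<occupancy_grid> %d x %d x %d voxels @ %.2f A, probe %.2f A, %.1f%% occupied\n",
              d[1], d[2], d[3], x$spacing, x$probe_radius,
              100 * mean(x$occupied)))
  invisible(x)
}

voxel_centres <- function(grid, flat) {
  d <- dim(grid$occupied)
  i <- ((flat - 1L) %% d[1]) + 1L
  j <- (((flat - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((flat - 1L) %/% (d[1] * d[2])) + 1L
  cbind(grid$origin[1] + (i - 1L) * grid$spacing,
        grid$origin[2] + (j - 1L) * grid$spacing,
        grid$origin[3] + (k - 1L) * grid$spacing)
}

# 6-neighbour flat indices of a set of flat indices; NA where out of bounds.
flat_neighbours6 <- function(flat, dims) {
  n1 <- dims[1]; n12 <- dims[1] * dims[2]
  i <- ((flat - 1L) %% n1) + 1L
  j <- (((flat - 1L) %/% n1) %% dims[2]) + 1L
  k <- ((flat - 1L) %/% n12) + 1L
  out <- cbind(
    ifelse(i > 1L, flat - 1L, NA_integer_),
    ifelse(i < n1, flat + 1L, NA_integer_),
    ifelse(j > 1L, flat - n1, NA_integer_),
    ifelse(j < dims[2], flat + n1, NA_integer_),
    ifelse(k > 1L, flat - n12, NA_integer_),
    ifelse(k < dims[3], flat + n12, NA_integer_)
  )
  out
}

# Connected components (6-connectivity) of a sparse voxel set given as flat
# indices. Returns an integer component label per input voxel.
sparse_components <- function(flat, dims) {
  n <- length(flat)
  labels <- integer(n)
  if (n == 0L) return(labels)
  nb <- flat_neighbours6(flat, dims)
  nb_pos <- matrix(match(nb, flat), nrow = n)
  comp <- 0L
  for (seed in seq_len(n)) {
    if (labels[seed] != 0L) next
    comp <- comp + 1L
    frontier <- seed
    labels[seed] <- comp
    while (length(frontier)) {
      nxt <- as.vector(nb_pos[frontier, , drop = FALSE])
      nxt <- nxt[!is.na(nxt)]
      nxt <- unique(nxt[labels[nxt] == 0L])
      if (length(nxt)) labels[nxt] <- comp
      frontier <- nxt
    }
  }
  labels
}

# Flood fill over solvent from a seed voxel; returns logical over all voxels
# (TRUE = reachable). Used by tests on small grids to verify shell topology.
flood_solvent <- function(grid, seed_xyz) {
  occ <- grid$occupied
  dims <- dim(occ)
  seed <- as.integer(round((seed_xyz - grid$origin) / grid$spacing)) + 1L
  stopifnot(all(seed >= 1L), all(seed <= dims))
  flat0 <- seed[1] + (seed[2] - 1L) * dims[1] + (seed[3] - 1L) * dims[1] * dims[2]
  if (occ[flat0]) stop("seed voxel is occupied", call. = FALSE)
  reach <- array(FALSE, dim = dims)
  reach[flat0] <- TRUE
  frontier <- flat0
  while (length(frontier)) {
    nb <- as.vector(flat_neighbours6(frontier, dims))
    nb <- nb[!is.na(nb)]
    nb <- unique(nb[!occ[nb] & !reach[nb]])
    if (length(nb)) reach[nb] <- TRUE
    frontier <- nb
  }
  reach
}

# Exact clearance (distance to the probe-inflated bead surface) at points.
clearance_at <- function(pts, xyz, r_eff) {
  apply(pts, 1, function(p) {
    min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2) - r_eff)
  })
}

wall_regions <- function(grid) {
  cfg <- attr(grid$structure, "config")
  if (is.null(cfg)) stop("grid structure carries no assembly configuration", call. = FALSE)
  r_eff <- cfg$bead_radius + grid$probe_radius
  H <- 4 * cfg$ring_spacing
  list(
    r_in = cfg$outer_radius - cfg$wall_thickness,
    r_out = cfg$outer_radius,
    H = H,
    cap_halfwidth = r_eff + 1,
    corridor = max(6, cfg$gate_diameter / 2 + r_eff + 1.5)
  )
}

#' Detect wall pores of a barrel assembly
#'
#' Finds solvent channels that cross the barrel wall (or its caps) and
#' link the interior cavity to the exterior, excluding the axial gate
#' corridor, which is reported separately by [measure_gate()]. Channels
#' are 6-connected solvent components within the wall shell; each
#' detected channel is measured with [measure_pore()]. Pores are ordered
#' by constriction height then azimuth.
#'
#' @param grid an `occupancy_grid` of a `bead_model` built by
#'   [build_assembly()] (the wall geometry is taken from its
#'   configuration).
#' @param barrel_axis unit 3-vector; only +z is supported by the surrogate
#'   geometry.
#' @return tibble of class `pore_set`: columns `pore_id`, `x`, `y`, `z`
#'   (constriction centre), `d_min_A`, `d_max_A`, `releasing`
#'   (`d_min > 7 A`, strict), `n_voxels`, and a list-column `voxels` of
#'   flat grid indices.
#' @export
detect_pores <- function(grid, barrel_axis = c(0, 0, 1)) {
  stopifnot(inherits(grid, "occupancy_grid"))
  geo <- wall_regions(grid)
  occ <- grid$occupied
  dims <- dim(occ)
  solvent <- which(!occ)
  pts <- voxel_centres(grid, solvent)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  z <- pts[, 3]
  in_side <- r >= geo$r_in - 1.5 & r <= geo$r_out + 1.5 & z >= -1.5 & z <= geo$H + 1.5
  in_cap <- r < geo$r_in - 1.5 & r >= geo$corridor &
    (abs(z) <= geo$cap_halfwidth | abs(z - geo$H) <= geo$cap_halfwidth)
  in_wall <- in_side | in_cap
  interior <- !in_wall & r < geo$r_in - 1.5 & r >= 0 &
    z > geo$cap_halfwidth & z < geo$H - geo$cap_halfwidth
  if (!any(interior)) stop("no interior cavity found", call. = FALSE)
  interior_set <- solvent[interior]
  exterior_set <- solvent[!in_wall & !interior &
                            !(r < geo$corridor & z > 0 & z < geo$H)]
  wall_set <- solvent[in_wall]
  empty <- tibble::tibble(
    pore_id = integer(), x = numeric(), y = numeric(), z = numeric(),
    d_min_A = numeric(), d_max_A = numeric(), releasing = logical(),
    n_voxels = integer(), voxels = list()
  )
  class(empty) <- c("pore_set", class(empty))
  if (length(wall_set) == 0L) return(empty)
  labels <- sparse_components(wall_set, dims)
  nbr <- flat_neighbours6(wall_set, dims)
  touches <- function(set) {
    inset <- matrix(nbr %in% set, nrow = length(wall_set))
    rowSums(inset) > 0
  }
  t_in <- touches(interior_set)
  t_out <- touches(exterior_set)
  rows <- list()
  for (cmp in sort(unique(labels))) {
    sel <- labels == cmp
    if (!any(t_in[sel]) || !any(t_out[sel])) next
    vox <- wall_set[sel]
    meas <- measure_pore(list(voxels = vox,
                              entries = wall_set[sel & t_in],
                              exits = wall_set[sel & t_out]), grid)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x = meas$centre[1], y = meas$centre[2], z = meas$centre[3],
      d_min_A = meas$d_min, d_max_A = meas$d_max,
      releasing = meas$d_min > 7,
      n_voxels = length(vox), voxels = list(vox)
    )
  }
  if (length(rows) == 0L) return(empty)
  out <- dplyr::bind_rows(rows)
  az <- atan2(out$y, out$x)
  out <- out[order(round(out$z, 6), round(az, 9)), ]
  out <- dplyr::mutate(out, pore_id = dplyr::row_number(), .before = 1)
  class(out) <- c("pore_set", class(tibble::tibble()))
  out
}

#' Measure a pore's constriction diameters
#'
#' `d_min` is twice the radius of the largest sphere that can pass through
#' the channel (the bottleneck of the widest path from the interior
#' opening to the exterior opening); `d_max` is the longest chord of the
#' constriction cross-section perpendicular to the channel direction.
#' Both are refined against the exact probe-inflated bead geometry, so
#' they are accurate well below the voxel size.
#'
#' @param pore a row of [detect_pores()] output, or a list with fields
#'   `voxels` (flat indices), `entries`, `exits`.
#' @param grid the `occupancy_grid` the pore was detected on.
#' @return list with `d_min`, `d_max`, `centre` (3-vector).
#' @export
measure_pore <- function(pore, grid) {
  if (is.data.frame(pore)) {
    stopifnot(nrow(pore) == 1L)
    pore <- list(voxels = pore$voxels[[1]], entries = NULL, exits = NULL)
  }
  vox <- pore$voxels
  if (length(vox) == 0L) {
    warning("empty channel: below grid resolution; d_min reported as 0")
    return(list(d_min = 0, d_max = 0, centre = c(NA_real_, NA_real_, NA_real_)))
  }
  dims <- dim(grid$occupied)
  pts <- voxel_centres(grid, vox)
  model <- grid$structure
  xyz <- bead_coords(model)
  r_eff <- model$radius + grid$probe_radius
  # restrict to beads near the channel
  lo <- apply(pts, 2, min) - max(r_eff) - 8
  hi <- apply(pts, 2, max) + max(r_eff) + 8
  near <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  bx <- xyz[near, , drop = FALSE]
  br <- r_eff[near]
  cl <- clearance_at(pts, bx, br)
  entries <- pore$entries
  exits <- pore$exits
  if (is.null(entries) || is.null(exits)) {
    # fall back: treat extremes along the channel's radial extent as openings
    rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    entries <- vox[rad <= stats::quantile(rad, 0.05)]
    exits <- vox[rad >= stats::quantile(rad, 0.95)]
  }
  res <- percolation_bottleneck(vox, cl, entries, exits, dims)
  if (is.null(res) || res$threshold <= 0) {
    warning("channel thinner than one voxel; d_min reported as 0")
    ctr <- colMeans(pts)
    return(list(d_min = 0, d_max = 0, centre = ctr))
  }
  ctr0 <- voxel_centres(grid, res$bottleneck)[1, ]
  u <- unit_vec(c(ctr0[1], ctr0[2], 0))  # channel direction: radial
  e1 <- unit_vec(c(-u[2], u[1], 0))
  e2 <- c(0, 0, 1)
  obj <- function(ab) {
    p <- ctr0 + ab[1] * e1 + ab[2] * e2
    -min(sqrt((bx[, 1] - p[1])^2 + (bx[, 2] - p[2])^2 + (bx[, 3] - p[3])^2) - br)
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  refined <- max(res$threshold, -opt$value)
  centre <- ctr0 + opt$par[1] * e1 + opt$par[2] * e2
  d_max <- longest_chord(centre, e1, e2, bx, br)
  list(d_min = 2 * refined, d_max = max(d_max, 2 * refined), centre = centre)
}

# Union-find percolation: activate voxels in decreasing clearance order
# until an interior entry connects to an exterior exit; the clearance of
# the voxel added at that moment is the bottleneck radius.
percolation_bottleneck <- function(vox, cl, entries, exits, dims) {
  n <- length(vox)
  nb_pos <- matrix(match(flat_neighbours6(vox, dims), vox), nrow = n)
  is_entry <- vox %in% entries
  is_exit <- vox %in% exits
  if (!any(is_entry) || !any(is_exit)) return(NULL)
  ord <- order(cl, decreasing = TRUE)
  parent <- seq_len(n)
  has_in <- logical(n); has_out <- logical(n)
  active <- logical(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (v in ord) {
    active[v] <- TRUE
    has_in[v] <- is_entry[v]; has_out[v] <- is_exit[v]
    for (w in nb_pos[v, ]) {
      if (is.na(w) || !active[w]) next
      rv <- find(v); rw <- find(w)
      if (rv != rw) {
        parent[rw] <- rv
        has_in[rv] <- has_in[rv] || has_in[rw]
        has_out[rv] <- has_out[rv] || has_out[rw]
      }
    }
    rv <- find(v)
    if (has_in[rv] && has_out[rv]) {
      return(list(threshold = cl[v], bottleneck = vox[v]))
    }
  }
  NULL
}

# Longest free chord through `centre` in the plane spanned by e1, e2.
longest_chord <- function(centre, e1, e2, bx, br, step = 0.1, max_half = 40) {
  march <- function(dir) {
    t <- 0
    repeat {
      t2 <- t + step
      p <- centre + t2 * dir
      if (min(sqrt((bx[, 1] - p[1])^2 + (bx[, 2] - p[2])^2 +
                   (bx[, 3] - p[3])^2) - br) < 0 || t2 > max_half) {
        return(t)
      }
      t <- t2
    }
  }
  best <- 0
  for (th in seq(0, pi, length.out = 61)[-61]) {
    dir <- cos(th) * e1 + sin(th) * e2
    len <- march(dir) + march(-dir)
    if (len > best) best <- len
  }
  best
}

#' Measure the axial gate diameter
#'
#' Diameter of the largest solvent circle inscribed in the distal-ring
#' plane, centred on the barrel axis: twice the clearance between the
#' axis point in the distal cap plane and the nearest probe-inflated bead
#' surface. Returns 0 when the cap is closed.
#'
#' @param structure a `bead_model`.
#' @param barrel_axis unit 3-vector (only +z supported).
#' @param probe_radius probe radius in Angstrom; defaults to the value in
#'   the assembly configuration.
#' @return gate diameter in Angstrom.
#' @export
measure_gate <- function(structure, barrel_axis = c(0, 0, 1), probe_radius = NULL) {
  stopifnot(inherits(structure, "bead_model"))
  distal <- structure[structure$group == "cp_alpha_distal", ]
  if (nrow(distal) == 0L) stop("distal ring group not present", call. = FALSE)
  cfg <- attr(structure, "config")
  if (is.null(probe_radius)) {
    probe_radius <- if (!is.null(cfg)) cfg$probe_radius else 1.4
  }
  z_plane <- max(distal$z)
  p <- c(0, 0, z_plane)
  xyz <- bead_coords(structure)
  r_eff <- structure$radius + probe_radius
  dz <- xyz[, 3] - z_plane
  near <- abs(dz) < r_eff
  if (!any(near)) return(0)
  d_inplane <- sqrt(xyz[near, 1]^2 + xyz[near, 2]^2)
  cover <- sqrt(pmax(0, r_eff[near]^2 - dz[near]^2))
  clearance <- min(d_inplane - cover)
  max(0, 2 * clearance)
}

#' Characterise pore lining chemistry
#'
#' Lining residues are the pseudo-residues of beads whose surface lies
#' within 4 A of a channel voxel. The net formal charge counts D/E as -1
#' and K/R as +1 at neutral pH (H neutral); hydropathy is the
#' Kyte-Doolittle average; pores with positive mean hydropathy are called
#' hydrophobic, otherwise hydrophilic.
#'
#' @param pores a `pore_set` from [detect_pores()].
#' @param grid the `occupancy_grid` the pores were detected on.
#' @return the pore tibble with columns `n_lining`, `net_charge`,
#'   `mean_hydropathy`, `class` added.
#' @export
characterize_pore <- function(pores, grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  model <- grid$structure
  xyz <- bead_coords(model)
  chem <- purrr::map(pores$voxels, function(vox) {
    pts <- voxel_centres(grid, vox)
    cutoff <- model$radius + 4
    lo <- apply(pts, 2, min) - max(cutoff)
    hi <- apply(pts, 2, max) + max(cutoff)
    near <- which(xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
                    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
                    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3])
    lining <- near[vapply(near, function(b) {
      any((pts[, 1] - xyz[b, 1])^2 + (pts[, 2] - xyz[b, 2])^2 +
            (pts[, 3] - xyz[b, 3])^2 <= cutoff[b]^2)
    }, logical(1))]
    res <- model$pseudo_residue[lining]
    if (length(res) == 0L) {
      warning("pore has no lining residues; chemistry undefined")
      return(tibble::tibble(n_lining = 0L, net_charge = NA_integer_,
                            mean_hydropathy = NA_real_, class = "unknown"))
    }
    charge <- sum(FORMAL_CHARGE[res], na.rm = TRUE)
    hyd <- mean(KD_HYDROPATHY[res])
    tibble::tibble(n_lining = length(res), net_charge = as.integer(charge),
                   mean_hydropathy = hyd,
                   class = if (hyd > 0) "hydrophobic" else "hydrophilic")
  })
  dplyr::bind_cols(pores, dplyr::bind_rows(chem))
}

#' Filter pores by the peptide-release size threshold
#'
#' Keeps pores whose minimal constriction diameter strictly exceeds 7 A --
#' the transverse size of the bulkiest amino-acid side chains (arginine,
#' tryptophan, tyrosine) a released product must push through. A pore at
#' exactly 7 A is excluded.
#'
#' @param pores a pore tibble with a `d_min_A` column.
#' @return the retained subset; the retained count is attached as
#'   attribute `"n_releasing"`.
#' @export
filter_releasing <- function(pores) {
  keep <- pores[pores$d_min_A > 7, , drop = FALSE]
  attr(keep, "n_releasing") <- nrow(keep)
  keep
}
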