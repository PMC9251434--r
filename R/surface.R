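#' Construct a free-energy surface from a grid of energies
#'
#' Wraps a matrix of energies (kT) over two mode coordinates into a
#' sampling-ready surface. Energies are re-referenced so the global
#' minimum is 0. Bin probabilities are proportional to `exp(-E) * area`;
#' when `target_fractions` is given, each watershed basin's probability
#' mass is rescaled to the requested value, which fixes the ground-truth
#' state fractions exactly without touching the well shapes.
#'
#' @param energies numeric matrix (rows = q1 bins, cols = q2 bins); `NA`
#'   or `Inf` marks forbidden bins.
#' @param q1_edges,q2_edges bin edge vectors (length `nrow+1`, `ncol+1`).
#' @param target_fractions optional named numeric summing to 1; names must
#'   match the basin labels (see `basin_labels`).
#' @param basin_labels optional character matrix/vector labelling each bin
#'   with a basin name; if omitted and `target_fractions` is given, basins
#'   are found by watershed and labelled `basin1`, `basin2`, ... in order
#'   of increasing minimum energy.
#' @param axes names of the two coordinates (used in outputs).
#' @return object of class `free_energy_surface`.
#' @export
free_energy_surface <- function(energies, q1_edges, q2_edges,
                                target_fractions = NULL, basin_labels = NULL,
                                axes = c("q1", "q2")) {
  stopifnot(is.matrix(energies),
            length(q1_edges) == nrow(energies) + 1L,
            length(q2_edges) == ncol(energies) + 1L)
  E <- energies
  E[!is.finite(E)] <- NA_real_
  if (all(is.na(E))) stop("surface has no finite bins", call. = FALSE)
  E <- E - min(E, na.rm = TRUE)
  area <- diff(q1_edges) %o% diff(q2_edges)
  w <- exp(-E) * area
  w[is.na(w)] <- 0
  basin <- NULL
  if (!is.null(target_fractions)) {
    if (is.null(basin_labels)) {
      ws <- watershed_labels(E, min_depth = 0.5)
      basin <- matrix(NA_character_, nrow(E), ncol(E))
      basin[!is.na(ws$labels)] <- paste0("basin", ws$labels[!is.na(ws$labels)])
    } else {
      basin <- basin_labels
    }
    if (!setequal(names(target_fractions), unique(stats::na.omit(as.vector(basin))))) {
      stop("`target_fractions` names must match the basin labels", call. = FALSE)
    }
    if (abs(sum(target_fractions) - 1) > 1e-9) {
      stop("`target_fractions` must sum to 1", call. = FALSE)
    }
    for (b in names(target_fractions)) {
      sel <- !is.na(basin) & basin == b
      mass <- sum(w[sel])
      if (mass <= 0) stop(sprintf("basin '%s' carries no probability mass", b), call. = FALSE)
      w[sel] <- w[sel] * target_fractions[[b]] / mass
    }
  }
  prob <- w / sum(w)
  structure(
    list(energies = E, prob = prob,
         bin_edges_q1 = q1_edges, bin_edges_q2 = q2_edges,
         basin = basin, target_fractions = target_fractions, axes = axes),
    class = "free_energy_surface"
  )
}

#' Effective (sampling) energies of a surface
#'
#' The energies actually realised by sampling: `-ln(p_i / p_max)`. They
#' differ from the constructed energies by a per-basin constant whenever
#' basin masses were rescaled to target fractions.
#'
#' @param surface a `free_energy_surface`.
#' @return numeric matrix, minimum 0, `NA` in forbidden bins.
#' @export
effective_energies <- function(surface) {
  p <- surface$prob
  E <- -log(p / max(p))
  E[p <= 0] <- NA_real_
  E
}

# Valley profile along a transition path: linear rise from the well floor
# to a short flat saddle plateau, linear descent to the far well. The
# sharp (piecewise-linear) approach keeps the population of near-saddle
# bins low, so the watershed divide between the flanking basins is
# localised to the plateau. s in [0, 1].
valley_profile <- function(s, saddle, end_depth, rise = c(0.455, 0.545),
                           notch = 0.7) {
  # square-root rise concentrates the wells; the approach tops out `notch`
  # below the plateau so the saddle occupies a single clean grid column
  shoulder <- saddle - notch
  out <- numeric(length(s))
  up <- s < rise[1]
  out[up] <- shoulder * sqrt(s[up] / rise[1])
  mid <- s >= rise[1] & s <= rise[2]
  out[mid] <- saddle
  dn <- s > rise[2]
  u <- (s[dn] - rise[2]) / (1 - rise[2])
  out[dn] <- end_depth + (shoulder - end_depth) * sqrt(1 - u)
  out
}

# Transverse half-width of the valley: wide at the wells, pinched at the
# saddle so the transition corridor is effectively one bin wide.
valley_width <- function(s, w_well, w_saddle, rise = c(0.455, 0.545)) {
  tri <- numeric(length(s))
  up <- s < rise[1]
  tri[up] <- s[up] / rise[1]
  tri[s >= rise[1] & s <= rise[2]] <- 1
  dn <- s > rise[2]
  tri[dn] <- (1 - s[dn]) / (1 - rise[2])
  w_well + (w_saddle - w_well) * tri
}

valley_energy <- function(P1, P2, saddle, end_depth, pts,
                          w_well = 0.6, w_saddle = 0.65) {
  v <- P2 - P1
  L2 <- sum(v^2)
  t <- pmin(1, pmax(0, ((pts[, 1] - P1[1]) * v[1] + (pts[, 2] - P1[2]) * v[2]) / L2))
  px <- P1[1] + t * v[1]
  py <- P1[2] + t * v[2]
  dperp <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
  w <- valley_width(t, w_well, w_saddle)
  valley_profile(t, saddle, end_depth) + (dperp / w)^2
}

#' Default two-basin conformational surface
#'
#' Builds the reference landscape over the two canonical mode coordinates
#' -- q1, lid rotation (degrees) and q2, core compression (Angstrom) --
#' with a resting basin at low rotation/low compression, a rotated basin
#' at high rotation, and a compressed basin at the extreme of the
#' compression coordinate. The two transition valleys (resting->rotated
#' and resting->compressed) carry flat saddle plateaus whose heights are
#' calibrated by a deterministic fixed-point loop so that, after the
#' per-basin mass rescaling to `fractions`, the minimax barrier from the
#' resting basin to each remote basin on the realised (sampling) energy
#' grid equals `saddle` exactly.
#'
#' @param saddle barrier height from the resting basin, kT (default 5.6).
#' @param fractions named probability masses of the three basins
#'   (`resting`, `rotated`, `compressed`); must sum to 1.
#' @param n_bins grid resolution (default 30 x 30).
#' @param q1_range,q2_range coordinate ranges (deg, A).
#' @return a `free_energy_surface` whose `basin` matrix uses the three
#'   state names; attribute `"calibration"` records the fitted plateau
#'   heights and realised barriers.
#' @export
two_basin_surface <- function(saddle = 5.6,
                              fractions = c(resting = 0.58, rotated = 0.35,
                                            compressed = 0.07),
                              n_bins = c(30, 30),
                              q1_range = c(0, 35), q2_range = c(0, 12)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9,
            setequal(names(fractions), c("resting", "rotated", "compressed")))
  e1 <- seq(q1_range[1], q1_range[2], length.out = n_bins[1] + 1L)
  e2 <- seq(q2_range[1], q2_range[2], length.out = n_bins[2] + 1L)
  c1 <- mid_points(e1); c2 <- mid_points(e2)
  bw1 <- diff(e1)[1]; bw2 <- diff(e2)[1]
  # work in bin units so the transverse width is resolution-independent
  pts <- cbind(rep(c1 / bw1, times = length(c2)),
               rep(c2 / bw2, each = length(c1)))
  # snap the designed well centres to bin centres so the peak and saddle
  # populations are not split across neighbouring bins
  snap <- function(q) c(round(q[1] / bw1 - 0.5) + 0.5, round(q[2] / bw2 - 0.5) + 0.5)
  A <- snap(c(4, 1.5))
  B <- snap(c(30, 1.5))
  C <- snap(c(6, 10.5))
  bowl <- function(ctr, depth, wq1, wq2) {
    depth + ((pts[, 1] - ctr[1]) * bw1 / wq1)^2 + ((pts[, 2] - ctr[2]) * bw2 / wq2)^2
  }
  # bins more than `cap` above the floor are treated as unvisited
  # (forbidden), which keeps stray fringe populations from seeding
  # spurious noise basins in the sampled landscape
  cap <- 10
  build <- function(S_ab, S_ac, d_B, d_C) {
    E <- pmin(
      valley_energy(A, B, S_ab, d_B, pts),
      valley_energy(A, C, S_ac, d_C, pts),
      bowl(B, d_B, 3.0, 1.4),
      bowl(C, d_C, 1.3, 0.55)
    )
    E[E > cap] <- NA_real_
    matrix(E, length(c1), length(c2))
  }
  cell_of <- function(P) {
    i <- which.min(abs(c1 / bw1 - P[1])); j <- which.min(abs(c2 / bw2 - P[2]))
    c(i, j)
  }
  label_matrix <- function(E) {
    ws <- watershed_labels(E, min_depth = 0.5)
    lab <- matrix(NA_character_, nrow(E), ncol(E))
    key <- c(resting = ws$labels[t(cell_of(A))],
             rotated = ws$labels[t(cell_of(B))],
             compressed = ws$labels[t(cell_of(C))])
    if (anyNA(key) || anyDuplicated(key)) {
      stop("surface construction failed to separate the three designed basins", call. = FALSE)
    }
    for (nm in names(key)) lab[ws$labels == key[[nm]]] <- nm
    # any residual catchments (there should be none) join the resting basin
    lab[is.na(lab) & !is.na(ws$labels)] <- "resting"
    lab
  }
  realised_barriers <- function(surf) {
    Eef <- effective_energies(surf)
    cellA <- cell_of(A); cellB <- cell_of(B); cellC <- cell_of(C)
    n1 <- nrow(Eef)
    idx <- function(cell) cell[1] + (cell[2] - 1L) * n1
    # minima may have shifted by the rescale; descend to the local minimum
    refine <- function(cell) {
      repeat {
        nb <- rbind(cell, neighbours8(cell[1], cell[2], nrow(Eef), ncol(Eef)))
        vals <- Eef[cbind(nb[, 1], nb[, 2])]
        k <- which.min(vals)
        if (k == 1L) return(cell)
        cell <- nb[k, ]
      }
    }
    cellA <- refine(cellA); cellB <- refine(cellB); cellC <- refine(cellC)
    vab <- bottleneck_value(Eef, idx(cellA), idx(cellB))$value
    vac <- bottleneck_value(Eef, idx(cellA), idx(cellC))$value
    c(ab = vab - Eef[t(cellA)], ac = vac - Eef[t(cellA)])
  }
  S_ab <- saddle; S_ac <- saddle
  d_B <- 0.4; d_C <- 0.8
  surf <- NULL
  make_surf <- function(E, lab) {
    free_energy_surface(E, e1, e2, target_fractions = fractions,
                        basin_labels = lab,
                        axes = c("lid_rotation_deg", "compression_A"))
  }
  for (iter in 1:20) {
    E <- build(S_ab, S_ac, d_B, d_C)
    lab <- label_matrix(E)
    # balance the remote well depths so each basin's natural mass matches
    # its target: then the per-basin rescaling is a near-identity and the
    # effective (sampling) surface keeps the designed well/saddle shape
    mass <- vapply(c("resting", "rotated", "compressed"), function(b) {
      sum(exp(-E[!is.na(lab) & lab == b]))
    }, numeric(1))
    adj_B <- log((mass[["rotated"]] / mass[["resting"]]) /
                   (fractions[["rotated"]] / fractions[["resting"]]))
    adj_C <- log((mass[["compressed"]] / mass[["resting"]]) /
                   (fractions[["compressed"]] / fractions[["resting"]]))
    d_B <- d_B + adj_B
    d_C <- d_C + adj_C
    E <- build(S_ab, S_ac, d_B, d_C)
    lab <- label_matrix(E)
    # basin ground truth must be the watershed of the surface particles are
    # actually drawn from; iterate the labels on the effective energies
    # until they are self-consistent
    for (k in 1:10) {
      surf <- make_surf(E, lab)
      lab2 <- label_matrix(effective_energies(surf))
      if (identical(lab2, lab)) break
      lab <- lab2
    }
    surf <- make_surf(E, lab)
    bar <- realised_barriers(surf)
    err <- c(saddle - bar[["ab"]], saddle - bar[["ac"]])
    if (max(abs(err)) < 1e-10 && max(abs(c(adj_B, adj_C))) < 1e-10) break
    S_ab <- S_ab + err[1]
    S_ac <- S_ac + err[2]
  }
  attr(surf, "calibration") <- list(plateau_ab = S_ab, plateau_ac = S_ac,
                                    well_depths = c(rotated = d_B, compressed = d_C),
                                    realised = realised_barriers(surf),
                                    saddle_target = saddle)
  surf
}

#' Sample a particle ensemble from a free-energy surface
#'
#' Draws bins with probability proportional to `exp(-E) * area` (after any
#' per-basin rescaling encoded in the surface), then places each particle
#' uniformly within its bin. The two nuisance modes (lid tilt, RPN1 swing)
#' are sampled independently and uniformly over their amplitude ranges.
#'
#' @param surface a `free_energy_surface`.
#' @param n number of particles (>= 1).
#' @param seed integer seed; one private generator per call.
#' @return tibble of class `particle_set` with columns `particle_id`,
#'   `q1`, `q2`, `basin` (ground-truth label, `NA` when the surface has no
#'   basin annotation), `tilt_deg`, `rpn1_A`.
#' @export
sample_particles <- function(surface, n, seed = 20220311) {
  stopifnot(inherits(surface, "free_energy_surface"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  p <- as.vector(surface$prob)
  if (all(p <= 0)) stop("surface is everywhere forbidden; cannot sample", call. = FALSE)
  rng <- local_rng(seed)
  cells <- rng(function() sample.int(length(p), n, replace = TRUE, prob = p))
  n1 <- nrow(surface$prob)
  i1 <- ((cells - 1L) %% n1) + 1L
  i2 <- ((cells - 1L) %/% n1) + 1L
  e1 <- surface$bin_edges_q1; e2 <- surface$bin_edges_q2
  u1 <- rng(function() stats::runif(n))
  u2 <- rng(function() stats::runif(n))
  q1 <- e1[i1] + u1 * (e1[i1 + 1L] - e1[i1])
  q2 <- e2[i2] + u2 * (e2[i2 + 1L] - e2[i2])
  basin <- if (is.null(surface$basin)) NA_character_ else surface$basin[cbind(i1, i2)]
  tilt <- rng(function() stats::runif(n, 4, 10))
  swing <- rng(function() stats::runif(n, 1, 25))
  structure(
    tibble::tibble(particle_id = seq_len(n), q1 = q1, q2 = q2,
                   basin = basin, tilt_deg = tilt, rpn1_A = swing),
    seed = seed, axes = surface$axes,
    class = c("particle_set", class(tibble::tibble()))
  )
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface> %d x %d bins over %s x %s\n",
              nrow(x$energies), ncol(x$energies), x$axes[1], x$axes[2]))
  if (!is.null(x$target_fractions)) {
    cat("  basin masses:",
        paste(sprintf("%s=%.2f", names(x$target_fractions), x$target_fractions),
              collapse = ", "), "\n")
  }
  invisible(x)
}
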