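#' Bin particles over two mode coordinates
#'
#' Builds the 2-D occupancy histogram underlying a conformational
#' free-energy landscape. Bin edges span the observed coordinate range
#' exactly; bins are right-open except the last, which is closed, so all
#' particles are counted.
#'
#' @param particles data frame with numeric columns `q1` and `q2`.
#' @param n_bins integer length-2, bins along q1 and q2 (default 30 x 30).
#' @return object of class `landscape_grid`: a list with `counts`
#'   (n1 x n2 integer matrix), `bin_edges_q1`, `bin_edges_q2`,
#'   `empty_mask`, and `energies` (`NULL` until [boltzmann_invert()]).
#' @export
bin_particles <- function(particles, n_bins = c(30, 30)) {
  stopifnot(is.data.frame(particles), all(c("q1", "q2") %in% names(particles)))
  if (nrow(particles) == 0L) stop("`particles` is empty", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (length(n_bins) == 1L) n_bins <- rep(n_bins, 2L)
  if (any(n_bins < 2L)) stop("need at least 2 bins per coordinate", call. = FALSE)
  rng1 <- range(particles$q1)
  rng2 <- range(particles$q2)
  if (diff(rng1) == 0 || diff(rng2) == 0) {
    stop("degenerate binning: a mode coordinate has zero variance; ",
         "inspect the ensemble or drop the coordinate", call. = FALSE)
  }
  e1 <- seq(rng1[1], rng1[2], length.out = n_bins[1] + 1L)
  e2 <- seq(rng2[1], rng2[2], length.out = n_bins[2] + 1L)
  i1 <- findInterval(particles$q1, e1, rightmost.closed = TRUE)
  i2 <- findInterval(particles$q2, e2, rightmost.closed = TRUE)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  tab <- table(factor(i1, levels = seq_len(n_bins[1])),
               factor(i2, levels = seq_len(n_bins[2])))
  counts[] <- as.integer(tab)
  structure(
    list(counts = counts, bin_edges_q1 = e1, bin_edges_q2 = e2,
         empty_mask = counts == 0L, energies = NULL,
         basins = NULL, basin_map = NULL),
    class = "landscape_grid"
  )
}

#' Convert bin occupancies to free energies
#'
#' Boltzmann inversion of relative populations: for every non-empty bin,
#' `E_i = -ln(N_i / N_max)` in units of kT, so the most populated bin sits
#' at energy zero. Empty bins carry no energy -- they are masked, never set
#' to a large finite value, preserving the "at least" semantics of barrier
#' estimates across unsampled regions.
#'
#' @param grid a `landscape_grid` from [bin_particles()].
#' @return the grid with `energies` filled (masked bins are `NA`).
#' @export
boltzmann_invert <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (all(grid$empty_mask)) stop("no non-empty bins to invert", call. = FALSE)
  nmax <- max(grid$counts)
  E <- -log(grid$counts / nmax)
  E[grid$empty_mask] <- NA_real_
  grid$energies <- E
  grid
}

# --- watershed machinery (8-connectivity) ---------------------------------

neighbours8 <- function(i, j, n1, n2) {
  di <- rep(c(-1L, 0L, 1L), times = 3L)
  dj <- rep(c(-1L, 0L, 1L), each = 3L)
  keep <- !(di == 0L & dj == 0L)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1L & ii <= n1 & jj >= 1L & jj <= n2
  cbind(ii[ok], jj[ok])
}

# Ordered-flooding watershed with persistence merging. `E` numeric matrix
# with NA for masked cells. Returns integer label matrix (NA where masked)
# plus a table of basin minima. Basins shallower than `min_depth` (saddle
# minus basin minimum) are merged into their deeper neighbour when first
# touched.
watershed_labels <- function(E, min_depth = 0) {
  n1 <- nrow(E); n2 <- ncol(E)
  cells <- which(!is.na(E))
  ord <- cells[order(E[cells], cells)]
  labels <- matrix(NA_integer_, n1, n2)
  parent <- integer(0)
  basin_min <- numeric(0)
  basin_seed <- integer(0)
  find_root <- function(k) {
    while (parent[k] != k) {
      parent[k] <<- parent[parent[k]]
      k <- parent[k]
    }
    k
  }
  for (cell in ord) {
    i <- ((cell - 1L) %% n1) + 1L
    j <- ((cell - 1L) %/% n1) + 1L
    nb <- neighbours8(i, j, n1, n2)
    lab <- labels[cbind(nb[, 1], nb[, 2])]
    roots <- unique(vapply(lab[!is.na(lab)], find_root, integer(1)))
    if (length(roots) == 0L) {
      k <- length(parent) + 1L
      parent[k] <- k
      basin_min[k] <- E[cell]
      basin_seed[k] <- cell
      labels[cell] <- k
    } else if (length(roots) == 1L) {
      labels[cell] <- roots
    } else {
      # saddle between several catchments: merge the shallow ones here
      deepest <- roots[order(basin_min[roots], basin_seed[roots])][1L]
      for (r in roots) {
        if (r != deepest && (E[cell] - basin_min[r]) < min_depth) {
          parent[r] <- deepest
        }
      }
      labels[cell] <- find_root(deepest)
    }
  }
  idx <- which(!is.na(labels))
  labels[idx] <- vapply(labels[idx], find_root, integer(1))
  roots <- sort(unique(labels[idx]))
  # deterministic final ids: by basin minimum energy, then seed index
  ordr <- roots[order(basin_min[roots], basin_seed[roots])]
  relab <- integer(max(ordr)); relab[ordr] <- seq_along(ordr)
  labels[idx] <- relab[labels[idx]]
  list(labels = labels,
       minima = tibble::tibble(
         basin = seq_along(ordr),
         min_cell = basin_seed[ordr],
         min_energy = basin_min[ordr]
       ))
}

#' Detect basins of a free-energy landscape
#'
#' Watershed assignment of every non-empty bin to the catchment of a local
#' minimum of the energy surface (8-neighbourhoods). Catchments whose depth
#' below the first connecting saddle is less than `min_depth` are merged
#' into their deeper neighbour, which absorbs the spurious shallow minima
#' that Poisson counting noise creates in sparsely sampled regions.
#'
#' @param grid a `landscape_grid` with energies filled.
#' @param min_depth persistence threshold in kT (default 1); use 0 for
#'   noise-free analytic grids.
#' @return the grid with `basin_map` (integer matrix) and `basins` (tibble
#'   with `basin`, `min_q1`, `min_q2`, `min_energy`, `n`, `fraction`).
#' @export
find_basins <- function(grid, min_depth = 1) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (is.null(grid$energies)) stop("energies not filled; run boltzmann_invert() first", call. = FALSE)
  if (all(grid$empty_mask)) stop("no non-empty bins", call. = FALSE)
  ws <- watershed_labels(grid$energies, min_depth = min_depth)
  n1 <- nrow(grid$counts)
  total <- sum(grid$counts)
  cnt <- vapply(seq_len(nrow(ws$minima)), function(b) {
    sum(grid$counts[which(ws$labels == b)])
  }, numeric(1))
  c1 <- mid_points(grid$bin_edges_q1)
  c2 <- mid_points(grid$bin_edges_q2)
  mi <- ((ws$minima$min_cell - 1L) %% n1) + 1L
  mj <- ((ws$minima$min_cell - 1L) %/% n1) + 1L
  grid$basin_map <- ws$labels
  grid$basins <- tibble::tibble(
    basin = ws$minima$basin,
    min_bin_q1 = mi, min_bin_q2 = mj,
    min_q1 = c1[mi], min_q2 = c2[mj],
    min_energy = ws$minima$min_energy,
    n = cnt, fraction = cnt / total
  )
  grid
}

mid_points <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

# --- minimax (bottleneck) barrier -----------------------------------------

# Bottleneck path value between two cells over non-NA cells of E:
# minimises, over 8-connected paths, the maximum energy en route.
bottleneck_value <- function(E, from, to) {
  n1 <- nrow(E); n2 <- ncol(E)
  best <- matrix(Inf, n1, n2)
  done <- matrix(FALSE, n1, n2)
  amax <- matrix(NA_integer_, n1, n2)  # cell attaining the path maximum
  best[from] <- E[from]
  amax[from] <- from
  repeat {
    open <- which(!done & is.finite(best))
    if (length(open) == 0L) return(list(value = Inf, argmax = NA_integer_))
    cur <- open[which.min(best[open])]
    if (cur == to) break
    done[cur] <- TRUE
    i <- ((cur - 1L) %% n1) + 1L
    j <- ((cur - 1L) %/% n1) + 1L
    nb <- neighbours8(i, j, n1, n2)
    for (k in seq_len(nrow(nb))) {
      cell <- nb[k, 1] + (nb[k, 2] - 1L) * n1
      if (is.na(E[cell]) || done[cell]) next
      cand <- max(best[cur], E[cell])
      if (cand < best[cell]) {
        best[cell] <- cand
        amax[cell] <- if (E[cell] >= best[cur]) cell else amax[cur]
      }
    }
  }
  list(value = best[to], argmax = amax[to])
}

#' Barrier between two basins
#'
#' Minimax barrier: over all 8-connected paths of non-empty bins linking
#' the two basin minima, the minimum of the path-maximum energy. The
#' saddle energy is symmetric; barrier heights are direction-dependent
#' (saddle minus the starting basin's minimum). When no path of non-empty
#' bins connects the basins the barrier is only bounded from below by the
#' largest observed energy, and `lower_bound` is set.
#'
#' @param grid a `landscape_grid` after [find_basins()].
#' @param basin_a,basin_b basin ids (rows of `grid$basins`).
#' @return one-row tibble: `saddle_energy`, `barrier_from_a`,
#'   `barrier_from_b`, `saddle_q1`, `saddle_q2`, `lower_bound`.
#' @export
find_barrier <- function(grid, basin_a, basin_b) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (is.null(grid$basins)) stop("run find_basins() first", call. = FALSE)
  ba <- grid$basins[grid$basins$basin == basin_a, ]
  bb <- grid$basins[grid$basins$basin == basin_b, ]
  if (nrow(ba) != 1L || nrow(bb) != 1L) stop("unknown basin id", call. = FALSE)
  E <- grid$energies
  n1 <- nrow(E)
  if (basin_a == basin_b) {
    return(tibble::tibble(saddle_energy = ba$min_energy, barrier_from_a = 0,
                          barrier_from_b = 0, saddle_q1 = ba$min_q1,
                          saddle_q2 = ba$min_q2, lower_bound = FALSE))
  }
  from <- ba$min_bin_q1 + (ba$min_bin_q2 - 1L) * n1
  to <- bb$min_bin_q1 + (bb$min_bin_q2 - 1L) * n1
  bn <- bottleneck_value(E, from, to)
  if (!is.finite(bn$value)) {
    emax <- max(E, na.rm = TRUE)
    return(tibble::tibble(saddle_energy = emax,
                          barrier_from_a = emax - ba$min_energy,
                          barrier_from_b = emax - bb$min_energy,
                          saddle_q1 = NA_real_, saddle_q2 = NA_real_,
                          lower_bound = TRUE))
  }
  c1 <- mid_points(grid$bin_edges_q1); c2 <- mid_points(grid$bin_edges_q2)
  si <- ((bn$argmax - 1L) %% n1) + 1L
  sj <- ((bn$argmax - 1L) %/% n1) + 1L
  tibble::tibble(
    saddle_energy = bn$value,
    barrier_from_a = bn$value - ba$min_energy,
    barrier_from_b = bn$value - bb$min_energy,
    saddle_q1 = c1[si], saddle_q2 = c2[sj],
    lower_bound = FALSE
  )
}

#' Assign particles to basins and summarise state fractions
#'
#' Each particle inherits the basin of the bin it fell in. The summary
#' reports one row per basin with its particle fraction, flagging as
#' "compressed" any basin whose minimum lies beyond half the compression
#' range along q2.
#'
#' @param particles the data frame that produced `grid`.
#' @param grid a `landscape_grid` after [find_basins()].
#' @param compression_range full amplitude of the compression coordinate
#'   (A); basins with `|min_q2| >= compression_range / 2` are flagged.
#' @return the particle tibble with a `basin` column; the per-basin summary
#'   (columns `basin`, `n`, `fraction`, `compressed`) is attached as
#'   attribute `"summary"` and retrievable with [state_fractions()].
#' @export
assign_states <- function(particles, grid, compression_range = 12) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (is.null(grid$basins)) stop("run find_basins() first", call. = FALSE)
  i1 <- findInterval(particles$q1, grid$bin_edges_q1, rightmost.closed = TRUE)
  i2 <- findInterval(particles$q2, grid$bin_edges_q2, rightmost.closed = TRUE)
  n1 <- nrow(grid$counts)
  bad <- i1 < 1L | i1 > n1 | i2 < 1L | i2 > ncol(grid$counts)
  if (any(bad)) stop("internal inconsistency: particle outside the grid that binned it", call. = FALSE)
  lab <- grid$basin_map[cbind(i1, i2)]
  if (anyNA(lab)) stop("internal inconsistency: particle in an empty bin", call. = FALSE)
  out <- tibble::as_tibble(particles)
  out$basin <- lab
  summ <- grid$basins |>
    dplyr::mutate(compressed = abs(.data$min_q2) >= compression_range / 2) |>
    dplyr::select("basin", "n", "fraction", "compressed")
  attr(out, "summary") <- summ
  out
}

#' @rdname assign_states
#' @param assigned result of [assign_states()].
#' @export
state_fractions <- function(assigned) attr(assigned, "summary")

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d bins, %d particles, %d empty bins\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), sum(x$empty_mask)))
  if (!is.null(x$energies)) {
    cat(sprintf("  energies 0 .. %.2f kT\n", max(x$energies, na.rm = TRUE)))
  }
  if (!is.null(x$basins)) {
    cat(sprintf("  %d basin(s); fractions %s\n", nrow(x$basins),
                paste(sprintf("%.3f", x$basins$fraction), collapse = ", ")))
  }
  invisible(x)
}
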