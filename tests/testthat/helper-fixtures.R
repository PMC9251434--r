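# Shared fixtures: a reduced barrel keeps the voxel grids small enough for
# fast rasterization while staying in the same measurement regime as the
# full-size assembly.

mini_config <- function(...) {
  assembly_config(outer_radius = 30, ring_spacing = 10, include_rp = FALSE, ...)
}

full_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_assembly(assembly_config(gate_diameter = 14))
    cache
  }
})

zero_amps <- function(modes) stats::setNames(rep(0, nrow(modes)), modes$name)

one_mode_amps <- function(modes, name, value) {
  a <- zero_amps(modes)
  a[[name]] <- value
  a
}

# Independent oracle for the minimax barrier: exhaustive enumeration of all
# simple 8-connected paths between two cells, minimising the path maximum.
brute_minimax <- function(E, from, to) {
  n1 <- nrow(E); n2 <- ncol(E)
  best <- Inf
  visited <- matrix(FALSE, n1, n2)
  recurse <- function(i, j, cur_max) {
    cur_max <- max(cur_max, E[i, j])
    if (cur_max >= best) return(invisible())
    if (i == to[1] && j == to[2]) {
      best <<- cur_max
      return(invisible())
    }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
      if (visited[ii, jj] || is.na(E[ii, jj])) next
      recurse(ii, jj, cur_max)
    }
    visited[i, j] <<- FALSE
  }
  if (is.na(E[from[1], from[2]]) || is.na(E[to[1], to[2]])) return(Inf)
  recurse(from[1], from[2], -Inf)
  best
}

# Landscape grid built directly from an energy matrix (bypassing sampling),
# for analytic watershed/barrier tests: counts are scaled Boltzmann weights.
grid_from_energies <- function(E, scale = 1e6) {
  counts <- round(scale * exp(-(E - min(E, na.rm = TRUE))))
  counts[is.na(E)] <- 0L
  n1 <- nrow(E); n2 <- ncol(E)
  g <- structure(
    list(counts = matrix(as.integer(counts), n1, n2),
         bin_edges_q1 = seq(0, n1, length.out = n1 + 1L),
         bin_edges_q2 = seq(0, n2, length.out = n2 + 1L),
         empty_mask = matrix(counts == 0, n1, n2),
         energies = NULL, basins = NULL, basin_map = NULL),
    class = "landscape_grid"
  )
  boltzmann_invert(g)
}
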