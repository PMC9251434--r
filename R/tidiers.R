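#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a landscape grid into one row per bin
#'
#' @param x a `landscape_grid`.
#' @param ... unused.
#' @return tibble with `q1`, `q2` (bin centres), `count`, `energy`
#'   (`NA` for empty bins) and, when basins have been found, `basin`.
#' @export
tidy.landscape_grid <- function(x, ...) {
  c1 <- mid_points(x$bin_edges_q1)
  c2 <- mid_points(x$bin_edges_q2)
  out <- tibble::tibble(
    q1 = rep(c1, times = length(c2)),
    q2 = rep(c2, each = length(c1)),
    count = as.integer(x$counts)
  )
  out$energy <- if (is.null(x$energies)) NA_real_ else as.vector(x$energies)
  if (!is.null(x$basin_map)) out$basin <- as.vector(x$basin_map)
  out
}

#' @rdname tidy.landscape_grid
#' @export
glance.landscape_grid <- function(x, ...) {
  tibble::tibble(
    n_particles = sum(x$counts),
    n_bins_q1 = nrow(x$counts), n_bins_q2 = ncol(x$counts),
    n_empty = sum(x$empty_mask),
    n_basins = if (is.null(x$basins)) NA_integer_ else nrow(x$basins),
    max_energy = if (is.null(x$energies)) NA_real_ else max(x$energies, na.rm = TRUE)
  )
}

#' Tidy a free-energy surface into one row per bin
#'
#' @param x a `free_energy_surface`.
#' @param ... unused.
#' @export
tidy.free_energy_surface <- function(x, ...) {
  c1 <- mid_points(x$bin_edges_q1)
  c2 <- mid_points(x$bin_edges_q2)
  out <- tibble::tibble(
    q1 = rep(c1, times = length(c2)),
    q2 = rep(c2, each = length(c1)),
    energy = as.vector(x$energies),
    prob = as.vector(x$prob)
  )
  if (!is.null(x$basin)) out$basin <- as.vector(x$basin)
  out
}

#' Tidy the variance spectrum of a principal-mode decomposition
#'
#' @param x a `principal_modes` object.
#' @param ... unused.
#' @export
tidy.principal_modes <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$all_variances),
    variance = x$all_variances,
    prop_variance = x$all_variances / max(x$total_variance, .Machine$double.eps)
  )
}

#' @rdname tidy.principal_modes
#' @export
glance.principal_modes <- function(x, ...) {
  tibble::tibble(
    k = ncol(x$modes),
    n_conformers = nrow(x$projections),
    total_variance = x$total_variance,
    prop_first = x$all_variances[1] / max(x$total_variance, .Machine$double.eps)
  )
}

#' Flatten a rigid-motion descriptor
#'
#' @param x a `rigid_motion` (one row).
#' @param ... unused.
#' @return one-row tibble with the axis and pivot expanded to scalar
#'   columns.
#' @export
tidy.rigid_motion <- function(x, ...) {
  ax <- x$rotation_axis[[1]]; pv <- x$pivot[[1]]
  tibble::tibble(
    group = x$group,
    rotation_angle = x$rotation_angle,
    axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
    pivot_x = pv[1], pivot_y = pv[2], pivot_z = pv[3],
    translation_along_axis = x$translation_along_axis,
    max_displacement = x$max_displacement
  )
}

#' Heatmap of a free-energy landscape
#'
#' @param object a `landscape_grid` (energies filled) or
#'   `free_energy_surface`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.landscape_grid <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$q1, .data$q2, fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "E (kT)") +
    ggplot2::labs(x = "lid rotation (deg)", y = "compression (\u00c5)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.landscape_grid
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$q1, .data$q2, fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "E (kT)") +
    ggplot2::labs(x = object$axes[1], y = object$axes[2]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.landscape_grid
#' @export
autoplot.particle_set <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$q1, .data$q2, colour = .data$basin)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.4) +
    ggplot2::labs(x = "lid rotation (deg)", y = "compression (\u00c5)") +
    ggplot2::theme_minimal()
}
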