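#' Define the rigid-body mode catalogue
#'
#' Returns the default catalogue of conformational modes of the assembly as
#' a tibble, one row per mode: the clockwise lid rotation about the barrel
#' axis pivoted at the RPN11 marker (0-35 degrees), the lid tilt about an
#' axis perpendicular to the barrel axis pivoted in the gap between lid and
#' ATPase base (4-10 degrees), the axial compression of the two distal core
#' rings (0-12 A translation toward the proximal face), and the free RPN1
#' swing (1-25 A translation).
#'
#' @param model a `bead_model`; pivots are derived from its geometry.
#' @param modes optional list of custom mode specifications; each a list
#'   with fields `name`, `kind` (rotation/tilt/translation/compression),
#'   `groups` (character), `pivot` (length-3), `axis` (length-3, will be
#'   normalised), `range` (length-2, degrees for rotation/tilt, Angstrom
#'   otherwise). `list()` requests an empty catalogue; `NULL` (default)
#'   requests the standard four-mode catalogue.
#' @return tibble of class `mode_catalogue` with columns `name`, `kind`,
#'   `groups` (list), `pivot` (list), `axis` (list), `range_min`,
#'   `range_max`.
#' @export
define_modes <- function(model, modes = NULL) {
  stopifnot(inherits(model, "bead_model"))
  if (is.null(modes)) {
    marker <- colMeans(bead_coords(model, "rpn11_marker"))
    has_rp <- all(c("lid", "base_atpase", "rpn1") %in% model$group)
    if (!has_rp) stop("default mode catalogue needs the regulatory-particle groups", call. = FALSE)
    lid_c <- colMeans(bead_coords(model, "lid"))
    base_c <- colMeans(bead_coords(model, "base_atpase"))
    gap <- (lid_c + base_c) / 2  # free space between ATPase and lid
    modes <- list(
      list(name = "lid_rotation", kind = "rotation", groups = "lid",
           pivot = marker, axis = c(0, 0, 1), range = c(0, 35)),
      list(name = "lid_tilt", kind = "tilt", groups = "lid",
           pivot = gap, axis = c(1, 0, 0), range = c(4, 10)),
      list(name = "cp_compression", kind = "compression",
           groups = c("cp_alpha_distal", "cp_beta_2"),
           pivot = c(0, 0, 0), axis = c(0, 0, -1), range = c(0, 12)),
      list(name = "rpn1_swing", kind = "translation", groups = "rpn1",
           pivot = c(0, 0, 0), axis = c(0, 1, 0), range = c(1, 25))
    )
  }
  if (length(modes) == 0L) {
    return(new_mode_catalogue(tibble::tibble(
      name = character(), kind = character(), groups = list(),
      pivot = list(), axis = list(), range_min = numeric(), range_max = numeric()
    )))
  }
  known <- unique(model$group)
  rows <- purrr::map(modes, function(m) {
    stopifnot(is.list(m), all(c("name", "kind", "groups", "axis", "range") %in% names(m)))
    bad <- setdiff(m$groups, known)
    if (length(bad)) {
      stop(sprintf("mode '%s' references unknown group(s): %s",
                   m$name, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (m$range[1] > m$range[2]) {
      stop(sprintf("mode '%s': amplitude range min exceeds max", m$name), call. = FALSE)
    }
    tibble::tibble(
      name = m$name, kind = m$kind, groups = list(m$groups),
      pivot = list(as.numeric(if (is.null(m$pivot)) c(0, 0, 0) else m$pivot)),
      axis = list(unit_vec(as.numeric(m$axis))),
      range_min = m$range[1], range_max = m$range[2]
    )
  })
  new_mode_catalogue(dplyr::bind_rows(rows))
}

new_mode_catalogue <- function(tbl) {
  structure(tbl, class = c("mode_catalogue", class(tibble::tibble())))
}

#' Apply mode amplitudes to a reference assembly
#'
#' Transforms the affected groups of each mode rigidly -- rotation modes
#' rotate about their pivot/axis by the amplitude in degrees, translation
#' and compression modes translate along their axis by the amplitude in
#' Angstrom -- in catalogue order. Beads outside every affected group are
#' returned bit-identical.
#'
#' An amplitude of exactly 0 always means "mode not engaged" and is
#' accepted even for modes whose nominal range starts above 0; any other
#' amplitude must fall inside the mode's amplitude range.
#'
#' @param reference a `bead_model`.
#' @param modes a `mode_catalogue` from [define_modes()].
#' @param amplitudes named numeric vector, one entry per mode name.
#' @return a `bead_model` of the deformed conformer.
#' @export
apply_modes <- function(reference, modes, amplitudes) {
  stopifnot(inherits(reference, "bead_model"), inherits(modes, "mode_catalogue"))
  if (nrow(modes) == 0L) return(reference)
  if (is.null(names(amplitudes)) || !setequal(names(amplitudes), modes$name)) {
    stop("`amplitudes` must be named, one amplitude per catalogue mode", call. = FALSE)
  }
  out <- reference
  xyz <- bead_coords(reference)
  for (i in seq_len(nrow(modes))) {
    m <- modes[i, ]
    amp <- unname(amplitudes[[m$name]])
    if (!is.finite(amp)) stop(sprintf("amplitude for '%s' is not finite", m$name), call. = FALSE)
    if (amp != 0 && (amp < m$range_min - 1e-12 || amp > m$range_max + 1e-12)) {
      stop(sprintf("amplitude %.3f for mode '%s' outside range [%g, %g]",
                   amp, m$name, m$range_min, m$range_max), call. = FALSE)
    }
    if (amp == 0) next
    sel <- out$group %in% m$groups[[1]]
    if (m$kind %in% c("rotation", "tilt")) {
      R <- rotation_matrix(m$axis[[1]], amp)
      p <- m$pivot[[1]]
      moved <- sweep(xyz[sel, , drop = FALSE], 2, p) %*% t(R)
      xyz[sel, ] <- sweep(moved, 2, p, `+`)
    } else {
      xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, amp * m$axis[[1]], `+`)
    }
  }
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}
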