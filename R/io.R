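# Ensemble I/O: multi-model PDB for conformer coordinates (CA-only bead
# records, one chain per group) plus a TSV of ground-truth mode
# coordinates. Standard fixed-column PDB ATOM records, Angstrom, barrel
# axis = +z, proximal (RP-occupied) face at low z.

GROUP_CHAINS <- stats::setNames(LETTERS[seq_along(ALL_GROUPS)], ALL_GROUPS)

#' Write a conformer ensemble to disk
#'
#' Writes `ensemble.pdb` (one MODEL per conformer, one chain per bead
#' group, CA-only ATOM records, occupancy 1.00, B-factor 0.00) and
#' `particles.tsv` with the ground-truth mode coordinates and basin label
#' of every particle. Coordinates round-trip through [read_ensemble()]
#' losslessly at the PDB's 3-decimal precision.
#'
#' @param particles a `particle_set`; rows for which conformers are
#'   written are taken from `conformer_ids` (coordinate files for very
#'   large ensembles are rarely useful in full).
#' @param reference the reference `bead_model`.
#' @param modes the `mode_catalogue` used to pose conformers: `q1` drives
#'   the lid rotation, `q2` the compression, `tilt_deg` and `rpn1_A` the
#'   two nuisance modes.
#' @param out_dir output directory (created if missing).
#' @param conformer_ids particle ids to write as PDB MODELs (default: all,
#'   capped at 100).
#' @return invisibly, a list with the two file paths.
#' @export
write_ensemble <- function(particles, reference, modes, out_dir,
                           conformer_ids = NULL) {
  stopifnot(inherits(reference, "bead_model"), inherits(modes, "mode_catalogue"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  if (is.null(conformer_ids)) {
    conformer_ids <- utils::head(particles$particle_id, 100L)
  }
  pdb_path <- file.path(out_dir, "ensemble.pdb")
  tsv_path <- file.path(out_dir, "particles.tsv")

  con <- file(pdb_path, open = "wt")
  on.exit(close(con), add = TRUE)
  cfg <- attr(reference, "config")
  writeLines(c(
    "REMARK 250 COARSE-GRAINED BARREL ASSEMBLY ENSEMBLE",
    sprintf("REMARK 250 BEAD RADIUS %.3f A", cfg$bead_radius),
    sprintf("REMARK 250 CHAIN MAP %s",
            paste(sprintf("%s=%s", GROUP_CHAINS[unique(reference$group)],
                          unique(reference$group)), collapse = " "))
  ), con)
  for (pid in conformer_ids) {
    row <- particles[particles$particle_id == pid, ]
    if (nrow(row) != 1L) stop(sprintf("particle id %s not found", pid), call. = FALSE)
    amps <- amplitudes_for(row, modes)
    conf <- apply_modes(reference, modes, amps)
    writeLines(sprintf("MODEL     %4d", as.integer(pid)), con)
    writeLines(pdb_atom_lines(conf), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)

  tsv <- tibble::as_tibble(particles)[, intersect(
    c("particle_id", "q1", "q2", "basin", "tilt_deg", "rpn1_A"),
    names(particles))]
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(pdb = pdb_path, tsv = tsv_path))
}

# Map a particle row onto mode amplitudes: q1 -> lid rotation, q2 ->
# compression, nuisance columns -> tilt and RPN1 swing; any other
# catalogue mode is held at 0.
amplitudes_for <- function(row, modes) {
  amps <- stats::setNames(rep(0, nrow(modes)), modes$name)
  if ("lid_rotation" %in% modes$name) amps[["lid_rotation"]] <- row$q1
  if ("cp_compression" %in% modes$name) amps[["cp_compression"]] <- row$q2
  if ("lid_tilt" %in% modes$name && "tilt_deg" %in% names(row)) {
    amps[["lid_tilt"]] <- row$tilt_deg
  }
  if ("rpn1_swing" %in% modes$name && "rpn1_A" %in% names(row)) {
    amps[["rpn1_swing"]] <- row$rpn1_A
  }
  amps
}

pdb_atom_lines <- function(model) {
  chain <- GROUP_CHAINS[model$group]
  res3 <- AA_THREE[model$pseudo_residue]
  resseq <- stats::ave(seq_len(nrow(model)), model$group, FUN = seq_along)
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          model$bead_id %% 100000L, res3, chain, resseq %% 10000L,
          model$x, model$y, model$z, 1.0, 0.0)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param out_dir directory containing `ensemble.pdb` and `particles.tsv`.
#' @return list with `conformers` (list of bead tibbles, one per MODEL,
#'   with columns `bead_id`, `group`, `x`, `y`, `z`, `radius`,
#'   `pseudo_residue`), `particles` (tibble), and `bead_radius`.
#' @export
read_ensemble <- function(out_dir) {
  pdb_path <- file.path(out_dir, "ensemble.pdb")
  tsv_path <- file.path(out_dir, "particles.tsv")
  for (p in c(pdb_path, tsv_path)) {
    if (!file.exists(p)) stop(sprintf("missing ensemble file '%s'", p), call. = FALSE)
  }
  lines <- readLines(pdb_path)
  radius_line <- grep("^REMARK 250 BEAD RADIUS", lines, value = TRUE)
  bead_radius <- if (length(radius_line)) {
    as.numeric(strsplit(radius_line[1], "\\s+")[[1]][5])
  } else NA_real_
  chain_line <- grep("^REMARK 250 CHAIN MAP", lines, value = TRUE)
  chain_map <- character()
  if (length(chain_line)) {
    toks <- strsplit(sub("^REMARK 250 CHAIN MAP ", "", chain_line[1]), " ")[[1]]
    kv <- strsplit(toks, "=")
    chain_map <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  stopifnot(length(model_starts) == length(model_ends))
  conformers <- purrr::map2(model_starts, model_ends, function(s, e) {
    at <- lines[(s + 1):(e - 1)]
    at <- at[startsWith(at, "ATOM")]
    tibble::tibble(
      bead_id = as.integer(substr(at, 7, 11)),
      group = unname(chain_map[substr(at, 22, 22)]),
      x = as.numeric(substr(at, 31, 38)),
      y = as.numeric(substr(at, 39, 46)),
      z = as.numeric(substr(at, 47, 54)),
      radius = bead_radius,
      pseudo_residue = unname(AA_ONE[substr(at, 18, 20)])
    )
  })
  particles <- tibble::as_tibble(utils::read.table(
    tsv_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  list(conformers = conformers, particles = particles, bead_radius = bead_radius)
}
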