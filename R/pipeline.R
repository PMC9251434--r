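#' Default pipeline configuration
#'
#' The reference parameterisation of the full analysis: the standard
#' barrel assembly with a 14 A open distal gate and a small catalogue of
#' wall pores spanning the 4-17 A regime (including an 11.3 x 7.9 A
#' elliptical pore), the default four-mode catalogue, the two-basin
#' surface (58/35/7% masses, 5.6 kT saddles), 1e5 particles, 30 x 30
#' landscape bins, 0.5 A pore-grid spacing with a 1.4 A probe, and the
#' canonical kinetics parameters (L = 10 residues, x = 1 nm,
#' D = 3 um^2/s, v = 40 aa/s).
#'
#' @param n number of particles to sample.
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(n = 1e5, seed = 20220311) {
  cfg <- list(
    assembly = list(
      outer_radius = 55, ring_spacing = 15, wall_thickness = 10,
      bead_radius = 2.5, wall_bead_spacing = 2.5, gate_diameter = 14,
      pores = list(
        list(azimuth_deg = 0, z = 30, d_long = 11.3, d_short = 7.9),
        list(azimuth_deg = 75, z = 22, d_long = 4, d_short = 4),
        list(azimuth_deg = 150, z = 38, d_long = 10, d_short = 10),
        list(azimuth_deg = 255, z = 30, d_long = 17, d_short = 17)
      ),
      probe_radius = 1.4, include_rp = TRUE, residue_seed = 20220311
    ),
    surface = list(
      saddle = 5.6,
      fractions = c(resting = 0.58, rotated = 0.35, compressed = 0.07),
      n_bins = c(30, 30), q1_range = c(0, 35), q2_range = c(0, 12)
    ),
    sampling = list(n = n, seed = seed, n_conformers = 25),
    mode_endpoints = c(lid_rotation = 35, lid_tilt = 10,
                       cp_compression = 12, rpn1_swing = 25),
    landscape = list(n_bins = c(30, 30), min_depth = 1, compression_range = 12),
    pores = list(spacing = 0.5, probe_radius = 1.4, include_rp = FALSE),
    kinetics = list(L = 10, x = 1, D = 3, v = 40)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

MODE_RANGES <- list(lid_rotation = c(0, 35), lid_tilt = c(4, 10),
                    cp_compression = c(0, 12), rpn1_swing = c(1, 25))

#' Validate a pipeline configuration
#'
#' Checks every typed field and returns all violations, never just the
#' first; an empty character vector means the configuration is valid.
#'
#' @param config a configuration list as produced by [default_config()].
#' @return character vector of problems (empty when ok).
#' @export
validate_config <- function(config) {
  p <- character()
  note <- function(msg) p <<- c(p, msg)
  if (!is.list(config)) return("config must be a list")
  a <- config$assembly
  if (is.null(a)) {
    note("missing `assembly` section")
  } else {
    ac <- try(do.call(assembly_config, a), silent = TRUE)
    if (inherits(ac, "try-error")) {
      note(sub("^Error[^:]*: *", "", trimws(as.character(ac))))
    }
  }
  s <- config$surface
  if (!is.null(s)) {
    if (!is.null(s$fractions) && abs(sum(s$fractions) - 1) > 1e-9) {
      note("surface `fractions` must sum to 1")
    }
    if (!is.null(s$saddle) && (!is.numeric(s$saddle) || s$saddle <= 0)) {
      note("surface `saddle` must be positive")
    }
  }
  n <- config$sampling$n
  if (is.null(n) || !is.numeric(n) || length(n) != 1L || n < 1) {
    note("sampling `n` must be >= 1")
  }
  for (nm in names(config$mode_endpoints)) {
    amp <- config$mode_endpoints[[nm]]
    rng <- MODE_RANGES[[nm]]
    if (is.null(rng)) {
      note(sprintf("unknown mode '%s' in `mode_endpoints`", nm))
    } else if (amp != 0 && (amp < rng[1] || amp > rng[2])) {
      note(sprintf("mode_endpoints['%s'] = %g outside range [%g, %g]",
                   nm, amp, rng[1], rng[2]))
    }
  }
  lb <- config$landscape$n_bins
  if (!is.null(lb) && (length(lb) < 1L || any(lb < 2))) {
    note("landscape `n_bins` must be at least 2 per coordinate")
  }
  if (!is.null(config$pores$spacing) && config$pores$spacing <= 0) {
    note("pore grid `spacing` must be positive")
  }
  k <- config$kinetics
  for (nm in c("L", "x", "D", "v")) {
    if (!is.null(k[[nm]]) && (!is.numeric(k[[nm]]) || k[[nm]] <= 0)) {
      note(sprintf("kinetics `%s` must be positive", nm))
    }
  }
  p
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order -- assembly construction, mode catalogue,
#' surface construction, particle sampling, ensemble writing, principal
#' components, rigid-motion recovery of every mode endpoint, landscape
#' binning/inversion/basins/barriers, pore and gate geometry, release
#' kinetics -- and writes per-stage tables, a consolidated key-value
#' summary and a timestamped log to `out_dir`. Given the same
#' configuration and seed, the summary and tables are byte-identical
#' across runs. A stage failure aborts with the stage name and leaves a
#' `FAILED` marker in `out_dir`.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory.
#' @return invisibly, a list with the key results (`summary` tibble,
#'   `landscape`, `pores`, `modes`, `kinetics`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  cat(sprintf("corelandscape %s\n",
              as.character(utils::packageVersion("corelandscape"))),
      file = log_path)
  log_line("seed %d, n = %d", as.integer(config$sampling$seed),
           as.integer(config$sampling$n))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      log_line("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_line("stage %s: done", name)
    res
  }
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  model <- stage("assembly", build_assembly(do.call(assembly_config, config$assembly)))
  modes <- stage("modes", define_modes(model))
  surface <- stage("surface", do.call(two_basin_surface, config$surface))
  particles <- stage("sampling", sample_particles(
    surface, config$sampling$n, seed = config$sampling$seed))
  stage("ensemble", write_ensemble(
    particles, model, modes, out_dir,
    conformer_ids = utils::head(particles$particle_id, config$sampling$n_conformers)))

  pca <- stage("principal_modes", {
    ens <- read_ensemble(out_dir)
    confs <- lapply(ens$conformers, new_bead_model, cfg = attr(model, "config"))
    aligned <- align_ensemble(confs, model)
    pm <- principal_modes(aligned, k = 2)
    wtsv(tibble::tibble(particle_id = utils::head(particles$particle_id,
                                                  length(confs)),
                        pc1 = pm$projections[, 1], pc2 = pm$projections[, 2]),
         "projections.tsv")
    pm
  })

  mode_tbl <- stage("mode_recovery", {
    rows <- purrr::map(seq_len(nrow(modes)), function(i) {
      m <- modes[i, ]
      amp <- config$mode_endpoints[[m$name]]
      if (is.null(amp)) amp <- m$range_max
      amps <- stats::setNames(rep(0, nrow(modes)), modes$name)
      amps[[m$name]] <- amp
      conf <- apply_modes(model, modes, amps)
      grp <- m$groups[[1]][1]
      desc <- decompose_rigid_motion(model, conf, grp)
      dplyr::mutate(tidy(desc), mode = m$name, amplitude_in = amp,
                    kind = classify_mode(desc, barrel_axis_of(model)),
                    .before = 1)
    })
    tbl <- dplyr::bind_rows(rows)
    wtsv(tbl, "mode_descriptors.tsv")
    tbl
  })

  land <- stage("landscape", {
    grid <- bin_particles(particles, n_bins = config$landscape$n_bins)
    grid <- boltzmann_invert(grid)
    grid <- find_basins(grid, min_depth = config$landscape$min_depth)
    grid
  })
  assigned <- stage("states", assign_states(
    particles, land, compression_range = config$landscape$compression_range))
  fr <- state_fractions(assigned)
  resting_id <- fr$basin[which.max(fr$fraction)]
  compressed_id <- fr$basin[fr$compressed][which.max(fr$fraction[fr$compressed])]
  others <- fr[!fr$basin %in% c(resting_id, compressed_id), ]
  rotated_id <- if (nrow(others)) others$basin[which.max(others$n)] else NA_integer_
  barriers <- stage("barriers", {
    pairs <- expand.grid(a = fr$basin, b = fr$basin)
    pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
    tbl <- purrr::pmap_dfr(pairs, function(a, b) {
      dplyr::mutate(find_barrier(land, a, b), basin_a = a, basin_b = b,
                    .before = 1)
    })
    wtsv(tbl, "barriers.tsv")
    tbl
  })
  wtsv(dplyr::mutate(tidy(land), energy = round(energy, 6)), "landscape.tsv")
  wtsv(fr, "state_fractions.tsv")

  pore_res <- stage("pores", {
    pa <- config$assembly
    pa$include_rp <- isTRUE(config$pores$include_rp)
    pmodel <- build_assembly(do.call(assembly_config, pa))
    grid <- rasterize_assembly(pmodel, spacing = config$pores$spacing,
                               probe_radius = config$pores$probe_radius)
    pores <- detect_pores(grid)
    pores <- characterize_pore(pores, grid)
    gate <- measure_gate(pmodel)
    wtsv(dplyr::select(pores, -"voxels"), "pores.tsv")
    list(pores = pores, gate = gate)
  })
  kin <- stage("kinetics", do.call(release_kinetics, config$kinetics))
  wtsv(kin, "kinetics.tsv")

  rec <- function(name) {
    row <- mode_tbl[mode_tbl$mode == name, ]
    if (nrow(row) != 1L) return(NA_real_)
    row
  }
  lid <- rec("lid_rotation"); cmpn <- rec("cp_compression"); sw <- rec("rpn1_swing")
  releasing <- filter_releasing(pore_res$pores)
  fr_of <- function(id) if (length(id) && !is.na(id)) fr$fraction[fr$basin == id] else NA_real_
  bar_to <- function(id) {
    if (!length(id) || is.na(id)) return(NA_real_)
    row <- barriers[(barriers$basin_a == resting_id & barriers$basin_b == id) |
                      (barriers$basin_b == resting_id & barriers$basin_a == id), ]
    if (!nrow(row)) return(NA_real_)
    if (row$basin_a[1] == resting_id) row$barrier_from_a[1] else row$barrier_from_b[1]
  }
  summary <- tibble::tibble(
    quantity = c("resting_fraction", "rotated_fraction", "compressed_fraction",
                 "barrier_resting_to_rotated_kT", "barrier_resting_to_compressed_kT",
                 "lid_rotation_deg", "compression_A", "rpn1_swing_max_A",
                 "gate_diameter_A", "n_pores", "n_releasing_pores",
                 "tau_free_ns", "tau_pore_us", "orders_of_magnitude"),
    value = c(fr_of(resting_id), fr_of(rotated_id), fr_of(compressed_id),
              bar_to(rotated_id), bar_to(compressed_id),
              if (is.data.frame(lid)) lid$rotation_angle else NA_real_,
              if (is.data.frame(cmpn)) abs(cmpn$translation_along_axis) else NA_real_,
              if (is.data.frame(sw)) sw$max_displacement else NA_real_,
              pore_res$gate, nrow(pore_res$pores), nrow(releasing),
              kin$tau_free_ns, kin$tau_pore_us, kin$orders_of_magnitude)
  )
  sum_lines <- sprintf("%s\t%.10g", summary$quantity, summary$value)
  writeLines(sum_lines, file.path(out_dir, "summary.tsv"))
  log_line("pipeline complete")
  invisible(list(summary = summary, landscape = land, assigned = assigned,
                 barriers = barriers, modes = mode_tbl, pca = pca,
                 pores = pore_res$pores, gate = pore_res$gate, kinetics = kin))
}
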