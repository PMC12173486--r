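#' End-to-end run configuration
#'
#' Serializable description of a full sweep: geometry, material, cohort
#' stress ratios, twist grid, gait profile, reduced-model closure
#' parameters and output location.  A run is reproducible from its
#' configuration alone.
#'
#' @param geometry a [mesh_config()] (its `twist_deg` is ignored; the
#'   sweep's `twist_grid` governs twist).
#' @param material a [material_params()].
#' @param cohorts named soleus/gastrocnemius stress ratios.
#' @param twist_grid twist angles, degrees.
#' @param profile a [gait_profile()] (default [synth_gait_profile()]
#'   with 100 increments).
#' @param coupling_coeff reduced contact-coupling coefficient.
#' @param kprime shear correction factor.
#' @param angle_grid Radon projection angles, degrees.
#' @param out_dir optional output directory for CSV artefacts.
#' @param seed integer seed recorded with the run (the reduced pipeline
#'   is deterministic; the seed governs any synthetic noise).
#' @return a `run_config`.
#' @export
run_config <- function(geometry = mesh_config(),
                       material = material_params(),
                       cohorts = c(uniform = 1, soleus_doubled = 2,
                                   soleus_halved = 0.5),
                       twist_grid = seq(0, 180, by = 10),
                       profile = synth_gait_profile(),
                       coupling_coeff = 0.1, kprime = 1,
                       angle_grid = seq(5, 85, by = 0.25),
                       out_dir = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "mesh_config"),
            inherits(material, "material_params"),
            inherits(profile, "gait_profile"))
  structure(list(geometry = geometry, material = material,
                 cohorts = cohorts, twist_grid = twist_grid,
                 profile = profile, coupling_coeff = coupling_coeff,
                 kprime = kprime, angle_grid = angle_grid,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full generate / load / simulate / estimate / regress sweep
#'
#' For every (cohort, twist) condition: builds the twisted mesh, forms
#' the reduced coupled-beam assembly, simulates the transient shear
#' wave at every gait increment, measures per-subtendon wave speeds
#' (directional filter + Radon), and regresses nominal axial stress on
#' squared speed.  Per-condition failures are recorded and the sweep
#' continues.
#'
#' @param config a [run_config()].
#' @param verbose print stage-boundary progress.
#' @return list with `speeds` (tidy data.frame: cohort, ratio,
#'   twist_deg, increment, subtendon, stress_Pa, speed, flags),
#'   `regressions` (one row per cohort x twist x subtendon, see
#'   [regression_table()]), `failures` (data.frame of skipped
#'   conditions) and `config`.  If `config$out_dir` is set, writes
#'   `speeds.csv`, `regressions.csv` and `config.json` there.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  base_cfg <- config$geometry
  base_cfg$twist_deg <- 0
  base <- generate_butterfly_mesh(base_cfg)
  areas <- distal_areas(base)
  speed_rows <- list(); regs <- list(); fails <- list()
  for (tw in config$twist_grid) {
    mesh <- if (tw == 0) base else apply_helical_twist(base, tw)
    assembly <- beam_assembly(mesh, config$material,
                              kprime = config$kprime,
                              coupling_coeff = config$coupling_coeff)
    if (verbose)
      message(sprintf("twist %5.1f deg: assembly ready (paths %.1f/%.1f/%.1f mm)",
                      tw, assembly$paths$LG$length, assembly$paths$MG$length,
                      assembly$paths$S$length))
    for (ci in seq_along(config$cohorts)) {
      cname <- names(config$cohorts)[ci]
      ratio <- config$cohorts[[ci]]
      est <- array(NA_real_, c(config$profile$n_increments, 3),
                   dimnames = list(NULL, c("LG", "MG", "S")))
      sig <- est
      flagged <- est
      for (inc in seq_len(config$profile$n_increments)) {
        res <- tryCatch({
          lc <- partition_cohort_forces(config$profile$total_force[inc],
                                        areas, ratio, tw, inc)
          maps <- simulate_coupled_beams(set_assembly_loads(assembly, lc))
          for (l in c("LG", "MG", "S")) {
            ws <- measure_wave_speed(maps[[l]], config$angle_grid)
            est[inc, l] <- ws$speed
            flagged[inc, l] <- any(ws$flags)
            sig[inc, l] <- lc$stress[[l]]
          }
          NULL
        }, error = function(e) conditionMessage(e))
        if (!is.null(res))
          fails[[length(fails) + 1]] <- data.frame(
            cohort = cname, twist_deg = tw, increment = inc, error = res)
      }
      for (l in c("LG", "MG", "S")) {
        ok <- is.finite(est[, l])
        speed_rows[[length(speed_rows) + 1]] <- data.frame(
          cohort = cname, ratio = ratio, twist_deg = tw,
          increment = which(ok), subtendon = l,
          stress_Pa = sig[ok, l], speed = est[ok, l],
          flagged = as.logical(flagged[ok, l]))
        reg <- tryCatch(
          fit_wave_speed_stress(est[ok, l], sig[ok, l],
                                subtendon = l, cohort = cname,
                                twist_deg = tw),
          error = function(e) NULL)
        if (!is.null(reg)) regs[[length(regs) + 1]] <- reg
        else fails[[length(fails) + 1]] <- data.frame(
          cohort = cname, twist_deg = tw, increment = NA,
          error = paste("regression failed for", l))
      }
      if (verbose)
        message(sprintf("  cohort %-16s done (%d increments)", cname,
                        config$profile$n_increments))
    }
  }
  out <- list(speeds = do.call(rbind, speed_rows),
              regressions = regression_table(regs),
              failures = if (length(fails)) do.call(rbind, fails) else
                data.frame(),
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$speeds, file.path(config$out_dir, "speeds.csv"),
                     row.names = FALSE)
    utils::write.csv(out$regressions,
                     file.path(config$out_dir, "regressions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, cohorts = as.list(config$cohorts),
           twist_grid = config$twist_grid,
           coupling_coeff = config$coupling_coeff, kprime = config$kprime,
           n_increments = config$profile$n_increments,
           geometry = unclass(config$geometry)[c(
             "distal_width", "distal_thickness", "proximal_width",
             "proximal_thickness", "length", "n_slices")]),
      file.path(config$out_dir, "config.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}

#' Export a batch of FEBio model files
#'
#' Writes one `.feb` file per row of a [build_batch()] manifest into
#' `out_dir`, reusing one mesh per twist angle.  File names encode
#' cohort, twist and increment; a `manifest.csv` accompanies the files.
#'
#' @param batch a [build_batch()] data.frame.
#' @param config a [mesh_config()] (twist taken from the batch rows).
#' @param params a [material_params()].
#' @param excitation an [excitation_spec()].
#' @param out_dir output directory.
#' @param ... forwarded to [write_feb()].
#' @return invisible character vector of written file paths.
#' @export
export_feb_batch <- function(batch, config = mesh_config(),
                             params = material_params(),
                             excitation = excitation_spec(),
                             out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg0 <- config; cfg0$twist_deg <- 0
  base <- generate_butterfly_mesh(cfg0)
  areas <- distal_areas(base)
  paths <- character(nrow(batch))
  for (tw in unique(batch$twist_deg)) {
    mesh <- if (tw == 0) base else apply_helical_twist(base, tw)
    mesh <- assign_fiber_directions(mesh)
    rows <- which(batch$twist_deg == tw)
    for (r in rows) {
      lc <- partition_cohort_forces(batch$total_force[r], areas,
                                    batch$ratio[r], tw, batch$increment[r])
      fn <- file.path(out_dir, sprintf("%s_twist%03d_inc%03d.feb",
                                       batch$cohort[r], as.integer(tw),
                                       as.integer(batch$increment[r])))
      write_feb(mesh, params, lc, excitation, fn, ...)
      paths[r] <- fn
    }
  }
  utils::write.csv(cbind(batch, file = basename(paths)),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}
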