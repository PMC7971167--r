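# Orchestration: configuration, the end-to-end pipeline
# (geometry -> field -> population -> thresholds), and run reporting.
# Every stochastic stage derives its seed from the master seed, solves are
# deterministic, and outputs carry no timestamps, so a rerun of the same
# configuration reproduces every artifact bit-identically.

#' Pipeline run configuration
#'
#' @param seed master seed; all per-stage seeds derive from it.
#' @param geometry a [patient_geometry()], or `NULL` to generate a
#'   synthetic patient from the master seed and `ranges`.
#' @param ranges [synth_ranges()] used when generating geometry.
#' @param cond a [tissue_conductivities()].
#' @param wave_spec a [stimulus_waveform()].
#' @param n_neurons population size per electrode (device-style default
#'   250).
#' @param sample_radius_um sampling disk radius (um), default 500.
#' @param lloyd_iterations Lloyd relaxation iterations.
#' @param grid_spacing_um voxel spacing (um).
#' @param solver_tol relative residual tolerance.
#' @param threshold_tol_uA bisection tolerance (uA).
#' @param bracket_hi_uA initial bisection upper bracket (uA).
#' @param map_amplitude_rel activation maps are drawn at
#'   `map_amplitude_rel * electrode threshold`.
#' @param sim_window_ms simulated window per threshold evaluation (ms);
#'   `NULL` simulates the full train. A short window (e.g. 10 ms for a
#'   single-pulse train) is enough to catch every attributable spike and
#'   cuts runtime proportionally.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, geometry = NULL, ranges = synth_ranges(),
                       cond = tissue_conductivities(),
                       wave_spec = stimulus_waveform(),
                       n_neurons = 250L, sample_radius_um = 500,
                       lloyd_iterations = 50L,
                       grid_spacing_um = 25,
                       solver_tol = 1e-6,
                       threshold_tol_uA = 0.25,
                       bracket_hi_uA = 1000,
                       map_amplitude_rel = 1,
                       sim_window_ms = NULL) {
  structure(list(seed = as.integer(seed), geometry = geometry,
                 ranges = ranges, cond = cond, wave_spec = wave_spec,
                 n_neurons = as.integer(n_neurons),
                 sample_radius_um = sample_radius_um,
                 lloyd_iterations = as.integer(lloyd_iterations),
                 grid_spacing_um = grid_spacing_um,
                 solver_tol = solver_tol,
                 threshold_tol_uA = threshold_tol_uA,
                 bracket_hi_uA = bracket_hi_uA,
                 map_amplitude_rel = map_amplitude_rel,
                 sim_window_ms = sim_window_ms),
            class = "run_config")
}

# Sample a field solution at points, continuing radially (~1/r from the
# electrode center) beyond the grid: distal axon compartments leave the
# solved domain where the potential is small; a hard zero would create an
# artificial extracellular step at the boundary.
sample_potentials_extended <- function(sol, points, center_um) {
  g <- sol$grid
  lo <- c(g$x[1], g$y[1], g$z[1])
  hi <- c(g$x[length(g$x)], g$y[length(g$y)], g$z[length(g$z)])
  points <- matrix(points, ncol = 3)
  clamped <- pmin(pmax(points, rep(lo, each = nrow(points))),
                  rep(hi, each = nrow(points)))
  v <- sample_potentials(sol, clamped)
  outside <- rowSums(points != clamped) > 0
  if (any(outside)) {
    r_full <- sqrt(rowSums(sweep(points, 2, center_um)^2))
    r_clmp <- sqrt(rowSums(sweep(clamped, 2, center_um)^2))
    v[outside] <- v[outside] * (r_clmp[outside] / pmax(r_full[outside], 1))
  }
  v
}

#' Run the end-to-end pipeline
#'
#' For each requested electrode: unit-current field solve (terminal active
#' electrode, floating others), impedance, Lloyd population placement,
#' Jansonius axon routing and 3D embedding, per-neuron bisection
#' thresholds, electrode threshold, and an activation map. Artifacts are
#' written as plain text (CSV/JSON) under `out_dir` with an md5 manifest.
#'
#' @param cfg a [run_config()].
#' @param electrodes electrode labels to simulate.
#' @param out_dir output directory (created).
#' @param resume skip electrodes whose threshold table already exists.
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(cfg, electrodes, out_dir, resume = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  g <- cfg$geometry %||%
    generate_synthetic_patient(derive_seed(cfg$seed, "geometry"),
                               ranges = cfg$ranges)
  write_patient_geometry(g, file.path(out_dir, "geometry.json"))
  cfg_out <- cfg; cfg_out$geometry <- NULL
  jsonlite::write_json(
    list(seed = cfg$seed, n_neurons = cfg$n_neurons,
         sample_radius_um = cfg$sample_radius_um,
         grid_spacing_um = cfg$grid_spacing_um,
         solver_tol = cfg$solver_tol,
         threshold_tol_uA = cfg$threshold_tol_uA,
         bracket_hi_uA = cfg$bracket_hi_uA,
         wave = unclass(cfg$wave_spec), cond = unclass(cfg$cond),
         electrodes = electrodes),
    file.path(out_dir, "config.json"), digits = NA, auto_unbox = TRUE)

  dist <- electrode_retina_distances(g)
  utils::write.csv(data.frame(electrode = names(dist), gap_um = unname(dist)),
                   file.path(out_dir, "distances.csv"), row.names = FALSE)

  grid <- build_conductivity_grid(g, cfg$grid_spacing_um, cond = cfg$cond)
  lay <- electrode_layout(g$array)
  jans <- jansonius_params()

  imp_rows <- list(); el_rows <- list()
  for (el in electrodes) {
    say("electrode %s: field solve", el)
    thr_file <- file.path(out_dir, sprintf("thresholds_%s.csv", el))
    sol <- solve_field(grid, source_spec(electrode = el),
                       tol = cfg$solver_tol)
    Z <- compute_impedance(sol)
    imp_rows[[el]] <- data.frame(electrode = el, Z_ohm = Z,
                                 iterations = sol$iterations,
                                 relres = sol$relres)
    if (resume && file.exists(thr_file)) {
      thr_tab <- utils::read.csv(thr_file)
    } else {
      e_xy <- as.numeric(lay[lay$label == el, c("x_um", "y_um")])
      pl <- lloyd_disk_sample(cfg$n_neurons, cfg$sample_radius_um,
                              seed = derive_seed(cfg$seed, paste0("place_", el)),
                              iterations = cfg$lloyd_iterations,
                              center_um = e_xy)
      rows <- vector("list", cfg$n_neurons)
      for (i in seq_len(cfg$n_neurons)) {
        soma_mm <- g$array$center_mm + pl$points[i, ] / 1000
        traj <- jansonius_path(soma_mm, eye_side = "right", params = jans)
        path <- embed_neuron(soma_mm, traj, g$retina,
                             array_center_mm = g$array$center_mm)
        chain <- build_cable(morphometry(), path)
        ve <- sample_potentials_extended(sol, chain$centers,
                                         c(e_xy, 0))
        res <- neuron_threshold(chain, ve, cfg$wave_spec,
                                tol_uA = cfg$threshold_tol_uA,
                                bracket_hi_uA = cfg$bracket_hi_uA,
                                t_end_ms = cfg$sim_window_ms)
        rows[[i]] <- data.frame(
          electrode = el, neuron = i,
          x_um = pl$points[i, 1], y_um = pl$points[i, 2],
          threshold_uA = res$threshold_uA, lo_uA = res$lo_uA,
          hi_uA = res$hi_uA, excitable = res$excitable,
          init_region = res$init_region %||% NA_character_,
          init_comp = res$init_comp %||% NA_integer_)
      }
      thr_tab <- do.call(rbind, rows)
      utils::write.csv(thr_tab, thr_file, row.names = FALSE)
    }
    et <- electrode_threshold(thr_tab)
    el_rows[[el]] <- data.frame(electrode = el,
                                threshold_uA = et$threshold_uA,
                                argmin_neuron = et$neuron,
                                n_resolved = et$n_resolved,
                                gap_um = unname(dist[el]))
    if (!is.na(et$threshold_uA)) {
      e_xy <- as.numeric(lay[lay$label == el, c("x_um", "y_um")])
      pl <- lloyd_disk_sample(cfg$n_neurons, cfg$sample_radius_um,
                              seed = derive_seed(cfg$seed, paste0("place_", el)),
                              iterations = cfg$lloyd_iterations,
                              center_um = e_xy)
      am <- activation_map(pl, thr_tab$threshold_uA,
                           cfg$map_amplitude_rel * et$threshold_uA)
      utils::write.csv(
        data.frame(electrode = el,
                   amplitude_uA = cfg$map_amplitude_rel * et$threshold_uA,
                   bounding_radius_um = am$bounding_radius_um,
                   n_active = sum(am$active)),
        file.path(out_dir, sprintf("activation_%s.csv", el)),
        row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, imp_rows),
                   file.path(out_dir, "impedance.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, el_rows),
                   file.path(out_dir, "electrode_thresholds.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Summarize a completed run directory
#'
#' Aggregates stored tables only (no recomputation): impedance per
#' electrode, electrode thresholds (mean +- sample SD), initiation-site
#' tally, and the electrode-retina distance vs threshold relation.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return List of class `run_report`.
#' @export
report <- function(run_dir) {
  need <- c("impedance.csv", "electrode_thresholds.csv", "distances.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    return(structure(list(gaps = missing), class = "run_report"))
  imp <- utils::read.csv(file.path(run_dir, "impedance.csv"))
  et <- utils::read.csv(file.path(run_dir, "electrode_thresholds.csv"))
  thr_files <- list.files(run_dir, pattern = "^thresholds_.*\\.csv$",
                          full.names = TRUE)
  neuron_tabs <- lapply(thr_files, utils::read.csv)
  init_tally <- if (length(neuron_tabs)) {
    all_init <- unlist(lapply(neuron_tabs, function(tt)
      tt$init_region[!is.na(tt$threshold_uA)]))
    table(all_init)
  } else table(character(0))
  th <- et$threshold_uA[!is.na(et$threshold_uA)]
  dist_cor <- if (nrow(et) >= 3 && stats::sd(et$gap_um) > 0 &&
                  length(th) == nrow(et) && stats::sd(th) > 0)
    stats::cor(et$gap_um, et$threshold_uA) else NA_real_
  structure(list(
    impedance = imp,
    electrode_thresholds = et,
    mean_threshold_uA = mean(th),
    sd_threshold_uA = stats::sd(th),
    initiation_tally = init_tally,
    n_resolved = sum(vapply(neuron_tabs, function(tt)
      sum(!is.na(tt$threshold_uA)), integer(1))),
    distance_threshold_r = dist_cor,
    gaps = character(0)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  if (length(x$gaps)) {
    cat("<run_report> incomplete run; missing:",
        paste(x$gaps, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat(sprintf("<run_report> %d electrodes; threshold %.1f +- %.1f uA\n",
              nrow(x$electrode_thresholds), x$mean_threshold_uA,
              x$sd_threshold_uA))
  cat(sprintf("  impedance %.2f-%.2f kOhm; distance-threshold r = %.2f\n",
              min(x$impedance$Z_ohm) / 1e3, max(x$impedance$Z_ohm) / 1e3,
              x$distance_threshold_r))
  cat("  initiation sites:",
      paste(sprintf("%s=%d", names(x$initiation_tally), x$initiation_tally),
            collapse = " "), "\n")
  invisible(x)
}
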