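# Activation thresholds. Per neuron: bisection on stimulus amplitude until
# the bracket is 0.25 uA wide, with the criterion that every pulse of the
# train elicits at least one action potential somewhere along the cable.
# Per electrode: the minimum over the sampled population (the single-cell
# definition of perceptual threshold used by the framework).

#' Bisection threshold of one neuron
#'
#' Searches the stimulus amplitude at which the activation criterion turns
#' on. The criterion is assumed monotone in amplitude; the bracket
#' endpoints are spot-checked (the search itself evaluates both) and a
#' violation of the assumed one-spike-per-pulse pattern above threshold is
#' reported in `flags`.
#'
#' @param chain a [build_cable()] chain.
#' @param ve_unit per-compartment unit-current extracellular potential
#'   (V/A).
#' @param wave_spec a [stimulus_waveform()].
#' @param tol_uA bracket tolerance (uA), default 0.25.
#' @param bracket_hi_uA initial upper bracket (uA); doubled geometrically
#'   (up to `cap_uA`) while subthreshold.
#' @param cap_uA expansion cap (uA); not-excitable beyond this.
#' @param t_end_ms simulated window; defaults to one pulse period past the
#'   train (so late spikes of the last pulse are attributable).
#' @param criterion `"every"` pulse must elicit a spike (default) or
#'   `"any"`.
#' @param dt_ms integration step.
#' @param spike_level detection level (mV).
#' @return List: `threshold_uA` (bracket midpoint, or `NA` if not
#'   excitable), `lo_uA`, `hi_uA`, `excitable`, `init_comp`, `init_region`,
#'   `init_t_ms` (initiation site at the lowest suprathreshold amplitude
#'   evaluated), `n_sims`, `flags`.
#' @export
neuron_threshold <- function(chain, ve_unit, wave_spec = stimulus_waveform(),
                             tol_uA = 0.25, bracket_hi_uA = 1000,
                             cap_uA = 10000, t_end_ms = NULL,
                             criterion = c("every", "any"),
                             dt_ms = NULL, spike_level = 0) {
  criterion <- match.arg(criterion)
  period <- 1000 / wave_spec$frequency_hz
  t_end <- t_end_ms %||% (wave_spec$train_ms + 0)
  n_sims <- 0L
  flags <- character(0)

  eval_amp <- function(amp) {
    wave <- make_waveform(amp, wave_spec)
    sim <- simulate_cable(chain, ve_unit, wave, dt_ms = dt_ms,
                          t_end_ms = t_end, record = c(1L),
                          record_stride = 1000L, spike_level = spike_level)
    n_sims <<- n_sims + 1L
    win <- pulse_windows(wave, t_end_ms = t_end)
    det <- detect_spikes(sim, win)
    ok <- if (criterion == "every") all(det$spikes_per_pulse == 1L) else
      any(det$spikes_per_pulse == 1L)
    list(ok = ok, sim = sim, det = det)
  }

  if (max(abs(ve_unit)) == 0) {
    return(list(threshold_uA = NA_real_, lo_uA = 0, hi_uA = Inf,
                excitable = FALSE, init_comp = NA_integer_,
                init_region = NA_character_, init_t_ms = NA_real_,
                n_sims = 0L, flags = "zero_field"))
  }

  lo <- 0
  hi <- bracket_hi_uA
  r_hi <- eval_amp(hi)
  while (!r_hi$ok && hi < cap_uA) {
    lo <- hi
    hi <- min(2 * hi, cap_uA)
    r_hi <- eval_amp(hi)
  }
  if (!r_hi$ok) {
    return(list(threshold_uA = NA_real_, lo_uA = lo, hi_uA = hi,
                excitable = FALSE, init_comp = NA_integer_,
                init_region = NA_character_, init_t_ms = NA_real_,
                n_sims = n_sims, flags = c(flags, "not_excitable_at_cap")))
  }
  best_supra <- r_hi
  while (hi - lo > tol_uA) {
    mid <- (lo + hi) / 2
    r_mid <- eval_amp(mid)
    if (r_mid$ok) {
      hi <- mid
      best_supra <- r_mid
    } else {
      lo <- mid
    }
  }
  # near-threshold spike pattern check at the suprathreshold endpoint
  if (criterion == "every" &&
      any(best_supra$det$per_pulse_counts > 2))
    flags <- c(flags, "multi_spike_per_pulse")
  init <- initiation_site(best_supra$sim)
  list(threshold_uA = (lo + hi) / 2, lo_uA = lo, hi_uA = hi,
       excitable = TRUE,
       init_comp = init$comp, init_region = init$region,
       init_t_ms = init$t_ms, n_sims = n_sims, flags = flags)
}

#' Electrode threshold from a population of neuron thresholds
#'
#' The perceptual-threshold proxy: minimum amplitude that excites at least
#' one neuron of the sampled population.
#'
#' @param results list of [neuron_threshold()] results (or a data.frame
#'   with `threshold_uA`).
#' @return List: `threshold_uA`, `neuron` (argmin index), `n_resolved`; or
#'   `threshold_uA = NA` when no neuron is excitable.
#' @export
electrode_threshold <- function(results) {
  th <- if (is.data.frame(results)) results$threshold_uA else
    vapply(results, function(r) r$threshold_uA %||% NA_real_, numeric(1))
  ok <- which(!is.na(th))
  if (!length(ok))
    return(list(threshold_uA = NA_real_, neuron = NA_integer_,
                n_resolved = 0L))
  i <- ok[which.min(th[ok])]
  list(threshold_uA = th[i], neuron = i, n_resolved = length(ok))
}

#' Activation map at a stimulus amplitude
#'
#' Active set, minimum bounding radius (the phosphene-extent proxy), and an
#' interpolated threshold contour grid over the sampling disk (inverse-
#' distance weighting; presentational only).
#'
#' @param placement a [lloyd_disk_sample()] placement.
#' @param thresholds_uA per-neuron thresholds (NA = not excitable).
#' @param amplitude_uA stimulus amplitude (uA).
#' @param grid_n contour grid resolution per axis.
#' @return List: `active` (logical), `bounding_radius_um` (max distance of
#'   active somas from the electrode center; 0 when none), `contour`
#'   (list x, y, z matrix of interpolated thresholds).
#' @export
activation_map <- function(placement, thresholds_uA, amplitude_uA,
                           grid_n = 41L) {
  stopifnot(inherits(placement, "soma_placement"),
            nrow(placement$points) == length(thresholds_uA))
  active <- !is.na(thresholds_uA) & thresholds_uA <= amplitude_uA
  ctr <- placement$center_um
  dist <- sqrt((placement$points[, 1] - ctr[1])^2 +
               (placement$points[, 2] - ctr[2])^2)
  radius <- if (any(active)) max(dist[active]) else 0
  gx <- seq(ctr[1] - placement$radius_um, ctr[1] + placement$radius_um,
            length.out = grid_n)
  gy <- seq(ctr[2] - placement$radius_um, ctr[2] + placement$radius_um,
            length.out = grid_n)
  zi <- matrix(NA_real_, grid_n, grid_n)
  ok <- !is.na(thresholds_uA)
  if (any(ok)) {
    px <- placement$points[ok, 1]; py <- placement$points[ok, 2]
    tv <- thresholds_uA[ok]
    for (j in seq_len(grid_n)) {
      d2 <- outer(gx, px, "-")^2 +
        matrix((gy[j] - py)^2, grid_n, length(px), byrow = TRUE)
      w <- 1 / pmax(d2, 1e-6)
      zi[, j] <- (w %*% tv) / rowSums(w)
    }
    inside <- outer(gx - ctr[1], gy - ctr[2],
                    function(a, b) a^2 + b^2) <= placement$radius_um^2
    zi[!inside] <- NA_real_
  }
  list(active = active, bounding_radius_um = radius,
       contour = list(x = gx, y = gy, z = zi))
}

#' Axon-length convergence study
#'
#' Recomputes the bisection threshold of the same scenario with the distal
#' axon truncated to each candidate total length, and reports the shortest
#' length whose threshold is within `rel_tol` of the longest-length
#' reference.
#'
#' @param lengths_um increasing candidate total lengths (um).
#' @param make_neuron function(total_length_um) returning
#'   `list(chain, ve_unit)`.
#' @param wave_spec,tol_uA,... passed to [neuron_threshold()].
#' @param rel_tol convergence tolerance relative to the reference (0.01).
#' @return List: `table` (length vs threshold), `convergence_length_um`,
#'   `reference_uA`.
#' @export
axon_length_convergence <- function(lengths_um, make_neuron,
                                    wave_spec = stimulus_waveform(),
                                    tol_uA = 0.25, rel_tol = 0.01, ...) {
  stopifnot(length(lengths_um) >= 2, !is.unsorted(lengths_um))
  th <- vapply(lengths_um, function(L) {
    sc <- make_neuron(L)
    neuron_threshold(sc$chain, sc$ve_unit, wave_spec, tol_uA = tol_uA,
                     ...)$threshold_uA
  }, numeric(1))
  ref <- th[length(th)]
  within <- abs(th - ref) <= rel_tol * abs(ref)
  conv <- if (any(within)) lengths_um[which(within)[1]] else NA_real_
  list(table = data.frame(length_um = lengths_um, threshold_uA = th),
       convergence_length_um = conv, reference_uA = ref)
}

#' Electrode-retina distance versus threshold sweep
#'
#' @param distances_um standoff distances (um).
#' @param threshold_fun function(distance_um) returning an electrode
#'   threshold (uA).
#' @return List: `table`, `monotone` (non-decreasing flag), `pearson_r`.
#' @export
distance_threshold_table <- function(distances_um, threshold_fun) {
  th <- vapply(distances_um, threshold_fun, numeric(1))
  mono <- all(diff(th[order(distances_um)]) >= 0)
  if (!mono) warning("threshold is not monotone in electrode-retina distance")
  r <- if (stats::sd(th) > 0 && stats::sd(distances_um) > 0)
    stats::cor(distances_um, th) else NA_real_
  list(table = data.frame(distance_um = distances_um, threshold_uA = th),
       monotone = mono, pearson_r = r)
}

#' Point-source stimulation scenario over the SOCB
#'
#' Convenience builder for oracle-style threshold studies: a straight
#' cable embedded at the standard depths under a flat retina, driven by
#' the analytic point-source field of a monopole at `distance_um` above
#' the SOCB center.
#'
#' @param distance_um source-to-SOCB distance (um).
#' @param total_um total cable length (um).
#' @param sigma_s_m medium conductivity (S/m); default the retinal bulk
#'   value.
#' @param params a [channel_params()].
#' @param compartment_um compartment length (um).
#' @return `list(chain, ve_unit, source_um)`.
#' @export
point_source_scenario <- function(distance_um, total_um = 3000,
                                  sigma_s_m = 0.1,
                                  params = channel_params(),
                                  compartment_um = 1) {
  m <- morphometry(total_um = total_um, compartment_um = compartment_um)
  # straight path: vertical ascent (soma 55 um -> axon 15 um) then along x
  ascent <- 40
  n_up <- ascent + 1
  vert <- cbind(0, 0, seq(55, 15, length.out = n_up))
  horiz <- cbind(seq(5, total_um + 50, by = 5), 0, 15)
  chain <- build_cable(m, rbind(vert, horiz), params)
  bounds <- cumsum(m$L_um)
  socb_mid <- (bounds[["hillock"]] + bounds[["socb"]]) / 2
  idx <- which(chain$region == "socb")
  socb_center <- colMeans(chain$centers[idx, , drop = FALSE])
  src <- socb_center + c(0, 0, -distance_um)
  r_um <- sqrt(rowSums(sweep(chain$centers, 2, src)^2))
  ve_unit <- point_source_potential(sigma_s_m, pmax(r_um, 1))
  list(chain = chain, ve_unit = ve_unit, source_um = src)
}
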