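# Multi-compartment RGC cable model. Morphology is the standard reduced
# block form used for epiretinal stimulation modelling: soma, axon hillock,
# sodium-channel band (SOCB), narrow segment, and distal axon, laid out as
# 1-um compartments along a 3D path with a 90-degree bend from the soma
# depth up to the nerve-fiber-layer depth.
#
# Membrane kinetics are the five-channel amphibian (tiger salamander) RGC
# set of the Fohlmeister lineage, at 22 C without Q10 scaling. The
# supplementary parameter table of the motivating study is unpublished, so
# the per-region maximal conductances below are a documented reconstruction
# from that literature; every value is config-visible and overridable.

#' Voltage-dependent rate functions of the five-channel RGC membrane
#'
#' The single table-driven definition of the gating kinetics (ms^-1, V in
#' mV): m/h (Na), n (delayed-rectifier K), a/hA (A-type K), c (L-type Ca).
#' The C++ integrator carries a transcription of the same functions; tests
#' assert their equality so that the R side can serve as the oracle.
#'
#' @param v membrane potential(s), mV.
#' @return data.frame with columns `alpha_m`, `beta_m`, ..., `beta_c`.
#' @export
fcm_rates <- function(v) {
  linexp <- function(num_scale, v, v0, inv_b) {
    x <- inv_b * (v - v0)
    small <- abs(x) < 1e-7
    out <- num_scale * (v - v0) / expm1(x)
    out[small] <- (-num_scale / inv_b * (1 - 0.5 * x))[small]
    out
  }
  data.frame(
    alpha_m = linexp(-0.6, v, -30, -0.1),
    beta_m = 20 * exp(-(v + 55) / 18),
    alpha_h = 0.4 * exp(-(v + 50) / 20),
    beta_h = 6 / (1 + exp(-0.1 * (v + 20))),
    alpha_n = linexp(-0.02, v, -40, -0.1),
    beta_n = 0.4 * exp(-(v + 50) / 80),
    alpha_a = linexp(-0.006, v, -90, -0.1),
    beta_a = 0.1 * exp(-(v + 30) / 10),
    alpha_hA = 0.04 * exp(-(v + 70) / 20),
    beta_hA = 0.6 / (1 + exp(-0.1 * (v + 40))),
    alpha_c = linexp(-0.3, v, -13, -0.1),
    beta_c = 10 * exp(-(v + 38) / 18))
}

#' @rdname fcm_rates
#' @return `fcm_steady_state()` returns the steady-state gating vector
#'   (m, h, n, a, hA, c) at potential `v`.
#' @export
fcm_steady_state <- function(v) {
  r <- fcm_rates(v)
  a <- as.numeric(r[1, c("alpha_m", "alpha_h", "alpha_n", "alpha_a",
                         "alpha_hA", "alpha_c")])
  b <- as.numeric(r[1, c("beta_m", "beta_h", "beta_n", "beta_a",
                         "beta_hA", "beta_c")])
  stats::setNames(a / (a + b), c("m", "h", "n", "a", "hA", "c"))
}

REGIONS <- c("soma", "hillock", "socb", "narrow", "distal")

#' Reduced RGC morphometry
#'
#' Region lengths and diameters of the block morphology. The defaults give
#' the conventional 3,000 um total at 1 um per compartment; the distal axon
#' absorbs changes in total length.
#'
#' @param total_um total cable length (um).
#' @param compartment_um compartment length (um); must divide every region
#'   length.
#' @param L_um named region lengths (um); `distal` may be `NA` to absorb
#'   the remainder.
#' @param d_um named region diameters (um), all positive.
#' @return Object of class `morphometry`.
#' @export
morphometry <- function(total_um = 3000, compartment_um = 1,
                        L_um = c(soma = 20, hillock = 40, socb = 40,
                                 narrow = 90, distal = NA),
                        d_um = c(soma = 20, hillock = 2, socb = 1.5,
                                 narrow = 0.5, distal = 1)) {
  stopifnot(setequal(names(L_um), REGIONS), setequal(names(d_um), REGIONS))
  L_um <- L_um[REGIONS]; d_um <- d_um[REGIONS]
  if (is.na(L_um[["distal"]]))
    L_um[["distal"]] <- total_um - sum(L_um[-5])
  if (abs(sum(L_um) - total_um) > 1e-9)
    stop_config("region lengths must sum to the total length")
  if (any(L_um <= 0) || any(d_um <= 0))
    stop_config("region lengths and diameters must be > 0")
  if (any(abs(round(L_um / compartment_um) - L_um / compartment_um) > 1e-9))
    stop_config("compartment length must divide every region length")
  structure(list(total_um = total_um, compartment_um = compartment_um,
                 L_um = L_um, d_um = d_um),
            class = "morphometry")
}

#' Five-channel membrane parameters
#'
#' Per-region maximal conductances (mS/cm^2) and global passive/ionic
#' constants. The SOCB carries the highest Na density by a wide margin,
#' which is what makes it the preferred extracellular excitation site. The
#' Ca reversal potential is not a fixed parameter: it is recomputed each
#' step by the Nernst equation from the instantaneous submembrane Ca concentration.
#'
#' @param table data.frame with columns `region`, `gNa`, `gK`, `gKA`,
#'   `gKCa`, `gCa`, `gL` (mS/cm^2), one row per region.
#' @param e_na,e_k reversal potentials (mV).
#' @param e_l leak reversal (mV) or `"auto"`: per-compartment value chosen
#'   so that the stated resting potential is an exact equilibrium.
#' @param cm_uF_cm2 specific membrane capacitance.
#' @param ra_ohm_cm axial resistivity.
#' @param v_rest_mV resting potential used for initialization (and for the
#'   `"auto"` leak reversal).
#' @param ca_rest_mM,ca_out_mM,ca_diss_mM resting/extracellular/half-
#'   activation Ca concentrations (mM).
#' @param tau_ca_ms Ca pool removal time constant (ms).
#' @param temperature_C temperature for the Ca Nernst potential.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(table = default_channel_table(),
                           e_na = 35, e_k = -75, e_l = "auto",
                           cm_uF_cm2 = 1, ra_ohm_cm = 110,
                           v_rest_mV = -65,
                           ca_rest_mM = 1e-4, ca_out_mM = 1.8,
                           ca_diss_mM = 1e-3, tau_ca_ms = 10,
                           temperature_C = 22) {
  need <- c("region", "gNa", "gK", "gKA", "gKCa", "gCa", "gL")
  stopifnot(all(need %in% names(table)), setequal(table$region, REGIONS))
  if (any(as.matrix(table[, -1]) < 0))
    stop_config("conductance densities must be >= 0")
  gna <- stats::setNames(table$gNa, table$region)
  if (!(gna[["socb"]] > max(gna[setdiff(REGIONS, "socb")])))
    stop_config("SOCB Na density must be strictly greatest across regions")
  structure(list(table = table[match(REGIONS, table$region), ],
                 e_na = e_na, e_k = e_k, e_l = e_l,
                 cm_uF_cm2 = cm_uF_cm2, ra_ohm_cm = ra_ohm_cm,
                 v_rest_mV = v_rest_mV,
                 ca_rest_mM = ca_rest_mM, ca_out_mM = ca_out_mM,
                 ca_diss_mM = ca_diss_mM, tau_ca_ms = tau_ca_ms,
                 temperature_C = temperature_C),
            class = "channel_params")
}

#' @rdname channel_params
#' @export
default_channel_table <- function() {
  data.frame(
    region = c("soma", "hillock", "socb", "narrow", "distal"),
    gNa  = c(80, 150, 2000, 100, 40),
    gK   = c(18, 18, 18, 18, 18),
    gKA  = c(54, 54, 54, 54, 54),
    gKCa = c(0.065, 0.065, 0.065, 0.065, 0.065),
    gCa  = c(1.5, 1.5, 1.5, 1.5, 1.5),
    gL   = c(0.05, 0.05, 0.05, 0.05, 0.05))
}

# Nernst factor RT/(2F) in mV at the configured temperature.
nernst_ca_factor <- function(params)
  8.314462 * (273.15 + params$temperature_C) / (2 * 96485.33) * 1000

#' Build a compartment chain along a 3D path
#'
#' Lays `total/compartment` compartments of the block morphometry along a
#' polyline (um), assigns per-region channel densities, and initializes the
#' state to rest.
#'
#' @param m a [morphometry()].
#' @param path matrix (n x 3) polyline (um) with arc length at least the
#'   total cable length.
#' @param params a [channel_params()].
#' @return Object of class `compartment_chain`.
#' @export
build_cable <- function(m, path, params = channel_params()) {
  stopifnot(inherits(m, "morphometry"))
  path <- matrix(path, ncol = 3)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] < m$total_um - 1e-6)
    stop_config("path arc length (%.1f um) shorter than the cable (%g um)",
                arc[length(arc)], m$total_um)
  dx <- m$compartment_um
  n <- round(m$total_um / dx)
  s_mid <- (seq_len(n) - 0.5) * dx
  centers <- cbind(stats::approx(arc, path[, 1], xout = s_mid)$y,
                   stats::approx(arc, path[, 2], xout = s_mid)$y,
                   stats::approx(arc, path[, 3], xout = s_mid)$y)
  bounds <- cumsum(m$L_um)
  region <- REGIONS[findInterval(s_mid, c(0, bounds), rightmost.closed = TRUE,
                                 left.open = TRUE)]
  region[s_mid <= m$L_um[[1]]] <- "soma"
  ridx <- match(region, REGIONS)
  d_um <- m$d_um[ridx]

  area_cm2 <- pi * d_um * dx * 1e-8           # lateral cylinder area
  cm_uF <- params$cm_uF_cm2 * area_cm2
  tab <- params$table
  dens <- as.matrix(tab[, c("gNa", "gK", "gKA", "gKCa", "gCa", "gL")])
  gabs <- t(dens[ridx, ]) * rep(area_cm2, each = 6)  # mS, 6 x n

  # axial conductance between neighbors: series half-compartments
  r_half <- params$ra_ohm_cm * (dx / 2 * 1e-4) / (pi * (d_um / 2 * 1e-4)^2)
  g_ax <- 1000 / (r_half[-n] + r_half[-1])     # mS

  shell_vol_L <- pi * (d_um / 2 * 1e-4)^2 * (dx * 1e-4) * 1e-3

  v0 <- params$v_rest_mV
  ss <- fcm_steady_state(v0)
  eca0 <- nernst_ca_factor(params) * log(params$ca_out_mM / params$ca_rest_mM)
  kca0 <- (params$ca_rest_mM / params$ca_diss_mM)^2
  kca0 <- kca0 / (1 + kca0)
  g_at_rest <- rbind(gabs[1, ] * ss[["m"]]^3 * ss[["h"]],
                     gabs[2, ] * ss[["n"]]^4,
                     gabs[3, ] * ss[["a"]]^3 * ss[["hA"]],
                     gabs[4, ] * kca0,
                     gabs[5, ] * ss[["c"]]^3)
  i_other <- g_at_rest[1, ] * (v0 - params$e_na) +
    (g_at_rest[2, ] + g_at_rest[3, ] + g_at_rest[4, ]) * (v0 - params$e_k) +
    g_at_rest[5, ] * (v0 - eca0)
  el <- if (identical(params$e_l, "auto")) {
    v0 + i_other / gabs[6, ]
  } else rep(params$e_l, n)

  structure(list(n = n, region = region, centers = centers,
                 compartment_um = dx, diameter_um = d_um,
                 area_cm2 = area_cm2, cm_uF = cm_uF, gabs = gabs,
                 g_ax = g_ax, el = el, shell_vol_L = shell_vol_L,
                 gates0 = ss, v0 = v0, params = params, morph = m),
            class = "compartment_chain")
}

#' @export
print.compartment_chain <- function(x, ...) {
  cat(sprintf("<compartment_chain> %d compartments x %g um (%s)\n",
              x$n, x$compartment_um,
              paste(sprintf("%s:%g", REGIONS, x$morph$L_um), collapse = " ")))
  invisible(x)
}

#' Simulate the cable under extracellular (and/or intracellular) drive
#'
#' Integrates the cable equation with the theta-method (backward Euler by
#' default, Crank-Nicolson with `theta = 0.5`) on the tridiagonal system,
#' gating by Rush-Larsen. The extracellular potential enters through
#' neighbor differences of `V_e(t) = ve_unit * I(t)`.
#'
#' @param chain a [build_cable()] result.
#' @param ve_unit per-compartment unit-current extracellular potential
#'   (V/A); scalar 0 allowed.
#' @param wave a [make_waveform()] result (its `dt` is the integration
#'   step unless `dt_ms` is given).
#' @param dt_ms integration step (ms).
#' @param t_end_ms simulate beyond the waveform by padding with zero
#'   current up to this time.
#' @param record compartment indices to record (default: a sparse subset).
#' @param record_stride record every k-th step.
#' @param spike_level upward-crossing detection level (mV).
#' @param theta implicitness (1 backward Euler, 0.5 Crank-Nicolson).
#' @param intracellular optional list(amp_uA, comp, t0_ms, t1_ms) step
#'   current injection.
#' @return Object of class `cable_sim`: recorded `t_ms`, `v` (time x
#'   compartment), raw upward `crossings`, and final state.
#' @export
simulate_cable <- function(chain, ve_unit, wave = NULL, dt_ms = NULL,
                           t_end_ms = NULL, record = NULL,
                           record_stride = 10L, spike_level = 0,
                           theta = 1, intracellular = NULL) {
  stopifnot(inherits(chain, "compartment_chain"))
  n <- chain$n
  if (length(ve_unit) == 1) ve_unit <- rep(ve_unit, n)
  stopifnot(length(ve_unit) == n, all(is.finite(ve_unit)))
  dt <- dt_ms %||% (if (!is.null(wave)) wave$spec$dt_ms else 0.005)
  i_wave <- if (is.null(wave)) numeric(0) else wave$i_uA
  if (!is.null(wave) && !is.null(dt_ms) && abs(dt_ms - wave$spec$dt_ms) > 1e-12) {
    # resample the waveform at the integration step
    nt <- round(wave$spec$train_ms / dt)
    idx <- pmin(floor((seq_len(nt) - 0.5) * dt / wave$spec$dt_ms) + 1,
                length(wave$i_uA))
    i_wave <- wave$i_uA[idx]
  }
  t_total <- t_end_ms %||% (if (!is.null(wave)) wave$spec$train_ms else 300)
  nt <- round(t_total / dt)
  if (length(i_wave) < nt) i_wave <- c(i_wave, numeric(nt - length(i_wave)))
  i_wave <- i_wave[seq_len(nt)]

  if (is.null(record))
    record <- unique(round(seq(1, n, length.out = min(n, 60L))))
  ic <- intracellular %||% list(amp_uA = 0, comp = 1, t0_ms = 0, t1_ms = 0)

  res <- .cable_integrate(
    chain$gabs, chain$el, chain$params$e_na, chain$params$e_k,
    chain$cm_uF, chain$g_ax, ve_unit, i_wave, dt,
    chain$v0, as.numeric(chain$gates0),
    chain$params$ca_rest_mM, chain$params$ca_out_mM, chain$params$ca_diss_mM,
    chain$params$tau_ca_ms, chain$shell_vol_L,
    nernst_ca_factor(chain$params),
    as.integer(record - 1L), as.integer(record_stride),
    spike_level, theta,
    ic$amp_uA, as.integer(ic$comp - 1L), ic$t0_ms, ic$t1_ms)
  if (res$diverged)
    stop_config("cable integration diverged at t = %.3f ms", res$t_fail)

  structure(list(t_ms = as.numeric(res$t), v = as.matrix(res$v),
                 record = record,
                 crossings = data.frame(comp = as.integer(res$cross_comp),
                                        t_ms = as.numeric(res$cross_time)),
                 v_final = res$v_final, ca_final = res$ca_final,
                 gates_final = res$gates_final,
                 region = chain$region, dt_ms = dt,
                 spike_level = spike_level),
            class = "cable_sim")
}

# Upward-crossing events from a dense trace (time x compartments).
trace_crossings <- function(t_ms, v, level = 0, comps = seq_len(ncol(v))) {
  ev <- lapply(seq_along(comps), function(j) {
    up <- which(v[-1, j] >= level & v[-nrow(v), j] < level)
    if (!length(up)) return(NULL)
    data.frame(comp = comps[j], t_ms = t_ms[up + 1])
  })
  out <- do.call(rbind, ev)
  if (is.null(out)) data.frame(comp = integer(0), t_ms = numeric(0)) else out
}

#' Detect spikes and attribute them to stimulus pulses
#'
#' A pulse "has a spike" iff some compartment crosses the detection level
#' upward within its attribution window. Multiple crossings of the same
#' compartment within the refractory merge window count once.
#'
#' @param x a `cable_sim`, or a list with `t_ms` and a voltage matrix `v`
#'   (columns = compartments).
#' @param windows_ms matrix (n x 2) of per-pulse windows (see
#'   [pulse_windows()]).
#' @param level detection level (mV); for a `cable_sim` the level used
#'   during integration applies.
#' @param merge_ms refractory merge window (ms).
#' @return List: `events` (merged spike events: comp, t_ms),
#'   `spikes_per_pulse` (integer vector: 1 if the pulse elicited at least
#'   one spike), `per_pulse_counts` (merged event counts per window).
#' @export
detect_spikes <- function(x, windows_ms, level = 0, merge_ms = 1) {
  raw <- if (inherits(x, "cable_sim")) {
    x$crossings
  } else {
    trace_crossings(x$t_ms, as.matrix(x$v), level)
  }
  merged <- if (nrow(raw)) {
    raw <- raw[order(raw$comp, raw$t_ms), , drop = FALSE]
    keep <- unlist(lapply(split(raw$t_ms, raw$comp), function(tt) {
      k <- logical(length(tt)); last <- -Inf
      for (i in seq_along(tt)) {
        if (tt[i] - last > merge_ms) { k[i] <- TRUE; last <- tt[i] }
      }
      k
    }))
    raw[keep, , drop = FALSE]
  } else raw
  windows_ms <- matrix(windows_ms, ncol = 2)
  counts <- vapply(seq_len(nrow(windows_ms)), function(p) {
    sum(merged$t_ms >= windows_ms[p, 1] & merged$t_ms < windows_ms[p, 2])
  }, integer(1))
  list(events = merged, spikes_per_pulse = as.integer(counts > 0),
       per_pulse_counts = counts)
}

#' Action-potential initiation site
#'
#' The first compartment in which a spike occurred: earliest merged
#' crossing wins, ties broken toward the smaller compartment index.
#'
#' @param x a `cable_sim` or a `detect_spikes()` result.
#' @param region optional per-compartment region labels (taken from the
#'   `cable_sim` when available).
#' @return List with `comp`, `t_ms`, `region`, or `NULL` if no spike
#'   occurred (a no-site result, not an error).
#' @export
initiation_site <- function(x, region = NULL) {
  ev <- if (inherits(x, "cable_sim")) {
    region <- region %||% x$region
    x$crossings
  } else x$events
  if (is.null(ev) || nrow(ev) == 0) return(NULL)
  best <- ev[order(ev$t_ms, ev$comp), , drop = FALSE][1, ]
  list(comp = best$comp, t_ms = best$t_ms,
       region = if (!is.null(region)) region[best$comp] else NA_character_)
}
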