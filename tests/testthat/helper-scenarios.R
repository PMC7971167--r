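# Shared fixtures, all built in code.

# Collapsed-range synthetic patient: flat retina of fixed thickness, fixed
# electrode-retina gap, no tilt, uniform capsule.
flat_patient <- function(standoff_um = 150, thickness_um = 200,
                         capsule_um = 25, seed = 5) {
  rng <- synth_ranges(thickness_um = rep(thickness_um, 2),
                      gap_um = rep(standoff_um, 2),
                      tilt_deg = c(0, 0),
                      capsule_um = rep(capsule_um, 2))
  g <- generate_synthetic_patient(seed, ranges = rng, height_amp_um = 0)
  g
}

# Tiny 2x2-electrode patient for voxelization tests.
small_patient <- function(thickness_um = 200, standoff_um = 100,
                          tilt_deg = c(0, 0), height_fun = NULL,
                          thickness_fun = NULL, capsule_um = 0) {
  arr <- electrode_array(rows = 2L, cols = 2L, center_mm = c(0, 0),
                         tilt_deg = tilt_deg, standoff_um = standoff_um)
  x <- seq(-1500, 1500, length.out = 13)
  y <- seq(-1500, 1500, length.out = 13)
  thick <- if (is.null(thickness_fun)) {
    matrix(thickness_um, 13, 13)
  } else outer(x, y, thickness_fun)
  ht <- if (is.null(height_fun)) matrix(0, 13, 13) else outer(x, y, height_fun)
  patient_geometry(
    eye_params(),
    arr,
    retinal_surface(x, y, thick, ht),
    fibrotic_capsule(x, y, matrix(capsule_um, 13, 13)))
}

# Single-pulse waveform used throughout threshold tests (one 20 Hz pulse).
ws_single <- stimulus_waveform(train_ms = 50, dt_ms = 0.005)

# Hand-built single-compartment chain (soma patch) for the brute-force
# membrane oracle.
single_comp_chain <- function(params = channel_params(), d_um = 20,
                              L_um = 20) {
  dens <- params$table[params$table$region == "soma", ]
  A <- pi * d_um * L_um * 1e-8
  gabs <- matrix(as.numeric(dens[c("gNa", "gK", "gKA", "gKCa", "gCa",
                                   "gL")]) * A, ncol = 1)
  ss <- fcm_steady_state(params$v_rest_mV)
  nf <- retistim:::nernst_ca_factor(params)
  eca0 <- nf * log(params$ca_out_mM / params$ca_rest_mM)
  kca0 <- (params$ca_rest_mM / params$ca_diss_mM)^2
  kca0 <- kca0 / (1 + kca0)
  v0 <- params$v_rest_mV
  gr <- c(gabs[1] * ss[["m"]]^3 * ss[["h"]], gabs[2] * ss[["n"]]^4,
          gabs[3] * ss[["a"]]^3 * ss[["hA"]], gabs[4] * kca0,
          gabs[5] * ss[["c"]]^3)
  i_other <- gr[1] * (v0 - params$e_na) +
    (gr[2] + gr[3] + gr[4]) * (v0 - params$e_k) + gr[5] * (v0 - eca0)
  structure(list(
    n = 1L, region = "soma", centers = matrix(0, 1, 3),
    compartment_um = L_um, diameter_um = d_um, area_cm2 = A,
    cm_uF = A * params$cm_uF_cm2, gabs = gabs, g_ax = numeric(0),
    el = v0 + i_other / gabs[6],
    shell_vol_L = pi * (d_um / 2 * 1e-4)^2 * (L_um * 1e-4) * 1e-3,
    gates0 = ss, v0 = v0, params = params, morph = NULL),
    class = "compartment_chain")
}

# Independent brute-force integration (classic RK4) of the same membrane
# ODEs, driven by an intracellular current step. This is the oracle: it
# shares only the rate-function table with the production integrator.
rk4_single_comp <- function(chain, amp_uA, t0_ms, t1_ms, dt_ms, t_end_ms) {
  par <- chain$params
  gabs <- chain$gabs
  nf <- retistim:::nernst_ca_factor(par)
  el <- chain$el
  CA_K <- 1e-6 / (2 * 96485.33)
  deriv <- function(t, y) {
    v <- y[1]; g <- y[2:7]; ca <- y[8]
    r <- fcm_rates(v)
    a <- as.numeric(r[c("alpha_m", "alpha_h", "alpha_n", "alpha_a",
                        "alpha_hA", "alpha_c")])
    b <- as.numeric(r[c("beta_m", "beta_h", "beta_n", "beta_a",
                        "beta_hA", "beta_c")])
    kca <- (ca / par$ca_diss_mM)^2; kca <- kca / (1 + kca)
    eca <- nf * log(par$ca_out_mM / ca)
    gch <- c(gabs[1] * g[1]^3 * g[2], gabs[2] * g[3]^4,
             gabs[3] * g[4]^3 * g[5], gabs[4] * kca, gabs[5] * g[6]^3)
    iion <- gch[1] * (v - par$e_na) +
      (gch[2] + gch[3] + gch[4]) * (v - par$e_k) +
      gch[5] * (v - eca) + gabs[6] * (v - el)
    iinj <- if (t > t0_ms && t <= t1_ms) amp_uA else 0
    c((-iion + iinj) / chain$cm_uF,
      a * (1 - g) - b * g,
      -gch[5] * (v - eca) * CA_K / chain$shell_vol_L -
        (ca - par$ca_rest_mM) / par$tau_ca_ms)
  }
  nt <- round(t_end_ms / dt_ms)
  y <- c(chain$v0, as.numeric(chain$gates0), par$ca_rest_mM)
  out <- numeric(nt + 1); out[1] <- y[1]
  tt <- 0
  for (s in seq_len(nt)) {
    k1 <- deriv(tt, y)
    k2 <- deriv(tt + dt_ms / 2, y + dt_ms / 2 * k1)
    k3 <- deriv(tt + dt_ms / 2, y + dt_ms / 2 * k2)
    k4 <- deriv(tt + dt_ms, y + dt_ms * k3)
    y <- y + dt_ms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt <- tt + dt_ms
    out[s + 1] <- y[1]
  }
  out
}
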