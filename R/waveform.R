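# Stimulus waveforms: biphasic, charge-balanced, cathodic-first current
# pulse trains, as delivered by the implant during threshold measurements
# (0.45 ms/phase at 20 Hz for 250 ms by default).

#' Stimulus waveform specification
#'
#' @param phase_ms duration of each phase (ms).
#' @param interphase_gap_ms gap between the cathodic and anodic phase (ms).
#' @param frequency_hz pulse repetition rate (Hz).
#' @param train_ms total train duration (ms).
#' @param dt_ms sampling step (ms); must divide the phase width and the
#'   inter-phase gap.
#' @return Object of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(phase_ms = 0.45, interphase_gap_ms = 0,
                              frequency_hz = 20, train_ms = 250,
                              dt_ms = 0.005) {
  stopifnot(phase_ms > 0, interphase_gap_ms >= 0, frequency_hz > 0,
            train_ms > 0, dt_ms > 0)
  divides <- function(a, b) abs(round(a / b) - a / b) < 1e-9
  if (!divides(phase_ms, dt_ms) || !divides(interphase_gap_ms, dt_ms))
    stop_config("dt must divide the phase width and inter-phase gap")
  period_ms <- 1000 / frequency_hz
  if (2 * phase_ms + interphase_gap_ms > period_ms)
    stop_config("pulse does not fit in the stimulation period")
  structure(list(phase_ms = phase_ms, interphase_gap_ms = interphase_gap_ms,
                 frequency_hz = frequency_hz, train_ms = train_ms,
                 dt_ms = dt_ms),
            class = "stimulus_waveform")
}

#' Sample a charge-balanced biphasic waveform
#'
#' Cathodic (negative) phase first, then an equal-and-opposite anodic
#' phase; charge balance is exact by construction (equal sample counts per
#' phase). Sample `k` holds the current over `[ (k-1) dt, k dt )`.
#'
#' @param amplitude_uA phase amplitude (uA), non-negative.
#' @param spec a [stimulus_waveform()].
#' @return List with `t_ms` (sample start times), `i_uA` (sampled current),
#'   `shape` (normalized to -1/0/+1), `onsets_ms` (pulse onset times),
#'   `n_pulses`, and the spec.
#' @export
make_waveform <- function(amplitude_uA, spec = stimulus_waveform()) {
  stopifnot(inherits(spec, "stimulus_waveform"), amplitude_uA >= 0)
  dt <- spec$dt_ms
  nt <- round(spec$train_ms / dt)
  period_ms <- 1000 / spec$frequency_hz
  n_pulses <- floor(spec$train_ms / period_ms + 1e-9)
  if (n_pulses < 1) n_pulses <- 1
  onsets <- (seq_len(n_pulses) - 1) * period_ms
  shape <- numeric(nt)
  n_ph <- round(spec$phase_ms / dt)
  n_gap <- round(spec$interphase_gap_ms / dt)
  for (p in seq_len(n_pulses)) {
    s0 <- round(onsets[p] / dt)
    shape[s0 + seq_len(n_ph)] <- -1                     # cathodic first
    shape[s0 + n_ph + n_gap + seq_len(n_ph)] <- 1       # balancing anodic
  }
  list(t_ms = (seq_len(nt) - 1) * dt, i_uA = amplitude_uA * shape,
       shape = shape, onsets_ms = onsets, n_pulses = n_pulses, spec = spec)
}

#' Per-pulse attribution windows
#'
#' Window `p` is `[onset_p, onset_{p+1})`, the last one closing at the end
#' of the simulated interval.
#'
#' @param wave a waveform from [make_waveform()].
#' @param t_end_ms end of the simulated interval (ms); defaults to the
#'   train duration.
#' @return Matrix (n_pulses x 2) of window bounds (ms).
#' @export
pulse_windows <- function(wave, t_end_ms = wave$spec$train_ms) {
  on <- wave$onsets_ms
  cbind(start = on, end = c(on[-1], t_end_ms))
}
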