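#' Sweep-series container for stimulus-response recordings
#'
#' @param stimulus Strictly monotone stimulus axis (e.g. mmHg steps of -5,
#'   or probe displacement in 0.8 um increments).
#' @param time_s Shared time base (s) of the current traces.
#' @param current_pA Matrix, one column per sweep, `length(time_s)` rows.
#' @param stim_onset_s,stim_duration_s Stimulus window.
#' @param stimulus_unit Unit label of the stimulus axis.
#' @return An object of class `sweep_series`.
#' @export
sweep_series <- function(stimulus, time_s, current_pA, stim_onset_s,
                         stim_duration_s, stimulus_unit = "mmHg") {
  current_pA <- as.matrix(current_pA)
  stopifnot(length(stimulus) == ncol(current_pA),
            length(time_s) == nrow(current_pA))
  ds <- diff(stimulus)
  if (length(ds) > 0 && !(all(ds > 0) || all(ds < 0))) {
    stop("stimulus axis must be strictly monotone", call. = FALSE)
  }
  structure(
    list(stimulus = stimulus, time_s = time_s, current_pA = current_pA,
         stim_onset_s = stim_onset_s, stim_duration_s = stim_duration_s,
         stimulus_unit = stimulus_unit),
    class = "sweep_series"
  )
}

#' @export
print.sweep_series <- function(x, ...) {
  cat(sprintf("Sweep series: %d sweeps (%s %g..%g), %d samples/sweep\n",
              length(x$stimulus), x$stimulus_unit, x$stimulus[1],
              x$stimulus[length(x$stimulus)], length(x$time_s)))
  invisible(x)
}

#' Generate synthetic pressure-clamp sweeps with a Boltzmann response
#'
#' Peak current at pressure P follows
#' `I(P) = imax / (1 + exp((P - p50)/k))` with `k > 0`, so the response
#' grows as the pressure becomes more negative. Each sweep is a square
#' current pulse over the stimulus window whose amplitude is the Boltzmann
#' peak plus Gaussian noise (noise acts on the per-sweep peak, matching how
#' peak-current scatter presents after low-pass filtering).
#'
#' @param p50 Half-maximal pressure (mmHg, typically negative).
#' @param slope Boltzmann slope factor k (mmHg, positive).
#' @param imax Maximal peak current (pA).
#' @param pressures Monotone pressure protocol (default -5 mmHg increments
#'   to -80 mmHg).
#' @param noise_sd Gaussian SD (pA) of the per-sweep peak noise.
#' @param seed Integer seed.
#' @param rate_hz Sampling rate; the defaults keep sweeps light (0.7 s at
#'   2 kHz, 500 ms stimulus from 0.1 s).
#' @return A [sweep_series()].
#' @export
generate_pressure_sweeps <- function(p50, slope, imax,
                                     pressures = seq(-5, -80, by = -5),
                                     noise_sd = 0, seed = 1L,
                                     rate_hz = 2000) {
  if (length(pressures) == 0) stop("empty pressure list", call. = FALSE)
  set.seed(seed)
  onset <- 0.1; dur <- 0.5
  t <- seq(0, 0.7, by = 1 / rate_hz)
  in_stim <- t >= onset & t < onset + dur
  peaks <- imax / (1 + exp((pressures - p50) / slope)) +
    stats::rnorm(length(pressures), 0, noise_sd)
  cur <- sapply(peaks, function(pk) {
    tr <- numeric(length(t))
    tr[in_stim] <- pk
    tr
  })
  sweep_series(pressures, t, cur, onset, dur, "mmHg")
}

#' Generate a synthetic inactivating current decay
#'
#' Samples `I(t) = c1 + c2 * exp(-(t - t0)/tau)` for `t >= t0` plus
#' Gaussian noise.
#'
#' @param c1 Steady-state (sustained) current (pA).
#' @param c2 Decaying amplitude (pA); peak at `t0` is `c1 + c2`.
#' @param t0 Decay start (s).
#' @param tau_ms Inactivation time constant in ms (> 0).
#' @param rate_hz Sampling rate.
#' @param duration_s Trace length from `t0`.
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed Integer seed.
#' @return Data frame `t_s, i_pA`.
#' @export
generate_current_decay <- function(c1, c2, t0, tau_ms, rate_hz = 5000,
                                   duration_s = 0.15, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(tau_ms > 0)
  set.seed(seed)
  t <- seq(t0, t0 + duration_s, by = 1 / rate_hz)
  i <- c1 + c2 * exp(-(t - t0) / (tau_ms / 1000)) +
    stats::rnorm(length(t), 0, noise_sd)
  data.frame(t_s = t, i_pA = i)
}

#' Generate synthetic two-level single-channel traces
#'
#' For each holding potential the trace alternates between a closed level
#' at 0 pA and an open level offset by Ohm's law,
#' `conductance * (V - reversal) / 1000` pA (pS times mV gives fA), with
#' per-sample Gaussian noise. Openings are drawn independently per sample
#' with probability `open_prob`, which is sufficient for amplitude
#' histograms.
#'
#' @param voltages Holding potentials (mV); the standard protocol is -140
#'   to -40 mV in 20 mV steps.
#' @param conductance_pS Unitary conductance (> 0).
#' @param reversal_mV Reversal potential.
#' @param open_prob Per-sample open probability.
#' @param rate_hz Sampling rate.
#' @param duration_s Trace length per voltage.
#' @param noise_sd Gaussian noise SD (pA); recycled across voltages, so a
#'   vector can scale the noise with the per-voltage amplitude.
#' @param seed Integer seed.
#' @return List of class `single_channel_series` with `voltages`,
#'   `traces` (one `t_s, i_pA` data frame per voltage), `rate_hz` and the
#'   generating parameters.
#' @export
generate_single_channel <- function(voltages = seq(-140, -40, by = 20),
                                    conductance_pS = 40, reversal_mV = 0,
                                    open_prob = 0.35, rate_hz = 2000,
                                    duration_s = 2, noise_sd = 0,
                                    seed = 1L) {
  stopifnot(conductance_pS > 0)
  set.seed(seed)
  m <- round(rate_hz * duration_s)
  t <- seq_len(m) / rate_hz
  noise_sd <- rep_len(noise_sd, length(voltages))
  traces <- lapply(seq_along(voltages), function(vi) {
    amp <- conductance_pS * (voltages[vi] - reversal_mV) / 1000
    open <- stats::runif(m) < open_prob
    data.frame(t_s = t,
               i_pA = open * amp + stats::rnorm(m, 0, noise_sd[vi]))
  })
  structure(
    list(voltages = voltages, traces = traces, rate_hz = rate_hz,
         conductance_pS = conductance_pS, reversal_mV = reversal_mV),
    class = "single_channel_series"
  )
}

#' Generate a synthetic per-cell dose-response table
#'
#' Per-cell maximal F/F0 responses follow a logistic in log10
#' concentration, `bottom + (fmax - bottom) / (1 + 10^(hill *
#' (log10(ec50) - log10(c))))`, plus cell-level Gaussian noise. At
#' `c = ec50` the noiseless response is the midpoint of bottom and fmax.
#'
#' @param ec50 Half-maximal concentration (uM, > 0).
#' @param hill Hill coefficient.
#' @param fmax Top asymptote (max F/F0).
#' @param concentrations Tested concentrations (uM).
#' @param n_cells Cells per concentration.
#' @param noise_sd Cell-level response noise SD.
#' @param bottom Bottom asymptote (default 1, i.e. no response).
#' @param seed Integer seed.
#' @return Data frame `conc_uM, cell, max_f_over_f0`.
#' @export
generate_dose_response <- function(ec50, hill, fmax,
                                   concentrations = 10^seq(-3, 1.5, length.out = 7),
                                   n_cells = 30, noise_sd = 0, bottom = 1,
                                   seed = 1L) {
  stopifnot(ec50 > 0)
  set.seed(seed)
  rows <- lapply(seq_along(concentrations), function(i) {
    cc <- concentrations[i]
    mu <- bottom + (fmax - bottom) /
      (1 + 10^(hill * (log10(ec50) - log10(cc))))
    data.frame(conc_uM = cc, cell = seq_len(n_cells),
               max_f_over_f0 = mu + stats::rnorm(n_cells, 0, noise_sd))
  })
  do.call(rbind, rows)
}
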