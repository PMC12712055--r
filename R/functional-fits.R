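#' Mechanical activation threshold of a sweep series
#'
#' The threshold is the first stimulus (in protocol order) whose peak
#' deviation from the baseline mean exceeds `k_sd` times the baseline
#' standard deviation; "not reached" if none does.
#'
#' @param series A [sweep_series()].
#' @param baseline_window Time window (s) preceding the stimulus used for
#'   the baseline mean and SD; default is everything before stimulus onset.
#' @param k_sd Multiplier of the baseline SD (default 6).
#' @param sd_floor Absolute floor (pA) substituted when the baseline SD is
#'   zero (noise-free synthetic traces); logged in the result.
#' @return List of class `threshold_result`: `threshold` (stimulus value or
#'   `NA`), `reached`, `index`, `baseline_mean`, `baseline_sd`,
#'   `sd_floor_used`.
#' @export
detect_threshold <- function(series, baseline_window = NULL, k_sd = 6,
                             sd_floor = 0.5) {
  stopifnot(inherits(series, "sweep_series"))
  if (is.null(baseline_window)) baseline_window <- c(0, series$stim_onset_s)
  if (baseline_window[2] > series$stim_onset_s) {
    stop("baseline window must precede stimulus onset", call. = FALSE)
  }
  bl <- series$time_s >= baseline_window[1] & series$time_s < baseline_window[2]
  in_stim <- series$time_s >= series$stim_onset_s &
    series$time_s < series$stim_onset_s + series$stim_duration_s
  bmean <- mean(series$current_pA[bl, ])
  bsd <- stats::sd(as.vector(series$current_pA[bl, ]))
  floor_used <- FALSE
  if (!is.finite(bsd) || bsd == 0) {
    bsd <- sd_floor
    floor_used <- TRUE
  }
  peaks <- apply(abs(series$current_pA[in_stim, , drop = FALSE] - bmean), 2, max)
  idx <- which(peaks > k_sd * bsd)
  structure(
    list(threshold = if (length(idx)) series$stimulus[min(idx)] else NA_real_,
         reached = length(idx) > 0,
         index = if (length(idx)) min(idx) else NA_integer_,
         baseline_mean = bmean, baseline_sd = bsd,
         sd_floor_used = floor_used, k_sd = k_sd),
    class = "threshold_result"
  )
}

#' Fit a single-exponential inactivation decay
#'
#' Nonlinear least squares of `I(t) = c1 + c2 * exp(-(t - t0)/tau)` with
#' `t0` fixed at the start of the fit window; leaving t0 free would be
#' degenerate with c2. Returns tau in ms.
#'
#' @param trace Data frame `t_s, i_pA`; the window should start at or after
#'   the current peak.
#' @param window Fit window `c(start, end)` in s; default the full trace.
#' @return List of class `inactivation_fit`: `c1`, `c2`, `t0`, `tau_ms`,
#'   `peak_pA` (extreme current in the window), `converged`, `degenerate`
#'   (no decaying component detectable).
#' @export
fit_inactivation <- function(trace, window = range(trace$t_s)) {
  sel <- trace$t_s >= window[1] & trace$t_s <= window[2]
  t <- trace$t_s[sel]
  i <- trace$i_pA[sel]
  t0 <- window[1]
  peak <- i[which.max(abs(i))]
  out <- list(c1 = NA_real_, c2 = NA_real_, t0 = t0, tau_ms = NA_real_,
              peak_pA = peak, converged = FALSE, degenerate = FALSE)
  c1_0 <- mean(utils::tail(i, max(3, round(length(i) * 0.1))))
  c2_0 <- i[1] - c1_0
  if (abs(c2_0) < max(1e-12, 1e-3 * stats::sd(i), na.rm = TRUE) ||
      stats::sd(i) < 1e-12) {
    out$degenerate <- TRUE
    out$c1 <- mean(i)
    out$c2 <- 0
    class(out) <- "inactivation_fit"
    return(out)
  }
  tau_0 <- (max(t) - t0) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      i ~ c1 + c2 * exp(-(t - t0) / tau),
      start = list(c1 = c1_0, c2 = c2_0, tau = tau_0),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out$c1 <- unname(cf["c1"])
    out$c2 <- unname(cf["c2"])
    out$tau_ms <- unname(cf["tau"]) * 1000
    out$converged <- TRUE
    if (abs(out$c2) < 1e-6 * max(abs(i))) out$degenerate <- TRUE
  }
  class(out) <- "inactivation_fit"
  out
}

#' Cell-level mean inactivation time constant
#'
#' Averages tau over the sweeps of one cell, using only fits whose peak
#' current magnitude lies in the `peak_range` gate (100-1500 pA by
#' default); non-converged or degenerate fits are excluded. Sweeps are
#' weighted equally.
#'
#' @param fits List of [fit_inactivation()] results from one cell.
#' @param peak_range Inclusive gate on `abs(peak_pA)`.
#' @return List: `tau_ms` (mean, `NA` if no sweep qualifies), `n_used`,
#'   `n_total`.
#' @export
cell_inactivation_tau <- function(fits, peak_range = c(100, 1500)) {
  ok <- vapply(fits, function(f) {
    isTRUE(f$converged) && !isTRUE(f$degenerate) &&
      abs(f$peak_pA) >= peak_range[1] && abs(f$peak_pA) <= peak_range[2]
  }, logical(1))
  taus <- vapply(fits[ok], function(f) f$tau_ms, numeric(1))
  list(tau_ms = if (length(taus)) mean(taus) else NA_real_,
       n_used = sum(ok), n_total = length(fits))
}

#' Normalize pressure-evoked peak currents to the cell maximum
#'
#' The peak response of each sweep is the maximal deviation from the
#' pre-stimulus baseline over the stimulus window; responses are divided by
#' the cell's absolute maximal response at any pressure (Imax).
#'
#' @param series A [sweep_series()] with at least 3 pressures.
#' @return Data frame `pressure, response` with responses in `[0, 1]`.
#' @export
normalize_pressure_response <- function(series) {
  stopifnot(inherits(series, "sweep_series"))
  if (length(series$stimulus) < 3) stop("need >= 3 pressures", call. = FALSE)
  bl <- series$time_s < series$stim_onset_s
  in_stim <- series$time_s >= series$stim_onset_s &
    series$time_s < series$stim_onset_s + series$stim_duration_s
  bmean <- colMeans(series$current_pA[bl, , drop = FALSE])
  dev <- sweep(series$current_pA[in_stim, , drop = FALSE], 2, bmean)
  peaks <- apply(abs(dev), 2, max)
  imax <- max(peaks)
  if (imax == 0) stop("no response: Imax is zero", call. = FALSE)
  data.frame(pressure = series$stimulus, response = peaks / imax)
}

#' Fit a Boltzmann sigmoid to a normalized pressure-response curve
#'
#' Fits `R(P) = 1 / (1 + exp((P - p50)/k))` with `k > 0`, so the response
#' grows as the pressure becomes more negative; P50 is reported on the
#' pressure axis as sampled (negative mmHg for suction protocols), with the
#' magnitude alongside since figure legends mix sign conventions.
#'
#' @param pressure Pressure values (mmHg).
#' @param response Normalized responses in `[0, 1]`.
#' @return List of class `boltzmann_fit`: `p50_mmHg`, `p50_magnitude_mmHg`,
#'   `slope_mmHg`, `residuals`, `converged`, `extrapolated` (P50 outside
#'   the sampled range plus one protocol step).
#' @export
fit_boltzmann <- function(pressure, response) {
  stopifnot(length(pressure) == length(response), length(pressure) >= 3)
  p50_0 <- pressure[which.min(abs(response - 0.5))]
  k_0 <- max(abs(diff(range(pressure))) / 10, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ 1 / (1 + exp((pressure - p50) / k)),
      start = list(p50 = p50_0, k = k_0),
      lower = c(-Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(p50_mmHg = NA_real_, p50_magnitude_mmHg = NA_real_,
                          slope_mmHg = NA_real_, residuals = NA,
                          converged = FALSE, extrapolated = NA),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  step <- if (length(pressure) > 1) max(abs(diff(sort(pressure)))) else 0
  rng <- range(pressure)
  structure(
    list(p50_mmHg = unname(cf["p50"]),
         p50_magnitude_mmHg = abs(unname(cf["p50"])),
         slope_mmHg = unname(cf["k"]),
         residuals = stats::residuals(fit),
         converged = TRUE,
         extrapolated = cf["p50"] < rng[1] - step || cf["p50"] > rng[2] + step),
    class = "boltzmann_fit"
  )
}

#' Peak over sustained current ratio of one sweep
#'
#' Peak current divided by the mean current over the final fraction
#' (default 10%) of the stimulus window, both baseline-subtracted. A fully
#' inactivating trace (sustained near zero) gets a capped ratio and a flag.
#'
#' @param trace Data frame `t_s, i_pA`.
#' @param stim_window `c(onset, end)` of the stimulus (s).
#' @param baseline_window Pre-stimulus window; default everything before
#'   onset.
#' @param sustained_frac Final fraction of the stimulus window used as the
#'   sustained level.
#' @param cap Ratio cap applied when the sustained current is ~0.
#' @return List: `ratio`, `peak_pA`, `sustained_pA`, `capped`.
#' @export
peak_sustained_ratio <- function(trace, stim_window,
                                 baseline_window = NULL,
                                 sustained_frac = 0.1, cap = 1000) {
  if (is.null(baseline_window)) baseline_window <- c(min(trace$t_s), stim_window[1])
  bl <- trace$t_s >= baseline_window[1] & trace$t_s < baseline_window[2]
  base <- if (any(bl)) mean(trace$i_pA[bl]) else 0
  in_stim <- trace$t_s >= stim_window[1] & trace$t_s < stim_window[2]
  dev <- trace$i_pA[in_stim] - base
  peak <- dev[which.max(abs(dev))]
  tail_start <- stim_window[2] - sustained_frac * diff(stim_window)
  tail_sel <- trace$t_s >= tail_start & trace$t_s < stim_window[2]
  sustained <- mean(trace$i_pA[tail_sel] - base)
  if (abs(sustained) < 1e-9 * max(abs(peak), 1e-12) || sustained == 0) {
    return(list(ratio = cap, peak_pA = peak, sustained_pA = sustained,
                capped = TRUE))
  }
  ratio <- peak / sustained
  capped <- FALSE
  if (abs(ratio) > cap) {
    ratio <- sign(ratio) * cap
    capped <- TRUE
  }
  list(ratio = ratio, peak_pA = peak, sustained_pA = sustained,
       capped = capped)
}

# Freedman-Diaconis histogram of a vector, with a sane fallback
.fd_hist <- function(x) {
  iqr <- stats::IQR(x)
  bw <- 2 * iqr / length(x)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / 30
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  graphics::hist(x, breaks = breaks, plot = FALSE)
}

# locate the two dominant, separated modes of histogram counts
.two_modes <- function(h) {
  cnt <- h$counts
  mids <- h$mids
  n <- length(cnt)
  if (n < 5) return(NULL)
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    cnt[i] == max(cnt[lo:hi]) && cnt[i] > 0.05 * max(cnt)
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(NULL)
  ord <- peaks[order(cnt[peaks], decreasing = TRUE)]
  first <- ord[1]
  # second mode: highest peak at least 3 bins away from the first
  rest <- ord[abs(ord - first) >= 3]
  if (length(rest) == 0) return(NULL)
  second <- rest[1]
  list(m = sort(mids[c(first, second)]),
       a = cnt[c(first, second)][order(mids[c(first, second)])])
}

#' Single-channel amplitude from histogram double-Gaussian fits
#'
#' Splits the trace into 1 s segments, builds a Freedman-Diaconis histogram
#' per segment and fits the counts with the sum of two Gaussians
#' initialized at the two histogram modes. The segment amplitude is the
#' difference of the two fitted peak positions (open minus closed, where
#' the closed level is the taller component); the trace amplitude is the
#' mean over segments. A unimodal histogram yields a no-event flag.
#'
#' @param trace Data frame `t_s, i_pA`.
#' @param segment_s Segment length in s (default 1).
#' @return List: `amplitude_pA` (signed open-closed difference, `NA` if no
#'   event), `n_segments_used`, `no_event`.
#' @export
single_channel_amplitude <- function(trace, segment_s = 1) {
  t <- trace$t_s
  i <- trace$i_pA
  seg <- floor((t - min(t)) / segment_s)
  seg_amps <- c()
  for (s in unique(seg)) {
    x <- i[seg == s]
    if (length(x) < 50) next
    u <- unique(x)
    if (length(u) == 1) next                       # no openings in segment
    if (length(u) == 2) {
      # noise-free two-level trace: closed = more frequent level
      cnt <- tabulate(match(x, u))
      closed <- u[which.max(cnt)]
      seg_amps <- c(seg_amps, u[u != closed] - closed)
      next
    }
    h <- .fd_hist(x)
    modes <- .two_modes(h)
    if (is.null(modes)) next
    sd0 <- max(diff(modes$m) / 6, diff(h$mids[1:2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ a1 * exp(-(mids - m1)^2 / (2 * s1^2)) +
          a2 * exp(-(mids - m2)^2 / (2 * s2^2)),
        data = data.frame(mids = h$mids, counts = h$counts),
        start = list(a1 = modes$a[1], m1 = modes$m[1], s1 = sd0,
                     a2 = modes$a[2], m2 = modes$m[2], s2 = sd0),
        lower = c(0, -Inf, 1e-9, 0, -Inf, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    # closed = taller component; signed amplitude = open - closed
    if (cf["a1"] >= cf["a2"]) {
      amp <- unname(cf["m2"] - cf["m1"])
    } else {
      amp <- unname(cf["m1"] - cf["m2"])
    }
    # reject fits whose modes are not separated relative to their widths or
    # to the bin resolution: those are unimodal (no-opening) segments
    if (abs(amp) < 2 * max(cf["s1"], cf["s2"]) ||
        abs(amp) < 2 * diff(h$mids[1:2])) next
    seg_amps <- c(seg_amps, amp)
  }
  if (length(seg_amps) == 0) {
    return(list(amplitude_pA = NA_real_, n_segments_used = 0L,
                no_event = TRUE))
  }
  list(amplitude_pA = mean(seg_amps), n_segments_used = length(seg_amps),
       no_event = FALSE)
}

#' Unitary conductance from an I/V plot
#'
#' Ordinary least-squares regression of single-channel amplitudes (pA)
#' against holding potential (mV); the slope in pA/mV times 1000 is the
#' conductance in pS and the x-intercept estimates the reversal potential.
#'
#' @param voltages_mV Holding potentials (>= 2).
#' @param amplitudes_pA Signed unitary amplitudes.
#' @return List of class `iv_fit`: `conductance_pS`, `reversal_mV`,
#'   `slope_pA_per_mV`, `intercept_pA`, `r_squared`.
#' @export
fit_iv <- function(voltages_mV, amplitudes_pA) {
  ok <- is.finite(voltages_mV) & is.finite(amplitudes_pA)
  v <- voltages_mV[ok]; a <- amplitudes_pA[ok]
  if (length(v) < 2) stop("need amplitudes from >= 2 voltages", call. = FALSE)
  fit <- stats::lm(a ~ v)
  cf <- stats::coef(fit)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(conductance_pS = unname(cf[2]) * 1000,
         reversal_mV = -unname(cf[1]) / unname(cf[2]),
         slope_pA_per_mV = unname(cf[2]), intercept_pA = unname(cf[1]),
         r_squared = r2),
    class = "iv_fit"
  )
}

#' Amplitudes and conductance for a whole single-channel series
#'
#' @param series A `single_channel_series` (see
#'   [generate_single_channel()]) or a list with `voltages` and `traces`.
#' @param segment_s Segment length passed to [single_channel_amplitude()].
#' @return List: `amplitudes` (data frame `voltage_mV, amplitude_pA,
#'   no_event`) and the [fit_iv()] result over voltages with events.
#' @export
single_channel_iv <- function(series, segment_s = 1) {
  amps <- lapply(series$traces, single_channel_amplitude, segment_s = segment_s)
  tab <- data.frame(
    voltage_mV = series$voltages,
    amplitude_pA = vapply(amps, function(a) a$amplitude_pA, numeric(1)),
    no_event = vapply(amps, function(a) a$no_event, logical(1)))
  fit <- if (sum(!tab$no_event) >= 2) {
    fit_iv(tab$voltage_mV[!tab$no_event], tab$amplitude_pA[!tab$no_event])
  } else {
    NULL
  }
  list(amplitudes = tab, iv = fit)
}

#' Normalize a calcium-imaging fluorescence time course
#'
#' F/F0 per frame, with F0 the mean fluorescence over a control window
#' (default the first 10 s of the control perfusion).
#'
#' @param time_s Frame times (s); frames are typically 2 s apart.
#' @param f_au Fluorescence intensities (a.u.).
#' @param control_window `c(start, end)` in s of the baseline window.
#' @return List of class `calcium_timecourse`: `time_s`, `f_over_f0`, `f0`.
#' @export
compute_f_over_f0 <- function(time_s, f_au, control_window = c(0, 10)) {
  sel <- time_s >= control_window[1] & time_s <= control_window[2]
  if (!any(sel)) stop("control window contains no frames", call. = FALSE)
  f0 <- mean(f_au[sel])
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive", call. = FALSE)
  structure(list(time_s = time_s, f_over_f0 = f_au / f0, f0 = f0),
            class = "calcium_timecourse")
}

#' Fit a sigmoid dose-response curve for EC50 determination
#'
#' Averages the per-cell maximal F/F0 responses per concentration and fits
#' a four-parameter logistic in log10 concentration.
#'
#' @param conc_uM Concentration per observation (uM).
#' @param response Per-cell maximal F/F0.
#' @return List of class `dose_response_fit`: `ec50_uM`, `hill`, `top`,
#'   `bottom`, `per_concentration` (mean and SEM per concentration),
#'   `converged`, `extrapolated` (EC50 outside the tested range).
#' @export
fit_ec50 <- function(conc_uM, response) {
  stopifnot(length(conc_uM) == length(response))
  concs <- sort(unique(conc_uM))
  if (length(concs) < 4) stop("need >= 4 concentrations", call. = FALSE)
  means <- vapply(concs, function(cc) mean(response[conc_uM == cc]), numeric(1))
  sems <- vapply(concs, function(cc) {
    x <- response[conc_uM == cc]
    if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  lx <- log10(concs)
  bottom_0 <- min(means); top_0 <- max(means)
  half <- (bottom_0 + top_0) / 2
  lec_0 <- lx[which.min(abs(means - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      means ~ bottom + (top - bottom) / (1 + 10^(hill * (lec - lx))),
      start = list(bottom = bottom_0, top = top_0, lec = lec_0, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  per_conc <- data.frame(conc_uM = concs, mean = means, sem = sems)
  if (is.null(fit)) {
    return(structure(list(ec50_uM = NA_real_, hill = NA_real_,
                          top = NA_real_, bottom = NA_real_,
                          per_concentration = per_conc, converged = FALSE,
                          extrapolated = NA),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  ec50 <- 10^unname(cf["lec"])
  structure(
    list(ec50_uM = ec50, hill = unname(cf["hill"]), top = unname(cf["top"]),
         bottom = unname(cf["bottom"]), per_concentration = per_conc,
         converged = TRUE,
         extrapolated = ec50 < min(concs) || ec50 > max(concs)),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("EC50 = %.4g uM (hill %.3g, bottom %.3g, top %.3g)%s\n",
              x$ec50_uM, x$hill, x$bottom, x$top,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("P50 = %.4g mmHg (|P50| = %.4g, slope k = %.4g mmHg)%s\n",
              x$p50_mmHg, x$p50_magnitude_mmHg, x$slope_mmHg,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
print.inactivation_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Inactivation fit: degenerate (no decaying component)\n")
  } else {
    cat(sprintf("Inactivation fit: tau = %.4g ms, c1 = %.4g pA, c2 = %.4g pA\n",
                x$tau_ms, x$c1, x$c2))
  }
  invisible(x)
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("Unitary conductance = %.4g pS, reversal = %.4g mV (R2 = %.3f)\n",
              x$conductance_pS, x$reversal_mV, x$r_squared))
  invisible(x)
}
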