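flat_series <- function(stimuli, response_at = NULL, amp = -300,
                        noise_sd = 1, seed = 1) {
  set.seed(seed)
  t <- seq(0, 0.7, by = 1e-3)
  in_stim <- t >= 0.1 & t < 0.6
  cur <- sapply(stimuli, function(s) {
    tr <- rnorm(length(t), 0, noise_sd)
    if (!is.null(response_at) && s >= response_at) tr[in_stim] <- tr[in_stim] + amp
    tr
  })
  sweep_series(stimuli, t, cur, 0.1, 0.5, "um")
}

test_that("mechanical threshold is the first supra-6SD stimulus", {
  disp <- seq(0.8, 12, by = 0.8)
  s <- flat_series(disp, response_at = 4.0)
  th <- detect_threshold(s)
  expect_true(th$reached)
  expect_equal(th$threshold, 4.0)

  none <- flat_series(disp, response_at = NULL)
  th2 <- detect_threshold(none)
  expect_false(th2$reached)
  expect_true(is.na(th2$threshold))

  # one sweep barely above 7x the baseline SD is detected
  just <- flat_series(disp, response_at = disp[7], amp = -7.5)
  expect_equal(detect_threshold(just)$threshold, disp[7])

  # zero baseline SD falls back to the absolute floor
  quiet <- flat_series(disp, response_at = 2.4, noise_sd = 0)
  th3 <- detect_threshold(quiet)
  expect_true(th3$sd_floor_used)
  expect_equal(th3$threshold, 2.4)
})

test_that("inactivation fit recovers tau on noiseless decays", {
  for (tau in c(15.9, 6.39, 41.1)) {
    tr <- generate_current_decay(c1 = -60, c2 = -700, t0 = 0.02,
                                 tau_ms = tau, noise_sd = 0)
    fit <- fit_inactivation(tr)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau_ms - tau) / tau, 1e-3)
  }

  flat <- generate_current_decay(c1 = -100, c2 = 0, t0 = 0, tau_ms = 10,
                                 noise_sd = 0)
  expect_true(fit_inactivation(flat)$degenerate)
})

test_that("tau recovery stays within 10% under 10% noise", {
  errs <- sapply(1:30, function(seed) {
    tr <- generate_current_decay(c1 = -50, c2 = -450, t0 = 0, tau_ms = 15.9,
                                 noise_sd = 45, seed = seed)
    abs(fit_inactivation(tr)$tau_ms - 15.9) / 15.9
  })
  expect_lt(median(errs), 0.1)
})

test_that("the peak-current gate controls which sweeps enter the cell tau", {
  mk <- function(c2, seed) {
    fit_inactivation(generate_current_decay(0, c2, 0, tau_ms = 12,
                                            noise_sd = abs(c2) * 0.02,
                                            seed = seed))
  }
  fits <- list(mk(-50, 1),    # peak below 100 pA: gated out
               mk(-400, 2),   # in range
               mk(-900, 3),   # in range
               mk(-1900, 4))  # above 1500 pA: gated out
  cell <- cell_inactivation_tau(fits)
  expect_equal(cell$n_used, 2)
  expect_equal(cell$n_total, 4)
  expect_lt(abs(cell$tau_ms - 12) / 12, 0.05)
  expect_true(is.na(cell_inactivation_tau(fits[c(1, 4)])$tau_ms))
})

test_that("pressure responses normalize to the cell maximum", {
  sw <- generate_pressure_sweeps(p50 = -35, slope = 6, imax = -800,
                                 noise_sd = 0)
  nr <- normalize_pressure_response(sw)
  expect_equal(max(nr$response), 1)
  expect_true(all(nr$response >= 0 & nr$response <= 1))
  # relative shape matches the generator (normalized by the largest peak)
  truth <- 1 / (1 + exp((nr$pressure + 35) / 6))
  expect_equal(nr$response, truth / max(truth), tolerance = 1e-9)

  dead <- generate_pressure_sweeps(-35, 6, imax = 0, noise_sd = 0)
  expect_error(normalize_pressure_response(dead), "Imax")
})

test_that("Boltzmann fit round-trips exactly and flags extrapolation", {
  p <- seq(-5, -80, by = -5)
  r <- 1 / (1 + exp((p + 35) / 6))
  fit <- fit_boltzmann(p, r)
  expect_lt(abs(fit$p50_mmHg + 35), 1e-6)
  expect_lt(abs(fit$slope_mmHg - 6), 1e-6)
  expect_equal(1 / (1 + exp((fit$p50_mmHg - fit$p50_mmHg) / fit$slope_mmHg)),
               0.5)  # response at P50 is half-maximal by construction
  expect_false(fit$extrapolated)

  # full generated path: tiny deviation only from the Imax normalization
  sw <- generate_pressure_sweeps(p50 = -35, slope = 6, imax = -800,
                                 noise_sd = 0)
  nr <- normalize_pressure_response(sw)
  fit2 <- fit_boltzmann(nr$pressure, nr$response)
  expect_lt(abs(fit2$p50_mmHg + 35), 0.1)
})

test_that("P50 recovery is accurate under noise", {
  errs <- sapply(1:60, function(seed) {
    sw <- generate_pressure_sweeps(p50 = -35, slope = 6, imax = -800,
                                   noise_sd = 40, seed = seed)
    nr <- normalize_pressure_response(sw)
    abs(fit_boltzmann(nr$pressure, nr$response)$p50_mmHg + 35)
  })
  expect_lt(median(errs), 2)
})

test_that("peak/sustained ratio distinguishes inactivating sweeps", {
  t <- seq(0, 0.7, by = 1e-3)
  sq <- data.frame(t_s = t, i_pA = ifelse(t >= 0.1 & t < 0.6, -200, 0))
  r <- peak_sustained_ratio(sq, c(0.1, 0.6))
  expect_equal(r$ratio, 1)
  expect_false(r$capped)

  # programmed ratio 4: peak -400, sustained plateau -100
  dec <- data.frame(t_s = t, i_pA = 0)
  in_stim <- t >= 0.1 & t < 0.6
  dec$i_pA[in_stim] <- -100 - 300 * exp(-(t[in_stim] - 0.1) / 0.02)
  r2 <- peak_sustained_ratio(dec, c(0.1, 0.6))
  expect_equal(r2$ratio, 4, tolerance = 1e-6)

  full <- data.frame(t_s = t, i_pA = 0)
  full$i_pA[t >= 0.1 & t < 0.15] <- -300
  r3 <- peak_sustained_ratio(full, c(0.1, 0.6))
  expect_true(r3$capped)
})

test_that("single-channel amplitudes come from the two histogram peaks", {
  sc <- generate_single_channel(voltages = -100, conductance_pS = 40,
                                noise_sd = 0, seed = 2)
  amp <- single_channel_amplitude(sc$traces[[1]])
  expect_false(amp$no_event)
  expect_equal(amp$amplitude_pA, -4)

  set.seed(42)
  noise_only <- data.frame(t_s = seq(0, 2, by = 5e-4),
                           i_pA = rnorm(4001, 0, 0.3))
  expect_true(single_channel_amplitude(noise_only)$no_event)

  noisy <- generate_single_channel(voltages = -100, conductance_pS = 40,
                                   noise_sd = 0.4, seed = 3)
  amp2 <- single_channel_amplitude(noisy$traces[[1]])
  expect_lt(abs(amp2$amplitude_pA + 4) / 4, 0.05)
})

test_that("I/V regression yields the unitary conductance", {
  v <- seq(-140, -40, by = 20)
  a <- 40 * v / 1000
  fit <- fit_iv(v, a)
  expect_equal(fit$conductance_pS, 40)
  expect_equal(fit$reversal_mV, 0)

  two <- fit_iv(c(-100, -60), c(-4, -2.4))
  expect_equal(two$conductance_pS, 40)

  set.seed(9)
  an <- a + rnorm(length(a), 0, 0.2)
  fit2 <- fit_iv(v, an)
  # closed-form OLS oracle
  slope <- sum((v - mean(v)) * (an - mean(an))) / sum((v - mean(v))^2)
  expect_equal(fit2$conductance_pS, slope * 1000)
  expect_error(fit_iv(-100, -4), ">= 2")

  series <- generate_single_channel(conductance_pS = 40, noise_sd = 0,
                                    seed = 4)
  iv <- single_channel_iv(series)
  expect_equal(iv$iv$conductance_pS, 40, tolerance = 1e-9)
})

test_that("F/F0 normalization matches hand computation", {
  t <- seq(0, 60, by = 2)
  const <- compute_f_over_f0(t, rep(500, length(t)))
  expect_true(all(const$f_over_f0 == 1))
  expect_equal(const$f0, 500)

  stepped <- ifelse(t < 20, 400, 800)
  tc <- compute_f_over_f0(t, stepped)
  expect_equal(tc$f_over_f0[t >= 20], rep(2, sum(t >= 20)))

  f <- 100 + 50 * (t >= 12) * exp(-(t - 12) / 10)
  tc2 <- compute_f_over_f0(t, f)
  expect_equal(tc2$f_over_f0, f / mean(f[t <= 10]))

  expect_error(compute_f_over_f0(t, rep(-1, length(t))), "positive")
  expect_error(compute_f_over_f0(t, rep(1, length(t)),
                                 control_window = c(100, 110)), "no frames")
})

test_that("EC50 fit round-trips and reports per-concentration summaries", {
  dr <- generate_dose_response(ec50 = 0.03, hill = 1.2, fmax = 6,
                               n_cells = 20, noise_sd = 0)
  fit <- fit_ec50(dr$conc_uM, dr$max_f_over_f0)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50_uM - 0.03) / 0.03, 1e-6)
  expect_lt(abs(fit$hill - 1.2), 1e-5)
  # midpoint property of the fitted curve
  mid <- fit$bottom + (fit$top - fit$bottom) / 2
  at_ec50 <- fit$bottom + (fit$top - fit$bottom) /
    (1 + 10^(fit$hill * (log10(fit$ec50_uM) - log10(fit$ec50_uM))))
  expect_equal(at_ec50, mid)
  expect_equal(nrow(fit$per_concentration), 7)
  expect_error(fit_ec50(c(1, 2, 3), c(1, 2, 3)), ">= 4")
})

test_that("quantifications are scale-consistent in the current axis", {
  disp <- seq(0.8, 12, by = 0.8)
  s1 <- flat_series(disp, response_at = 4.0, seed = 5)
  s2 <- s1
  s2$current_pA <- s1$current_pA * 7.3
  expect_equal(detect_threshold(s1)$threshold, detect_threshold(s2)$threshold)

  tr <- generate_current_decay(-50, -450, 0, tau_ms = 15.9, noise_sd = 20,
                               seed = 6)
  tr2 <- tr; tr2$i_pA <- tr$i_pA * 3
  expect_equal(fit_inactivation(tr2)$tau_ms, fit_inactivation(tr)$tau_ms,
               tolerance = 1e-6)

  v <- seq(-140, -40, 20)
  a <- 40 * v / 1000
  expect_equal(fit_iv(v, a * 2)$conductance_pS, 80)
})
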