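test_that("ECoG generator honors duration, events, amplitude contrast and determinism", {
  ev <- data.frame(start_s = c(60, 150), duration_s = c(20, 25))
  p <- ecog_gen_params(240, seed = 11, seizure_events = ev)
  s <- generate_ecog_session(p)
  expect_length(s$recording$samples, 240 * 256)
  expect_equal(nrow(s$annotations), 2)
  expect_true(all(s$annotations$state == "ictal"))

  # measured ictal/interictal RMS contrast close to the requested ratio of 6
  seg <- function(a, b) s$recording$samples[(a * 256 + 1):(b * 256)]
  bg <- rms_of(seg(0, 55))
  for (i in 1:2) {
    ict <- rms_of(seg(ev$start_s[i], ev$start_s[i] + ev$duration_s[i]))
    expect_gt(ict / bg, 4)
    expect_lt(ict / bg, 8)
    flank <- rms_of(seg(ev$start_s[i] - 15, ev$start_s[i] - 1))
    expect_gte(ict, 2 * flank)
  }

  s2 <- generate_ecog_session(p)
  expect_identical(s$recording$samples, s2$recording$samples)

  # empty event list -> no ictal annotations
  s0 <- generate_ecog_session(ecog_gen_params(30, seed = 1))
  expect_equal(nrow(s0$annotations), 0)

  # an hour at 256 Hz is 921,600 samples
  sh <- generate_ecog_session(ecog_gen_params(3600, seed = 2))
  expect_length(sh$recording$samples, 921600)
})

test_that("overlapping or out-of-range seizure events are rejected", {
  bad <- data.frame(start_s = c(10, 25), duration_s = c(20, 10))
  expect_error(ecog_gen_params(100, seizure_events = bad), "overlap")
  expect_error(ecog_gen_params(100, seizure_events = data.frame(start_s = 95, duration_s = 10)),
               "within")
  expect_error(ecog_gen_params(100, ictal_amplitude_ratio = 1), "ictal_amplitude_ratio")
})

test_that("background periodogram slope matches the requested spectral exponent", {
  for (beta in c(1, 2)) {
    acc <- NULL
    for (r in 1:30) {
      s <- generate_ecog_session(ecog_gen_params(60, spectral_exponent = beta,
                                                 seed = 4000 + r))
      p <- welch_oracle(s$recording$samples, 256)
      acc <- if (is.null(acc)) p$psd else acc + p$psd
    }
    sel <- p$freq >= 2 & p$freq <= 60
    fit <- lm(log(acc[sel]) ~ log(p$freq[sel]))
    expect_lt(abs(coef(fit)[2] + beta), 0.3)
  }
})

test_that("every generated ictal interval maps onto an ictal-labeled chunk", {
  ev <- sample_seizure_events(600, 8, seed = 3)
  s <- generate_ecog_session(ecog_gen_params(600, seizure_events = ev, seed = 4))
  idx <- chunk_recording(s$recording, 5)
  lab <- label_chunks(idx, s$annotations)
  t0 <- (seq_len(idx$n_chunks) - 1) * 5
  for (i in seq_len(nrow(ev))) {
    hit <- t0 < (ev$start_s[i] + ev$duration_s[i]) & (t0 + 5) > ev$start_s[i]
    expect_true(any(lab[hit] == "ictal"))
  }
})

test_that("current-clamp generator reproduces Ohmic deflections and true spike counts", {
  cell <- model_cell_params(input_resistance = 150, membrane_tau = 15)
  pr <- step_protocol(n_steps = 3)  # -20, -10, 0 pA
  sw <- generate_current_clamp_sweeps(pr, cell, noise_rms_mV = 0)
  # steady-state deflection of the -20 pA step: I*R = -3 mV
  i_ss <- round((pr$onset_ms + 0.9 * pr$step_duration_ms) / sw$sweeps$dt_ms)
  defl <- sw$sweeps$voltage[i_ss, 1] - cell$resting_potential
  expect_equal(defl, -3, tolerance = 0.01)

  # unreachable threshold -> no spikes anywhere
  hi <- model_cell_params(spike_threshold = 200, reset_potential = -55)
  swh <- generate_current_clamp_sweeps(step_protocol(n_steps = 25), hi,
                                       noise_rms_mV = 0)
  expect_true(all(lengths(swh$truth$spike_times_ms) == 0))

  # spike counts vs an independent 10x finer integration: equal on strongly
  # suprathreshold steps, never off by more than one near threshold
  pr2 <- step_protocol(n_steps = 25)
  sw2 <- generate_current_clamp_sweeps(pr2, cell, noise_rms_mV = 0)
  amps <- sw2$sweeps$amplitudes_pA
  fine <- eif_oracle_spikes(cell, amps, pr2$onset_ms, pr2$step_duration_ms,
                            100, sw2$sweeps$dt_ms / 10)
  truth_n <- lengths(sw2$truth$spike_times_ms)
  strong <- which(amps == 220)          # rheobase + 60 pA
  expect_equal(truth_n[strong], fine[strong])
  expect_equal(truth_n[strong], 11L)    # frozen from the fine-step oracle
  expect_true(all(abs(truth_n - fine) <= 1))

  expect_error(generate_current_clamp_sweeps(pr, model_cell_params(membrane_tau = -1)),
               "membrane_tau")
})

test_that("conductance templates have the requested burst structure and peaks", {
  tm <- generate_conductance_templates(n_bursts = 24, seed = 9)
  expect_true(all(tm$g_exc >= 0) && all(tm$g_inh >= 0))
  expect_equal(max(tm$g_exc), 20, tolerance = 1e-9)
  expect_equal(max(tm$g_inh), 10, tolerance = 1e-9)
  # exactly 24 disjoint intervals where g_exc exceeds 5% of its peak
  above <- tm$g_exc > 0.05 * max(tm$g_exc)
  n_runs <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(n_runs, 24)
  expect_equal(nrow(tm$burst_bounds_s), 24)
  expect_true(all(diff(t(tm$burst_bounds_s)) > 0))

  tm0 <- generate_conductance_templates(peak_g_exc = 0, peak_g_inh = 0, seed = 1)
  expect_true(all(tm0$g_exc == 0) && all(tm0$g_inh == 0))

  tm2 <- generate_conductance_templates(n_bursts = 24, seed = 9)
  expect_identical(tm$g_exc, tm2$g_exc)

  expect_error(generate_conductance_templates(peak_g_exc = -1), "peak_g_exc")
})

test_that("exploration logs recover the requested totals exactly", {
  lg <- generate_exploration_log(10, 10, seed = 2)
  expect_equal(sum(lg$duration_s[lg$object == "altered"]), 10, tolerance = 1e-9)
  expect_equal(sum(lg$duration_s[lg$object == "unchanged"]), 10, tolerance = 1e-9)
  expect_equal(discrimination_index(lg), 0)

  expect_equal(discrimination_index(generate_exploration_log(12, 4, seed = 3)), 0.5)
  expect_equal(discrimination_index(generate_exploration_log(0, 7, seed = 4)), -1)

  lg0 <- generate_exploration_log(0, 0)
  expect_true(attr(lg0, "no_exploration"))
})
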