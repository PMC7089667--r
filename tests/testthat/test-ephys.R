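# Analytic sweep builder: ideal RC charging V = V0 + I*R*(1 - exp(-t/tau)).
analytic_sweeps <- function(amps_pA, r_MOhm = 150, tau_ms = 15, v0 = -70,
                            dt_ms = 0.02, onset_ms = 50, dur_ms = 250,
                            post_ms = 100) {
  t <- seq(0, onset_ms + dur_ms + post_ms - dt_ms, by = dt_ms)
  v <- sapply(amps_pA, function(I) {
    out <- rep(v0, length(t))
    on <- t >= onset_ms & t < onset_ms + dur_ms
    ts <- t[on] - onset_ms
    out[on] <- v0 + I * r_MOhm / 1000 * (1 - exp(-ts / tau_ms))
    off <- t >= onset_ms + dur_ms
    vend <- v0 + I * r_MOhm / 1000 * (1 - exp(-dur_ms / tau_ms))
    out[off] <- v0 + (vend - v0) * exp(-(t[off] - onset_ms - dur_ms) / tau_ms)
    out
  })
  inc <- if (length(amps_pA) > 1) diff(amps_pA[1:2]) else 10
  structure(list(voltage = v, amplitudes_pA = amps_pA, dt_ms = dt_ms,
                 protocol = step_protocol(n_steps = length(amps_pA),
                                          step_duration_ms = dur_ms,
                                          start_pA = amps_pA[1],
                                          increment_pA = inc,
                                          onset_ms = onset_ms)),
            class = "sweep_set")
}

# Symmetric triangular spike (equal rise and fall slopes) on a flat baseline.
triangle_trace <- function(base_mV = -60, thr_mV = -40, peak_mV = 20,
                           base_width_ms = 2, dt_ms = 0.01) {
  pre <- rep(base_mV, 500)
  rise0 <- seq(base_mV, thr_mV, length.out = 200)   # slow approach (< 20 mV/ms)
  half <- base_width_ms / 2 / dt_ms
  slope <- (peak_mV - thr_mV) / (base_width_ms / 2)  # mV/ms
  up <- seq(thr_mV, peak_mV, length.out = half + 1)
  n_down <- round((peak_mV - base_mV) / (slope * dt_ms))
  down <- seq(peak_mV, base_mV, length.out = n_down + 1)[-1]
  c(pre, rise0, up, down, rep(base_mV, 500))
}

test_that("AP detection enforces the crossing and slope criteria", {
  cell <- model_cell_params()
  # subthreshold exponential charging: no events
  sub <- analytic_sweeps(10)
  expect_equal(nrow(detect_aps(sub$voltage[, 1], sub$dt_ms)), 0)

  # slow ramp through 0 mV at 5 mV/ms: crossing without the slope criterion
  dt <- 0.02
  ramp <- c(seq(-60, 20, by = 5 * dt), rep(20, 100))
  expect_equal(nrow(detect_aps(ramp, dt)), 0)

  expect_warning(detect_aps(c(-1, 1, -1), 0.5), "dt")
  expect_error(detect_aps(c(-1, NA, 1), 0.02), "non-finite")
})

test_that("detected spikes match generator ground truth within 1 ms", {
  cell <- model_cell_params()
  pr <- step_protocol(n_steps = 25)
  sw <- generate_current_clamp_sweeps(pr, cell, noise_rms_mV = 0.2)
  truth_n <- lengths(sw$truth$spike_times_ms)
  for (k in which(truth_n > 0)) {
    ev <- detect_aps(sw$sweeps$voltage[, k], sw$sweeps$dt_ms)
    expect_equal(nrow(ev), truth_n[k])
    expect_lt(max(abs(ev$peak_time_ms - sw$truth$spike_times_ms[[k]])), 1)
    expect_true(all(ev$peak_V > 0))
    expect_true(all(ev$max_rise_slope > 20))
    expect_true(all(ev$half_width_ms > 0))
  }
})

test_that("half-width follows triangle geometry, refines with dt, ignores offsets", {
  tr <- triangle_trace()
  ev <- detect_aps(tr, 0.01)
  expect_equal(nrow(ev), 1)
  # threshold-to-peak amplitude -40 -> 20 over a 2 ms base: half-width 1 ms
  expect_equal(ev$half_width_ms, 1, tolerance = 0.02)

  # interpolation convergence: sampling a smooth spike at half the interval
  # changes the measured half-width by < 2%
  smooth_spike <- function(dt) {
    t <- seq(0, 20, by = dt)
    -60 + 88 * exp(-((t - 10) / 0.7)^2)
  }
  h1 <- detect_aps(smooth_spike(0.02), 0.02)$half_width_ms[1]
  h2 <- detect_aps(smooth_spike(0.01), 0.01)$half_width_ms[1]
  expect_lt(abs(h1 - h2) / h2, 0.02)

  # a +5 mV offset shifts threshold and peak together: width unchanged
  tr5 <- triangle_trace(base_mV = -55, thr_mV = -35, peak_mV = 25)
  ev5 <- detect_aps(tr5, 0.01)
  expect_equal(ev5$half_width_ms, ev$half_width_ms, tolerance = 0.01)
})

test_that("AP count is invariant under resampling traces to a finer grid", {
  cell <- model_cell_params()
  pr <- step_protocol(n_steps = 25)
  sw <- generate_current_clamp_sweeps(pr, cell, dt_ms = 0.02, noise_rms_mV = 0)
  for (k in seq_along(sw$sweeps$amplitudes_pA)) {
    v <- sw$sweeps$voltage[, k]
    n1 <- nrow(detect_aps(v, 0.02))
    fine <- approx(seq_along(v), v, xout = seq(1, length(v), by = 0.25))$y
    n2 <- nrow(detect_aps(fine, 0.005))
    expect_equal(n1, n2)
  }
})

test_that("half-width shrinks when repolarization speeds up", {
  pr <- step_protocol(n_steps = 25)
  widths <- sapply(c(80, 150, 300), function(rr) {
    cell <- model_cell_params(repolarization_rate = rr)
    sw <- generate_current_clamp_sweeps(pr, cell, noise_rms_mV = 0)
    k <- which(lengths(sw$truth$spike_times_ms) > 0)[1]
    detect_aps(sw$sweeps$voltage[, k], sw$sweeps$dt_ms)$half_width_ms[1]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("firing curves report rates, maximum and rheobase", {
  cell <- model_cell_params()
  pr <- step_protocol(n_steps = 25)
  sw <- generate_current_clamp_sweeps(pr, cell, noise_rms_mV = 0.2)
  fc <- firing_curve(sw$sweeps)
  # rate definition: count / step duration (250 ms)
  k <- which(fc$rates$n_ap > 0)[1]
  expect_equal(fc$rates$rate_hz[k], fc$rates$n_ap[k] / 0.25)
  expect_equal(fc$max_rate_hz, max(fc$rates$rate_hz, na.rm = TRUE))
  # recovered threshold within one 10 pA increment of the true rheobase
  expect_lte(abs(fc$current_threshold_pA - sw$truth$rheobase_pA), 10)
  # negative amplitudes are outside the detection-eligible range
  expect_true(all(is.na(fc$rates$rate_hz[fc$rates$amplitude_pA < 0])))

  quiet <- generate_current_clamp_sweeps(step_protocol(n_steps = 4),
                                         cell, noise_rms_mV = 0)
  fq <- firing_curve(quiet$sweeps)
  expect_equal(fq$max_rate_hz, 0)
  expect_true(is.na(fq$current_threshold_pA))
})

test_that("passive properties follow Ohm's law on analytic traces", {
  sw <- analytic_sweeps(c(-20, -10, 10))
  pp <- passive_properties(sw)
  expect_equal(pp$per_step$r_MOhm, rep(150, 3), tolerance = 1e-3)
  expect_equal(pp$input_resistance_MOhm, 150, tolerance = 1e-3)
  # -3 mV deflection at -20 pA
  defl <- pp$per_step$steady_mV[1] - pp$per_step$baseline_mV[1]
  expect_equal(defl, -3, tolerance = 1e-3)

  # doubling both dV and dI leaves R unchanged
  sw2 <- analytic_sweeps(c(-40, -20, 20))
  pp2 <- passive_properties(sw2)
  expect_equal(pp2$input_resistance_MOhm, pp$input_resistance_MOhm,
               tolerance = 1e-6)
})

test_that("passive recovery holds over an (R, tau) grid with and without noise", {
  pr <- step_protocol(n_steps = 4)   # -20, -10, 0, +10 pA
  for (r in c(80, 150, 300)) {
    for (tau in c(8, 15, 30)) {
      cell <- model_cell_params(input_resistance = r, membrane_tau = tau,
                                seed = round(r + tau))
      for (noise in c(0, 0.2)) {
        f <- if (noise == 0) 1 else 2
        sw <- generate_current_clamp_sweeps(pr, cell, noise_rms_mV = noise)
        pp <- passive_properties(sw$sweeps)
        expect_lt(abs(pp$input_resistance_MOhm - r) / r, 0.01 * f)
        expect_lt(abs(pp$tau_ms - tau) / tau, 0.02 * f)
        expect_lt(abs(pp$capacitance_pF - tau / r * 1000) / (tau / r * 1000),
                  0.03 * f)
      }
    }
  }
})

test_that("sweep sets round-trip through CSV + JSON storage", {
  cell <- model_cell_params(seed = 4)
  sw <- generate_current_clamp_sweeps(step_protocol(n_steps = 3), cell)
  d <- file.path(tempdir(), "sweeps_rt")
  write_sweeps_csv(sw$sweeps, d)
  back <- read_sweeps_csv(d)
  expect_equal(back$voltage, sw$sweeps$voltage, tolerance = 1e-9)
  expect_equal(back$amplitudes_pA, sw$sweeps$amplitudes_pA)
  expect_equal(back$protocol$step_duration_ms, 250)
  unlink(d, recursive = TRUE)
})
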