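#' Model neuron parameters
#'
#' An exponential integrate-and-fire (EIF) cell with an absolute refractory
#' period and a stereotyped linear repolarization. The EIF is used as a test
#' harness because its spike times, input resistance and time constant are
#' exact ground truth for validating the current-clamp analysis and the
#' activity-clamp computation; it makes no claim of biophysical fidelity to
#' recorded neurons.
#'
#' Membrane equation (subthreshold, units mV/ms/MOhm/pA/nS):
#' `tau dV/dt = -(V - V_rest) + sharpness * exp((V - V_T)/sharpness) + R*I/1000`.
#' When V reaches `peak_potential` a spike is registered; V then falls at
#' `repolarization_rate` mV/ms to `reset_potential` and is clamped there for
#' the refractory period.
#'
#' @param resting_potential Resting/leak potential, mV.
#' @param input_resistance Input resistance R, MOhm (> 0).
#' @param membrane_tau Membrane time constant tau, ms (> 0).
#' @param spike_threshold Soft spike-initiation threshold V_T, mV; must
#'   exceed `reset_potential`.
#' @param reset_potential Post-spike reset, mV.
#' @param refractory Absolute refractory period, ms.
#' @param sharpness Spike-initiation width Delta_T, mV.
#' @param peak_potential Voltage at which the upstroke is truncated and a
#'   spike is recorded, mV.
#' @param repolarization_rate Downstroke rate, mV/ms.
#' @param seed Integer seed used when measurement noise is added to traces.
#' @return Object of class `model_cell_params`.
#' @export
model_cell_params <- function(resting_potential = -70, input_resistance = 150,
                              membrane_tau = 15, spike_threshold = -45,
                              reset_potential = -55, refractory = 3,
                              sharpness = 2, peak_potential = 30,
                              repolarization_rate = 150, seed = NULL) {
  assert_scalar_num(input_resistance, "input_resistance", 0, strict_lower = TRUE)
  assert_scalar_num(membrane_tau, "membrane_tau", 0, strict_lower = TRUE)
  assert_scalar_num(sharpness, "sharpness", 0, strict_lower = TRUE)
  assert_scalar_num(repolarization_rate, "repolarization_rate", 0, strict_lower = TRUE)
  assert_scalar_num(refractory, "refractory", 0)
  if (reset_potential >= spike_threshold) {
    stop("`reset_potential` must be below `spike_threshold`")
  }
  structure(list(resting_potential = resting_potential,
                 input_resistance = input_resistance,
                 membrane_tau = membrane_tau,
                 spike_threshold = spike_threshold,
                 reset_potential = reset_potential,
                 refractory = refractory, sharpness = sharpness,
                 peak_potential = peak_potential,
                 repolarization_rate = repolarization_rate, seed = seed),
            class = "model_cell_params")
}

# Forward-Euler integration of the EIF cell. Inputs per step: injected
# current i_inj (pA) and optional conductances g_exc/g_inh (nS) with
# effective reversals e_exc/e_inh (mV), plus a static conductance.
# Returns the voltage trace and spike times (ms, time of upstroke peak).
eif_simulate <- function(cell, dt_ms, n_steps, i_inj = NULL,
                         g_exc = NULL, g_inh = NULL,
                         e_exc = 0, e_inh = -75,
                         g_static = 0, e_static = -90,
                         v0 = cell$resting_potential) {
  if (is.null(i_inj)) i_inj <- numeric(n_steps)
  has_g <- !is.null(g_exc) || !is.null(g_inh)
  if (is.null(g_exc)) g_exc <- numeric(n_steps)
  if (is.null(g_inh)) g_inh <- numeric(n_steps)
  stopifnot(length(i_inj) == n_steps, length(g_exc) == n_steps,
            length(g_inh) == n_steps)
  el <- cell$resting_potential; tau <- cell$membrane_tau
  r <- cell$input_resistance; vt <- cell$spike_threshold
  dT <- cell$sharpness; vpeak <- cell$peak_potential
  vreset <- cell$reset_potential; repol <- cell$repolarization_rate
  refr <- cell$refractory
  v <- numeric(n_steps)
  spikes <- numeric(0)
  V <- v0
  refr_until <- -Inf
  repolarizing <- FALSE
  for (i in seq_len(n_steps)) {
    t <- i * dt_ms
    if (repolarizing) {
      V <- V - repol * dt_ms
      if (V <= vreset) {
        V <- vreset
        repolarizing <- FALSE
        refr_until <- t + refr
      }
      v[i] <- V
      next
    }
    if (t < refr_until) {
      V <- vreset
      v[i] <- V
      next
    }
    I <- i_inj[i] + g_exc[i] * (e_exc - V) + g_inh[i] * (e_inh - V) +
      g_static * (e_static - V)
    V <- V + dt_ms / tau * (-(V - el) + dT * exp((V - vt) / dT) + r * I * 1e-3)
    if (!is.finite(V) || V < -500) {
      stop(sprintf("integration diverged at step %d (t = %.3f ms)", i, t))
    }
    if (V >= vpeak) {
      V <- vpeak
      spikes <- c(spikes, t)
      repolarizing <- TRUE
    }
    v[i] <- V
  }
  list(v = v, spike_times_ms = spikes)
}

#' Generate current-clamp sweeps from the model neuron
#'
#' Simulates the standard step protocol (250-ms depolarizing steps of
#' increasing amplitude from -20 pA in 10 pA increments by default) on an
#' exponential integrate-and-fire cell and returns both the "recorded"
#' sweeps (with additive Gaussian measurement noise) and the noiseless
#' ground truth: true spike times per sweep, true input resistance, time
#' constant, and rheobase.
#'
#' @param protocol A [step_protocol()].
#' @param cell A [model_cell_params()].
#' @param dt_ms Sample interval of the simulated recording, ms
#'   (default 0.02 ms, i.e. 50 kHz).
#' @param noise_rms_mV RMS of additive Gaussian voltage noise applied to the
#'   returned traces (ground truth is computed noise-free). Default 0.2 mV.
#' @param post_ms Trace duration after the step, ms.
#' @return A list with components `sweeps` (a `sweep_set`) and `truth`
#'   (list: `spike_times_ms` per sweep, `input_resistance`, `membrane_tau`,
#'   `rheobase_pA`, `cell`).
#' @export
generate_current_clamp_sweeps <- function(protocol, cell, dt_ms = 0.02,
                                          noise_rms_mV = 0.2, post_ms = 100) {
  if (!inherits(protocol, "step_protocol")) stop("`protocol` must be a step_protocol")
  if (!inherits(cell, "model_cell_params")) stop("`cell` must be model_cell_params")
  assert_scalar_num(dt_ms, "dt_ms", 0, strict_lower = TRUE)
  assert_scalar_num(noise_rms_mV, "noise_rms_mV", 0)
  amps <- protocol_amplitudes(protocol)
  n_pre <- round(protocol$onset_ms / dt_ms)
  n_step <- round(protocol$step_duration_ms / dt_ms)
  n_post <- round(post_ms / dt_ms)
  n_t <- n_pre + n_step + n_post
  v <- matrix(0, n_t, length(amps))
  spikes <- vector("list", length(amps))
  for (k in seq_along(amps)) {
    i_inj <- c(rep(0, n_pre), rep(amps[k], n_step), rep(0, n_post))
    sim <- eif_simulate(cell, dt_ms, n_t, i_inj = i_inj)
    v[, k] <- sim$v
    spikes[[k]] <- sim$spike_times_ms
  }
  noisy <- with_seed(cell$seed, {
    if (noise_rms_mV > 0) v + rnorm(length(v), sd = noise_rms_mV) else v
  })
  n_ap <- vapply(spikes, length, integer(1))
  supra <- which(n_ap > 0)
  sweeps <- structure(
    list(voltage = noisy, amplitudes_pA = amps, dt_ms = dt_ms,
         protocol = protocol),
    class = "sweep_set")
  truth <- list(spike_times_ms = spikes,
                input_resistance = cell$input_resistance,
                membrane_tau = cell$membrane_tau,
                rheobase_pA = if (length(supra)) amps[min(supra)] else NA_real_,
                cell = cell)
  list(sweeps = sweeps, truth = truth)
}

#' Generate excitatory/inhibitory conductance templates
#'
#' Builds paired nonnegative conductance series emulating a train of
#' epileptiform synaptic barrages: `n_bursts` disjoint bursts, each a
#' strictly unimodal alpha-function envelope with per-burst amplitude
#' jitter, sampled at the activity-clamp iteration rate (15 kHz by
#' default). The inhibitory series uses the same burst windows with a short
#' onset lag. Series are normalized so their maxima equal the requested
#' peaks exactly.
#'
#' @param n_bursts Number of bursts (>= 1; the reference protocol uses 24).
#' @param burst_duration_s Duration of each burst window, s.
#' @param peak_g_exc,peak_g_inh Peak conductances, nS (>= 0).
#' @param inter_burst_s Gap between consecutive burst windows, s.
#' @param dt_ms Template sample interval, ms (default 1/15 ms = 15 kHz).
#' @param e_exc_set,e_inh_set Nominal reversal potentials, mV.
#' @param junction_mV Liquid junction potential subtracted from the set
#'   reversals at injection time, mV.
#' @param inh_lag_ms Onset lag of the inhibitory burst, ms.
#' @param seed Integer seed.
#' @return Object of class `conductance_template` with fields `g_exc`,
#'   `g_inh` (nS), `dt_ms`, `burst_bounds_s` (n_bursts x 2 matrix) and the
#'   reversal/junction constants.
#' @export
generate_conductance_templates <- function(n_bursts = 24,
                                           burst_duration_s = 0.3,
                                           peak_g_exc = 20, peak_g_inh = 10,
                                           inter_burst_s = 0.4,
                                           dt_ms = 1 / 15,
                                           e_exc_set = 0, e_inh_set = -75,
                                           junction_mV = 14.9,
                                           inh_lag_ms = 5, seed = NULL) {
  if (!is.numeric(n_bursts) || n_bursts < 1) stop("`n_bursts` must be >= 1")
  n_bursts <- as.integer(n_bursts)
  assert_scalar_num(burst_duration_s, "burst_duration_s", 0, strict_lower = TRUE)
  assert_scalar_num(peak_g_exc, "peak_g_exc", 0)
  assert_scalar_num(peak_g_inh, "peak_g_inh", 0)
  assert_scalar_num(dt_ms, "dt_ms", 0, strict_lower = TRUE)
  with_seed(seed, {
    dt_s <- dt_ms / 1000
    L <- round(burst_duration_s / dt_s)
    gap <- round(inter_burst_s / dt_s)
    lead <- round(inter_burst_s / 2 / dt_s)
    n_total <- lead + n_bursts * L + (n_bursts - 1L) * gap + lead
    tt <- seq_len(L) * dt_s
    tr <- burst_duration_s / 8
    shape <- (tt / tr) * exp(1 - tt / tr)      # unimodal, ~0 at both ends
    lag <- round(inh_lag_ms / dt_ms)
    g_exc <- numeric(n_total)
    g_inh <- numeric(n_total)
    bounds <- matrix(0, n_bursts, 2,
                     dimnames = list(NULL, c("start_s", "end_s")))
    amp_e <- runif(n_bursts, 0.7, 1)
    amp_i <- runif(n_bursts, 0.7, 1)
    for (b in seq_len(n_bursts)) {
      i0 <- lead + (b - 1L) * (L + gap)
      g_exc[i0 + seq_len(L)] <- amp_e[b] * shape
      ii <- i0 + lag + seq_len(L)
      ii <- ii[ii <= n_total]
      g_inh[ii] <- amp_i[b] * shape[seq_along(ii)]
      bounds[b, ] <- c(i0 * dt_s, (i0 + L + lag) * dt_s)
    }
    if (peak_g_exc > 0) g_exc <- g_exc / max(g_exc) * peak_g_exc else g_exc[] <- 0
    if (peak_g_inh > 0) g_inh <- g_inh / max(g_inh) * peak_g_inh else g_inh[] <- 0
    structure(list(g_exc = g_exc, g_inh = g_inh, dt_ms = dt_ms,
                   burst_bounds_s = bounds, e_exc_set = e_exc_set,
                   e_inh_set = e_inh_set, junction_mV = junction_mV),
              class = "conductance_template")
  })
}

#' Generate an object-exploration bout log
#'
#' Splits each requested per-object total exploration time into a plausible
#' sequence of bouts whose durations sum exactly to the total, as a fixture
#' for the discrimination index.
#'
#' @param t_altered,t_unchanged Total exploration time of the altered
#'   (moved/novel) and unchanged object, seconds (>= 0).
#' @param mean_bout_s Mean bout length used to pick the number of bouts.
#' @param seed Integer seed.
#' @return Object of class `exploration_log`: a data frame with columns
#'   `object` ("altered"/"unchanged"), `start_s`, `duration_s`. If both
#'   totals are zero the log is empty and carries attribute
#'   `no_exploration = TRUE`.
#' @export
generate_exploration_log <- function(t_altered, t_unchanged,
                                     mean_bout_s = 2, seed = NULL) {
  assert_scalar_num(t_altered, "t_altered", 0)
  assert_scalar_num(t_unchanged, "t_unchanged", 0)
  with_seed(seed, {
    make_bouts <- function(total) {
      if (total <= 0) return(numeric())
      n <- max(1L, round(total / mean_bout_s))
      w <- rgamma(n, shape = 2, rate = 1)
      total * w / sum(w)
    }
    d_a <- make_bouts(t_altered)
    d_u <- make_bouts(t_unchanged)
    obj <- c(rep("altered", length(d_a)), rep("unchanged", length(d_u)))
    dur <- c(d_a, d_u)
    if (length(dur)) {
      ord <- sample.int(length(dur))     # interleave bouts
      obj <- obj[ord]; dur <- dur[ord]
      gaps <- runif(length(dur), 1, 5)
      starts <- cumsum(gaps) + c(0, cumsum(dur[-length(dur)]))
    } else {
      starts <- numeric()
    }
    structure(data.frame(object = obj, start_s = starts, duration_s = dur,
                         stringsAsFactors = FALSE),
              class = c("exploration_log", "data.frame"),
              no_exploration = length(dur) == 0L)
  })
}
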