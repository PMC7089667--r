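#' Current-step protocol
#'
#' The standard excitability protocol: square current steps of fixed
#' duration and linearly increasing amplitude (default 250 ms steps from
#' -20 pA in +10 pA increments), delivered from a fixed holding potential.
#'
#' @param n_steps Number of steps.
#' @param step_duration_ms Step duration, ms.
#' @param start_pA First step amplitude, pA.
#' @param increment_pA Amplitude increment, pA (> 0).
#' @param onset_ms Baseline duration before step onset, ms.
#' @param holding_mV Holding potential, mV.
#' @return Object of class `step_protocol`.
#' @export
step_protocol <- function(n_steps = 20, step_duration_ms = 250,
                          start_pA = -20, increment_pA = 10,
                          onset_ms = 50, holding_mV = -70) {
  assert_scalar_num(step_duration_ms, "step_duration_ms", 0, strict_lower = TRUE)
  assert_scalar_num(increment_pA, "increment_pA", 0, strict_lower = TRUE)
  assert_scalar_num(onset_ms, "onset_ms", 0)
  if (n_steps < 1) stop("`n_steps` must be >= 1")
  structure(list(n_steps = as.integer(n_steps),
                 step_duration_ms = step_duration_ms, start_pA = start_pA,
                 increment_pA = increment_pA, onset_ms = onset_ms,
                 holding_mV = holding_mV),
            class = "step_protocol")
}

protocol_amplitudes <- function(protocol) {
  protocol$start_pA + (seq_len(protocol$n_steps) - 1) * protocol$increment_pA
}

central_dvdt <- function(v, dt_ms) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' Detect action potentials in a voltage trace
#'
#' An event is an action potential if the voltage crosses 0 mV upward and
#' the preceding rising phase reaches dV/dt > `min_slope_mV_ms`
#' (default 20 mV/ms). A further event is not registered until the voltage
#' has fallen back below 0 mV. The AP threshold point is the earliest
#' sample of the contiguous run with dV/dt at or above the slope criterion
#' found by searching backward from the 0 mV crossing; dV/dt uses central
#' differences.
#'
#' @param v Voltage trace, mV.
#' @param dt_ms Sample interval, ms. Traces coarser than 0.1 ms trigger a
#'   warning (slopes become unreliable).
#' @param min_slope_mV_ms Rising-slope criterion, mV/ms.
#' @return Data frame with one row per AP: `peak_time_ms`,
#'   `threshold_time_ms`, `threshold_V`, `peak_V`, `half_width_ms`,
#'   `max_rise_slope` plus the sample indices `threshold_idx`, `peak_idx`.
#' @export
detect_aps <- function(v, dt_ms, min_slope_mV_ms = 20) {
  if (any(!is.finite(v))) stop("trace contains non-finite samples")
  assert_scalar_num(dt_ms, "dt_ms", 0, strict_lower = TRUE)
  if (dt_ms > 0.1) warning("dt > 0.1 ms: slope-based AP detection may be unreliable")
  n <- length(v)
  empty <- data.frame(peak_time_ms = numeric(), threshold_time_ms = numeric(),
                      threshold_V = numeric(), peak_V = numeric(),
                      half_width_ms = numeric(), max_rise_slope = numeric(),
                      threshold_idx = integer(), peak_idx = integer())
  if (n < 3L) return(empty)
  dvdt <- central_dvdt(v, dt_ms)
  crossings <- which(v[-n] < 0 & v[-1] >= 0)   # v rises through 0 between k, k+1
  out <- list()
  for (k in crossings) {
    # rising phase preceding the crossing
    j <- k
    while (j > 1L && dvdt[j] > 0) j <- j - 1L
    rise <- dvdt[j:k]
    if (max(rise) <= min_slope_mV_ms) next     # slope criterion not met
    # threshold: earliest sample of the contiguous >= min_slope run ending at k
    thr <- k
    while (thr > 1L && dvdt[thr - 1L] >= min_slope_mV_ms) thr <- thr - 1L
    # peak: maximum until v falls back below 0
    e <- k + 1L
    while (e < n && v[e + 1L] >= 0) e <- e + 1L
    pk <- k + which.max(v[(k + 1L):e])
    ev <- list(threshold_idx = thr, peak_idx = pk,
               threshold_time_ms = (thr - 1L) * dt_ms,
               peak_time_ms = (pk - 1L) * dt_ms,
               threshold_V = v[thr], peak_V = v[pk],
               max_rise_slope = max(dvdt[thr:pk]))
    ev$half_width_ms <- ap_half_width(v, dt_ms, ev)
    out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(empty)
  do.call(rbind, lapply(out, function(e) {
    data.frame(peak_time_ms = e$peak_time_ms,
               threshold_time_ms = e$threshold_time_ms,
               threshold_V = e$threshold_V, peak_V = e$peak_V,
               half_width_ms = e$half_width_ms,
               max_rise_slope = e$max_rise_slope,
               threshold_idx = e$threshold_idx, peak_idx = e$peak_idx)
  }))
}

#' Action-potential half-width
#'
#' Full width at half amplitude, where amplitude is measured from the AP
#' threshold to the peak; crossing times on the rising and falling flanks
#' are located by linear interpolation between samples.
#'
#' @param v Voltage trace, mV.
#' @param dt_ms Sample interval, ms.
#' @param event One detected event: a list or one-row data frame with
#'   `threshold_idx`, `peak_idx`, `threshold_V`, `peak_V`.
#' @return Half-width in ms.
#' @export
ap_half_width <- function(v, dt_ms, event) {
  thr <- as.integer(event$threshold_idx)
  pk <- as.integer(event$peak_idx)
  level <- (event$threshold_V + event$peak_V) / 2
  if (event$peak_V <= level) stop("malformed event: peak below half-amplitude level")
  i <- thr + which(v[(thr + 1L):pk] >= level)[1]   # first sample at/above level
  if (is.na(i)) stop("malformed event: rising flank never reaches half level")
  t_rise <- (i - 1L) - (v[i] - level) / (v[i] - v[i - 1L])
  after <- v[(pk + 1L):length(v)]
  jrel <- which(after <= level)[1]
  if (is.na(jrel)) stop("malformed event: falling flank never returns to half level")
  j <- pk + jrel
  t_fall <- (j - 2L) + (v[j - 1L] - level) / (v[j - 1L] - v[j])
  (t_fall - t_rise) * dt_ms
}

#' Firing curve, maximal rate and current threshold
#'
#' Runs [detect_aps()] on every sweep whose injected amplitude lies in the
#' detection-eligible range 0--500 pA, converts counts to rates over the
#' step duration, and reports the maximal firing rate and the current
#' threshold (rheobase): the lowest injected amplitude evoking at least
#' one action potential.
#'
#' @param sweeps A `sweep_set` (see [generate_current_clamp_sweeps()] or
#'   [read_sweeps_csv()]).
#' @return List: `rates` (data frame `amplitude_pA`, `n_ap`, `rate_hz`;
#'   rate is `NA` for amplitudes outside the eligible range),
#'   `max_rate_hz`, `current_threshold_pA` (`NA` if no sweep is
#'   suprathreshold).
#' @export
firing_curve <- function(sweeps) {
  amps <- sweeps$amplitudes_pA
  dur_s <- sweeps$protocol$step_duration_ms / 1000
  n_ap <- integer(length(amps))
  rate <- rep(NA_real_, length(amps))
  eligible <- amps >= 0 & amps <= 500
  for (k in seq_along(amps)) {
    if (!eligible[k]) next
    n_ap[k] <- nrow(detect_aps(sweeps$voltage[, k], sweeps$dt_ms))
    rate[k] <- n_ap[k] / dur_s
  }
  supra <- which(eligible & n_ap > 0)
  list(rates = data.frame(amplitude_pA = amps, n_ap = n_ap, rate_hz = rate),
       max_rate_hz = if (any(eligible)) max(rate[eligible]) else 0,
       current_threshold_pA = if (length(supra)) amps[min(supra)] else NA_real_)
}

#' Passive membrane properties from the step protocol
#'
#' Per-step resistance is the steady-state voltage deflection (mean of the
#' last 20% of the step, relative to the pre-step baseline) divided by the
#' injected current. Input resistance averages the two most negative steps
#' and the first subthreshold positive step. The membrane time constant is
#' a single-exponential least-squares fit of the voltage relaxation on the
#' largest hyperpolarizing step, fitted over the whole step window (a
#' 63%-crossing estimate of tau seeds the optimizer); the long window pins
#' the plateau and averages recording noise. Capacitance is tau / R,
#' reported in pF.
#'
#' @param sweeps A `sweep_set`; the protocol must include at least two
#'   hyperpolarizing steps and one subthreshold depolarizing step.
#' @return Object of class `passive_properties`: `input_resistance_MOhm`,
#'   `tau_ms`, `capacitance_pF`, `resting_potential_mV`, and the per-step
#'   table `per_step`.
#' @export
passive_properties <- function(sweeps) {
  amps <- sweeps$amplitudes_pA
  dt <- sweeps$dt_ms
  onset <- sweeps$protocol$onset_ms
  dur <- sweeps$protocol$step_duration_ms
  i_on <- round(onset / dt) + 1L
  i_off <- round((onset + dur) / dt)
  i_ss <- round((onset + 0.8 * dur) / dt):i_off      # last 20% of the step
  if (i_on <= 2L) stop("protocol has no pre-step baseline")

  neg <- which(amps < 0)
  if (length(neg) < 2L) stop("need at least two hyperpolarizing steps")
  baseline <- colMeans(sweeps$voltage[seq_len(i_on - 1L), , drop = FALSE])
  steady <- colMeans(sweeps$voltage[i_ss, , drop = FALSE])
  r_step <- (steady - baseline) / amps * 1000        # mV/pA -> MOhm

  pos <- which(amps > 0)
  pos_sub <- pos[vapply(pos, function(k) {
    nrow(detect_aps(sweeps$voltage[, k], dt)) == 0L
  }, logical(1))]
  if (!length(pos_sub)) stop("need at least one subthreshold depolarizing step")
  use <- c(neg[order(amps[neg])][1:2], pos_sub[which.min(amps[pos_sub])])
  r_in <- mean(r_step[use])

  k <- neg[which.min(amps[neg])]                     # largest hyperpolarizing step
  dv_ss <- steady[k] - baseline[k]
  relax <- sweeps$voltage[i_on:i_off, k]
  t_rel <- (seq_along(relax) - 1) * dt
  cross <- which(relax - baseline[k] <= 0.632 * dv_ss)[1]
  tau_guess <- if (is.na(cross) || cross < 2L) dur / 10 else t_rel[cross]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ v0 + dv * (1 - exp(-tt / tau)),
      data = data.frame(y = relax, tt = t_rel),
      start = list(v0 = baseline[k], dv = dv_ss, tau = tau_guess),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("exponential fit failed: %s (baseline %.2f mV, deflection %.2f mV)",
                   conditionMessage(e), baseline[k], dv_ss))
    })
  tau <- coef(fit)[["tau"]]
  structure(list(
    input_resistance_MOhm = r_in,
    tau_ms = tau,
    capacitance_pF = tau / r_in * 1000,              # ms/MOhm = nF -> pF
    resting_potential_mV = mean(baseline),
    per_step = data.frame(amplitude_pA = amps, r_MOhm = r_step,
                          baseline_mV = baseline, steady_mV = steady)),
    class = "passive_properties")
}

#' @export
print.passive_properties <- function(x, ...) {
  cat(sprintf("<passive_properties> R = %.1f MOhm, tau = %.2f ms, C = %.1f pF, Vrest = %.1f mV\n",
              x$input_resistance_MOhm, x$tau_ms, x$capacitance_pF,
              x$resting_potential_mV))
  invisible(x)
}

#' Read/write a sweep set as per-sweep CSV files plus a JSON sidecar
#'
#' Each sweep is a two-column CSV (`t_ms`, `v_mV`); the sidecar stores the
#' protocol, sample interval and step amplitudes.
#'
#' @param sweeps A `sweep_set`.
#' @param dir Directory to write into (created if needed).
#' @name sweep_io
#' @export
write_sweeps_csv <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_ms <- (seq_len(nrow(sweeps$voltage)) - 1) * sweeps$dt_ms
  for (k in seq_along(sweeps$amplitudes_pA)) {
    write.csv(data.frame(t_ms = t_ms, v_mV = sweeps$voltage[, k]),
              file.path(dir, sprintf("sweep_%03d.csv", k)), row.names = FALSE)
  }
  meta <- list(dt_ms = sweeps$dt_ms, amplitudes_pA = sweeps$amplitudes_pA,
               protocol = unclass(sweeps$protocol))
  jsonlite::write_json(meta, file.path(dir, "sweeps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname sweep_io
#' @export
read_sweeps_csv <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sweeps.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^sweep_\\d+\\.csv$",
                           full.names = TRUE))
  v <- vapply(files, function(f) read.csv(f)$v_mV,
              numeric(nrow(read.csv(files[1]))))
  dimnames(v) <- NULL
  structure(list(voltage = v, amplitudes_pA = meta$amplitudes_pA,
                 dt_ms = meta$dt_ms,
                 protocol = do.call(step_protocol, meta$protocol[
                   c("n_steps", "step_duration_ms", "start_pA",
                     "increment_pA", "onset_ms", "holding_mV")])),
            class = "sweep_set")
}
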