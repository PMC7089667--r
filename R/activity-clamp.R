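effective_reversals <- function(tmpl) {
  # Liquid-junction-potential correction: recorded potentials read more
  # depolarized than true, so the set reversals are shifted negative.
  list(e_exc = tmpl$e_exc_set - tmpl$junction_mV,
       e_inh = tmpl$e_inh_set - tmpl$junction_mV)
}

#' Dynamic-clamp command current
#'
#' The current injected by the activity clamp for given conductances and
#' membrane potential:
#' `I = g_exc (E_exc_eff - V) + g_inh (E_inh_eff - V)` with
#' `E_eff = E_set - junction_potential`. Positive current depolarizes.
#'
#' @param g_exc,g_inh Conductances, nS (scalars or vectors).
#' @param v Membrane potential, mV.
#' @param tmpl A [generate_conductance_templates()] object (supplies the
#'   reversal potentials and junction correction).
#' @return Current in pA.
#' @export
clamp_current <- function(g_exc, g_inh, v, tmpl) {
  e <- effective_reversals(tmpl)
  g_exc * (e$e_exc - v) + g_inh * (e$e_inh - v)
}

resample_linear <- function(x, factor) {
  if (factor == 1L) return(x)
  n <- length(x)
  stats::approx(seq_len(n), x, xout = seq(1, n, by = 1 / factor))$y
}

#' Simulate an activity-clamp experiment on the model neuron
#'
#' Closed-loop forward-Euler integration at the clamp iteration rate
#' (15 kHz for the default template): at each step the command current is
#' computed from the instantaneous membrane potential and the scaled
#' conductance templates, the model cell is advanced one step, and spikes
#' are recorded and assigned to bursts. An optional static potassium-like
#' conductance can be added to emulate increased K+ channel expression.
#'
#' @param tmpl A [generate_conductance_templates()] object.
#' @param cell A [model_cell_params()] object.
#' @param scale Dimensionless factor applied to both conductance series
#'   (>= 0).
#' @param dt_ms Integration step, ms. Defaults to the template's own rate;
#'   a finer step linearly resamples the templates (used by the
#'   step-refinement validation).
#' @param extra_g_nS Static added conductance, nS.
#' @param extra_e_mV Reversal of the static conductance, mV (default -90,
#'   potassium-like).
#' @return Object of class `activity_clamp_result`: `spikes_per_burst`,
#'   `total_spikes`, `mean_spikes_per_burst`, `scale`, `spike_times_s`.
#' @export
simulate_activity_clamp <- function(tmpl, cell, scale = 1,
                                    dt_ms = tmpl$dt_ms,
                                    extra_g_nS = 0, extra_e_mV = -90) {
  if (!inherits(tmpl, "conductance_template")) {
    stop("`tmpl` must be a conductance_template")
  }
  assert_scalar_num(scale, "scale", 0)
  assert_scalar_num(extra_g_nS, "extra_g_nS", 0)
  factor <- tmpl$dt_ms / dt_ms
  if (abs(factor - round(factor)) > 1e-9) {
    stop("`dt_ms` must divide the template sample interval")
  }
  ge <- resample_linear(tmpl$g_exc, round(factor)) * scale
  gi <- resample_linear(tmpl$g_inh, round(factor)) * scale
  e <- effective_reversals(tmpl)
  sim <- eif_simulate(cell, dt_ms, length(ge), g_exc = ge, g_inh = gi,
                      e_exc = e$e_exc, e_inh = e$e_inh,
                      g_static = extra_g_nS, e_static = extra_e_mV)
  sp_s <- sim$spike_times_ms / 1000
  b <- tmpl$burst_bounds_s
  n_b <- nrow(b)
  counts <- integer(n_b)
  for (i in seq_len(n_b)) {
    # spikes within the burst window, allowing a short post-burst margin
    counts[i] <- sum(sp_s >= b[i, 1] & sp_s < b[i, 2] + 0.05)
  }
  structure(list(spikes_per_burst = counts,
                 total_spikes = length(sp_s),
                 mean_spikes_per_burst = length(sp_s) / n_b,
                 scale = scale, spike_times_s = sp_s),
            class = "activity_clamp_result")
}

#' @export
print.activity_clamp_result <- function(x, ...) {
  cat(sprintf("<activity_clamp_result> scale %.3g: %d spikes over %d bursts (mean %.2f/burst)\n",
              x$scale, x$total_spikes, length(x$spikes_per_burst),
              x$mean_spikes_per_burst))
  invisible(x)
}

#' Conductance threshold for action-potential generation
#'
#' Finds the smallest template scale factor at which the activity clamp
#' elicits at least one spike, by geometric bracketing followed by
#' bisection to a 1% relative tolerance.
#'
#' @inheritParams simulate_activity_clamp
#' @param scale_max Upper bound of the search (default 100).
#' @param rel_tol Relative tolerance of the returned scale.
#' @return The threshold scale (dimensionless), or `NULL` with a warning
#'   if the cell does not spike at `scale_max`.
#' @export
conductance_threshold <- function(tmpl, cell, scale_max = 100,
                                  rel_tol = 0.01, extra_g_nS = 0,
                                  extra_e_mV = -90) {
  spikes_at <- function(s) {
    simulate_activity_clamp(tmpl, cell, scale = s,
                            extra_g_nS = extra_g_nS,
                            extra_e_mV = extra_e_mV)$total_spikes > 0
  }
  s <- 1
  if (s > scale_max) s <- scale_max
  if (spikes_at(s)) {
    hi <- s
    lo <- s / 2
    while (lo > 1e-6 && spikes_at(lo)) {
      hi <- lo
      lo <- lo / 2
    }
    if (spikes_at(lo)) return(lo)      # spiking persists at negligible drive
  } else {
    lo <- s
    hi <- s * 2
    while (hi <= scale_max && !spikes_at(hi)) {
      lo <- hi
      hi <- hi * 2
    }
    if (hi > scale_max) {
      if (!spikes_at(scale_max)) {
        warning(sprintf("no spiking up to scale_max = %g", scale_max))
        return(NULL)
      }
      hi <- scale_max
    }
  }
  while ((hi - lo) / hi > rel_tol) {
    mid <- (hi + lo) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Read/write conductance templates as CSV plus JSON sidecar
#'
#' Three-column CSV (`t_ms`, `g_exc_nS`, `g_inh_nS`) and a sidecar JSON
#' holding reversal potentials, junction potential and burst boundaries.
#'
#' @param tmpl A `conductance_template`.
#' @param path CSV path; the sidecar is `path` with extension `.json`.
#' @name template_io
#' @export
write_template_csv <- function(tmpl, path) {
  t_ms <- (seq_along(tmpl$g_exc) - 1) * tmpl$dt_ms
  write.csv(data.frame(t_ms = t_ms, g_exc_nS = tmpl$g_exc,
                       g_inh_nS = tmpl$g_inh),
            path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(dt_ms = tmpl$dt_ms, e_exc_set = tmpl$e_exc_set,
         e_inh_set = tmpl$e_inh_set, junction_mV = tmpl$junction_mV,
         burst_bounds_s = as.data.frame(tmpl$burst_bounds_s)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname template_io
#' @export
read_template_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  bb <- as.matrix(as.data.frame(meta$burst_bounds_s))
  dimnames(bb) <- list(NULL, c("start_s", "end_s"))
  structure(list(g_exc = df$g_exc_nS, g_inh = df$g_inh_nS,
                 dt_ms = meta$dt_ms, burst_bounds_s = bb,
                 e_exc_set = meta$e_exc_set, e_inh_set = meta$e_inh_set,
                 junction_mV = meta$junction_mV),
            class = "conductance_template")
}
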