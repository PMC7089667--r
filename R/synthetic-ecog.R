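#' Parameters for the synthetic ECoG generator
#'
#' The generator emulates the statistical structure of chronic wireless ECoG
#' telemetry: background activity with an approximately 1/f^beta spectrum,
#' band-limited to 1--160 Hz at a 256 Hz sampling rate, with embedded
#' high-amplitude rhythmic discharges of known start and duration standing in
#' for electrographic seizures.
#'
#' @param duration_s Session length in seconds (> 0).
#' @param fs Sampling rate in Hz (default 256).
#' @param background_rms Background RMS amplitude in microvolts.
#' @param spectral_exponent beta of the 1/f^beta background spectrum.
#' @param seizure_events `NULL`, or a data frame with columns `start_s` and
#'   `duration_s`; events must be non-overlapping and lie within
#'   `[0, duration_s)`.
#' @param ictal_freq_hz Base frequency of the rhythmic ictal discharge (Hz).
#' @param ictal_amplitude_ratio Target ictal RMS / background RMS (> 1).
#' @param seed Integer seed; identical parameters including seed give
#'   identical output.
#' @return A validated parameter object of class `ecog_gen_params`.
#' @export
ecog_gen_params <- function(duration_s, fs = 256, background_rms = 50,
                            spectral_exponent = 1, seizure_events = NULL,
                            ictal_freq_hz = 5, ictal_amplitude_ratio = 6,
                            seed = NULL) {
  assert_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  assert_scalar_num(background_rms, "background_rms", lower = 0, strict_lower = TRUE)
  assert_scalar_num(spectral_exponent, "spectral_exponent", lower = 0)
  assert_scalar_num(ictal_freq_hz, "ictal_freq_hz", lower = 0, strict_lower = TRUE)
  assert_scalar_num(ictal_amplitude_ratio, "ictal_amplitude_ratio",
                    lower = 1, strict_lower = TRUE)
  ev <- seizure_events
  if (is.null(ev)) {
    ev <- data.frame(start_s = numeric(), duration_s = numeric())
  }
  if (!all(c("start_s", "duration_s") %in% names(ev))) {
    stop("`seizure_events` needs columns start_s and duration_s")
  }
  if (nrow(ev)) {
    ev <- ev[order(ev$start_s), , drop = FALSE]
    rownames(ev) <- NULL
    if (any(ev$start_s < 0) || any(ev$duration_s <= 0) ||
        any(ev$start_s + ev$duration_s > duration_s)) {
      stop("seizure events must lie within [0, duration_s) with positive duration")
    }
    ends <- ev$start_s + ev$duration_s
    if (nrow(ev) > 1L && any(ev$start_s[-1] < ends[-nrow(ev)])) {
      stop("seizure events overlap; events must be disjoint")
    }
  }
  structure(list(duration_s = duration_s, fs = fs,
                 background_rms = background_rms,
                 spectral_exponent = spectral_exponent,
                 seizure_events = ev, ictal_freq_hz = ictal_freq_hz,
                 ictal_amplitude_ratio = ictal_amplitude_ratio, seed = seed),
            class = "ecog_gen_params")
}

# Band-limited Gaussian noise with amplitude spectrum |f|^(-beta/2) inside
# [lo, hi] Hz and zero outside, unit RMS.
colored_noise <- function(n, fs, beta, lo = 1, hi = 160) {
  X <- fft(rnorm(n))
  k <- 0:(n - 1)
  fk <- k * fs / n
  fk <- pmin(fk, fs - fk)                # |f| with aliased mapping
  gain <- numeric(n)
  band <- fk >= lo & fk <= hi
  gain[band] <- fk[band]^(-beta / 2)
  x <- Re(fft(X * gain, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Rhythmic discharge: base frequency plus attenuated 2nd/3rd harmonics,
# with a raised-cosine amplitude ramp at each end.
ictal_waveform <- function(n, fs, f0, ramp_s) {
  t <- (seq_len(n) - 1) / fs
  ph <- runif(3, 0, 2 * pi)
  w <- sin(2 * pi * f0 * t + ph[1]) +
    0.5 * sin(2 * pi * 2 * f0 * t + ph[2]) +
    0.3 * sin(2 * pi * 3 * f0 * t + ph[3])
  nr <- min(round(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- r
    env[n + 1 - seq_len(nr)] <- r
  }
  w * env
}

#' Generate a synthetic ECoG session with ground-truth annotations
#'
#' Background activity is 1/f^beta Gaussian noise band-limited to
#' `[1, 160]` Hz, scaled to `background_rms`. Each seizure event adds a
#' rhythmic discharge (base frequency plus 2nd and 3rd harmonics, 1.5 s
#' raised-cosine ramp-in/out) scaled so the RMS of the ictal interval is
#' approximately `ictal_amplitude_ratio` times the background RMS.
#'
#' @param params An [ecog_gen_params()] object.
#' @return A list with components `recording` (an [ecog_recording()]) and
#'   `annotations` (an [annotation_set()] with one ictal interval per event,
#'   provenance `"human"`).
#' @export
generate_ecog_session <- function(params) {
  if (!inherits(params, "ecog_gen_params")) params <- do.call(ecog_gen_params, params)
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration_s * p$fs)
    x <- colored_noise(n, p$fs, p$spectral_exponent) * p$background_rms
    ev <- p$seizure_events
    if (nrow(ev)) {
      target_add_rms <- p$background_rms * sqrt(p$ictal_amplitude_ratio^2 - 1)
      for (i in seq_len(nrow(ev))) {
        i0 <- floor(ev$start_s[i] * p$fs) + 1L
        i1 <- min(n, floor((ev$start_s[i] + ev$duration_s[i]) * p$fs))
        m <- i1 - i0 + 1L
        ramp <- min(1.5, ev$duration_s[i] / 4)
        w <- ictal_waveform(m, p$fs, p$ictal_freq_hz, ramp)
        w <- w * target_add_rms / sqrt(mean(w^2))
        x[i0:i1] <- x[i0:i1] + w
      }
    }
    rec <- ecog_recording(x, p$fs)
    ann <- annotation_set(ev$start_s, ev$start_s + ev$duration_s,
                          rep("ictal", nrow(ev)), provenance = "human")
    list(recording = rec, annotations = ann)
  })
}

#' Draw random non-overlapping seizure events for a session
#'
#' Helper for building synthetic cohorts: places `n_events` events of
#' duration uniform in `duration_range` into `[0, duration_s)` with at least
#' `min_gap_s` of interictal signal between events and at the session edges.
#'
#' @param duration_s Session length (s).
#' @param n_events Number of events.
#' @param duration_range Length-2 numeric, event duration bounds (s).
#' @param min_gap_s Minimum separation between events and from edges (s).
#' @param seed Integer seed.
#' @return Data frame with columns `start_s`, `duration_s`, suitable for
#'   [ecog_gen_params()].
#' @export
sample_seizure_events <- function(duration_s, n_events,
                                  duration_range = c(15, 25),
                                  min_gap_s = 15, seed = NULL) {
  with_seed(seed, {
    d <- runif(n_events, duration_range[1], duration_range[2])
    free <- duration_s - sum(d) - min_gap_s * (n_events + 1)
    if (free < 0) stop("events do not fit: reduce n_events or durations")
    u <- sort(runif(n_events))
    extra <- diff(c(0, u)) * free
    starts <- numeric(n_events)
    pos <- 0
    for (i in seq_len(n_events)) {
      starts[i] <- pos + min_gap_s + extra[i]
      pos <- starts[i] + d[i]
    }
    data.frame(start_s = starts, duration_s = d)
  })
}
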