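# Independent oracles and small fixtures used across the test files.

rms_of <- function(x) sqrt(mean(x^2))

# Brute-force HMM posterior: enumerate every hidden state path, accumulate
# joint probabilities, marginalize per time step.
fb_bruteforce <- function(obs, hmm) {
  o <- obs + 1L
  n <- length(o)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  joint <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    pr <- hmm$pi[s[1]] * hmm$B[s[1], o[1]]
    if (n > 1) {
      for (t in 2:n) pr <- pr * hmm$A[s[t - 1], s[t]] * hmm$B[s[t], o[t]]
    }
    joint[p] <- pr
  }
  z <- sum(joint)
  g <- matrix(0, n, 2)
  for (t in 1:n) for (s in 1:2) g[t, s] <- sum(joint[paths[, t] == s]) / z
  g
}

# Random valid 2-state HMM parameters.
random_hmm <- function() {
  rrow <- function() { x <- runif(2, 0.05, 1); x / sum(x) }
  hmm_parameters(rbind(rrow(), rrow()), rbind(rrow(), rrow()), rrow())
}

# Step-by-step EIF integration, written independently of the package
# integrator, for validating generated spike counts at a finer time step.
eif_oracle_spikes <- function(cell, amps_pA, onset_ms, dur_ms, post_ms, dt_ms) {
  n <- round((onset_ms + dur_ms + post_ms) / dt_ms)
  out <- integer(length(amps_pA))
  for (k in seq_along(amps_pA)) {
    V <- cell$resting_potential
    nspk <- 0L
    mode <- "sub"          # sub | down | refr
    refr_end <- -1
    for (i in seq_len(n)) {
      t <- i * dt_ms
      if (mode == "down") {
        V <- V - cell$repolarization_rate * dt_ms
        if (V <= cell$reset_potential) { V <- cell$reset_potential; mode <- "refr"; refr_end <- t + cell$refractory }
        next
      }
      if (mode == "refr") {
        if (t >= refr_end) mode <- "sub" else { V <- cell$reset_potential; next }
      }
      I <- if (t > onset_ms && t <= onset_ms + dur_ms) amps_pA[k] else 0
      dv <- (-(V - cell$resting_potential) +
               cell$sharpness * exp((V - cell$spike_threshold) / cell$sharpness) +
               cell$input_resistance * I / 1000) / cell$membrane_tau
      V <- V + dv * dt_ms
      if (V >= cell$peak_potential) { nspk <- nspk + 1L; V <- cell$peak_potential; mode <- "down" }
    }
    out[k] <- nspk
  }
  out
}

# Exact two-sided Fisher p by direct factorial enumeration of all tables
# with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lp_table <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(n - r1 - c1 + x)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- exp(vapply(xs, lp_table, numeric(1)))
  p_obs <- exp(lp_table(a))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Small synthetic cohort session for detector tests.
make_test_session <- function(seed, n_events, duration_s = 1200) {
  ev <- if (n_events > 0) {
    sample_seizure_events(duration_s, n_events, seed = seed)
  } else NULL
  generate_ecog_session(ecog_gen_params(duration_s, seizure_events = ev,
                                        seed = seed + 1000))
}

make_test_library <- function(n_sessions = 3, n_events = 12, seed0 = 1,
                              duration_s = 1200) {
  sess <- list()
  for (i in seq_len(n_sessions)) {
    s <- make_test_session(seed0 + i, n_events, duration_s)
    sess[[sprintf("s%02d", i)]] <- list(rec = s$recording, ann = s$annotations)
  }
  build_library(sess)
}

# Independent Welch PSD (1-s Hann segments, 50% overlap), written from the
# estimator's definition for cross-checking the feature implementations.
welch_oracle <- function(x, fs) {
  L <- fs
  hop <- L / 2
  nseg <- floor((length(x) - L) / hop) + 1
  win <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  spec <- rep(0, L)
  for (j in seq_len(nseg)) {
    seg <- x[((j - 1) * hop + 1):((j - 1) * hop + L)]
    seg <- seg - mean(seg)
    spec <- spec + abs(fft(seg * win))^2
  }
  spec <- spec / nseg / (fs * sum(win^2))
  half <- L / 2
  onesided <- spec[1:(half + 1)]
  onesided[2:half] <- 2 * onesided[2:half]
  list(freq = (0:half) * fs / L, psd = onesided, df = fs / L)
}
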