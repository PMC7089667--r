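#' Coastline (line length) of a signal
#'
#' Sum of absolute successive sample differences, a classic
#' amplitude-and-frequency-sensitive EEG feature.
#'
#' @param x Numeric vector, length >= 2.
#' @return Coastline in the units of `x` (microvolts for ECoG).
#' @export
coastline <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) stop("`x` must be numeric with length >= 2")
  sum(abs(diff(x)))
}

# Welch-averaged one-sided periodogram: 1-s Hann segments, 50% overlap.
# psd is in power per Hz; sum(psd) * df approximates the signal power.
welch_psd <- function(x, fs, seg_s = 1, overlap = 0.5) {
  n <- length(x)
  L <- round(seg_s * fs)
  if (L > n) L <- n
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0, L - 1) / (L - 1))
  U <- sum(w^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  P <- acc / (length(starts) * fs * U)
  half <- L %/% 2
  psd <- P[seq_len(half + 1L)]
  if (half >= 2L) {
    dbl <- 2:(half + if (L %% 2L == 0L) 0L else 1L)
    psd[dbl] <- 2 * psd[dbl]
  }
  list(freq = (0:half) * fs / L, psd = psd, df = fs / L)
}

#' Band power of a signal
#'
#' Integrated Welch periodogram power over the half-open frequency band
#' `[lo, hi)`, using 1-s Hann-windowed segments with 50% overlap.
#'
#' @param x Numeric signal (microvolts).
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return Power in squared signal units (uV^2).
#' @export
band_power <- function(x, fs, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi <= lo || hi > fs / 2) {
    stop("need 0 <= lo < hi <= fs/2")
  }
  if (length(x) < 2L) stop("`x` must have length >= 2")
  p <- welch_psd(x, fs)
  sel <- p$freq >= lo & p$freq < hi
  sum(p$psd[sel]) * p$df
}

spectral_entropy <- function(x, fs) {
  p <- welch_psd(x, fs)
  keep <- p$freq > 0
  v <- p$psd[keep]
  tot <- sum(v)
  if (tot <= 0 || !is.finite(tot)) return(0)
  q <- v / tot
  q <- q[q > 0]
  if (length(q) <= 1L) return(0)
  -sum(q * log(q)) / log(sum(keep))
}

moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(0)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(0)
  mean((x - m)^4) / m2^2 - 3
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(diff(s) != 0)
}

#' The canonical 15-feature set
#'
#' Named list of per-chunk feature functions `function(x, fs)`. The default
#' set spans amplitude (coastline, variance, RMS, peak-to-peak, 95th
#' percentile of absolute amplitude), waveform shape (skewness, excess
#' kurtosis, zero crossings) and spectrum (six band powers between 1 and
#' 120 Hz plus spectral entropy). The set is pluggable: pass any named list
#' of such functions to [extract_features()] to substitute an alternative
#' feature catalogue.
#'
#' @return Named list of 15 functions.
#' @export
ecog_features <- function() {
  list(
    coastline        = function(x, fs) coastline(x),
    variance         = function(x, fs) mean((x - mean(x))^2),
    skewness         = function(x, fs) moment_skewness(x),
    kurtosis         = function(x, fs) moment_kurtosis(x),
    rms              = function(x, fs) sqrt(mean(x^2)),
    peak_to_peak     = function(x, fs) max(x) - min(x),
    zero_crossings   = function(x, fs) zero_crossings(x),
    abs_p95          = function(x, fs) unname(quantile(abs(x), 0.95)),
    power_1_4        = function(x, fs) band_power(x, fs, 1, 4),
    power_4_8        = function(x, fs) band_power(x, fs, 4, 8),
    power_8_12       = function(x, fs) band_power(x, fs, 8, 12),
    power_12_30      = function(x, fs) band_power(x, fs, 12, 30),
    power_30_70      = function(x, fs) band_power(x, fs, 30, 70),
    power_70_120     = function(x, fs) band_power(x, fs, 70, 120),
    spectral_entropy = function(x, fs) spectral_entropy(x, fs)
  )
}

#' Extract the feature vector of one chunk
#'
#' Maps a 5-s signal chunk to the ordered feature vector used by the chunk
#' classifier. Degenerate-moment convention: skewness, kurtosis and
#' spectral entropy of a constant chunk are returned as 0.
#'
#' @param chunk Numeric signal chunk (microvolts), finite, length >= 2.
#' @param fs Sampling rate, Hz.
#' @param feature_set Named list of feature functions; default
#'   [ecog_features()].
#' @return Named numeric vector, one finite value per feature.
#' @export
extract_features <- function(chunk, fs, feature_set = ecog_features()) {
  if (!is.numeric(chunk) || length(chunk) < 2L) {
    stop("`chunk` must be numeric with length >= 2")
  }
  if (any(!is.finite(chunk))) stop("`chunk` contains non-finite values")
  vals <- vapply(feature_set, function(f) f(chunk, fs), numeric(1))
  if (any(!is.finite(vals))) stop("feature computation produced non-finite values")
  vals
}

#' Extract the chunk-by-feature matrix of a recording
#'
#' @param rec An [ecog_recording()].
#' @param idx A [chunk_recording()] index derived from `rec`.
#' @param feature_set Named list of feature functions.
#' @return Numeric matrix, one row per chunk, one column per feature.
#' @export
extract_matrix <- function(rec, idx, feature_set = ecog_features()) {
  m <- matrix(NA_real_, idx$n_chunks, length(feature_set),
              dimnames = list(NULL, names(feature_set)))
  for (i in seq_len(idx$n_chunks)) {
    m[i, ] <- extract_features(chunk_samples(rec, idx, i), idx$fs, feature_set)
  }
  m
}

#' Write/read a feature matrix as CSV
#' @param m Feature matrix from [extract_matrix()].
#' @param path File path.
#' @name feature_io
#' @export
write_feature_matrix <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_io
#' @export
read_feature_matrix <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}
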