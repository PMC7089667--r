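#' Single-channel ECoG recording
#'
#' Container for a uniformly sampled single-channel electrocorticogram, the
#' unit of storage being one recording session (typically one hour of
#' telemetry sampled at 256 Hz and band-limited to 1--160 Hz).
#'
#' @param samples Numeric vector of voltage samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param session_start Session start time in seconds (numeric) or any
#'   timestamp-like scalar; kept as metadata only.
#' @param channel_id,animal_id Identifying metadata strings.
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(samples, fs, session_start = 0,
                           channel_id = "ch1", animal_id = "animal") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a numeric vector of length >= 1")
  }
  if (any(!is.finite(samples))) stop("`samples` must all be finite")
  assert_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(
    list(samples = as.numeric(samples), fs = fs,
         session_start = session_start,
         channel_id = as.character(channel_id),
         animal_id = as.character(animal_id)),
    class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [ecog_recording()].
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Labeled ictal/interictal intervals
#'
#' Intervals are half-open `[start_s, end_s)`, in seconds from the start of
#' the session. Intervals of equal state must not overlap.
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @param state Character vector, each `"ictal"` or `"interictal"`.
#'   Recycled if length 1.
#' @param provenance One of `"human"`, `"detector"`, `"verified"`.
#' @return A data frame of class `annotation_set` with attribute
#'   `provenance`.
#' @export
annotation_set <- function(start_s = numeric(), end_s = numeric(),
                           state = character(), provenance = "human") {
  if (length(state) == 1L) state <- rep(state, length(start_s))
  if (length(start_s) != length(end_s) || length(start_s) != length(state)) {
    stop("`start_s`, `end_s` and `state` must have equal length")
  }
  provenance <- match.arg(provenance, c("human", "detector", "verified"))
  if (length(start_s)) {
    if (!all(state %in% c("ictal", "interictal"))) {
      stop("`state` entries must be 'ictal' or 'interictal'")
    }
    if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
      stop("interval bounds must be finite")
    }
    if (any(end_s <= start_s)) stop("every interval needs end_s > start_s")
    for (st in unique(state)) {
      k <- state == st
      o <- order(start_s[k])
      s <- start_s[k][o]; e <- end_s[k][o]
      if (length(s) > 1L && any(s[-1] < e[-length(e)])) {
        stop(sprintf("'%s' intervals overlap", st))
      }
    }
  }
  out <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    state = as.character(state), stringsAsFactors = FALSE)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("annotation_set", "data.frame"),
            provenance = provenance)
}

ictal_intervals <- function(ann) {
  ann[ann$state == "ictal", c("start_s", "end_s"), drop = FALSE]
}

#' Tile a recording into fixed-length chunks
#'
#' Recordings are divided into consecutive non-overlapping blocks of
#' `chunk_s` seconds (default 5 s). A trailing partial block is dropped so
#' that every window holds exactly `chunk_s * fs` samples.
#'
#' @param rec An [ecog_recording()].
#' @param chunk_s Chunk length in seconds; `chunk_s * fs` must be an
#'   integer number of samples.
#' @return An object of class `chunk_index` with fields `n_chunks`,
#'   `samples_per_chunk`, `starts` (1-based start sample of each window),
#'   `chunk_s` and `fs`.
#' @export
chunk_recording <- function(rec, chunk_s = 5) {
  assert_scalar_num(chunk_s, "chunk_s", lower = 0, strict_lower = TRUE)
  L <- chunk_s * rec$fs
  if (abs(L - round(L)) > 1e-9) {
    stop("`chunk_s * fs` must be an integer number of samples")
  }
  L <- as.integer(round(L))
  n <- length(rec$samples) %/% L
  if (n == 0L) {
    warning("chunk length exceeds recording length; zero windows produced")
  }
  structure(
    list(chunk_s = chunk_s, fs = rec$fs, n_chunks = n,
         samples_per_chunk = L,
         starts = if (n) seq.int(1L, by = L, length.out = n) else integer()),
    class = "chunk_index")
}

#' Extract the samples of one chunk window
#' @param rec An [ecog_recording()].
#' @param idx A [chunk_recording()] index built from `rec`.
#' @param i Chunk number (1-based).
#' @export
chunk_samples <- function(rec, idx, i) {
  if (i < 1L || i > idx$n_chunks) stop("chunk index out of range")
  s <- idx$starts[i]
  rec$samples[s:(s + idx$samples_per_chunk - 1L)]
}

#' Label chunks from interval annotations
#'
#' A chunk is labeled `"ictal"` iff its half-open time window overlaps any
#' ictal annotation interval by more than 0 s; otherwise `"interictal"`.
#'
#' @param idx A `chunk_index`.
#' @param ann An [annotation_set()].
#' @return Character vector of per-chunk labels.
#' @export
label_chunks <- function(idx, ann) {
  t0 <- (seq_len(idx$n_chunks) - 1) * idx$chunk_s
  t1 <- t0 + idx$chunk_s
  iv <- ictal_intervals(ann)
  lab <- rep("interictal", idx$n_chunks)
  if (nrow(iv)) {
    for (i in seq_len(idx$n_chunks)) {
      if (overlaps_any(t0[i], t1[i], iv$start_s, iv$end_s)) lab[i] <- "ictal"
    }
  }
  lab
}

#' Assemble the seizure training library
#'
#' The training corpus keeps every chunk of every session that contains at
#' least one annotated seizure (the full session, not just the ictal part),
#' plus any seizure-free sessions named in `include`. Chunk labels are
#' computed with [label_chunks()].
#'
#' @param sessions A named list; each element a list with components `rec`
#'   (an [ecog_recording()]) and `ann` (an [annotation_set()]). Names are the
#'   session ids and must be unique.
#' @param include Character vector of ids of seizure-free sessions to force
#'   into the library (e.g. as negative examples).
#' @param chunk_s Chunk length in seconds.
#' @return An object of class `seizure_library`.
#' @export
build_library <- function(sessions, include = character(), chunk_s = 5) {
  if (!length(sessions)) stop("`sessions` is empty")
  ids <- names(sessions)
  if (is.null(ids) || any(!nzchar(ids))) stop("`sessions` must be a named list")
  if (anyDuplicated(ids)) stop("duplicate session id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- character()
  for (id in ids) {
    s <- sessions[[id]]
    if (is.null(s$ann)) stop(sprintf("session '%s' has no annotations", id))
    if (is.null(s$rec)) stop(sprintf("session '%s' has no recording", id))
    if (nrow(ictal_intervals(s$ann)) > 0L || id %in% include) {
      keep <- c(keep, id)
    }
  }
  if (!length(keep)) stop("no session contains a seizure and none was force-included")
  chunk_labels <- list()
  indices <- list()
  for (id in keep) {
    idx <- chunk_recording(sessions[[id]]$rec, chunk_s)
    indices[[id]] <- idx
    chunk_labels[[id]] <- label_chunks(idx, sessions[[id]]$ann)
  }
  counts <- table(factor(unlist(chunk_labels), c("interictal", "ictal")))
  structure(
    list(sessions = sessions[keep], chunk_index = indices,
         chunk_labels = chunk_labels, chunk_s = chunk_s,
         class_counts = counts),
    class = "seizure_library")
}

#' @export
print.seizure_library <- function(x, ...) {
  cat(sprintf("<seizure_library> %d session(s), %d chunks (%d ictal / %d interictal)\n",
              length(x$sessions), sum(x$class_counts),
              x$class_counts[["ictal"]], x$class_counts[["interictal"]]))
  invisible(x)
}

# ---- session storage ------------------------------------------------------

#' Read and write recording sessions
#'
#' Two on-disk dialects are supported. The CSV dialect is lossless: samples
#' are printed with 17 significant digits so a write/read round trip is
#' bit-exact. The EDF dialect writes a standard single-signal European Data
#' Format file (16-bit samples, physical dimension uV, 1-s data records);
#' round trips are exact up to one quantization step of the physical range.
#'
#' @param rec An [ecog_recording()].
#' @param path File path.
#' @return `read_session_csv()`/`read_session_edf()` return an
#'   [ecog_recording()]; the writers return `path` invisibly.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_session_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ecogseize-session v1",
               sprintf("# fs=%.17g", rec$fs),
               sprintf("# session_start=%s", format(rec$session_start)),
               sprintf("# channel_id=%s", rec$channel_id),
               sprintf("# animal_id=%s", rec$animal_id),
               "# unit=uV",
               "sample_uV"), con)
  writeLines(sprintf("%.17g", rec$samples), con)
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("session file missing '%s' metadata", key))
    sub(sprintf("^# %s=", key), "", m[1])
  }
  if (get("unit") != "uV") stop("session file unit metadata is not 'uV'")
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "sample_uV" & nzchar(body)]
  ecog_recording(as.numeric(body), fs = as.numeric(get("fs")),
                 session_start = get("session_start"),
                 channel_id = get("channel_id"),
                 animal_id = get("animal_id"))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' @rdname session_io
#' @export
write_session_edf <- function(rec, path) {
  x <- rec$samples
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF dialect requires an integer sampling rate")
  spr <- as.integer(round(fs))            # samples per 1-s record
  n_rec <- ceiling(length(x) / spr)
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1  # degenerate constant signal
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  dig <- pmin(pmax(dig, dmin), dmax)
  pad_val <- as.integer(round((0 - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))
  pad_val <- min(max(pad_val, dmin), dmax)
  dig <- c(dig, rep(pad_val, n_rec * spr - length(dig)))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_ascii(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                   # version
  wr(rec$animal_id, 80)                        # patient id
  wr(rec$channel_id, 80)                       # recording id
  wr("01.01.20", 8); wr("00.00.00", 8)         # start date/time (nominal)
  wr(format(256L + 256L), 8)                   # header bytes (1 signal)
  wr(sprintf("NSAMP=%d", length(x)), 44)       # reserved: true sample count
  wr(format(n_rec), 8)
  wr("1", 8)                                   # record duration, s
  wr("1", 4)                                   # number of signals
  wr(rec$channel_id, 16)                       # label
  wr("", 80)                                   # transducer
  wr("uV", 8)                                  # physical dimension
  wr(sprintf("%.8g", pmin_), 8); wr(sprintf("%.8g", pmax_), 8)
  wr(format(dmin), 8); wr(format(dmax), 8)
  wr("BP:1-160Hz", 80)                         # prefiltering
  wr(format(spr), 8)
  wr("", 32)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname session_io
#' @export
read_session_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                               # version
  animal <- rd(80)
  channel <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (ns != 1L) stop("only single-signal EDF files are supported")
  label <- rd(16); rd(80)
  dim_ <- rd(8)
  if (dim_ != "uV") stop(sprintf("EDF physical dimension is '%s', expected 'uV'", dim_))
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8)); rd(32)
  seek(con, header_bytes)
  dig <- readBin(con, "integer", n = n_rec * spr, size = 2L, signed = TRUE,
                 endian = "little")
  x <- (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_) + pmin_
  nsamp <- if (grepl("^NSAMP=", reserved)) {
    as.integer(sub("^NSAMP=", "", reserved))
  } else length(x)
  ecog_recording(x[seq_len(nsamp)], fs = spr / rec_dur,
                 channel_id = channel, animal_id = animal)
}

#' Read and write interval annotations as CSV
#'
#' Columns `start_s,end_s,state,provenance`; intervals half-open, 0-based
#' seconds from session start.
#'
#' @param ann An [annotation_set()].
#' @param path File path.
#' @name annotation_io
#' @export
write_annotations <- function(ann, path) {
  df <- as.data.frame(ann)
  df$provenance <- attr(ann, "provenance") %||% "human"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  prov <- if (nrow(df)) df$provenance[1] else "human"
  annotation_set(df$start_s, df$end_s, df$state, provenance = prov)
}
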