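library_design <- function(lib, feature_set) {
  Xs <- list(); ys <- list(); sess <- list()
  for (id in names(lib$sessions)) {
    idx <- lib$chunk_index[[id]]
    Xs[[id]] <- extract_matrix(lib$sessions[[id]]$rec, idx, feature_set)
    ys[[id]] <- lib$chunk_labels[[id]]
    sess[[id]] <- rep(id, idx$n_chunks)
  }
  list(X = do.call(rbind, Xs), y = unlist(ys, use.names = FALSE),
       session = unlist(sess, use.names = FALSE))
}

zscore_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

zscore_apply <- function(X, z) {
  scale(X, center = z$center, scale = z$scale)
}

fit_forest <- function(X, y, n_trees, seed) {
  y <- factor(y, levels = HMM_STATES)
  w <- 0.5 / table(y)[as.character(y)]     # class-balanced case weights
  df <- as.data.frame(X)
  ranger::ranger(x = df, y = y, num.trees = n_trees, probability = TRUE,
                 seed = seed, num.threads = 1, case.weights = as.numeric(w))
}

forest_predict_labels <- function(forest, X, threshold = 0.5) {
  p <- predict(forest, data = as.data.frame(X), num.threads = 1)$predictions
  ifelse(p[, "ictal"] >= threshold, "ictal", "interictal")
}

#' Train the chunk classifier and collect cross-validated predictions
#'
#' Fits a class-weighted random forest on the z-scored 15-feature vectors
#' of every labeled chunk in the library, and separately produces
#' out-of-fold predicted labels from session-grouped cross-validation
#' (folds are whole sessions, so temporally adjacent chunks never straddle
#' a train/test split). The out-of-fold predictions are the emissions used
#' to parameterize the smoothing HMM with [estimate_hmm()].
#'
#' @param lib A [build_library()] object containing both classes.
#' @param cv_folds Number of cross-validation folds (>= 2); capped at the
#'   number of sessions.
#' @param n_trees Number of trees in the forest.
#' @param seed Integer seed (mandatory for reproducible training).
#' @param feature_set Feature catalogue, default [ecog_features()].
#' @return List with components `model` (class `classifier_model`: forest,
#'   z-score parameters, configuration) and `cv_predictions` (data frame
#'   with columns `session`, `chunk`, `truth`, `pred`).
#' @export
train_classifier <- function(lib, cv_folds = 5, n_trees = 100, seed = 1,
                             feature_set = ecog_features()) {
  if (!inherits(lib, "seizure_library")) stop("`lib` must be a seizure_library")
  if (cv_folds < 2) stop("`cv_folds` must be >= 2")
  d <- library_design(lib, feature_set)
  if (length(unique(d$y)) < 2L) {
    stop("library contains a single class; need both ictal and interictal chunks")
  }
  z <- zscore_fit(d$X)
  forest <- fit_forest(zscore_apply(d$X, z), d$y, n_trees, seed)

  sessions <- unique(d$session)
  k <- min(cv_folds, length(sessions))
  if (length(sessions) >= 2L) {
    fold_of <- with_seed(seed, {
      setNames(rep_len(seq_len(k), length(sessions))[sample.int(length(sessions))],
               sessions)
    })
    fold <- fold_of[d$session]
  } else {
    warning("single session: falling back to chunk-level folds")
    fold <- with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(d$X))))
    k <- cv_folds
  }
  pred <- rep(NA_character_, nrow(d$X))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    if (length(unique(d$y[tr])) < 2L) {
      stop("a cross-validation fold lost one class; use more sessions or fewer folds")
    }
    zf <- zscore_fit(d$X[tr, , drop = FALSE])
    ff <- fit_forest(zscore_apply(d$X[tr, , drop = FALSE], zf), d$y[tr],
                     n_trees, seed + f)
    pred[te] <- forest_predict_labels(
      ff, zscore_apply(d$X[te, , drop = FALSE], zf))
  }
  chunk_no <- stats::ave(seq_along(d$session), d$session, FUN = seq_along)
  model <- structure(
    list(forest = forest, center = z$center, scale = z$scale,
         feature_names = colnames(d$X), classes = HMM_STATES,
         chunk_s = lib$chunk_s, fs = lib$sessions[[1]]$rec$fs,
         n_trees = n_trees, seed = seed, cv_folds = k),
    class = "classifier_model")
  list(model = model,
       cv_predictions = data.frame(session = d$session, chunk = chunk_no,
                                   truth = d$y, pred = pred,
                                   stringsAsFactors = FALSE))
}

#' Estimate the smoothing HMM from a training result
#'
#' Convenience wrapper: splits the cross-validated predictions of
#' [train_classifier()] back into per-session sequences and calls
#' [estimate_hmm()].
#'
#' @param cv_predictions The `cv_predictions` data frame from
#'   [train_classifier()].
#' @param smoothing Additive smoothing pseudo-count.
#' @return An [hmm_parameters()] object.
#' @export
estimate_hmm_from_cv <- function(cv_predictions, smoothing = 1) {
  truth <- split(cv_predictions$truth, cv_predictions$session)
  pred <- split(cv_predictions$pred, cv_predictions$session)
  estimate_hmm(truth, pred, smoothing = smoothing)
}

runs_to_events <- function(lab, chunk_s, merge_gap_chunks = 1) {
  n <- length(lab)
  ict <- lab == "ictal"
  if (!any(ict)) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  r <- rle(ict)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  if (merge_gap_chunks > 0 && nrow(ev) > 1L) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      gap <- ev$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap_chunks) {
        merged$end[nrow(merged)] <- ev$end[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  data.frame(start_s = (ev$start - 1) * chunk_s, end_s = ev$end * chunk_s)
}

#' Detect seizures in a recording
#'
#' Full automated pipeline: chunk the recording, extract features, z-score
#' with the training parameters, predict chunk labels with the random
#' forest, smooth the discrete predictions with the forward-backward
#' algorithm, threshold the ictal posterior, and merge consecutive
#' above-threshold chunks (bridging gaps of up to `merge_gap_chunks`
#' chunks) into candidate seizure events.
#'
#' @param rec An [ecog_recording()]; its sampling rate must match the
#'   training configuration.
#' @param model A `classifier_model` from [train_classifier()].
#' @param hmm An [hmm_parameters()] object.
#' @param threshold Posterior probability threshold for calling a chunk
#'   ictal (default 0.5).
#' @param merge_gap_chunks Maximum interictal gap, in chunks, bridged when
#'   assembling events (default 1).
#' @param feature_set Feature catalogue; must match the one used in
#'   training.
#' @return Object of class `detection_result`: per-chunk ictal posterior
#'   `gamma_ictal`, raw classifier labels, smoothed labels, assembled
#'   `events` (data frame `start_s`, `end_s`) and the threshold used.
#' @export
detect <- function(rec, model, hmm, threshold = 0.5, merge_gap_chunks = 1,
                   feature_set = ecog_features()) {
  if (!inherits(model, "classifier_model")) stop("`model` must be a classifier_model")
  if (abs(rec$fs - model$fs) > 1e-9) {
    stop(sprintf("recording fs (%g Hz) does not match training fs (%g Hz)",
                 rec$fs, model$fs))
  }
  idx <- chunk_recording(rec, model$chunk_s)
  X <- extract_matrix(rec, idx, feature_set)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature set does not match the model's training features")
  }
  Z <- zscore_apply(X, model)
  raw <- forest_predict_labels(model$forest, Z)
  g <- forward_backward(raw, hmm)
  smoothed <- ifelse(g[, "ictal"] >= threshold, "ictal", "interictal")
  ev <- runs_to_events(smoothed, model$chunk_s, merge_gap_chunks)
  structure(list(gamma_ictal = g[, "ictal"], raw_labels = raw,
                 smoothed_labels = smoothed, events = ev,
                 threshold = threshold, chunk_s = model$chunk_s),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d chunks, %d event(s), threshold %.2f\n",
              length(x$gamma_ictal), nrow(x$events), x$threshold))
  invisible(x)
}

#' Score detections against ground-truth annotations
#'
#' Seizure-level scoring: a true seizure counts as detected iff any
#' detected event overlaps it by more than 0 s; a detected event counts as
#' a false positive iff it overlaps no true seizure. Also reports the
#' chunk-level confusion matrix of the smoothed labels when `result` is a
#' full `detection_result`.
#'
#' @param result A `detection_result` from [detect()], or a data frame of
#'   events with columns `start_s`, `end_s`.
#' @param truth An [annotation_set()] with the ground-truth ictal
#'   intervals.
#' @param duration_s Total recording duration scored, seconds (for the
#'   false-positives-per-day rate).
#' @return Object of class `detection_metrics`: `n_true`, `n_detected`,
#'   `sensitivity`, `fn_rate` (`NA` when there are no true seizures),
#'   `n_fp`, `fp_per_day`, and `confusion` (or `NULL`).
#' @export
evaluate_detections <- function(result, truth, duration_s) {
  events <- if (inherits(result, "detection_result")) result$events else result
  iv <- ictal_intervals(truth)
  n_true <- nrow(iv)
  detected <- logical(n_true)
  if (n_true && nrow(events)) {
    for (i in seq_len(n_true)) {
      detected[i] <- overlaps_any(iv$start_s[i], iv$end_s[i],
                                  events$start_s, events$end_s)
    }
  }
  fp <- logical(nrow(events))
  if (nrow(events)) {
    for (j in seq_len(nrow(events))) {
      fp[j] <- !(n_true && overlaps_any(events$start_s[j], events$end_s[j],
                                        iv$start_s, iv$end_s))
    }
  }
  confusion <- NULL
  if (inherits(result, "detection_result")) {
    n_chunks <- length(result$smoothed_labels)
    fake_idx <- list(n_chunks = n_chunks, chunk_s = result$chunk_s)
    true_lab <- label_chunks(fake_idx, truth)
    confusion <- table(truth = factor(true_lab, HMM_STATES),
                       predicted = factor(result$smoothed_labels, HMM_STATES))
  }
  structure(list(
    n_true = n_true,
    n_detected = sum(detected),
    sensitivity = if (n_true) mean(detected) else NA_real_,
    fn_rate = if (n_true) mean(!detected) else NA_real_,
    n_fp = sum(fp),
    fp_per_day = sum(fp) / (duration_s / 86400),
    confusion = confusion), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> %d/%d seizures detected (sensitivity %s, FN rate %s); %d FP (%.2f/day)\n",
              x$n_detected, x$n_true,
              formatC(x$sensitivity, digits = 4),
              formatC(x$fn_rate, digits = 4),
              x$n_fp, x$fp_per_day))
  invisible(x)
}

#' Export candidate events for manual review, and re-import edits
#'
#' `export_for_review()` writes a CSV of candidate events with posterior
#' statistics and editable columns: set `accept` to FALSE to reject an
#' event, or fill `adj_start_s`/`adj_end_s` to override boundaries (human
#' overrides win, including boundaries off the 5-s chunk grid).
#' `import_review()` reads the edited table back and returns the accepted
#' events as a `provenance = "verified"` [annotation_set()].
#'
#' @param result A `detection_result`.
#' @param path CSV path.
#' @return `export_for_review()` returns `path` invisibly;
#'   `import_review()` returns an [annotation_set()].
#' @name review
#' @export
export_for_review <- function(result, path) {
  ev <- result$events
  stats_for <- function(s, e) {
    i0 <- floor(s / result$chunk_s) + 1
    i1 <- ceiling(e / result$chunk_s)
    g <- result$gamma_ictal[i0:i1]
    c(max(g), mean(g))
  }
  gm <- if (nrow(ev)) t(mapply(stats_for, ev$start_s, ev$end_s)) else
    matrix(numeric(), 0, 2)
  df <- data.frame(event_id = seq_len(nrow(ev)),
                   start_s = ev$start_s, end_s = ev$end_s,
                   max_gamma = if (nrow(ev)) gm[, 1] else numeric(),
                   mean_gamma = if (nrow(ev)) gm[, 2] else numeric(),
                   accept = rep(TRUE, nrow(ev)),
                   adj_start_s = rep(NA_real_, nrow(ev)),
                   adj_end_s = rep(NA_real_, nrow(ev)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname review
#' @export
import_review <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "start_s", "end_s", "accept", "adj_start_s", "adj_end_s")
  if (!all(need %in% names(df))) {
    stop("review file missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    line <- i + 1L   # header is line 1
    if (is.na(df$accept[i]) || !df$accept[i] %in% c(TRUE, FALSE)) {
      stop(sprintf("line %d: `accept` must be TRUE or FALSE", line))
    }
    s <- if (!is.na(df$adj_start_s[i])) df$adj_start_s[i] else df$start_s[i]
    e <- if (!is.na(df$adj_end_s[i])) df$adj_end_s[i] else df$end_s[i]
    if (!is.finite(s) || !is.finite(e) || e <= s) {
      stop(sprintf("line %d: invalid event boundaries", line))
    }
  }
  keep <- df[df$accept %in% TRUE, , drop = FALSE]
  s <- ifelse(is.na(keep$adj_start_s), keep$start_s, keep$adj_start_s)
  e <- ifelse(is.na(keep$adj_end_s), keep$end_s, keep$adj_end_s)
  annotation_set(s, e, rep("ictal", nrow(keep)), provenance = "verified")
}
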