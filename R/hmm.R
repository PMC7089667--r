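HMM_STATES <- c("interictal", "ictal")

as_state_index <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    i <- match(x, HMM_STATES)
    if (any(is.na(i))) stop("labels must be 'interictal' or 'ictal'")
    return(i)
  }
  if (is.numeric(x) || is.logical(x)) {
    x <- as.integer(x)
    if (any(!x %in% c(0L, 1L))) stop("numeric labels must be 0 (interictal) or 1 (ictal)")
    return(x + 1L)
  }
  stop("unsupported label type")
}

#' Two-state HMM parameters
#'
#' Hidden states are the human annotations (interictal, ictal) of 5-s
#' chunks; observations are the discrete chunk-classifier predictions over
#' the same alphabet.
#'
#' @param A 2x2 transition matrix (rows = from-state, per 5-s step).
#' @param B 2x2 emission matrix, `B[s, o] = P(classifier outputs o | true
#'   state s)`.
#' @param pi Length-2 initial/stationary state distribution.
#' @return Object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(A, B, pi) {
  A <- as.matrix(A); B <- as.matrix(B); pi <- as.numeric(pi)
  if (!all(dim(A) == 2L) || !all(dim(B) == 2L) || length(pi) != 2L) {
    stop("A and B must be 2x2 and pi length 2")
  }
  if (any(A < 0) || any(B < 0) || any(pi < 0)) stop("probabilities must be >= 0")
  if (any(abs(rowSums(A) - 1) > 1e-9) || any(abs(rowSums(B) - 1) > 1e-9) ||
      abs(sum(pi) - 1) > 1e-9) {
    stop("rows of A and B and pi must sum to 1")
  }
  dimnames(A) <- dimnames(B) <- list(HMM_STATES, HMM_STATES)
  names(pi) <- HMM_STATES
  structure(list(A = A, B = B, pi = pi), class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat("<hmm_parameters>\nA (transition):\n"); print(round(x$A, 4))
  cat("B (emission):\n"); print(round(x$B, 4))
  cat("pi:", paste(round(x$pi, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate HMM parameters from annotations and cross-validated predictions
#'
#' The transition matrix comes from add-k smoothed transition counts of the
#' true (annotated) per-session label sequences; the emission matrix from
#' add-k smoothed confusion counts of classifier predictions against the
#' truth; `pi` from smoothed overall state frequencies. Add-one smoothing
#' (the default) keeps every entry strictly inside (0, 1) so the smoothed
#' chain can always enter and leave the ictal state.
#'
#' @param truth List of per-session true label sequences (characters
#'   "interictal"/"ictal", or 0/1).
#' @param predictions List of per-session predicted label sequences, each
#'   aligned with the corresponding element of `truth`.
#' @param smoothing Additive smoothing pseudo-count (0 disables smoothing).
#' @return An [hmm_parameters()] object.
#' @export
estimate_hmm <- function(truth, predictions, smoothing = 1) {
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(predictions)) predictions <- list(predictions)
  if (length(truth) != length(predictions)) {
    stop("`truth` and `predictions` must have the same number of sessions")
  }
  if (!length(truth) || !sum(lengths(truth))) stop("empty input")
  A_cnt <- matrix(0, 2, 2)
  B_cnt <- matrix(0, 2, 2)
  pi_cnt <- numeric(2)
  for (k in seq_along(truth)) {
    s <- as_state_index(truth[[k]])
    o <- as_state_index(predictions[[k]])
    if (length(s) != length(o)) {
      stop(sprintf("session %d: truth and predictions differ in length", k))
    }
    if (length(s) > 1L) {
      for (t in seq_len(length(s) - 1L)) {
        A_cnt[s[t], s[t + 1L]] <- A_cnt[s[t], s[t + 1L]] + 1
      }
    }
    for (t in seq_along(s)) B_cnt[s[t], o[t]] <- B_cnt[s[t], o[t]] + 1
    pi_cnt <- pi_cnt + tabulate(s, 2)
  }
  norm_rows <- function(m) m / rowSums(m)
  A <- norm_rows(A_cnt + smoothing)
  B <- norm_rows(B_cnt + smoothing)
  pi <- (pi_cnt + smoothing) / sum(pi_cnt + smoothing)
  if (any(!is.finite(A)) || any(!is.finite(B))) {
    stop("a state was never observed; use smoothing > 0")
  }
  hmm_parameters(A, B, pi)
}

#' Posterior state marginals by the forward-backward algorithm
#'
#' Computes `gamma_t(s) = P(state_t = s | o_1..o_n)` for a sequence of
#' discrete classifier predictions, with per-step scaling of the forward
#' and backward variables so sequences of a million chunks do not
#' underflow.
#'
#' @param obs Observation sequence: "interictal"/"ictal" labels or 0/1.
#' @param hmm An [hmm_parameters()] object.
#' @return An n x 2 matrix of posteriors with columns `interictal`,
#'   `ictal`; each row sums to 1.
#' @export
forward_backward <- function(obs, hmm) {
  o <- as_state_index(obs)
  n <- length(o)
  if (n < 1L) stop("`obs` must have length >= 1")
  A <- hmm$A; B <- hmm$B; pi <- hmm$pi
  Bo <- t(B[, o, drop = FALSE])         # n x 2: Bo[t, s] = B[s, o_t]
  alpha <- matrix(0, n, 2)
  cs <- numeric(n)
  a <- pi * Bo[1, ]
  cs[1] <- sum(a)
  if (cs[1] <= 0) stop("observation impossible under the model")
  alpha[1, ] <- a / cs[1]
  if (n > 1L) {
    for (t in 2:n) {
      a <- as.numeric(crossprod(A, alpha[t - 1L, ])) * Bo[t, ]
      cs[t] <- sum(a)
      if (cs[t] <= 0) stop("observation impossible under the model")
      alpha[t, ] <- a / cs[t]
    }
  }
  beta <- matrix(0, n, 2)
  beta[n, ] <- 1
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      b <- as.numeric(A %*% (Bo[t + 1L, ] * beta[t + 1L, ]))
      beta[t, ] <- b / cs[t + 1L]
    }
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  colnames(g) <- HMM_STATES
  g
}

#' Simulate a labeled observation sequence from an HMM
#'
#' Draws a hidden state path from `(pi, A)` and observations from `B`;
#' used for parameter-recovery checks.
#'
#' @param hmm An [hmm_parameters()] object.
#' @param n Sequence length.
#' @param seed Integer seed.
#' @return List with integer vectors `states` and `obs` (0 = interictal,
#'   1 = ictal).
#' @export
simulate_hmm <- function(hmm, n, seed = NULL) {
  with_seed(seed, {
    s <- integer(n)
    o <- integer(n)
    s[1] <- sample.int(2L, 1L, prob = hmm$pi)
    o[1] <- sample.int(2L, 1L, prob = hmm$B[s[1], ])
    if (n > 1L) {
      for (t in 2:n) {
        s[t] <- sample.int(2L, 1L, prob = hmm$A[s[t - 1L], ])
        o[t] <- sample.int(2L, 1L, prob = hmm$B[s[t], ])
      }
    }
    list(states = s - 1L, obs = o - 1L)
  })
}
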