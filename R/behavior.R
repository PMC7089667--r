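#' Discrimination index
#'
#' `(time with altered object - time with unchanged object) / total
#' exploration time`, the memory metric of the object-location and
#' novel-object-recognition tests. Bounded in \[-1, 1\]; antisymmetric
#' under swapping the object labels.
#'
#' @param log An `exploration_log` data frame (columns `object`,
#'   `duration_s`; see [generate_exploration_log()]).
#' @return The discrimination index, or `NA` (with a warning) when total
#'   exploration is zero.
#' @export
discrimination_index <- function(log) {
  t_alt <- sum(log$duration_s[log$object == "altered"])
  t_unc <- sum(log$duration_s[log$object == "unchanged"])
  tot <- t_alt + t_unc
  if (tot <= 0) {
    warning("no exploration recorded; discrimination index undefined")
    return(NA_real_)
  }
  (t_alt - t_unc) / tot
}

#' Relative expression by the delta-delta-CT method
#'
#' Per sample, `dCT = CT_target - CT_reference`; for each sample,
#' `ddCT = dCT - ref_dCT` where `ref_dCT` is the mean control `dCT`
#' (`reference = "mean_control"`, the default) or the `dCT` of the paired
#' control sample (`reference = "paired"`, e.g. the contralateral
#' hippocampus of the same animal); the fold change is `2^(-ddCT)`.
#'
#' @param ct Data frame with columns `sample`, `condition` (`"test"` or
#'   `"control"`), `ct_target`, `ct_reference`, and (for paired mode)
#'   `pair`.
#' @param reference `"mean_control"` or `"paired"`.
#' @return The input with added columns `dct`, `ddct`, `fold`.
#' @export
ddct_relative_expression <- function(ct, reference = c("mean_control", "paired")) {
  reference <- match.arg(reference)
  need <- c("sample", "condition", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("`ct` must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    stop("CT values must be finite (missing reference-gene measurement?)")
  }
  if (!any(ct$condition == "control")) stop("need at least one control sample")
  ct$dct <- ct$ct_target - ct$ct_reference
  if (reference == "mean_control") {
    ref <- mean(ct$dct[ct$condition == "control"])
    ct$ddct <- ct$dct - ref
  } else {
    if (!"pair" %in% names(ct)) stop("paired mode needs a `pair` column")
    ctrl <- ct[ct$condition == "control", ]
    ref <- stats::setNames(ctrl$dct, ctrl$pair)
    if (anyDuplicated(ctrl$pair)) stop("paired mode needs one control per pair")
    ct$ddct <- ct$dct - as.numeric(ref[as.character(ct$pair)])
    if (any(is.na(ct$ddct))) stop("unmatched pair id(s)")
  }
  ct$fold <- 2^(-ct$ddct)
  ct
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Computes the two-sided p-value by enumerating, with both margins fixed,
#' every admissible table and summing the hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (with a 1e-7 relative tolerance on the comparison, so ties at machine
#' precision are included).
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("cell counts must be nonnegative integers")
  }
  counts <- round(counts)
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) stop("empty table")
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)   # degenerate margin
  x <- max(0, r1 + c1 - n):min(r1, c1)
  p_all <- dhyper(x, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(p_all[p_all <= p_obs * (1 + 1e-7)])
}

#' Bonferroni per-comparison significance level
#'
#' The per-comparison alpha that controls the family-wise error rate at
#' `family_alpha` over `m` comparisons (e.g. 0.05 over six off-target
#' genes gives 0.0083).
#'
#' @param family_alpha Family-wise error rate.
#' @param m Number of comparisons.
#' @return `family_alpha / m`.
#' @export
per_comparison_alpha <- function(family_alpha, m) {
  assert_scalar_num(family_alpha, "family_alpha", 0, strict_lower = TRUE)
  if (m < 1) stop("`m` must be >= 1")
  family_alpha / m
}

#' Cohort-level seizure summaries
#'
#' Per animal: seizures/day in the baseline and treatment phases, a
#' "fewer" vs "more_or_equal" classification of the phase comparison
#' (ties count against "fewer", by strict comparison of the daily rates),
#' the inclusion flag (baseline rate of at least one seizure per week),
#' and the terminal value of the cumulative seizure count normalized to
#' the animal's baseline total. Group summary: counts of animals in each
#' classification per group, suitable for a 2x2 Fisher test.
#'
#' @param events Data frame of seizure events: columns `animal`, `day`
#'   (days since the start of the baseline recording).
#' @param phases Data frame, one row per animal: columns `animal`,
#'   `group`, `baseline_days`, `treatment_days` (both > 0). The baseline
#'   phase is `[0, baseline_days)`, the treatment phase
#'   `[baseline_days, baseline_days + treatment_days)`.
#' @return Object of class `cohort_summary`: `per_animal` data frame and
#'   `by_group` data frame.
#' @export
cohort_summary <- function(events, phases) {
  if (!all(c("animal", "day") %in% names(events))) {
    stop("`events` needs columns animal, day")
  }
  if (!all(c("animal", "group", "baseline_days", "treatment_days") %in% names(phases))) {
    stop("`phases` needs columns animal, group, baseline_days, treatment_days")
  }
  if (any(phases$baseline_days <= 0) || any(phases$treatment_days <= 0)) {
    stop("phase durations must be positive")
  }
  per <- lapply(seq_len(nrow(phases)), function(i) {
    an <- phases$animal[i]
    b_end <- phases$baseline_days[i]
    t_end <- b_end + phases$treatment_days[i]
    ev <- events$day[events$animal == an]
    if (any(ev < 0 | ev >= t_end)) {
      stop(sprintf("animal %s has events outside the recording span", an))
    }
    nb <- sum(ev < b_end)
    nt <- sum(ev >= b_end)
    rb <- nb / phases$baseline_days[i]
    rt <- nt / phases$treatment_days[i]
    data.frame(animal = an, group = phases$group[i],
               n_baseline = nb, n_treatment = nt,
               baseline_rate = rb, treatment_rate = rt,
               classification = if (rt < rb) "fewer" else "more_or_equal",
               included = rb >= 1 / 7,
               cum_norm_terminal = if (nb > 0) (nb + nt) / nb else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  by_group <- do.call(rbind, lapply(split(per, per$group), function(g) {
    data.frame(group = g$group[1],
               n_animals = nrow(g),
               n_fewer = sum(g$classification == "fewer"),
               n_more_or_equal = sum(g$classification == "more_or_equal"),
               mean_baseline_rate = mean(g$baseline_rate),
               mean_treatment_rate = mean(g$treatment_rate),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  structure(list(per_animal = per, by_group = by_group),
            class = "cohort_summary")
}

#' Cumulative seizure count normalized to baseline
#'
#' Step curve of the cumulative number of seizures of one animal divided
#' by its baseline total (so the curve reaches 1.0 at the end of the
#' baseline phase by construction).
#'
#' @param events Event data frame (`animal`, `day`).
#' @param animal Animal id.
#' @param baseline_days Baseline phase length, days.
#' @return Data frame `day`, `cum_norm`.
#' @export
cumulative_normalized <- function(events, animal, baseline_days) {
  ev <- sort(events$day[events$animal == animal])
  nb <- sum(ev < baseline_days)
  if (nb == 0) stop("animal has no baseline seizures; curve undefined")
  data.frame(day = ev, cum_norm = seq_along(ev) / nb)
}
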