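test_that("the discrimination index follows its formula and symmetry", {
  lg <- function(a, u) {
    data.frame(object = c("altered", "unchanged"), start_s = c(0, 100),
               duration_s = c(a, u))
  }
  expect_equal(discrimination_index(lg(8, 8)), 0)
  expect_equal(discrimination_index(lg(12, 4)), 0.5)
  expect_equal(discrimination_index(lg(0, 7)), -1)
  expect_warning(di0 <- discrimination_index(lg(0, 0)), "no exploration")
  expect_true(is.na(di0))

  # antisymmetry and bounds over random logs
  set.seed(14)
  for (r in 1:20) {
    a <- runif(1, 0, 30); u <- runif(1, 0.1, 30)
    d <- discrimination_index(lg(a, u))
    expect_gte(d, -1); expect_lte(d, 1)
    expect_equal(discrimination_index(lg(u, a)), -d)
  }
})

test_that("delta-delta-CT folds match a spreadsheet-style recomputation", {
  set.seed(15)
  ct <- data.frame(sample = paste0("s", 1:8),
                   condition = rep(c("control", "test"), each = 4),
                   ct_target = runif(8, 18, 28),
                   ct_reference = runif(8, 14, 18))
  out <- ddct_relative_expression(ct)
  dct <- ct$ct_target - ct$ct_reference
  ref <- mean(dct[1:4])
  expect_equal(out$fold, 2^(-(dct - ref)))

  # test dCT equal to the control mean -> fold 1
  ct1 <- data.frame(sample = c("c1", "c2", "t"),
                    condition = c("control", "control", "test"),
                    ct_target = c(20, 22, 21.5), ct_reference = c(15, 16, 16))
  out1 <- ddct_relative_expression(ct1)   # control dCTs 5, 6 -> mean 5.5
  expect_equal(out1$fold[3], 1)
  # one-cycle doubling: ddCT = -1 -> fold 2
  ct2 <- ct1; ct2$ct_target[3] <- 20.5
  expect_equal(ddct_relative_expression(ct2)$fold[3], 2)

  # shifting one gene's CT by a constant multiplies all folds by 2^(-const)
  ct3 <- ct; ct3$ct_target <- ct3$ct_target + 1.5
  out3 <- ddct_relative_expression(ct3)
  expect_equal(out3$fold / out$fold, rep(1, 8))  # shift cancels via control mean
  ct4 <- ct; ct4$ct_target[ct4$condition == "test"] <- ct4$ct_target[ct4$condition == "test"] + 1.5
  out4 <- ddct_relative_expression(ct4)
  expect_equal(out4$fold[5:8] / out$fold[5:8], rep(2^(-1.5), 4))

  # paired (within-animal) reference
  ctp <- data.frame(sample = paste0("s", 1:4),
                    condition = c("control", "control", "test", "test"),
                    pair = c(1, 2, 1, 2),
                    ct_target = c(20, 21, 19, 22), ct_reference = c(15, 15, 15, 15))
  outp <- ddct_relative_expression(ctp, reference = "paired")
  expect_equal(outp$fold[3], 2^(-(4 - 5)))
  expect_equal(outp$fold[4], 2^(-(7 - 6)))

  expect_error(ddct_relative_expression(ct[ct$condition == "test", ]), "control")
  ctna <- ct; ctna$ct_reference[2] <- NA
  expect_error(ddct_relative_expression(ctna), "finite")
})

test_that("the exact Fisher test matches enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # the treated-vs-control seizure-outcome proportions (8/9 vs 5/13)
  p <- fisher_exact_2x2(8, 1, 5, 8)
  expect_equal(p, fisher_oracle(8, 1, 5, 8), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(rbind(c(8, 1), c(5, 8)))$p.value,
               tolerance = 1e-9)
  expect_lt(p, 0.05)

  set.seed(16)
  for (r in 1:50) {
    tb <- rbinom(4, 12, 0.5)
    p1 <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p1, fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
    # transpose symmetry
    expect_equal(p1, fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4]), tolerance = 1e-12)
    # independent reference implementation
    expect_equal(p1, stats::fisher.test(rbind(tb[1:2], tb[3:4]))$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integer")
})

test_that("Bonferroni per-comparison alpha matches the six-gene worked example", {
  a <- per_comparison_alpha(0.05, 6)
  expect_equal(round(a, 4), 0.0083)
  expect_equal(per_comparison_alpha(0.05, 1), 0.05)
  expect_error(per_comparison_alpha(0.05, 0), ">= 1")
})

test_that("cohort summaries classify animals and normalize cumulative counts", {
  events <- data.frame(
    animal = c(rep("m1", 14), rep("m1", 7), rep("m2", 6), rep("m2", 6),
               rep("m3", 10), rep("m3", 2)),
    day = c(seq(0.5, 13.5, 1), seq(14.5, 20.5, 1),      # m1: 14 then 7
            seq(1, 11, 2), seq(15, 25, 2),               # m2: 6 then 6 (tie)
            seq(0.5, 13, length.out = 10), c(15, 20)))   # m3: 10 then 2
  phases <- data.frame(animal = c("m1", "m2", "m3"),
                       group = c("ctrl", "ctrl", "treated"),
                       baseline_days = 14, treatment_days = 14)
  cs <- cohort_summary(events, phases)
  m1 <- cs$per_animal[cs$per_animal$animal == "m1", ]
  expect_equal(m1$baseline_rate, 1)
  expect_true(m1$included)
  expect_equal(m1$classification, "fewer")

  m2 <- cs$per_animal[cs$per_animal$animal == "m2", ]
  expect_equal(m2$classification, "more_or_equal")   # tie counts against "fewer"
  expect_equal(m2$cum_norm_terminal, 2)              # equal counts -> (n+n)/n

  expect_equal(cs$by_group$n_fewer[cs$by_group$group == "ctrl"], 1)
  expect_equal(cs$by_group$n_more_or_equal[cs$by_group$group == "ctrl"], 1)

  curve <- cumulative_normalized(events, "m2", 14)
  expect_equal(curve$cum_norm[nrow(curve)], 2)
  expect_equal(curve$cum_norm[6], 1)   # baseline total reached at event 6

  bad <- data.frame(animal = "m1", day = 40)
  expect_error(cohort_summary(rbind(events, bad), phases), "outside")
  expect_error(cohort_summary(events, transform(phases, baseline_days = 0)),
               "positive")
})
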