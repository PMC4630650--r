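test_that("ratio is the linear-scale group mean over reference mean", {
  spec <- tiny_spec(n_metabolites = 2, subject_sd = 0, noise_sd = 0,
                    treatment_profile = rbind(c(log10(0.5), 0, 0, 0), 0),
                    n_pool_replicates = 0)
  p <- log10_transform(generate_cohort(spec))
  cmp <- treatment_comparisons()$post6h
  r <- ratio(p, cmp)
  expect_equal(unname(r), c(0.5, 1))
  # identical groups give exactly 1
  same <- comparison("same", "d1_evening", "d2_evening")
  expect_equal(unname(ratio(p, same)), c(1, 1))
})

test_that("bh_adjust matches the hand step-up oracle", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh q-values are monotone in p, >= p, and <= 1", {
  set.seed(9)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("mixed-model estimate agrees with paired means on balanced data", {
  # balanced one-sample-per-subject-per-group design, no covariates:
  # the REML group estimate equals the difference of group means, and
  # the reported t has a closed paired-t counterpart in rank order
  spec <- cohort_spec(n_subjects = 10, n_metabolites = 4,
                      subject_sd = 0.2, noise_sd = 0.05,
                      treatment_profile = matrix(c(rep(0.1, 4), rep(0, 12)),
                                                 4, 4, byrow = FALSE),
                      n_pool_replicates = 0, seed = 21)
  p <- log10_transform(generate_cohort(spec))
  cmp <- comparison("one_vs_one", "d3_evening", "d2_evening")
  res <- fit_mixed_anova(p, cmp, covariates = FALSE)
  for (j in seq_len(4)) {
    lv <- p$log_values[, j]
    g <- p$sample_meta$slot == "d3_evening"
    r <- p$sample_meta$slot == "d2_evening"
    diffs <- lv[g][order(p$sample_meta$subject_id[g])] -
      lv[r][order(p$sample_meta$subject_id[r])]
    tt <- t.test(diffs)
    # same estimate is implied; p-values must agree closely (paired t is
    # the balanced-case reduction of the random-intercept model, up to
    # REML convergence tolerance)
    expect_equal(res$p_value[j], tt$p.value, tolerance = 1e-4)
  }
})

test_that("strong planted effect is detected with a calibrated ratio", {
  treat <- matrix(0, 6, 4); treat[1, ] <- log10(1.5)
  spec <- cohort_spec(n_subjects = 20, n_metabolites = 6,
                      subject_sd = 0.05, noise_sd = 0.02,
                      treatment_profile = treat,
                      n_pool_replicates = 5, seed = 31)
  p <- autoscale(log10_transform(normalize_to_pool(generate_cohort(spec))))
  res <- fit_mixed_anova(p, treatment_comparisons()$post6h)
  expect_gt(res$ratio[1], 1.45); expect_lt(res$ratio[1], 1.55)
  expect_lt(res$p_value[1], 0.01)
  expect_gt(min(res$p_value[-1]), 0.01)  # nulls stay quiet at this noise
})

test_that("ols fallback engages instead of dropping singular fits", {
  # zero variance everywhere makes the mixed fit degenerate
  spec <- tiny_spec(n_metabolites = 1, subject_sd = 0, noise_sd = 0,
                    n_pool_replicates = 0)
  p <- log10_transform(generate_cohort(spec))
  cmp <- comparison("one_vs_one", "d3_evening", "d2_evening")
  res <- suppressWarnings(fit_mixed_anova(p, cmp, covariates = FALSE))
  expect_equal(nrow(res), 1)
  expect_true(res$fit_flag %in% c("lme", "ols_fallback"))
})

test_that("precheck counts false positives between replicate slots", {
  spec <- tiny_spec(n_subjects = 10, n_metabolites = 20, seed = 41)
  p <- log10_transform(generate_cohort(spec))
  pc <- precheck_combination(p, "d1_evening", "d2_evening")
  expect_equal(pc$expected, 0.05 * 20)
  expect_true(pc$count >= 0 && pc$count <= 20)
  # identical data in both slots: no differences at all
  p2 <- p
  ia <- which(p2$sample_meta$slot == "d1_evening")
  ib <- which(p2$sample_meta$slot == "d2_evening")
  p2$log_values[ib, ] <- p2$log_values[ia, ]
  expect_equal(suppressWarnings(
    precheck_combination(p2, "d1_evening", "d2_evening"))$count, 0)
  # guards: mismatched day times and treated slots are refused
  expect_error(precheck_combination(p, "d1_evening", "d2_morning"),
               "day times")
  expect_error(precheck_combination(p, "d3_evening", "d2_evening"),
               "untreated")
})

test_that("precheck closed form equals stats::t.test exactly", {
  spec <- tiny_spec(n_subjects = 8, n_metabolites = 5, seed = 42)
  p <- log10_transform(generate_cohort(spec))
  pc <- precheck_combination(p, "d2_midday", "d3_midday")
  meta <- p$sample_meta
  for (j in 1:5) {
    a <- p$log_values[meta$slot == "d2_midday", j][
      order(meta$subject_id[meta$slot == "d2_midday"])]
    b <- p$log_values[meta$slot == "d3_midday", j][
      order(meta$subject_id[meta$slot == "d3_midday"])]
    expect_equal(unname(pc$p_values[j]), t.test(a, b, paired = TRUE)$p.value)
  }
})

test_that("monotone circadian increments order the contrast ratios", {
  circ <- matrix(rep(c(0.08, 0.06), each = 5), 5, 2)
  spec <- cohort_spec(n_subjects = 20, n_metabolites = 5,
                      subject_sd = 0.05, noise_sd = 0.02,
                      circadian_profile = circ,
                      n_pool_replicates = 0, seed = 51)
  p <- log10_transform(generate_cohort(spec))
  res <- circadian_contrasts(p, covariates = FALSE)
  mid <- res[res$comparison == "midday_vs_morning", ]
  eve <- res[res$comparison == "evening_vs_morning", ]
  expect_true(all(eve$ratio > mid$ratio))
  expect_true(all(mid$ratio > 1))
  expect_true(all(eve$q_value < 0.05))
})

test_that("deregulation counting matches a brute-force tally", {
  # hand-built 5 metabolites x 4 comparisons q-table
  q <- c(0.01, 0.2, 0.01, 0.04,   # m1: slots 1,3,4
         1, 1, 1, 1,              # m2: none
         0.04, 0.04, 0.04, 0.04,  # m3: all
         0.2, 0.01, 0.2, 0.2,     # m4: slot 2
         0.049, 0.2, 0.2, 0.2)    # m5: slot 1
  res <- data.frame(
    metabolite = rep(paste0("m", 1:5), each = 4),
    comparison = rep(paste0("post", c(6, 18, 24, 30), "h"), 5),
    q_value = q)
  ct <- count_deregulated(res, 0.05)
  expect_equal(unname(ct$per_slot), c(3, 2, 2, 2))
  expect_equal(ct$any_slot, 4)
  expect_equal(ct$all_slots, 1)
  # all q = 1 gives zero everywhere
  res$q_value <- 1
  ct0 <- count_deregulated(res)
  expect_equal(unname(ct0$per_slot), rep(0L, 4))
  expect_equal(ct0$any_slot, 0)
  expect_equal(ct0$all_slots, 0)
})
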