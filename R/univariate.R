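#' Linear-scale fold-change ratio per metabolite
#'
#' The ratio is the arithmetic mean of all linear-scale values for a
#' metabolite in the group slots divided by the arithmetic mean in the
#' reference slots (not a back-transformed log-mean).
#'
#' @param p a `processed_matrix` (ratios are computed from
#'   `10^log_values`) or a `metabolite_matrix`.
#' @param cmp a [comparison()].
#' @return Named numeric vector of ratios, one per metabolite.
#' @export
ratio <- function(p, cmp) {
  stopifnot(inherits(cmp, "comparison"))
  if (inherits(p, "processed_matrix")) {
    values <- 10^p$log_values; meta <- p$sample_meta
  } else if (inherits(p, "metabolite_matrix")) {
    values <- p$values; meta <- p$sample_meta
  } else stop("p must be a processed_matrix or metabolite_matrix")
  g <- meta$slot %in% cmp$group_slots
  r <- meta$slot %in% cmp$reference_slots
  if (!any(g) || !any(r))
    stop("comparison '", cmp$name, "': empty group or reference")
  colMeans(values[g, , drop = FALSE]) / colMeans(values[r, , drop = FALSE])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate q-values: with ordered p-values p_(1) <= ... <=
#' p_(m), q_(i) = min over j >= i of min(1, m p_(j) / j), returned in the
#' original order. Monotone in p and never below it.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Time-matched mixed-effects ANOVA per metabolite
#'
#' For each metabolite, fits on the samples of
#' `group_slots` \eqn{\cup} `reference_slots`:
#' \deqn{\log_{10} y = \beta_0 + \beta_1\,group + \beta_2\,age +
#'   \beta_3\,BMI + u_{subject} + \epsilon}
#' with a random intercept per subject (REML via nlme), and reports the
#' group-indicator Wald t statistic with its two-sided p-value. The fold
#' change is [ratio()]'s linear-scale mean ratio. If the mixed fit is
#' singular or otherwise fails, the row falls back to ordinary least
#' squares and is flagged `ols_fallback` rather than dropped. q-values
#' are Benjamini-Hochberg across metabolites within the comparison.
#'
#' @param p a `processed_matrix` carrying `log_values`, with subject ids
#'   and (if `covariates = TRUE`) age and BMI in `sample_meta`.
#' @param cmp a [comparison()].
#' @param covariates include age and BMI as numeric fixed effects
#'   (default TRUE); when TRUE their Wald p-values are reported too, for
#'   the covariate screen.
#' @return Data frame, one row per metabolite: `metabolite`,
#'   `comparison`, `ratio`, `t_value`, `p_value`, `q_value`, `n_group`,
#'   `n_reference`, `fit_flag`, and with covariates also `p_age`,
#'   `p_bmi`, `q_age`, `q_bmi`.
#' @export
fit_mixed_anova <- function(p, cmp, covariates = TRUE) {
  stopifnot(inherits(p, "processed_matrix"), inherits(cmp, "comparison"))
  meta <- p$sample_meta
  sel <- meta$slot %in% c(cmp$group_slots, cmp$reference_slots) &
    !meta$is_pool_reference
  meta <- meta[sel, , drop = FALSE]
  X <- p$log_values[sel, , drop = FALSE]
  grp <- as.numeric(meta$slot %in% cmp$group_slots)
  if (length(unique(meta$subject_id[grp == 1])) < 2L ||
      length(unique(meta$subject_id[grp == 0])) < 2L)
    stop("comparison '", cmp$name,
         "': need >= 2 subjects in both slot sets")
  df0 <- data.frame(grp = grp,
                    subject = factor(meta$subject_id),
                    age = meta$age, bmi = meta$bmi)
  use_cov <- covariates && length(unique(df0$age)) > 1L &&
    length(unique(df0$bmi)) > 1L
  form <- if (use_cov) y ~ grp + age + bmi else y ~ grp
  rat <- ratio(p, cmp)[colnames(X)]

  M <- ncol(X)
  t_value <- p_value <- p_age <- p_bmi <- rep(NA_real_, M)
  fit_flag <- rep("lme", M)
  for (j in seq_len(M)) {
    df0$y <- X[, j]
    fit <- tryCatch(
      nlme::lme(form, random = ~ 1 | subject, data = df0, method = "REML"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tt <- summary(fit)$tTable
      t_value[j] <- tt["grp", "t-value"]
      p_value[j] <- tt["grp", "p-value"]
      if (use_cov) { p_age[j] <- tt["age", "p-value"]
                     p_bmi[j] <- tt["bmi", "p-value"] }
    } else {
      fit_flag[j] <- "ols_fallback"
      ols <- summary(stats::lm(form, data = df0))$coefficients
      t_value[j] <- ols["grp", "t value"]
      p_value[j] <- ols["grp", "Pr(>|t|)"]
      if (use_cov) { p_age[j] <- ols["age", "Pr(>|t|)"]
                     p_bmi[j] <- ols["bmi", "Pr(>|t|)"] }
    }
  }
  out <- data.frame(metabolite = colnames(X),
                    comparison = cmp$name,
                    ratio = unname(rat),
                    t_value = t_value, p_value = p_value,
                    q_value = bh_adjust(p_value),
                    n_group = sum(grp == 1), n_reference = sum(grp == 0),
                    fit_flag = fit_flag, stringsAsFactors = FALSE)
  if (use_cov) {
    out$p_age <- p_age; out$p_bmi <- p_bmi
    out$q_age <- bh_adjust(p_age); out$q_bmi <- bh_adjust(p_bmi)
  }
  out
}

#' Run all time-matched treatment comparisons
#'
#' @param p a `processed_matrix`.
#' @param design a [study_design()].
#' @inheritParams fit_mixed_anova
#' @return Row-bound [fit_mixed_anova()] results for every post-dose
#'   comparison ([treatment_comparisons()]).
#' @export
treatment_anova <- function(p, design = study_design(), covariates = TRUE) {
  do.call(rbind, lapply(treatment_comparisons(design), fit_mixed_anova,
                        p = p, covariates = covariates))
}

#' Circadian contrasts: untreated midday and evening vs morning
#'
#' Same model machinery as [fit_mixed_anova()], with day time as the
#' group factor, restricted to untreated slots.
#'
#' @inheritParams treatment_anova
#' @return Row-bound results for `midday_vs_morning` and
#'   `evening_vs_morning`.
#' @export
circadian_contrasts <- function(p, design = study_design(),
                                covariates = TRUE) {
  do.call(rbind, lapply(circadian_comparisons(design), fit_mixed_anova,
                        p = p, covariates = covariates))
}

#' Pre-check for combining replicate untreated slots
#'
#' Before pooling untreated slots that share a day time (e.g. day 1 and
#' day 2 evening), verify that the number of metabolites differing
#' between them at p < 0.05 is near the expected false-positive count
#' (0.05 x number of metabolites). Uses a per-metabolite paired t-test
#' across subjects on log10 values (closed form, df = n_subjects - 1).
#'
#' @param p a `processed_matrix`.
#' @param slot_a,slot_b two untreated slots with the same day time.
#' @param alpha significance level (default 0.05).
#' @return List with `count` (metabolites with p < alpha), `expected`
#'   (alpha x n_metabolites), and the per-metabolite `p_values`.
#' @export
precheck_combination <- function(p, slot_a, slot_b, alpha = 0.05) {
  stopifnot(inherits(p, "processed_matrix"))
  meta <- p$sample_meta
  info <- function(s) {
    i <- which(meta$slot == s)
    if (length(i) == 0L) stop("slot '", s, "' not found")
    i
  }
  ia <- info(slot_a); ib <- info(slot_b)
  if (any(meta$treated[c(ia, ib)]))
    stop("precheck slots must both be untreated")
  if (meta$daytime[ia[1L]] != meta$daytime[ib[1L]])
    stop("slots '", slot_a, "' and '", slot_b,
         "' have different day times")
  sa <- meta$subject_id[ia]; sb <- meta$subject_id[ib]
  common <- sort(intersect(sa, sb))
  ia <- ia[match(common, sa)]; ib <- ib[match(common, sb)]
  d <- p$log_values[ia, , drop = FALSE] - p$log_values[ib, , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 paired subjects")
  mns <- colMeans(d)
  sds <- sqrt(colSums(sweep(d, 2L, mns, "-")^2) / (n - 1L))
  tstat <- mns / (sds / sqrt(n))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  list(count = sum(pv < alpha, na.rm = TRUE),
       expected = alpha * ncol(d),
       p_values = pv)
}

#' Count deregulated metabolites across post-dose comparisons
#'
#' @param results output of [treatment_anova()] (all four post-dose
#'   comparisons present).
#' @param q_threshold FDR threshold (default 0.05).
#' @return List with `per_slot` (named count per comparison), `any_slot`
#'   (metabolites significant at >= 1 post-dose offset) and `all_slots`
#'   (significant at every offset).
#' @export
count_deregulated <- function(results, q_threshold = 0.05) {
  cmps <- unique(results$comparison)
  sig <- results$q_value < q_threshold
  per_slot <- vapply(cmps, function(cc)
    sum(sig[results$comparison == cc]), 0L)
  tab <- tapply(sig, list(results$metabolite, results$comparison), any)
  tab <- tab[, cmps, drop = FALSE]
  list(per_slot = per_slot,
       any_slot = sum(apply(tab, 1L, any)),
       all_slots = sum(apply(tab, 1L, all)))
}

#' Write univariate results as tidy CSV
#'
#' @param results data frame from [treatment_anova()] or
#'   [circadian_contrasts()].
#' @param path output CSV path.
#' @export
write_univariate_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
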