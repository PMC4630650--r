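#' Specify a synthetic metabolomics cohort
#'
#' Defines the generative model for a repeated-measures plasma metabolome
#' study. On the log10 scale, the value for subject i, metabolite j at
#' slot t is
#' \deqn{y_{ijt} = \mu_j + b_{ij} + c_j(daytime_t) + d_j(h_t) + \epsilon_{ijt}}
#' with a fixed metabolite baseline \eqn{\mu_j}, a subject offset
#' \eqn{b_{ij} \sim N(0, \sigma_{subj,j}^2)} drawn once per (subject,
#' metabolite), a monotone circadian term \eqn{c_j} (0 at morning,
#' cumulative signed increments towards midday and evening, identical on
#' all days), a post-dose effect \eqn{d_j} that is exactly zero at
#' untreated slots, and residual noise
#' \eqn{\epsilon \sim N(0, \sigma_{noise,j}^2)}. Abundances are
#' \eqn{10^{y}}, so all effects are multiplicative on the linear scale and
#' the post-dose fold change at offset h is \eqn{10^{d_j(h)}}.
#'
#' Scalar arguments are recycled across metabolites.
#'
#' @param n_subjects,n_metabolites cohort dimensions.
#' @param design a [study_design()].
#' @param baseline_log_mean per-metabolite location, log10 scale.
#' @param subject_sd per-metabolite between-subject SD, log10 scale.
#' @param noise_sd per-metabolite residual SD, log10 scale.
#' @param circadian_profile `n_metabolites x 2` matrix of signed log10
#'   increments (morning to midday, midday to evening); a scalar or
#'   length-2 vector is recycled.
#' @param treatment_profile `n_metabolites x 4` matrix of log10 effects at
#'   the post-dose offsets (+6, +18, +24, +30 h for the default design);
#'   scalar recycled.
#' @param phenotype_set integer indices of metabolites carrying a stable
#'   individual phenotype; their `subject_sd`/`noise_sd` ratio should be
#'   large for the phenotype to be recoverable.
#' @param n_pool_replicates number of pooled reference samples appended to
#'   the cohort.
#' @param pool_noise_sd SD of the pooled-sample noise, log10 scale;
#'   defaults to `noise_sd / 4`.
#' @param age_mean,age_sd,bmi_mean,bmi_sd subject covariate distributions
#'   (years, kg/m2), truncated to plausible adult ranges. By default the
#'   covariates have no effect on any metabolite.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `cohort_spec` object (validated list).
#' @seealso [generate_cohort()], [truth_table()], [study_cohort_spec()]
#' @export
cohort_spec <- function(n_subjects = 20L,
                        n_metabolites = 214L,
                        design = study_design(),
                        baseline_log_mean = 2,
                        subject_sd = 0.15,
                        noise_sd = 0.1,
                        circadian_profile = 0,
                        treatment_profile = 0,
                        phenotype_set = integer(0),
                        n_pool_replicates = 10L,
                        pool_noise_sd = NULL,
                        age_mean = 25.5, age_sd = 2.9,
                        bmi_mean = 23.3, bmi_sd = 2.7,
                        seed = 1L) {
  validate_design(design)
  M <- as.integer(n_metabolites)
  n_treated <- sum(design$slots$treated)

  expand_vec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, M)
    if (length(x) != M)
      stop("field '", nm, "' must have length 1 or n_metabolites (", M, ")")
    x
  }
  expand_mat <- function(x, k, nm) {
    if (is.null(dim(x))) {
      if (length(x) == 1L) x <- matrix(x, M, k)
      else if (length(x) == k) x <- matrix(x, M, k, byrow = TRUE)
      else if (length(x) == M) x <- matrix(x, M, k)
      else stop("field '", nm, "' cannot be recycled to ", M, " x ", k)
    }
    if (!all(dim(x) == c(M, k)))
      stop("field '", nm, "' must be ", M, " x ", k)
    x
  }

  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_metabolites = M,
    design = design,
    baseline_log_mean = expand_vec(baseline_log_mean, "baseline_log_mean"),
    subject_sd = expand_vec(subject_sd, "subject_sd"),
    noise_sd = expand_vec(noise_sd, "noise_sd"),
    circadian_profile = expand_mat(circadian_profile, 2L, "circadian_profile"),
    treatment_profile = expand_mat(treatment_profile, n_treated,
                                   "treatment_profile"),
    phenotype_set = as.integer(phenotype_set),
    n_pool_replicates = as.integer(n_pool_replicates),
    pool_noise_sd = if (is.null(pool_noise_sd))
      expand_vec(noise_sd, "noise_sd") / 4 else expand_vec(pool_noise_sd,
                                                           "pool_noise_sd"),
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  colnames(spec$treatment_profile) <- paste0(
    "post", sort(design$slots$hours_post_dose[design$slots$treated]), "h")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (nm in c("subject_sd", "noise_sd", "pool_noise_sd")) {
    if (any(spec[[nm]] < 0)) stop("field '", nm, "' must be non-negative")
  }
  if (spec$n_subjects < 1L) stop("field 'n_subjects' must be positive")
  if (spec$n_metabolites < 1L) stop("field 'n_metabolites' must be positive")
  if (length(spec$phenotype_set) &&
      (min(spec$phenotype_set) < 1L ||
       max(spec$phenotype_set) > spec$n_metabolites))
    stop("field 'phenotype_set' must index metabolites 1..",
         spec$n_metabolites)
  if (spec$n_pool_replicates < 0L)
    stop("field 'n_pool_replicates' must be non-negative")
  invisible(spec)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from the generative model of a [cohort_spec()]:
#' subject offsets once per (subject, metabolite), residual noise per
#' sample, then exponentiation to strictly positive linear-scale
#' abundances. Pooled reference samples are appended as the per-metabolite
#' mean of all study samples times a small multiplicative noise, emulating
#' repeated injections of an aliquot pool.
#'
#' @param spec a [cohort_spec()].
#' @return A `metabolite_matrix`: list with `values`
#'   (samples x metabolites, linear scale, strictly positive),
#'   `sample_meta` (sample_id, subject_id, slot, day, daytime, treated,
#'   hours_post_dose, is_pool_reference, age, bmi) and `metabolite_meta`
#'   (name, is_phenotype_truth).
#' @examples
#' m <- generate_cohort(cohort_spec(n_subjects = 4, n_metabolites = 6))
#' dim(m$values)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  S <- spec$n_subjects; M <- spec$n_metabolites
  slots <- spec$design$slots
  Tn <- nrow(slots)

  age <- rnorm_trunc(S, spec$age_mean, spec$age_sd, 18, 40)
  bmi <- rnorm_trunc(S, spec$bmi_mean, spec$bmi_sd, 17, 32)

  # subject offsets: S x M, one draw per (subject, metabolite)
  b <- matrix(stats::rnorm(S * M, 0, rep(spec$subject_sd, each = S)), S, M)

  # circadian term per slot (identical across days): 0 / inc1 / inc1+inc2
  circ <- matrix(0, Tn, M)
  circ[slots$daytime == "midday", ] <-
    matrix(spec$circadian_profile[, 1L], sum(slots$daytime == "midday"), M,
           byrow = TRUE)
  circ[slots$daytime == "evening", ] <-
    matrix(spec$circadian_profile[, 1L] + spec$circadian_profile[, 2L],
           sum(slots$daytime == "evening"), M, byrow = TRUE)

  # post-dose term per slot
  treat <- matrix(0, Tn, M)
  treated_rows <- which(slots$treated)
  treated_order <- order(slots$hours_post_dose[treated_rows])
  for (k in seq_along(treated_rows))
    treat[treated_rows[treated_order[k]], ] <- spec$treatment_profile[, k]

  n_samp <- S * Tn
  subj_idx <- rep(seq_len(S), each = Tn)
  slot_idx <- rep(seq_len(Tn), times = S)
  logv <- matrix(spec$baseline_log_mean, n_samp, M, byrow = TRUE) +
    b[subj_idx, , drop = FALSE] +
    circ[slot_idx, , drop = FALSE] +
    treat[slot_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_samp * M, 0, rep(spec$noise_sd, each = n_samp)),
           n_samp, M)
  values <- 10^logv

  met_names <- sprintf("met_%03d", seq_len(M))
  colnames(values) <- met_names
  sample_meta <- data.frame(
    sample_id = sprintf("s%02d_%s", subj_idx, slots$slot[slot_idx]),
    subject_id = sprintf("s%02d", subj_idx),
    slot = slots$slot[slot_idx],
    day = slots$day[slot_idx],
    daytime = slots$daytime[slot_idx],
    treated = slots$treated[slot_idx],
    hours_post_dose = slots$hours_post_dose[slot_idx],
    is_pool_reference = FALSE,
    age = age[subj_idx],
    bmi = bmi[subj_idx],
    stringsAsFactors = FALSE
  )

  if (spec$n_pool_replicates > 0L) {
    pool_base <- colMeans(values)
    P <- spec$n_pool_replicates
    pool_vals <- matrix(pool_base, P, M, byrow = TRUE) *
      10^matrix(stats::rnorm(P * M, 0, rep(spec$pool_noise_sd, each = P)),
                P, M)
    colnames(pool_vals) <- met_names
    values <- rbind(values, pool_vals)
    sample_meta <- rbind(sample_meta, data.frame(
      sample_id = sprintf("pool_%02d", seq_len(P)),
      subject_id = NA_character_, slot = NA_character_,
      day = NA_integer_, daytime = NA_character_, treated = NA,
      hours_post_dose = NA_real_, is_pool_reference = TRUE,
      age = NA_real_, bmi = NA_real_, stringsAsFactors = FALSE
    ))
  }
  rownames(values) <- sample_meta$sample_id

  metabolite_meta <- data.frame(
    name = met_names,
    is_phenotype_truth = seq_len(M) %in% spec$phenotype_set,
    stringsAsFactors = FALSE
  )
  metabolite_matrix(values, sample_meta, metabolite_meta)
}

#' Construct a metabolite abundance matrix with metadata
#'
#' The universal currency between pipeline stages: strictly positive
#' linear-scale abundances plus per-sample and per-metabolite metadata.
#'
#' @param values samples x metabolites numeric matrix, strictly positive.
#' @param sample_meta data frame, one row per sample (same order as
#'   `values` rows).
#' @param metabolite_meta data frame, one row per metabolite.
#' @return A `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values, sample_meta, metabolite_meta) {
  values <- as.matrix(values)
  if (nrow(sample_meta) != nrow(values))
    stop("sample_meta must have one row per sample")
  if (nrow(metabolite_meta) != ncol(values))
    stop("metabolite_meta must have one row per metabolite")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be strictly positive and finite (log10 must exist)")
  study <- sample_meta[!sample_meta$is_pool_reference, , drop = FALSE]
  if (anyDuplicated(paste(study$subject_id, study$slot)))
    stop("duplicate (subject, slot) combination among study samples")
  structure(list(values = values, sample_meta = sample_meta,
                 metabolite_meta = metabolite_meta),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  n_pool <- sum(x$sample_meta$is_pool_reference)
  cat("metabolite_matrix:", nrow(x$values) - n_pool, "study samples",
      if (n_pool) paste0("(+", n_pool, " pool refs)") else "",
      "x", ncol(x$values), "metabolites\n")
  invisible(x)
}

#' Ground truth of a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with one row per metabolite: true linear-scale fold
#'   change at each post-dose offset (`10^treatment_profile`), circadian
#'   direction (`up` / `down` / `flat` / `mixed` from the sign of the
#'   increments) and the phenotype flag. Used by recovery tests.
#' @export
truth_table <- function(spec) {
  validate_cohort_spec(spec)
  ratios <- 10^spec$treatment_profile
  colnames(ratios) <- paste0("true_ratio_", colnames(spec$treatment_profile))
  sgn <- sign(spec$circadian_profile)
  dir <- ifelse(sgn[, 1L] == 0 & sgn[, 2L] == 0, "flat",
         ifelse(sgn[, 1L] >= 0 & sgn[, 2L] >= 0, "up",
         ifelse(sgn[, 1L] <= 0 & sgn[, 2L] <= 0, "down", "mixed")))
  data.frame(metabolite = sprintf("met_%03d", seq_len(spec$n_metabolites)),
             ratios,
             circadian_direction = dir,
             is_phenotype = seq_len(spec$n_metabolites) %in%
               spec$phenotype_set,
             stringsAsFactors = FALSE)
}

#' Cohort spec emulating the dexamethasone study conditions
#'
#' A ready-made [cohort_spec()] whose planted structure mirrors a
#' single-dose glucocorticoid time-course study in 20 healthy young men:
#' 214 plasma metabolites over 11 slots; about half the metabolome
#' circadian (78 metabolites rising towards the evening, 25 falling);
#' 150 metabolites perturbed at one or more post-dose offsets, 9 of them
#' at all four; and 27 "metabolic phenotype" metabolites whose
#' between-subject spread dominates their within-subject noise
#' (subject SD 0.35 vs residual SD 0.1 on the log10 scale, ratio 3.5).
#'
#' @param seed integer seed controlling both the planted structure and the
#'   cohort draw.
#' @param effect_scale multiplier on the post-dose log10 effect sizes
#'   (default 1; raise for a strongly separated cohort).
#' @return A `cohort_spec`.
#' @export
study_cohort_spec <- function(seed = 1L, effect_scale = 1) {
  M <- 214L
  set.seed(seed + 1000L)

  circ <- matrix(0, M, 2L)
  idx <- sample.int(M)
  up <- idx[1:78]; down <- idx[79:103]
  circ[up, ] <- stats::runif(length(up) * 2, 0.04, 0.12)
  circ[down, ] <- -stats::runif(length(down) * 2, 0.04, 0.12)

  treat <- matrix(0, M, 4L)
  affected <- sort(sample.int(M, 150L))
  all4 <- affected[1:9]
  rest <- affected[-(1:9)]
  for (j in all4)
    treat[j, ] <- sample(c(-1, 1), 1) * stats::runif(4, 0.1, 0.4)
  for (j in rest) {
    k <- sample(1:3, 1)
    treat[j, sample.int(4L, k)] <- sample(c(-1, 1), 1) *
      stats::runif(k, 0.1, 0.4)
  }
  treat <- treat * effect_scale

  phen <- sort(sample(setdiff(seq_len(M), integer(0)), 27L))
  subj_sd <- rep(0.1, M)
  subj_sd[phen] <- 0.35

  cohort_spec(
    n_subjects = 20L, n_metabolites = M,
    baseline_log_mean = stats::rnorm(M, 2, 0.5),
    subject_sd = subj_sd, noise_sd = 0.1,
    circadian_profile = circ, treatment_profile = treat,
    phenotype_set = phen, n_pool_replicates = 10L,
    seed = seed
  )
}
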