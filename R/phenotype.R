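#' Kendall rank correlation (tau-b) between two time points
#'
#' Tie-corrected Kendall tau over subjects: how well the between-subject
#' ranking of a metabolite at one time point is preserved at another.
#' Invariant under strictly monotone transforms of either vector, so it
#' does not matter whether raw, normalized or log-scale values are used.
#'
#' @param x,y per-subject values at two time points (same subjects, same
#'   order, n >= 3).
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must pair the same subjects")
  if (length(x) < 3L) stop("need >= 3 subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: tau undefined")
  stats::cor(x, y, method = "kendall")
}

#' Rank-stability scores across time points
#'
#' For every metabolite, Kendall tau is computed over subjects for each
#' unordered pair of the chosen time slots (21 pairs for 7 slots, 55 for
#' 11). A metabolite whose between-subject ranking is preserved across
#' time — a metabolic phenotype constituent — has high mean tau and low
#' SD; selection uses \eqn{mean(\tau) - SD(\tau) \ge threshold}. Pairs
#' where tau is undefined (constant values) are excluded and `n_pairs`
#' decremented, flagged in `n_pairs_excluded`.
#'
#' @param m a `metabolite_matrix` or `processed_matrix` (tau is
#'   rank-based, so the scale is immaterial).
#' @param slots character vector of slot ids to use (default: all
#'   untreated slots in the data); >= 3 required.
#' @param threshold selection threshold on mean - SD (default 0.6).
#' @return Data frame per metabolite: `metabolite`, `mean_tau`,
#'   `sd_tau` (n-1 denominator across pairs), `n_pairs`,
#'   `n_pairs_excluded`, `selected`.
#' @export
stability_scores <- function(m, slots = NULL, threshold = 0.6) {
  if (inherits(m, "processed_matrix")) {
    values <- m$log_values; meta <- m$sample_meta
  } else if (inherits(m, "metabolite_matrix")) {
    values <- m$values; meta <- m$sample_meta
  } else stop("m must be a metabolite_matrix or processed_matrix")
  keep <- !meta$is_pool_reference
  values <- values[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (is.null(slots)) slots <- unique(meta$slot[!meta$treated])
  if (length(slots) < 3L) stop("need >= 3 slots")
  subjects <- sort(unique(meta$subject_id))
  # subjects x slots index matrix into the sample rows
  idx <- vapply(slots, function(s)
    match(paste(subjects, s), paste(meta$subject_id, meta$slot)),
    integer(length(subjects)))
  if (anyNA(idx)) stop("missing (subject, slot) combinations")
  pairs <- utils::combn(length(slots), 2L)
  M <- ncol(values)
  mean_tau <- sd_tau <- numeric(M)
  n_excl <- integer(M)
  for (j in seq_len(M)) {
    V <- matrix(values[idx, j], length(subjects), length(slots))
    taus <- apply(pairs, 2L, function(pr)
      tryCatch(kendall_tau(V[, pr[1L]], V[, pr[2L]]),
               error = function(e) NA_real_))
    n_excl[j] <- sum(is.na(taus))
    taus <- taus[!is.na(taus)]
    mean_tau[j] <- mean(taus)
    sd_tau[j] <- stats::sd(taus)
  }
  n_pairs <- ncol(pairs) - n_excl
  data.frame(metabolite = colnames(values),
             mean_tau = mean_tau, sd_tau = sd_tau,
             n_pairs = n_pairs, n_pairs_excluded = n_excl,
             selected = (mean_tau - sd_tau) >= threshold,
             stringsAsFactors = FALSE)
}

#' Stability of the phenotype set when post-dose slots are included
#'
#' Recomputes [stability_scores()] over all slots (untreated + treated)
#' and compares with the untreated-only scores. A treatment effect that
#' shifts every subject equally leaves the between-subject ranking — and
#' hence tau — untouched; subject-specific treatment responses lower it.
#'
#' @param m a `metabolite_matrix` or `processed_matrix`.
#' @param design a [study_design()].
#' @param threshold selection threshold (default 0.6).
#' @return List: `untreated` and `all_slots` score tables,
#'   `delta_mean_tau` (all-slots minus untreated, per metabolite),
#'   `selected_untreated`, `selected_all`, `overlap` (metabolites
#'   selected in both), `jaccard`.
#' @export
stability_under_treatment <- function(m, design = study_design(),
                                      threshold = 0.6) {
  s <- design$slots
  unt <- stability_scores(m, slots = s$slot[!s$treated],
                          threshold = threshold)
  all_s <- stability_scores(m, slots = s$slot, threshold = threshold)
  sel_u <- unt$metabolite[unt$selected]
  sel_a <- all_s$metabolite[all_s$selected]
  uni <- union(sel_u, sel_a)
  list(untreated = unt, all_slots = all_s,
       delta_mean_tau = stats::setNames(all_s$mean_tau - unt$mean_tau,
                                        unt$metabolite),
       selected_untreated = sel_u, selected_all = sel_a,
       overlap = intersect(sel_u, sel_a),
       jaccard = if (length(uni)) length(intersect(sel_u, sel_a)) /
         length(uni) else NA_real_)
}

#' Write stability scores as tidy CSV
#'
#' @param report output of [stability_under_treatment()].
#' @param path output CSV path.
#' @export
write_stability_csv <- function(report, path) {
  out <- report$untreated
  out$selected_with_treatment <- report$all_slots$selected
  out$delta_mean_tau <- unname(report$delta_mean_tau)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
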