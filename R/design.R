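#' Four-day sampling schedule with a mid-study treatment boundary
#'
#' Builds the default repeated-measures design: 20 subjects are sampled on
#' four consecutive days at up to three fixed day times (morning 7:30,
#' midday 13:30, evening 19:30). Day 1 has no morning sample. A single oral
#' dose is taken after midday of day 3, so seven slots are untreated
#' (day 1 midday/evening, day 2 morning/midday/evening, day 3
#' morning/midday) and four are post-dose (day 3 evening = +6 h, day 4
#' morning/midday/evening = +18/+24/+30 h).
#'
#' @return A `study_design` object: a list with a `slots` data frame
#'   (columns `slot`, `day`, `daytime`, `treated`, `hours_post_dose`,
#'   chronological order).
#' @examples
#' d <- study_design()
#' d$slots
#' @export
study_design <- function() {
  slots <- data.frame(
    slot = c("d1_midday", "d1_evening",
             "d2_morning", "d2_midday", "d2_evening",
             "d3_morning", "d3_midday", "d3_evening",
             "d4_morning", "d4_midday", "d4_evening"),
    day = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L),
    daytime = c("midday", "evening",
                "morning", "midday", "evening",
                "morning", "midday", "evening",
                "morning", "midday", "evening"),
    treated = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE),
    hours_post_dose = c(NA, NA, NA, NA, NA, NA, NA, 6, 18, 24, 30),
    stringsAsFactors = FALSE
  )
  out <- structure(list(slots = slots), class = "study_design")
  validate_design(out)
  out
}

validate_design <- function(design) {
  stopifnot(inherits(design, "study_design"))
  s <- design$slots
  if (nrow(s) != 11L) stop("design must have exactly 11 slots, got ", nrow(s))
  if (sum(s$treated) != 4L) stop("design must have exactly 4 treated slots")
  if (any(s$day == 1L & s$daytime == "morning"))
    stop("day 1 has no morning slot")
  if (any(is.na(s$hours_post_dose[s$treated])))
    stop("every treated slot needs hours_post_dose")
  # every treated slot must have at least one untreated slot at the same
  # day time, otherwise no time-matched comparison exists
  for (i in which(s$treated)) {
    if (!any(!s$treated & s$daytime == s$daytime[i]))
      stop("treated slot ", s$slot[i], " has no matched untreated slot")
  }
  invisible(design)
}

#' Define a two-group comparison over design slots
#'
#' @param name label for the comparison.
#' @param group_slots,reference_slots character vectors of slot ids; the
#'   ratio and the model contrast are group over reference. The two sets
#'   must be disjoint.
#' @return A `comparison` object.
#' @export
comparison <- function(name, group_slots, reference_slots) {
  if (length(group_slots) == 0L || length(reference_slots) == 0L)
    stop("comparison '", name, "': both slot sets must be non-empty")
  if (length(intersect(group_slots, reference_slots)) > 0L)
    stop("comparison '", name, "': group and reference slots overlap")
  structure(list(name = name,
                 group_slots = group_slots,
                 reference_slots = reference_slots),
            class = "comparison")
}

#' Time-matched treatment comparisons
#'
#' One comparison per post-dose slot, each against the pooled untreated
#' slots sharing its day time. Diurnal variation makes unmatched contrasts
#' uninterpretable, so a treated morning is only ever compared with
#' untreated mornings, and likewise for midday and evening. Pooling the
#' untreated replicate days is justified by [precheck_combination()].
#'
#' @param design a [study_design()].
#' @return Named list of [comparison()] objects, in post-dose time order
#'   (`post6h`, `post18h`, `post24h`, `post30h` for the default design).
#' @export
treatment_comparisons <- function(design = study_design()) {
  s <- design$slots
  treated <- s[s$treated, , drop = FALSE]
  treated <- treated[order(treated$hours_post_dose), , drop = FALSE]
  out <- lapply(seq_len(nrow(treated)), function(i) {
    dt <- treated$daytime[i]
    ref <- s$slot[!s$treated & s$daytime == dt]
    comparison(paste0("post", treated$hours_post_dose[i], "h"),
               treated$slot[i], ref)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Circadian contrasts among untreated slots
#'
#' Untreated midday and evening levels against untreated morning levels,
#' pooling replicate days per day time.
#'
#' @param design a [study_design()].
#' @return Named list of two [comparison()] objects
#'   (`midday_vs_morning`, `evening_vs_morning`).
#' @export
circadian_comparisons <- function(design = study_design()) {
  s <- design$slots[!design$slots$treated, , drop = FALSE]
  morning <- s$slot[s$daytime == "morning"]
  list(
    midday_vs_morning = comparison("midday_vs_morning",
                                   s$slot[s$daytime == "midday"], morning),
    evening_vs_morning = comparison("evening_vs_morning",
                                    s$slot[s$daytime == "evening"], morning)
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$slots), "slots,",
      sum(x$slots$treated), "post-dose\n")
  print(x$slots, row.names = FALSE)
  invisible(x)
}
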