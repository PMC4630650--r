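#' Write a cohort to plain-text CSV files
#'
#' Writes three UTF-8 CSVs with "." decimal separators and header rows:
#' a wide matrix (`matrix.csv`: sample_id + one column per metabolite), a
#' sample-metadata table (`samples.csv`) and a tidy long table
#' (`long.csv`: sample_id, subject_id, day, daytime, treated,
#' hours_post_dose, metabolite, value).
#'
#' @param m a `metabolite_matrix`.
#' @param dir output directory (created if missing).
#' @param long also write the long-format file (default TRUE; it is the
#'   largest of the three).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(m, dir, long = TRUE) {
  stopifnot(inherits(m, "metabolite_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.csv"),
             samples = file.path(dir, "samples.csv"))
  wide <- data.frame(sample_id = m$sample_meta$sample_id, m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(wide, paths["matrix"], row.names = FALSE)
  utils::write.csv(m$sample_meta, paths["samples"], row.names = FALSE)
  if (long) {
    paths <- c(paths, long = file.path(dir, "long.csv"))
    lf <- data.frame(
      sample_id = rep(m$sample_meta$sample_id, times = ncol(m$values)),
      subject_id = rep(m$sample_meta$subject_id, times = ncol(m$values)),
      day = rep(m$sample_meta$day, times = ncol(m$values)),
      daytime = rep(m$sample_meta$daytime, times = ncol(m$values)),
      treated = rep(m$sample_meta$treated, times = ncol(m$values)),
      hours_post_dose = rep(m$sample_meta$hours_post_dose,
                            times = ncol(m$values)),
      metabolite = rep(colnames(m$values), each = nrow(m$values)),
      value = as.vector(m$values),
      stringsAsFactors = FALSE
    )
    utils::write.csv(lf, paths["long"], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir directory holding `matrix.csv` and `samples.csv`.
#' @return A `metabolite_matrix`.
#' @export
read_cohort_csv <- function(dir) {
  wide <- utils::read.csv(file.path(dir, "matrix.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "samples.csv"),
                          stringsAsFactors = FALSE)
  values <- as.matrix(wide[, -1, drop = FALSE])
  rownames(values) <- wide$sample_id
  metabolite_matrix(values, meta,
                    data.frame(name = colnames(values),
                               is_phenotype_truth = NA,
                               stringsAsFactors = FALSE))
}

#' Build a cohort spec from a plain-text config file
#'
#' The config is YAML-flavoured `key: value` text; every [cohort_spec()]
#' argument is addressable by name (vector fields as YAML lists,
#' `circadian_profile` / `treatment_profile` as nested lists of rows).
#' Unknown keys are an error, so typos cannot silently fall back to
#' defaults.
#'
#' @param path path to the config file.
#' @return A `cohort_spec`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(cohort_spec)), "design")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown cohort config keys: ", paste(bad, collapse = ", "))
  for (nm in c("circadian_profile", "treatment_profile"))
    if (!is.null(cfg[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- do.call(rbind, lapply(cfg[[nm]], as.numeric))
  do.call(cohort_spec, cfg)
}
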