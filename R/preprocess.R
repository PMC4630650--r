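#' Normalize study samples to pooled-reference medians
#'
#' Divides every study sample's value by the per-metabolite median of the
#' pooled reference samples (repeated injections of an aliquot pool of all
#' study samples). This removes inter- and intra-instrumental intensity
#' variation: any global rescaling of a run cancels because it multiplies
#' study samples and pool medians alike. Pool rows are dropped from the
#' output.
#'
#' @param raw a `metabolite_matrix` containing at least one pool-reference
#'   sample.
#' @return A `metabolite_matrix` of normalized study samples; a
#'   `provenance` attribute records the transform.
#' @export
normalize_to_pool <- function(raw) {
  stopifnot(inherits(raw, "metabolite_matrix"))
  is_pool <- raw$sample_meta$is_pool_reference
  if (!any(is_pool)) stop("no pool-reference samples present")
  med <- apply(raw$values[is_pool, , drop = FALSE], 2L, stats::median)
  bad <- !is.finite(med) | med <= 0
  if (any(bad))
    stop("zero or missing pool median for metabolite(s): ",
         paste(colnames(raw$values)[bad], collapse = ", "))
  values <- sweep(raw$values[!is_pool, , drop = FALSE], 2L, med, "/")
  out <- metabolite_matrix(values,
                           raw$sample_meta[!is_pool, , drop = FALSE],
                           raw$metabolite_meta)
  attr(out, "provenance") <- c(attr(raw, "provenance"), "pool_normalized")
  out
}

#' Log10-transform abundances
#'
#' @param m a `metabolite_matrix` with strictly positive values.
#' @return A `processed_matrix`: list with `log_values`
#'   (samples x metabolites, log10 scale), the metadata tables, and a
#'   `provenance` character vector of applied transforms.
#' @export
log10_transform <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  bad <- which(!is.finite(m$values) | m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive value at sample '",
         m$sample_meta$sample_id[bad[1L, 1L]], "', metabolite '",
         colnames(m$values)[bad[1L, 2L]], "'")
  structure(list(log_values = log10(m$values),
                 scaled_values = NULL,
                 scale_center = NULL, scale_sd = NULL,
                 sample_meta = m$sample_meta,
                 metabolite_meta = m$metabolite_meta,
                 provenance = c(attr(m, "provenance"), "log10")),
            class = "processed_matrix")
}

#' Autoscale (center and scale to unit variance)
#'
#' Centers each metabolite and divides by its standard deviation
#' (denominator n-1), estimated over `sample_subset` (default: all
#' samples) but applied to every sample, so held-out samples can be
#' projected with the training parameters. Autoscaling puts all
#' metabolites on a common scale so that multivariate models cannot be
#' dominated by a few high-variance metabolites.
#'
#' @param p a `processed_matrix` from [log10_transform()].
#' @param sample_subset logical or integer selector of the rows used to
#'   estimate center and scale; default all rows.
#' @return The `processed_matrix` with `scaled_values`, `scale_center`
#'   and `scale_sd` filled in and provenance appended.
#' @export
autoscale <- function(p, sample_subset = NULL) {
  stopifnot(inherits(p, "processed_matrix"))
  X <- p$log_values
  if (is.null(sample_subset)) sample_subset <- seq_len(nrow(X))
  Xs <- X[sample_subset, , drop = FALSE]
  if (nrow(Xs) < 2L) stop("need at least 2 samples to autoscale")
  ctr <- colMeans(Xs)
  sdv <- apply(Xs, 2L, stats::sd)   # n-1 denominator
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad))
    stop("zero variance over the scaling subset for metabolite(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  p$scaled_values <- scale_project(X, ctr, sdv)
  p$scale_center <- ctr
  p$scale_sd <- sdv
  p$provenance <- c(p$provenance, "autoscaled")
  p
}

#' Project data through stored autoscaling parameters
#'
#' @param X samples x metabolites matrix on the log10 scale.
#' @param center,scale per-metabolite parameters from [autoscale()].
#' @return The scaled matrix `(X - center) / scale`.
#' @export
scale_project <- function(X, center, scale) {
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

#' Write transform provenance to a sidecar text file
#'
#' @param p a `processed_matrix` (or `metabolite_matrix` with a
#'   provenance attribute).
#' @param path output path (JSON).
#' @export
write_provenance <- function(p, path) {
  prov <- if (inherits(p, "processed_matrix")) p$provenance
          else attr(p, "provenance")
  writeLines(paste0('{"provenance": [',
                    paste(sprintf('"%s"', prov), collapse = ", "), ']}'),
             path)
  invisible(path)
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat("processed_matrix:", nrow(x$log_values), "samples x",
      ncol(x$log_values), "metabolites; transforms:",
      paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}
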