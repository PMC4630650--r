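#' Split autoscaled data into one table per subject
#'
#' Each subject contributes a time points x metabolites table (rows in
#' chronological slot order). All tables share metabolite column order,
#' which is what lets STATIS compare subjects through their time-point
#' cross-product structure.
#'
#' @param p a `processed_matrix` that has been through [autoscale()].
#' @param design a [study_design()] giving the chronological slot order.
#' @return Named list of matrices (one per subject, names = subject ids),
#'   each `n_slots x n_metabolites` with slot rownames.
#' @export
build_subject_tables <- function(p, design = study_design()) {
  stopifnot(inherits(p, "processed_matrix"))
  if (is.null(p$scaled_values))
    stop("autoscale() the data before building subject tables")
  meta <- p$sample_meta
  keep <- !meta$is_pool_reference
  meta <- meta[keep, , drop = FALSE]
  X <- p$scaled_values[keep, , drop = FALSE]
  slots <- design$slots$slot
  subjects <- sort(unique(meta$subject_id))
  out <- lapply(subjects, function(s) {
    idx <- match(slots, meta$slot[meta$subject_id == s])
    if (anyNA(idx))
      stop("subject ", s, " is missing slot(s): ",
           paste(slots[is.na(idx)], collapse = ", "))
    rows <- which(meta$subject_id == s)[idx]
    tab <- X[rows, , drop = FALSE]
    rownames(tab) <- slots
    tab
  })
  names(out) <- subjects
  out
}

#' Time-point cross-product matrix of one subject table
#'
#' \eqn{W_k = X_k X_k^\top / M} with M the metabolite count: entry (s, t)
#' is the average over metabolites of the product of the profiles at
#' slots s and t, i.e. how similar the subject's metabolic state at the
#' two time points is. Symmetric positive semi-definite by construction.
#'
#' @param tab a time points x metabolites matrix (one element of
#'   [build_subject_tables()]).
#' @return A `n_slots x n_slots` matrix.
#' @export
crossproduct_matrix <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L) stop("table needs >= 2 time points")
  tcrossprod(tab) / ncol(tab)
}

#' RV-coefficient interstructure matrix
#'
#' The RV coefficient between two cross-product matrices is their
#' Frobenius inner product normalized by the Frobenius norms,
#' \eqn{RV(W_i, W_j) = \langle W_i, W_j\rangle_F /
#' (\|W_i\|_F \|W_j\|_F)} — the matrix analogue of a squared
#' correlation, in \[0, 1\] for positive semi-definite inputs.
#'
#' @param Ws list of equal-shaped cross-product matrices.
#' @return Symmetric K x K matrix with unit diagonal.
#' @export
rv_matrix <- function(Ws) {
  K <- length(Ws)
  dims <- vapply(Ws, dim, integer(2L))
  if (any(dims != dims[, 1L])) stop("all cross-product matrices must share shape")
  nrms <- vapply(Ws, function(W) sqrt(sum(W * W)), 0)
  if (any(nrms == 0))
    stop("zero-norm cross-product matrix at position ",
         paste(which(nrms == 0), collapse = ", "))
  C <- diag(1, K)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    C[i, j] <- C[j, i] <- sum(Ws[[i]] * Ws[[j]]) / (nrms[i] * nrms[j])
  }
  dimnames(C) <- list(names(Ws), names(Ws))
  C
}

#' STATIS table weights from the interstructure
#'
#' The weights are the components of the first eigenvector of the RV
#' matrix, sign-fixed non-negative and of unit Euclidean norm. Subjects
#' whose cross-product structure resembles everyone else's get higher
#' weight; outlying subjects are down-weighted. With K identical tables
#' every weight is 1/sqrt(K) (0.224 at K = 20).
#'
#' @param C symmetric non-negative similarity matrix from [rv_matrix()].
#' @return Named numeric vector of K non-negative weights, unit L2 norm.
#' @export
statis_weights <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-10)) stop("C must be symmetric")
  if (any(C < -1e-10)) stop("C must be non-negative")
  e <- eigen(C, symmetric = TRUE)
  a <- e$vectors[, 1L]
  if (sum(a) < 0) a <- -a
  # Perron-Frobenius: leading eigenvector of a non-negative matrix is
  # non-negative; clip the roundoff
  a[a < 0 & a > -1e-10] <- 0
  if (any(a < 0)) stop("leading eigenvector has negative components")
  a <- a / sqrt(sum(a^2))
  names(a) <- colnames(C)
  a
}

#' Compromise matrix and its eigendecomposition
#'
#' The compromise \eqn{W = \sum_k \alpha_k W_k} is the weighted average
#' of the per-subject cross-product matrices — the consensus time-point
#' similarity structure. Its eigendecomposition plays the role of a PCA:
#' eigenvalues sorted descending (tiny negatives clipped to zero),
#' time-point scores \eqn{U\,\mathrm{diag}(\sqrt\lambda)}, explained
#' variance \eqn{\lambda_a / \sum\lambda}. Each eigenvector's
#' largest-magnitude entry is made positive for deterministic output.
#'
#' @param Ws list of cross-product matrices.
#' @param alpha weights from [statis_weights()].
#' @return List: `W`, `eigenvalues`, `eigenvectors`, `timepoint_scores`,
#'   `explained_variance`.
#' @export
compromise_eigen <- function(Ws, alpha) {
  stopifnot(length(Ws) == length(alpha))
  W <- Reduce(`+`, Map(`*`, Ws, alpha))
  e <- eigen(W, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-8 * max(lam)))
    stop("compromise is not positive semi-definite (min eigenvalue ",
         format(min(lam)), ")")
  lam[lam < 0] <- 0
  U <- e$vectors
  for (a in seq_len(ncol(U))) {
    i <- which.max(abs(U[, a]))
    if (U[i, a] < 0) U[, a] <- -U[, a]
  }
  rownames(U) <- rownames(W)
  scores <- U %*% diag(sqrt(lam), nrow = length(lam))
  dimnames(scores) <- list(rownames(W), paste0("axis", seq_along(lam)))
  list(W = W, eigenvalues = lam, eigenvectors = U,
       timepoint_scores = scores,
       explained_variance = lam / sum(lam))
}

#' Project each subject's table onto the compromise axes
#'
#' Subject k's trajectory on axis a is \eqn{W_k u_a / \sqrt{\lambda_a}};
#' the alpha-weighted average of all trajectories reproduces the
#' compromise time-point scores exactly.
#'
#' @param Ws list of cross-product matrices.
#' @param model a fitted [statis()] model (or [compromise_eigen()]
#'   output).
#' @param axes axes to project on (default first two).
#' @return Named list (per subject) of `n_slots x length(axes)` score
#'   matrices.
#' @export
project_tables <- function(Ws, model, axes = 1:2) {
  lam <- model$eigenvalues
  if (any(lam[axes] <= 0))
    stop("cannot project on zero-variance axis ",
         paste(axes[lam[axes] <= 0], collapse = ", "))
  U <- model$eigenvectors
  lapply(Ws, function(Wk) {
    out <- vapply(axes, function(a) as.vector(Wk %*% U[, a] / sqrt(lam[a])),
                  numeric(nrow(Wk)))
    out <- matrix(out, nrow(Wk), length(axes))
    dimnames(out) <- list(rownames(Wk), paste0("axis", axes))
    out
  })
}

#' Metabolite loadings on the compromise axes
#'
#' The alpha-weighted average table \eqn{\bar X = \sum_k \alpha_k X_k}
#' is projected: loading of metabolite m on axis a is column m of
#' \eqn{\bar X^\top u_a / \sqrt{\lambda_a}}. Metabolites that are flat in
#' time for every subject load near zero everywhere.
#'
#' @param tables subject tables from [build_subject_tables()].
#' @param model a fitted [statis()] model.
#' @param axes axes to report (default first two).
#' @return metabolites x axes matrix.
#' @export
metabolite_loadings <- function(tables, model, axes = 1:2) {
  lam <- model$eigenvalues
  if (any(lam[axes] <= 0))
    stop("cannot project on zero-variance axis ",
         paste(axes[lam[axes] <= 0], collapse = ", "))
  Xbar <- Reduce(`+`, Map(`*`, tables, model$weights))
  out <- vapply(axes, function(a)
    as.vector(crossprod(Xbar, model$eigenvectors[, a]) / sqrt(lam[a])),
    numeric(ncol(Xbar)))
  out <- matrix(out, ncol(Xbar), length(axes))
  dimnames(out) <- list(colnames(Xbar), paste0("axis", axes))
  out
}

#' STATIS multi-table ordination of a time-course cohort
#'
#' Full STATIS analysis: one time points x metabolites table per subject
#' (autoscaled data), per-subject cross-product matrices, RV-coefficient
#' interstructure, leading-eigenvector subject weights, weighted
#' compromise, eigendecomposition, and projection of time points,
#' subject trajectories and metabolites. The result resembles a PCA
#' score plot of the consensus time course with between-subject
#' variability averaged out — useful when inter-individual differences
#' dominate the first components of an ordinary PCA.
#'
#' @param p a `processed_matrix` through [autoscale()].
#' @param design a [study_design()].
#' @param axes axes for trajectories and loadings (default 1:2).
#' @return A `statis_model`: list with `tables`, `crossproducts`,
#'   `rv` (interstructure), `weights`, `W` (compromise), `eigenvalues`,
#'   `eigenvectors`, `timepoint_scores`, `explained_variance`,
#'   `trajectories`, `loadings`.
#' @export
statis <- function(p, design = study_design(), axes = 1:2) {
  tables <- build_subject_tables(p, design)
  Ws <- lapply(tables, crossproduct_matrix)
  C <- rv_matrix(Ws)
  alpha <- statis_weights(C)
  ce <- compromise_eigen(Ws, alpha)
  model <- c(list(tables = tables, crossproducts = Ws, rv = C,
                  weights = alpha), ce)
  class(model) <- "statis_model"
  model$trajectories <- project_tables(Ws, model, axes)
  model$loadings <- metabolite_loadings(tables, model, axes)
  model
}

#' @export
print.statis_model <- function(x, ...) {
  cat("statis_model:", length(x$tables), "subject tables,",
      nrow(x$W), "time points\n")
  cat("  weights:", paste(format(range(x$weights), digits = 3),
                          collapse = " - "),
      "(equal-weight value", format(1 / sqrt(length(x$weights)),
                                    digits = 3), ")\n")
  ev <- x$explained_variance[1:2] * 100
  cat("  explained variance: axis1", sprintf("%.1f%%", ev[1]),
      "axis2", sprintf("%.1f%%", ev[2]), "\n")
  invisible(x)
}

#' Write STATIS outputs as tidy CSVs
#'
#' Writes weights, time-point scores, subject trajectories, metabolite
#' loadings and explained variance.
#'
#' @param model a `statis_model`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_statis_csv <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("statis_weights.csv", "statis_scores.csv",
                            "statis_trajectories.csv",
                            "statis_loadings.csv",
                            "statis_explained_variance.csv"))
  utils::write.csv(data.frame(subject = names(model$weights),
                              weight = unname(model$weights)),
                   paths[1], row.names = FALSE)
  sc <- model$timepoint_scores
  utils::write.csv(data.frame(slot = rownames(sc)[row(sc)],
                              axis = colnames(sc)[col(sc)],
                              value = as.vector(sc)),
                   paths[2], row.names = FALSE)
  tr <- do.call(rbind, lapply(names(model$trajectories), function(s) {
    m <- model$trajectories[[s]]
    data.frame(subject = s, slot = rownames(m)[row(m)],
               axis = colnames(m)[col(m)], value = as.vector(m))
  }))
  utils::write.csv(tr, paths[3], row.names = FALSE)
  ld <- model$loadings
  utils::write.csv(data.frame(metabolite = rownames(ld)[row(ld)],
                              axis = colnames(ld)[col(ld)],
                              value = as.vector(ld)),
                   paths[4], row.names = FALSE)
  utils::write.csv(data.frame(axis = seq_along(model$eigenvalues),
                              eigenvalue = model$eigenvalues,
                              explained = model$explained_variance),
                   paths[5], row.names = FALSE)
  invisible(paths)
}
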