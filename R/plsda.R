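#' Two-class PLS-DA via NIPALS
#'
#' Partial least squares regression of a centered 0/1 class indicator on
#' autoscaled metabolite data (PLS1 regression mode, NIPALS). Per
#' component a: weight \eqn{w_a = E^\top f / \|E^\top f\|}, score
#' \eqn{t_a = E w_a}, X loading \eqn{p_a = E^\top t_a / t_a^\top t_a},
#' y loading \eqn{q_a = f^\top t_a / t_a^\top t_a}, then deflation of
#' both E and f. Deterministic: PLS1 needs no iteration.
#'
#' @param X samples x metabolites matrix (autoscaled).
#' @param y class labels (two levels; factor, logical or 0/1).
#' @param n_components number of latent components.
#' @return A `plsda_model`: scores `T`, weights `W`, X loadings `P`,
#'   y loadings `q`, `y_mean`, class `levels`, `r2y` (per-component
#'   fraction of y variance explained), `residual_ss` (y residual sum of
#'   squares after 0..A components), `n_components`.
#' @export
fit_plsda <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  enc <- encode_classes(y)
  if (nrow(X) != length(enc$y)) stop("X rows and labels differ in length")
  y0 <- enc$y
  y_mean <- mean(y0)
  f <- y0 - y_mean
  ss0 <- sum(f^2)
  if (ss0 == 0) stop("single-class input: y has no variance")
  A <- as.integer(n_components)
  if (A < 1L) stop("n_components must be >= 1")
  n <- nrow(X); p <- ncol(X)
  E <- X
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  qv <- r2y <- numeric(A)
  resid_ss <- numeric(A + 1L); resid_ss[1L] <- ss0
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      A <- a - 1L
      warning("y residual orthogonal to X after ", A,
              " components; truncating")
      break
    }
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    qv[a] <- q_a
    r2y[a] <- q_a^2 * tt / ss0
    resid_ss[a + 1L] <- sum(f^2)
  }
  structure(list(W = W[, seq_len(A), drop = FALSE],
                 P = P[, seq_len(A), drop = FALSE],
                 T = Tm[, seq_len(A), drop = FALSE],
                 q = qv[seq_len(A)],
                 y_mean = y_mean, levels = enc$levels,
                 r2y = r2y[seq_len(A)],
                 residual_ss = resid_ss[seq_len(A + 1L)],
                 n_components = A),
            class = "plsda_model")
}

encode_classes <- function(y) {
  if (is.factor(y) || is.character(y) || is.logical(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L)
      stop("need exactly 2 classes, got ", nlevels(y))
    list(y = as.numeric(y) - 1, levels = levels(y))
  } else {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1)) || length(u) != 2L)
      stop("numeric labels must be 0/1 with both classes present")
    list(y = as.numeric(y), levels = c("0", "1"))
  }
}

#' Predict class scores from a PLS-DA model
#'
#' Regression coefficients for the first a components are
#' \eqn{B_a = W_a (P_a^\top W_a)^{-1} q_a}; the continuous score is
#' \eqn{\hat y = \bar y + X_{new} B_a} and the class call thresholds it
#' at the midpoint (0.5) of the 0/1 encoding.
#'
#' @param object a `plsda_model`.
#' @param newdata samples x metabolites matrix on the same (autoscaled)
#'   scale as the training data.
#' @param n_components components to use (default: all fitted).
#' @param ... unused.
#' @return Data frame with `score` (continuous predicted indicator) and
#'   `class` (predicted label).
#' @export
predict.plsda_model <- function(object, newdata,
                                n_components = object$n_components, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W))
    stop("newdata has ", ncol(newdata), " columns, model expects ",
         nrow(object$W))
  a <- as.integer(n_components)
  stopifnot(a >= 1L, a <= object$n_components)
  Wa <- object$W[, seq_len(a), drop = FALSE]
  Pa <- object$P[, seq_len(a), drop = FALSE]
  B <- Wa %*% solve(crossprod(Pa, Wa), object$q[seq_len(a)])
  score <- as.vector(object$y_mean + newdata %*% B)
  data.frame(score = score,
             class = object$levels[1L + (score >= 0.5)],
             stringsAsFactors = FALSE)
}

#' Leave-one-subject-out cross-validated Q2
#'
#' All samples of one subject are held out together (repeated measures
#' of one individual are not independent, so sample-wise CV would leak).
#' For each fold the model is refit on the remaining subjects and the
#' held-out samples predicted with 1..A components. Per component
#' \eqn{Q^2_a = 1 - PRESS_a / SS_{a-1}} with \eqn{SS_{a-1}} the y
#' residual sum of squares after a-1 components of the all-data fit, and
#' cumulatively \eqn{Q^2_{cum}(A) = 1 - \prod_{a \le A} PRESS_a /
#' SS_{a-1}} (the convention of mainstream chemometrics software). The
#' plain \eqn{1 - PRESS_A / SS_0} is also reported.
#'
#' @param X samples x metabolites matrix (autoscaled).
#' @param y class labels (two levels).
#' @param subject_ids per-sample subject identifiers defining the folds.
#' @param n_components number of components.
#' @return List: `q2_per_component`, `q2_cum`, `q2_simple`, `press`,
#'   `ss` (SS_0 .. SS_{A-1}), `n_folds_used`.
#' @export
q2_loso <- function(X, y, subject_ids, n_components = 2L) {
  X <- as.matrix(X)
  enc <- encode_classes(y)
  subjects <- unique(subject_ids)
  if (length(subjects) < 3L) stop("need >= 3 subjects for LOSO CV")
  A <- as.integer(n_components)
  full <- fit_plsda(X, y, A)
  if (full$n_components < A)
    stop("data supports only ", full$n_components, " components")
  ss <- full$residual_ss[seq_len(A)]   # SS_0 .. SS_{A-1}
  press <- numeric(A)
  used <- 0L
  for (s in subjects) {
    test <- subject_ids == s
    if (length(unique(enc$y[!test])) < 2L) {
      warning("fold ", s, " skipped: training set single-class")
      next
    }
    fit <- fit_plsda(X[!test, , drop = FALSE], enc$y[!test], A)
    if (fit$n_components < A) {
      warning("fold ", s, " skipped: only ", fit$n_components,
              " components supported")
      next
    }
    for (a in seq_len(A)) {
      pred <- predict(fit, X[test, , drop = FALSE], n_components = a)
      press[a] <- press[a] + sum((enc$y[test] - pred$score)^2)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("all LOSO folds were skipped")
  ratio <- press / ss
  list(q2_per_component = 1 - ratio,
       q2_cum = 1 - cumprod(ratio),
       q2_simple = 1 - press / ss[1L],
       press = press, ss = ss, n_folds_used = used)
}

#' Fit PLS-DA of treated vs untreated and report Q2
#'
#' Convenience wrapper for a processed cohort: classes are the treated
#' flag, folds are subjects.
#'
#' @param p a `processed_matrix` through [autoscale()].
#' @param n_components number of components (default 2).
#' @return List with the fitted `model` and the [q2_loso()] `cv` output.
#' @export
plsda_treated <- function(p, n_components = 2L) {
  stopifnot(inherits(p, "processed_matrix"))
  if (is.null(p$scaled_values)) stop("autoscale() the data first")
  keep <- !p$sample_meta$is_pool_reference
  X <- p$scaled_values[keep, , drop = FALSE]
  y <- factor(ifelse(p$sample_meta$treated[keep], "treated", "untreated"),
              levels = c("untreated", "treated"))
  list(model = fit_plsda(X, y, n_components),
       cv = q2_loso(X, y, p$sample_meta$subject_id[keep], n_components))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("plsda_model:", x$n_components, "components, classes",
      paste(x$levels, collapse = " vs "), "\n")
  cat("  R2Y per component:",
      paste(sprintf("%.3f", x$r2y), collapse = ", "), "\n")
  invisible(x)
}
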