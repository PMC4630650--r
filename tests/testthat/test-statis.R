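test_that("subject tables have shared shape and chronological rows", {
  p <- tiny_processed(tiny_spec(n_subjects = 5, n_metabolites = 7))
  tabs <- build_subject_tables(p)
  expect_length(tabs, 5)
  for (tab in tabs) {
    expect_equal(dim(tab), c(11, 7))
    expect_equal(rownames(tab), study_design()$slots$slot)
  }
  # missing slot is refused with subject and slot named
  p2 <- p
  drop <- which(p2$sample_meta$subject_id == "s02" &
                  p2$sample_meta$slot == "d4_midday")
  p2$scaled_values <- p2$scaled_values[-drop, ]
  p2$sample_meta <- p2$sample_meta[-drop, ]
  expect_error(build_subject_tables(p2), "s02.*d4_midday")
})

test_that("cross-product matrix matches hand computation", {
  X <- rbind(c(1, 0), c(1, 0))
  expect_equal(crossproduct_matrix(X), matrix(0.5, 2, 2))
  # orthogonal rows of squared norm M give the identity
  Xo <- rbind(c(sqrt(2), 0), c(0, sqrt(2)))
  expect_equal(crossproduct_matrix(Xo), diag(2))
  # duplicated rows duplicate the corresponding rows/columns
  set.seed(12)
  Xd <- matrix(rnorm(12), 3, 4); Xd[3, ] <- Xd[1, ]
  W <- crossproduct_matrix(Xd)
  expect_equal(W[1, ], W[3, ])
  expect_equal(W, t(W))
})

test_that("RV matrix is a unit-diagonal normalized inner product", {
  W1 <- diag(2); W2 <- matrix(c(1, 0, 0, 0), 2, 2)
  C <- rv_matrix(list(W1, W2))
  expect_equal(diag(C), c(1, 1))
  expect_equal(C[1, 2], 1 / sqrt(2))
  # orthogonal matrices have RV zero
  W3 <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(rv_matrix(list(W2, W3))[1, 2], 0)
  expect_error(rv_matrix(list(W1, matrix(0, 2, 2))), "zero-norm")
})

test_that("identical tables give equal weights 1/sqrt(K)", {
  set.seed(13)
  X <- matrix(rnorm(33), 11, 3)
  W <- crossproduct_matrix(X)
  for (K in c(2, 4, 20)) {
    a <- statis_weights(rv_matrix(rep(list(W), K)))
    expect_equal(unname(a), rep(1 / sqrt(K), K), tolerance = 1e-10)
  }
  # K = 2 with any off-diagonal r has eigenvector (1,1)/sqrt(2)
  for (r in c(0.1, 0.5, 0.9)) {
    C <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(unname(statis_weights(C)), rep(1 / sqrt(2), 2))
  }
  expect_error(statis_weights(matrix(c(1, 0.5, 0.2, 1), 2, 2)),
               "symmetric")
})

test_that("compromise eigensystem matches a brute-force small oracle", {
  # 3x3 PSD matrix with known characteristic polynomial roots
  A <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 1))
  ce <- compromise_eigen(list(A), 1)
  expect_equal(ce$eigenvalues, c(3, 1, 1))
  expect_equal(sum(ce$eigenvalues), sum(diag(A)))
  # eigen equation holds for every pair
  for (a in 1:3)
    expect_equal(as.vector(A %*% ce$eigenvectors[, a]),
                 ce$eigenvalues[a] * ce$eigenvectors[, a])
  # scores have squared column norms equal to the eigenvalues
  expect_equal(colSums(ce$timepoint_scores^2), ce$eigenvalues,
               ignore_attr = TRUE)
  expect_error(compromise_eigen(list(-diag(3)), 1), "semi-definite")
})

test_that("eigenvalue sum equals the trace on real cohorts", {
  p <- tiny_processed(tiny_spec(n_subjects = 6, n_metabolites = 15))
  sm <- statis(p)
  expect_equal(sum(sm$eigenvalues), sum(diag(sm$W)),
               tolerance = 1e-8)
  expect_equal(sum(sm$explained_variance), 1)
  expect_equal(dim(sm$W), c(11, 11))
})

test_that("K = 1 STATIS reduces to PCA of the single cross-product", {
  spec <- tiny_spec(n_subjects = 1, n_metabolites = 9, seed = 14)
  p <- tiny_processed(spec)
  sm <- statis(p)
  expect_equal(unname(sm$weights), 1)
  W1 <- crossproduct_matrix(build_subject_tables(p)[[1]])
  e <- eigen(W1, symmetric = TRUE)
  expect_equal(sm$eigenvalues, pmax(e$values, 0), tolerance = 1e-10)
  # scores match up to sign
  sc_pca <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  for (a in 1:3)
    expect_equal(abs(sm$timepoint_scores[, a]), abs(sc_pca[, a]),
                 ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("weighted mean of subject trajectories is the compromise", {
  p <- tiny_processed(tiny_spec(n_subjects = 8, n_metabolites = 12,
                                seed = 15))
  sm <- statis(p, axes = 1:3)
  tr <- project_tables(sm$crossproducts, sm, axes = 1:3)
  wmean <- Reduce(`+`, Map(`*`, tr, sm$weights))
  expect_equal(wmean, sm$timepoint_scores[, 1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  # identical tables: all trajectories coincide, and under the unit-norm
  # weight convention (sum(alpha) = sqrt(K)) each equals the compromise
  # scores divided by sqrt(K)
  W <- crossproduct_matrix(build_subject_tables(p)[[1]])
  Ws <- rep(list(W), 4)
  a <- statis_weights(rv_matrix(Ws))
  ce <- compromise_eigen(Ws, a)
  ce$weights <- a
  tr2 <- project_tables(Ws, ce, axes = 1:2)
  expect_equal(tr2[[1]], tr2[[2]])
  expect_equal(tr2[[1]], tr2[[4]])
  for (t2 in tr2)
    expect_equal(t2 * sqrt(4), ce$timepoint_scores[, 1:2],
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("subject permutation permutes weights identically", {
  p <- tiny_processed(tiny_spec(n_subjects = 6, n_metabolites = 10,
                                seed = 16))
  Ws <- lapply(build_subject_tables(p), crossproduct_matrix)
  a1 <- statis_weights(rv_matrix(Ws))
  perm <- c(4, 1, 6, 2, 5, 3)
  a2 <- statis_weights(rv_matrix(Ws[perm]))
  expect_equal(unname(a2), unname(a1[perm]), tolerance = 1e-10)
})

test_that("a noise-replaced subject loses weight", {
  spec <- cohort_spec(n_subjects = 8, n_metabolites = 30,
                      subject_sd = 0.05, noise_sd = 0.05,
                      circadian_profile = matrix(0.15, 30, 2),
                      n_pool_replicates = 5, seed = 17)
  p <- tiny_processed(spec)
  Ws <- lapply(build_subject_tables(p), crossproduct_matrix)
  a_before <- statis_weights(rv_matrix(Ws))
  set.seed(1)
  Ws[[3]] <- crossproduct_matrix(matrix(rnorm(11 * 30), 11, 30))
  a_after <- statis_weights(rv_matrix(Ws))
  expect_lt(a_after[3], a_before[3])
  expect_lt(a_after[3], min(a_after[-3]))
})

test_that("flat metabolites load near zero; effect metabolites separate", {
  treat <- matrix(0, 20, 4); treat[1:5, ] <- 0.5
  spec <- cohort_spec(n_subjects = 10, n_metabolites = 20,
                      subject_sd = 0.02, noise_sd = 0.02,
                      treatment_profile = treat,
                      n_pool_replicates = 5, seed = 18)
  p <- tiny_processed(spec)
  sm <- statis(p)
  strength <- sqrt(rowSums(sm$loadings^2))
  # every planted-effect metabolite outranks every null metabolite
  expect_gt(min(strength[1:5]), max(strength[6:20]))
})

test_that("post-dose shift separates treated from untreated slots", {
  skip_if_not_installed("cluster")
  spec <- study_cohort_spec(seed = 2)
  p <- tiny_processed(spec)
  sm <- statis(p)
  sc <- sm$timepoint_scores[, 1:2]
  treated <- study_design()$slots$treated
  sil <- cluster::silhouette(as.integer(treated) + 1L, dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
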