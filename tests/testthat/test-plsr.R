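test_that("PLSR recovers a rank-1 planted coupling", {
  set.seed(1)
  s <- rnorm(60)
  u <- runif(25); u <- u / sqrt(sum(u^2))
  v <- rnorm(80); v <- v / sqrt(sum(v^2))
  atrophy <- outer(s, u) + 0.01 * matrix(rnorm(60 * 25), 60)
  fc <- outer(s, v) + 0.01 * matrix(rnorm(60 * 80), 60)
  fit <- fit_plsr_components(atrophy, fc, 2)
  expect_gt(abs(cor(fit$structure_scores[, 1], s)), 0.99)
  expect_gt(abs(fit$score_correlation[1]), 0.99)
  expect_gt(fit$atrophy_variance_explained[1], 0.9)
})

test_that("component 1 tracks overall mean atrophy in a severity cohort", {
  sf <- make_sf_cohort(n_subjects = 120, n_regions = 40, seed = 4)
  fit <- fit_plsr_components(sf$atrophy, sf$fc_edges, 3)
  expect_gt(abs(cor(fit$structure_scores[, 1], rowMeans(sf$atrophy))), 0.99)
  expect_gt(abs(cor(fit$structure_scores[, 1], sf$truths$factors[, 1])), 0.95)
})

test_that("permuting FC rows destroys the score correlation", {
  set.seed(2)
  sf <- make_sf_cohort(n_subjects = 100, n_regions = 30, seed = 5)
  r_perm <- replicate(10, {
    fit <- fit_plsr_components(sf$atrophy,
                               sf$fc_edges[sample(nrow(sf$fc_edges)), ], 1)
    fit$score_correlation[1]
  })
  fit0 <- fit_plsr_components(sf$atrophy, sf$fc_edges, 1)
  expect_lt(median(abs(r_perm)), 0.35)
  expect_gt(abs(fit0$score_correlation[1]), median(abs(r_perm)) + 0.2)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  sf <- make_sf_cohort(n_subjects = 40, n_regions = 12, seed = 6)
  fit <- fit_plsr_components(sf$atrophy, sf$fc_edges, 2)
  ref <- mixOmics::pls(sf$atrophy, sf$fc_edges, ncomp = 2, scale = FALSE,
                       mode = "regression")
  for (c in 1:2) {
    expect_gt(abs(cor(fit$structure_scores[, c],
                      ref$variates$X[, c])), 0.999)
  }
})

test_that("PLSR validates its preconditions", {
  set.seed(7)
  x <- matrix(rnorm(20 * 5), 20)
  y <- matrix(rnorm(20 * 8), 20)
  expect_error(fit_plsr_components(x, y[1:10, ], 2), "same subjects")
  expect_error(fit_plsr_components(x, y, 25), "< number of subjects")
  xr1 <- outer(rnorm(20), rnorm(5))  # rank 1
  expect_error(fit_plsr_components(xr1, y, 3), "rank")
})

test_that("split-half reliability separates planted from noise components", {
  sf <- make_sf_cohort(n_subjects = 160, n_regions = 50, seed = 8)
  rel <- split_half_reliability(sf$atrophy, sf$fc_edges, sf$labels,
                                n_components = 4, n_splits = 30, seed = 1)
  expect_gt(min(rel$median_r[1:3]), 0.9)
  expect_lt(rel$median_r[4], min(rel$median_r[1:3]) - 0.1)
  ## pure-noise cohort: reliability collapses toward the null
  set.seed(9)
  noise_rel <- split_half_reliability(matrix(rnorm(160 * 50), 160),
                                      matrix(rnorm(160 * 100), 160),
                                      sf$labels, n_components = 3,
                                      n_splits = 10, seed = 2)
  expect_lt(median(noise_rel$correlations[, 1]), 0.6)
  ## determinism
  r1 <- split_half_reliability(sf$atrophy, sf$fc_edges, sf$labels, 2,
                               n_splits = 1, seed = 3)
  r2 <- split_half_reliability(sf$atrophy, sf$fc_edges, sf$labels, 2,
                               n_splits = 1, seed = 3)
  expect_identical(r1$correlations, r2$correlations)
  ## singleton label refused
  bad_labels <- sf$labels; bad_labels[1] <- "AD"
  lab1 <- factor(c("solo", as.character(sf$labels[-1])))
  expect_error(split_half_reliability(sf$atrophy, sf$fc_edges, lab1, 2,
                                      n_splits = 1), "at least 2 members")
})

test_that("atrophy PCA matches PLSR structure and reconstructs at full rank", {
  sf <- make_sf_cohort(n_subjects = 120, n_regions = 30, seed = 10)
  plsr <- fit_plsr_components(sf$atrophy, sf$fc_edges, 3)
  pca <- atrophy_pca_scores(sf$atrophy, 3)
  for (c in 1:3)
    expect_gt(abs(cor(pca$loadings[, c], plsr$structure_loadings[, c])), 0.95)
  ## orthogonal planted patterns with distinct variances come out in order
  set.seed(11)
  pat <- qr.Q(qr(matrix(rnorm(20 * 2), 20)))
  scores <- cbind(rnorm(100, sd = 3), rnorm(100, sd = 1))
  x <- scores %*% t(pat)
  rec <- atrophy_pca_scores(x, 2)
  expect_gt(abs(cor(rec$scores[, 1], scores[, 1])), 0.99)
  expect_gt(abs(cor(rec$scores[, 2], scores[, 2])), 0.99)
  ## full-rank round trip
  full <- atrophy_pca_scores(x, 20)
  back <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(back - scale(x, scale = FALSE))), 1e-10)
})

test_that("ridge function scores recover planted coupling out of fold", {
  sf <- make_sf_cohort(n_subjects = 200, n_regions = 40, sf_r = 0.6,
                       seed = 12)
  pca <- atrophy_pca_scores(sf$atrophy, 2)
  rr <- ridge_function_scores(pca$scores, sf$fc_edges, sf$labels,
                              alpha = 1000, n_trials = 5, seed = 1)
  expect_equal(median(rr$fold_r[, , 1]), 0.6, tolerance = 0.15)
  expect_gt(cor(rr$function_scores[, 1], pca$scores[, 1]), 0.4)
  ## null cohort: out-of-fold correlation centres on zero (no leakage)
  set.seed(13)
  null_edges <- matrix(rnorm(200 * nrow(sf$truths$edge_loadings)), 200)
  rr0 <- ridge_function_scores(pca$scores, null_edges, sf$labels,
                               alpha = 1000, n_trials = 5, seed = 1)
  expect_lt(abs(median(rr0$fold_r[, , 1])), 0.12)
  ## stratification guard
  few <- factor(c("rare", as.character(sf$labels[-1])))
  expect_error(ridge_function_scores(pca$scores, sf$fc_edges, few,
                                     n_trials = 1), "n_folds members")
})

test_that("FC reconstruction from components is linear", {
  set.seed(14)
  loadings <- matrix(rnorm(45 * 3), 45)
  expect_equal(reconstruct_fc_from_components(c(0, 0, 0), loadings),
               rep(0, 45))
  expect_equal(reconstruct_fc_from_components(c(0, 1, 0), loadings),
               loadings[, 2])
  ## rank-3 planted group means are recovered
  sf <- make_sf_cohort(n_subjects = 150, n_regions = 30, sf_r = 0.95,
                       edge_noise_sd = 0.1, seed = 15)
  fit <- fit_plsr_components(sf$atrophy, sf$fc_edges, 3)
  grp <- sf$labels == "AD"
  actual_diff <- colMeans(sf$fc_edges[grp, ]) - colMeans(sf$fc_edges)
  rec <- reconstruct_fc_from_components(
    colMeans(fit$function_scores[grp, , drop = FALSE]),
    fit$function_loadings)
  expect_gt(cor(actual_diff, rec), 0.9)
})

test_that("network summary map equals dense row sums", {
  expect_equal(network_summary_map(rep(1, 6)), rep(3, 4))
  v <- rep(0, 6); v[2] <- 5  # edge (1,3) in row-major order for R = 4
  expect_equal(network_summary_map(v), c(5, 0, 5, 0))
  set.seed(16)
  m <- matrix(rnorm(100), 10); m <- m + t(m); diag(m) <- 0
  expect_lt(max(abs(network_summary_map(edge_vector(m)) - rowSums(m))), 1e-12)
})

test_that("MDS embedding preserves what it can", {
  set.seed(17)
  flat <- cbind(rnorm(30), rnorm(30), 1)
  emb <- mds_embed(flat)
  expect_lt(max(abs(dist(emb) - dist(flat))), 1e-8)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  emb3 <- mds_embed(tri)
  expect_equal(max(dist(emb3)), min(dist(emb3)), tolerance = 1e-8)
  cloud <- matrix(rnorm(120), 40)
  expect_gt(attr(mds_embed(cloud), "distance_correlation"), 0.8)
  expect_error(mds_embed(matrix(1, 5, 3)), "degenerate")
})

test_that("LDA typicality flags separate and null cases correctly", {
  set.seed(18)
  x <- rbind(matrix(rnorm(60, mean = 0), 20),
             matrix(rnorm(60, mean = 8), 20))
  labels <- rep(c("a", "b"), each = 20)
  res <- typical_patients_lda(x, labels)
  expect_true(all(res$typical))
  expect_false(attr(res, "regularized"))
  ## identical class distributions: about chance-level flagging
  x0 <- matrix(rnorm(400 * 3), 400)
  lab0 <- rep(c("a", "b"), each = 200)
  res0 <- typical_patients_lda(x0, lab0)
  expect_lt(abs(mean(res0$typical) - 0.5), 0.12)
  ## deterministic
  res2 <- typical_patients_lda(x, labels)
  expect_identical(res$predicted, res2$predicted)
})
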