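test_that("basis fitting recovers coordinate axes for diagonal covariance", {
  set.seed(1)
  x <- sapply(c(4, 2, 1), function(sdv) rnorm(400, sd = sdv))
  b <- fit_gradient_basis(region_timeseries(x), k = 3)
  expect_lt(max(abs(abs(b$eigenvectors) - diag(3))), 0.06)
  expect_true(all(diff(b$explained_variance_fraction) <= 0))
  expect_lt(max(abs(crossprod(b$eigenvectors) - diag(3))), 1e-10)
})

test_that("basis fitting recovers the planted gradient subspace", {
  cfg <- tiny_config(n_subjects = 8, noise_sd = 0.005, n_timepoints = 300)
  coh <- make_cohort(cfg)
  b <- fit_gradient_basis(lapply(coh$subjects, `[[`, "timeseries"),
                          k = cfg$n_gradients)
  ## principal angles between fitted and true subspaces
  sv <- svd(crossprod(cfg$basis$eigenvectors, b$eigenvectors))$d
  max_angle <- max(acos(pmin(sv, 1))) * 180 / pi
  expect_lt(max_angle, 5)
})

test_that("basis fitting validates shapes and region alignment", {
  set.seed(2)
  pool <- list(region_timeseries(matrix(rnorm(150 * 246), 150)),
               region_timeseries(matrix(rnorm(150 * 246), 150)))
  b <- fit_gradient_basis(pool, k = 6)
  expect_equal(dim(b$eigenvectors), c(246, 6))
  bad <- region_timeseries(matrix(rnorm(150 * 246), 150),
                           region_ids = paste0("X", 1:246))
  expect_error(fit_gradient_basis(list(pool[[1]], bad), k = 6),
               "region")
})

test_that("projection is linear, exact at full rank, and alignment-checked", {
  set.seed(3)
  x <- matrix(rnorm(80 * 12), 80)
  ts <- region_timeseries(x)
  b <- fit_gradient_basis(ts, k = 12)
  g <- project_timeseries(ts, b)
  ## zero input
  g0 <- project_timeseries(region_timeseries(matrix(0, 10, 12),
                                             region_ids = b$region_ids), b)
  expect_equal(max(abs(g0$scores)), 0)
  ## single-column broadcast: score 1 carries the centered coefficient
  cc <- sin(seq_len(50))
  ts1 <- region_timeseries(outer(cc, b$eigenvectors[, 1]),
                           region_ids = b$region_ids)
  g1 <- project_timeseries(ts1, b)
  expect_equal(g1$scores[, 1], cc - mean(cc), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(g1$scores[, -1])), 1e-10)
  ## full-rank round trip reproduces the centered data
  back <- g$scores %*% t(b$eigenvectors)
  expect_lt(max(abs(back - scale(x, scale = FALSE))), 1e-10)
  ## projection isometry at full rank
  expect_equal(sum(apply(g$scores, 2, var)),
               sum(apply(x, 2, var)), tolerance = 1e-10)
  expect_error(project_timeseries(matrix(0, 10, 5), b), "mismatch")
})

test_that("gradient covariance matches the textbook estimator", {
  set.seed(4)
  s <- matrix(rnorm(60 * 4), 60)
  expect_lt(max(abs(gradient_covariance(s) - cov(s))), 1e-12)
  two <- cbind(a = s[, 1], b = s[, 1])
  cv <- gradient_covariance(two)
  expect_equal(max(cv), min(cv), tolerance = 1e-12)
  tt <- seq(0, 4 * 2 * pi, length.out = 401)[-401]
  sc <- cbind(sin(tt), cos(tt))
  expect_lt(abs(gradient_covariance(sc)[1, 2]), 1e-3)
  expect_error(gradient_covariance(matrix(1, 1, 2)), "at least 2")
})

test_that("FC from gradient covariance matches direct correlation at full rank", {
  set.seed(5)
  x <- matrix(rnorm(50 * 5), 50)
  ts <- region_timeseries(x)
  b <- fit_gradient_basis(ts, k = 5)
  fc <- fc_from_gradient_covariance(b, gradient_covariance(project_timeseries(ts, b)))
  expect_lt(max(abs(fc - fc_direct(ts))), 1e-10)
  expect_symmetric_unit_diag(fc)
  ## identity covariance through a square orthonormal basis gives identity FC
  fc_id <- fc_from_gradient_covariance(b, diag(5))
  expect_lt(max(abs(fc_id - diag(5))), 1e-10)
  ## K dimension guard
  expect_error(fc_from_gradient_covariance(
    fit_gradient_basis(ts, k = 3), diag(5)), "exceeds")
})

test_that("zero-variance regions are flagged, not silently zeroed", {
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40)
  b <- fit_gradient_basis(region_timeseries(x), k = 4)
  sigma <- matrix(0, 4, 4)  # no variance anywhere
  expect_warning(fc <- fc_from_gradient_covariance(b, sigma), "zero variance")
  expect_true(anyNA(fc))
})

test_that("edge and covariance flattening counts match the atlas sizes", {
  m <- matrix(0, 246, 246)
  expect_length(edge_vector(m), 30135)
  expect_length(flatten_covariance(m), 30381)
  ## row-major order
  m3 <- matrix(1:9, 3, byrow = TRUE)
  expect_equal(edge_vector(m3), c(2, 3, 6))
  expect_equal(flatten_covariance(m3), c(1, 2, 3, 5, 6, 9))
  v <- edge_vector(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
  expect_equal(edges_to_matrix(v, diag_value = 0),
               matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3))
})

test_that("direct FC behaves on perfectly (anti-)correlated pairs", {
  x <- cbind(1:20, 2 * (1:20) + 3, -(1:20))
  fc <- fc_direct(x)
  expect_equal(fc[1, 2], 1, tolerance = 1e-12)
  expect_equal(fc[1, 3], -1, tolerance = 1e-12)
  expect_symmetric_unit_diag(fc)
})

test_that("global signal amplitude follows its analytic identities", {
  x <- sin(seq_len(100))
  expect_equal(global_signal_amplitude(matrix(rep(x, 5), ncol = 5)), sd(x))
  expect_equal(global_signal_amplitude(cbind(x, -x, x, -x)), 0)
  ## unipolar equal-weight basis: amplitude proportional to sqrt(G1 variance)
  set.seed(7)
  amp <- v1 <- numeric(10)
  for (i in 1:10) {
    g1 <- rnorm(120, sd = runif(1, 0.5, 3))
    ts <- outer(g1, rep(1 / sqrt(8), 8))
    amp[i] <- global_signal_amplitude(ts)
    v1[i] <- var(g1)
  }
  expect_equal(cor(amp, sqrt(v1)), 1, tolerance = 1e-10)
})

test_that("variance partition attributes shares correctly", {
  set.seed(8)
  n <- 400
  moments <- matrix(rnorm(n * 21), n)
  colnames(moments) <- paste0("m", 1:21)
  ## response identical to one moment
  vp <- variance_partition(moments[, 3], moments, n_orders = 50, seed = 1)
  expect_gt(vp$shares[3], 0.9)
  expect_lt(max(vp$shares[-3]), 0.05)
  expect_true(all(vp$shares >= 0) && sum(vp$shares) <= 1 + 1e-8)
  ## analytic split under orthogonality: 0.8^2 / 0.6^2
  f <- 0.8 * scale(moments[, 1]) + 0.6 * scale(moments[, 2])
  vp2 <- variance_partition(drop(f), moments, n_orders = 100, seed = 1)
  expect_equal(unname(vp2$shares[1]), 0.64, tolerance = 0.05)
  expect_equal(unname(vp2$shares[2]), 0.36, tolerance = 0.05)
  expect_equal(vp2$r_squared, 1, tolerance = 1e-8)
  ## permutation null: total explained variance near p / (n - 1)
  r2_null <- replicate(30, {
    variance_partition(sample(moments[, 3]), moments, n_orders = 3,
                       seed = 2)$r_squared
  })
  expect_lt(abs(mean(r2_null) - 21 / (n - 1)), 0.015)
  ## collinear moments trigger the recorded fallback
  mom_bad <- cbind(moments[, 1:3], moments[, 3])
  expect_warning(vp3 <- variance_partition(moments[, 1], mom_bad,
                                           n_orders = 10, seed = 1),
                 "collinear")
  expect_true(vp3$ridge_fallback)
})
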