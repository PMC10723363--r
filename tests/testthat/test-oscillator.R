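test_that("finite differences are exact for low-order polynomials", {
  tt <- 1:50
  d <- finite_difference_derivatives(cbind(tt))
  expect_equal(drop(d$g1), rep(1, 50))
  expect_lt(max(abs(d$g2[2:49, ])), 1e-12)
  dq <- finite_difference_derivatives(cbind(tt^2))
  expect_equal(drop(dq$g2)[2:49], rep(2, 48))
  ## Taylor-error oracle: central second difference of sin(wt) errs O(w^4)
  for (w in c(0.05, 0.1, 0.2)) {
    g <- sin(w * (1:400))
    dd <- finite_difference_derivatives(cbind(g))
    err <- max(abs(dd$g2[2:399] + w^2 * g[2:399]))
    expect_lt(err, w^4)
  }
  expect_error(finite_difference_derivatives(matrix(0, 2, 1)), "at least 3")
})

test_that("coupling regression identifies a single undamped oscillator", {
  w <- 0.3
  tt <- 0:999
  g <- cbind(cos(w * tt), sin(0.47 * tt))
  ## exact analytic derivatives supplied
  g1 <- cbind(-w * sin(w * tt), 0.47 * cos(0.47 * tt))
  g2 <- cbind(-w^2 * cos(w * tt), -0.47^2 * sin(0.47 * tt))
  cm <- fit_coupling_parameters(g, g1, g2)
  expect_equal(cm$position_coeffs[1, 1], -w^2, tolerance = 1e-8)
  expect_lt(abs(cm$position_coeffs[1, 2]), 1e-8)
  expect_lt(max(abs(cm$velocity_coeffs[1, ])), 1e-8)
  expect_lt(max(abs(cm$intercepts)), 1e-8)
  expect_gt(min(cm$r_squared), 1 - 1e-10)
})

test_that("fine-step integration plus downsampling recovers a known system", {
  sys <- coupled_system(k = 2, seed = 2)
  gts <- system_trajectory(sys, n_steps = 2000)
  ## endpoint rows dropped: their one-sided derivatives are the only
  ## inaccurate samples of a noiseless decaying trajectory
  cm <- fit_oscillator(gts, endpoint_rows = "drop")
  rel_p <- abs(cm$position_coeffs - sys$P) / abs(sys$P)
  expect_lt(max(rel_p[abs(sys$P) > 1e-10]), 0.05)
  rel_d <- abs(cm$velocity_coeffs - sys$D) / abs(sys$D)
  expect_lt(max(rel_d[abs(sys$D) > 1e-10]), 0.05)
})

test_that("white noise yields near-zero dynamics", {
  set.seed(3)
  g <- matrix(rnorm(1000 * 2), 1000)
  cm <- fit_oscillator(gradient_timeseries(g))
  ## no oscillatory structure: variance explained beyond the trivial
  ## second-difference autocorrelation is essentially nil for the
  ## position terms
  expect_lt(max(abs(cm$position_coeffs[row(cm$position_coeffs) !=
                                         col(cm$position_coeffs)])), 0.2)
  expect_lt(max(abs(cm$intercepts)), 0.2)
})

test_that("state matrix has companion form and textbook eigenvalues", {
  w <- 0.4
  g2body <- function(p, d, k = 1) {
    cm <- structure(list(intercepts = rep(0, k),
                         position_coeffs = matrix(p, k, k),
                         velocity_coeffs = matrix(d, k, k),
                         r_squared = 1, k = k, n_timepoints = 100,
                         tr_seconds = 2,
                         states = matrix(0, 2, 2 * k),
                         residuals = NULL),
                    class = "coupling_model")
    build_state_matrix(cm)
  }
  sm <- g2body(-w^2, 0)
  expect_equal(sm$A, rbind(c(0, 1), c(-w^2, 0)))
  expect_equal(sort(Im(eigen(sm$A)$values)), c(-w, w), tolerance = 1e-12)
  ## damped: eigenvalues -zeta w0 +/- i w0 sqrt(1 - zeta^2)
  w0 <- 0.5; zeta <- 0.3
  smd <- g2body(-w0^2, -2 * zeta * w0)
  ev <- eigen(smd$A)$values
  expect_equal(unique(round(Re(ev), 10)), -zeta * w0, tolerance = 1e-10)
  expect_equal(max(Im(ev)), w0 * sqrt(1 - zeta^2), tolerance = 1e-10)
  ## random K = 3: companion eigenvalues solve the quadratic eigenproblem
  sys <- coupled_system(k = 3, seed = 4)
  ev3 <- eigen(rbind(cbind(matrix(0, 3, 3), diag(3)),
                     cbind(sys$P, sys$D)))$values
  det_c <- function(m) {  # |det| of a complex matrix via real embedding
    sqrt(abs(det(rbind(cbind(Re(m), -Im(m)), cbind(Im(m), Re(m))))))
  }
  qep <- vapply(ev3, function(l)
    det_c(l^2 * diag(3) - l * sys$D - sys$P), numeric(1))
  expect_lt(max(qep), 1e-8)
  ## companion rows are exactly [0 | I]
  cm <- fit_oscillator(system_trajectory(sys, 400))
  smf <- build_state_matrix(cm)
  expect_equal(unname(smf$A[1:3, ]), cbind(matrix(0, 3, 3), diag(3)))
})

test_that("eigenmodes report frequencies in hertz and conserve the trace", {
  w <- pi / 10
  a <- rbind(c(0, 1), c(-w^2, 0))
  m <- compute_eigenmodes(a, tr_seconds = 2)
  expect_equal(m$frequency_hz, w / (2 * pi) / 2, tolerance = 1e-12)
  expect_equal(m$damping, 0, tolerance = 1e-12)
  ## trace oracle on random systems
  for (seed in 1:5) {
    sys <- coupled_system(k = 4, seed = seed)
    m4 <- compute_eigenmodes(sys$A, 2)
    expect_lt(abs(sum(m4$values_full) - sum(diag(sys$A))), 1e-10)
    ## conjugate closure of the spectrum
    ev <- m4$values_full
    expect_lt(max(abs(sort(Re(ev)) - sort(Re(Conj(ev))))), 1e-10)
    expect_lt(abs(sum(Im(ev))), 1e-10)
  }
  ## pure damping: overdamped modes retained and flagged
  ad <- rbind(c(0, 1), c(-0.01, -0.5))  # overdamped (zeta > 1)
  md <- compute_eigenmodes(ad, 2)
  expect_true(all(md$overdamped))
  expect_equal(md$frequency_hz, c(0, 0))
})

test_that("simulation matches analytic solutions and the RK4 integrator", {
  ## zero initial state, zero intercepts: stays at the fixed point
  sys <- coupled_system(k = 2, seed = 5)
  z <- simulate_gradients(sys$A, rep(0, 4), 100)
  expect_equal(max(abs(z$scores)), 0)
  ## undamped K = 1 from (1, 0): cos(w t)
  w <- 0.3
  a <- rbind(c(0, 1), c(-w^2, 0))
  tr_cos <- simulate_gradients(a, c(1, 0), 200)
  expect_equal(drop(tr_cos$scores), cos(w * (0:199)), tolerance = 1e-8)
  ## closed form vs numerical on random stable systems
  set.seed(99)
  for (seed in 1:3) {
    sysk <- coupled_system(k = 6, seed = seed)
    y0 <- rnorm(12)
    cf <- simulate_gradients(sysk$A, y0, 500, method = "closed_form")
    nm <- simulate_gradients(sysk$A, y0, 500, method = "numerical")
    expect_lt(max(abs(cf$scores - nm$scores)), 1e-6)
  }
  ## overflow guard on unstable systems
  au <- rbind(c(0, 1), c(0.04, 0.2))
  expect_error(simulate_gradients(au, c(1, 0), 5000), "unstable")
})

test_that("simulate method launches from observed states", {
  sys <- coupled_system(k = 2, seed = 6)
  gts <- system_trajectory(sys, 300)
  cm <- fit_oscillator(gts)
  sims <- simulate(cm, nsim = 2, n_steps = 50)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$scores[1, ], gts$scores[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("self-simulated FC reproduces a subject's own FC", {
  ## noise-free self-consistency: the single-trajectory simulation of a
  ## near-exactly fitted system reproduces the subject's FC
  sys <- coupled_system(k = 4, seed = 7)
  gts <- system_trajectory(sys, 400)
  basis <- make_synthetic_basis(25, 4, seed = 8)
  actual_fc <- fc_from_gradient_covariance(basis, gradient_covariance(gts))
  sim_fc <- simulate_subject_fc(gts, basis, mode = "single",
                                endpoint_rows = "drop")
  expect_gt(cor(edge_vector(actual_fc), edge_vector(sim_fc)), 0.99)
  expect_false(attr(sim_fc, "unstable_fallback"))
  ## stationary noise-driven subject: ensemble and single agree, and the
  ## ensemble tracks the subject's actual FC pattern
  cfg <- tiny_config(n_subjects = 1, n_regions = 25, n_timepoints = 500,
                     burn_in = 100, seed = 3)
  sub <- simulate_oscillator_subject(cfg, 0.5, seed = 4)
  gts2 <- sub$true_gradient_timeseries
  act2 <- fc_from_gradient_covariance(cfg$basis, gradient_covariance(gts2))
  ens <- simulate_subject_fc(gts2, cfg$basis, mode = "ensemble", max_ic = 60)
  sgl <- simulate_subject_fc(gts2, cfg$basis, mode = "single")
  expect_gt(cor(edge_vector(act2), edge_vector(ens)), 0.9)
  expect_gt(cor(edge_vector(ens), edge_vector(sgl)), 0.9)
})

test_that("subjects are identifiable from their simulated FC", {
  basis <- make_synthetic_basis(20, 3, seed = 9)
  actual <- sim <- list()
  for (i in 1:5) {
    sys <- coupled_system(k = 3, seed = 20 + i,
                          omega = seq(0.15, 0.5, length.out = 3) *
                            (1 + 0.15 * (i - 3) / 3))
    gts <- system_trajectory(sys, 400, seed = i)
    actual[[i]] <- fc_from_gradient_covariance(basis,
                                               gradient_covariance(gts))
    sim[[i]] <- simulate_subject_fc(gts, basis, mode = "single",
                                    endpoint_rows = "drop")
  }
  res <- fc_identifiability(actual, sim)
  expect_gt(res$median_self, res$median_other)
  ## perfect case: simulated identical to actual
  res_id <- fc_identifiability(actual, actual)
  expect_equal(unname(res_id$self_r), rep(1, 5), tolerance = 1e-12)
  expect_true(all(res_id$self_rank == 1))
  ## shuffled simulations: self similarity falls to the other level
  res_sh <- fc_identifiability(actual, sim[c(3, 4, 5, 1, 2)])
  expect_lt(res_sh$median_self, res$median_self)
  expect_error(fc_identifiability(actual, sim[1:3]), "equal length")
})

test_that("round trip from known system preserves eigenstructure", {
  sys <- coupled_system(k = 3, seed = 10)
  gts <- system_trajectory(sys, 2000)
  cm <- fit_oscillator(gts, endpoint_rows = "drop")
  smf <- build_state_matrix(cm)
  ev_true <- eigen(sys$A)$values
  ev_fit <- eigen(smf$A)$values
  f_true <- sort(Im(ev_true[Im(ev_true) > 0]))
  f_fit <- sort(Im(ev_fit[Im(ev_fit) > 0]))
  expect_lt(max(abs(f_fit - f_true) / f_true), 0.02)
  a_true <- Re(ev_true[Im(ev_true) > 0])[order(Im(ev_true[Im(ev_true) > 0]))]
  a_fit <- Re(ev_fit[Im(ev_fit) > 0])[order(Im(ev_fit[Im(ev_fit) > 0]))]
  expect_lt(max(abs(a_fit - a_true) / abs(a_true)), 0.10)
})
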