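## Shared small fixtures for the test suite. Everything is generated in
## code under fixed seeds; nothing is read from disk.

## compact cohort configuration for fast tests
tiny_config <- function(...) {
  defaults <- list(n_subjects = 12, n_regions = 20, n_gradients = 4,
                   n_timepoints = 160, burn_in = 50, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

## a moderately coupled, stable K-oscillator system with all-nonzero
## position couplings (direct coefficient planting, not eigen-planting)
coupled_system <- function(k = 3, zeta = 0.05, seed = 1,
                           omega = seq(0.18, 0.45, length.out = k)) {
  set.seed(seed)
  p <- diag(-omega^2)
  off <- matrix(0, k, k)
  off[upper.tri(off)] <- stats::runif(k * (k - 1) / 2, -1, 1)
  off <- (off + t(off)) * 0.1 * outer(omega, omega)
  p <- p + off
  d <- diag(-2 * zeta * omega, k)
  a <- rbind(cbind(matrix(0, k, k), diag(k)), cbind(p, d))
  stopifnot(max(Re(eigen(a, only.values = TRUE)$values)) < -1e-6)
  list(P = p, D = d, A = a, omega = omega, zeta = zeta)
}

## deterministic trajectory from a system, as a gradient_timeseries
system_trajectory <- function(sys, n_steps = 1500, seed = 1, tr = 2) {
  set.seed(seed)
  k <- nrow(sys$P)
  y0 <- stats::rnorm(2 * k)
  tr_out <- simulate_gradients(sys$A, y0, n_steps)
  gradient_timeseries(tr_out$scores, tr_seconds = tr)
}

## dominant-shared-mode two-gradient system with a planted phase offset
## theta (degrees): gradient 2 lags gradient 1 by theta on both modes.
phase_pair_system <- function(theta, beta = c(0.25, 0.4), damping = 0.01,
                              eps = 0.3) {
  th <- matrix(90, 2, 2)
  th[1, 2] <- theta
  plant_oscillator_system(beta, -damping * beta, th, eps)
}

## trajectory exciting (almost only) the first mode of a planted system
dominant_mode_trajectory <- function(sys, n_steps = 800, minor = 0.02) {
  e <- eigen(sys$A)
  o <- order(-Im(e$values))
  main <- which(Im(e$values) > 1e-9)[1]
  other <- setdiff(which(Im(e$values) > 1e-9), main)[1]
  y0 <- Re(e$vectors[, main]) + minor * Re(e$vectors[, other])
  simulate_gradients(sys$A, y0, n_steps)
}

expect_symmetric_unit_diag <- function(fc, tol = 1e-10) {
  expect_lt(max(abs(fc - t(fc)), na.rm = TRUE), tol)
  expect_lt(max(abs(diag(fc) - 1), na.rm = TRUE), tol)
  expect_true(all(fc >= -1 - tol & fc <= 1 + tol, na.rm = TRUE))
}
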