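## Linear coupled damped harmonic-oscillator model of gradient dynamics:
## derivative estimation, coupling regression, companion-form state matrix,
## eigenmodes, closed-form and numerical simulation, simulated FC.

#' Finite-difference derivatives of a gradient timeseries
#'
#' First derivative by central differences (one-sided at the endpoints,
#' as in the usual numerical `gradient` convention). Second derivative
#' by the direct central second difference `g[t+1] - 2 g[t] + g[t-1]`,
#' which is exact for quadratics over the whole interior, with one-sided
#' copies at the endpoints. Time is measured in TR units, so
#' coefficients fitted on these derivatives are per-TR and per-TR^2.
#'
#' @param gts A `gradient_timeseries` or T x K matrix (T >= 3).
#' @return List with `g` (the input scores), `g1` (T x K first
#'   derivative), `g2` (T x K second derivative).
#' @export
finite_difference_derivatives <- function(gts) {
  g <- if (inherits(gts, "gradient_timeseries")) gts$scores else as.matrix(gts)
  tn <- nrow(g)
  if (tn < 3) stop("need at least 3 timepoints for finite differences")
  g1 <- g
  g1[1, ] <- g[2, ] - g[1, ]
  g1[tn, ] <- g[tn, ] - g[tn - 1, ]
  g1[2:(tn - 1), ] <- (g[3:tn, , drop = FALSE] - g[1:(tn - 2), , drop = FALSE]) / 2
  g2 <- g * 0
  g2[2:(tn - 1), ] <- g[3:tn, , drop = FALSE] - 2 * g[2:(tn - 1), , drop = FALSE] +
    g[1:(tn - 2), , drop = FALSE]
  g2[1, ] <- g2[2, ]
  g2[tn, ] <- g2[tn - 1, ]
  list(g = g, g1 = g1, g2 = g2)
}

#' Fit coupling parameters of the oscillator system
#'
#' For each gradient k, least-squares regression of its second
#' derivative on an intercept, all gradients' positions, and all
#' gradients' first derivatives (2K + 1 coefficients per equation; 13
#' when K = 6). The fitted equations define the linear coupled damped
#' harmonic-oscillator system
#' \deqn{G_k'' = b_{k0} + \sum_j P_{kj} G_j + \sum_j D_{kj} G_j'}
#' with position coefficients `P` (per TR^2) and velocity (damping)
#' coefficients `D` (per TR).
#'
#' @param g,g1,g2 T x K matrices of positions, first and second
#'   derivatives (see [finite_difference_derivatives()]).
#' @param tr_seconds Repetition time, carried through for frequency
#'   conversion.
#' @param endpoint_rows `"keep"` (default) fits on every timepoint;
#'   `"drop"` excludes the first and last rows, whose one-sided
#'   derivative estimates are less accurate — preferable for noiseless
#'   decaying trajectories where the large-amplitude first row would
#'   otherwise dominate the fit.
#' @return An object of class `coupling_model`.
#' @seealso [fit_oscillator()] for the one-call interface.
#' @export
fit_coupling_parameters <- function(g, g1, g2, tr_seconds = 2,
                                    endpoint_rows = c("keep", "drop")) {
  endpoint_rows <- match.arg(endpoint_rows)
  g <- as.matrix(g); g1 <- as.matrix(g1); g2 <- as.matrix(g2)
  k <- ncol(g)
  tn <- nrow(g)
  if (tn - 2 <= 2 * k + 1)
    stop("too few timepoints (", tn, ") to fit ", 2 * k + 1,
         " coefficients per equation")
  rows <- if (endpoint_rows == "drop") 2:(tn - 1) else seq_len(tn)
  x <- cbind(1, g, g1)[rows, , drop = FALSE]
  g2fit <- g2[rows, , drop = FALSE]
  qd <- qr(x)
  if (qd$rank < ncol(x))
    stop("singular regressor matrix: gradients or derivatives are collinear")
  kappa_x <- kappa(qr.R(qd), exact = FALSE)
  if (kappa_x > 1e10)
    warning("ill-conditioned coupling regression (condition number ",
            format(kappa_x, digits = 3), ")")
  b <- qr.coef(qd, g2fit)
  fitted <- x %*% b
  res <- g2fit - fitted
  r2 <- 1 - colSums(res^2) / colSums(scale(g2fit, scale = FALSE)^2)
  structure(list(
    intercepts = b[1, ],
    position_coeffs = t(b[2:(k + 1), , drop = FALSE]),
    velocity_coeffs = t(b[(k + 2):(2 * k + 1), , drop = FALSE]),
    r_squared = r2,
    k = k,
    n_timepoints = tn,
    tr_seconds = tr_seconds,
    states = cbind(g, g1),
    residuals = res
  ), class = "coupling_model")
}

#' Fit the coupled-oscillator model to a gradient timeseries
#'
#' One-call interface: computes finite-difference derivatives and fits
#' the coupling regression. Returns a `coupling_model` with `print`,
#' `summary`, `coef`, `residuals` and `simulate` methods.
#'
#' @param gts A `gradient_timeseries` or T x K score matrix.
#' @param endpoint_rows Passed to [fit_coupling_parameters()].
#' @return An object of class `coupling_model`.
#' @export
fit_oscillator <- function(gts, endpoint_rows = c("keep", "drop")) {
  tr <- if (inherits(gts, "gradient_timeseries")) gts$tr_seconds else 2
  d <- finite_difference_derivatives(gts)
  fit_coupling_parameters(d$g, d$g1, d$g2, tr_seconds = tr,
                          endpoint_rows = match.arg(endpoint_rows))
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("Coupled damped harmonic-oscillator model:", x$k, "gradients,",
      x$n_timepoints, "timepoints, TR =", x$tr_seconds, "s\n")
  cat("Equation R-squared:",
      paste0(sprintf("%.3f", x$r_squared), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.coupling_model <- function(object, ...) {
  rbind(intercept = object$intercepts,
        t(cbind(object$position_coeffs, object$velocity_coeffs)))
}

#' @export
residuals.coupling_model <- function(object, ...) object$residuals

#' @export
summary.coupling_model <- function(object, ...) {
  modes <- compute_eigenmodes(build_state_matrix(object), object$tr_seconds)
  out <- list(model = object, modes = modes)
  class(out) <- "summary.coupling_model"
  out
}

#' @export
print.summary.coupling_model <- function(x, ...) {
  print(x$model)
  print(x$modes)
  invisible(x)
}

#' Build the companion-form state matrix
#'
#' Converts the K fitted second-order equations into the first-order
#' system `dY/dt = A Y + b` over the 2K-state `Y = (positions,
#' velocities)`. The position-row block of `A` is exactly `[0 | I]`; the
#' intercepts form an affine offset whose fixed point is subtracted
#' before simulation and added back afterwards.
#'
#' @param cm A `coupling_model`.
#' @return Object of class `state_matrix`: `A` (2K x 2K), `offset`
#'   (length 2K), `fixed_point` (length 2K or NULL when A is singular),
#'   `k`, `tr_seconds`.
#' @export
build_state_matrix <- function(cm) {
  stopifnot(inherits(cm, "coupling_model"))
  k <- cm$k
  a <- rbind(cbind(matrix(0, k, k), diag(k)),
             cbind(cm$position_coeffs, cm$velocity_coeffs))
  if (any(!is.finite(a))) stop("non-finite coupling coefficients")
  offset <- c(rep(0, k), cm$intercepts)
  fp <- tryCatch(solve(a, -offset), error = function(e) NULL)
  structure(list(A = a, offset = offset, fixed_point = fp, k = k,
                 tr_seconds = cm$tr_seconds),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat("Companion-form state matrix:", 2 * x$k, "x", 2 * x$k, "\n")
  invisible(x)
}

as_state_matrix <- function(x) {
  if (inherits(x, "state_matrix")) return(x)
  if (inherits(x, "coupling_model")) return(build_state_matrix(x))
  a <- as.matrix(x)
  k <- nrow(a) / 2
  structure(list(A = a, offset = rep(0, nrow(a)), fixed_point = rep(0, nrow(a)),
                 k = k, tr_seconds = 2), class = "state_matrix")
}

#' Eigenmodes of the fitted oscillator system
#'
#' Eigendecomposition of the state matrix. Complex-conjugate pairs are
#' collapsed to one mode each (the representative with non-negative
#' imaginary part); purely real eigenvalues are retained as overdamped
#' modes with zero frequency. Per mode: the eigenvalue
#' `alpha + i beta` (damping per TR, angular frequency rad/TR), the
#' frequency in hertz (`beta / (2 pi TR)`), and each gradient's complex
#' component `a + i b` read from the position rows of the eigenvector.
#'
#' Eigenvector gauge: each mode's position subvector is normalized to
#' unit modulus-norm and rotated so gradient 1's component has phase 0
#' (falling back to the largest-amplitude gradient when gradient 1's
#' amplitude is below 1e-8). Pairwise phase differences are invariant to
#' this gauge. Modes are sorted by ascending frequency.
#'
#' @param sm A `state_matrix`, `coupling_model`, or raw 2K x 2K matrix.
#' @param tr_seconds Repetition time (taken from `sm` if available).
#' @return Object of class `eigenmode_set`: `eigenvalues`,
#'   `frequency_hz`, `damping`, `components` (K x M complex, gauge
#'   fixed), `overdamped` (logical M), plus the raw decomposition
#'   (`vectors_full`, `values_full`) and bookkeeping (`k`, `tr_seconds`,
#'   `mode_index`, `degenerate`, `condition_number`).
#' @export
compute_eigenmodes <- function(sm, tr_seconds = NULL) {
  sm <- as_state_matrix(sm)
  tr <- if (is.null(tr_seconds)) sm$tr_seconds else tr_seconds
  k <- sm$k
  e <- eigen(sm$A)
  if (abs(sum(e$values) - sum(diag(sm$A))) >
      1e-8 * max(1, sum(abs(diag(sm$A)))))
    warning("eigenvalue sum deviates from trace; decomposition suspect")
  kap <- tryCatch({
    d <- svd(e$vectors, nu = 0, nv = 0)$d
    max(d) / max(min(d), 1e-300)
  }, error = function(err) Inf)
  degenerate <- !is.finite(kap) || kap > 1e8
  if (degenerate)
    warning("near-degenerate eigenvectors (condition number ",
            format(kap, digits = 3), "); mode quantities unreliable")
  ## representatives: one per conjugate pair (Im > 0) plus all real modes
  keep <- which(Im(e$values) > 1e-12)
  real_modes <- which(abs(Im(e$values)) <= 1e-12)
  idx <- c(keep, real_modes)
  lam <- e$values[idx]
  comp <- e$vectors[seq_len(k), idx, drop = FALSE]
  ## gauge: unit modulus-norm of position subvector, gradient-1 phase zero
  for (m in seq_along(lam)) {
    nrm <- sqrt(sum(Mod(comp[, m])^2))
    if (nrm > 0) comp[, m] <- comp[, m] / nrm
    ref <- if (Mod(comp[1, m]) >= 1e-8) 1 else which.max(Mod(comp[, m]))
    ph <- Arg(comp[ref, m])
    comp[, m] <- comp[, m] * exp(-1i * ph)
  }
  ord <- order(Im(lam))
  lam <- lam[ord]
  comp <- comp[, ord, drop = FALSE]
  overdamped <- abs(Im(lam)) <= 1e-12
  structure(list(
    eigenvalues = lam,
    frequency_hz = Im(lam) / (2 * pi * tr),
    damping = Re(lam),
    components = comp,
    overdamped = overdamped,
    vectors_full = e$vectors,
    values_full = e$values,
    k = k,
    tr_seconds = tr,
    condition_number = kap,
    degenerate = degenerate
  ), class = "eigenmode_set")
}

#' @export
print.eigenmode_set <- function(x, digits = 4, ...) {
  cat("Eigenmode set:", length(x$eigenvalues), "modes,", x$k, "gradients\n")
  df <- data.frame(frequency_hz = round(x$frequency_hz, digits),
                   damping_per_tr = round(x$damping, digits),
                   overdamped = x$overdamped)
  print(df)
  invisible(x)
}

#' Simulate gradient trajectories from a fitted system
#'
#' Deterministic evolution of the linear system from an initial state,
#' either in closed form through the eigendecomposition
#' (`Y(t) = V exp(lambda t) V^{-1} Y0`, real part, on deviations from
#' the affine fixed point) or by 4th-order Runge-Kutta integration at
#' `substeps` internal steps per TR. The two paths agree to integration
#' tolerance on any stable system and expose the same contract.
#'
#' @param sys A `state_matrix`, `coupling_model`, `eigenmode_set`, or
#'   raw 2K x 2K matrix.
#' @param initial_state Length-2K state (positions then velocities).
#' @param n_steps Number of TR steps to generate (including t = 0).
#' @param method `"closed_form"` (default) or `"numerical"`.
#' @param substeps Internal RK4 steps per TR for the numerical path.
#' @return List of class `simulated_trajectory`: `scores` (n_steps x K
#'   positions), `states` (n_steps x 2K), `method`, `initial_state`.
#' @export
simulate_gradients <- function(sys, initial_state, n_steps,
                               method = c("closed_form", "numerical"),
                               substeps = 20) {
  method <- match.arg(method)
  if (inherits(sys, "eigenmode_set")) {
    sm <- structure(list(A = Re(sys$vectors_full %*% diag(sys$values_full) %*%
                                  solve(sys$vectors_full)),
                         offset = rep(0, 2 * sys$k),
                         fixed_point = rep(0, 2 * sys$k),
                         k = sys$k, tr_seconds = sys$tr_seconds),
                    class = "state_matrix")
  } else sm <- as_state_matrix(sys)
  k <- sm$k
  if (length(initial_state) != 2 * k)
    stop("initial_state must have length ", 2 * k)
  a <- sm$A
  amax <- max(Re(eigen(a, only.values = TRUE)$values))
  if (amax > 1e-10 && amax * n_steps > 30)
    stop("unstable system (max Re eigenvalue ", format(amax, digits = 3),
         ") over ", n_steps, " steps would overflow; shorten the horizon")
  fp <- sm$fixed_point
  if (is.null(fp)) fp <- rep(0, 2 * k)
  y0 <- initial_state - fp
  tt <- seq_len(n_steps) - 1
  if (method == "closed_form") {
    e <- eigen(a)
    cc <- solve(e$vectors, y0)
    states <- Re(exp(outer(tt, e$values)) %*% (cc * t(e$vectors)))
  } else {
    rhs <- function(t, y, parms) list(parms %*% y)
    sol <- deSolve::ode(y = y0, times = tt, func = rhs, parms = a,
                        method = "rk4", hini = 1 / substeps)
    states <- unname(sol[, -1, drop = FALSE])
  }
  states <- sweep(states, 2, fp, `+`)
  structure(list(scores = states[, seq_len(k), drop = FALSE],
                 states = states,
                 method = method,
                 initial_state = initial_state),
            class = "simulated_trajectory")
}

#' @export
print.simulated_trajectory <- function(x, ...) {
  cat("Simulated trajectory:", nrow(x$scores), "steps x",
      ncol(x$scores), "gradients (", x$method, ")\n")
  invisible(x)
}

#' Simulate trajectories from a fitted coupling model
#'
#' `simulate` method for `coupling_model`: deterministic trajectories
#' from the model's own observed states as initial conditions.
#'
#' @param object A `coupling_model`.
#' @param nsim Number of trajectories (taken from the first `nsim`
#'   observed timepoints as initial conditions).
#' @param seed Ignored (deterministic); present for generic
#'   compatibility.
#' @param n_steps Steps per trajectory (default: the fitted length).
#' @param method Passed to [simulate_gradients()].
#' @param ... Unused.
#' @return A list of `simulated_trajectory` objects (length `nsim`).
#' @export
simulate.coupling_model <- function(object, nsim = 1, seed = NULL,
                                    n_steps = NULL, method = "closed_form",
                                    ...) {
  sm <- build_state_matrix(object)
  if (is.null(n_steps)) n_steps <- object$n_timepoints
  lapply(seq_len(nsim), function(i)
    simulate_gradients(sm, object$states[i, ], n_steps, method = method))
}

#' Simulated functional connectivity for one subject
#'
#' Fits the oscillator model to the subject's gradient timeseries,
#' simulates gradient activity from the fitted system, mixes it to
#' region space through the basis, and computes FC. In `"ensemble"`
#' mode (default) one trajectory is launched from every observed
#' timepoint's state, each trajectory runs for the scan length, and the
#' per-trajectory FC matrices are averaged; `"single"` mode uses one
#' trajectory from the first state. If the fitted system is unstable,
#' the function falls back to a single short-horizon simulation and
#' records it.
#'
#' @param gts The subject's `gradient_timeseries`.
#' @param basis A `gradient_basis` (only the first K columns matching
#'   the gradient count are used).
#' @param mode `"ensemble"` or `"single"`.
#' @param max_ic For `"ensemble"`, cap on the number of initial
#'   conditions (evenly thinned); `Inf` uses every timepoint.
#' @param endpoint_rows Passed to [fit_oscillator()].
#' @return R x R simulated FC matrix; attributes `mode` (as run) and
#'   `unstable_fallback`.
#' @export
simulate_subject_fc <- function(gts, basis, mode = c("ensemble", "single"),
                                max_ic = Inf,
                                endpoint_rows = c("keep", "drop")) {
  mode <- match.arg(mode)
  cm <- fit_oscillator(gts, endpoint_rows = match.arg(endpoint_rows))
  sm <- build_state_matrix(cm)
  k <- cm$k
  tn <- cm$n_timepoints
  amax <- max(Re(eigen(sm$A, only.values = TRUE)$values))
  fallback <- FALSE
  horizon <- tn
  if (amax > 1e-10) {
    fallback <- TRUE
    mode <- "single"
    horizon <- min(tn, max(2 * k + 2, floor(25 / max(amax, 1e-6))))
  }
  e <- eigen(sm$A)
  vinv <- solve(e$vectors)
  fp <- sm$fixed_point
  if (is.null(fp)) fp <- rep(0, 2 * k)
  tt <- seq_len(horizon) - 1
  emat <- exp(outer(tt, e$values))
  run_fc <- function(y0) {
    cc <- vinv %*% (y0 - fp)
    states <- Re(emat %*% (drop(cc) * t(e$vectors)))
    scores <- sweep(states[, seq_len(k), drop = FALSE], 2, fp[seq_len(k)], `+`)
    sig <- stats::cov(scores)
    fc_from_gradient_covariance(basis, sig)
  }
  ics <- if (mode == "ensemble") {
    idx <- seq_len(tn)
    if (is.finite(max_ic) && tn > max_ic)
      idx <- unique(round(seq(1, tn, length.out = max_ic)))
    idx
  } else 1L
  acc <- NULL
  nok <- 0
  for (i in ics) {
    fc <- suppressWarnings(run_fc(cm$states[i, ]))
    if (anyNA(fc)) next
    acc <- if (is.null(acc)) fc else acc + fc
    nok <- nok + 1
  }
  if (nok == 0) stop("all simulated trajectories produced degenerate FC")
  out <- acc / nok
  attr(out, "mode") <- mode
  attr(out, "unstable_fallback") <- fallback
  out
}

#' Self- versus other-subject FC identifiability
#'
#' Correlates every actual FC matrix with every simulated FC matrix
#' (upper-triangle edges) and summarises whether each subject's
#' simulation matches their own data better than other subjects' data.
#'
#' @param actual_fcs,simulated_fcs Equal-length lists of R x R FC
#'   matrices, subject-aligned.
#' @return List with the full `similarity` matrix (actual x simulated),
#'   `self_r`, `median_self`, `median_other`, `self_rank` (rank of the
#'   self match within each row, 1 = best), and a paired `t_statistic`
#'   (self vs mean other per subject).
#' @export
fc_identifiability <- function(actual_fcs, simulated_fcs) {
  if (length(actual_fcs) != length(simulated_fcs))
    stop("actual and simulated lists must have equal length")
  s <- length(actual_fcs)
  av <- vapply(actual_fcs, edge_vector, numeric(length(edge_vector(actual_fcs[[1]]))))
  sv <- vapply(simulated_fcs, edge_vector, numeric(nrow(av)))
  sim <- suppressWarnings(stats::cor(av, sv))
  self_r <- diag(sim)
  other <- sim; diag(other) <- NA
  mean_other <- rowMeans(other, na.rm = TRUE)
  tstat <- if (s >= 3 && stats::sd(self_r - mean_other) > 0)
    unname(stats::t.test(self_r, mean_other, paired = TRUE)$statistic)
  else NA_real_
  list(similarity = sim,
       self_r = self_r,
       median_self = stats::median(self_r),
       median_other = stats::median(other[!is.na(other)]),
       self_rank = apply(-sim, 1, function(row) rank(row, ties.method = "min"))[
         cbind(seq_len(s), seq_len(s))],
       t_statistic = tstat)
}
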