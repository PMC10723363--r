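## Eigenmode amplitude and phase-angle metrics and their relation to
## gradient variances/covariances across a cohort.

#' Per-mode excitation weights from observed states
#'
#' Expresses each observed state in the eigenbasis
#' (`c(t) = V^{-1} (y(t) - fixed point)`) and returns the RMS modulus of
#' each retained mode's coefficient over time. Multiplying a mode's
#' eigenvector by its excitation gives amplitudes that are invariant to
#' the arbitrary eigenvector scale and exactly homogeneous under a
#' rescaling of the data.
#'
#' @param modes An `eigenmode_set`.
#' @param states T x 2K matrix of observed states (positions then
#'   velocities), e.g. `fit$states` from [fit_oscillator()].
#' @return Numeric vector of excitations, one per retained mode.
#' @export
mode_excitation <- function(modes, states) {
  stopifnot(inherits(modes, "eigenmode_set"))
  states <- as.matrix(states)
  if (ncol(states) != 2 * modes$k)
    stop("states must have 2K = ", 2 * modes$k, " columns")
  cc <- solve(modes$vectors_full, t(states))
  exc_full <- sqrt(rowMeans(Mod(cc)^2))
  ## map retained (conjugate-collapsed) modes back to full eigenvalues
  idx <- vapply(seq_along(modes$eigenvalues), function(m)
    which.min(Mod(modes$values_full - modes$eigenvalues[m])), integer(1))
  exc_full[idx]
}

#' Cumulative gradient amplitude across eigenmodes
#'
#' Sums, over eigenmodes, the per-mode amplitude of one gradient
#' following the solution form: for a component `a + i b` the per-mode
#' term is `sqrt((b - a)^2 + (a + b)^2) = sqrt(2) |a + i b|`. With
#' `excitation` weights (recommended; see [mode_excitation()]) each
#' mode's component is scaled by how strongly the mode is excited in
#' the subject's data, which makes the cumulative amplitude
#' gauge-invariant and exactly proportional to the gradient's scale.
#'
#' @param modes An `eigenmode_set`.
#' @param gradient Gradient index (1..K).
#' @param excitation Optional per-mode weights; default 1 (pure
#'   eigenvector amplitudes in the fixed gauge).
#' @return Non-negative scalar.
#' @export
cumulative_gradient_amplitude <- function(modes, gradient, excitation = NULL) {
  stopifnot(inherits(modes, "eigenmode_set"))
  if (gradient > modes$k) stop("gradient index exceeds K")
  if (is.null(excitation)) excitation <- rep(1, length(modes$eigenvalues))
  comp <- modes$components[gradient, ] * excitation
  sum(sqrt((Im(comp) - Re(comp))^2 + (Re(comp) + Im(comp))^2))
}

#' Pairwise phase angle between two gradients
#'
#' Per mode, the angle difference `arg(a1 + i b1) - arg(a2 + i b2)`
#' between the two gradients' components, wrapped to (-180, 180], then
#' averaged circularly with weights equal to the product of the two
#' gradients' eigenvector amplitudes on that mode (normalized per
#' subject). Overdamped modes participate with their real components.
#' 90 degrees means temporal orthogonality; departures toward 0 or 180
#' are phase collapse.
#'
#' @param modes An `eigenmode_set`.
#' @param g1,g2 Gradient indices.
#' @return Angle in degrees in (-180, 180].
#' @export
pairwise_phase_angle <- function(modes, g1, g2) {
  stopifnot(inherits(modes, "eigenmode_set"))
  if (max(g1, g2) > modes$k) stop("gradient index exceeds K")
  a1 <- modes$components[g1, ]
  a2 <- modes$components[g2, ]
  w <- Mod(a1) * Mod(a2)
  if (sum(w) <= 0)
    stop("phase angle undefined: gradients share no mode with nonzero amplitude")
  d <- wrap_angle((Arg(a1) - Arg(a2)) * 180 / pi)
  circular_mean(d, w / sum(w))
}

#' Eigenmode metrics for one subject
#'
#' Computes the K cumulative amplitudes (excitation-weighted) and the
#' K(K-1)/2 pairwise phase angles from a fitted coupling model, in
#' row-major pair order matching [gradient_moments()].
#'
#' With `angle_convention = "absolute"` the magnitude of each angle is
#' reported instead of its signed value. Because a gradient pair's
#' covariance depends on the cosine of the phase angle — an even
#' function — second moments cannot identify the sign of the angle, and
#' across-subject comparisons against covariance moments should use the
#' absolute angle (the collapse index |angle|, with 90 degrees meaning
#' orthogonality).
#'
#' @param fit A `coupling_model` (or a `gradient_timeseries`, which is
#'   fitted first).
#' @param angle_convention `"signed"` (default; range (-180, 180]) or
#'   `"absolute"`.
#' @return Named numeric vector: `amp1..ampK`, then `ang_i_j` per pair.
#' @export
eigen_metrics <- function(fit, angle_convention = c("signed", "absolute")) {
  angle_convention <- match.arg(angle_convention)
  if (inherits(fit, "gradient_timeseries") || is.matrix(fit))
    fit <- fit_oscillator(fit)
  stopifnot(inherits(fit, "coupling_model"))
  modes <- compute_eigenmodes(build_state_matrix(fit))
  exc <- mode_excitation(modes, fit$states)
  k <- fit$k
  amps <- vapply(seq_len(k), function(g)
    cumulative_gradient_amplitude(modes, g, excitation = exc), numeric(1))
  prs <- upper_tri_pairs(k)
  angs <- vapply(seq_len(nrow(prs)), function(p)
    pairwise_phase_angle(modes, prs[p, 1], prs[p, 2]), numeric(1))
  if (angle_convention == "absolute") angs <- abs(angs)
  stats::setNames(c(amps, angs),
                  c(paste0("amp", seq_len(k)),
                    paste0("ang_", prs[, 1], "_", prs[, 2])))
}

#' Gradient temporal moments for one subject
#'
#' The K gradient variances followed by the K(K-1)/2 pairwise second
#' moments in row-major order. Pairwise moments are reported as Pearson
#' correlations by default — the scale-free counterpart of the
#' covariances, which keeps amplitude differences from masking phase
#' structure — or as raw covariances with `pairwise = "covariance"`.
#'
#' @param gts A `gradient_timeseries` or T x K matrix.
#' @param pairwise `"correlation"` (default) or `"covariance"`.
#' @return Named numeric vector: `var1..varK`, then `cov_i_j` per pair.
#' @export
gradient_moments <- function(gts, pairwise = c("correlation", "covariance")) {
  pairwise <- match.arg(pairwise)
  sig <- gradient_covariance(gts)
  k <- nrow(sig)
  prs <- upper_tri_pairs(k)
  pw <- if (pairwise == "correlation") stats::cov2cor(sig) else sig
  stats::setNames(c(diag(sig), pw[prs]),
                  c(paste0("var", seq_len(k)),
                    paste0("cov_", prs[, 1], "_", prs[, 2])))
}

#' Correlate eigenmode metrics with gradient moments across a cohort
#'
#' Builds the (K + K(K-1)/2)-squared correlation table between
#' per-subject eigenmode metrics (amplitudes then angles) and gradient
#' moments (variances then pairwise moments), both in the same column
#' order, and summarises the corresponding (diagonal) versus
#' non-corresponding entries. Constant columns are flagged and their
#' correlations left `NA`.
#'
#' @param metrics Subjects x 21 metric table (for K = 6).
#' @param moments Subjects x 21 moment table, same column order.
#' @param min_subjects Minimum cohort size (default 25).
#' @return Object of class `metric_moment_correlation`: `correlation`
#'   (21 x 21), `corresponding` (its diagonal), `median_corresponding`,
#'   `median_noncorresponding`, `constant_columns`.
#' @export
metrics_variance_correlation <- function(metrics, moments, min_subjects = 25) {
  x <- as.matrix(metrics); y <- as.matrix(moments)
  if (nrow(x) != nrow(y)) stop("metric and moment tables must share subjects")
  if (ncol(x) != ncol(y)) stop("metric and moment tables must share columns")
  if (nrow(x) < min_subjects)
    stop("need at least ", min_subjects, " subjects")
  const <- c(which(apply(x, 2, stats::sd) == 0),
             which(apply(y, 2, stats::sd) == 0))
  if (length(const))
    warning("constant column(s): ", paste(unique(const), collapse = ", "),
            "; correlations undefined there")
  cm <- suppressWarnings(stats::cor(x, y))
  corr <- diag(cm)
  off <- cm[row(cm) != col(cm)]
  structure(list(correlation = cm,
                 corresponding = corr,
                 median_corresponding = stats::median(abs(corr), na.rm = TRUE),
                 median_noncorresponding = stats::median(abs(off), na.rm = TRUE),
                 constant_columns = unique(const)),
            class = "metric_moment_correlation")
}

#' @export
print.metric_moment_correlation <- function(x, ...) {
  cat("Eigenmode metric vs gradient moment correlation (",
      nrow(x$correlation), "x", ncol(x$correlation), ")\n", sep = "")
  cat("Median |r| corresponding entries:   ",
      sprintf("%.3f", x$median_corresponding), "\n")
  cat("Median |r| non-corresponding entries:",
      sprintf("%.3f", x$median_noncorresponding), "\n")
  invisible(x)
}
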