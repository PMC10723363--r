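## Gradient latent space: basis fitting, projection, covariance -> FC algebra.

#' Construct a region timeseries object
#'
#' A light container for a T x R matrix of (typically standardized) BOLD
#' values with region labels and the repetition time.
#'
#' @param values T x R numeric matrix, one column per region.
#' @param region_ids Region labels; defaults to column names or `V1..VR`.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `region_timeseries`.
#' @export
region_timeseries <- function(values, region_ids = NULL, tr_seconds = 2) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("region timeseries contains missing values")
  if (nrow(values) < 2) stop("need at least 2 timepoints")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- paste0("V", seq_len(ncol(values)))
  }
  if (length(region_ids) != ncol(values))
    stop("region_ids length does not match number of columns")
  colnames(values) <- region_ids
  structure(list(values = values, region_ids = region_ids,
                 tr_seconds = tr_seconds),
            class = "region_timeseries")
}

#' @export
print.region_timeseries <- function(x, ...) {
  cat("Region timeseries:", nrow(x$values), "timepoints x",
      ncol(x$values), "regions, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

as_ts_matrix <- function(ts) {
  if (inherits(ts, "region_timeseries")) ts$values else as.matrix(ts)
}

#' Fit a gradient basis from a pool of region timeseries
#'
#' Temporally concatenates the pool, centers each region's series, and
#' performs PCA. The leading `k` eigenvectors (orthonormal) define the
#' gradient spatial maps; their component scores are the gradient
#' timeseries. Display loadings scale each eigenvector by the square root
#' of its eigenvalue (or by the raw eigenvalue with
#' `display_scaling = "eigenvalue"`); the orthonormal eigenvectors are
#' always what is used for projection and covariance algebra, since any
#' per-component scaling cancels in correlations.
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude region
#' weight is positive, making the decomposition reproducible.
#'
#' @param pool A `region_timeseries`, a T x R matrix, or a list of either
#'   (all sharing the same region order).
#' @param k Number of gradients to retain.
#' @param display_scaling `"sqrt_eigenvalue"` (default) or `"eigenvalue"`.
#' @return An object of class `gradient_basis` with elements
#'   `eigenvectors` (R x k), `display_loadings` (R x k),
#'   `explained_variance_fraction` (length k), `region_ids`, `k`.
#' @export
fit_gradient_basis <- function(pool, k,
                               display_scaling = c("sqrt_eigenvalue", "eigenvalue")) {
  display_scaling <- match.arg(display_scaling)
  if (inherits(pool, "region_timeseries") || is.matrix(pool)) pool <- list(pool)
  ids <- NULL
  mats <- lapply(pool, function(p) {
    m <- as_ts_matrix(p)
    if (is.null(ids)) ids <<- colnames(m)
    if (!is.null(ids) && !is.null(colnames(m)) && !identical(colnames(m), ids))
      stop("region sets/order differ across the pool; align regions first")
    m
  })
  x <- do.call(rbind, mats)
  r <- ncol(x)
  if (k > r) stop("k (", k, ") exceeds number of regions (", r, ")")
  if (nrow(x) <= r)
    stop("total pooled timepoints (", nrow(x), ") must exceed regions (", r, ")")
  xc <- scale(x, center = TRUE, scale = FALSE)
  pr <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  vectors <- fix_signs(pr$rotation[, seq_len(k), drop = FALSE])
  scale_fac <- switch(display_scaling,
                      sqrt_eigenvalue = pr$sdev[seq_len(k)],
                      eigenvalue = ev[seq_len(k)])
  structure(list(
    eigenvectors = vectors,
    display_loadings = sweep(vectors, 2, scale_fac, `*`),
    explained_variance_fraction = ev[seq_len(k)] / sum(ev),
    region_ids = if (is.null(ids)) paste0("V", seq_len(r)) else ids,
    k = k,
    display_scaling = display_scaling
  ), class = "gradient_basis")
}

#' @export
print.gradient_basis <- function(x, ...) {
  cat("Gradient basis:", nrow(x$eigenvectors), "regions x", x$k, "gradients\n")
  cat("Variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' Project a region timeseries into a gradient basis
#'
#' Centers each region's series and right-multiplies by the orthonormal
#' eigenvectors. The projection is linear, so the projection of a sum of
#' timeseries equals the sum of the projections.
#'
#' @param ts A `region_timeseries` (or T x R matrix).
#' @param basis A `gradient_basis` with matching region order.
#' @return An object of class `gradient_timeseries` with elements
#'   `scores` (T x k) and `tr_seconds`.
#' @export
project_timeseries <- function(ts, basis) {
  x <- as_ts_matrix(ts)
  if (ncol(x) != nrow(basis$eigenvectors))
    stop("region count mismatch: timeseries has ", ncol(x),
         ", basis expects ", nrow(basis$eigenvectors))
  if (!is.null(colnames(x)) && !identical(colnames(x), basis$region_ids))
    stop("region order differs from basis; align regions first")
  xc <- scale(x, center = TRUE, scale = FALSE)
  gradient_timeseries(xc %*% basis$eigenvectors,
                      tr_seconds = if (inherits(ts, "region_timeseries"))
                        ts$tr_seconds else 2)
}

#' Construct a gradient timeseries object
#' @param scores T x K matrix of gradient scores.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `gradient_timeseries`.
#' @export
gradient_timeseries <- function(scores, tr_seconds = 2) {
  scores <- as.matrix(scores)
  colnames(scores) <- paste0("G", seq_len(ncol(scores)))
  structure(list(scores = scores, tr_seconds = tr_seconds),
            class = "gradient_timeseries")
}

#' @export
print.gradient_timeseries <- function(x, ...) {
  cat("Gradient timeseries:", nrow(x$scores), "timepoints x",
      ncol(x$scores), "gradients, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' Gradient covariance matrix
#'
#' Unbiased (n - 1) sample covariance of the gradient score columns:
#' variances on the diagonal, covariances off it. Scores enter raw by
#' default; `standardize = TRUE` scales each column to unit variance
#' first (yielding a correlation matrix).
#'
#' @param gts A `gradient_timeseries` (or T x K matrix).
#' @param standardize Standardize score columns before the covariance.
#' @return K x K symmetric covariance matrix.
#' @export
gradient_covariance <- function(gts, standardize = FALSE) {
  s <- if (inherits(gts, "gradient_timeseries")) gts$scores else as.matrix(gts)
  if (nrow(s) < 2) stop("need at least 2 timepoints for a covariance")
  if (standardize) s <- scale(s)
  stats::cov(s)
}

#' Functional connectivity from gradient covariance
#'
#' Maps a K x K gradient covariance back to region space through the
#' basis (`V sigma V'`), then converts the implied region variances and
#' covariances to Pearson correlations. With all R components retained
#' this reproduces the direct region-wise correlation matrix exactly;
#' with K < R it is the rank-K reconstruction.
#'
#' Regions whose implied variance is (numerically) zero get `NA`
#' correlations and are reported in the `zero_variance` attribute rather
#' than being silently set to 0.
#'
#' @param basis A `gradient_basis`.
#' @param sigma K x K gradient covariance (K <= basis k).
#' @return R x R correlation matrix (class `fc_matrix` attribute layer).
#' @export
fc_from_gradient_covariance <- function(basis, sigma) {
  sigma <- as.matrix(sigma)
  k <- nrow(sigma)
  if (k > basis$k)
    stop("sigma dimension (", k, ") exceeds basis gradients (", basis$k, ")")
  v <- basis$eigenvectors[, seq_len(k), drop = FALSE]
  cov_r <- v %*% sigma %*% t(v)
  d <- diag(cov_r)
  zero <- which(d <= .Machine$double.eps * max(d, 1))
  sdv <- sqrt(pmax(d, 0))
  fc <- cov_r / tcrossprod(sdv)
  if (length(zero)) {
    fc[zero, ] <- NA_real_
    fc[, zero] <- NA_real_
    warning(length(zero), " region(s) with zero variance; correlations set NA")
  }
  diag(fc)[setdiff(seq_along(d), zero)] <- 1
  fc <- (fc + t(fc)) / 2
  attr(fc, "zero_variance") <- zero
  fc
}

#' Direct region-wise functional connectivity
#'
#' Pairwise Pearson correlation of region timeseries; the oracle and
#' default FC path.
#'
#' @param ts A `region_timeseries` (or T x R matrix).
#' @return R x R correlation matrix.
#' @export
fc_direct <- function(ts) {
  x <- as_ts_matrix(ts)
  fc <- suppressWarnings(stats::cor(x))
  diag(fc) <- 1
  (fc + t(fc)) / 2
}

#' Global signal amplitude
#'
#' Standard deviation of the across-region mean timeseries. For a cohort
#' dominated by a unipolar first gradient this tracks the square root of
#' the first gradient's variance.
#'
#' @param ts A `region_timeseries` (or T x R matrix).
#' @return Scalar standard deviation.
#' @export
global_signal_amplitude <- function(ts) {
  x <- as_ts_matrix(ts)
  if (nrow(x) < 2) stop("need at least 2 timepoints")
  stats::sd(rowMeans(x))
}

#' Variance partition of function scores over gradient moments
#'
#' Regresses a per-subject function score on the 21 gradient moment
#' columns (6 variances + 15 covariances for K = 6) and attributes the
#' explained variance to individual terms by averaging sequential
#' sums-of-squares over random predictor orderings (LMG-style
#' hierarchical partitioning). Shares are non-negative and sum to the
#' full-model R-squared.
#'
#' If the moment matrix is severely collinear (condition number of the
#' standardized predictors above `cond_tol`) a warning is issued and a
#' small ridge term is added before computing t-statistics; the
#' partition itself is unaffected because sequential fits are always
#' full-rank in the retained order.
#'
#' @param f_scores Numeric vector, one score per subject.
#' @param moments Subjects x terms matrix of gradient variances and
#'   covariances.
#' @param n_orders Number of random orderings to average (default 200).
#' @param seed Seed for the ordering sampler.
#' @param cond_tol Condition-number threshold for the collinearity
#'   warning.
#' @return List with `shares` (per-term variance fraction of the
#'   response), `t_statistics` (full-model t values), `r_squared`
#'   (full model), `ridge_fallback` flag.
#' @export
variance_partition <- function(f_scores, moments, n_orders = 200, seed = 1,
                               cond_tol = 1e8) {
  y <- as.numeric(f_scores)
  x <- as.matrix(moments)
  n <- length(y)
  p <- ncol(x)
  if (n < 25) stop("variance_partition needs at least 25 subjects")
  if (nrow(x) != n) stop("moments rows must match f_scores length")
  xs <- scale(x)
  sv <- svd(xs, nu = 0, nv = 0)$d
  ridge_fallback <- FALSE
  if (min(sv) <= 0 || max(sv) / max(min(sv), 1e-300) > cond_tol) {
    warning("moment columns are near-collinear (condition number > ",
            format(cond_tol), "); ridge-stabilised t-statistics reported")
    ridge_fallback <- TRUE
  }
  yc <- y - mean(y)
  tss <- sum(yc^2)
  inc <- matrix(0, n_orders, p)
  perms <- with_seed(seed, replicate(n_orders, sample.int(p), simplify = FALSE))
  for (o in seq_len(n_orders)) {
    perm <- perms[[o]]
    qd <- qr(cbind(1, x[, perm, drop = FALSE]))
    qy <- qr.qty(qd, y)[seq_len(p + 1)][-1]
    inc[o, perm[seq_len(qd$rank - 1)]] <- qy[seq_len(qd$rank - 1)]^2
  }
  shares <- colMeans(inc) / tss
  names(shares) <- colnames(x)
  ## full-model t statistics
  xr <- cbind(1, x)
  xtx <- crossprod(xr)
  if (ridge_fallback) diag(xtx)[-1] <- diag(xtx)[-1] * (1 + 1e-8)
  beta <- solve(xtx, crossprod(xr, y))
  res <- y - xr %*% beta
  df <- n - p - 1
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tstat <- (beta / se)[-1]
  names(tstat) <- colnames(x)
  fitted_ss <- tss - sum(res^2)
  list(shares = shares,
       t_statistics = tstat,
       r_squared = fitted_ss / tss,
       ridge_fallback = ridge_fallback)
}
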