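## Atrophy W-scores, PLSR structure-function components, reliability,
## cross-validated ridge function scores, reconstruction and summaries.

#' Fit a normative W-score model
#'
#' Per-region multiple regression of gray-matter values on covariates in
#' a reference (cognitively normal) sample. The model stores, for each
#' region, the regression coefficients and the residual standard
#' deviation used to scale deviations.
#'
#' @param reference_gm Subjects x regions matrix of gray-matter values.
#' @param covariates Data frame of covariates (one row per reference
#'   subject); expanded via `model.matrix(~ .)`.
#' @return Object of class `wscore_model`.
#' @export
fit_wscore_model <- function(reference_gm, covariates) {
  gm <- as.matrix(reference_gm)
  covariates <- as.data.frame(covariates)
  n <- nrow(gm)
  if (nrow(covariates) != n) stop("covariates rows must match reference_gm rows")
  form <- if (ncol(covariates) == 0) ~ 1 else ~ .
  mm <- stats::model.matrix(form, data = covariates)
  p <- ncol(mm)
  if (n <= p + 1)
    stop("reference sample too small: need n > number of covariates + 2")
  qd <- qr(mm)
  if (qd$rank < p) {
    bad <- colnames(mm)[-seq_len(qd$rank)]
    stop("rank-deficient covariates: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qd, gm)
  res <- gm - mm %*% beta
  sd_res <- sqrt(colSums(res^2) / (n - p))
  if (any(sd_res <= .Machine$double.eps^0.5 * max(abs(gm))))
    stop("zero residual standard deviation in ",
         sum(sd_res <= .Machine$double.eps^0.5 * max(abs(gm))),
         " region(s): reference fit is exact; add variability or drop regions")
  structure(list(coefficients = beta, residual_sd = sd_res,
                 covariate_names = colnames(covariates),
                 terms = stats::terms(form, data = covariates),
                 xlevels = lapply(Filter(is.factor, covariates), levels),
                 n_reference = n),
            class = "wscore_model")
}

#' @export
print.wscore_model <- function(x, ...) {
  cat("W-score model:", ncol(x$coefficients), "regions,",
      nrow(x$coefficients), "design columns, reference n =", x$n_reference, "\n")
  invisible(x)
}

#' Compute atrophy W-scores
#'
#' W = (predicted - actual) / residual SD under the atrophy-positive
#' convention: positive scores mean less gray matter than expected for
#' the subject's covariates. Set `orientation = "deficit-negative"` to
#' flip to the raw (actual - predicted) / SD form.
#'
#' @param gm Gray-matter values: an R-vector for one subject or an
#'   S x R matrix.
#' @param covariates Data frame with one row per subject and the same
#'   columns used to fit the model.
#' @param model A `wscore_model`.
#' @param orientation `"atrophy-positive"` (default) or
#'   `"deficit-negative"`.
#' @return W-scores with the same shape as `gm`.
#' @export
apply_wscores <- function(gm, covariates, model,
                          orientation = c("atrophy-positive", "deficit-negative")) {
  orientation <- match.arg(orientation)
  one <- is.null(dim(gm))
  gm <- if (one) matrix(gm, nrow = 1) else as.matrix(gm)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(gm))
    stop("covariates rows must match subjects")
  missing_cov <- setdiff(model$covariate_names, names(covariates))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  mm <- stats::model.matrix(stats::delete.response(model$terms),
                            data = covariates, xlev = model$xlevels)
  pred <- mm %*% model$coefficients
  w <- sweep(pred - gm, 2, model$residual_sd, `/`)
  if (orientation == "deficit-negative") w <- -w
  if (one) drop(w) else w
}

## NIPALS PLS2: X decomposed into components maximally covarying with Y.
## Columns centered; not variance-scaled by default (W-scores and FC edges
## are already on comparable scales).
nipals_pls2 <- function(x, y, ncomp, scale. = FALSE, tol = 1e-10, maxit = 500) {
  x0 <- scale(x, center = TRUE, scale = scale.)
  y0 <- scale(y, center = TRUE, scale = scale.)
  n <- nrow(x0)
  tt <- matrix(0, n, ncomp)          # X scores
  uu <- matrix(0, n, ncomp)          # Y scores
  ww <- matrix(0, ncol(x0), ncomp)   # X weights
  pp <- matrix(0, ncol(x0), ncomp)   # X loadings
  qq <- matrix(0, ncol(y0), ncomp)   # Y loadings
  xd <- x0; yd <- y0
  for (c in seq_len(ncomp)) {
    u <- yd[, which.max(apply(yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(xd, u)
      w <- w / sqrt(sum(w^2))
      t_ <- xd %*% w
      q <- crossprod(yd, t_) / sum(t_^2)
      u <- yd %*% q / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p <- crossprod(xd, t_) / sum(t_^2)
    xd <- xd - tcrossprod(t_, p)
    yd <- yd - tcrossprod(t_, q)
    tt[, c] <- t_; uu[, c] <- u; ww[, c] <- w; pp[, c] <- p; qq[, c] <- q
  }
  list(t = tt, u = uu, w = ww, p = pp, q = qq,
       x_totvar = sum(x0^2), x_center = attr(x0, "scaled:center"))
}

#' Fit structure-function components by partial least squares regression
#'
#' Decomposes the atrophy matrix (X) into components that maximally
#' covary with the functional-connectivity edge matrix (Y), using
#' NIPALS PLS2 with deflation. Atrophy is the grounding side: structure
#' loadings live in region space, function loadings in edge space, and
#' each subject receives paired structure and function scores whose
#' correlation measures the strength of that structure-function
#' relationship.
#'
#' @param atrophy Subjects x regions W-score matrix.
#' @param fc_edges Subjects x edges FC matrix (row-major upper triangle,
#'   see [edge_vector()]).
#' @param n_components Number of components to extract.
#' @param scale. Standardize columns to unit variance first (default
#'   FALSE).
#' @return Object of class `sf_components` with structure/function
#'   loadings and scores, per-component score correlations, and the
#'   fraction of atrophy variance explained per component.
#' @export
fit_plsr_components <- function(atrophy, fc_edges, n_components,
                                scale. = FALSE) {
  x <- as.matrix(atrophy); y <- as.matrix(fc_edges)
  s <- nrow(x)
  if (nrow(y) != s) stop("atrophy and fc_edges must have the same subjects")
  if (n_components >= s) stop("n_components must be < number of subjects")
  if (n_components > qr(scale(x, scale = FALSE))$rank)
    stop("n_components exceeds the rank of the centered atrophy matrix")
  fit <- nipals_pls2(x, y, n_components, scale. = scale.)
  ## sign convention: largest-|weight| region of each structure loading is
  ## positive; scores and function loadings flip with it so all products
  ## are unchanged
  for (c in seq_len(n_components)) {
    s <- sign(fit$p[which.max(abs(fit$p[, c])), c])
    if (s < 0) {
      fit$p[, c] <- -fit$p[, c]; fit$w[, c] <- -fit$w[, c]
      fit$t[, c] <- -fit$t[, c]; fit$q[, c] <- -fit$q[, c]
      fit$u[, c] <- -fit$u[, c]
    }
  }
  comp_var <- vapply(seq_len(n_components), function(c)
    sum(tcrossprod(fit$t[, c], fit$p[, c])^2), numeric(1))
  structure(list(
    n_components = n_components,
    structure_loadings = fit$p,
    structure_weights = fit$w,
    function_loadings = fit$q,
    structure_scores = fit$t,
    function_scores = fit$u,
    score_correlation = vapply(seq_len(n_components), function(c)
      stats::cor(fit$t[, c], fit$u[, c]), numeric(1)),
    atrophy_variance_explained = comp_var / fit$x_totvar,
    scaled = scale.
  ), class = "sf_components")
}

#' @export
print.sf_components <- function(x, ...) {
  cat("Structure-function components (PLSR):", x$n_components, "components\n")
  cat("Atrophy variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$atrophy_variance_explained),
             collapse = " "), "\n")
  cat("Structure-function score correlation:",
      paste0(sprintf("%.2f", x$score_correlation), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.sf_components <- function(object, ...) {
  out <- data.frame(
    component = seq_len(object$n_components),
    atrophy_variance = object$atrophy_variance_explained,
    score_correlation = object$score_correlation)
  class(out) <- c("summary.sf_components", "data.frame")
  out
}

#' Split-half reliability of PLSR structure loadings
#'
#' Repeatedly splits the cohort into two label-balanced halves, fits an
#' independent PLSR in each, and correlates the structure loadings
#' across halves. Because component order and sign are arbitrary between
#' fits, half-2 components are matched to half-1 components by a greedy
#' maximum-|r| assignment and the absolute correlation is recorded.
#'
#' @param atrophy Subjects x regions matrix.
#' @param fc_edges Subjects x edges matrix.
#' @param labels Syndrome/diagnosis label per subject (balanced across
#'   halves); each label needs at least 2 members.
#' @param n_components Components per fit.
#' @param n_splits Number of random splits.
#' @param seed RNG seed.
#' @param cutoff Median-|r| threshold used to flag components as
#'   acceptable (default 0.7; reported, never enforced).
#' @return Object of class `split_half_reliability`: matrix
#'   `n_splits` x `n_components` of absolute loading correlations, a
#'   `median_r` summary, and an `acceptable` flag per component.
#' @export
split_half_reliability <- function(atrophy, fc_edges, labels, n_components,
                                   n_splits = 100, seed = 1, cutoff = 0.7) {
  x <- as.matrix(atrophy); y <- as.matrix(fc_edges)
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    stop("every label needs at least 2 members for balanced splitting")
  res <- matrix(NA_real_, n_splits, n_components)
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      h1 <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
        idx <- sample(idx)
        idx[seq_len(floor(length(idx) / 2))]
      }))
      h2 <- setdiff(seq_along(labels), h1)
      f1 <- fit_plsr_components(x[h1, , drop = FALSE], y[h1, , drop = FALSE],
                                n_components)
      f2 <- fit_plsr_components(x[h2, , drop = FALSE], y[h2, , drop = FALSE],
                                n_components)
      cm <- abs(stats::cor(f1$structure_loadings, f2$structure_loadings))
      ## greedy maximum-|r| assignment
      for (c in seq_len(n_components)) {
        best <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
        res[s, best[1]] <- cm[best[1], best[2]]
        cm[best[1], ] <- -Inf
        cm[, best[2]] <- -Inf
      }
    }
  })
  med <- apply(res, 2, stats::median)
  structure(list(correlations = res,
                 median_r = med,
                 cutoff = cutoff,
                 acceptable = med >= cutoff),
            class = "split_half_reliability")
}

#' @export
print.split_half_reliability <- function(x, ...) {
  cat("Split-half reliability over", nrow(x$correlations), "splits\n")
  cat("Median |r| per component:",
      paste0(sprintf("%.3f", x$median_r), collapse = " "), "\n")
  cat("Acceptable (median |r| >=", x$cutoff, "):",
      paste(which(x$acceptable), collapse = " "), "\n")
  invisible(x)
}

#' Atrophy component scores by PCA
#'
#' Principal component analysis of the atrophy matrix alone (no FC
#' involvement), used to obtain structure scores that can enter
#' cross-validation without contamination. Signs follow the package
#' convention (largest-|weight| region positive).
#'
#' @param atrophy Subjects x regions matrix.
#' @param n_components Components to keep.
#' @return List with `scores` (S x C), `loadings` (R x C),
#'   `explained_variance_fraction`.
#' @export
atrophy_pca_scores <- function(atrophy, n_components) {
  x <- as.matrix(atrophy)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pr$rotation[, seq_len(n_components), drop = FALSE]
  sgn <- vapply(seq_len(n_components), function(c)
    { s <- sign(load[which.max(abs(load[, c])), c]); if (s == 0) 1 else s },
    numeric(1))
  list(scores = sweep(pr$x[, seq_len(n_components), drop = FALSE], 2, sgn, `*`),
       loadings = sweep(load, 2, sgn, `*`),
       explained_variance_fraction =
         (pr$sdev^2 / sum(pr$sdev^2))[seq_len(n_components)])
}

## SVD ridge with intercept (penalty a||b||^2, intercept unpenalised);
## y_train may have several columns, which share one decomposition.
ridge_svd <- function(x_train, y_train, x_test, alpha) {
  y_train <- as.matrix(y_train)
  xm <- colMeans(x_train)
  ym <- colMeans(y_train)
  xc <- sweep(x_train, 2, xm)
  sv <- svd(xc)
  d <- sv$d / (sv$d^2 + alpha)
  beta <- sv$v %*% (d * crossprod(sv$u, sweep(y_train, 2, ym)))
  pred <- sweep(sweep(x_test, 2, xm) %*% beta, 2, ym, `+`)
  list(beta = beta, pred = pred)
}

#' Cross-validated ridge function scores
#'
#' For each atrophy component, ridge-regresses the component score on
#' the FC edge matrix with label-stratified k-fold cross-validation.
#' Each subject's function score is taken only from folds where the
#' subject was left out, averaged over trials, so structure and function
#' scores are decorrelated by construction and free of training leakage.
#' Edge coefficients are averaged over folds and trials.
#'
#' @param atrophy_scores S x C matrix of atrophy component scores (e.g.
#'   from [atrophy_pca_scores()]).
#' @param fc_edges S x E matrix of FC edge values.
#' @param labels Stratification labels (syndrome), one per subject.
#' @param alpha Ridge penalty (default 1000).
#' @param n_folds Folds per trial (default 4).
#' @param n_trials Random refolds to average (default 20).
#' @param seed RNG seed.
#' @return List with `function_scores` (S x C out-of-fold),
#'   `coefficients` (E x C averaged), `fold_r` (trials x folds x C
#'   array of per-fold out-of-sample correlations).
#' @export
ridge_function_scores <- function(atrophy_scores, fc_edges, labels,
                                  alpha = 1000, n_folds = 4, n_trials = 20,
                                  seed = 1) {
  a <- as.matrix(atrophy_scores)
  y <- as.matrix(fc_edges)
  s <- nrow(a); ncomp <- ncol(a)
  labels <- as.factor(labels)
  if (n_folds < 2) stop("need at least 2 folds")
  if (any(table(labels) < n_folds))
    stop("every label needs at least n_folds members for stratification")
  scores_sum <- matrix(0, s, ncomp)
  scores_cnt <- matrix(0, s, ncomp)
  coef_sum <- matrix(0, ncol(y), ncomp)
  fold_r <- array(NA_real_, c(n_trials, n_folds, ncomp))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      fold <- integer(s)
      for (lv in levels(labels)) {
        idx <- sample(which(labels == lv))
        fold[idx] <- rep_len(sample(n_folds), length(idx))
      }
      for (f in seq_len(n_folds)) {
        test <- which(fold == f); train <- which(fold != f)
        if (!all(levels(labels) %in% labels[train]))
          stop("stratification failed: a fold lost a label entirely")
        rr <- ridge_svd(y[train, , drop = FALSE], a[train, , drop = FALSE],
                        y[test, , drop = FALSE], alpha)
        scores_sum[test, ] <- scores_sum[test, ] + rr$pred
        scores_cnt[test, ] <- scores_cnt[test, ] + 1
        coef_sum <- coef_sum + rr$beta
        for (c in seq_len(ncomp))
          fold_r[tr, f, c] <- suppressWarnings(stats::cor(rr$pred[, c],
                                                          a[test, c]))
      }
    }
  })
  list(function_scores = scores_sum / scores_cnt,
       coefficients = coef_sum / (n_trials * n_folds),
       fold_r = fold_r)
}

#' Reconstruct an FC difference pattern from component scores
#'
#' Linear reconstruction: the sum over components of score times
#' function-loading column (the outer product for a score matrix).
#'
#' @param function_scores Length-C vector (one subject/group) or S x C
#'   matrix.
#' @param function_loadings E x C matrix.
#' @return Length-E vector or S x E matrix of reconstructed edge values.
#' @export
reconstruct_fc_from_components <- function(function_scores, function_loadings) {
  l <- as.matrix(function_loadings)
  one <- is.null(dim(function_scores))
  sc <- if (one) matrix(function_scores, nrow = 1) else as.matrix(function_scores)
  if (ncol(sc) != ncol(l))
    stop("component count mismatch between scores and loadings")
  out <- tcrossprod(sc, l)
  if (one) drop(out) else out
}

#' Region-wise summary map of edge weights
#'
#' Sums each region's incident edge weights: the row sums of the dense
#' symmetric edge-weight matrix implied by the edge vector.
#'
#' @param edge_weights Length R(R-1)/2 edge vector (row-major upper
#'   triangle).
#' @return Length-R vector of per-region sums.
#' @export
network_summary_map <- function(edge_weights) {
  m <- edges_to_matrix(edge_weights, diag_value = 0)
  rowSums(m)
}

#' Classical MDS embedding of structure scores
#'
#' Embeds subjects into two dimensions by classical multidimensional
#' scaling of Euclidean distances, reporting how well embedded distances
#' correlate with the input distances.
#'
#' @param scores S x d matrix (d >= 2, typically 3 component scores).
#' @return S x 2 matrix with attribute `distance_correlation`.
#' @export
mds_embed <- function(scores) {
  x <- as.matrix(scores)
  if (nrow(x) < 3) stop("need at least 3 subjects")
  d <- stats::dist(x)
  if (max(d) <= 0) stop("degenerate input: all points identical")
  emb <- stats::cmdscale(d, k = 2)
  de <- as.numeric(stats::dist(emb))
  attr(emb, "distance_correlation") <-
    if (stats::sd(de) > 0 && stats::sd(as.numeric(d)) > 0)
      stats::cor(as.numeric(d), de) else NA_real_
  emb
}

#' Flag subjects expressing the typical pattern of their syndrome
#'
#' Linear discriminant analysis on structure component scores with the
#' syndrome label as response; subjects whose predicted label equals
#' their true label are flagged typical. If the within-class scatter is
#' singular, a regularized fallback (pooled covariance inflated by a
#' small ridge, Gaussian classification with class priors) is used and
#' recorded.
#'
#' @param structure_scores S x C score matrix.
#' @param labels Syndrome label per subject (>= 2 levels, each with > 3
#'   members).
#' @return Data frame with `label`, `predicted`, `typical`; attributes
#'   `counts` (typical/total per label) and `regularized`.
#' @export
typical_patients_lda <- function(structure_scores, labels) {
  x <- as.matrix(structure_scores)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 labels")
  if (any(table(labels) <= 3)) stop("every label needs more than 3 members")
  regularized <- FALSE
  pred <- tryCatch({
    fit <- MASS::lda(x, grouping = labels)
    stats::predict(fit, x)$class
  }, error = function(e) {
    regularized <<- TRUE
    pooled_gaussian_classify(x, labels)
  })
  typical <- pred == labels
  counts <- t(vapply(levels(labels), function(lv)
    c(typical = sum(typical[labels == lv]), total = sum(labels == lv)),
    numeric(2)))
  out <- data.frame(label = labels, predicted = pred, typical = typical)
  attr(out, "counts") <- counts
  attr(out, "regularized") <- regularized
  out
}

## regularized LDA fallback: pooled covariance + ridge, shared across classes
pooled_gaussian_classify <- function(x, labels) {
  lev <- levels(labels)
  mus <- t(vapply(lev, function(lv) colMeans(x[labels == lv, , drop = FALSE]),
                  numeric(ncol(x))))
  centered <- x - mus[as.integer(labels), , drop = FALSE]
  sp <- crossprod(centered) / (nrow(x) - length(lev))
  sp <- sp + diag(1e-6 * max(diag(sp), 1), ncol(x))
  spi <- solve(sp)
  priors <- as.numeric(table(labels)) / nrow(x)
  disc <- vapply(seq_along(lev), function(g) {
    diff <- sweep(x, 2, mus[g, ])
    -0.5 * rowSums((diff %*% spi) * diff) + log(priors[g])
  }, numeric(nrow(x)))
  factor(lev[max.col(disc)], levels = lev)
}
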