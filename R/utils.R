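#' @keywords internal
"_PACKAGE"

## Shared helpers: edge vectorisation, circular statistics, seeded RNG.

#' Row-major upper-triangle index pairs
#'
#' Enumerates the region (or gradient) pairs `(i, j)` with `i < j` in
#' row-major order: (1,2), (1,3), ..., (1,K), (2,3), ... This ordering is
#' used for every flattened edge vector and pairwise-angle table in the
#' package.
#'
#' @param k Matrix dimension.
#' @return Integer matrix with columns `i` and `j`, one row per pair.
#' @export
upper_tri_pairs <- function(k) {
  stopifnot(k >= 2)
  p <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' Flatten a symmetric matrix to its upper-triangle edge vector
#'
#' Returns the strictly-upper-triangle entries in row-major order
#' (diagonal excluded), the package-wide edge convention. For R = 246
#' regions this gives 30135 entries.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `nrow(m) * (nrow(m) - 1) / 2`.
#' @seealso [edges_to_matrix()], [flatten_covariance()]
#' @export
edge_vector <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [edge_vector()]; the diagonal is filled with `diag_value`.
#'
#' @param edges Edge vector in row-major upper-triangle order.
#' @param diag_value Value placed on the diagonal (default 1, as for a
#'   correlation matrix).
#' @return Symmetric matrix.
#' @export
edges_to_matrix <- function(edges, diag_value = 1) {
  r <- (1 + sqrt(1 + 8 * length(edges))) / 2
  if (abs(r - round(r)) > 1e-8)
    stop("edge vector length ", length(edges), " is not R*(R-1)/2 for integer R")
  r <- round(r)
  m <- matrix(0, r, r)
  tm <- t(m)
  tm[lower.tri(tm)] <- edges
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Flatten a covariance matrix including the diagonal
#'
#' Upper triangle in row-major order, diagonal included — the convention
#' used when stacking subject covariance matrices (30381 entries for
#' R = 246).
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length `R * (R + 1) / 2`.
#' @export
flatten_covariance <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  tm <- t(m)
  tm[lower.tri(tm, diag = TRUE)]
}

#' Wrap angles in degrees to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Weighted circular mean of angles in degrees
#'
#' Resultant-vector mean: `atan2(sum(w sin), sum(w cos))`, returned in
#' (-180, 180]. Errors if all weights are zero (the direction is
#' undefined).
#'
#' @param angles Angles in degrees.
#' @param weights Non-negative weights, recycled if scalar.
#' @return Circular mean in degrees.
#' @export
circular_mean <- function(angles, weights = 1) {
  weights <- rep_len(weights, length(angles))
  if (any(weights < 0)) stop("circular_mean: negative weights")
  if (sum(weights) <= 0) stop("circular_mean: all weights are zero; angle undefined")
  a <- angles * pi / 180
  wrap_angle(atan2(sum(weights * sin(a)), sum(weights * cos(a))) * 180 / pi)
}

#' Derive a child RNG seed from a base seed and a stream index
#'
#' All randomness in the synthetic-data generator flows from one integer
#' seed through this splitting scheme, so that per-subject streams are
#' reproducible and mutually distinct:
#' `child = (seed + 1000003 * stream) mod (2^31 - 1)`.
#'
#' @param seed Base integer seed.
#' @param stream Non-negative stream index.
#' @return Integer seed.
#' @export
split_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %% 2147483647)
}

## Evaluate expr with a local seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Fix eigenvector/loading signs: largest-|weight| entry positive.
fix_signs <- function(v) {
  apply(v, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) s <- 1
    col * s
  })
}
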