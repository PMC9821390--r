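#' Partitioned asymptotic covariance matrix
#'
#' A `(p+q) x (p+q)` symmetric positive semi-definite matrix on the
#' `sqrt(n)` (asymptotic) scale, partitioned into theta/eta blocks. This
#' container holds the limiting covariances of all estimators in the package
#' (the plug-in, two-step and summary-combination matrices as well as the
#' current-study sandwich).
#'
#' @param mat numeric `(p+q) x (p+q)` matrix; symmetrized internally, an error
#'   is raised if asymmetry exceeds `1e-8` relative to its magnitude or the
#'   minimum eigenvalue is below `-1e-8 * trace`.
#' @param p,q block dimensions.
#' @return An object of class `"partitioned_cov"`.
#' @seealso [pc_block()], [per_study_scale()], [loewner_leq()]
#' @export
partitioned_cov <- function(mat, p, q) {
  mat <- as.matrix(mat)
  p <- as.integer(p); q <- as.integer(q)
  if (nrow(mat) != p + q || ncol(mat) != p + q)
    stop("matrix must be ", p + q, " x ", p + q, call. = FALSE)
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat))))
    stop("matrix is not symmetric", call. = FALSE)
  mat <- sym(mat)
  tr <- sum(diag(mat))
  ev_min <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(tr, 1))
    stop("matrix is not positive semi-definite (min eigenvalue ", format(ev_min), ")",
         call. = FALSE)
  dimnames(mat) <- rep(list(c(sprintf("theta.%d", seq_len(p)),
                              sprintf("eta.%d", seq_len(q)))), 2)
  structure(list(full = mat, p = p, q = q), class = "partitioned_cov")
}

#' Extract a block of a partitioned covariance
#'
#' @param x a [partitioned_cov()] object.
#' @param which one of `"tt"` (theta-theta), `"te"` (theta-eta), `"et"`,
#'   `"ee"` (eta-eta) or `"full"`.
#' @return A numeric matrix.
#' @export
pc_block <- function(x, which = c("tt", "te", "et", "ee", "full")) {
  stopifnot(inherits(x, "partitioned_cov"))
  which <- match.arg(which)
  it <- seq_len(x$p); ie <- x$p + seq_len(x$q)
  switch(which,
         tt = x$full[it, it, drop = FALSE],
         te = x$full[it, ie, drop = FALSE],
         et = x$full[ie, it, drop = FALSE],
         ee = x$full[ie, ie, drop = FALSE],
         full = x$full)
}

#' @export
as.matrix.partitioned_cov <- function(x, ...) x$full

#' @export
print.partitioned_cov <- function(x, digits = 4, ...) {
  cat("Partitioned asymptotic covariance (sqrt(n) scale), p =", x$p, ", q =", x$q, "\n")
  print(round(x$full, digits))
  invisible(x)
}

#' Rescale an asymptotic covariance to the per-study scale
#'
#' Asymptotic covariances in this package are stated on the `sqrt(n)` scale;
#' the finite-sample covariance of the estimator itself is obtained by
#' dividing every entry by the current-study size.
#'
#' @param cov a matrix or [partitioned_cov()].
#' @param n current-study sample size.
#' @return A numeric matrix, `cov / n`.
#' @export
per_study_scale <- function(cov, n) {
  stopifnot(n >= 1)
  if (inherits(cov, "partitioned_cov")) cov <- cov$full
  as.matrix(cov) / n
}

#' Loewner-order comparison of two symmetric matrices
#'
#' Tests `V1` \\eqn{\\preceq} `V2`, i.e. whether `V2 - V1` is positive
#' semi-definite, with relative numerical slack: the comparison holds when the
#' smallest eigenvalue of the (symmetrized) difference is at least
#' `-tol * trace(V2)`. A smaller matrix in this order means a uniformly more
#' efficient estimator.
#'
#' @param V1,V2 symmetric matrices (or [partitioned_cov()] objects) of equal
#'   dimension.
#' @param tol relative tolerance.
#' @return A list with `leq` (logical) and `min_eig` (smallest eigenvalue of
#'   `V2 - V1`).
#' @examples
#' loewner_leq(diag(2), 2 * diag(2))$leq
#' @export
loewner_leq <- function(V1, V2, tol = 1e-8) {
  if (inherits(V1, "partitioned_cov")) V1 <- V1$full
  if (inherits(V2, "partitioned_cov")) V2 <- V2$full
  V1 <- as.matrix(V1); V2 <- as.matrix(V2)
  if (!all(dim(V1) == dim(V2))) stop("dimension mismatch", call. = FALSE)
  for (V in list(V1, V2))
    if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
      stop("inputs must be symmetric", call. = FALSE)
  d <- sym(V2 - V1)
  min_eig <- min(eigen(d, symmetric = TRUE, only.values = TRUE)$values)
  list(leq = min_eig >= -tol * max(sum(diag(V2)), 1), min_eig = min_eig)
}
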