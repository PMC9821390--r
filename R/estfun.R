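#' Declare a pair of unbiased estimating functions
#'
#' Wraps the user-supplied per-observation estimating functions. `psi` is an
#' estimating function for the current-study parameter `theta` given the
#' nuisance vector `eta` (e.g. the score for `theta`); the optional `gamma`
#' estimates `eta` given `theta` and is required for two-step and augmented
#' analyses, where `theta` and `eta` are jointly identified by the data.
#'
#' Both functions are called as `f(theta, eta, y)`. In the default
#' (per-observation) form `y` is a one-row data frame and the value is a
#' numeric vector of length `p` (for `psi`) or `q` (for `gamma`). With
#' `vectorized = TRUE` the functions receive the full data frame and must
#' return an `n x p` (resp. `n x q`) matrix — much faster in R and used by all
#' built-in models.
#'
#' @param psi per-observation estimating function for `theta`.
#' @param gamma optional per-observation estimating function for `eta`.
#' @param p,q dimensions of `theta` and `eta`.
#' @param vectorized logical; do `psi`/`gamma` operate on the whole data frame?
#' @return An object of class `"estfun"`.
#' @examples
#' # mean of y with two known nuisance offsets: psi = y - eta1 - eta2 - theta
#' ef <- estfun(function(theta, eta, y) y$y - eta[1] - eta[2] - theta,
#'              p = 1, q = 2)
#' @export
estfun <- function(psi, gamma = NULL, p, q, vectorized = FALSE) {
  stopifnot(is.function(psi), is.null(gamma) || is.function(gamma),
            p >= 1, q >= 1)
  structure(list(psi = psi, gamma = gamma, p = as.integer(p),
                 q = as.integer(q), vectorized = isTRUE(vectorized)),
            class = "estfun")
}

#' @export
print.estfun <- function(x, ...) {
  cat("Estimating functions: p =", x$p, "(theta), q =", x$q, "(eta);",
      if (is.null(x$gamma)) "psi only (Type I capable)" else "psi and gamma (Type II capable)",
      "\n")
  invisible(x)
}

# n x d matrix of per-observation values of f at (theta, eta)
ef_values <- function(f, d, ef, theta, eta, data) {
  n <- nrow(data)
  if (ef$vectorized) {
    out <- f(theta, eta, data)
    out <- matrix(as.numeric(out), nrow = n)
  } else {
    out <- t(vapply(seq_len(n),
                    function(i) as.numeric(f(theta, eta, data[i, , drop = FALSE])),
                    numeric(d)))
  }
  if (ncol(out) != d)
    stop("estimating function returned length ", ncol(out), ", expected ", d,
         call. = FALSE)
  bad <- which(!stats::complete.cases(out) | rowSums(!is.finite(out)) > 0)
  if (length(bad))
    stop("non-finite estimating-function value at observation ", bad[1L],
         call. = FALSE)
  out
}

psi_values <- function(ef, theta, eta, data) ef_values(ef$psi, ef$p, ef, theta, eta, data)
gamma_values <- function(ef, theta, eta, data) {
  if (is.null(ef$gamma)) stop("estimating function has no 'gamma' component", call. = FALSE)
  ef_values(ef$gamma, ef$q, ef, theta, eta, data)
}

# averaged estimating equations
Psi_bar <- function(ef, theta, eta, data) colMeans(psi_values(ef, theta, eta, data))
Gamma_bar <- function(ef, theta, eta, data) colMeans(gamma_values(ef, theta, eta, data))

#' Empirical Jacobians and meat matrix of an estimating function
#'
#' Computes the sample analogues of the limit matrices entering the sandwich
#' covariance: `D_theta` (the p x p derivative of the averaged `psi` in
#' `theta`), `D_eta` (p x q, in `eta`), the per-historical-study column blocks
#' `D_blocks` of `D_eta`, and the "meat" matrix, the sample average of
#' `psi psi^T`. Population expectations are replaced by sample averages at the
#' plugged-in `(theta, eta)`; derivatives use central finite differences, so
#' differentiating the average equals averaging per-observation derivatives.
#'
#' @param ef an [estfun()] object.
#' @param data data frame of current-study observations.
#' @param theta,eta evaluation point.
#' @param q_splits integer vector partitioning the `q` columns of `D_eta` into
#'   per-study blocks; must sum to `q`. Default: a single block.
#' @return An object of class `"jacobian_set"`: a list with `D_theta`, `D_eta`,
#'   `D_blocks`, `meat`, `p`, `q`, `n`.
#' @export
estimate_jacobians <- function(ef, data, theta, eta, q_splits = NULL) {
  stopifnot(inherits(ef, "estfun"))
  if (nrow(data) < 1) stop("'data' is empty", call. = FALSE)
  theta <- as.numeric(theta); eta <- as.numeric(eta)
  if (length(theta) != ef$p || length(eta) != ef$q)
    stop("theta/eta dimensions do not match the estimating function", call. = FALSE)
  q_splits <- as.integer(q_splits %||% ef$q)
  if (sum(q_splits) != ef$q)
    stop("'q_splits' must sum to q = ", ef$q, call. = FALSE)

  vals <- psi_values(ef, theta, eta, data)
  meat <- sym(crossprod(vals) / nrow(data))

  D_theta <- num_jacobian(function(th) Psi_bar(ef, th, eta, data), theta)
  D_eta <- num_jacobian(function(et) Psi_bar(ef, theta, et, data), eta)
  if (rcond(D_theta) < .Machine$double.eps * 1e2)
    stop("D_theta is numerically singular: theta is not identified by psi at this point",
         call. = FALSE)
  ends <- cumsum(q_splits)
  starts <- c(1L, head(ends, -1L) + 1L)
  D_blocks <- lapply(seq_along(q_splits),
                     function(j) D_eta[, starts[j]:ends[j], drop = FALSE])

  structure(list(D_theta = D_theta, D_eta = D_eta, D_blocks = D_blocks,
                 meat = meat, p = ef$p, q = ef$q, n = nrow(data)),
            class = "jacobian_set")
}

# sandwich of the stacked (psi, gamma) system at (theta, eta): the sqrt(n)-scale
# covariance Upsilon of the joint first-step estimator
joint_sandwich <- function(ef, data, theta, eta) {
  if (is.null(ef$gamma))
    stop("joint sandwich requires a 'gamma' estimating function", call. = FALSE)
  vals <- cbind(psi_values(ef, theta, eta, data),
                gamma_values(ef, theta, eta, data))
  meat <- sym(crossprod(vals) / nrow(data))
  omega <- c(theta, eta)
  Fj <- function(w) c(Psi_bar(ef, w[seq_len(ef$p)], w[-seq_len(ef$p)], data),
                      Gamma_bar(ef, w[seq_len(ef$p)], w[-seq_len(ef$p)], data))
  D <- num_jacobian(Fj, omega)
  if (rcond(D) < .Machine$double.eps * 1e2)
    stop("joint Jacobian of (psi, gamma) is singular: (theta, eta) not jointly ",
         "identified; consider a Type I analysis", call. = FALSE)
  Di <- solve(D)
  partitioned_cov(sym(Di %*% meat %*% t(Di)), p = ef$p, q = ef$q)
}
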