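#' Current-study summary statistics
#'
#' The "coarsened data" interface: point estimates from the current study
#' together with their joint asymptotic covariance and the sample size. Used
#' by the summary-combination estimator when the raw data are unavailable.
#'
#' @param theta,eta current-study estimates of the parameter of interest and
#'   the nuisance vector.
#' @param upsilon `(p+q) x (p+q)` covariance of `(theta, eta)`; a matrix or
#'   [partitioned_cov()]. With `scale = "asymptotic"` (default) it is on the
#'   `sqrt(n)` scale; with `scale = "finite"` it is the estimator covariance
#'   and is multiplied by `n` internally.
#' @param n current-study sample size.
#' @param scale interpretation of `upsilon`.
#' @return An object of class `"current_summary"`.
#' @export
current_summary <- function(theta, eta, upsilon, n,
                            scale = c("asymptotic", "finite")) {
  scale <- match.arg(scale)
  theta <- as.numeric(theta); eta <- as.numeric(eta)
  p <- length(theta); q <- length(eta)
  if (n < 1) stop("'n' must be a positive integer", call. = FALSE)
  if (!inherits(upsilon, "partitioned_cov")) {
    upsilon <- as.matrix(upsilon)
    if (scale == "finite") upsilon <- upsilon * n
    upsilon <- partitioned_cov(upsilon, p, q)
  } else if (upsilon$p != p || upsilon$q != q) {
    stop("'upsilon' block dimensions do not match (theta, eta)", call. = FALSE)
  }
  check_spd(upsilon$full, "upsilon")
  structure(list(theta = theta, eta = eta, upsilon = upsilon,
                 n = as.integer(n), p = p, q = q),
            class = "current_summary")
}

#' @export
print.current_summary <- function(x, ...) {
  cat("Current-study summary: n =", x$n, "\n")
  cat("theta:", paste(format(x$theta, digits = 4), collapse = " "), "\n")
  cat("eta:  ", paste(format(x$eta, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Asymptotic covariance of the Type-I plug-in estimator
#'
#' The limiting covariance of `sqrt(n) * (theta_A - theta0, eta_A - eta0)`
#' when the nuisance parameters are fixed at their historical estimates:
#' \deqn{A_{\theta\theta} = D_\theta^{-1}[\Sigma_\psi +
#'   \rho D_\eta \Sigma D_\eta^T] D_\theta^{-T}, \quad
#'   A_{\theta\eta} = -\rho D_\theta^{-1} D_\eta \Sigma, \quad
#'   A_{\eta\eta} = \rho\Sigma.}
#' The additive term \eqn{\rho D_\eta \Sigma D_\eta^T} is the plug-in penalty
#' for substituting estimates for the true nuisance values; it is returned in
#' the `"penalty"` attribute and vanishes as `rho -> 0` (historical data much
#' larger than current).
#'
#' @param jac a `"jacobian_set"` from [estimate_jacobians()].
#' @param hist a [historical_set()].
#' @param rho limiting sampling ratio `n/m` (> 0).
#' @return A [partitioned_cov()] with attribute `"penalty"` (p x p matrix).
#' @export
avar_type_a <- function(jac, hist, rho) {
  stopifnot(inherits(jac, "jacobian_set"), inherits(hist, "historical_set"), rho > 0)
  if (jac$q != hist$q) stop("q mismatch between Jacobians and historical set", call. = FALSE)
  Dti <- inv(jac$D_theta, "D_theta")
  penalty <- rho * jac$D_eta %*% hist$Sigma %*% t(jac$D_eta)
  A_tt <- sym(Dti %*% (jac$meat + penalty) %*% t(Dti))
  A_te <- -rho * Dti %*% jac$D_eta %*% hist$Sigma
  A_ee <- rho * hist$Sigma
  out <- partitioned_cov(rbind(cbind(A_tt, A_te), cbind(t(A_te), A_ee)),
                         p = jac$p, q = jac$q)
  attr(out, "penalty") <- sym(penalty)
  out
}

#' Asymptotic covariance of the Type-II two-step estimator
#'
#' Identical in structure to [avar_type_a()] except that the historical
#' covariance `rho * Sigma` is everywhere replaced by the pooled-precision
#' kernel `K = (Upsilon_ee^-1 + (rho Sigma)^-1)^-1`, reflecting that the
#' nuisance parameters are re-estimated from the current data and pooled with
#' the historical estimates.
#'
#' @param jac a `"jacobian_set"` for `psi` at the two-step solution.
#' @param upsilon [partitioned_cov()] of the first-step (current-data-only)
#'   estimator.
#' @param hist a [historical_set()].
#' @param rho limiting sampling ratio `n/m`.
#' @return A [partitioned_cov()].
#' @export
avar_type_b <- function(jac, upsilon, hist, rho) {
  stopifnot(inherits(jac, "jacobian_set"), inherits(upsilon, "partitioned_cov"),
            inherits(hist, "historical_set"), rho > 0)
  K <- pooled_kernel(pc_block(upsilon, "ee"), rho * hist$Sigma)
  Dti <- inv(jac$D_theta, "D_theta")
  B_tt <- sym(Dti %*% (jac$meat + jac$D_eta %*% K %*% t(jac$D_eta)) %*% t(Dti))
  B_te <- -Dti %*% jac$D_eta %*% K
  partitioned_cov(rbind(cbind(B_tt, B_te), cbind(t(B_te), K)),
                  p = jac$p, q = jac$q)
}

#' Asymptotic covariance of the summary-combination estimator
#'
#' Computed by two algebraically equivalent routes and cross-checked: (i) as
#' `M V M^T` with `V = BlockDiag(Upsilon, rho * Sigma)` and
#' `M = [I, -R W2, R W2; 0, W1, W2]`, `R = Upsilon_te Upsilon_ee^-1`; and (ii)
#' via the closed-form blocks
#' \deqn{C_{\theta\theta} = \Upsilon_{\theta\theta} -
#'   \Upsilon_{\theta\eta}\Upsilon_{\eta\eta}^{-1} K (\rho\Sigma)^{-1}
#'   \Upsilon_{\theta\eta}^T, \quad
#'   C_{\theta\eta} = \Upsilon_{\theta\eta}\Upsilon_{\eta\eta}^{-1}K, \quad
#'   C_{\eta\eta} = K,}
#' with `K` the pooled kernel. Disagreement beyond `1e-10` (relative) raises an
#' error, flagging an implementation bug.
#'
#' @param upsilon [partitioned_cov()] of the current-study estimator.
#' @param hist a [historical_set()].
#' @param rho limiting sampling ratio `n/m`.
#' @return A [partitioned_cov()].
#' @export
avar_type_c <- function(upsilon, hist, rho) {
  stopifnot(inherits(upsilon, "partitioned_cov"), inherits(hist, "historical_set"),
            rho > 0)
  p <- upsilon$p; q <- upsilon$q
  Uee <- pc_block(upsilon, "ee")
  Ute <- pc_block(upsilon, "te")
  Uee_inv <- inv(Uee, "Upsilon_ee")
  rSig <- rho * hist$Sigma
  rSig_inv <- inv(rSig, "rho * Sigma")
  K <- pooled_kernel(Uee, rSig)
  # route 1: closed-form blocks
  C_tt <- pc_block(upsilon, "tt") - Ute %*% Uee_inv %*% K %*% rSig_inv %*% t(Ute)
  C_te <- Ute %*% Uee_inv %*% K
  C1 <- rbind(cbind(sym(C_tt), C_te), cbind(t(C_te), K))
  # route 2: M V M^T with the limiting GLS weights W1 = K Uee^-1, W2 = K (rho Sigma)^-1
  W1 <- K %*% Uee_inv
  W2 <- K %*% rSig_inv
  R <- Ute %*% Uee_inv
  M <- rbind(cbind(diag(p), -R %*% W2, R %*% W2),
             cbind(matrix(0, q, p), W1, W2))
  V <- block_diag(list(upsilon$full, rSig))
  C2 <- M %*% V %*% t(M)
  if (max(abs(C1 - C2)) > 1e-10 * max(1, max(abs(C1))))
    stop("internal disagreement between the closed-form and M V M^T routes ",
         "for the summary-combination covariance (max diff ",
         format(max(abs(C1 - C2))), "); this flags an implementation bug",
         call. = FALSE)
  partitioned_cov(sym(C1), p = p, q = q)
}

#' Delta-method variance of a functional of the parameters
#'
#' For a differentiable map `phi` of the stacked parameter `(theta, eta)`,
#' returns `grad(phi) %*% cov %*% t(grad(phi))` with a central
#' finite-difference gradient.
#'
#' @param phi function mapping a `(p+q)`-vector to an s-vector.
#' @param omega evaluation point (length `p+q`).
#' @param cov [partitioned_cov()] or `(p+q) x (p+q)` matrix.
#' @return An `s x s` matrix.
#' @export
delta_variance <- function(phi, omega, cov) {
  if (inherits(cov, "partitioned_cov")) cov <- cov$full
  omega <- as.numeric(omega)
  if (length(omega) != nrow(cov)) stop("dimension mismatch", call. = FALSE)
  G <- num_jacobian(function(w) as.numeric(phi(w)), omega)
  sym(G %*% cov %*% t(G))
}

#' Scalar efficiency of combining with a historical estimate
#'
#' In the bivariate case (`p = q = 1`) the asymptotic relative efficiency of
#' the summary-combination estimator to the current-only estimator is
#' `1 - w2 * r^2`, where `r` is the asymptotic correlation between the current
#' estimates of theta and eta and `w2` the limiting historical pooling weight.
#' The ARE is at most one (no covariance, no gain) and at least `1 - r^2`
#' (infinitely informative historical data).
#'
#' @param upsilon_tt,upsilon_te,upsilon_ee entries of the 2 x 2 current-study
#'   asymptotic covariance.
#' @param sigma2 `sqrt(m)`-scale historical variance of `eta_hat`.
#' @param gamma limiting ratio `n / (n + m)` in (0, 1).
#' @return A list of class `"scalar_case"`: `r`, `w2`, `are`, `c_tt`
#'   (the combined estimator's asymptotic theta-variance).
#' @export
scalar_are <- function(upsilon_tt, upsilon_te, upsilon_ee, sigma2, gamma) {
  stopifnot(upsilon_tt > 0, upsilon_ee > 0, sigma2 > 0, gamma > 0, gamma < 1)
  r <- upsilon_te / sqrt(upsilon_tt * upsilon_ee)
  if (abs(r) > 1) stop("invalid covariance: |correlation| > 1", call. = FALSE)
  w2 <- ((1 - gamma) / sigma2) / (gamma / upsilon_ee + (1 - gamma) / sigma2)
  are <- 1 - w2 * r^2
  structure(list(r = r, w2 = w2, are = are, c_tt = upsilon_tt * are),
            class = "scalar_case")
}

#' Sufficient conditions for the two-step estimator to dominate
#'
#' Evaluates, at the sample level, the two sufficient conditions under which
#' the two-step estimator's covariance is Loewner-below the
#' summary-combination estimator's: (17) the sensitivity matrices satisfy
#' `D_theta(psi)^-1 D_eta(psi) <= D_theta(lambda)^-1 D_eta(lambda)`
#' component-wise, and (18) the known-nuisance sandwich core of `psi` is
#' Loewner-below that of `lambda`.
#'
#' @param jac_psi,jac_lambda `"jacobian_set"` objects for the two estimating
#'   functions, evaluated at the same point.
#' @param tol numerical slack for the component-wise comparison.
#' @return A list with `cond17`, `cond18` (logicals), `implies_b_leq_c`
#'   (their conjunction) and the two sandwich cores.
#' @export
check_comparison_conditions <- function(jac_psi, jac_lambda, tol = 1e-8) {
  stopifnot(inherits(jac_psi, "jacobian_set"), inherits(jac_lambda, "jacobian_set"))
  if (jac_psi$p != jac_lambda$p || jac_psi$q != jac_lambda$q)
    stop("dimension mismatch between the two Jacobian sets", call. = FALSE)
  S_psi <- solve(jac_psi$D_theta, jac_psi$D_eta)
  S_lam <- solve(jac_lambda$D_theta, jac_lambda$D_eta)
  scale <- max(1, max(abs(S_lam)))
  cond17 <- all(S_psi <= S_lam + tol * scale)
  core <- function(j) {
    Di <- inv(j$D_theta, "D_theta")
    sym(Di %*% j$meat %*% t(Di))
  }
  core_psi <- core(jac_psi)
  core_lam <- core(jac_lambda)
  cond18 <- loewner_leq(core_psi, core_lam, tol)$leq
  list(cond17 = cond17, cond18 = cond18,
       implies_b_leq_c = cond17 && cond18,
       core_psi = core_psi, core_lambda = core_lam)
}
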