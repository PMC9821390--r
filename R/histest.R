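#' Fit a model using historical parameter estimates
#'
#' The package's central fitting function. Four estimation strategies are
#' available, depending on what the current study identifies and on whether
#' raw data are at hand:
#'
#' * `kind = "A"` (Type-I plug-in): the nuisance vector is fixed at the
#'   stacked historical estimate and `psi(theta, eta_hat) = 0` is solved for
#'   `theta` alone. Used when the current data do not identify `eta`.
#' * `kind = "B"` (Type-II two-step): step 1 solves `psi = gamma = 0` jointly
#'   for `(theta_tilde, eta_tilde)` and estimates their sandwich covariance;
#'   step 2 pools `eta_tilde` with the historical estimate by precision
#'   weighting ([pool_eta()]); step 3 re-solves `psi(theta, eta_bar) = 0`.
#' * `kind = "C"` (summary combination): requires only `current`, a
#'   [current_summary()]; the point estimate is
#'   `theta_tilde - Upsilon_te Upsilon_ee^-1 (eta_tilde - eta_bar)`, a
#'   regression adjustment toward the pooled nuisance estimate.
#' * `kind = "augmented"`: solves the single augmented system
#'   `psi(theta, eta) = 0`, `n * gamma_bar(theta, eta) +
#'   m * Sigma_hat^-1 (eta_hat - eta) = 0`; first-order equivalent to `"B"`.
#'
#' Requesting a Type-I analysis when `gamma` is available (so a Type-II
#' analysis is possible) triggers a warning: re-estimating the nuisance
#' parameters from the current data is always asymptotically at least as
#' efficient.
#'
#' @param ef an [estfun()] object (required for kinds `"A"`, `"B"`,
#'   `"augmented"`; kinds `"B"` and `"augmented"` need its `gamma`).
#' @param data data frame of current-study observations (not used by `"C"`).
#' @param historical a [historical_set()].
#' @param kind estimator: `"B"` (default), `"A"`, `"C"` or `"augmented"`.
#' @param current a [current_summary()], required for `kind = "C"` (and
#'   accepted for `"B"` in place of running step 1).
#' @param init optional starting value(s) for the root solves; defaults to the
#'   step-1/joint solution when available, else zeros.
#' @param upsilon optional [partitioned_cov()] overriding the step-1 sandwich
#'   estimate (e.g. a model-based covariance when the residual variance is
#'   known).
#' @param control list of solver settings passed to [solve_root()]
#'   (`tol`, `max_iter`).
#' @return An object of class `"histest"`: a list with `theta`, `eta`, `kind`,
#'   `avar` (a [partitioned_cov()] on the `sqrt(n)` scale), `n`, `m`, `rho`,
#'   `gamma`, `pooled` (for kinds B/C/augmented), `solver` diagnostics and the
#'   matched `call`. Methods: [print.histest()], [summary.histest()],
#'   [coef.histest()], [vcov.histest()], [confint.histest()].
#' @examples
#' ## Type-I: all current observations receive the treatment combination
#' hist <- historical_set(list(historical_study(
#'   c(2, 3, 2), diag(0.01, 3), m = 300, label = "S12")))
#' ef <- estfun(function(theta, eta, y) y$y - sum(eta) - theta,
#'              p = 1, q = 3, vectorized = TRUE)
#' dat <- data.frame(y = 10 + rnorm(50, sd = 0.2))
#' fit <- histest(ef, dat, hist, kind = "A")
#' coef(fit)
#' @export
histest <- function(ef = NULL, data = NULL, historical,
                    kind = c("B", "A", "C", "augmented"),
                    current = NULL, init = NULL, upsilon = NULL,
                    control = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(historical, "historical_set"))
  tol <- control$tol %||% 1e-10
  max_iter <- control$max_iter %||% 100
  cl <- match.call()

  out <- switch(kind,
    A = estimate_type_a(ef, data, historical, init, tol, max_iter),
    B = estimate_type_b(ef, data, historical, init, upsilon, tol, max_iter,
                        current = current),
    C = estimate_type_c(current, historical),
    augmented = estimate_augmented(ef, data, historical, init, upsilon,
                                   tol, max_iter))
  out$call <- cl
  out
}

new_histest <- function(theta, eta, kind, avar, n, m, solver = NULL,
                        pooled = NULL) {
  structure(list(theta = as.numeric(theta), eta = as.numeric(eta),
                 kind = kind, avar = avar, n = n, m = m,
                 rho = n / m, gamma = n / (n + m),
                 pooled = pooled, solver = solver, call = NULL),
            class = "histest")
}

#' Type-I plug-in estimator
#'
#' Solves `psi(theta, eta_hat) = 0` with the nuisance vector fixed at the
#' stacked historical estimate; see [histest()] (`kind = "A"`). Exposed
#' directly for programmatic use.
#'
#' @inheritParams histest
#' @param tol,max_iter solver settings.
#' @return A `"histest"` object with `kind = "A"`.
#' @export
estimate_type_a <- function(ef, data, historical, init = NULL,
                            tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(ef, "estfun"), is.data.frame(data),
            inherits(historical, "historical_set"))
  if (ef$q != historical$q)
    stop("eta dimension of the estimating function (", ef$q,
         ") does not match the historical set (", historical$q, ")", call. = FALSE)
  if (!is.null(ef$gamma))
    warning("a 'gamma' estimating function is available: the data likely ",
            "identify eta, and a Type II analysis (kind = \"B\") is ",
            "asymptotically at least as efficient as this Type I analysis",
            call. = FALSE)
  eta_hat <- as.numeric(historical$eta_hat)
  init <- as.numeric(init %||% rep(0, ef$p))
  sol <- solve_root(function(th) Psi_bar(ef, th, eta_hat, data), init,
                    tol = tol, max_iter = max_iter)
  jac <- estimate_jacobians(ef, data, sol$root, eta_hat,
                            q_splits = historical$q_splits)
  n <- nrow(data)
  avar <- avar_type_a(jac, historical, rho = n / historical$m)
  new_histest(sol$root, eta_hat, "A", avar, n, historical$m, solver = sol)
}

#' Type-II two-step estimator
#'
#' Joint first-step solve, precision-weighted pooling, and re-solve of `psi`
#' at the pooled nuisance estimate; see [histest()] (`kind = "B"`).
#'
#' @inheritParams histest
#' @param tol,max_iter solver settings.
#' @return A `"histest"` object with `kind = "B"`.
#' @export
estimate_type_b <- function(ef, data, historical, init = NULL, upsilon = NULL,
                            tol = 1e-10, max_iter = 100, current = NULL) {
  stopifnot(inherits(ef, "estfun"), is.data.frame(data),
            inherits(historical, "historical_set"))
  if (is.null(ef$gamma))
    stop("Type II estimation requires a 'gamma' estimating function", call. = FALSE)
  n <- nrow(data)
  if (is.null(current)) {
    step1 <- joint_solve(ef, data, init, tol, max_iter)
    ups <- upsilon %||% joint_sandwich(ef, data, step1$theta, step1$eta)
    current <- current_summary(step1$theta, step1$eta, ups, n)
    solver1 <- step1$solver
  } else {
    stopifnot(inherits(current, "current_summary"))
    if (!is.null(upsilon)) current$upsilon <- upsilon
    solver1 <- NULL
  }
  pooled <- pool_eta(current, historical)
  sol <- solve_root(function(th) Psi_bar(ef, th, pooled$eta_bar, data),
                    current$theta, tol = tol, max_iter = max_iter)
  jac <- estimate_jacobians(ef, data, sol$root, pooled$eta_bar,
                            q_splits = historical$q_splits)
  avar <- avar_type_b(jac, current$upsilon, historical, rho = n / historical$m)
  out <- new_histest(sol$root, pooled$eta_bar, "B", avar, n, historical$m,
                     solver = sol, pooled = pooled)
  out$step1 <- current
  out$solver1 <- solver1
  out
}

joint_solve <- function(ef, data, init, tol, max_iter) {
  init <- as.numeric(init %||% rep(0, ef$p + ef$q))
  it <- seq_len(ef$p)
  sol <- tryCatch(
    solve_root(function(w) c(Psi_bar(ef, w[it], w[-it], data),
                             Gamma_bar(ef, w[it], w[-it], data)),
               init, tol = tol, max_iter = max_iter),
    histest_solver_error = function(e) {
      e$message <- paste0(e$message,
        " [joint (psi, gamma) solve failed; if (theta, eta) is not jointly ",
        "identified by the data, use a Type I analysis]")
      stop(e)
    })
  list(theta = sol$root[it], eta = sol$root[-it], solver = sol)
}

#' Summary-combination estimator
#'
#' Combines current-study summary statistics with historical estimates when
#' the raw data are unavailable; see [histest()] (`kind = "C"`). No gain over
#' the current-only estimator is possible when the theta/eta covariance block
#' is zero.
#'
#' @param current a [current_summary()].
#' @param historical a [historical_set()].
#' @return A `"histest"` object with `kind = "C"`.
#' @export
estimate_type_c <- function(current, historical) {
  stopifnot(inherits(current, "current_summary"),
            inherits(historical, "historical_set"))
  pooled <- pool_eta(current, historical)
  R <- pc_block(current$upsilon, "te") %*% inv(pc_block(current$upsilon, "ee"),
                                               "Upsilon_ee")
  theta_c <- current$theta - as.numeric(R %*% (current$eta - pooled$eta_bar))
  avar <- avar_type_c(current$upsilon, historical,
                      rho = current$n / historical$m)
  new_histest(theta_c, pooled$eta_bar, "C", avar, current$n, historical$m,
              pooled = pooled)
}

#' Augmented-equation estimator
#'
#' Jointly solves `psi(theta, eta) = 0` together with the historical-augmented
#' nuisance equations `n * gamma_bar(theta, eta) + m * Sigma_hat^-1
#' (eta_hat - eta) = 0` (a pseudo-score for the historical normal limit).
#' First-order equivalent to the two-step estimator; the reported asymptotic
#' covariance is therefore the Type-II matrix evaluated at the solution.
#'
#' @inheritParams histest
#' @param tol,max_iter solver settings.
#' @return A `"histest"` object with `kind = "augmented"`.
#' @export
estimate_augmented <- function(ef, data, historical, init = NULL,
                               upsilon = NULL, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(ef, "estfun"), is.data.frame(data),
            inherits(historical, "historical_set"))
  if (is.null(ef$gamma))
    stop("the augmented system requires a 'gamma' estimating function", call. = FALSE)
  if (ef$q != historical$q)
    stop("eta dimension mismatch with the historical set", call. = FALSE)
  n <- nrow(data)
  m <- historical$m
  Sig_inv <- inv(historical$Sigma, "Sigma")
  eta_hat <- as.numeric(historical$eta_hat)
  it <- seq_len(ef$p)
  Faug <- function(w) {
    th <- w[it]; et <- w[-it]
    c(Psi_bar(ef, th, et, data),
      Gamma_bar(ef, th, et, data) + (m / n) * as.numeric(Sig_inv %*% (eta_hat - et)))
  }
  init <- as.numeric(init %||% rep(0, ef$p + ef$q))
  sol <- solve_root(Faug, init, tol = tol, max_iter = max_iter)
  theta_aug <- sol$root[it]; eta_aug <- sol$root[-it]
  jac <- estimate_jacobians(ef, data, theta_aug, eta_aug,
                            q_splits = historical$q_splits)
  ups <- upsilon %||% joint_sandwich(ef, data, theta_aug, eta_aug)
  avar <- avar_type_b(jac, ups, historical, rho = n / m)
  new_histest(theta_aug, eta_aug, "augmented", avar, n, m, solver = sol)
}

kind_label <- function(kind) switch(kind,
  A = "Type I plug-in (nuisance fixed at historical estimates)",
  B = "Type II two-step (pooled nuisance re-estimation)",
  C = "summary combination (coarsened current data)",
  augmented = "augmented estimating equations (first-order equivalent to Type II)")

#' @export
print.histest <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat("Estimator:", kind_label(x$kind), "\n")
  cat("n =", x$n, ", m =", x$m, ", rho = n/m =", format(x$rho, digits = digits), "\n")
  cat("theta:", paste(format(x$theta, digits = digits), collapse = " "), "\n")
  cat("eta:  ", paste(format(x$eta, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.histest <- function(object, ...) {
  stats::setNames(c(object$theta, object$eta),
                  c(sprintf("theta.%d", seq_along(object$theta)),
                    sprintf("eta.%d", seq_along(object$eta))))
}

#' Estimator covariance matrix
#'
#' @param object a `"histest"` fit.
#' @param scale `"finite"` (default) divides the asymptotic covariance by `n`,
#'   giving the covariance of the estimator itself; `"asymptotic"` returns the
#'   `sqrt(n)`-scale matrix.
#' @param ... unused.
#' @return A named covariance matrix.
#' @export
vcov.histest <- function(object, scale = c("finite", "asymptotic"), ...) {
  scale <- match.arg(scale)
  V <- as.matrix(object$avar)
  if (scale == "finite") V <- V / object$n
  V
}

#' @export
summary.histest <- function(object, ...) {
  est <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.histest")
}

#' @export
print.summary.histest <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.histest <- function(object, parm, level = 0.95, ...) {
  est <- coef(object)
  se <- sqrt(diag(vcov(object)))
  if (missing(parm)) parm <- names(est)
  a <- (1 - level) / 2
  zq <- stats::qnorm(1 - a)
  out <- cbind(est[parm] - zq * se[parm], est[parm] + zq * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  out
}

#' Serialize a fit to JSON
#'
#' @param fit a `"histest"` object.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
histest_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "histest"))
  payload <- list(
    kind = fit$kind, theta = fit$theta, eta = fit$eta,
    avar_blocks = list(tt = pc_block(fit$avar, "tt"),
                       te = pc_block(fit$avar, "te"),
                       ee = pc_block(fit$avar, "ee")),
    n = fit$n, m = fit$m, rho = fit$rho,
    solver = if (!is.null(fit$solver))
      list(iterations = fit$solver$iterations, norm = fit$solver$norm))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
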