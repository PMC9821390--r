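#' Solve a smooth system of estimating equations
#'
#' Damped Newton iteration with a central finite-difference Jacobian and a
#' step-halving line search. All estimating-equation systems in this package
#' are smooth and low-dimensional, for which this scheme converges in a
#' handful of iterations (one step, up to tolerance, on affine systems).
#'
#' @param F vector-valued function of a numeric d-vector; a root of `F` is
#'   sought.
#' @param init numeric starting value (finite).
#' @param tol convergence tolerance on the sup-norm of `F`.
#' @param max_iter maximum number of Newton iterations.
#' @param max_halvings maximum step halvings per iteration.
#'
#' @return A list with components `root`, `f_root`, `norm` (sup-norm of `F` at
#'   the root), `iterations` and `converged` (always `TRUE` on return; failure
#'   raises a condition of class `"histest_solver_error"` carrying the last
#'   iterate in its `last` field).
#'
#' @examples
#' solve_root(function(x) x - 3, 0)$root
#' solve_root(function(x) c(x[1]^2 - 4, x[2] - 1), c(1, 0))$root
#' @export
solve_root <- function(F, init, tol = 1e-10, max_iter = 100, max_halvings = 30) {
  x <- as.numeric(init)
  if (!all(is.finite(x))) stop("'init' must be finite", call. = FALSE)
  F_user <- F
  F <- function(z) as.numeric(F_user(z))
  fx <- F(x)
  if (length(fx) != length(x))
    stop("F must map d-vectors to d-vectors (got length ", length(fx),
         " for input of length ", length(x), ")", call. = FALSE)
  nx <- max(abs(fx))
  iter <- 0L
  while (nx > tol && iter < max_iter) {
    iter <- iter + 1L
    J <- num_jacobian(F, x, fx)
    rc <- rcond(J)
    if (!is.finite(rc) || rc < .Machine$double.eps * 1e2)
      solver_fail(sprintf(
        "singular Jacobian at iteration %d (reciprocal condition number %.3g)",
        iter, rc), x, iter)
    step <- solve(J, -fx)
    lambda <- 1
    for (k in seq_len(max_halvings + 1L)) {
      x_new <- x + lambda * step
      f_new <- tryCatch(F(x_new), error = function(e) rep(NaN, length(fx)))
      n_new <- suppressWarnings(max(abs(f_new)))
      if (is.finite(n_new) && n_new < nx) break
      lambda <- lambda / 2
      if (k == max_halvings + 1L)
        solver_fail(sprintf("line search failed at iteration %d (|F| = %.3g)",
                            iter, nx), x, iter)
    }
    x <- x_new; fx <- f_new; nx <- n_new
  }
  if (nx > tol)
    solver_fail(sprintf("no convergence after %d iterations (|F| = %.3g > tol = %.3g)",
                        iter, nx, tol), x, iter)
  list(root = x, f_root = fx, norm = nx, iterations = iter, converged = TRUE)
}

solver_fail <- function(msg, last, iterations) {
  cond <- structure(
    class = c("histest_solver_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), last = last, iterations = iterations))
  stop(cond)
}
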