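# internal numerical helpers

# re-symmetrize after products of inverses; numerical hygiene for Loewner checks
sym <- function(M) (M + t(M)) / 2

# all matrix "inverses" are linear solves
inv <- function(M, what = "matrix") {
  M <- as.matrix(M)
  out <- tryCatch(solve(M, diag(nrow(M))),
                  error = function(e) stop("singular ", what, ": ", conditionMessage(e),
                                           call. = FALSE))
  out
}

# solve (P1^-1 + P2^-1)^-1 style kernels without forming explicit inverses twice
pooled_kernel <- function(V1, V2) {
  sym(inv(inv(V1, "first kernel argument") + inv(V2, "second kernel argument"), "pooled precision"))
}

check_spd <- function(M, what = "covariance", tol = 1e-8) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop(what, " must be square", call. = FALSE)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(what, " is not symmetric", call. = FALSE)
  ev <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(what, " is not positive definite (min eigenvalue ", format(min(ev)), ")",
         call. = FALSE)
  invisible(TRUE)
}

block_diag <- function(blocks) {
  dims <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(dims), sum(dims))
  at <- 0L
  for (B in blocks) {
    idx <- at + seq_len(nrow(B))
    out[idx, idx] <- B
    at <- at + nrow(B)
  }
  out
}

# finite-difference step for the central scheme: h = eps^(1/3) * max(1, |x|)
# balances the O(h^2) truncation and O(eps/h) roundoff errors at ~eps^(2/3)
fd_step <- function(x) .Machine$double.eps^(1/3) * pmax(1, abs(x))

# central finite-difference Jacobian of a vector-valued function
num_jacobian <- function(F, x, f0 = NULL) {
  if (is.null(f0)) f0 <- F(x)
  d <- length(x)
  h <- fd_step(x)
  J <- matrix(NA_real_, length(f0), d)
  for (k in seq_len(d)) {
    xp <- x; xm <- x
    xp[k] <- x[k] + h[k]
    xm[k] <- x[k] - h[k]
    J[, k] <- (F(xp) - F(xm)) / (2 * h[k])
  }
  if (!all(is.finite(J))) stop("non-finite numerical derivative", call. = FALSE)
  J
}

`%||%` <- function(a, b) if (is.null(a)) b else a
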