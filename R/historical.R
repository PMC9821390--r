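#' A single historical study
#'
#' Represents one previously published estimate of a (block of the) nuisance
#' parameter: the point estimate, its *finite-sample* covariance (squared
#' standard errors and covariances, as reported in publications) and the study
#' sample size. The `sqrt(m_j)`-scale asymptotic covariance used by the theory
#' is derived internally as `m_j * cov`.
#'
#' @param estimate numeric vector, the published estimate of this study's
#'   nuisance block.
#' @param cov finite-sample covariance matrix of `estimate` (a single variance
#'   is accepted for scalar estimates).
#' @param m positive integer study size.
#' @param label optional identifier used in error messages.
#' @return An object of class `"historical_study"`.
#' @export
historical_study <- function(estimate, cov, m, label = NULL) {
  estimate <- as.numeric(estimate)
  cov <- as.matrix(cov)
  label <- label %||% "historical study"
  if (length(estimate) != nrow(cov))
    stop(label, ": estimate and covariance dimensions differ", call. = FALSE)
  tryCatch(check_spd(cov, "covariance"),
           error = function(e) stop(label, ": ", conditionMessage(e), call. = FALSE))
  if (m < 1) stop(label, ": 'm' must be a positive integer", call. = FALSE)
  structure(list(estimate = estimate, cov = cov, m = as.integer(m),
                 label = label, q = length(estimate)),
            class = "historical_study")
}

#' Assemble independent historical studies into one stacked set
#'
#' Stacks `K` independent historical estimates into the single nuisance vector
#' `eta_hat` and assembles the block-diagonal `sqrt(m)`-scale covariance
#' `Sigma = BlockDiag(kappa_1 Sigma_1, ..., kappa_K Sigma_K)`, where
#' `kappa_j = m / m_j` are the finite-sample plug-ins for the relative study
#' sizes and `Sigma_j = m_j * cov_j`. Note `kappa_j * Sigma_j = m * cov_j`.
#'
#' @param studies a list of [historical_study()] objects (K >= 1).
#' @return An object of class `"historical_set"` with fields `studies`,
#'   `eta_hat`, `Sigma`, `m`, `kappa`, `q`, `q_splits`.
#' @examples
#' s1 <- historical_study(0.4, 0.02, m = 50, label = "S1")
#' s2 <- historical_study(0.7, 0.02, m = 50, label = "S2")
#' historical_set(list(s1, s2))
#' @export
historical_set <- function(studies) {
  if (inherits(studies, "historical_study")) studies <- list(studies)
  stopifnot(length(studies) >= 1,
            all(vapply(studies, inherits, logical(1), "historical_study")))
  m <- sum(vapply(studies, `[[`, integer(1), "m"))
  kappa <- m / vapply(studies, `[[`, integer(1), "m")
  eta_hat <- unlist(lapply(studies, `[[`, "estimate"), use.names = FALSE)
  Sigma <- block_diag(lapply(studies, function(s) m * s$cov))
  q_splits <- vapply(studies, `[[`, integer(1), "q")
  nm <- unlist(lapply(studies, function(s) {
    nms <- rownames(s$cov) %||% as.character(seq_len(s$q))
    paste(s$label, nms, sep = ".")
  }))
  names(eta_hat) <- nm
  dimnames(Sigma) <- list(nm, nm)
  structure(list(studies = studies, eta_hat = eta_hat, Sigma = Sigma,
                 m = m, kappa = kappa, q = length(eta_hat), q_splits = q_splits),
            class = "historical_set")
}

#' @export
print.historical_set <- function(x, ...) {
  cat("Historical set: K =", length(x$studies), "studies, q =", x$q,
      "parameters, total m =", x$m, "\n")
  cat("eta_hat:", paste(format(x$eta_hat, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Read historical estimates from CSV
#'
#' Expects columns `study_id`, `param_name`, `estimate`, `se`, `m`. An optional
#' companion CSV supplies within-study covariances with columns `study_id`,
#' `param_a`, `param_b`, `cov`; off-diagonal covariances missing from it
#' default to zero with a warning.
#'
#' @param path path to the estimates CSV.
#' @param cov_path optional path to the within-study covariance CSV.
#' @return A [historical_set()].
#' @export
read_historical_csv <- function(path, cov_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "param_name", "estimate", "se", "m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("historical CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  covdf <- if (!is.null(cov_path)) utils::read.csv(cov_path, stringsAsFactors = FALSE)
  studies <- lapply(split(df, factor(df$study_id, levels = unique(df$study_id))),
                    function(s) {
    qj <- nrow(s)
    V <- diag(s$se^2, qj)
    dimnames(V) <- list(s$param_name, s$param_name)
    if (qj > 1) {
      filled <- FALSE
      if (!is.null(covdf)) {
        cs <- covdf[covdf$study_id == s$study_id[1], , drop = FALSE]
        for (i in seq_len(nrow(cs))) {
          a <- cs$param_a[i]; b <- cs$param_b[i]
          if (a %in% s$param_name && b %in% s$param_name) {
            V[a, b] <- V[b, a] <- cs$cov[i]
            filled <- TRUE
          }
        }
      }
      if (!filled)
        warning("study ", s$study_id[1],
                ": no within-study covariances supplied; off-diagonals set to 0",
                call. = FALSE)
    }
    if (length(unique(s$m)) != 1)
      stop("study ", s$study_id[1], ": inconsistent 'm'", call. = FALSE)
    historical_study(stats::setNames(s$estimate, s$param_name), V, s$m[1],
                     label = as.character(s$study_id[1]))
  })
  historical_set(unname(studies))
}

#' Precision-weighted pooling of current and historical nuisance estimates
#'
#' Combines the current-study estimate `eta_tilde` (with `sqrt(n)`-scale
#' covariance block `Upsilon_ee`) and the stacked historical estimate
#' `eta_hat` (with `sqrt(m)`-scale covariance `Sigma`) by generalized least
#' squares:
#' \deqn{\bar\eta = (n\Upsilon_{\eta\eta}^{-1} + m\Sigma^{-1})^{-1}
#'       (n\Upsilon_{\eta\eta}^{-1}\tilde\eta + m\Sigma^{-1}\hat\eta),}
#' the maximum-likelihood combination under normality with known covariances.
#' The associated weight matrices satisfy `W1 + W2 = I`; the pooled
#' `sqrt(n)`-scale covariance is the harmonic-mean kernel
#' `(Upsilon_ee^-1 + (rho Sigma)^-1)^-1` with `rho = n/m`.
#'
#' @param current a [current_summary()] (only its `eta`, `upsilon` eta-block
#'   and `n` are used).
#' @param hist a [historical_set()].
#' @return An object of class `"pooled_eta"`: list with `eta_bar`, `W1`, `W2`,
#'   `gamma` (`n/(n+m)`), `rho` (`n/m`), `cov_block`, `n`, `m`.
#' @export
pool_eta <- function(current, hist) {
  stopifnot(inherits(current, "current_summary"), inherits(hist, "historical_set"))
  if (current$q != hist$q)
    stop("dimension mismatch: current eta has length ", current$q,
         ", stacked historical estimate has length ", hist$q, call. = FALSE)
  n <- current$n; m <- hist$m
  Uee <- pc_block(current$upsilon, "ee")
  Uee_inv <- inv(Uee, "Upsilon_ee")
  Sig_inv <- inv(hist$Sigma, "Sigma")
  gamma <- n / (n + m)
  rho <- n / m
  P <- n * Uee_inv + m * Sig_inv
  eta_bar <- solve(P, n * Uee_inv %*% current$eta + m * Sig_inv %*% hist$eta_hat)
  W1 <- solve(gamma * Uee_inv + (1 - gamma) * Sig_inv, gamma * Uee_inv)
  W2 <- solve(gamma * Uee_inv + (1 - gamma) * Sig_inv, (1 - gamma) * Sig_inv)
  cov_block <- pooled_kernel(Uee, rho * hist$Sigma)
  structure(list(eta_bar = as.numeric(eta_bar), W1 = W1, W2 = W2,
                 gamma = gamma, rho = rho, cov_block = cov_block,
                 n = n, m = m),
            class = "pooled_eta")
}

#' @export
print.pooled_eta <- function(x, ...) {
  cat("Pooled nuisance estimate (n =", x$n, ", m =", x$m,
      ", gamma =", format(x$gamma, digits = 4), ")\n")
  cat("eta_bar:", paste(format(x$eta_bar, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Pool a linear summary of the current data with historical estimates
#'
#' Generalizes [pool_eta()] to the case where the current study observes only
#' a linear image `S` of the nuisance vector, with `E(S) = A eta` and
#' `sqrt(n)`-scale covariance `V`:
#' \deqn{\eta^\dagger = (nA^TV^{-1}A + m\Sigma^{-1})^{-1}
#'       (nA^TV^{-1}S + m\Sigma^{-1}\hat\eta).}
#' With `A = I` and `V = Upsilon_ee` this reduces to [pool_eta()].
#'
#' @param S observed r-vector of current-study summaries.
#' @param A `r x q` design matrix with `E(S) = A eta`.
#' @param V `r x r` covariance of `S` on the `sqrt(n)` scale.
#' @param hist a [historical_set()].
#' @param n current-study size.
#' @return Numeric q-vector `eta_dagger`.
#' @export
pool_linear <- function(S, A, V, hist, n) {
  stopifnot(inherits(hist, "historical_set"), n >= 1)
  S <- as.numeric(S); A <- as.matrix(A); V <- as.matrix(V)
  if (nrow(A) != length(S) || ncol(A) != hist$q || any(dim(V) != length(S)))
    stop("dimension mismatch among S, A, V and the historical set", call. = FALSE)
  Vi <- inv(V, "V")
  Sig_inv <- inv(hist$Sigma, "Sigma")
  P <- n * t(A) %*% Vi %*% A + hist$m * Sig_inv
  if (rcond(P) < .Machine$double.eps * 1e2)
    stop("combined precision matrix is singular", call. = FALSE)
  as.numeric(solve(P, n * t(A) %*% Vi %*% S + hist$m * Sig_inv %*% hist$eta_hat))
}
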