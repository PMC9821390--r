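#' Bliss-independence interaction contrast
#'
#' For two drugs with no-effect probabilities `eta1`, `eta2` and joint
#' no-effect probability `theta`, the drugs are Bliss independent when
#' `theta = eta1 * eta2`. The interaction measure is the log contrast
#' `log(theta) - log(eta1) - log(eta2)`: negative values indicate synergy
#' (`theta < eta1 * eta2`), positive values antagonism.
#'
#' @param theta_hat,eta1_hat,eta2_hat estimated probabilities, all in (0, 1).
#' @return The scalar log contrast.
#' @examples
#' bliss_phi(0.09, 0.3, 0.3)  # exactly independent: 0
#' @export
bliss_phi <- function(theta_hat, eta1_hat, eta2_hat) {
  p <- c(theta_hat, eta1_hat, eta2_hat)
  if (any(p <= 0) || any(p >= 1))
    stop("all probabilities must lie strictly in (0, 1)", call. = FALSE)
  log(theta_hat) - log(eta1_hat) - log(eta2_hat)
}

check_counts <- function(counts) {
  need <- c("n12", "n1", "n2", "m1", "m2")
  counts <- as.list(counts)
  if (!all(need %in% names(counts)))
    stop("'counts' must supply n12, n1, n2, m1, m2", call. = FALSE)
  counts <- lapply(counts[need], as.numeric)
  if (counts$n12 < 1)
    stop("the interaction contrast cannot be estimated unless n12 > 0", call. = FALSE)
  if (counts$n1 < 0 || counts$n2 < 0 || counts$m1 < 1 || counts$m2 < 1)
    stop("invalid arm counts", call. = FALSE)
  counts
}

#' Large-sample variance of the Bliss interaction contrast
#'
#' With independent binomial arms — `n12` current observations on the
#' combination, `n_i` current plus `m_i` historical observations on drug `i` —
#' the delta-method variance of [bliss_phi()] is
#' \deqn{\frac{1}{n_{12}}\frac{1-\theta}{\theta} +
#'       \frac{1}{n_1+m_1}\frac{1-\eta_1}{\eta_1} +
#'       \frac{1}{n_2+m_2}\frac{1-\eta_2}{\eta_2}.}
#'
#' @param counts list or named vector with `n12`, `n1`, `n2`, `m1`, `m2`.
#' @param params list or named vector with `theta`, `eta1`, `eta2`, all in
#'   (0, 1).
#' @return Scalar variance.
#' @export
bliss_variance <- function(counts, params) {
  counts <- check_counts(counts)
  params <- as.list(params)
  p <- c(params$theta, params$eta1, params$eta2)
  if (any(p <= 0) || any(p >= 1))
    stop("all probabilities must lie strictly in (0, 1)", call. = FALSE)
  (1 - p[1]) / p[1] / counts$n12 +
    (1 - p[2]) / p[2] / (counts$n1 + counts$m1) +
    (1 - p[3]) / p[3] / (counts$n2 + counts$m2)
}

#' Wald test of Bliss independence
#'
#' Convenience wrapper combining [bliss_phi()] and [bliss_variance()] (with
#' the plug-in probabilities) into a two-sided Wald test of the null
#' `theta = eta1 * eta2`.
#'
#' @param theta_hat,eta1_hat,eta2_hat estimated probabilities.
#' @param counts arm counts as in [bliss_variance()].
#' @return A list with `phi`, `se`, `z`, `p_value`.
#' @export
bliss_test <- function(theta_hat, eta1_hat, eta2_hat, counts) {
  phi <- bliss_phi(theta_hat, eta1_hat, eta2_hat)
  v <- bliss_variance(counts, list(theta = theta_hat, eta1 = eta1_hat,
                                   eta2 = eta2_hat))
  z <- phi / sqrt(v)
  list(phi = phi, se = sqrt(v), z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Greedy optimal allocation for a drug-interaction study
#'
#' Sequentially assigns each of the `n` current observations to the arm whose
#' unit increment most reduces the large-sample variance of the interaction
#' contrast, with the design probabilities set to the historical plug-ins and
#' `theta = eta1_hat * eta2_hat` (the value under Bliss independence). The
#' first observation necessarily goes to the combination arm (the variance is
#' infinite at `n12 = 0`). Because the objective is separable with decreasing
#' marginal gains, the greedy allocation attains the exhaustive integer
#' optimum. Ties are broken deterministically: combination arm first, then
#' drug 1, then drug 2 (the optimum need not be unique).
#'
#' @param n number of current observations to allocate (>= 1).
#' @param m1,m2 historical single-drug sample sizes.
#' @param eta1_hat,eta2_hat historical estimates of the single-drug no-effect
#'   probabilities, in (0, 1).
#' @return An object of class `"bliss_alloc"`: list with `counts`
#'   (`n12`, `n1`, `n2`, `m1`, `m2`), `variance` (achieved value), `params`
#'   (the plug-in design probabilities) and `trace` (the per-observation arm
#'   choices, values in `c("n12", "n1", "n2")`).
#' @examples
#' bliss_allocate(23, m1 = 10, m2 = 10, eta1_hat = 0.3, eta2_hat = 0.3)
#' @export
bliss_allocate <- function(n, m1, m2, eta1_hat, eta2_hat) {
  stopifnot(n >= 1, m1 >= 1, m2 >= 1)
  if (any(c(eta1_hat, eta2_hat) <= 0) || any(c(eta1_hat, eta2_hat) >= 1))
    stop("eta estimates must lie strictly in (0, 1)", call. = FALSE)
  theta <- eta1_hat * eta2_hat
  w <- c((1 - theta) / theta, (1 - eta1_hat) / eta1_hat,
         (1 - eta2_hat) / eta2_hat)
  cnt <- c(0, m1, m2)  # effective denominators: n12, n1 + m1, n2 + m2
  trace <- character(n)
  arms <- c("n12", "n1", "n2")
  for (i in seq_len(n)) {
    # reduction from incrementing arm k: w_k * (1/c_k - 1/(c_k+1)) = w_k / (c_k (c_k+1))
    gain <- ifelse(cnt == 0, Inf, w / (cnt * (cnt + 1)))
    k <- which.max(gain)  # ties: n12 first, then n1, then n2
    cnt[k] <- cnt[k] + 1
    trace[i] <- arms[k]
  }
  counts <- list(n12 = cnt[1], n1 = cnt[2] - m1, n2 = cnt[3] - m2,
                 m1 = m1, m2 = m2)
  params <- list(theta = theta, eta1 = eta1_hat, eta2 = eta2_hat)
  structure(list(counts = counts,
                 variance = bliss_variance(counts, params),
                 params = params, trace = trace, n = n),
            class = "bliss_alloc")
}

#' @export
print.bliss_alloc <- function(x, ...) {
  cat("Greedy allocation of n =", x$n, "observations (Bliss-independence design)\n")
  cat(sprintf("  combination arm n12 = %d, drug-1 arm n1 = %d, drug-2 arm n2 = %d\n",
              x$counts$n12, x$counts$n1, x$counts$n2))
  cat(sprintf("  historical m1 = %d, m2 = %d; achieved variance %.6g\n",
              x$counts$m1, x$counts$m2, x$variance))
  invisible(x)
}

#' Smallest study size at which historical arms are replicated
#'
#' Scans the greedy allocation for the smallest current-study size `n` at
#' which at least one observation is assigned to a single-drug arm (i.e. a
#' historically observed arm is replicated rather than all observations going
#' to the combination arm). Because the greedy procedure is incremental, a
#' single run at `n_max` determines the answer.
#'
#' @inheritParams bliss_allocate
#' @param n_max scan bound.
#' @return A list with `n_min` (or `NA` if no replication occurs up to
#'   `n_max`, with `exceeded = TRUE`) and `allocation`, the
#'   [bliss_allocate()] result at `n_min`.
#' @examples
#' bliss_nmin(m1 = 10, m2 = 10, eta1_hat = 0.3, eta2_hat = 0.3)$n_min  # 23
#' @export
bliss_nmin <- function(m1, m2, eta1_hat, eta2_hat, n_max = 10000) {
  alloc <- bliss_allocate(n_max, m1, m2, eta1_hat, eta2_hat)
  first <- which(alloc$trace != "n12")[1]
  if (is.na(first))
    return(list(n_min = NA_integer_, exceeded = TRUE, allocation = NULL))
  list(n_min = first, exceeded = FALSE,
       allocation = bliss_allocate(first, m1, m2, eta1_hat, eta2_hat))
}

#' Tabulate minimal replication sizes over a parameter grid
#'
#' Regenerates the reference grid of minimal current-study sizes and their
#' optimal allocations for selected no-effect probabilities and historical
#' sizes.
#'
#' @param eta_pairs two-column matrix (or data frame) of `(eta1, eta2)` pairs.
#' @param m_pairs two-column matrix of `(m1, m2)` pairs.
#' @param n_max scan bound passed to [bliss_nmin()].
#' @return A data frame with columns `eta1`, `eta2`, `m1`, `m2`, `n_min`,
#'   `n12`, `n1`, `n2`.
#' @export
bliss_table3 <- function(eta_pairs = cbind(c(0.3, 0.3, 0.3, 0.3, 0.5, 0.5, 0.7, 0.7),
                                           c(0.3, 0.5, 0.7, 0.9, 0.7, 0.9, 0.7, 0.9)),
                         m_pairs = cbind(c(10, 10, 10, 20, 30),
                                         c(10, 20, 30, 10, 10)),
                         n_max = 10000) {
  eta_pairs <- as.matrix(eta_pairs); m_pairs <- as.matrix(m_pairs)
  rows <- list()
  for (i in seq_len(nrow(eta_pairs))) for (j in seq_len(nrow(m_pairs))) {
    nm <- bliss_nmin(m_pairs[j, 1], m_pairs[j, 2],
                     eta_pairs[i, 1], eta_pairs[i, 2], n_max = n_max)
    cnt <- nm$allocation$counts
    rows[[length(rows) + 1L]] <- data.frame(
      eta1 = eta_pairs[i, 1], eta2 = eta_pairs[i, 2],
      m1 = m_pairs[j, 1], m2 = m_pairs[j, 2],
      n_min = nm$n_min, n12 = cnt$n12, n1 = cnt$n1, n2 = cnt$n2)
  }
  do.call(rbind, rows)
}
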