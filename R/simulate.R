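#' Simulation configuration
#'
#' Describes one synthetic-data scenario under the package's assumed models:
#' normal factorial outcomes for the ANOVA scenarios (all experimental units —
#' historical and current — drawn from the same population, so any mean shift
#' is attributable to treatment), or independent binomial no-effect counts for
#' the Bliss scenario.
#'
#' @param scenario one of `"anova_type1"`, `"anova_type2"`, `"anova_threearm"`,
#'   `"bliss"`.
#' @param params for ANOVA scenarios a list with `eta0`, `eta1`, `eta2`,
#'   `theta`, `sigma2`; for `"bliss"` a list with `eta1`, `eta2`, `theta`.
#' @param design for ANOVA scenarios a [design_xi()] (defaults: all-combination
#'   for type1, balanced for type2, `(0, 1/4, 1/4, 1/2)` for threearm); for
#'   `"bliss"` a list of arm counts `n12`, `n1`, `n2`.
#' @param n current-study size.
#' @param m total historical size (ANOVA: split over two balanced equal-size
#'   single-treatment studies, i.e. four arms of `m/4`; Bliss: split as
#'   `m1 = m2 = m/2` unless `design` supplies `m1`, `m2`).
#' @param reps Monte Carlo replication count.
#' @param seed integer seed; each replication derives its own RNG stream from
#'   `(seed, rep)` so results are independent of execution order.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(scenario = c("anova_type1", "anova_type2",
                                    "anova_threearm", "bliss"),
                       params = NULL, design = NULL, n, m,
                       reps = 1, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 1, m >= 1, reps >= 1)
  if (is.null(params)) {
    params <- if (scenario == "bliss")
      list(eta1 = 0.3, eta2 = 0.3, theta = 0.09)
    else list(eta0 = 1, eta1 = 0.5, eta2 = 0.5, theta = 0.25, sigma2 = 1)
  }
  if (is.null(design)) {
    design <- switch(scenario,
      anova_type1 = design_xi(0, 0, 0, 1),
      anova_type2 = design_xi(0.25, 0.25, 0.25, 0.25),
      anova_threearm = design_xi(0, 0.25, 0.25, 0.5),
      bliss = list(n12 = ceiling(n / 2), n1 = floor(n / 4),
                   n2 = n - ceiling(n / 2) - floor(n / 4)))
  }
  if (scenario == "bliss") {
    p <- c(params$theta, params$eta1, params$eta2)
    stopifnot(all(p > 0), all(p < 1))
  } else stopifnot(params$sigma2 > 0)
  structure(list(scenario = scenario, params = params, design = design,
                 n = as.integer(n), m = as.integer(m),
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-replication substream
rep_seed <- function(seed, rep) (seed * 48271 + rep * 9973) %% 2147483647

#' Simulate a current study
#'
#' ANOVA scenarios: arm sizes are `round(n * xi)` and outcomes are normal with
#' the factorial means and variance `sigma2`. Bliss: one Bernoulli no-effect
#' indicator per subject in each arm.
#'
#' @param cfg a [sim_config()].
#' @param rep replication index (selects the RNG substream).
#' @return A data frame: columns `t1`, `t2`, `y` for ANOVA scenarios; `arm`
#'   (one of `"12"`, `"1"`, `"2"`) and `y` (0/1 no-effect indicator) for Bliss.
#' @export
simulate_current <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(rep_seed(cfg$seed, rep))
  if (cfg$scenario == "bliss") {
    d <- cfg$design
    arm <- rep(c("12", "1", "2"), times = c(d$n12, d$n1, d$n2))
    pr <- c("12" = cfg$params$theta, "1" = cfg$params$eta1,
            "2" = cfg$params$eta2)[arm]
    return(data.frame(arm = arm, y = stats::rbinom(length(arm), 1, pr)))
  }
  xi <- as_design_xi(cfg$design)
  sizes <- round(cfg$n * xi)
  if (any(sizes == 0 & xi > 0))
    stop("rounding made an arm with positive allocation empty; increase n",
         call. = FALSE)
  t1 <- rep(c(0, 1, 0, 1), times = sizes)
  t2 <- rep(c(0, 0, 1, 1), times = sizes)
  p <- cfg$params
  mu <- p$eta0 + p$eta1 * t1 + p$eta2 * t2 + p$theta * t1 * t2
  data.frame(t1 = t1, t2 = t2, y = stats::rnorm(length(mu), mu, sqrt(p$sigma2)))
}

#' Simulate historical studies
#'
#' ANOVA scenarios: two balanced equal-size single-treatment trials (four arms
#' of `m/4`), back-calculated and aggregated via [anova_backcalculate()] with
#' the pooled *estimated* residual variance — the covariance passed downstream
#' is the estimated one, as in a real analysis. Bliss: two binomial
#' experiments of sizes `m1`, `m2`.
#'
#' @param cfg a [sim_config()].
#' @param rep replication index.
#' @return For ANOVA scenarios, the list returned by [anova_backcalculate()];
#'   for Bliss, a list with `eta1_hat`, `eta2_hat`, `m1`, `m2`.
#' @export
simulate_historical <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(rep_seed(cfg$seed, rep) + 1)
  p <- cfg$params
  if (cfg$scenario == "bliss") {
    m1 <- cfg$design$m1 %||% (cfg$m %/% 2)
    m2 <- cfg$design$m2 %||% (cfg$m - m1)
    return(list(eta1_hat = stats::rbinom(1, m1, p$eta1) / m1,
                eta2_hat = stats::rbinom(1, m2, p$eta2) / m2,
                m1 = m1, m2 = m2))
  }
  ma <- cfg$m %/% 4  # four arms of equal size
  if (ma < 2) stop("m too small for two balanced historical studies", call. = FALSE)
  sd0 <- sqrt(p$sigma2)
  arms <- list(
    y01 = stats::rnorm(ma, p$eta0, sd0),            # control, study 1
    y11 = stats::rnorm(ma, p$eta0 + p$eta1, sd0),   # treatment 1, study 1
    y02 = stats::rnorm(ma, p$eta0, sd0),            # control, study 2
    y22 = stats::rnorm(ma, p$eta0 + p$eta2, sd0))   # treatment 2, study 2
  s2_hat <- mean(vapply(arms, stats::var, numeric(1)))
  anova_backcalculate(
    study1 = list(mean_control = mean(arms$y01), mean_treated = mean(arms$y11),
                  m_control = ma, m_treated = ma),
    study2 = list(mean_control = mean(arms$y02), mean_treated = mean(arms$y22),
                  m_control = ma, m_treated = ma),
    sigma2 = s2_hat)
}

#' Monte Carlo validation of the asymptotic formulas
#'
#' Runs the full pipeline (fresh historical and current data each replication,
#' estimation, sandwich/asymptotic covariance) and compares the empirical
#' covariance of `sqrt(n) * (estimate - truth)` with the theoretical limit
#' matrix evaluated at the true parameters. Also reports per-parameter 95%
#' Wald coverage (using each replication's own estimated covariance) and the
#' theoretical Loewner ordering checks (two-step below plug-in; summary
#' combination below current-only).
#'
#' @param cfg a [sim_config()] (its `reps` and `seed` drive the loop).
#' @param kind estimator kind for ANOVA scenarios: `"A"`, `"B"`, `"C"` or
#'   `"augmented"` (`"anova_type1"` forces `"A"`; `"anova_threearm"` uses the
#'   three-arm estimator). Ignored for `"bliss"`, which runs the Wald test of
#'   Bliss independence.
#' @param fail_tol abort if more than this fraction of replications fails.
#' @return An object of class `"mc_report"`: `empirical_cov`, `asymptotic_cov`,
#'   `max_abs_rel_gap` (over variance entries), `coverage`, `bias`, `mc_se`
#'   (jackknife MC standard errors of the variance entries),
#'   `loewner_checks`, `failures`, `reps`. For `"bliss"`, empirical rejection
#'   rate of the nominal-5% Wald test instead of coverage.
#' @export
mc_validate <- function(cfg, kind = c("B", "A", "C", "augmented"),
                        fail_tol = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  kind <- match.arg(kind)
  if (cfg$scenario == "bliss") return(mc_validate_bliss(cfg, fail_tol))
  if (cfg$scenario == "anova_type1") kind <- "A"
  p <- cfg$params
  truth <- c(p$theta, p$eta0, p$eta1, p$eta2)
  design <- switch(cfg$scenario, anova_type1 = "type1",
                   anova_type2 = "type2", anova_threearm = "threearm")
  draws <- matrix(NA_real_, cfg$reps, 4)
  covered <- matrix(NA, cfg$reps, 4)
  failures <- 0L
  for (r in seq_len(cfg$reps)) {
    fit <- tryCatch({
      hist <- simulate_historical(cfg, r)
      dat <- simulate_current(cfg, r)
      if (design == "type2" && kind != "B")
        run_anova_kind(dat, hist, kind)
      else estimate_anova(dat, hist, design = design)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      if (failures > fail_tol * cfg$reps)
        stop("more than ", 100 * fail_tol, "% of replications failed",
             call. = FALSE)
      next
    }
    est <- c(fit$theta, fit$eta)
    draws[r, ] <- sqrt(cfg$n) * (est - truth)
    se <- sqrt(diag(per_study_scale(fit$avar, fit$n)))
    covered[r, ] <- abs(est - truth) <= stats::qnorm(0.975) * se
  }
  ok <- stats::complete.cases(draws)
  emp <- stats::cov(draws[ok, , drop = FALSE])
  theo <- anova_theoretical_cov(cfg, kind, design)
  dg <- diag(theo$full)
  gap <- max(abs(diag(emp) - dg) / dg)
  dimnames(emp) <- dimnames(theo$full)
  structure(list(
    empirical_cov = emp, asymptotic_cov = theo$full,
    max_abs_rel_gap = gap,
    coverage = colMeans(covered[ok, , drop = FALSE]),
    bias = colMeans(draws[ok, , drop = FALSE]) / sqrt(cfg$n),
    mc_se = jackknife_var_se(draws[ok, , drop = FALSE]),
    loewner_checks = anova_loewner_checks(cfg),
    failures = failures, reps = sum(ok), kind = kind,
    scenario = cfg$scenario),
    class = "mc_report")
}

# closed-form ANOVA estimating functions for kinds other than the default
run_anova_kind <- function(dat, hist, kind) {
  hs <- hist$hist
  ef <- estfun(
    psi = function(theta, eta, y) {
      r <- y$y - eta[1] - eta[2] * y$t1 - eta[3] * y$t2 - theta * y$t1 * y$t2
      r * y$t1 * y$t2
    },
    gamma = function(theta, eta, y) {
      r <- y$y - eta[1] - eta[2] * y$t1 - eta[3] * y$t2 - theta * y$t1 * y$t2
      cbind(r, r * y$t1, r * y$t2)
    },
    p = 1, q = 3, vectorized = TRUE)
  if (kind == "C") {
    st <- joint_solve(ef, dat, init = rep(0, 4), tol = 1e-10, max_iter = 100)
    ups <- joint_sandwich(ef, dat, st$theta, st$eta)
    cur <- current_summary(st$theta, st$eta, ups, nrow(dat))
    estimate_type_c(cur, hs)
  } else if (kind == "augmented") {
    estimate_augmented(ef, dat, hs, init = rep(0, 4))
  } else if (kind == "A") {
    efA <- estfun(ef$psi, p = 1, q = 3, vectorized = TRUE)
    dat11 <- dat  # plug-in analysis of the full factorial data
    suppressWarnings(estimate_type_a(efA, dat11, hs, init = 0))
  } else estimate_anova(dat, hist, design = "type2")
}

# theoretical limit covariance at the true parameters
anova_theoretical_cov <- function(cfg, kind, design) {
  p <- cfg$params
  rho <- cfg$n / cfg$m
  Sigma <- anova_sigma_balanced(p$sigma2)
  hist0 <- historical_set(list(historical_study(
    c(p$eta0, p$eta1, p$eta2), Sigma / cfg$m, m = cfg$m, label = "truth")))
  jac0 <- list(D_theta = matrix(-1, 1, 1), D_eta = matrix(-1, 1, 3),
               D_blocks = list(matrix(-1, 1, 3)),
               meat = matrix(p$sigma2, 1, 1), p = 1L, q = 3L, n = cfg$n)
  class(jac0) <- "jacobian_set"
  if (design == "type1") return(avar_type_a(jac0, hist0, rho))
  if (design == "threearm") {
    xi <- as_design_xi(cfg$design)
    v_tt <- anova_var_threearm(xi, rho, p$sigma2, Sigma / p$sigma2)
    A <- rbind(c(1, 1, 0), c(1, 0, 1))
    V <- p$sigma2 * diag(1 / c(xi[["xi10"]], xi[["xi01"]]))
    kern <- inv(t(A) %*% inv(V, "V") %*% A + inv(rho * Sigma, "rho Sigma"),
                "kernel")
    C_te <- -matrix(colSums(kern), 1)
    return(partitioned_cov(rbind(cbind(v_tt, C_te), cbind(t(C_te), kern)),
                           p = 1, q = 3))
  }
  xi <- as_design_xi(cfg$design)
  ups <- anova_upsilon(xi, p$sigma2)
  # quasi-score psi = r * t1 * t2: meat = sigma2 * xi11, D_theta = -xi11
  jac2 <- list(D_theta = matrix(-xi[["xi11"]], 1, 1),
               D_eta = -xi[["xi11"]] * matrix(1, 1, 3),
               D_blocks = list(-xi[["xi11"]] * matrix(1, 1, 3)),
               meat = matrix(p$sigma2 * xi[["xi11"]], 1, 1),
               p = 1L, q = 3L, n = cfg$n)
  class(jac2) <- "jacobian_set"
  if (kind %in% c("B", "augmented")) avar_type_b(jac2, ups, hist0, rho)
  else if (kind == "C") avar_type_c(ups, hist0, rho)
  else avar_type_a(jac2, hist0, rho)
}

anova_loewner_checks <- function(cfg) {
  p <- cfg$params
  rho <- cfg$n / cfg$m
  bal <- design_xi(0.25, 0.25, 0.25, 0.25)
  Sigma <- anova_sigma_balanced(p$sigma2)
  hist0 <- historical_set(list(historical_study(
    c(p$eta0, p$eta1, p$eta2), Sigma / cfg$m, m = cfg$m, label = "truth")))
  ups <- anova_upsilon(bal, p$sigma2)
  jac <- list(D_theta = matrix(-0.25, 1, 1), D_eta = -0.25 * matrix(1, 1, 3),
              D_blocks = list(-0.25 * matrix(1, 1, 3)),
              meat = matrix(p$sigma2 * 0.25, 1, 1), p = 1L, q = 3L, n = cfg$n)
  class(jac) <- "jacobian_set"
  A <- avar_type_a(jac, hist0, rho)
  B <- avar_type_b(jac, ups, hist0, rho)
  C <- avar_type_c(ups, hist0, rho)
  list(B_leq_A = loewner_leq(B, A)$leq,
       C_leq_Upsilon = loewner_leq(C, ups)$leq)
}

mc_validate_bliss <- function(cfg, fail_tol) {
  p <- cfg$params
  reject <- rep(NA, cfg$reps)
  phis <- rep(NA_real_, cfg$reps)
  failures <- 0L
  for (r in seq_len(cfg$reps)) {
    res <- tryCatch({
      hist <- simulate_historical(cfg, r)
      dat <- simulate_current(cfg, r)
      d <- cfg$design
      th_hat <- mean(dat$y[dat$arm == "12"])
      e1_hat <- (sum(dat$y[dat$arm == "1"]) + hist$eta1_hat * hist$m1) /
        (d$n1 + hist$m1)
      e2_hat <- (sum(dat$y[dat$arm == "2"]) + hist$eta2_hat * hist$m2) /
        (d$n2 + hist$m2)
      bliss_test(th_hat, e1_hat, e2_hat,
                 list(n12 = d$n12, n1 = d$n1, n2 = d$n2,
                      m1 = hist$m1, m2 = hist$m2))
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > fail_tol * cfg$reps)
        stop("more than ", 100 * fail_tol, "% of replications failed", call. = FALSE)
      next
    }
    reject[r] <- res$p_value < 0.05
    phis[r] <- res$phi
  }
  ok <- !is.na(reject)
  structure(list(rejection_rate = mean(reject[ok]), phi_mean = mean(phis[ok]),
                 failures = failures, reps = sum(ok), scenario = "bliss"),
            class = "mc_report")
}

# jackknife MC-SE of the empirical variances (diagonal entries)
jackknife_var_se <- function(draws) {
  n <- nrow(draws)
  apply(draws, 2, function(x) {
    v <- stats::var(x)
    # leave-one-out variances via updating formulas
    mu <- mean(x)
    loo <- ((n - 1) * v - (x - mu)^2 * n / (n - 1)) / (n - 2)
    sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  })
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat("Monte Carlo validation:", x$scenario,
      if (!is.null(x$kind)) paste0("(estimator ", x$kind, ")"), "-",
      x$reps, "replications,", x$failures, "failures\n")
  if (!is.null(x$rejection_rate)) {
    cat("Wald test rejection rate at nominal 5%:",
        format(x$rejection_rate, digits = digits), "\n")
    return(invisible(x))
  }
  cat("max |relative gap| empirical vs asymptotic variances:",
      format(x$max_abs_rel_gap, digits = digits), "\n")
  cat("95% Wald coverage:", paste(format(x$coverage, digits = digits),
                                  collapse = " "), "\n")
  cat("Loewner checks: B <= A:", x$loewner_checks$B_leq_A,
      "; C <= Upsilon:", x$loewner_checks$C_leq_Upsilon, "\n")
  invisible(x)
}
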