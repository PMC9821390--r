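#' Allocation fractions for the 2x2 factorial design
#'
#' Fractions of the current study assigned to the four treatment combinations
#' (neither, treatment 1 only, treatment 2 only, both), on the unit simplex.
#'
#' @param xi00,xi10,xi01,xi11 nonnegative fractions summing to one.
#' @return An object of class `"design_xi"` (a named numeric vector).
#' @export
design_xi <- function(xi00, xi10, xi01, xi11) {
  xi <- c(xi00 = xi00, xi10 = xi10, xi01 = xi01, xi11 = xi11)
  if (any(xi < 0)) stop("allocation fractions must be nonnegative", call. = FALSE)
  if (abs(sum(xi) - 1) > 1e-12)
    stop("allocation fractions must sum to 1 (got ", format(sum(xi)), ")",
         call. = FALSE)
  structure(xi, class = "design_xi")
}

as_design_xi <- function(xi) {
  if (inherits(xi, "design_xi")) return(xi)
  stopifnot(length(xi) == 4)
  design_xi(xi[1], xi[2], xi[3], xi[4])
}

#' Historical covariance for two balanced single-treatment studies
#'
#' The `sqrt(m)`-scale covariance of the back-calculated nuisance estimates
#' `(eta0, eta1, eta2)` when the two historical studies are balanced,
#' homoscedastic and of equal size (all four arms of size `m/4`).
#'
#' @param sigma2 residual variance.
#' @return A 3 x 3 matrix, `sigma2 * [[2, -2, -2], [-2, 6, 2], [-2, 2, 6]]`.
#' @export
anova_sigma_balanced <- function(sigma2 = 1) {
  sigma2 * matrix(c(2, -2, -2,
                    -2, 6, 2,
                    -2, 2, 6), 3, 3, byrow = TRUE)
}

#' Back-calculate pooled nuisance estimates from two historical trials
#'
#' Each historical study compared one treatment with a control. Given the four
#' arm means and sizes (reconstructed from the published estimates and
#' standard errors if necessary), the common control mean is pooled across the
#' two control arms and the treatment effects are re-expressed against it:
#' \deqn{\hat\eta_0 = \frac{m_{1,0}\bar Y_0(S_1) + m_{2,0}\bar Y_0(S_2)}
#'       {m_{1,0}+m_{2,0}}, \quad
#'       \hat\eta_i = \bar Y_i(S_i) - \hat\eta_0.}
#' The `sqrt(m)`-scale covariance follows from the linear map of the four
#' independent arm means (homoscedastic variance `sigma2`); in the balanced
#' equal-size case it equals [anova_sigma_balanced()].
#'
#' @param study1,study2 lists with fields `mean_control`, `mean_treated`,
#'   `m_control`, `m_treated` — or fields `estimates` (length 2: control mean
#'   estimate and treatment-effect estimate) and `se` (their standard errors),
#'   from which arm means and sizes are back-calculated under homoscedasticity.
#' @param sigma2 residual variance used for the covariance (and for
#'   back-calculating arm sizes from standard errors).
#' @return A list with `eta_hat` (3-vector), `Sigma` (3 x 3, `sqrt(m)` scale),
#'   `m` (total historical size), `cov` (finite-sample covariance `Sigma/m`)
#'   and `hist` (a one-study aggregated [historical_set()] ready for
#'   [histest()]).
#' @export
anova_backcalculate <- function(study1, study2, sigma2 = 1) {
  decode <- function(s, which) {
    if (!is.null(s$estimates)) {
      # published (estimate, SE) pairs: eta0_hat = control mean, effect = diff
      m_c <- sigma2 / s$se[1]^2
      # se(effect)^2 = sigma2 (1/m_c + 1/m_t)
      denom <- s$se[2]^2 / sigma2 - 1 / m_c
      if (denom <= 0)
        stop("study ", which, ": standard errors inconsistent with ",
             "homoscedastic arms", call. = FALSE)
      m_t <- 1 / denom
      list(mean_control = s$estimates[1],
           mean_treated = s$estimates[1] + s$estimates[2],
           m_control = m_c, m_treated = m_t)
    } else s
  }
  s1 <- decode(study1, 1); s2 <- decode(study2, 2)
  for (s in list(s1, s2))
    if (s$m_control < 1 || s$m_treated < 1)
      stop("all historical arm sizes must be at least 1", call. = FALSE)
  m <- s1$m_control + s1$m_treated + s2$m_control + s2$m_treated
  w1 <- s1$m_control / (s1$m_control + s2$m_control)
  w2 <- 1 - w1
  eta0 <- w1 * s1$mean_control + w2 * s2$mean_control
  eta_hat <- c(eta0 = eta0,
               eta1 = s1$mean_treated - eta0,
               eta2 = s2$mean_treated - eta0)
  # linear map of the independent arm means (Y0(S1), Y1(S1), Y0(S2), Y2(S2))
  L <- rbind(c(w1, 0, w2, 0),
             c(-w1, 1, -w2, 0),
             c(-w1, 0, -w2, 1))
  av <- sigma2 / c(s1$m_control, s1$m_treated, s2$m_control, s2$m_treated)
  cov <- L %*% diag(av) %*% t(L)
  Sigma <- m * cov
  dimnames(Sigma) <- dimnames(cov) <- rep(list(names(eta_hat)), 2)
  hist <- historical_set(list(historical_study(eta_hat, cov, m = round(m),
                                               label = "pooled")))
  list(eta_hat = eta_hat, Sigma = Sigma, m = m, cov = cov, hist = hist)
}

#' Current-study asymptotic covariance for a 2x2 factorial design
#'
#' The `sqrt(n)`-scale covariance of the usual estimators
#' `(theta, eta0, eta1, eta2)` (interaction contrast, control mean, two main
#' effects) as a function of the allocation fractions. All four cells must be
#' occupied; otherwise the matrix is singular and a Type-I or three-arm
#' analysis is indicated.
#'
#' @param xi a [design_xi()] (or length-4 vector) with all entries > 0.
#' @param sigma2 residual variance.
#' @return A 4 x 4 [partitioned_cov()] (p = 1, q = 3).
#' @export
anova_upsilon <- function(xi, sigma2 = 1) {
  xi <- as_design_xi(xi)
  if (any(xi <= 0))
    stop("all four allocation fractions must be positive; with an empty cell ",
         "use the Type I or three-arm analysis", call. = FALSE)
  a <- 1 / xi[["xi00"]]; b <- 1 / xi[["xi10"]]
  c_ <- 1 / xi[["xi01"]]; d <- 1 / xi[["xi11"]]
  U <- matrix(c(
    a + b + c_ + d,  a,        -(a + b), -(a + c_),
    a,               a,        -a,       -a,
    -(a + b),       -a,         a + b,    a,
    -(a + c_),      -a,         a,        a + c_), 4, 4, byrow = TRUE)
  partitioned_cov(sigma2 * U, p = 1, q = 3)
}

#' Asymptotic variance of the Type-I interaction estimator
#'
#' For the design assigning every current observation to the combination arm,
#' the interaction estimator has asymptotic variance `sigma2 * (1 + 10 rho)`
#' (`10` being the total mass of the balanced historical covariance) and exact
#' finite-sample variance `sigma2 * (1/n + 10/m)`.
#'
#' @param rho sampling ratio `n/m` (>= 0).
#' @param sigma2 residual variance.
#' @return A list with `asymptotic` (scalar) and `exact` (a `function(n, m)`).
#' @export
anova_var_type1 <- function(rho, sigma2 = 1) {
  stopifnot(rho >= 0)
  list(asymptotic = sigma2 * (1 + 10 * rho),
       exact = function(n, m) sigma2 * (1 / n + 10 / m))
}

#' Asymptotic variance of the Type-II interaction estimator
#'
#' For an interior 2x2 design, `sigma2 * (1/xi11 + 1' K 1)` where
#' `K = (Upsilon_ee^-1 + (rho Sigma)^-1)^-1` is the pooled kernel built from
#' the design's nuisance covariance and the historical covariance (both on the
#' unit-variance scale).
#'
#' @param xi a [design_xi()] with all entries > 0.
#' @param rho sampling ratio `n/m` (> 0).
#' @param sigma2 residual variance (scales the result).
#' @param Sigma 3 x 3 historical covariance on the unit-variance scale;
#'   defaults to the balanced [anova_sigma_balanced()].
#' @return Scalar asymptotic variance.
#' @export
anova_var_type2 <- function(xi, rho, sigma2 = 1, Sigma = anova_sigma_balanced()) {
  xi <- as_design_xi(xi)
  stopifnot(rho > 0)
  Uee <- pc_block(anova_upsilon(xi, sigma2 = 1), "ee")
  K <- pooled_kernel(Uee, rho * Sigma)
  sigma2 * (1 / xi[["xi11"]] + sum(K))
}

#' Asymptotic variance of the three-arm (no-control) interaction estimator
#'
#' With no control cell the current study observes the arm means of treatment
#' 1, treatment 2 and the combination. The single-arm means have expectation
#' `A eta` with `A = [[1,1,0],[1,0,1]]`; pooling them with the historical
#' estimates ([pool_linear()]) yields the interaction variance
#' `sigma2 * (1/xi11 + 1' (A' V^-1 A + (rho Sigma)^-1)^-1 1)` with
#' `V = diag(1/xi01, 1/xi10)`. With `xi01 = xi10 = 0` the design degenerates
#' to the Type-I single-arm study and the formula reduces to
#' `sigma2 * (1 + 10 rho)` for the balanced historical covariance.
#'
#' @param xi a [design_xi()] with `xi00 = 0` and `xi11 > 0`.
#' @param rho sampling ratio `n/m` (> 0).
#' @param sigma2 residual variance.
#' @param Sigma 3 x 3 unit-variance historical covariance.
#' @return Scalar asymptotic variance.
#' @export
anova_var_threearm <- function(xi, rho, sigma2 = 1,
                               Sigma = anova_sigma_balanced()) {
  xi <- as_design_xi(xi)
  stopifnot(rho > 0)
  if (xi[["xi00"]] != 0)
    stop("the three-arm formula requires xi00 = 0", call. = FALSE)
  if (xi[["xi11"]] <= 0) stop("xi11 must be positive", call. = FALSE)
  A <- rbind(c(1, 1, 0),
             c(1, 0, 1))
  keep <- c(xi[["xi01"]] > 0, xi[["xi10"]] > 0)
  core <- if (any(keep)) {
    V <- diag(1 / c(xi[["xi01"]], xi[["xi10"]]), 2)[keep, keep, drop = FALSE]
    Ak <- A[keep, , drop = FALSE]
    t(Ak) %*% inv(V, "V") %*% Ak
  } else matrix(0, 3, 3)
  kern <- inv(core + inv(rho * Sigma, "rho * Sigma"), "three-arm kernel")
  sigma2 * (1 / xi[["xi11"]] + sum(kern))
}

#' Optimal 2x2 allocation by exhaustive grid search
#'
#' Minimizes [anova_var_type2()] over the symmetric two-dimensional grid
#' `xi01 = xi10`, `xi00 = 1 - 2*xi10 - xi11 >= min_xi00` with the given step.
#' The floor on `xi00` keeps the design covariance invertible. Ties are broken
#' toward larger `xi11`, then larger `xi10`, for determinism. The search is
#' vectorized via the closed-form inverse of the 3 x 3 kernel, so the default
#' million-point grid runs in about a second.
#'
#' @param rho sampling ratio `n/m` (> 0).
#' @param step grid step for `xi10` and `xi11`.
#' @param min_xi00 lower bound on the control-cell fraction.
#' @param sigma2 residual variance.
#' @param Sigma 3 x 3 unit-variance historical covariance.
#' @return A list with `xi` (a [design_xi()]) and `value` (the minimal
#'   asymptotic variance).
#' @examples
#' anova_optimal_design(rho = 1)
#' @export
anova_optimal_design <- function(rho, step = 0.001, min_xi00 = 0.02,
                                 sigma2 = 1, Sigma = anova_sigma_balanced()) {
  stopifnot(rho > 0, step > 0, min_xi00 >= 0)
  Q <- inv(rho * Sigma, "rho * Sigma")
  # Upsilon_ee^-1 = xi00 u1 u1' + xi10 u2 u2' + xi01 u3 u3'
  U1 <- tcrossprod(c(1, 0, 0))
  U2 <- tcrossprod(c(1, 1, 0))
  U3 <- tcrossprod(c(1, 0, 1))
  best_v <- Inf; best_xi <- NULL
  x10_grid <- seq(step, (1 - min_xi00) / 2, by = step)
  for (x10 in x10_grid) {
    x11_max <- 1 - 2 * x10 - min_xi00
    if (x11_max < step - 1e-15) next
    x11 <- seq(step, x11_max, by = step)
    x00 <- 1 - 2 * x10 - x11
    g11 <- Q[1, 1] + x00 * U1[1, 1] + x10 * (U2[1, 1] + U3[1, 1])
    g12 <- Q[1, 2] + x00 * U1[1, 2] + x10 * (U2[1, 2] + U3[1, 2])
    g13 <- Q[1, 3] + x00 * U1[1, 3] + x10 * (U2[1, 3] + U3[1, 3])
    g22 <- Q[2, 2] + x00 * U1[2, 2] + x10 * (U2[2, 2] + U3[2, 2])
    g23 <- Q[2, 3] + x00 * U1[2, 3] + x10 * (U2[2, 3] + U3[2, 3])
    g33 <- Q[3, 3] + x00 * U1[3, 3] + x10 * (U2[3, 3] + U3[3, 3])
    det <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
      g13 * (g12 * g23 - g22 * g13)
    ones_Ginv_ones <- ((g22 * g33 - g23^2) + (g11 * g33 - g13^2) +
                         (g11 * g22 - g12^2) -
                         2 * (g12 * g33 - g23 * g13) +
                         2 * (g12 * g23 - g22 * g13) -
                         2 * (g11 * g23 - g12 * g13)) / det
    v <- 1 / x11 + ones_Ginv_ones
    # tie-break: larger xi11 first, then larger xi10 (later x10 iterations win ties)
    i <- length(v) + 1L - which.max(rev(v <= min(v)))
    if (v[i] < best_v || (v[i] == best_v && !is.null(best_xi) &&
                          (x11[i] > best_xi[4] ||
                           (x11[i] == best_xi[4] && x10 > best_xi[2])))) {
      best_v <- v[i]
      best_xi <- c(x00[i], x10, x10, x11[i])
    }
  }
  if (is.null(best_xi))
    stop("empty feasible grid: decrease 'step' or 'min_xi00'", call. = FALSE)
  list(xi = design_xi(best_xi[1], best_xi[2], best_xi[3], best_xi[4]),
       value = sigma2 * best_v)
}

#' Regenerate the Type-I/Type-II asymptotic-variance comparison table
#'
#' For each pair of current and historical sizes, the asymptotic variance of
#' the interaction estimator under the single-arm Type-I design
#' (`sigma2 * (1 + 10 rho)`) and under the balanced four-arm Type-II design.
#'
#' @param n_sizes,m_sizes integer vectors of study sizes.
#' @param sigma2 residual variance.
#' @return A data frame with columns `n`, `m`, `A_tt`, `B_tt`.
#' @export
anova_table1 <- function(n_sizes = c(100, 200, 500, 1000, 2000, 5000),
                         m_sizes = n_sizes, sigma2 = 1) {
  grid <- expand.grid(n = n_sizes, m = m_sizes)
  bal <- design_xi(0.25, 0.25, 0.25, 0.25)
  grid$A_tt <- sigma2 * (1 + 10 * grid$n / grid$m)
  grid$B_tt <- vapply(seq_len(nrow(grid)), function(i)
    anova_var_type2(bal, grid$n[i] / grid$m[i], sigma2), numeric(1))
  grid
}

#' Fit the 2x2 factorial interaction model with historical estimates
#'
#' Dispatches arm-level current data to the appropriate estimator:
#' `"type1"` (combination arm only; Type-I plug-in), `"type2"` (all four
#' arms; two-step) or `"threearm"` (no control arm; linear pooling via
#' [pool_linear()]). The estimating functions are the quasi-score contrasts of
#' the factorial means model, and the reported covariance uses the matching
#' design formula.
#'
#' @param data data frame with columns `t1`, `t2` (0/1 treatment indicators)
#'   and `y` (outcome).
#' @param historical a [historical_set()] carrying the aggregated 3-vector
#'   `(eta0, eta1, eta2)` (see [anova_backcalculate()]), or the list returned
#'   by [anova_backcalculate()].
#' @param design one of `"type1"`, `"type2"`, `"threearm"`.
#' @param sigma2 residual variance; estimated from within-arm residuals when
#'   `NULL`.
#' @return A `"histest"` object (`kind` `"A"`, `"B"` or `"D"`).
#' @export
estimate_anova <- function(data, historical, design = c("type2", "type1", "threearm"),
                           sigma2 = NULL) {
  design <- match.arg(design)
  if (!is.null(historical$hist)) historical <- historical$hist
  stopifnot(inherits(historical, "historical_set"))
  need <- c("t1", "t2", "y")
  if (!all(need %in% names(data)))
    stop("'data' must have columns t1, t2, y", call. = FALSE)
  arm <- interaction(data$t1, data$t2, sep = "")
  counts <- table(factor(arm, levels = c("00", "10", "01", "11")))
  n <- nrow(data)
  if (counts[["11"]] == 0)
    stop("the combination arm (t1 = t2 = 1) is empty: theta is not estimable",
         call. = FALSE)

  if (design == "type1") {
    if (any(counts[c("00", "10", "01")] > 0))
      stop("Type I analysis expects only combination-arm observations; ",
           "found other arms (use design = \"type2\" or \"threearm\")", call. = FALSE)
    ef <- estfun(function(theta, eta, y) y$y - eta[1] - eta[2] - eta[3] - theta,
                 p = 1, q = 3, vectorized = TRUE)
    init <- mean(data$y) - sum(historical$eta_hat)
    return(suppressWarnings(
      estimate_type_a(ef, data, historical, init = init)))
  }

  if (design == "type2") {
    if (any(counts == 0))
      stop("Type II analysis requires all four arms; missing: ",
           paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
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
    mns <- tapply(data$y, arm, mean)
    init <- c(mns[["11"]] - mns[["10"]] - mns[["01"]] + mns[["00"]],
              mns[["00"]], mns[["10"]] - mns[["00"]], mns[["01"]] - mns[["00"]])
    return(estimate_type_b(ef, data, historical, init = init))
  }

  # three-arm: no control cell
  if (counts[["00"]] > 0)
    stop("three-arm analysis requires an empty control arm", call. = FALSE)
  mns <- tapply(data$y, arm, mean)
  if (is.null(sigma2)) {
    res <- data$y - ave(data$y, arm)
    k <- sum(counts > 0)
    sigma2 <- sum(res^2) / (n - k)
  }
  S <- c(mns[["10"]], mns[["01"]])
  A <- rbind(c(1, 1, 0), c(1, 0, 1))
  V <- sigma2 * diag(n / counts[c("10", "01")])
  eta_dag <- pool_linear(S, A, V, historical, n)
  theta_d <- mns[["11"]] - sum(eta_dag)
  xi <- design_xi(0, counts[["10"]] / n, counts[["01"]] / n, counts[["11"]] / n)
  v_tt <- anova_var_threearm(xi, rho = n / historical$m, sigma2 = sigma2,
                             Sigma = historical$Sigma / sigma2)
  kern <- inv(t(A) %*% inv(V / sigma2, "V") %*% A / sigma2 +
                inv((n / historical$m) * historical$Sigma, "rho * Sigma"),
              "three-arm kernel")
  C_te <- -matrix(colSums(kern), 1)
  full <- rbind(cbind(v_tt, C_te), cbind(t(C_te), kern))
  out <- new_histest(theta_d, eta_dag, "D",
                     partitioned_cov(full, p = 1, q = 3), n, historical$m)
  out$sigma2 <- sigma2
  out
}
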