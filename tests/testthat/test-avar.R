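# the ANOVA reduction: D_theta = -1, D_eta = -(1,1,1), meat = sigma2
anova_jac <- function(sigma2 = 1) {
  structure(list(D_theta = matrix(-1, 1, 1), D_eta = matrix(-1, 1, 3),
                 D_blocks = list(matrix(-1, 1, 3)),
                 meat = matrix(sigma2, 1, 1), p = 1L, q = 3L, n = 100L),
            class = "jacobian_set")
}
anova_hist <- function(m = 100, sigma2 = 1) {
  historical_set(list(historical_study(
    c(1, 0.5, 0.5), anova_sigma_balanced(sigma2) / m, m = m)))
}

test_that("plug-in covariance: penalty structure and the 1 + 10*rho reduction", {
  A <- avar_type_a(anova_jac(), anova_hist(), rho = 1)
  expect_equal(pc_block(A, "tt")[1, 1], 11, tolerance = 1e-12)
  expect_equal(unname(pc_block(A, "ee")), anova_sigma_balanced(), tolerance = 1e-12)

  # rho -> 0: penalty inconsequential
  A0 <- avar_type_a(anova_jac(), anova_hist(), rho = 1e-12)
  expect_equal(pc_block(A0, "tt")[1, 1], 1, tolerance = 1e-9)

  # penalty equals the block sum rho * sum_j kappa_j D_j Sigma_j D_j'
  set.seed(19)
  studies <- list(historical_study(rnorm(2), rand_pd(2, 0.01), m = 60, label = "a"),
                  historical_study(rnorm(1), rand_pd(1, 0.01), m = 140, label = "b"))
  hist <- historical_set(studies)
  jac <- structure(list(D_theta = matrix(2, 1, 1),
                        D_eta = matrix(rnorm(3), 1, 3),
                        meat = matrix(1, 1, 1), p = 1L, q = 3L, n = 50L),
                   class = "jacobian_set")
  jac$D_blocks <- list(jac$D_eta[, 1:2, drop = FALSE], jac$D_eta[, 3, drop = FALSE])
  rho <- 0.7
  A <- avar_type_a(jac, hist, rho)
  block_sum <- rho * (hist$kappa[1] * jac$D_blocks[[1]] %*% (60 * studies[[1]]$cov) %*% t(jac$D_blocks[[1]]) +
                      hist$kappa[2] * jac$D_blocks[[2]] %*% (140 * studies[[2]]$cov) %*% t(jac$D_blocks[[2]]))
  expect_equal(attr(A, "penalty"), block_sum, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two-step covariance: balanced value, rho limits, kernel dominance", {
  ups <- anova_upsilon(design_xi(0.25, 0.25, 0.25, 0.25))
  jac2 <- structure(list(D_theta = matrix(-0.25, 1, 1),
                         D_eta = -0.25 * matrix(1, 1, 3),
                         D_blocks = list(-0.25 * matrix(1, 1, 3)),
                         meat = matrix(0.25, 1, 1), p = 1L, q = 3L, n = 100L),
                    class = "jacobian_set")
  B <- avar_type_b(jac2, ups, anova_hist(), rho = 1)
  expect_equal(round(pc_block(B, "tt")[1, 1], 2), 9.33)
  # matches the design-formula route
  expect_equal(pc_block(B, "tt")[1, 1],
               anova_var_type2(design_xi(0.25, 0.25, 0.25, 0.25), 1),
               tolerance = 1e-10)
  # rho -> infinity: kernel -> Upsilon_ee, value -> 4 + 12 = 16
  Binf <- avar_type_b(jac2, ups, anova_hist(), rho = 1e9)
  expect_equal(pc_block(Binf, "tt")[1, 1], 16, tolerance = 1e-6)
  # B_ee dominated by A_ee for random PD inputs
  set.seed(29)
  for (i in 1:5) {
    inst <- rand_instance()
    A <- avar_type_a(inst$jac, inst$hist, inst$rho)
    B <- avar_type_b(inst$jac, inst$upsilon, inst$hist, inst$rho)
    expect_true(loewner_leq(pc_block(B, "ee"), pc_block(A, "ee"))$leq)
  }
})

test_that("summary-combination covariance: no-gain case, scalar formula, dual routes", {
  set.seed(43)
  # zero cross-covariance: C_tt = Upsilon_tt
  Uee <- rand_pd(2)
  ups0 <- partitioned_cov(rbind(c(3, 0, 0), cbind(0, Uee)), p = 1, q = 2)
  hist <- historical_set(list(historical_study(rnorm(2), rand_pd(2, 0.01), m = 100)))
  C <- avar_type_c(ups0, hist, rho = 0.5)
  expect_equal(pc_block(C, "tt")[1, 1], 3, tolerance = 1e-12)

  # scalar case reproduces upsilon_tt * (1 - w2 r^2)
  u_tt <- 2.5; u_te <- -0.9; u_ee <- 1.8; s2 <- 1.1; rho <- 0.6
  ups1 <- partitioned_cov(matrix(c(u_tt, u_te, u_te, u_ee), 2, 2), p = 1, q = 1)
  m <- 500
  hist1 <- historical_set(list(historical_study(0, s2 / m, m = m)))
  C1 <- avar_type_c(ups1, hist1, rho)
  sc <- scalar_are(u_tt, u_te, u_ee, s2, gamma = rho / (1 + rho))
  expect_equal(pc_block(C1, "tt")[1, 1], sc$c_tt, tolerance = 1e-10)
  expect_gte(sc$are, 1 - sc$r^2)
  expect_lte(sc$are, 1)

  # dual routes agree on random instances (asserted internally) and C_ee = B_ee
  for (i in 1:5) {
    inst <- rand_instance()
    C <- avar_type_c(inst$upsilon, inst$hist, inst$rho)
    B <- avar_type_b(inst$jac, inst$upsilon, inst$hist, inst$rho)
    expect_equal(pc_block(C, "ee"), pc_block(B, "ee"), tolerance = 1e-12)
  }
})

test_that("delta-method variances: identity, linear map and the Bliss log contrast", {
  A <- avar_type_a(anova_jac(), anova_hist(), rho = 1)
  expect_equal(delta_variance(identity, rep(0.5, 4), A), as.matrix(A),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(delta_variance(sum, rep(0.5, 4), A)[1, 1], sum(as.matrix(A)),
               tolerance = 1e-7)

  # Bliss log contrast on a diagonal covariance reproduces the design variance
  p <- c(theta = 0.12, eta1 = 0.4, eta2 = 0.3)
  counts <- list(n12 = 30, n1 = 5, n2 = 0, m1 = 15, m2 = 20)
  cov_diag <- diag(c(p[1] * (1 - p[1]) / counts$n12,
                     p[2] * (1 - p[2]) / (counts$n1 + counts$m1),
                     p[3] * (1 - p[3]) / (counts$n2 + counts$m2)))
  v <- delta_variance(function(w) log(w[1]) - log(w[2]) - log(w[3]), p, cov_diag)
  expect_equal(v[1, 1], bliss_variance(counts, as.list(p)), tolerance = 1e-7)
})

test_that("Loewner comparisons behave and reject asymmetric input", {
  expect_true(loewner_leq(diag(2), 2 * diag(2))$leq)
  V <- rand_pd(3)
  expect_true(loewner_leq(V, V)$leq)
  set.seed(59)
  for (i in 1:10) {
    V1 <- rand_pd(3)
    G <- matrix(rnorm(9), 3, 3)
    V2 <- V1 + crossprod(G)
    expect_true(loewner_leq(V1, V2)$leq)
    expect_false(loewner_leq(V2, V1)$leq)
  }
  M <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_error(loewner_leq(M, diag(2)), "symmetric")
})

test_that("efficiency hierarchy: two-step below plug-in, combination below current-only", {
  set.seed(67)
  for (rho in c(1/8, 1/4, 1, 4, 8)) {
    for (i in 1:5) {
      inst <- rand_instance()
      A <- avar_type_a(inst$jac, inst$hist, rho)
      B <- avar_type_b(inst$jac, inst$upsilon, inst$hist, rho)
      C <- avar_type_c(inst$upsilon, inst$hist, rho)
      expect_true(loewner_leq(B, A)$leq)
      expect_true(loewner_leq(C, inst$upsilon)$leq)
    }
  }
})

test_that("theta-variances are monotone non-decreasing in rho", {
  rhos <- c(0.1, 0.5, 1, 2, 8)
  jac <- anova_jac(); hist <- anova_hist()
  ups <- anova_upsilon(design_xi(0.25, 0.25, 0.25, 0.25))
  jac2 <- structure(list(D_theta = matrix(-0.25, 1, 1),
                         D_eta = -0.25 * matrix(1, 1, 3),
                         D_blocks = list(-0.25 * matrix(1, 1, 3)),
                         meat = matrix(0.25, 1, 1), p = 1L, q = 3L, n = 100L),
                    class = "jacobian_set")
  a_vals <- vapply(rhos, function(r) pc_block(avar_type_a(jac, hist, r), "tt")[1, 1],
                   numeric(1))
  b_vals <- vapply(rhos, function(r)
    pc_block(avar_type_b(jac2, ups, hist, r), "tt")[1, 1], numeric(1))
  expect_true(all(diff(a_vals) >= 0))
  expect_true(all(diff(b_vals) >= 0))
})

test_that("sufficient dominance conditions evaluate correctly", {
  set.seed(73)
  inst <- rand_instance()
  # identical estimating functions: both conditions hold with equality
  rep1 <- check_comparison_conditions(inst$jac, inst$jac)
  expect_true(rep1$cond17)
  expect_true(rep1$cond18)
  expect_true(rep1$implies_b_leq_c)

  # inflating the meat of the comparison function preserves condition 18
  jac_l <- inst$jac
  jac_l$meat <- 2 * jac_l$meat
  expect_true(check_comparison_conditions(inst$jac, jac_l)$cond18)

  # end-to-end on an ANOVA-style instance: conditions + Loewner conclusion
  jac_psi <- anova_jac()
  jac_lam <- anova_jac()
  jac_lam$meat <- matrix(1.5, 1, 1)   # lambda is a noisier estimating function
  rep2 <- check_comparison_conditions(jac_psi, jac_lam)
  expect_true(rep2$implies_b_leq_c)
  ups <- anova_upsilon(design_xi(0.25, 0.25, 0.25, 0.25))
  hist <- anova_hist()
  B <- avar_type_b(jac_psi, ups, hist, rho = 1)
  # C built from the same pooled kernel dominates B (theta block)
  C <- avar_type_c(ups, hist, rho = 1)
  expect_true(loewner_leq(pc_block(B, "ee"), pc_block(C, "ee"))$leq)
})

test_that("per_study_scale divides the asymptotic matrix by n", {
  A <- avar_type_a(anova_jac(), anova_hist(), rho = 1)
  expect_equal(per_study_scale(A, 100), as.matrix(A) / 100,
               ignore_attr = TRUE)
})
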