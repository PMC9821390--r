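# shared fixtures, built in code

# random symmetric positive-definite matrix
rand_pd <- function(d, scale = 1) {
  G <- matrix(rnorm(d * d), d, d)
  scale * (crossprod(G) + diag(d))
}

# factorial ANOVA estimating functions (quasi-score contrasts), vectorized
anova_ef <- function() {
  estfun(
    psi = function(theta, eta, y) {
      r <- y$y - eta[1] - eta[2] * y$t1 - eta[3] * y$t2 - theta * y$t1 * y$t2
      r * y$t1 * y$t2
    },
    gamma = function(theta, eta, y) {
      r <- y$y - eta[1] - eta[2] * y$t1 - eta[3] * y$t2 - theta * y$t1 * y$t2
      cbind(r, r * y$t1, r * y$t2)
    },
    p = 1, q = 3, vectorized = TRUE)
}

# plug-in (combination-arm only) ANOVA estimating function
anova_ef_type1 <- function() {
  estfun(function(theta, eta, y) y$y - eta[1] - eta[2] - eta[3] - theta,
         p = 1, q = 3, vectorized = TRUE)
}

# balanced four-arm dataset with exact arm sizes
balanced_anova_data <- function(n, params = list(eta0 = 1, eta1 = 0.5,
                                                 eta2 = 0.5, theta = 0.25,
                                                 sigma2 = 1)) {
  stopifnot(n %% 4 == 0)
  t1 <- rep(c(0, 1, 0, 1), each = n / 4)
  t2 <- rep(c(0, 0, 1, 1), each = n / 4)
  mu <- params$eta0 + params$eta1 * t1 + params$eta2 * t2 + params$theta * t1 * t2
  data.frame(t1 = t1, t2 = t2, y = rnorm(n, mu, sqrt(params$sigma2)))
}

# a random consistent (jacobian_set, historical_set, upsilon) triple with p = 1
rand_instance <- function(q = 3, m = 200, n = 100) {
  jac <- structure(list(
    D_theta = matrix(runif(1, 0.5, 2), 1, 1),
    D_eta = matrix(rnorm(q), 1, q),
    meat = matrix(runif(1, 0.5, 2), 1, 1),
    p = 1L, q = as.integer(q), n = n), class = "jacobian_set")
  jac$D_blocks <- list(jac$D_eta)
  hist <- historical_set(list(historical_study(
    rnorm(q), rand_pd(q, 1 / m), m = m, label = "rand")))
  ups <- partitioned_cov(rand_pd(1 + q), p = 1, q = q)
  list(jac = jac, hist = hist, upsilon = ups, rho = n / m)
}

# exhaustive minimizer of the interaction variance over integer allocations
brute_force_alloc <- function(n, m1, m2, eta1, eta2) {
  theta <- eta1 * eta2
  w <- c((1 - theta) / theta, (1 - eta1) / eta1, (1 - eta2) / eta2)
  grid <- expand.grid(n12 = seq_len(n), n1 = 0:(n - 1))
  grid <- grid[grid$n12 + grid$n1 <= n, ]
  grid$n2 <- n - grid$n12 - grid$n1
  v <- w[1] / grid$n12 + w[2] / (grid$n1 + m1) + w[3] / (grid$n2 + m2)
  min(v)
}
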