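# histest

Frequentist inference and study design when some model parameters come from
previously published ("historical") estimates.

## The problem

A current study of size *n* is analysed with a model indexed by
ω = (θ, η), where θ (the parameter of interest) must be estimated from the
new data but the nuisance vector η = (η₁, …, η_K) has already been estimated
by *K* independent historical studies of total size *m*, each reporting an
estimate η̂ⱼ with its covariance. Common practice plugs the η̂ⱼ in as if they
were the truth, which understates the variance of the resulting estimator —
sometimes drastically. `histest` implements estimators that account for the
historical uncertainty, in two regimes:

* **Type I** (η not identified by the current data): solve the estimating
  equation Ψ(θ, η̂) = 0. The asymptotic covariance of √n(θ̄_A − θ₀) is

  ```
  A_θθ = D_θ⁻¹ [Σ_ψ + ρ D_η Σ D_ηᵀ] D_θ⁻ᵀ,   ρ = lim n/m,
  ```

  where ρ D_η Σ D_ηᵀ is the *plug-in penalty* for substituting estimates for
  the true nuisance values.

* **Type II** (both θ and η identified): first solve Ψ = Γ = 0 jointly for
  (θ̃, η̃) with sandwich covariance Υ; pool η̃ with η̂ by precision weighting
  (GLS), η̄ = (nΥ_ηη⁻¹ + mΣ⁻¹)⁻¹(nΥ_ηη⁻¹η̃ + mΣ⁻¹η̂); then re-solve
  Ψ(θ, η̄) = 0. In the resulting covariance the historical matrix ρΣ is
  replaced by the strictly smaller kernel (Υ_ηη⁻¹ + (ρΣ)⁻¹)⁻¹, and the
  two-step estimator dominates the plug-in one in the Loewner order (B ⪯ A).
  A *summary-combination* variant, θ̄_C = θ̃ − Υ_θη Υ_ηη⁻¹ (η̃ − η̄), needs only
  the current study's summary statistics and satisfies C ⪯ Υ. An
  augmented-equation variant solves both steps as one system and is
  first-order equivalent to the two-step estimator.

Two design applications are included: optimal allocation fractions for a 2×2
factorial combination trial given two historical single-treatment trials
(grid search over the allocation simplex), and a greedy — provably optimal —
integer allocation for a Bliss-independence drug-interaction study that
minimises the large-sample variance of the log contrast
Φ = log θ − log η₁ − log η₂.

## Worked example

Two historical single-treatment trials (balanced, 25 patients per arm) are
pooled and combined with a balanced 2×2 factorial current study of 80
patients to estimate the treatment interaction θ:

```r
library(histest)
set.seed(7)

hist <- anova_backcalculate(
  study1 = list(mean_control = 1.02, mean_treated = 1.55,
                m_control = 25, m_treated = 25),
  study2 = list(mean_control = 0.98, mean_treated = 1.48,
                m_control = 25, m_treated = 25))

t1 <- rep(c(0, 1, 0, 1), each = 20); t2 <- rep(c(0, 0, 1, 1), each = 20)
y  <- rnorm(80, 1 + 0.5 * t1 + 0.5 * t2 + 0.25 * t1 * t2)
fit <- estimate_anova(data.frame(t1, t2, y), hist, design = "type2")
summary(fit)
```

```
Estimator: Type II two-step (pooled nuisance re-estimation) 
n = 80 , m = 100 , rho = n/m = 0.8 
theta: 0.3599 
eta:   1.0955 0.4818 0.4515 

Coefficients:
        Estimate Std. Error z value Pr(>|z|)    
theta.1   0.3599     0.3168   1.136  0.25594    
eta.1     1.0955     0.1253   8.746  < 2e-16 ***
eta.2     0.4818     0.1820   2.647  0.00813 ** 
eta.3     0.4515     0.1857   2.431  0.01505 *  
```

`theta.1` is the estimated interaction with a standard error that carries
both the current-study noise and the (pooled, precision-weighted) historical
uncertainty; under plain plug-in the same data give a larger variance
(Loewner-dominated, here 11 vs 9.33 per unit on the asymptotic scale at
ρ = 1).

Design questions are one-liners:

```r
anova_optimal_design(rho = 1)            # xi = (0.020, 0.243, 0.243, 0.494), value 8.00
bliss_allocate(23, m1 = 10, m2 = 10,
               eta1_hat = 0.3, eta2_hat = 0.3)  # (n12, n1, n2) = (22, 1, 0)
bliss_nmin(10, 10, 0.3, 0.3)$n_min       # 23
```

A thin command-line wrapper for table regeneration and CSV-driven estimation
lives at `inst/cli/histest.R`.

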