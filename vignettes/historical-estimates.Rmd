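---
title: "Accounting for the uncertainty of historical estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for the uncertainty of historical estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histest)
```

## The model and its assumptions

A current study collects data $\mathcal D$ of $n$ i.i.d. observations whose
distribution is indexed by $\omega = (\theta, \eta)$, $\theta \in \mathbb R^p$
the parameter of interest and $\eta \in \mathbb R^q$ a nuisance vector.
Independently, $K$ historical studies of sizes $m_1, \dots, m_K$ (total $m$)
have published estimates $\hat\eta_j$ of disjoint blocks of $\eta$, each
asymptotically normal, $\sqrt{m_j}(\hat\eta_j - \eta_{j,0}) \Rightarrow
N(0, \Sigma_j)$, together with usable estimates of their covariances — the
whole methodology is predicated on the historical studies reporting standard
errors, which is why `historical_study()` takes the *finite-sample*
covariance (squared SEs) as input and derives $\Sigma_j = m_j \,\mathrm{cov}_j$
internally. The stacked historical covariance is
$\Sigma = \mathrm{BlockDiag}(\kappa_1\Sigma_1,\dots,\kappa_K\Sigma_K)$ with
$\kappa_j = m/m_j$.

Two standing assumptions matter in practice:

* **Interchangeability.** All experimental units, historical and current, are
  draws from one population; differences in means are attributable to
  treatment alone. Heterogeneous populations (random-effects pooling) are out
  of scope.
* **Distinct historical blocks.** The general theory treats the $\eta_j$ as
  disjoint. When historical studies share a parameter (both single-treatment
  trials estimate the same control mean, say), the caller must aggregate them
  into one pseudo-study first; `anova_backcalculate()` does exactly this for
  the factorial application, pooling the two control arms by sample size.

All asymptotics are stated for $n/m \to \rho \in (0, \infty)$; the package
uses the finite-sample plug-ins $\rho = n/m$, $\gamma = n/(n+m)$,
$\kappa_j = m/m_j$.

## The three estimators

**Type I (plug-in), `kind = "A"`.** When $\mathcal D$ does not identify
$\eta$, solve $\Psi(\theta, \hat\eta) = 0$. The limiting covariance of
$\sqrt n(\bar\theta_A - \theta_0)$ is
$D_\theta^{-1}[\Sigma_\psi + \rho D_\eta \Sigma D_\eta^T]D_\theta^{-T}$:
the usual sandwich plus the *plug-in penalty*
$\rho D_\eta \Sigma D_\eta^T = \rho \sum_j \kappa_j D_j \Sigma_j D_j^T$,
which grows with the sampling ratio, with the historical noise, and with the
sensitivity $D_j$ of the estimating function to the $j$-th block. The penalty
is returned explicitly (attribute `"penalty"` of `avar_type_a()`) because it
is the quantity a design should try to control; it vanishes only when
$m \gg n$.

**Type II (two-step), `kind = "B"`.** When $\mathcal D$ identifies
$(\theta, \eta)$, step 1 solves $\Psi = \Gamma = 0$ jointly and estimates the
sandwich covariance $\tilde\Upsilon$; step 2 pools
$\bar\eta = (n\tilde\Upsilon_{\eta\eta}^{-1} + m\hat\Sigma^{-1})^{-1}
(n\tilde\Upsilon_{\eta\eta}^{-1}\tilde\eta + m\hat\Sigma^{-1}\hat\eta)$ — the
GLS/normal-MLE combination, with weight matrices satisfying $W_1 + W_2 = I$;
step 3 re-solves $\Psi(\theta, \bar\eta) = 0$. Everywhere $\rho\Sigma$
appeared in the Type-I covariance, the pooled kernel
$K = (\Upsilon_{\eta\eta}^{-1} + (\rho\Sigma)^{-1})^{-1}$ appears instead.
Since $K \preceq \rho\Sigma$, the two-step covariance is Loewner-below the
plug-in one — re-estimating the nuisance parameters never hurts
asymptotically, and `estimate_type_a()` warns when it detects that a Type-II
analysis was possible.

**Summary combination, `kind = "C"`.** When only the current study's
estimates and covariance are available (coarsened data), a regression
adjustment $\bar\theta_C = \tilde\theta - \tilde\Upsilon_{\theta\eta}
\tilde\Upsilon_{\eta\eta}^{-1}(\tilde\eta - \bar\eta)$ moves $\tilde\theta$
toward the information in $\hat\eta$; this generalizes the classical double
sampling regression estimator. Its covariance satisfies $C \preceq \Upsilon$
(always beneficial), collapsing in the scalar case to the relative efficiency
$1 - w_2 r^2 \in [1 - r^2,\, 1]$ computed by `scalar_are()`. Operating on
summaries can lose efficiency relative to the two-step estimator;
`check_comparison_conditions()` evaluates the two sufficient conditions
(component-wise sensitivity and Loewner order of the known-nuisance sandwich
cores) under which $B \preceq C$.

**Augmented equations, `kind = "augmented"`.** A referee-style variant that
solves $\Psi(\theta,\eta) = 0$ and $n\bar\Gamma(\theta,\eta) +
m\hat\Sigma^{-1}(\hat\eta - \eta) = 0$ as a single system (the second term is
the pseudo-score of the historical normal limit). It has the same limiting
distribution as the two-step estimator, so its reported covariance is the
Type-II matrix. On fixed data the two coincide *exactly* in the linear normal
model only when the pooling uses the model-based $\Upsilon_{\eta\eta}$; with
the empirical sandwich they differ by $O_p(n^{-1})$, which the test suite
checks as a rate property (log-RMS difference with slope $\le -1/2$ in
$\log n$). The evaluation point for $\hat\Sigma$ is the published historical
covariance, not a re-estimate — the stated form of the augmented system.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `tol` | `solve_root()` | `1e-10` on $\|F\|_\infty$ | all in-scope systems are smooth and low-dimensional; damped Newton reaches this in a handful of steps |
| `max_iter` | `solve_root()` | 100 | generous for the intended systems |
| finite-difference step | internal | $\varepsilon^{1/3}\max(1,|x|)$, central | balances $O(h^2)$ truncation and $O(\varepsilon/h)$ roundoff at $\sim\!3\times10^{-11}$; $\sqrt\varepsilon$ (the forward-difference optimum) leaves $\sim\!10^{-8}$ roundoff and breaks the $10^{-10}$ closed-form coincidences the linear model admits |
| Loewner tolerance | `loewner_leq()` | `1e-8` relative to trace | the orderings are exact mathematically; floating point needs slack |
| `min_xi00` | `anova_optimal_design()` | 0.02 | below this the design covariance is numerically non-invertible; a configuration floor, not a hard-coded constant |
| `step` | `anova_optimal_design()` | 0.001 | grid resolution of the published search |
| `n_max` | `bliss_nmin()` | 10000 | scan bound; an explicit "exceeded" result is returned rather than an error |

Expectations appearing in the limit matrices are replaced by sample averages
at the plugged-in parameter values (standard sandwich practice). All matrix
inverses are computed as linear solves and symmetric results are
re-symmetrized as $(M + M^T)/2$; all covariances live on the $\sqrt n$ scale,
with `per_study_scale()` (or `vcov()`) converting to the estimator scale.

## Design applications

**2×2 factorial combination trial.** Two historical single-treatment trials
give, after back-calculation and control pooling, $\hat\eta =
(\hat\eta_0,\hat\eta_1,\hat\eta_2)$ with covariance
$\sigma^2\left(\begin{smallmatrix}2&-2&-2\\-2&6&2\\-2&2&6\end{smallmatrix}\right)$
in the balanced equal-size case. For a current study allocating fractions
$\xi = (\xi_{00},\xi_{10},\xi_{01},\xi_{11})$ to the four cells, the
interaction variance is $\sigma^2(1 + 10\rho)$ for the single-arm (Type I)
design and $\sigma^2(\xi_{11}^{-1} + \mathbf 1^T K \mathbf 1)$ for interior
(Type II) designs. `anova_optimal_design()` minimizes the latter by
exhaustive grid search restricted to $\xi_{01} = \xi_{10}$ (a symmetry of the
balanced historical covariance; an asymmetric $\Sigma$ could in principle
break it, which is why `Sigma` is an argument) — ties are broken toward
larger $\xi_{11}$, then larger $\xi_{10}$, for determinism. A three-arm
variant with no control cell (`anova_var_threearm()`, `pool_linear()`)
interpolates between the two and shows that for small $\rho$ the single-arm
design is essentially optimal. Two printing notes: the general design
covariance display we reproduce had its $(4,4)$ entry corrected to
$\xi_{00}^{-1} + \xi_{01}^{-1}$ (verified against the covariance of the
explicit linear map of arm means), and the reference table of asymptotic
variances carries a rounding inconsistency in its first row (9.30 where the
$\rho$-only formula gives 9.33); the formula is authoritative.

**Bliss-independence interaction study.** Two drugs with no-effect
probabilities $\eta_1, \eta_2$ are Bliss independent when the combination's
no-effect probability is $\theta = \eta_1\eta_2$; the interaction measure is
$\Phi = \log\theta - \log\eta_1 - \log\eta_2$ with large-sample variance
$\frac{1}{n_{12}}\frac{1-\theta}{\theta} +
\frac{1}{n_1+m_1}\frac{1-\eta_1}{\eta_1} +
\frac{1}{n_2+m_2}\frac{1-\eta_2}{\eta_2}$. Allocation uses integer counts
throughout (single-dose experiments must be analysed on observed
frequencies) and plug-in design values $\hat\eta_1, \hat\eta_2,
\theta = \hat\eta_1\hat\eta_2$. The greedy allocator assigns each observation
to the arm with the largest marginal variance reduction; because the
objective is separable with strictly decreasing marginal gains, the greedy
solution attains the exhaustive integer optimum (the suite verifies this by
enumeration for all $n \le 40$ over an $(\eta, m)$ grid). Optima need not be
unique — with equal arms the single replication can go to either margin — so
ties are broken deterministically: combination arm, then drug 1, then drug 2.
`bliss_nmin()` reports the smallest $n$ at which the optimal design starts
replicating a historical arm; one prose example in the source literature
(55/1 at $m_1=30, m_2=50, \hat\eta_1=0.7, \hat\eta_2=0.8, n=56$) is
inconsistent with the stated marginal-reduction algorithm (which first
replicates arm 1 near $n \approx 42$) and is deliberately not reproduced.

## What the synthetic generators emulate — and what they do not

`simulate_current()` / `simulate_historical()` generate exactly the stated
worlds: homoscedastic normal factorial outcomes with arm sizes
$\mathrm{round}(n\xi)$, and two balanced, equal-size historical
single-treatment trials (four arms of $m/4$) whose back-calculated estimates
carry the *estimated* covariance downstream, as a real analysis would; the
Bliss scenario draws independent binomial arms. Default parameter values
($\eta_0 = 1, \eta_1 = \eta_2 = 0.5, \theta = 0.25, \sigma^2 = 1$; no-effect
probabilities $0.3$) match the magnitudes used in the reference tables.
Replication $r$ of a run with seed $s$ uses an RNG stream derived from
$(s, r)$, so replications are order-independent.

A green Monte Carlo test therefore establishes that the asymptotic formulas
describe these generators at the tested $(n, m)$ — it does not establish
robustness to heteroscedasticity, dependent observations, non-normal
outcomes, or historical studies drawn from a different population, none of
which the theory covers. Monte Carlo acceptance windows are $\pm 3$ MC
standard errors with the MC-SE of variance entries obtained by jackknife over
replications; coverage checks use the band $[0.93, 0.97]$ at nominal 95% with
2000 replications.

## Degenerate inputs and numerical corners

* $n_{12} = 0$ makes the interaction contrast inestimable; the variance and
  allocation code refuse it (the greedy's first observation is forced to the
  combination arm, where the marginal gain is infinite).
* An empty factorial cell makes the design covariance singular;
  `anova_upsilon()` directs the caller to the Type-I or three-arm analysis.
* Probabilities at 0 or 1 make the log contrast undefined and are rejected.
* `avar_type_c()` computes its result twice — once as the closed-form blocks,
  once as $MVM^T$ from the GLS weights — and errors if the routes disagree
  beyond $10^{-10}$ (relative), turning an implementation bug into a loud
  failure rather than a wrong covariance.
* A singular joint Jacobian in the first step is reported with the advice to
  run a Type-I analysis (the data do not identify $\omega$).

## Known limitations

Small-sample behaviour of the summary-combination estimator can be worse
than the current-only estimator when the regression matrix
$\Upsilon_{\theta\eta}\Upsilon_{\eta\eta}^{-1}$ is poorly estimated; the
package quantifies estimators asymptotically and through its Monte Carlo
harness but implements no small-sample correction. Clustered or longitudinal
meat corrections, random-effects (heterogeneous-population) pooling,
overlapping historical parameter blocks beyond the factorial back-calculation,
and multi-dose response-surface interaction designs are out of scope.
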