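---
title: "Correcting measurement error in baseline biomarkers with a joint longitudinal-survival model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting measurement error in baseline biomarkers with a joint longitudinal-survival model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmbaseline)
```

## The model

A subject's biomarker is observed repeatedly with error,

$$Y_i(t_{ij}) = W_i(t_{ij}) + \varepsilon_{ij}, \qquad
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

where the error-free trajectory is a linear mixed model

$$W_i(t_{ij}) = X_i'(t_{ij})\beta + Z_i'(t_{ij})\,b_i + u_i'\delta, \qquad
b_i \sim \mathrm{MVN}(0, \Sigma).$$

The fixed design holds an intercept, baseline covariates as main effects, and
either a linear term or a restricted cubic spline of measurement time; the
random design holds an intercept and optionally a linear slope or a spline of
time. Measurement errors are independent across occasions with constant
variance (no serial correlation); responses are Gaussian.

The time-to-event submodel is a parametric proportional-hazards model. The
primary association structure ties the hazard to the subject's *true baseline
value*, the subject-specific intercept:

$$h_i(t) = h_0(t)\exp\!\big(\alpha_2(\beta_0 + b_{0i}) + \phi'v_i\big).$$

Two baseline families are supported: Weibull
($H_0(t) = \lambda t^\gamma$) and the flexible parametric (Royston–Parmar)
model, $\log H_0(t) = s(\log t;\, \gamma, k_S)$ with a restricted cubic
spline $s$; with one degree of freedom the spline model is exactly Weibull.
Semi-parametric (unspecified) baselines are deliberately out of scope: with a
shared-random-effects likelihood they understate standard errors.

Because the intercept association is constant in time, the subject's
cumulative hazard is available in closed form,
$H_i(t) = H_0(t)\exp(\alpha_2(\beta_0 + b_{0i}) + \phi'v_i)$, so the joint
likelihood needs quadrature only over the random effects — the key
computational convenience of this parameterisation, and the reason it scales
to simulation studies.

A secondary *current-value* association
$h_i(t) = h_0(t)\exp(\alpha_1 W_i(t) + \phi'v_i)$ is also implemented; there
the inner integral $\int_0^T h_i$ has no closed form and is evaluated with a
fixed 15-node Gauss–Legendre rule per subject (the magnitude used by
established joint-model software). Consequences of that choice are noted
under *Numerical details*.

### Why this corrects regression dilution

The naive comparator model uses the observed baseline measurement,
$h_i(t) = h_0(t)\exp(\alpha_3 Y_{0i} + \phi'v_i)$. Classical measurement
error in $Y_{0i}$ attenuates $\hat\alpha_3$ by roughly
$\Sigma_{11}/(\Sigma_{11} + \sigma_e^2)$ — about one half when the error SD
equals the between-subject SD. The joint model separates $\sigma_e$ from
$\Sigma$ using the repeated measures and estimates the association with the
latent level itself, removing that bias. `surv_fit(..., baseline = TRUE)`
fits the naive model so both are always available for comparison.

## Estimation

The joint log-likelihood per subject integrates
(longitudinal density) × (survival density) × (random-effect prior) over
$b_i$:

* **Adaptive Gauss–Hermite quadrature.** For each subject the log-integrand
  (which is log-concave here) is maximised by a safeguarded Newton method
  warm-started at the longitudinal-only empirical-Bayes mean; the rule is
  recentred at that mode and rescaled by the Cholesky factor of the inverse
  negative Hessian (Laplace rescaling). The default is 9 nodes per dimension
  (odd, so a node sits at the mode); a non-adaptive fallback centred at the
  prior is available via `jm_control(adaptive = FALSE)`. On the designs used
  in the tests the adaptive log-likelihood moves by less than $10^{-4}$ per
  subject between 9, 15 and 25 nodes.
* **Unconstrained parameterisation.** $\log\sigma_e$ and the log-Cholesky
  factor of $\Sigma$ (log diagonal, free off-diagonal), so every iterate
  corresponds to a positive-definite covariance. Weibull baselines are
  parameterised as $(\log\lambda, \gamma)$ through the same spline-coefficient
  slot used by the flexible parametric family.
* **Two-phase quasi-Newton.** BFGS with central-difference gradients, a loose
  phase (relative tolerance $10^{-4}$) followed by a tight phase
  ($10^{-9}$). Starting values are two-stage: the mixed model is fitted by
  profiled (GLS) maximum likelihood, then a survival model is fitted with the
  empirical-Bayes subject intercepts as a covariate; this start is usually
  within a few likelihood units of the optimum. One jittered restart is
  attempted on failure; non-convergence is flagged on the returned object,
  never silently ignored.
* **Standard errors** come from the inverse of the numeric observed
  information (central second differences) at the optimum; Wald 95% intervals
  are reported on the estimation scale, with delta-method natural-scale
  summaries in `summary()`.

The likelihood kernel is compiled (RcppArmadillo) because a simulation study
evaluates it millions of times; all orchestration stays in R.

## Restricted cubic splines

Both spline uses (trajectory in time; log cumulative hazard in log time)
share one basis: column 1 is $x$ itself, higher columns are truncated-cubic
terms constrained so every fitted function is linear beyond the boundary
knots. Boundary knots sit at the data minimum/maximum and interior knots at
equally spaced centiles (linear-interpolation quantiles) — for the survival
baseline, centiles of the *log event times*. The basis is deliberately left
unscaled and unorthogonalised so coefficients correspond directly to the
basis construction; this means reported spline coefficients are
parameterisation-dependent and not comparable across software that scales or
orthogonalises. Degrees of freedom are chosen by the user, typically by
AIC/BIC comparison of separate submodel fits (`compare_models()`); BIC uses
the number of subjects as $n$.

## The synthetic-data generator

`sim_scenario()` / `simulate_joint()` generate the study conditions used
throughout the tests: 300 subjects; random intercept (SD 1) and slope
(SD 0.25), correlation 0.25; zero fixed intercept and slope; measurement
error SD in {0.1, 0.5, 1}; Weibull hazard with $\lambda = 0.1$,
$\gamma = 1.5$; a Bernoulli(0.5) treatment with log hazard ratio $-0.5$ and a
N(65, 12²) age with log hazard ratio 0.01 (the "N(65,12)" of the design is
read as an SD of 12, the conventional notation in the applied literature);
association acting on the subject intercept with
$\alpha \in \{-0.5, -0.25, 0.25, 0.5\}$; up to five annual visits (baseline
always retained, later visits only while the subject is still under
observation — the only coherent choice under the joint likelihood's
factorisation); administrative censoring at 5 years. Event times are drawn by
analytic inversion of the Weibull cumulative hazard. At the covariate means
(treatment 0.5, age 65, zero random intercept) 5-year survival is
$\exp(-0.1\cdot 5^{1.5} e^{0.4}) \approx 18.9\%$.

One `set.seed()` call per dataset drives all draws, so a (scenario, seed)
pair is fully reproducible; replicate $r$ of a study uses seed
`base_seed + r`.

What the generator does *not* emulate: covariate effects on the biomarker,
non-linear true trajectories, non-Gaussian errors, serial correlation,
informative censoring or visit schedules tied to disease severity. Passing
tests therefore demonstrate correctness of the estimator under the stated
generating model, not robustness to those violations.

## The simulation harness

`run_scenario()` simulates replicates, fits the naive Weibull model (observed
baseline + age + treatment) and the joint model (random intercept + slope,
intercept association, age and treatment in the survival submodel), and
summarises bias, percentage bias ($100 \cdot \text{bias}/\alpha$, so
attenuation is negative for either sign of $\alpha$), MSE, and coverage of
nominal 95% Wald intervals, each with Monte-Carlo standard errors
(sd$/\sqrt{R}$ for bias, binomial for coverage) so scaled-down runs remain
interpretable. Non-convergent replicates are dropped and counted, never
imputed. Replicate-level estimates are persisted to CSV so any summary can be
recomputed exactly (`summarise_replicates()`, CLI `report`).

Desk-scale defaults in the tests and the acceptance script use 100–200
replicates per scenario rather than 1000; the Monte-Carlo standard errors
reported alongside every metric quantify the resulting noise.

## Prediction for a new baseline-only patient

For a new patient with one baseline measurement $Y_0$, the posterior of the
random effects given that single record is Gaussian in closed form — the
posterior mean of $b_0$ is the classic shrinkage estimator
$\frac{\Sigma_{11}}{\Sigma_{11} + \sigma_e^2}(Y_0 - \text{fixed part})$.
Survival information is deliberately *not* conditioned on (the patient's
future is unknown at prediction time; conditioning on event-free survival to
a landmark is out of scope). `predict_survival()` returns two curves:

* **plug-in** — $S(t)$ at the posterior mean of $b_0$;
* **marginal** (the default to report) —
  $E[\exp(-H(t \mid b_0))]$ over the Gaussian posterior by Gauss–Hermite
  quadrature, which propagates the baseline-measurement uncertainty into the
  curve. This is the package's recommended output since that propagation is
  the point of the method.

A naive-model curve can be attached for comparison. Note one subtlety
verified in the tests: in the generating design above, the naive model is
close to the correctly marginalised model (Gaussian shrinkage and attenuation
nearly cancel), so the joint-vs-naive gap in *predictions* is modest and the
posterior-averaged curve can even sit above the naive curve deep in the tail
(Jensen's inequality); the clear, large bias is in the *association
estimate*, which is what drives risk discrimination.

`fitted_trajectories()` returns empirical-Bayes trajectories for training
subjects for spaghetti-style diagnostics (`plot()` on a fitted model).

## Numerical details and edge cases

* Quadrature overflow is guarded by computing every subject's contribution
  with log-sum-exp and capping exponents; invalid parameter proposals
  (non-positive-definite $\Sigma$, non-positive hazard at an event time)
  return a large penalty rather than an error, so the optimiser can retreat.
* A flexible parametric baseline can propose a non-monotone cumulative hazard
  during optimisation (negative spline derivative). Event-time contributions
  then have no valid log hazard and are penalised; a *fitted* model whose
  baseline is non-monotone anywhere on the observed time range carries a
  `monotone = FALSE` flag and a printed warning rather than a hard failure —
  the standard practice for this model family.
* Under the current-value association the inner Gauss–Legendre rule carries
  $O(m^{-3})$ error from the $t^{\gamma-1}$ kink at the origin; at 15 nodes
  this is of order $10^{-5}$ per subject, visible only in exact-identity
  tests (the $\alpha = 0$ factorisation holds to $5\times10^{-3}$ over 150
  subjects rather than machine precision). The intercept association — the
  primary structure — has no such term.
* Ties and duplicated measurement times are permitted; measurements recorded
  after a subject's observed time are a validation error, since the model
  assumes observation stops at the event/censoring time.
* The random-slope column of the random design is raw time (not the first
  fixed-spline column) when the fixed part is a spline; the two scalings
  coincide for linear fixed parts.

## Design choices made where the design was open

* **Knot conventions** (boundary at min/max, interior at equal centiles,
  survival knots on log event times) follow the flexible-parametric software
  tradition; there are no canonical knot locations to match, so spline
  *coefficients* are not comparable across implementations, only fitted
  curves are.
* **Adaptive quadrature with 9 nodes** as the default: the accepted standard
  for shared-random-effects joint models; the node-stability invariant above
  is the evidence it suffices on these designs.
* **Replicate seeds** `base_seed + r` with one RNG stream per dataset: simple,
  exactly reproducible, and independent of parallelisation (which this
  package does not use).
* **Coverage** uses symmetric Wald intervals on the untransformed association
  parameter, matching how such models are routinely reported.
* **Problem sizes** in the tests: 100–200 replicates at $n = 300$ for
  operating characteristics, one $n = 5000$ run for parameter recovery —
  sizes at which the Monte-Carlo error is small relative to the effects being
  demonstrated.

## Known limitations

Delayed entry/left truncation, competing risks, non-Gaussian biomarkers,
serial correlation in the errors, multiple biomarkers, slope/variability
association structures, Bayesian estimation and dynamic (post-baseline)
risk updating are not implemented. The naive model's direction-of-bias
results here concern classical (independent, additive, Gaussian) measurement
error; other error mechanisms can bias away from the null.
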