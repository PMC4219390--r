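# jmbaseline

Joint longitudinal–survival models for error-prone **baseline** biomarkers.

## The problem

Prognostic survival models routinely include a biomarker measured at baseline
(blood pressure, BMI, lab values) as a fixed covariate:

```
h_i(t) = h_0(t) exp(α₃ Y_0i + φ'v_i)
```

But a single measurement `Y_0i` is the true level plus measurement error, and
classical error in a regressor attenuates its estimated log hazard ratio
toward the null (*regression dilution*). Registry data usually contain many
repeated measurements per subject that are simply ignored by this approach.

`jmbaseline` instead fits a **joint model**: a linear mixed model for the
repeated biomarker,

```
Y_i(t_ij) = W_i(t_ij) + ε_ij,   ε_ij ~ N(0, σ_e²)
W_i(t_ij) = X_i'(t_ij)β + Z_i'(t_ij)b_i + u_i'δ,   b_i ~ MVN(0, Σ)
```

linked to a parametric proportional-hazards model through the
**subject-specific intercept** (the true baseline value):

```
h_i(t) = h_0(t) exp(α₂ (β₀ + b_0i) + φ'v_i)
```

Because this association is time-independent, the cumulative hazard stays in
closed form under parametric baselines — no nested quadrature — and only the
random effects are integrated out, by adaptive Gauss–Hermite quadrature. The
association `α₂` is the log hazard ratio per unit of the *true* baseline
level, free of dilution bias, and the same machinery yields
measurement-error-corrected survival predictions for new patients seen only
once at baseline.

Trajectories may be flexible (restricted cubic splines of time in the mixed
model) and the baseline hazard may be Weibull or a Royston–Parmar flexible
parametric model (restricted cubic spline for the log cumulative hazard in
log time; with 1 df it *is* Weibull).

## A worked example

Simulate the package's evaluation design (300 subjects, annual biomarker
visits, Weibull hazard λ=0.1, γ=1.5, administrative censoring at 5 years,
association α=0.5, measurement error SD 1), then fit the naive model and the
joint model:

```r
library(jmbaseline)

sim <- simulate_joint(sim_scenario(alpha = 0.5, sigma_e = 1), seed = 42)

naive <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
naive$alpha
#> [1] 0.1776771

joint <- jm_fit(sim$long, sim$surv, long_spec(random = "slope"),
                surv_covariates = c("trt", "age"))
print(joint)
#> Joint longitudinal-survival model (intercept association, weibull baseline)
#>   subjects: 300  measurements: 934  events: 244
#>   logLik: -2062.74
#>   association alpha: 0.5373 (SE 0.1075, 95% CI 0.3265 to 0.7480)
#>   sigma_e: 0.9994
```

The naive log hazard ratio (0.178) is attenuated to roughly a third of the
generating value 0.5; the joint estimate (0.54, 95% CI 0.33–0.75) covers it.
Over replicates the naive bias is ≈ −0.26 (−52%) with near-zero coverage,
while the joint model is unbiased with ~95% coverage — see
`run_scenario()` / `table1_report()` for the full bias/%bias/MSE/coverage
machinery, and `predict_survival()` for corrected survival curves for a new
patient with a single baseline measurement.

A thin command-line wrapper covering `simulate`, `fit`, `simstudy`,
`predict` and `report` is installed at
`system.file("cli/jmbaseline", package = "jmbaseline")`.

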