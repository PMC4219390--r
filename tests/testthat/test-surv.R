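test_that("Weibull hazard/cumulative hazard match closed forms", {
  # the evaluation design: lambda 0.1, gamma 1.5, linpred at covariate means
  lin <- -0.5 * 0.5 + 0.01 * 65
  out <- weibull_hazard_cumhaz(5, 0.1, 1.5, lin)
  expect_equal(round(exp(-out$cumhaz), 3), 0.189)
  expect_equal(weibull_hazard_cumhaz(0, 0.1, 1.5)$cumhaz, 0)

  # gamma = 1: constant hazard (exponential)
  h <- weibull_hazard_cumhaz(c(0.5, 1, 2, 7), 0.3, 1, 0.2)$hazard
  expect_equal(h, rep(0.3 * exp(0.2), 4))

  # numeric integral of h equals H
  for (tt in c(0.5, 2, 5)) {
    Hnum <- stats::integrate(function(s) weibull_hazard_cumhaz(s, 0.1, 1.5, lin)$hazard,
                             0, tt, rel.tol = 1e-12)$value
    expect_equal(Hnum, weibull_hazard_cumhaz(tt, 0.1, 1.5, lin)$cumhaz,
                 tolerance = 1e-8)
  }
  expect_error(weibull_hazard_cumhaz(-1, 0.1, 1.5), "negative")
})

test_that("one-df spline baseline is exactly Weibull", {
  kn <- rcs_knots(c(0.2, 5), df = 1, scale = "log")
  lam <- 0.23; gam <- 1.7
  tt <- seq(0.01, 10, length.out = 200)
  ev <- fpm_eval(tt, c(log(lam), gam), kn, linpred = 0.3)
  wb <- weibull_hazard_cumhaz(tt, lam, gam, 0.3)
  expect_equal(exp(ev$logcumhaz), wb$cumhaz, tolerance = 1e-10)
  expect_equal(ev$hazard, wb$hazard, tolerance = 1e-10)
  expect_true(ev$monotone)
})

test_that("spline cumulative hazard is monotone when s' > 0, hazard matches numeric differentiation", {
  set.seed(4)
  kn <- rcs_knots(rexp(300, 0.3), df = 3, scale = "log")
  gam <- c(-1.5, 1.2, 0.1, -0.05)
  tt <- seq(0.05, 8, length.out = 100)
  ev <- fpm_eval(tt, gam, kn)
  if (ev$monotone) expect_true(all(diff(exp(ev$logcumhaz)) > 0))
  h <- 1e-6
  Hnum <- (exp(fpm_eval(tt + h, gam, kn)$logcumhaz) -
           exp(fpm_eval(tt - h, gam, kn)$logcumhaz)) / (2 * h)
  expect_equal(ev$hazard, Hnum, tolerance = 1e-5)
  expect_error(fpm_eval(c(-1, 2), gam, kn), "positive")
})

test_that("naive Weibull fit finds no signal when there is none", {
  # alpha = 0 and large measurement error: baseline_obs carries no hazard signal
  sim <- sim_small(seed = 10, n = 400, alpha = 0, sigma_e = 2)
  f <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  expect_true(f$converged)
  expect_lt(abs(f$alpha / f$alpha_se), 2)
})

test_that("fitted log-likelihood beats the generating parameters and doubles with duplicated data", {
  sim <- sim_small(seed = 2, n = 200, alpha = 0.5, sigma_e = 0.5)
  f <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  # ML property: optimum at least as good as any other point, e.g. the truth
  lin_true <- 0.5 * sim$surv$baseline_obs - 0.5 * sim$surv$trt + 0.01 * sim$surv$age
  expect_gte(f$loglik, surv_loglik_oracle(sim$surv, 0.1, 1.5, lin_true))

  # doubling every subject doubles the log-likelihood exactly
  lin_hat <- drop(as.matrix(sim$surv[, c("baseline_obs", "trt", "age")]) %*%
                    f$coefficients)
  ll1 <- surv_loglik_oracle(sim$surv, exp(f$gamma[1]), f$gamma[2], lin_hat)
  doubled <- rbind(sim$surv, transform(sim$surv, id = id + 10000))
  lin2 <- c(lin_hat, lin_hat)
  ll2 <- surv_loglik_oracle(doubled, exp(f$gamma[1]), f$gamma[2], lin2)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  expect_equal(f$loglik, ll1, tolerance = 1e-8)
})

test_that("Weibull PH estimates agree with survreg (AFT reparameterisation)", {
  skip_if_not_installed("survival")
  sim <- sim_small(seed = 6, n = 300, alpha = 0.5, sigma_e = 0.5)
  f <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  sr <- survival::survreg(survival::Surv(time, event) ~ baseline_obs + trt + age,
                          data = sim$surv, dist = "weibull")
  # PH log hazard ratios = -AFT coefficients / scale
  expect_equal(unname(f$coefficients), unname(-coef(sr)[-1] / sr$scale),
               tolerance = 1e-4)
  expect_equal(f$gamma[2], 1 / sr$scale, tolerance = 1e-4)
})

test_that("cumulative hazard vanishes at the time origin for fitted models", {
  sim <- sim_small(seed = 12, n = 250, alpha = 0.25, sigma_e = 0.5)
  fw <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  expect_lt(weibull_hazard_cumhaz(1e-8, exp(fw$gamma[1]), fw$gamma[2])$cumhaz, 1e-8)
  ff <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE,
                 family = "fpm", df = 2)
  expect_true(ff$converged)
  expect_lt(exp(fpm_eval(1e-8, ff$gamma, ff$knots)$logcumhaz), 1e-6)
})

test_that("information criteria support the df-selection workflow", {
  sim <- sim_small(seed = 8, n = 250, alpha = 0.25, sigma_e = 0.5)
  fw <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  ff <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE,
                 family = "fpm", df = 2)
  cmp <- compare_models(weibull = fw, fpm2 = ff)
  # AIC/BIC recomputed from the fields
  expect_equal(cmp["weibull", "AIC"], -2 * fw$loglik + 2 * attr(logLik(fw), "df"))
  expect_equal(cmp["fpm2", "BIC"],
               -2 * ff$loglik + log(nrow(sim$surv)) * attr(logLik(ff), "df"))
  # nesting: the df-2 spline model contains the Weibull (df-1) model
  expect_gte(ff$loglik, fw$loglik - 1e-6)
  # BIC penalty uses the number of subjects
  expect_equal(attr(logLik(fw), "nobs"), nrow(sim$surv))
})
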