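test_that("at alpha = 0 the joint likelihood factorises into LMM + survival", {
  sim <- sim_small(seed = 7, n = 150)
  sp <- long_spec(random = "slope")
  pars <- design_params(alpha = 0)
  ll_lmm <- lmm_loglik(list(beta = pars$beta, sigma_e = pars$sigma_e,
                            Sigma = pars$Sigma), sim$long, sp)
  lin <- -0.5 * sim$surv$trt + 0.01 * sim$surv$age
  ll_surv <- surv_loglik_oracle(sim$surv, 0.1, 1.5, lin)
  jl <- joint_loglik(pars, sim$long, sim$surv, sp,
                     surv_covariates = c("trt", "age"))
  expect_equal(jl, ll_lmm + ll_surv, tolerance = 1e-6)
  # current-value association: the inner cumulative-hazard integral uses a
  # fixed Gauss-Legendre rule, so the factorisation holds to that rule's
  # accuracy rather than exactly
  jc <- joint_loglik(pars, sim$long, sim$surv, sp,
                     surv_covariates = c("trt", "age"), association = "current")
  expect_equal(jc, ll_lmm + ll_surv, tolerance = 5e-3)
})

test_that("closed-form intercept-association cumulative hazard equals numeric quadrature", {
  sim <- sim_small(seed = 15, n = 20)
  pars <- design_params()
  set.seed(3)
  for (i in 1:20) {
    b0 <- rnorm(1)
    lin <- pars$alpha * (0 + b0) - 0.5 * sim$surv$trt[i] + 0.01 * sim$surv$age[i]
    Ti <- sim$surv$time[i]
    Hcf <- weibull_hazard_cumhaz(Ti, 0.1, 1.5, lin)$cumhaz
    Hq <- stats::integrate(function(s) weibull_hazard_cumhaz(s, 0.1, 1.5, lin)$hazard,
                           0, Ti, rel.tol = 1e-12, abs.tol = 1e-14)$value
    expect_equal(Hcf, Hq, tolerance = 1e-8)
  }
})

test_that("quadrature equals dense-grid integration for a single subject", {
  long <- data.frame(id = 1, time = 0, value = 1.3, trt = 0, age = 60)
  surv <- data.frame(id = 1, time = 2.5, event = 1, trt = 0, age = 60)
  pars <- list(beta = c(0.2, 0), sigma_e = 0.7, Sigma = matrix(1.2),
               gamma = c(log(0.1), 1.5), phi = c(-0.5, 0.01), alpha = 0.4)
  jl <- joint_loglik(pars, long, surv, long_spec(random = "intercept"),
                     surv_covariates = c("trt", "age"))
  b <- seq(-8 * sqrt(1.2), 8 * sqrt(1.2), length.out = 1e5)
  hz <- weibull_hazard_cumhaz(2.5, 0.1, 1.5, 0.4 * (0.2 + b) + 0.01 * 60)
  f <- dnorm(1.3, 0.2 + b, 0.7) * hz$hazard * exp(-hz$cumhaz) * dnorm(b, 0, sqrt(1.2))
  expect_equal(jl, log(pracma::trapz(b, f)), tolerance = 1e-6)
})

test_that("adaptive quadrature is stable in the node count", {
  sim <- sim_small(seed = 5, n = 120, sigma_e = 1)
  pars <- design_params(sigma_e = 1)
  lls <- vapply(c(9, 15, 25), function(nn)
    joint_loglik(pars, sim$long, sim$surv, long_spec(random = "slope"),
                 surv_covariates = c("trt", "age"),
                 control = jm_control(nodes = nn)), numeric(1))
  expect_lt(max(abs(diff(lls))) / 120, 1e-4)
  expect_error(jm_control(nodes = 8), "odd")
})

test_that("joint fit recovers the association and respects scaling invariance", {
  sim <- sim_small(seed = 30, n = 150, alpha = 0.5, sigma_e = 0.5)
  sp <- long_spec(random = "slope")
  f1 <- jm_fit(sim$long, sim$surv, sp, surv_covariates = c("trt", "age"))
  expect_true(f1$converged)
  expect_lt(abs(f1$alpha - 0.5), 3 * f1$alpha_se)
  expect_true(all(eigen(f1$vcov, symmetric = TRUE, only.values = TRUE)$values > 0))

  # multiply the biomarker by c: alpha scales by 1/c, the maximised loglik
  # shifts by the Gaussian Jacobian -N log(c)
  cc <- 3
  long2 <- transform(sim$long, value = value * cc)
  surv2 <- transform(sim$surv, baseline_obs = baseline_obs * cc)
  f2 <- jm_fit(long2, surv2, sp, surv_covariates = c("trt", "age"))
  expect_true(f2$converged)
  expect_equal(f2$alpha, f1$alpha / cc, tolerance = 1e-2)
  expect_equal(f2$loglik, f1$loglik - nrow(sim$long) * log(cc), tolerance = 1e-4)
})

test_that("negating the response mirrors the fit (sign symmetry)", {
  sim <- sim_small(seed = 31, n = 120, alpha = 0.5, sigma_e = 0.5)
  sp <- long_spec(random = "slope")
  f1 <- jm_fit(sim$long, sim$surv, sp, surv_covariates = c("trt", "age"))
  long2 <- transform(sim$long, value = -value)
  surv2 <- transform(sim$surv, baseline_obs = -baseline_obs)
  f2 <- jm_fit(long2, surv2, sp, surv_covariates = c("trt", "age"))
  expect_equal(f2$alpha, -f1$alpha, tolerance = 1e-3)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-4)
})

test_that("current-value association fits and nests the separate models", {
  sim <- sim_small(seed = 33, n = 80, alpha = 0.25, sigma_e = 0.5)
  sp <- long_spec(random = "slope")
  f <- jm_fit(sim$long, sim$surv, sp, surv_covariates = c("trt", "age"),
              association = "current")
  expect_true(f$converged)
  expect_true(is.finite(f$alpha_se))
})

test_that("model comparison table is consistent across joint model families", {
  sim <- sim_small(seed = 34, n = 120, alpha = 0.5, sigma_e = 0.5)
  sp <- long_spec(random = "slope")
  fw <- jm_fit(sim$long, sim$surv, sp, surv_covariates = c("trt", "age"))
  ff <- jm_fit(sim$long, sim$surv, sp, surv_covariates = c("trt", "age"),
               family = "fpm", df = 2)
  expect_true(ff$converged)
  # the df-2 spline baseline nests the Weibull: no loglik decrease
  expect_gte(ff$loglik, fw$loglik - 1e-4)
  cmp <- compare_models(weibull = fw, fpm = ff)
  expect_equal(cmp$k, c(11, 12))
  expect_equal(cmp["weibull", "AIC"], -2 * fw$loglik + 2 * 11)
  expect_equal(cmp["fpm", "BIC"], -2 * ff$loglik + log(120) * 12)
})

test_that("a fitted joint model serialises to JSON and back for prediction", {
  sim <- sim_small(seed = 35, n = 100, alpha = 0.5, sigma_e = 0.5)
  f <- jm_fit(sim$long, sim$surv, long_spec(random = "slope"),
              surv_covariates = c("trt", "age"))
  path <- tempfile(fileext = ".json")
  write_jm(f, path)
  f2 <- read_jm(path)
  expect_equal(f2$theta, f$theta, tolerance = 1e-12)
  expect_equal(f2$long$Sigma, f$long$Sigma, tolerance = 1e-12)
  p1 <- predict_survival(f, baseline = 1.2, covariates = c(trt = 1, age = 60),
                         times = c(1, 3, 5))
  p2 <- predict_survival(f2, baseline = 1.2, covariates = c(trt = 1, age = 60),
                         times = c(1, 3, 5))
  expect_equal(p1, p2, tolerance = 1e-10)
})
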