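test_that("single-record posterior is the classic shrinkage estimator", {
  sp <- jmbaseline:::resolve_long_spec(long_spec(random = "intercept"),
                                       data.frame(time = 0:4))
  sb2 <- 1.3; se <- 0.6; y0 <- 2.1; b0fix <- 0.4
  pars <- list(beta = c(b0fix, 0), sigma_e = se, Sigma = matrix(sb2), spec = sp)
  pr <- posterior_ranef(pars, times = 0, values = y0)
  expect_equal(pr$mean, sb2 / (sb2 + se^2) * (y0 - b0fix), tolerance = 1e-12)
  expect_equal(pr$cov[1, 1], 1 / (1 / se^2 + 1 / sb2), tolerance = 1e-12)

  # sigma_e -> 0: the posterior mean reproduces the observation exactly
  pars0 <- list(beta = c(b0fix, 0), sigma_e = 1e-9, Sigma = matrix(sb2), spec = sp)
  expect_equal(posterior_ranef(pars0, 0, y0)$mean, y0 - b0fix, tolerance = 1e-6)
})

test_that("posterior matches dense-grid integration of the joint density", {
  sp <- jmbaseline:::resolve_long_spec(long_spec(random = "intercept"),
                                       data.frame(time = 0:4))
  pars <- list(beta = c(0.2, -0.1), sigma_e = 0.5, Sigma = matrix(0.8), spec = sp)
  tt <- c(0, 1, 3); yy <- c(1.0, 0.6, 1.4)
  pr <- posterior_ranef(pars, tt, yy)
  b <- seq(-6, 6, length.out = 2e5)
  W0 <- 0.2 - 0.1 * tt
  dens <- vapply(b, function(bb)
    prod(dnorm(yy, W0 + bb, 0.5)) * dnorm(bb, 0, sqrt(0.8)), numeric(1))
  Znorm <- pracma::trapz(b, dens)
  mean_grid <- pracma::trapz(b, b * dens) / Znorm
  sd_grid <- sqrt(pracma::trapz(b, (b - mean_grid)^2 * dens) / Znorm)
  expect_equal(pr$mean[1], mean_grid, tolerance = 1e-6)
  expect_equal(sqrt(pr$cov[1, 1]), sd_grid, tolerance = 1e-6)
})

# one moderately sized fitted model shared by the prediction tests
fit_for_prediction <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- sim_small(seed = 40, n = 300, alpha = 0.5, sigma_e = 1)
      memo <<- list(
        sim = sim,
        joint = jm_fit(sim$long, sim$surv, long_spec(random = "slope"),
                       surv_covariates = c("trt", "age")),
        naive = surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE))
    }
    memo
  }
})

test_that("predicted survival is a proper, monotone curve in both modes", {
  fp <- fit_for_prediction()
  tt <- seq(0, 5, by = 0.25)
  for (y0 in c(-2, 0, 2)) {
    cv <- predict_survival(fp$joint, baseline = y0,
                           covariates = c(trt = 1, age = 65), times = tt,
                           naive_fit = fp$naive)
    for (cn in c("surv_plugin", "surv_marginal", "surv_naive")) {
      expect_true(all(cv[[cn]] >= 0 & cv[[cn]] <= 1))
      expect_true(all(diff(cv[[cn]]) <= 1e-12))
    }
    expect_equal(cv$surv_plugin[1], 1)
    expect_equal(cv$surv_marginal[1], 1)
  }
})

test_that("with no association the curve ignores the baseline value", {
  fp <- fit_for_prediction()
  f0 <- fp$joint
  f0$alpha <- 0 # switch the association channel off at the fitted parameters
  a <- predict_survival(f0, baseline = -3, covariates = c(trt = 0, age = 60),
                        times = c(1, 3, 5))
  b <- predict_survival(f0, baseline = 3, covariates = c(trt = 0, age = 60),
                        times = c(1, 3, 5))
  expect_equal(a$surv_marginal, b$surv_marginal, tolerance = 1e-12)
})

test_that("the marginal curve equals a Monte-Carlo average over the posterior", {
  fp <- fit_for_prediction()
  fit <- fp$joint
  y0 <- 1.5; cov <- c(trt = 0, age = 65); tt <- c(1, 3, 5)
  cv <- predict_survival(fit, baseline = y0, covariates = cov, times = tt)
  post <- posterior_ranef(fit, 0, y0)
  set.seed(1)
  b0 <- rnorm(1e6, post$mean[1], sqrt(post$cov[1, 1]))
  H0 <- exp(fit$gamma[1]) * tt^fit$gamma[2]
  vphi <- sum(fit$phi * cov)
  smc <- vapply(seq_along(tt), function(j)
    mean(exp(-H0[j] * exp(vphi + fit$alpha * (fit$long$beta[1] + b0)))),
    numeric(1))
  expect_equal(cv$surv_marginal, smc, tolerance = 1e-4)
  # plug-in and marginal genuinely differ
  expect_gt(max(abs(cv$surv_marginal - cv$surv_plugin)), 1e-4)
})

test_that("joint prediction corrects the naive curve towards more extreme risk", {
  # under attenuation the naive model understates the risk gradient, so for a
  # patient with a high observed baseline the joint model predicts lower
  # survival than the naive model; in the far tail (survival below ~1%) the
  # posterior-averaged curve is lifted by Jensen's inequality, so the
  # marginal-vs-naive comparison is made at a moderate horizon
  sim <- simulate_joint(sim_scenario(n_subjects = 2000, alpha = 0.5,
                                     sigma_e = 1), seed = 41)
  jf <- jm_fit(sim$long, sim$surv, long_spec(random = "slope"),
               surv_covariates = c("trt", "age"), vcov = FALSE)
  nf <- surv_fit(sim$surv, covariates = c("trt", "age"), baseline = TRUE)
  cv <- predict_survival(jf, baseline = 4, covariates = c(trt = 0, age = 65),
                         times = c(1, 5), naive_fit = nf)
  expect_lt(cv$surv_marginal[1], cv$surv_naive[1])
  expect_lt(cv$surv_plugin[2], cv$surv_naive[2])
})

test_that("fitted trajectories shrink towards subjects and respect the structure", {
  fp <- fit_for_prediction()
  fit <- fp$joint
  ids <- unique(fp$sim$long$id)[1:30]
  # zero random effects give the population-average curve
  grid <- seq(0, 4, by = 0.5)
  pop <- trajectory(fit$long_spec, list(beta = fit$long$beta), c(0, 0), grid)
  expect_equal(pop, fit$long$beta[1] + fit$long$beta[2] * grid,
               ignore_attr = TRUE)

  ft <- fitted_trajectories(fit, ids = ids, grid = grid)
  expect_setequal(unique(ft$curves$id), ids)
  # EB fit beats the population curve on average at the observed points
  resid_eb <- abs(residuals(fit))
  long <- fit$data$long
  resid_pop <- abs(long$value - (fit$long$beta[1] + fit$long$beta[2] * long$time))
  expect_lt(mean(resid_eb), mean(resid_pop))
  # linear random structure: fitted minus population curve is affine in t
  c1 <- ft$curves[ft$curves$id == ids[1], ]
  dd <- c1$fitted - pop
  expect_lt(max(abs(diff(diff(dd)))), 1e-10)
  expect_error(fitted_trajectories(fit, ids = -99), "unknown subject")
})

test_that("more measurement noise shrinks the posterior intercept towards zero", {
  fp <- fit_for_prediction()
  fit <- fp$joint
  y0 <- 2
  base <- abs(posterior_ranef(fit, 0, y0)$mean[1])
  inflated <- fit
  inflated$long$sigma_e <- fit$long$sigma_e * 3
  expect_lt(abs(posterior_ranef(inflated, 0, y0)$mean[1]), base)
})
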