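# shared fixtures and independent oracles, built in code at test time

# the generating design of the evaluation study, at its true parameter values
design_params <- function(alpha = 0.5, sigma_e = 0.5) {
  list(beta = c(0, 0), sigma_e = sigma_e,
       Sigma = matrix(c(1, 0.25 * 1 * 0.25, 0.25 * 1 * 0.25, 0.25^2), 2),
       gamma = c(log(0.1), 1.5), phi = c(-0.5, 0.01), alpha = alpha)
}

sim_small <- function(seed = 1, n = 80, alpha = 0.5, sigma_e = 0.5, ...) {
  simulate_joint(sim_scenario(n_subjects = n, alpha = alpha,
                              sigma_e = sigma_e, ...), seed = seed)
}

# independent restricted-cubic oracle: a basis of the constrained
# truncated-power space obtained by null-space elimination of the two
# linear-tail constraints (sum c_j = 0, sum c_j k_j = 0)
tp_constrained_basis <- function(x, knots_all) {
  K <- length(knots_all)
  TP <- sapply(knots_all, function(k) pmax(x - k, 0)^3)
  A <- rbind(rep(1, K), knots_all)
  N <- MASS::Null(t(A)) # K x (K-2) null-space basis
  TP %*% N
}

# span equality of two sets of columns, given a shared linear column
same_span <- function(B1, B2, x) {
  r1 <- max(abs(stats::lm.fit(cbind(1, x, B2), B1)$residuals))
  r2 <- max(abs(stats::lm.fit(cbind(1, x, B1), B2)$residuals))
  max(r1, r2)
}

# survival log-likelihood of a parametric PH model, written from the exported
# hazard functions only (independent of the fitting code path)
surv_loglik_oracle <- function(surv, lambda, gamma, linpred) {
  hz <- weibull_hazard_cumhaz(surv$time, lambda, gamma, linpred)
  sum(surv$event * log(hz$hazard)) - sum(hz$cumhaz)
}

# memoised replicate banks shared across acceptance blocks
.bank <- new.env(parent = emptyenv())
naive_bank <- function(alpha, sigma_e, n_reps = 200, base_seed = 1000) {
  key <- paste("naive", alpha, sigma_e, n_reps, base_seed)
  if (is.null(.bank[[key]]))
    .bank[[key]] <- run_scenario(sim_scenario(alpha = alpha, sigma_e = sigma_e),
                                 n_reps = n_reps, base_seed = base_seed,
                                 estimators = "naive")
  .bank[[key]]
}
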