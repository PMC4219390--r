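#' Specify the longitudinal submodel
#'
#' The trajectory is
#' \deqn{W_i(t) = X_i'(t)\beta + Z_i'(t) b_i + u_i'\delta, \quad b_i \sim MVN(0, \Sigma),}
#' observed with independent Gaussian measurement error of SD `sigma_e`.
#' The fixed time effect is linear or a restricted cubic spline; the random
#' part is a random intercept, a random intercept + linear slope, or a random
#' intercept + spline of time. Baseline covariates enter as main effects on
#' the intercept.
#'
#' @param fixed_df `NULL` for a linear fixed time trend, or an integer spline
#'   df (knots placed at equal centiles of the observed measurement times).
#' @param random `"intercept"`, `"slope"` (intercept + linear slope), or an
#'   integer df for an intercept + spline-of-time random structure.
#' @param covariates character vector of covariate column names.
#' @return an object of class `"long_spec"`.
#' @export
long_spec <- function(fixed_df = NULL, random = "slope", covariates = character()) {
  if (!is.null(fixed_df)) {
    stopifnot(length(fixed_df) == 1L, fixed_df >= 1)
    fixed_df <- as.integer(fixed_df)
  }
  random_df <- NULL
  if (is.numeric(random)) {
    random_df <- as.integer(random)
    stopifnot(random_df >= 1)
    random <- "spline"
  } else {
    random <- match.arg(random, c("intercept", "slope", "spline"))
    if (random == "spline") stop("give 'random' as an integer df for a spline random structure")
  }
  structure(list(fixed_df = fixed_df, random = random, random_df = random_df,
                 covariates = as.character(covariates),
                 fixed_knots = NULL, random_knots = NULL),
            class = "long_spec")
}

# dimension of the random effect
ranef_dim <- function(spec) {
  switch(spec$random, intercept = 1L, slope = 2L, spline = 1L + spec$random_df)
}

# place any spline knots from the data; idempotent
resolve_long_spec <- function(spec, data) {
  stopifnot(inherits(spec, "long_spec"))
  if (!is.null(spec$fixed_df) && is.null(spec$fixed_knots))
    spec$fixed_knots <- rcs_knots(data$time, spec$fixed_df)
  if (spec$random == "spline" && is.null(spec$random_knots))
    spec$random_knots <- rcs_knots(data$time, spec$random_df)
  if (spec$random == "spline" && !is.null(spec$fixed_df) &&
      spec$random_df > spec$fixed_df)
    stop("random spline df must not exceed the fixed spline df")
  spec
}

# time part of the fixed design (no intercept, no covariates)
fixed_time_cols <- function(t, spec) {
  if (is.null(spec$fixed_df)) matrix(t, ncol = 1, dimnames = list(NULL, "time"))
  else rcs_basis(t, spec$fixed_knots)
}

random_design <- function(t, spec) {
  Z <- switch(spec$random,
    intercept = matrix(1, length(t), 1),
    slope     = cbind(1, t),
    spline    = cbind(1, rcs_basis(t, spec$random_knots)))
  colnames(Z) <- c("(Intercept)", if (ncol(Z) > 1) paste0("rt", seq_len(ncol(Z) - 1L)))
  Z
}

#' Build fixed and random design matrices
#'
#' `X = [1, covariates, s_F(t)]`, `Z = [1, s_R(t)]` (or a single column of
#' ones for an intercept-only random structure), rows in data order.
#'
#' @param data longitudinal data.frame (columns `id`, `time`, `value`, covariates).
#' @param spec a [long_spec].
#' @return `list(X, Z, spec)` with `spec` carrying the resolved knots.
#' @export
build_design <- function(data, spec) {
  data <- validate_long(data)
  spec <- resolve_long_spec(spec, data)
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss)) stop("covariate(s) not in data: ", paste(miss, collapse = ", "))
  U <- if (length(spec$covariates))
    as.matrix(data[, spec$covariates, drop = FALSE]) else NULL
  S <- fixed_time_cols(data$time, spec)
  X <- cbind(`(Intercept)` = 1, U, S)
  Z <- random_design(data$time, spec)
  list(X = X, Z = Z, spec = spec)
}

#' Evaluate a subject's true (noiseless) trajectory
#'
#' @param spec a resolved [long_spec] (knots placed).
#' @param params list with element `beta`: coefficients in design order
#'   (intercept, covariates, time terms).
#' @param b random-effect vector for the subject (length [ranef_dim]).
#' @param t times at which to evaluate.
#' @param u named covariate values (required if the spec has covariates).
#' @return numeric vector `W(t)`.
#' @export
trajectory <- function(spec, params, b, t, u = NULL) {
  stopifnot(inherits(spec, "long_spec"))
  q <- ranef_dim(spec)
  if (length(b) != q) stop("random-effect vector has length ", length(b), ", expected ", q)
  uvals <- numeric(0)
  if (length(spec$covariates)) {
    if (is.null(u) || !all(spec$covariates %in% names(u)))
      stop("covariate values required: ", paste(spec$covariates, collapse = ", "))
    uvals <- as.numeric(u[spec$covariates])
  }
  S <- fixed_time_cols(t, spec)
  X <- cbind(1, matrix(rep(uvals, each = length(t)), nrow = length(t)), S)
  Z <- random_design(t, spec)
  drop(X %*% params$beta + Z %*% b)
}

# split row indices by subject, preserving first-appearance order
subject_index <- function(id) split(seq_along(id), factor(id, levels = unique(id)))

#' Closed-form marginal log-likelihood of the linear mixed model
#'
#' Sum over subjects of the log density of the response under
#' \eqn{N(X_i\beta, Z_i \Sigma Z_i' + \sigma_e^2 I)}. Used standalone and as
#' the closed-form oracle for the quadrature-based joint likelihood.
#'
#' @param params list with `beta` (coefficients in design order), `sigma_e`
#'   (> 0) and `Sigma` (random-effects covariance, positive definite).
#' @param data longitudinal data.frame.
#' @param spec a [long_spec].
#' @return log-likelihood (scalar).
#' @export
lmm_loglik <- function(params, data, spec) {
  data <- validate_long(data) # sorted copy; designs below match its row order
  des <- build_design(data, spec)
  if (params$sigma_e <= 0) stop("sigma_e must be positive")
  Sigma <- as.matrix(params$Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("random-effects covariance is not positive definite")
  idx <- subject_index(data$id)
  r <- data$value - drop(des$X %*% params$beta)
  ll <- 0
  for (ix in idx) {
    Zi <- des$Z[ix, , drop = FALSE]
    Vi <- Zi %*% Sigma %*% t(Zi) + diag(params$sigma_e^2, length(ix))
    ch <- chol(Vi)
    w <- backsolve(ch, r[ix], transpose = TRUE)
    ll <- ll - 0.5 * (length(ix) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
  }
  ll
}

# --- transformed variance parameterisation (log-Cholesky) ------------------

# theta = c(log sigma_e, lower-triangular Cholesky of Sigma column-major with
# log diagonal)
theta_to_varpar <- function(theta, q) {
  sigma_e <- exp(theta[1])
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- theta[-1]
  diag(L) <- exp(diag(L))
  list(sigma_e = sigma_e, L = L, Sigma = L %*% t(L))
}

varpar_to_theta <- function(sigma_e, Sigma) {
  L <- t(chol(as.matrix(Sigma)))
  diag(L) <- log(diag(L))
  c(log(sigma_e), L[lower.tri(L, diag = TRUE)])
}

#' Fit the longitudinal submodel by maximum likelihood
#'
#' Maximises the closed-form marginal likelihood over `log(sigma_e)` and the
#' log-Cholesky factor of `Sigma`, profiling the fixed effects by generalised
#' least squares.
#'
#' @param data longitudinal data.frame (`id`, `time`, `value`, covariates).
#' @param spec a [long_spec].
#' @return object of class `"jmb_lmm"`: coefficients, `sigma_e`, `Sigma`,
#'   `loglik`, `vcov_beta` (GLS covariance of the fixed effects at the ML
#'   variance parameters), resolved `spec`, convergence flag.
#' @export
lmm_fit <- function(data, spec = long_spec()) {
  data <- validate_long(data)
  des <- build_design(data, spec)
  spec <- des$spec
  q <- ranef_dim(spec)
  idx <- subject_index(data$id)
  starts <- vapply(idx, function(i) i[1] - 1L, integer(1))
  lens <- lengths(idx)

  # moment-based start: OLS residual spread split between subject and error
  ols <- stats::lm.fit(des$X, data$value)
  s2 <- sum(ols$residuals^2) / length(data$value)
  Sigma0 <- diag(pmax(s2 / 2, 1e-4), q)
  if (q > 1) diag(Sigma0)[-1] <- diag(Sigma0)[-1] / 10
  theta0 <- varpar_to_theta(sqrt(pmax(s2 / 2, 1e-4)), Sigma0)

  negpll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(1e10)
    vp <- theta_to_varpar(theta, q)
    out <- tryCatch(cpp_lmm_profile(data$value, des$X, des$Z, starts, lens,
                                    vp$sigma_e, vp$L),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$loglik)) return(1e10)
    -out$loglik
  }
  opt <- stats::optim(theta0, negpll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  vp <- theta_to_varpar(opt$par, q)
  fin <- cpp_lmm_profile(data$value, des$X, des$Z, starts, lens, vp$sigma_e, vp$L)
  beta <- drop(fin$beta)
  names(beta) <- colnames(des$X)
  dimnames(fin$vcov_beta) <- list(colnames(des$X), colnames(des$X))
  structure(list(coefficients = beta, sigma_e = vp$sigma_e, Sigma = vp$Sigma,
                 theta = opt$par, loglik = fin$loglik, vcov_beta = fin$vcov_beta,
                 spec = spec, n_subjects = length(idx), n_obs = nrow(data),
                 converged = opt$convergence == 0, data = data),
            class = "jmb_lmm")
}

#' @export
print.jmb_lmm <- function(x, digits = 4, ...) {
  cat("Linear mixed longitudinal submodel (ML)\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs,
      " logLik:", format(x$loglik, digits = digits + 2), "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat("sigma_e:", round(x$sigma_e, digits), "\n")
  cat("Random-effects covariance:\n")
  print(round(x$Sigma, digits))
  invisible(x)
}

#' @export
coef.jmb_lmm <- function(object, ...) object$coefficients

#' @export
logLik.jmb_lmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + 1L + ranef_dim(object$spec) *
              (ranef_dim(object$spec) + 1L) / 2L,
            nobs = object$n_subjects, class = "logLik")
}

#' Empirical-Bayes posterior of a subject's random effects
#'
#' Gaussian conditional distribution of `b` given the subject's longitudinal
#' records only (closed form): mean
#' \eqn{\Omega Z' r / \sigma_e^2}, covariance
#' \eqn{\Omega = (Z'Z/\sigma_e^2 + \Sigma^{-1})^{-1}}, with `r` the residual
#' from the fixed part. Survival information is deliberately not used, so the
#' same machinery applies to new patients whose event time is unknown.
#'
#' @param object a fitted `"jmb_lmm"` or `"jmb_jm"` model, or a bare parameter
#'   list with `beta`, `sigma_e`, `Sigma` plus a resolved spec in `spec`.
#' @param times,values the subject's measurement times and observed values.
#' @param u named covariate values (if the longitudinal spec has covariates).
#' @return `list(mean, cov)`.
#' @export
posterior_ranef <- function(object, times, values, u = NULL) {
  pp <- extract_long_params(object)
  spec <- pp$spec
  if (length(times) != length(values) || length(times) < 1L)
    stop("need at least one (time, value) record")
  uvals <- numeric(0)
  if (length(spec$covariates)) {
    if (is.null(u) || !all(spec$covariates %in% names(u)))
      stop("covariate values required: ", paste(spec$covariates, collapse = ", "))
    uvals <- as.numeric(u[spec$covariates])
  }
  S <- fixed_time_cols(times, spec)
  X <- cbind(1, matrix(rep(uvals, each = length(times)), nrow = length(times)), S)
  Z <- random_design(times, spec)
  r <- values - drop(X %*% pp$beta)
  Sinv <- solve(pp$Sigma)
  Omega <- solve(crossprod(Z) / pp$sigma_e^2 + Sinv)
  Omega <- unname((Omega + t(Omega)) / 2)
  list(mean = unname(drop(Omega %*% crossprod(Z, r)) / pp$sigma_e^2), cov = Omega)
}

# uniform access to longitudinal parameters across fitted classes
extract_long_params <- function(object) {
  if (inherits(object, "jmb_lmm"))
    list(beta = object$coefficients, sigma_e = object$sigma_e,
         Sigma = object$Sigma, spec = object$spec)
  else if (inherits(object, "jmb_jm"))
    list(beta = object$long$beta, sigma_e = object$long$sigma_e,
         Sigma = object$long$Sigma, spec = object$long_spec)
  else if (is.list(object) && all(c("beta", "sigma_e", "Sigma", "spec") %in% names(object)))
    object
  else stop("unsupported object for longitudinal parameter extraction")
}
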