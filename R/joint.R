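#' Control parameters for joint-model estimation
#'
#' @param nodes odd integer >= 3; Gauss-Hermite nodes per random-effect
#'   dimension (a node sits at the mode).
#' @param adaptive logical; recentre and rescale the rule at each subject's
#'   empirical-Bayes mode of the full joint integrand (Laplace-based
#'   rescaling). The non-adaptive fallback centres at zero and scales by the
#'   prior Cholesky factor.
#' @param gl_nodes Gauss-Legendre nodes for the inner cumulative-hazard
#'   integral (current-value association only).
#' @param maxit maximum BFGS iterations in the tight phase.
#' @param reltol_loose,reltol_tight relative log-likelihood tolerances for the
#'   loose-then-tight optimisation phases.
#' @return list of class `"jm_control"`.
#' @export
jm_control <- function(nodes = 9, adaptive = TRUE, gl_nodes = 15,
                       maxit = 400, reltol_loose = 1e-4, reltol_tight = 1e-9) {
  if (nodes < 3 || nodes %% 2 == 0) stop("'nodes' must be an odd integer >= 3")
  structure(list(nodes = as.integer(nodes), adaptive = isTRUE(adaptive),
                 gl_nodes = as.integer(gl_nodes), maxit = as.integer(maxit),
                 reltol_loose = reltol_loose, reltol_tight = reltol_tight),
            class = "jm_control")
}

# assemble everything the C++ likelihood needs; done once per fit
jm_prepare <- function(long, surv, long_spec, surv_covariates, family, df,
                       association, control) {
  validate_joint_data(long, surv)
  long <- validate_long(long)
  surv <- validate_surv(surv)
  surv <- surv[match(unique(long$id), surv$id), , drop = FALSE]
  des <- build_design(long, long_spec)
  spec <- des$spec
  idx <- subject_index(long$id)
  starts <- vapply(idx, function(i) i[1] - 1L, integer(1))
  lens <- lengths(idx)
  miss <- setdiff(surv_covariates, names(surv))
  if (length(miss)) stop("survival covariate(s) not in data: ", paste(miss, collapse = ", "))
  V <- if (length(surv_covariates))
    as.matrix(surv[, surv_covariates, drop = FALSE]) else matrix(0, nrow(surv), 0)

  knots <- NULL
  if (family == "fpm") {
    tev <- surv$time[surv$event == 1]
    if (length(unique(tev)) <= df)
      stop("too few distinct event times for a df=", df, " baseline spline")
    knots <- rcs_knots(tev, df, scale = "log")
  }
  bb <- baseline_basis(surv$time, family, knots)

  e <- new.env(parent = emptyenv())
  m0 <- matrix(0, 0, 0)
  if (association == "current") {
    gl <- pracma::gaussLegendre(control$gl_nodes, 0, 1)
    n <- nrow(surv)
    tt <- rep(surv$time, each = control$gl_nodes) * rep(gl$x, n)
    uid <- rep(seq_len(n), each = control$gl_nodes)
    Ug <- if (length(spec$covariates))
      as.matrix(long[match(unique(long$id), long$id), spec$covariates, drop = FALSE])[uid, , drop = FALSE]
      else NULL
    XG <- cbind(1, Ug, fixed_time_cols(tt, spec))
    ZG <- random_design(tt, spec)
    bg <- baseline_basis(tt, family, knots)
    UT <- if (length(spec$covariates))
      as.matrix(long[match(unique(long$id), long$id), spec$covariates, drop = FALSE])
      else NULL
    XT <- cbind(1, UT, fixed_time_cols(surv$time, spec))
    ZT <- random_design(surv$time, spec)
    list2env(list(XG = XG, ZG = ZG, BG = bg$B, BpG = bg$Bp,
                  glx = gl$x, glw = gl$w, XT = XT, ZT = ZT), envir = e)
  } else {
    list2env(list(XG = m0, ZG = m0, BG = m0, BpG = m0,
                  glx = numeric(0), glw = numeric(0), XT = m0, ZT = m0), envir = e)
  }
  gh <- pracma::gaussHermite(control$nodes)
  list(long = long, surv = surv, X = des$X, Z = des$Z, starts = starts,
       lens = lens, V = V, BT = bb$B, BpT = bb$Bp, knots = knots,
       spec = spec, family = family, df = df, association = association,
       control = control, gh = gh, gl = e,
       p = ncol(des$X), q = ncol(des$Z), K = ncol(bb$B), r = ncol(V),
       surv_covariates = surv_covariates,
       n_subjects = length(idx), n_obs = nrow(long))
}

theta_names <- function(prep) {
  q <- prep$q
  ln <- outer(seq_len(q), seq_len(q), function(i, j) paste0("chol", i, j))
  c(paste0("long:", colnames(prep$X)), "log(sigma_e)",
    ln[lower.tri(ln, diag = TRUE)],
    paste0("gamma", seq_len(prep$K) - 1L),
    if (prep$r) paste0("surv:", prep$surv_covariates), "alpha")
}

theta_split <- function(theta, prep) {
  p <- prep$p; q <- prep$q; nl <- q * (q + 1L) / 2L
  i <- p
  beta <- theta[seq_len(p)]
  log_sigma_e <- theta[i + 1L]; i <- i + 1L
  lvec <- theta[i + seq_len(nl)]; i <- i + nl
  L <- matrix(0, q, q)
  L[lower.tri(L, diag = TRUE)] <- lvec
  diag(L) <- exp(diag(L))
  gamma <- theta[i + seq_len(prep$K)]; i <- i + prep$K
  phi <- if (prep$r) theta[i + seq_len(prep$r)] else numeric(0)
  i <- i + prep$r
  list(beta = beta, log_sigma_e = log_sigma_e, L = L, gamma = gamma,
       phi = phi, alpha = theta[i + 1L])
}

jll_theta <- function(theta, prep) {
  pp <- theta_split(theta, prep)
  cpp_joint_loglik(prep$long$value, prep$X, prep$Z, prep$starts, prep$lens,
                   prep$surv$time, prep$surv$event, prep$V, prep$BT, prep$BpT,
                   if (prep$association == "current") 1L else 0L,
                   prep$gl$XT, prep$gl$ZT, prep$gl$XG, prep$gl$ZG,
                   prep$gl$BG, prep$gl$BpG, prep$gl$glx, prep$gl$glw,
                   pp$beta, pp$log_sigma_e, pp$L, pp$gamma, pp$phi, pp$alpha,
                   prep$gh$x, prep$gh$w, prep$control$adaptive)
}

#' Joint log-likelihood of the shared-random-effects model
#'
#' Evaluates
#' \deqn{\sum_i \log \int \prod_j N(Y_{ij}; W_i(t_{ij}), \sigma_e^2)\;
#'   h_i(T_i)^{d_i} e^{-H_i(T_i)}\; MVN(b_i; 0, \Sigma)\, db_i}
#' by (adaptive) Gauss-Hermite quadrature. Under the intercept association
#' the cumulative hazard is closed-form (no nested quadrature); under the
#' current-value association the inner integral uses fixed Gauss-Legendre
#' nodes on `[0, T_i]`.
#'
#' @param params named list: `beta` (longitudinal fixed effects in design
#'   order), `sigma_e`, `Sigma`, `gamma` (baseline coefficients; for the
#'   Weibull family `c(log(lambda), shape)`), `phi` (survival covariate log
#'   hazard ratios), `alpha` (association).
#' @param long,surv the two datasets.
#' @param long_spec a [long_spec].
#' @param surv_covariates survival covariate column names.
#' @param family `"weibull"` or `"fpm"`.
#' @param df baseline spline df (fpm).
#' @param association `"intercept"` (hazard depends on `beta0 + b0`) or
#'   `"current"` (hazard depends on `W_i(t)`).
#' @param control a [jm_control].
#' @return log-likelihood (scalar).
#' @export
joint_loglik <- function(params, long, surv, long_spec = long_spec(),
                         surv_covariates = character(),
                         family = c("weibull", "fpm"), df = 1,
                         association = c("intercept", "current"),
                         control = jm_control()) {
  family <- match.arg(family)
  association <- match.arg(association)
  prep <- jm_prepare(long, surv, long_spec, surv_covariates, family, df,
                     association, control)
  if (length(params$beta) != prep$p)
    stop("params$beta must have length ", prep$p, " (design columns: ",
         paste(colnames(prep$X), collapse = ", "), ")")
  if (!all(dim(as.matrix(params$Sigma)) == prep$q))
    stop("params$Sigma must be ", prep$q, "x", prep$q)
  if (length(params$gamma) != prep$K)
    stop("params$gamma must have length ", prep$K)
  if (length(params$phi) != prep$r)
    stop("params$phi must have length ", prep$r)
  theta <- c(params$beta, log(params$sigma_e),
             varpar_to_theta(params$sigma_e, params$Sigma)[-1],
             params$gamma, params$phi, params$alpha)
  jll_theta(theta, prep)
}

num_grad <- function(f, x, h = 1e-5 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

num_hessian <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# two-stage starting values: LMM fit, then a survival fit with the
# empirical-Bayes subject intercepts as a covariate
jm_init <- function(prep) {
  lfit <- lmm_fit(prep$long, prep$spec)
  idx <- subject_index(prep$long$id)
  b0 <- vapply(idx, function(ix) {
    posterior_ranef(lfit, prep$long$time[ix], prep$long$value[ix],
                    u = if (length(prep$spec$covariates))
                      unlist(prep$long[ix[1], prep$spec$covariates]) else NULL)$mean[1]
  }, numeric(1))
  assoc_cov <- matrix(lfit$coefficients[1] + b0, ncol = 1,
                      dimnames = list(NULL, ".eb_intercept"))
  sfit <- surv_fit(prep$surv, covariates = prep$surv_covariates,
                   family = prep$family, df = prep$df, baseline = FALSE,
                   extra = assoc_cov)
  cf <- sfit$coefficients
  alpha0 <- unname(cf[".eb_intercept"])
  phi0 <- if (prep$r) unname(cf[prep$surv_covariates]) else numeric(0)
  theta0 <- c(lfit$coefficients, lfit$theta[1],
              varpar_to_theta(lfit$sigma_e, lfit$Sigma)[-1],
              sfit$gamma, phi0, alpha0)
  list(theta = unname(theta0), lmm = lfit, surv = sfit)
}

#' Fit the joint longitudinal-survival model by maximum likelihood
#'
#' Maximises [joint_loglik] over an unconstrained parameterisation
#' (`log(sigma_e)`, log-Cholesky factor of `Sigma`) with a quasi-Newton
#' optimiser using numeric central-difference gradients, in a loose-then-tight
#' two-phase schedule. Starting values come from separate submodel fits (the
#' LMM, then a survival model with the empirical-Bayes intercepts as a
#' covariate). The covariance matrix is the inverse numeric observed
#' information (central differences) at the optimum.
#'
#' @inheritParams joint_loglik
#' @param init optional starting parameter vector on the internal scale.
#' @param vcov logical; compute the observed-information covariance matrix
#'   (needed for standard errors and Wald intervals).
#' @return object of class `"jmb_jm"`. Key fields: `theta` (internal-scale
#'   estimates), `vcov`, `alpha`, `alpha_se`, `long` (list: `beta`, `sigma_e`,
#'   `Sigma`), `gamma`, `phi`, `loglik`, `converged`, `knots`, and the data.
#'   Non-convergence is reported via `converged = FALSE`, never silently.
#' @export
jm_fit <- function(long, surv, long_spec = long_spec(),
                   surv_covariates = character(),
                   family = c("weibull", "fpm"), df = 1,
                   association = c("intercept", "current"),
                   control = jm_control(), init = NULL, vcov = TRUE) {
  family <- match.arg(family)
  association <- match.arg(association)
  prep <- jm_prepare(long, surv, long_spec, surv_covariates, family, df,
                     association, control)
  two_stage <- NULL
  if (is.null(init)) {
    two_stage <- jm_init(prep)
    init <- two_stage$theta
  }
  negll <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 30)) return(1e9)
    v <- jll_theta(th, prep)
    if (!is.finite(v) || v <= -1e9) 1e9 else -v
  }
  grll <- function(th) num_grad(negll, th)
  run_optim <- function(start) {
    o1 <- stats::optim(start, negll, grll, method = "BFGS",
                       control = list(maxit = 150,
                                      reltol = prep$control$reltol_loose))
    stats::optim(o1$par, negll, grll, method = "BFGS",
                 control = list(maxit = prep$control$maxit,
                                reltol = prep$control$reltol_tight))
  }
  opt <- tryCatch(run_optim(init), error = function(e) NULL)
  restarted <- FALSE
  if (is.null(opt) || opt$value >= 1e9 || opt$convergence != 0) {
    restarted <- TRUE
    jit <- init * 0.95 + stats::rnorm(length(init), 0, 0.02)
    opt2 <- tryCatch(run_optim(jit), error = function(e) NULL)
    if (!is.null(opt2) && (is.null(opt) || opt2$value < opt$value)) opt <- opt2
  }
  if (is.null(opt)) {
    out <- list(converged = FALSE, message = "optimiser failed on both starts",
                spec = prep$spec, n_subjects = prep$n_subjects)
    class(out) <- "jmb_jm"
    return(out)
  }
  theta <- opt$par
  names(theta) <- theta_names(prep)
  loglik <- -opt$value
  converged <- opt$convergence == 0 && opt$value < 1e9

  vc <- NULL
  se <- rep(NA_real_, length(theta))
  if (vcov) {
    Hn <- num_hessian(negll, theta)
    vc <- tryCatch(solve(Hn), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
      converged <- FALSE
      vc <- matrix(NA_real_, length(theta), length(theta))
    }
    dimnames(vc) <- list(names(theta), names(theta))
    se <- sqrt(pmax(diag(vc), 0))
  }
  pp <- theta_split(theta, prep)
  ia <- length(theta)
  out <- list(theta = theta, vcov = vc, se = se, loglik = loglik,
              converged = converged, restarted = restarted,
              alpha = unname(pp$alpha), alpha_se = unname(se[ia]),
              alpha_ci = unname(c(pp$alpha - 1.96 * se[ia], pp$alpha + 1.96 * se[ia])),
              long = list(beta = stats::setNames(pp$beta, colnames(prep$X)),
                          sigma_e = exp(pp$log_sigma_e),
                          Sigma = pp$L %*% t(pp$L)),
              gamma = pp$gamma, phi = stats::setNames(pp$phi, prep$surv_covariates),
              family = family, df = df, association = association,
              knots = prep$knots, long_spec = prep$spec,
              surv_covariates = prep$surv_covariates,
              control = prep$control, n_subjects = prep$n_subjects,
              n_obs = prep$n_obs, n_events = sum(prep$surv$event),
              data = list(long = prep$long, surv = prep$surv),
              init = init)
  class(out) <- "jmb_jm"
  out
}

#' @export
print.jmb_jm <- function(x, digits = 4, ...) {
  cat("Joint longitudinal-survival model (", x$association, " association, ",
      x$family, " baseline)\n", sep = "")
  if (!isTRUE(x$converged)) cat("WARNING: model did not converge\n")
  if (is.null(x$theta)) return(invisible(x))
  cat("  subjects:", x$n_subjects, " measurements:", x$n_obs,
      " events:", x$n_events, "\n")
  cat("  logLik:", format(x$loglik, digits = digits + 2), "\n")
  cat(sprintf("  association alpha: %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$alpha, x$alpha_se, x$alpha_ci[1], x$alpha_ci[2]))
  cat("  sigma_e:", signif(x$long$sigma_e, digits), "\n")
  invisible(x)
}

#' @export
coef.jmb_jm <- function(object, ...) object$theta

#' @export
vcov.jmb_jm <- function(object, ...) object$vcov

#' @export
logLik.jmb_jm <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n_subjects, class = "logLik")
}

#' @export
confint.jmb_jm <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$theta - z * object$se, object$theta + z * object$se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

# natural-scale parameter table with delta-method standard errors
natural_params <- function(object) {
  prep_q <- nrow(object$long$Sigma)
  to_nat <- function(theta) {
    p <- length(object$long$beta)
    nl <- prep_q * (prep_q + 1L) / 2L
    beta <- theta[seq_len(p)]
    sig <- exp(theta[p + 1L])
    L <- matrix(0, prep_q, prep_q)
    L[lower.tri(L, diag = TRUE)] <- theta[p + 1L + seq_len(nl)]
    diag(L) <- exp(diag(L))
    S <- L %*% t(L)
    sds <- sqrt(diag(S))
    cors <- stats::cov2cor(S)[lower.tri(S)]
    rest <- theta[-(seq_len(p + 1L + nl))]
    c(beta, sigma_e = sig, sd_b = sds, corr_b = cors, rest)
  }
  est <- to_nat(object$theta)
  se <- rep(NA_real_, length(est))
  if (!is.null(object$vcov) && all(is.finite(object$vcov))) {
    J <- matrix(0, length(est), length(object$theta))
    h <- 1e-5 * (1 + abs(object$theta))
    for (i in seq_along(object$theta)) {
      e <- numeric(length(object$theta)); e[i] <- h[i]
      J[, i] <- (to_nat(object$theta + e) - to_nat(object$theta - e)) / (2 * h[i])
    }
    se <- sqrt(pmax(diag(J %*% object$vcov %*% t(J)), 0))
  }
  nm <- c(names(object$long$beta), "sigma_e",
          paste0("sd_b", seq_len(prep_q) - 1L),
          if (prep_q > 1) paste0("corr_b", apply(which(lower.tri(diag(prep_q)), arr.ind = TRUE), 1, paste, collapse = "")),
          paste0("gamma", seq_along(object$gamma) - 1L),
          names(object$phi), "alpha")
  data.frame(parameter = nm, estimate = est, se = se,
             lower = est - 1.96 * se, upper = est + 1.96 * se,
             row.names = NULL)
}

#' @export
summary.jmb_jm <- function(object, ...) {
  tab <- cbind(estimate = object$theta, se = object$se,
               z = object$theta / object$se)
  structure(list(fit = object, theta_table = tab,
                 natural = natural_params(object)),
            class = "summary.jmb_jm")
}

#' @export
print.summary.jmb_jm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nEstimates (internal scale):\n")
  print(round(x$theta_table, digits))
  cat("\nNatural-scale parameters (delta-method SEs):\n")
  nt <- x$natural
  nt[, -1] <- round(nt[, -1], digits)
  print(nt)
  invisible(x)
}

#' @export
residuals.jmb_jm <- function(object, ...) {
  ft <- fitted(object)
  object$data$long$value - ft
}

#' @export
fitted.jmb_jm <- function(object, ...) {
  long <- object$data$long
  idx <- subject_index(long$id)
  out <- numeric(nrow(long))
  for (ix in idx) {
    u <- if (length(object$long_spec$covariates))
      unlist(long[ix[1], object$long_spec$covariates]) else NULL
    pr <- posterior_ranef(object, long$time[ix], long$value[ix], u = u)
    out[ix] <- trajectory(object$long_spec,
                          list(beta = object$long$beta), pr$mean,
                          long$time[ix], u = u)
  }
  out
}

#' Compare fitted models by information criteria
#'
#' AIC = -2 logLik + 2k; BIC uses n = number of subjects. Works for any mix
#' of joint, survival-only and longitudinal fits from this package.
#'
#' @param ... named fitted models (`jmb_jm`, `jmb_surv`, `jmb_lmm`).
#' @return data.frame with loglik, parameter count, AIC and BIC per fit.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  rows <- lapply(fits, function(f) {
    ll <- logLik(f)
    k <- attr(ll, "df")
    n <- attr(ll, "nobs")
    data.frame(loglik = as.numeric(ll), k = k, n_subjects = n,
               AIC = -2 * as.numeric(ll) + 2 * k,
               BIC = -2 * as.numeric(ll) + log(n) * k)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(fits)
  out
}

#' Serialise / restore a fitted joint model as JSON
#'
#' Stores estimates, covariance, knots and the model specification, enough to
#' reconstruct the object for prediction (training data are not stored).
#'
#' @param fit a `"jmb_jm"` object.
#' @param path output path.
#' @export
write_jm <- function(fit, path) {
  stopifnot(inherits(fit, "jmb_jm"))
  obj <- list(theta = unname(fit$theta), theta_names = names(fit$theta),
              vcov = fit$vcov, loglik = fit$loglik, converged = fit$converged,
              alpha = fit$alpha, alpha_se = fit$alpha_se,
              beta = unname(fit$long$beta), beta_names = names(fit$long$beta),
              sigma_e = fit$long$sigma_e, Sigma = fit$long$Sigma,
              gamma = fit$gamma, phi = as.list(fit$phi),
              family = fit$family, df = fit$df, association = fit$association,
              knots = if (!is.null(fit$knots)) rcs_knots_to_list(fit$knots),
              long_spec = list(fixed_df = fit$long_spec$fixed_df,
                               random = fit$long_spec$random,
                               random_df = fit$long_spec$random_df,
                               covariates = fit$long_spec$covariates,
                               fixed_knots = if (!is.null(fit$long_spec$fixed_knots))
                                 rcs_knots_to_list(fit$long_spec$fixed_knots),
                               random_knots = if (!is.null(fit$long_spec$random_knots))
                                 rcs_knots_to_list(fit$long_spec$random_knots)),
              surv_covariates = fit$surv_covariates,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_jm
#' @export
read_jm <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(list(fixed_df = o$long_spec$fixed_df,
                         random = o$long_spec$random,
                         random_df = o$long_spec$random_df,
                         covariates = as.character(unlist(o$long_spec$covariates)),
                         fixed_knots = if (!is.null(o$long_spec$fixed_knots))
                           rcs_knots_from_list(o$long_spec$fixed_knots),
                         random_knots = if (!is.null(o$long_spec$random_knots))
                           rcs_knots_from_list(o$long_spec$random_knots)),
                    class = "long_spec")
  fit <- list(theta = stats::setNames(o$theta, o$theta_names),
              vcov = o$vcov, loglik = o$loglik, converged = o$converged,
              alpha = o$alpha, alpha_se = o$alpha_se,
              alpha_ci = c(o$alpha - 1.96 * o$alpha_se, o$alpha + 1.96 * o$alpha_se),
              se = if (!is.null(o$vcov)) sqrt(pmax(diag(as.matrix(o$vcov)), 0)),
              long = list(beta = stats::setNames(o$beta, o$beta_names),
                          sigma_e = o$sigma_e, Sigma = as.matrix(o$Sigma)),
              gamma = o$gamma,
              phi = stats::setNames(as.numeric(unlist(o$phi)), names(o$phi)),
              family = o$family, df = o$df, association = o$association,
              knots = if (!is.null(o$knots)) rcs_knots_from_list(o$knots),
              long_spec = spec,
              surv_covariates = as.character(unlist(o$surv_covariates)),
              n_subjects = o$n_subjects, n_obs = o$n_obs)
  class(fit) <- "jmb_jm"
  fit
}
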