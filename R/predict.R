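# cumulative baseline hazard of a fitted joint model
jm_cumhaz0 <- function(fit, t) {
  if (fit$family == "weibull") exp(fit$gamma[1]) * t^fit$gamma[2]
  else exp(drop(cbind(1, rcs_basis(log(t), fit$knots)) %*% fit$gamma))
}

# conditional survival given random effects b (vector length q)
jm_surv_given_b <- function(fit, t, b, vphi, u = NULL, gl = NULL) {
  if (fit$association == "intercept") {
    H <- jm_cumhaz0(fit, t) * exp(vphi + fit$alpha * (fit$long$beta[1] + b[1]))
  } else {
    # current value: H(t) = int_0^t h0(s) exp(vphi + alpha W(s)) ds by
    # Gauss-Legendre on each (0, t)
    H <- vapply(t, function(tt) {
      if (tt == 0) return(0)
      s <- tt * gl$x
      W <- trajectory(fit$long_spec, list(beta = fit$long$beta), b, s, u = u)
      if (fit$family == "weibull")
        h0 <- exp(fit$gamma[1]) * fit$gamma[2] * s^(fit$gamma[2] - 1)
      else {
        ev <- fpm_eval(s, fit$gamma, fit$knots)
        h0 <- ev$hazard
      }
      tt * sum(gl$w * h0 * exp(vphi + fit$alpha * W))
    }, numeric(1))
  }
  exp(-H)
}

#' Measurement-error-corrected survival prediction for a new patient
#'
#' For a patient observed only at baseline (a single biomarker value `Y0` at
#' `t = 0`), the Gaussian posterior of the random effects given that one
#' record is combined with the fitted hazard two ways: a plug-in curve at the
#' posterior mean, and a marginal curve averaging `exp(-H(t | b))` over the
#' posterior by Gauss-Hermite quadrature (the default to report, since it
#' propagates baseline-measurement uncertainty). A naive comparator curve is
#' added when a naive baseline-covariate survival fit is supplied.
#'
#' @param fit a converged `"jmb_jm"` fit.
#' @param baseline the observed baseline biomarker value.
#' @param covariates named values covering the covariates of both submodels.
#' @param times increasing non-negative prediction times.
#' @param naive_fit optional `"jmb_surv"` fit with `baseline = TRUE`.
#' @param nodes Gauss-Hermite nodes for the marginal curve.
#' @return data.frame with `time`, `surv_plugin`, `surv_marginal` and, if a
#'   naive fit is given, `surv_naive`.
#' @export
predict_survival <- function(fit, baseline, covariates = NULL, times,
                             naive_fit = NULL, nodes = 15) {
  stopifnot(inherits(fit, "jmb_jm"))
  if (!isTRUE(fit$converged)) stop("joint model did not converge; refusing to predict")
  if (any(times < 0) || is.unsorted(times)) stop("'times' must be increasing and >= 0")
  u <- if (length(fit$long_spec$covariates)) {
    if (!all(fit$long_spec$covariates %in% names(covariates)))
      stop("missing longitudinal covariate(s)")
    covariates[fit$long_spec$covariates]
  } else NULL
  vphi <- if (length(fit$surv_covariates)) {
    if (!all(fit$surv_covariates %in% names(covariates)))
      stop("missing survival covariate(s)")
    sum(fit$phi * as.numeric(covariates[fit$surv_covariates]))
  } else 0
  post <- posterior_ranef(fit, times = 0, values = baseline, u = u)
  gl <- if (fit$association == "current") pracma::gaussLegendre(15, 0, 1)
  tpos <- pmax(times, .Machine$double.eps)
  s_plug <- jm_surv_given_b(fit, tpos, post$mean, vphi, u = u, gl = gl)

  q <- length(post$mean)
  gh <- pracma::gaussHermite(nodes)
  if (fit$association == "intercept") {
    # only b0 enters the hazard: one-dimensional rule on its posterior margin
    sd0 <- sqrt(post$cov[1, 1])
    smat <- matrix(vapply(seq_along(gh$x), function(k) {
      b <- post$mean
      b[1] <- post$mean[1] + sqrt(2) * sd0 * gh$x[k]
      jm_surv_given_b(fit, tpos, b, vphi, u = u, gl = gl)
    }, numeric(length(tpos))), nrow = length(tpos))
    s_marg <- drop(smat %*% gh$w) / sqrt(pi)
  } else {
    Lp <- t(chol(post$cov))
    grid <- as.matrix(expand.grid(rep(list(seq_along(gh$x)), q)))
    w <- apply(grid, 1, function(ix) prod(gh$w[ix])) / pi^(q / 2)
    smat <- matrix(vapply(seq_len(nrow(grid)), function(k) {
      z <- gh$x[grid[k, ]]
      b <- post$mean + sqrt(2) * drop(Lp %*% z)
      jm_surv_given_b(fit, tpos, b, vphi, u = u, gl = gl)
    }, numeric(length(tpos))), nrow = length(tpos))
    s_marg <- drop(smat %*% w)
  }
  s_plug[times == 0] <- 1
  s_marg[times == 0] <- 1
  out <- data.frame(time = times, surv_plugin = s_plug, surv_marginal = s_marg)
  if (!is.null(naive_fit)) {
    stopifnot(inherits(naive_fit, "jmb_surv"), isTRUE(naive_fit$baseline))
    eta <- naive_fit$alpha * baseline +
      if (length(naive_fit$covariates))
        sum(naive_fit$coefficients[naive_fit$covariates] *
              as.numeric(covariates[naive_fit$covariates])) else 0
    H0 <- if (naive_fit$family == "weibull")
      exp(naive_fit$gamma[1]) * tpos^naive_fit$gamma[2]
    else exp(drop(cbind(1, rcs_basis(log(tpos), naive_fit$knots)) %*% naive_fit$gamma))
    sn <- exp(-H0 * exp(eta))
    sn[times == 0] <- 1
    out$surv_naive <- sn
  }
  out
}

#' @export
predict.jmb_jm <- function(object, times, baseline, covariates = NULL,
                           naive_fit = NULL, nodes = 15, ...) {
  predict_survival(object, baseline = baseline, covariates = covariates,
                   times = times, naive_fit = naive_fit, nodes = nodes)
}

#' Fitted subject-specific trajectories
#'
#' Evaluates each requested training subject's trajectory `W_i(t)` on a time
#' grid at the posterior mean of the random effects (empirical Bayes), paired
#' with the observed measurements for plotting.
#'
#' @param fit a `"jmb_jm"` (or `"jmb_lmm"`) fit holding its training data.
#' @param ids subjects to evaluate (default: all).
#' @param grid evaluation times (default: 50 points over the observed range).
#' @return `list(curves, observed)`: data.frames with columns
#'   `id, time, fitted` and `id, time, value`.
#' @export
fitted_trajectories <- function(fit, ids = NULL, grid = NULL) {
  long <- if (inherits(fit, "jmb_jm")) fit$data$long else fit$data
  if (is.null(long)) stop("fit does not carry its training data")
  spec <- if (inherits(fit, "jmb_jm")) fit$long_spec else fit$spec
  beta <- if (inherits(fit, "jmb_jm")) fit$long$beta else fit$coefficients
  if (is.null(ids)) ids <- unique(long$id)
  unknown <- setdiff(ids, long$id)
  if (length(unknown)) stop("unknown subject id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(grid)) grid <- seq(min(long$time), max(long$time), length.out = 50)
  rows <- lapply(ids, function(i) {
    di <- long[long$id == i, ]
    u <- if (length(spec$covariates)) unlist(di[1, spec$covariates]) else NULL
    pr <- posterior_ranef(fit, di$time, di$value, u = u)
    data.frame(id = i, time = grid,
               fitted = trajectory(spec, list(beta = beta), pr$mean, grid, u = u))
  })
  list(curves = do.call(rbind, rows),
       observed = long[long$id %in% ids, c("id", "time", "value")])
}

#' @export
plot.jmb_jm <- function(x, ids = NULL, n_show = 9, ...) {
  if (is.null(ids)) ids <- utils::head(unique(x$data$long$id), n_show)
  ft <- fitted_trajectories(x, ids = ids)
  nc <- ceiling(sqrt(length(ids)))
  op <- graphics::par(mfrow = c(ceiling(length(ids) / nc), nc), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (i in ids) {
    ci <- ft$curves[ft$curves$id == i, ]
    oi <- ft$observed[ft$observed$id == i, ]
    graphics::plot(oi$time, oi$value, pch = 16,
                   xlim = range(ft$curves$time), ylim = range(c(oi$value, ci$fitted)),
                   xlab = "", ylab = "", main = paste("id", i))
    graphics::lines(ci$time, ci$fitted, lty = 2)
  }
  invisible(x)
}
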