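#' Run one simulation scenario over many replicates
#'
#' For replicate `r`: simulate a dataset with seed `base_seed + r`, fit the
#' requested estimators of the association parameter, and record the estimate
#' and its Wald 95% interval. Summaries (over converged replicates only):
#' bias = mean(est) - alpha, percentage bias = 100 * bias / alpha,
#' MSE = mean((est - alpha)^2), coverage = 100 * fraction of intervals
#' containing alpha, with Monte-Carlo standard errors
#' `SE(bias) = sd(est)/sqrt(R)` and `SE(coverage) = sqrt(p(1-p)/R)`.
#' Non-convergent replicates are dropped from the summaries and counted.
#'
#' @param scenario a [sim_scenario].
#' @param n_reps number of replicates (>= 2).
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`.
#' @param estimators any of `"naive"` (Weibull PH with the observed baseline
#'   measurement, age and treatment) and `"joint"` (Weibull-based joint model,
#'   intercept association, age and treatment in the survival submodel).
#' @param control [jm_control] for the joint fits.
#' @param estimator_fns optional named list of `function(sim) ->
#'   list(est, se, converged)` overriding/extending the built-in estimators
#'   (an injection hook; e.g. a degenerate estimator returning the truth).
#' @param progress print a line per replicate with convergence status.
#' @return object of class `"sim_summary"`: `metrics` (one row per estimator),
#'   `replicates` (per-replicate estimates and intervals), `scenario`.
#' @export
run_scenario <- function(scenario, n_reps, base_seed = 0L,
                         estimators = c("naive", "joint"),
                         control = jm_control(), estimator_fns = NULL,
                         progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"), n_reps >= 2)
  fns <- list()
  if ("naive" %in% estimators)
    fns$naive <- function(sim) {
      f <- surv_fit(sim$surv, covariates = c("trt", "age"),
                    family = "weibull", baseline = TRUE)
      list(est = f$alpha, se = f$alpha_se, converged = f$converged)
    }
  if ("joint" %in% estimators)
    fns$joint <- function(sim) {
      f <- jm_fit(sim$long, sim$surv, long_spec(random = "slope"),
                  surv_covariates = c("trt", "age"), family = "weibull",
                  association = "intercept", control = control)
      list(est = f$alpha, se = f$alpha_se, converged = isTRUE(f$converged))
    }
  if (!is.null(estimator_fns)) fns[names(estimator_fns)] <- estimator_fns
  if (!length(fns)) stop("no estimators requested")

  rows <- vector("list", n_reps * length(fns))
  k <- 0L
  for (r in seq_len(n_reps)) {
    seed <- as.integer(base_seed + r)
    sim <- simulate_joint(scenario, seed = seed)
    for (nm in names(fns)) {
      res <- tryCatch(fns[[nm]](sim),
                      error = function(e) list(est = NA_real_, se = NA_real_,
                                               converged = FALSE))
      ok <- isTRUE(res$converged) && is.finite(res$est) && is.finite(res$se)
      k <- k + 1L
      rows[[k]] <- data.frame(alpha = scenario$alpha,
                              sigma_e = scenario$sigma_e,
                              rep = r, seed = seed, estimator = nm,
                              est = res$est, se = res$se,
                              lower = res$est - 1.96 * res$se,
                              upper = res$est + 1.96 * res$se,
                              converged = ok)
      if (progress)
        message(sprintf("rep %d %s: est=%.4f %s", r, nm, res$est,
                        if (ok) "" else "[non-converged]"))
    }
  }
  reps <- do.call(rbind, rows)
  structure(list(metrics = summarise_replicates(reps), replicates = reps,
                 scenario = scenario, base_seed = base_seed),
            class = "sim_summary")
}

#' Summarise replicate-level association estimates
#'
#' Computes the bias / percentage bias / MSE / coverage block from a
#' replicate table (as produced by [run_scenario] or re-read from its
#' persisted CSV), so persisted runs can be re-summarised exactly.
#'
#' @param reps data.frame with columns `alpha`, `sigma_e`, `estimator`,
#'   `est`, `lower`, `upper`, `converged`.
#' @return data.frame with one row per estimator.
#' @export
summarise_replicates <- function(reps) {
  need <- c("alpha", "sigma_e", "estimator", "est", "lower", "upper", "converged")
  miss <- setdiff(need, names(reps))
  if (length(miss)) stop("replicate table missing column(s): ", paste(miss, collapse = ", "))
  alpha <- reps$alpha[1]
  out <- do.call(rbind, lapply(unique(reps$estimator), function(nm) {
    d <- reps[reps$estimator == nm, ]
    ok <- d[d$converged & is.finite(d$est), ]
    if (!nrow(ok)) stop("all replicates failed to converge for estimator '", nm, "'")
    R <- nrow(ok)
    bias <- mean(ok$est) - alpha
    covg <- mean(ok$lower <= alpha & alpha <= ok$upper)
    data.frame(estimator = nm, alpha = alpha, sigma_e = reps$sigma_e[1],
               bias = bias, pct_bias = 100 * bias / alpha,
               mse = mean((ok$est - alpha)^2),
               coverage = 100 * covg,
               n_converged = R, n_total = nrow(d),
               mc_se_bias = stats::sd(ok$est) / sqrt(R),
               mc_se_coverage = 100 * sqrt(covg * (1 - covg) / R))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.sim_summary <- function(x, digits = 4, ...) {
  cat("Simulation summary: alpha =", x$scenario$alpha,
      " sigma_e =", x$scenario$sigma_e,
      " n =", x$scenario$n_subjects, "\n")
  m <- x$metrics
  num <- vapply(m, is.numeric, logical(1))
  m[, num] <- round(m[, num], digits)
  print(m)
  invisible(x)
}

#' Assemble the bias/coverage table across scenarios
#'
#' One row per (alpha, sigma_e) scenario with bias, percentage bias, MSE and
#' coverage for each estimator, in the naive-then-joint column layout.
#'
#' @param summaries list of `"sim_summary"` objects (or bare metrics
#'   data.frames from [summarise_replicates]).
#' @param path optional base path; writes `<path>.csv` and a human-readable
#'   `<path>.txt`.
#' @return the table as a data.frame.
#' @export
table1_report <- function(summaries, path = NULL) {
  if (inherits(summaries, "sim_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("no summaries given")
  rows <- lapply(summaries, function(s) {
    m <- if (inherits(s, "sim_summary")) s$metrics else s
    out <- data.frame(alpha = m$alpha[1], sigma_e = m$sigma_e[1])
    for (nm in m$estimator) {
      r <- m[m$estimator == nm, ]
      block <- data.frame(r$bias, r$pct_bias, r$mse, r$coverage)
      names(block) <- paste0(nm, c("_bias", "_pct_bias", "_mse", "_coverage"))
      out <- cbind(out, block)
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$alpha, tab$sigma_e), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE)
    txt <- utils::capture.output(print(format(tab, digits = 3), row.names = FALSE))
    writeLines(txt, paste0(path, ".txt"))
  }
  tab
}

#' Persist replicate-level results
#'
#' @param summary a `"sim_summary"`.
#' @param path CSV path.
#' @export
write_replicates_csv <- function(summary, path) {
  stopifnot(inherits(summary, "sim_summary"))
  utils::write.csv(summary$replicates, path, row.names = FALSE)
  invisible(path)
}
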