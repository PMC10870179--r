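#' Maximum-likelihood fit of the panel multistate model
#'
#' Quasi-Newton (BFGS) maximisation of [panel_log_likelihood()] over the log
#' baseline intensities and covariate coefficients.  The covariance of the
#' estimates is the inverse of the numerically differentiated observed
#' information at the optimum.
#'
#' @param panel a `panel_dataset` or prebuilt [msm_data()] object.
#' @param structure a [transition_structure()] (ignored for prebuilt data).
#' @param init optional [msm_params()] starting values; defaults to
#'   [crude_initial_estimates()].
#' @param timing covariate-timing convention, see [msm_data()].
#' @param control list: `maxit` (default 300) and `reltol` (default 1e-10)
#'   passed to [stats::optim()].
#' @return an object of class `msm_fit` with elements `params`, `theta`,
#'   `covariance` (`NULL` when the information matrix is singular), `loglik`,
#'   `convergence` (logical), `grad_norm`, `n_patients`, `n_obs`,
#'   `n_transitions`, `structure`, `timing`.  Non-convergence returns the fit
#'   with `convergence = FALSE` rather than an error.
#' @export
fit_msm <- function(panel, structure = NULL, init = NULL,
                    timing = c("changepoint", "start"),
                    control = list()) {
  timing <- match.arg(timing)
  d <- if (inherits(panel, "msm_data")) panel
       else {
         if (is.null(structure))
           wt_stop("wtmsm_input_error", "structure required with a raw panel")
         msm_data(panel, structure, timing)
       }
  structure <- d$structure

  # identifiability check: masked covariates with zero variation in the data
  if (length(structure$covariates)) {
    flat <- apply(d$Z, 2L, function(col) diff(range(col)) == 0)
    used <- colSums(structure$masks) > 0
    if (any(flat & used))
      warning("covariate(s) constant in the data: ",
              paste(structure$covariates[flat & used], collapse = ", "),
              " (coefficients not identifiable)")
  }

  if (is.null(init)) init <- crude_initial_estimates(d)
  theta0 <- pack_theta(init)
  nll <- function(theta)
    cpp_panel_nll(theta, d$from, d$to, d$beta_idx, d$Z, d$seg_dt,
                  d$seg_group, d$obs_from, d$obs_to, d$n_states)
  # analytic gradient in the eigenbasis; numeric fallback for the rare
  # ill-conditioned eigensystem
  gr <- function(theta) {
    g <- cpp_panel_nll_grad(theta, d$from, d$to, d$beta_idx, d$Z, d$seg_dt,
                            d$seg_group, d$obs_from, d$obs_to, d$n_states)
    if (isTRUE(g$success) && all(is.finite(g$grad))) g$grad
    else num_gradient(nll, theta)
  }

  ctl <- list(maxit = 300L, reltol = 1e-10)
  ctl[names(control)] <- control
  opt <- optim(theta0, nll, gr, method = "BFGS",
               control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  theta_hat <- opt$par
  grad_norm <- max(abs(gr(theta_hat)))

  H <- tryCatch(stats::optimHess(theta_hat, nll, gr), error = function(e) NULL)
  covariance <- NULL
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    covariance <- tryCatch({
      V <- solve(H)
      V <- (V + t(V)) / 2
      if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values <= 0))
        NULL else V
    }, error = function(e) NULL)
    if (!is.null(covariance))
      dimnames(covariance) <- list(names(theta_hat), names(theta_hat))
  }
  if (is.null(covariance))
    warning("observed information singular or not positive definite; ",
            "covariance unavailable")

  structure(list(
    params = unpack_theta(theta_hat, structure),
    theta = theta_hat, covariance = covariance,
    loglik = -opt$value, convergence = opt$convergence == 0L,
    counts = opt$counts, grad_norm = grad_norm,
    n_patients = d$n_patients, n_obs = d$n_obs,
    n_transitions = d$n_transitions,
    structure = structure, timing = d$timing
  ), class = "msm_fit")
}

# central-difference gradient
num_gradient <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Panel multistate model fit\n")
  cat(sprintf("  patients: %d, observations: %d, observed state changes: %d\n",
              x$n_patients, x$n_obs, x$n_transitions))
  cat(sprintf("  log-likelihood: %.3f  (converged: %s, max|grad| = %.2e)\n",
              x$loglik, x$convergence, x$grad_norm))
  cat("  baseline intensities (per day):\n")
  print(round(exp(x$params$log_q0), 6))
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' `HR = exp(beta)` per transition and covariate, with
#' `exp(beta +/- z * SE)` intervals from the inverse observed information.
#' Masked (not estimated) transition-covariate cells are reported as `NA`.
#'
#' @param fit an [fit_msm()] result with available covariance.
#' @param covariates subset of covariates to report (default: all).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns `transition`, `covariate`, `hr`, `lo`,
#'   `hi`, `se_log`.
#' @export
hazard_ratios <- function(fit, covariates = NULL, conf_level = 0.95) {
  if (is.null(fit$covariance))
    wt_stop("wtmsm_fit_error", "covariance unavailable; cannot form CIs")
  st <- fit$structure
  if (is.null(covariates)) covariates <- st$covariates
  zq <- qnorm(1 - (1 - conf_level) / 2)
  idx <- beta_index(st)
  se <- sqrt(diag(fit$covariance))
  out <- expand.grid(transition = st$labels, covariate = covariates,
                     stringsAsFactors = FALSE)
  out$hr <- out$lo <- out$hi <- out$se_log <- NA_real_
  for (r in seq_len(nrow(out))) {
    k <- match(out$transition[r], st$labels)
    j <- match(out$covariate[r], st$covariates)
    if (idx[k, j] > 0L) {
      b <- fit$params$beta[k, j]
      s <- se[8L + idx[k, j]]
      out$hr[r] <- exp(b)
      out$lo[r] <- exp(b - zq * s)
      out$hi[r] <- exp(b + zq * s)
      out$se_log[r] <- s
    }
  }
  out
}
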