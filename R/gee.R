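#' Population-averaged (GEE) models for yearly cross-sections
#'
#' Generalized estimating equations with patient clusters and exchangeable
#' working correlation: Gaussian family with identity link for BMI, binomial
#' family with logit link for obesity prevalence and WMT utilization.
#' Unadjusted models contain only the year; adjusted models add age, sex,
#' race and ethnicity (age entered linearly).  Robust (sandwich) standard
#' errors are clustered on patient.
#'
#' @param cross_sections row-bound yearly cross-sections (see
#'   [extract_cross_section()]); must span two years and contain the outcome
#'   column (`bmi`, `obese`, or `wmt_any` for utilization).
#' @param outcome one of `"bmi"`, `"obesity"`, `"utilization"`.
#' @param adjusted add age, female, white, hispanic to the linear predictor.
#' @return an object of class `marginal_fit`: coefficients, robust and naive
#'   covariance, working-correlation `alpha`, dispersion `phi`, family/link
#'   tag, `n_patients`, `n_obs`, plus the model frame needed for
#'   [average_marginal_effect()].
#' @export
fit_marginal_model <- function(cross_sections,
                               outcome = c("bmi", "obesity", "utilization"),
                               adjusted = FALSE) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, bmi = "bmi", obesity = "obese",
                 utilization = "wmt_any")
  if (!ycol %in% names(cross_sections))
    wt_stop("wtmsm_input_error", "outcome column '%s' not present", ycol)
  years <- sort(unique(cross_sections$year))
  if (length(years) < 2)
    wt_stop("wtmsm_design_error",
            "cross-sections span a single year; year effect not estimable")
  fam <- if (outcome == "bmi") gaussian() else binomial()

  data <- cross_sections
  data$year <- factor(data$year, levels = years)
  rhs <- "year"
  if (adjusted) rhs <- paste(rhs, "+ age + female + white + hispanic")
  form <- stats::as.formula(paste(ycol, "~", rhs))
  fit <- gee_exchangeable(form, data, id = data$patient_id, family = fam)
  fit$outcome <- outcome
  fit$formula <- form
  fit$data <- data
  fit$contrast_levels <- years
  fit
}

# GEE with exchangeable working correlation; moment estimators for the
# dispersion and the within-cluster correlation; HC0-style sandwich
# covariance clustered on id.
gee_exchangeable <- function(formula, data, id, family, maxit = 50,
                             tol = 1e-10) {
  mf <- model.frame(formula, data)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  ord <- order(id)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; idv <- id[ord]
  p <- ncol(X); N <- length(y)
  cl <- split(seq_len(N), idv)

  beta <- coef(stats::glm.fit(X, y, family = family))
  alpha <- 0; phi <- 1
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- family$linkinv(eta)
    vmu <- family$variance(mu)
    r <- (y - mu) / sqrt(vmu)
    phi <- sum(r^2) / (N - p)
    num <- 0; den <- 0
    for (ix in cl) {
      ni <- length(ix)
      if (ni > 1) {
        s <- sum(r[ix])
        num <- num + (s^2 - sum(r[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > p) num / (phi * (den - p)) else 0
    alpha <- min(max(alpha, 0), 0.95)

    H <- matrix(0, p, p); U <- numeric(p)
    dmu <- family$mu.eta(eta)
    for (ix in cl) {
      ni <- length(ix)
      D <- dmu[ix] * X[ix, , drop = FALSE]
      A <- sqrt(vmu[ix])
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Vi <- phi * (A %o% A) * R
      DtW <- t(D) %*% solve(Vi)
      H <- H + DtW %*% D
      U <- U + drop(DtW %*% (y[ix] - mu[ix]))
    }
    delta <- solve(H, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }

  eta <- drop(X %*% beta)
  mu <- family$linkinv(eta)
  vmu <- family$variance(mu)
  dmu <- family$mu.eta(eta)
  H <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    D <- dmu[ix] * X[ix, , drop = FALSE]
    A <- sqrt(vmu[ix])
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    Vi <- phi * (A %o% A) * R
    DtW <- t(D) %*% solve(Vi)
    H <- H + DtW %*% D
    g <- drop(DtW %*% (y[ix] - mu[ix]))
    meat <- meat + g %o% g
  }
  bread <- solve(H)
  vr <- bread %*% meat %*% bread
  vr <- (vr + t(vr)) / 2
  dimnames(vr) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    vcov_robust = vr, vcov_naive = bread,
    alpha = alpha, phi = phi,
    family = family$family, link = family$link,
    n_patients = length(cl), n_obs = N, iterations = iter
  ), class = "marginal_fit")
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat(sprintf("GEE (%s/%s, exchangeable, alpha = %.3f)\n",
              x$family, x$link, x$alpha))
  se <- sqrt(diag(x$vcov_robust))
  print(data.frame(estimate = x$coefficients, robust_se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Average marginal effect of the year contrast
#'
#' AME = mean over observations of the predicted outcome with the contrast
#' variable set to its second level minus the prediction at its first level
#' (counterfactual averaging over the observed covariate distribution);
#' delta-method confidence interval from the robust covariance.
#'
#' @param fit a [fit_marginal_model()] result.
#' @param contrast name of the contrast variable (default `"year"`).
#' @param conf_level confidence level.
#' @return list with `ame`, `se`, `lower`, `upper`, and the two level means
#'   (`mean_at_levels`).
#' @export
average_marginal_effect <- function(fit, contrast = "year",
                                    conf_level = 0.95) {
  if (is.null(fit$data))
    wt_stop("wtmsm_input_error", "fit carries no model data")
  fam <- if (fit$family == "gaussian") gaussian() else binomial()
  tt <- delete.response(terms(fit$formula))
  lv <- levels(fit$data[[contrast]])
  predparts <- lapply(lv[c(1, length(lv))], function(v) {
    d <- fit$data
    d[[contrast]] <- factor(v, levels = lv)
    X <- model.matrix(tt, d)
    eta <- drop(X %*% fit$coefficients)
    list(mu = fam$linkinv(eta), grad = fam$mu.eta(eta) * X)
  })
  mu0 <- predparts[[1]]$mu; mu1 <- predparts[[2]]$mu
  ame <- mean(mu1 - mu0)
  grad <- colMeans(predparts[[2]]$grad) - colMeans(predparts[[1]]$grad)
  se <- sqrt(drop(t(grad) %*% fit$vcov_robust %*% grad))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(ame = ame, se = se, lower = ame - zq * se, upper = ame + zq * se,
       mean_at_levels = setNames(c(mean(mu0), mean(mu1)),
                                 lv[c(1, length(lv))]))
}
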