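#' Covariate/exposure profile for horizon prediction
#'
#' The reference patient is female, age 50, BMI 35, White, non-Hispanic,
#' with one primary-care visit in the prior year — all demographic design
#' columns zero.  `wmt` selects an idealized, uninterrupted year-long
#' exposure: for meal replacement the program phases advance (early for days
#' 0-183, late thereafter) unless `mr_mode = "early"`; for surgery the
#' time-since-surgery bins advance deterministically (0-90, 91-180, 181-364
#' within a 364-day horizon).
#'
#' @param wmt one of `"none"`, `"nutrition"`, `"mr"`, `"aom"`, `"surgery"`.
#' @param demographics named numeric overrides of demographic design columns
#'   (`male`, `age10`, `nonwhite`, `hispanic`, `bmi5`, `pcvisits`).
#' @param mr_mode `"phased"` (default) or `"early"` (early phase throughout).
#' @return object of class `wmt_profile`.
#' @export
reference_profile <- function(wmt = c("none", "nutrition", "mr", "aom",
                                      "surgery"),
                              demographics = NULL,
                              mr_mode = c("phased", "early")) {
  structure(list(wmt = match.arg(wmt), demographics = demographics,
                 mr_mode = match.arg(mr_mode)),
            class = "wmt_profile")
}

# expand a profile into exposure-constant segments covering [0, horizon]
profile_segments <- function(profile, structure, horizon) {
  z0 <- setNames(numeric(length(DEMOG_COLS) + length(WMT_COLS)),
                 c(DEMOG_COLS, WMT_COLS))
  if (!is.null(profile$demographics)) {
    nm <- intersect(names(profile$demographics), names(z0))
    z0[nm] <- profile$demographics[nm]
  }
  on <- function(z, cols) { z[cols] <- 1; z["wmt_any"] <- 1; z }
  segs <- switch(profile$wmt,
    none = list(list(dt = horizon, z = z0)),
    nutrition = list(list(dt = horizon, z = on(z0, "nutrition_90d"))),
    aom = list(list(dt = horizon, z = on(z0, "aom_any"))),
    mr = if (profile$mr_mode == "early" || horizon <= 184) {
      list(list(dt = horizon, z = on(z0, "mr_early")))
    } else {
      list(list(dt = 184, z = on(z0, "mr_early")),
           list(dt = horizon - 184, z = on(z0, "mr_late")))
    },
    surgery = {
      cuts <- c(0, 91, 181, 365, Inf)
      cols <- c("surg_0_90", "surg_91_180", "surg_181_364", "surg_ge365")
      out <- list()
      for (k in 1:4) {
        lo <- cuts[k]; hi <- min(cuts[k + 1], horizon)
        if (hi <= lo) next
        z <- on(z0, cols[k])
        if (k > 1) z["surg_gt90"] <- 1
        out[[length(out) + 1L]] <- list(dt = hi - lo, z = z)
      }
      out
    })
  df <- do.call(rbind, lapply(segs, function(s)
    data.frame(duration = s$dt, as.list(s$z), check.names = FALSE)))
  # keep only the structure's covariates (unknown ones default to zero)
  missing <- setdiff(structure$covariates, names(df))
  for (m in missing) df[[m]] <- 0
  df[, c("duration", structure$covariates), drop = FALSE]
}

#' One-year state probabilities for a covariate/exposure profile
#'
#' Row `start_state` of the interval transition-probability matrix under the
#' profile's exposure held over the whole horizon (with deterministic
#' surgery-bin and meal-replacement-phase advancement).
#'
#' @param fit an [fit_msm()] result or [msm_params()] object.
#' @param profile a [reference_profile()].
#' @param horizon days (default 364).
#' @param start_state starting state (default 3, baseline).
#' @return object of class `state_prob_vector`: `probs` (length 5, sums to
#'   1), `horizon`, `profile`, and the collapsed summaries of
#'   [collapse_states()].
#' @export
state_probabilities <- function(fit, profile = reference_profile(),
                                horizon = 364, start_state = 3L) {
  params <- if (inherits(fit, "msm_fit")) fit$params else fit
  if (!inherits(params, "msm_params"))
    wt_stop("wtmsm_input_error", "fit must be an msm_fit or msm_params")
  if (!(start_state %in% 1:5))
    wt_stop("wtmsm_input_error", "start_state must be in 1..5")
  segs <- profile_segments(profile, params$structure, horizon)
  P <- interval_probability(params, segs)
  probs <- setNames(P[start_state, ], c("loss10", "loss5_10", "stable",
                                        "gain5_10", "gain10"))
  structure(list(probs = probs, horizon = horizon, profile = profile,
                 collapsed = collapse_states(probs)),
            class = "state_prob_vector")
}

#' @export
print.state_prob_vector <- function(x, ...) {
  cat(sprintf("State probabilities at %g days (WMT: %s)\n", x$horizon,
              x$profile$wmt))
  print(round(x$probs, 4))
  cat(sprintf("  >=5%% loss %.3f | stable %.3f | >=5%% gain %.3f\n",
              x$collapsed$loss, x$collapsed$stable, x$collapsed$gain))
  invisible(x)
}

#' Collapse five-state probabilities to loss / stable / gain
#'
#' @param v a `state_prob_vector` or numeric vector of 5 probabilities.
#' @return list with `loss` (states 1+2), `stable` (state 3), `gain`
#'   (states 4+5), `loss10` (state 1) and `gain10` (state 5).
#' @export
collapse_states <- function(v) {
  p <- if (inherits(v, "state_prob_vector")) v$probs else as.numeric(v)
  if (length(p) != 5 || any(p < -1e-10) || abs(sum(p) - 1) > 1e-8)
    wt_stop("wtmsm_input_error", "need 5 nonnegative probabilities summing to 1")
  list(loss = p[[1]] + p[[2]], stable = p[[3]], gain = p[[4]] + p[[5]],
       loss10 = p[[1]], gain10 = p[[5]])
}

#' Simulation-based confidence interval for a functional of the fit
#'
#' Draws `B` parameter vectors from the multivariate normal with mean at the
#' estimate and the fit's covariance, evaluates the functional for each draw
#' and returns percentile intervals.  Deterministic given `seed`.
#'
#' @param fit an [fit_msm()] result with available covariance.
#' @param functional function taking an [msm_params()] object and returning
#'   a numeric scalar or vector.
#' @param B number of draws (default 1000).
#' @param seed optional integer seed.
#' @param conf_level confidence level.
#' @return list with `est` (functional at the estimate), `lower`, `upper`,
#'   and the `draws` matrix (B x length of the functional).
#' @export
simulate_parameter_uncertainty <- function(fit, functional, B = 1000,
                                           seed = NULL, conf_level = 0.95) {
  if (is.null(fit$covariance))
    wt_stop("wtmsm_fit_error", "fit covariance unavailable")
  if (!is.null(seed)) set.seed(seed)
  V <- fit$covariance
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(ev$values < 0)) {
    warning("covariance not positive semidefinite; nearest-PSD repair applied")
    V <- ev$vectors %*% diag(pmax(ev$values, 1e-12)) %*% t(ev$vectors)
  }
  thetas <- MASS::mvrnorm(B, fit$theta, V)
  est <- functional(fit$params)
  draws <- vapply(seq_len(B), function(b)
    as.numeric(functional(unpack_theta(thetas[b, ], fit$structure))),
    numeric(length(est)))
  draws <- if (is.null(dim(draws))) matrix(draws, ncol = 1L) else t(draws)
  a <- (1 - conf_level) / 2
  list(est = est,
       lower = apply(draws, 2, quantile, probs = a, names = FALSE),
       upper = apply(draws, 2, quantile, probs = 1 - a, names = FALSE),
       draws = draws)
}
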