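# Population counterfactuals: observed vs no-WMT one-year probabilities,
# average marginal effects, attributable fractions, fold-increase scenarios
# and the loss-vs-gain tipping point.

# remove one or all WMT components from a timeline
zero_timeline <- function(tl, which) {
  if (is.null(which)) return(tl)
  if (which %in% c("all", "nutrition")) tl$nutrition_90d <- 0L
  if (which %in% c("all", "mr")) { tl$mr_early <- 0L; tl$mr_late <- 0L }
  if (which %in% c("all", "aom")) tl$aom_any <- 0L
  if (which %in% c("all", "surgery")) tl$surgery_bin <- "none"
  tl
}

# flat segment arrays for per-patient horizon propagation (group = patient)
cohort_prob_data <- function(panel, structure, horizon = 364, zero = NULL,
                             ids = NULL, timeline_override = NULL) {
  covs <- structure$covariates
  extra <- setdiff(covs, c(DEMOG_COLS, WMT_COLS))
  if (is.null(ids)) {
    ids <- panel$covariates$patient_id[panel$covariates$followup_days >= horizon]
  }
  if (length(ids) == 0)
    wt_stop("wtmsm_input_error", "no patients with follow-up >= %g days", horizon)
  Zl <- list(); dtl <- list(); grpl <- list()
  for (g in seq_along(ids)) {
    p <- ids[g]
    cov_row <- panel$covariates[match(p, panel$covariates$patient_id), , drop = FALSE]
    if (cov_row$followup_days < horizon)
      wt_stop("wtmsm_input_error",
              "patient %s has follow-up shorter than the horizon", p)
    base_z <- panel_design_demog(cov_row)
    if (length(extra)) base_z <- c(base_z, unlist(cov_row[extra]))
    tl <- if (!is.null(timeline_override) &&
              !is.null(timeline_override[[as.character(p)]]))
      timeline_override[[as.character(p)]] else panel$timelines[[as.character(p)]]
    tl <- zero_timeline(tl, zero)
    keep <- tl$start < horizon
    tl <- tl[keep, , drop = FALSE]
    starts <- tl$start
    durs <- diff(c(starts, horizon))
    pos <- durs > 0
    zz <- vapply(which(pos), function(k)
      c(base_z, exposure_design(tl[k, , drop = FALSE]))[covs],
      numeric(length(covs)))
    # vapply drops to a plain vector when length(covs) == 1
    Zl[[g]] <- if (is.null(dim(zz)))
      matrix(zz, ncol = max(length(covs), 1L)) else t(zz)
    dtl[[g]] <- durs[pos]
    grpl[[g]] <- rep(g, sum(pos))
  }
  Z <- do.call(rbind, Zl)
  if (length(covs) == 0L) Z <- matrix(0, length(unlist(dtl)), 0L)
  list(Z = Z, seg_dt = unlist(dtl), seg_group = unlist(grpl),
       ids = ids, n_groups = length(ids),
       from = structure$from, to = structure$to,
       beta_idx = beta_index(structure), n_states = structure$n_states)
}

eval_cohort_probs <- function(theta, d, start_state = 3L) {
  P <- cpp_group_state_probs(theta, d$from, d$to, d$beta_idx, d$Z, d$seg_dt,
                             d$seg_group, d$n_groups, start_state, d$n_states)
  rownames(P) <- d$ids
  P
}

#' Per-patient one-year probability of 5% or greater weight loss
#'
#' Propagates the state distribution from the baseline state through the
#' patient's actual exposure segments over days `0..horizon` (changepoint-
#' split products of matrix exponentials) and returns `P(state in {1, 2})`.
#'
#' @param fit an [fit_msm()] result (or [msm_params()]).
#' @param panel the `panel_dataset` holding the patient.
#' @param patient_id patient identifier; must have follow-up >= `horizon`.
#' @param horizon days (default 364).
#' @return scalar probability.
#' @export
patient_level_prob <- function(fit, panel, patient_id, horizon = 364) {
  params <- if (inherits(fit, "msm_fit")) fit$params else fit
  d <- cohort_prob_data(panel, params$structure, horizon, ids = patient_id)
  P <- eval_cohort_probs(pack_theta(params), d)
  unname(P[1, 1] + P[1, 2])
}

#' Population average marginal effect of WMT exposure
#'
#' Mean over patients (with follow-up at least the horizon) of the one-year
#' probability of >=5% loss under observed exposures minus the same
#' probability with WMT exposure zeroed (`which = "all"` zeroes every WMT;
#' naming one WMT zeroes it alone).  The CI is a percentile interval from
#' multivariate-normal parameter simulation.
#'
#' @param fit an [fit_msm()] result.
#' @param panel a `panel_dataset`.
#' @param which `"all"`, `"nutrition"`, `"mr"`, `"aom"` or `"surgery"`.
#' @param horizon days (default 364).
#' @param B number of parameter draws for the CI (0 = point estimate only).
#' @param seed seed for the parameter draws.
#' @param conf_level confidence level.
#' @return list with `ame`, `observed_mean`, `counterfactual_mean`, `paf`
#'   (percent), `n`, and (when `B > 0`) `lower`, `upper`.
#' @export
population_ame <- function(fit, panel, which = "all", horizon = 364,
                           B = 0, seed = NULL, conf_level = 0.95) {
  params <- if (inherits(fit, "msm_fit")) fit$params else fit
  st <- params$structure
  d_obs <- cohort_prob_data(panel, st, horizon)
  d_cf <- cohort_prob_data(panel, st, horizon, zero = which)
  loss <- function(theta, d) {
    P <- eval_cohort_probs(theta, d)
    mean(P[, 1] + P[, 2])
  }
  th <- pack_theta(params)
  obs <- loss(th, d_obs); cf <- loss(th, d_cf)
  out <- list(ame = obs - cf, observed_mean = obs, counterfactual_mean = cf,
              paf = if (obs > 0) 100 * (obs - cf) / obs else NA_real_,
              n = d_obs$n_groups, which = which)
  if (B > 0) {
    if (is.null(fit$covariance))
      wt_stop("wtmsm_fit_error", "fit covariance unavailable")
    ci <- simulate_parameter_uncertainty(
      fit, function(p) {
        thb <- pack_theta(p)
        loss(thb, d_obs) - loss(thb, d_cf)
      }, B = B, seed = seed, conf_level = conf_level)
    out$lower <- ci$lower; out$upper <- ci$upper
  }
  out
}

#' Population attributable fraction
#'
#' `PAF = AME / observed mean`, reported as percent.  The AME and observed
#' mean must be on the same scale (both proportions or both percent).
#'
#' @param ame average marginal effect.
#' @param observed_mean observed population-average probability (> 0).
#' @return PAF in percent.
#' @export
attributable_fraction <- function(ame, observed_mean) {
  if (!is.finite(observed_mean) || observed_mean <= 0)
    wt_stop("wtmsm_input_error", "PAF undefined: observed mean must be > 0")
  100 * ame / observed_mean
}

#' Counterfactual scenarios for increased WMT utilization
#'
#' In the default linear-extrapolation mode the population mean probability
#' of >=5% loss under utilization multiplier `m` is
#' `noWMT_mean + m * AME` (per-patient exposure contributions scaled
#' linearly, then averaged), and analogously for the >=5% gain probability;
#' `m = 1` reproduces the observed means and `m = 0` the no-WMT means.  The
#' `fold_means` convention maps the requested fold values to multipliers:
#' `"multiply"` reads fold `k` as utilization times `k` (`m = k`);
#' `"increase-by"` reads fold `k` as a k-fold increase, i.e. utilization
#' times `k + 1` (`m = k + 1`).  The alternative resampling mode replicates
#' exposed patients' exposure histories onto sampled unexposed patients
#' `m - 1` additional times and recomputes the cohort means.
#'
#' @param fit an [fit_msm()] result.
#' @param panel a `panel_dataset`.
#' @param multipliers fold values for the scenarios (default 2:5).
#' @param mode `"linear"` or `"resample"`.
#' @param fold_means multiplier convention, see above.
#' @param horizon days (default 364).
#' @param B parameter draws for CIs (0 disables CIs).
#' @param seed seed (parameter draws and resampling).
#' @param conf_level confidence level.
#' @return data.frame of class `scenario_table` with one status-quo row
#'   (multiplier 1) plus one row per scenario: `fold`, `multiplier`,
#'   `mean_loss`, `mean_gain`, `diff` (loss - gain), `risk_ratio`, and CI
#'   columns when `B > 0`.  Attributes: `mode`, `ame`, `noWMT_mean`.
#' @export
fold_increase_scenarios <- function(fit, panel, multipliers = 2:5,
                                    mode = c("linear", "resample"),
                                    fold_means = c("multiply", "increase-by"),
                                    horizon = 364, B = 0, seed = NULL,
                                    conf_level = 0.95) {
  mode <- match.arg(mode)
  fold_means <- match.arg(fold_means)
  if (any(multipliers < 0))
    wt_stop("wtmsm_input_error", "multipliers must be >= 0")
  params <- if (inherits(fit, "msm_fit")) fit$params else fit
  st <- params$structure
  th <- pack_theta(params)
  m_eff <- if (fold_means == "multiply") multipliers else multipliers + 1
  sq_fold <- if (fold_means == "multiply") 1 else 0

  d_obs <- cohort_prob_data(panel, st, horizon)
  d_cf <- cohort_prob_data(panel, st, horizon, zero = "all")
  lg <- function(theta, d) {
    P <- eval_cohort_probs(theta, d)
    c(loss = mean(P[, 1] + P[, 2]), gain = mean(P[, 4] + P[, 5]))
  }

  if (mode == "linear") {
    base_quant <- function(theta) c(lg(theta, d_obs), lg(theta, d_cf))
    qhat <- base_quant(th)
    names(qhat) <- c("obs_loss", "obs_gain", "no_loss", "no_gain")
    mk <- function(q, m) {
      loss <- q[["no_loss"]] + m * (q[["obs_loss"]] - q[["no_loss"]])
      gain <- q[["no_gain"]] + m * (q[["obs_gain"]] - q[["no_gain"]])
      c(loss = loss, gain = gain, diff = loss - gain,
        rr = if (gain > 0) loss / gain else NA_real_)
    }
    mm <- c(1, m_eff)
    folds <- c(sq_fold, multipliers)
    pts <- t(vapply(mm, function(m) mk(qhat, m), numeric(4)))
    out <- data.frame(fold = folds, multiplier = mm,
                      mean_loss = pts[, "loss"], mean_gain = pts[, "gain"],
                      diff = pts[, "diff"], risk_ratio = pts[, "rr"])
    if (B > 0) {
      ci <- simulate_parameter_uncertainty(
        fit, function(p) {
          q <- base_quant(pack_theta(p))
          names(q) <- c("obs_loss", "obs_gain", "no_loss", "no_gain")
          as.numeric(t(vapply(mm, function(m) mk(q, m), numeric(4))))
        }, B = B, seed = seed, conf_level = conf_level)
      # t(vapply(...)) is scenarios x 4; as.numeric flattens column-major,
      # so the vector holds all losses, then gains, diffs, risk ratios
      lo <- matrix(ci$lower, nrow = length(mm), ncol = 4)
      hi <- matrix(ci$upper, nrow = length(mm), ncol = 4)
      out$loss_lo <- lo[, 1]; out$loss_hi <- hi[, 1]
      out$gain_lo <- lo[, 2]; out$gain_hi <- hi[, 2]
      out$diff_lo <- lo[, 3]; out$diff_hi <- hi[, 3]
      out$rr_lo <- lo[, 4]; out$rr_hi <- hi[, 4]
    }
    ame <- qhat[["obs_loss"]] - qhat[["no_loss"]]
    attr(out, "ame") <- ame
    attr(out, "noWMT_mean") <- qhat[["no_loss"]]
  } else {
    if (!is.null(seed)) set.seed(seed)
    elig <- panel$covariates$patient_id[panel$covariates$followup_days >= horizon]
    exp_ids <- intersect(elig, panel$covariates$patient_id[
      panel$covariates$wmt_exposed == 1])
    unexp_ids <- setdiff(elig, exp_ids)
    rows <- list()
    datas <- list(d_obs)
    mm <- c(1, m_eff)
    for (j in seq_along(m_eff)) {
      m <- m_eff[j]
      n_extra <- round((m - 1) * length(exp_ids))
      override <- NULL
      if (n_extra > 0 && length(exp_ids) > 0 && length(unexp_ids) > 0) {
        recip <- if (n_extra <= length(unexp_ids))
          sample(unexp_ids, n_extra) else
            sample(unexp_ids, n_extra, replace = TRUE)
        donors <- sample(exp_ids, n_extra, replace = TRUE)
        override <- setNames(panel$timelines[as.character(donors)],
                             as.character(recip))
        override <- override[!duplicated(names(override))]
      }
      datas[[j + 1]] <- cohort_prob_data(panel, st, horizon,
                                         timeline_override = override)
    }
    pts <- t(vapply(datas, function(d) {
      q <- lg(th, d)
      c(loss = q[["loss"]], gain = q[["gain"]],
        diff = q[["loss"]] - q[["gain"]],
        rr = if (q[["gain"]] > 0) q[["loss"]] / q[["gain"]] else NA_real_)
    }, numeric(4)))
    out <- data.frame(fold = c(sq_fold, multipliers), multiplier = mm,
                      mean_loss = pts[, "loss"], mean_gain = pts[, "gain"],
                      diff = pts[, "diff"], risk_ratio = pts[, "rr"])
    if (B > 0) {
      ci <- simulate_parameter_uncertainty(
        fit, function(p) {
          thb <- pack_theta(p)
          as.numeric(t(vapply(datas, function(d) {
            q <- lg(thb, d)
            c(q[["loss"]], q[["gain"]], q[["loss"]] - q[["gain"]],
              if (q[["gain"]] > 0) q[["loss"]] / q[["gain"]] else NA_real_)
          }, numeric(4))))
        }, B = B, seed = seed, conf_level = conf_level)
      lo <- matrix(ci$lower, nrow = length(mm), ncol = 4)
      hi <- matrix(ci$upper, nrow = length(mm), ncol = 4)
      out$loss_lo <- lo[, 1]; out$loss_hi <- hi[, 1]
      out$gain_lo <- lo[, 2]; out$gain_hi <- hi[, 2]
      out$diff_lo <- lo[, 3]; out$diff_hi <- hi[, 3]
      out$rr_lo <- lo[, 4]; out$rr_hi <- hi[, 4]
    }
    q0 <- lg(th, d_cf)
    attr(out, "ame") <- pts[1, "loss"] - q0[["loss"]]
    attr(out, "noWMT_mean") <- q0[["loss"]]
  }
  attr(out, "mode") <- mode
  attr(out, "fold_means") <- fold_means
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' Loss-versus-gain tipping point across utilization scenarios
#'
#' Flags the smallest utilization multiplier at which the population mean
#' probability of >=5% loss exceeds that of >=5% gain with a confidence
#' interval for the difference excluding zero (falling back to a positive
#' point difference when the table carries no CIs).
#'
#' @param scenarios a [fold_increase_scenarios()] table (>= 2 multipliers).
#' @return list with `table` (the input), `tipping_multiplier` (or `NA`),
#'   `tipping_fold`.
#' @export
tipping_point_summary <- function(scenarios) {
  if (nrow(scenarios) < 2)
    wt_stop("wtmsm_input_error", "scenario table must span >= 2 multipliers")
  hit <- if ("diff_lo" %in% names(scenarios))
    scenarios$diff_lo > 0 else scenarios$diff > 0
  i <- which(hit)[1]
  list(table = scenarios,
       tipping_multiplier = if (is.na(i)) NA_real_ else scenarios$multiplier[i],
       tipping_fold = if (is.na(i)) NA_real_ else scenarios$fold[i])
}
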