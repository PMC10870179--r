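# Conversion of a panel dataset into the flat arrays consumed by the C++
# likelihood: one row per exposure-constant segment, grouped by observation
# interval.

# demographic design columns, centred at the reference patient
# (female, age 50, White, non-Hispanic, BMI 35, 1 prior-year visit)
panel_design_demog <- function(cov_row) {
  c(male = as.numeric(cov_row$female == 0),
    age10 = (cov_row$age - 50) / 10,
    nonwhite = as.numeric(cov_row$white == 0),
    hispanic = as.numeric(cov_row$hispanic),
    bmi5 = (cov_row$baseline_bmi - 35) / 5,
    pcvisits = cov_row$prior_visits - 1)
}

#' Flatten a panel dataset for likelihood evaluation
#'
#' Splits every observation interval at the patient's exposure changepoints
#' (`timing = "changepoint"`, exact under piecewise-constant intensities) or
#' carries the exposure at the interval start across the whole interval
#' (`timing = "start"`, a compatibility convention).
#'
#' @param panel a `panel_dataset` from [build_panel()].
#' @param structure a [transition_structure()]; its covariates are resolved
#'   against the demographic design columns, the WMT exposure columns, or —
#'   failing those — columns of `panel$covariates`.
#' @param timing covariate-timing convention, see above.
#' @return an object of class `msm_data` (flat segment arrays).
#' @export
msm_data <- function(panel, structure, timing = c("changepoint", "start")) {
  timing <- match.arg(timing)
  covs <- structure$covariates
  extra <- setdiff(covs, c(DEMOG_COLS, WMT_COLS))
  if (length(extra) && !all(extra %in% names(panel$covariates)))
    wt_stop("wtmsm_input_error", "unknown covariate(s): %s",
            paste(setdiff(extra, names(panel$covariates)), collapse = ", "))

  obs <- panel$obs
  if (any(!(obs$state %in% 1:5)))
    wt_stop("wtmsm_data_error", "observed states must be in 1..5")
  ids <- unique(obs$patient_id)
  o_idx <- split(seq_len(nrow(obs)), factor(obs$patient_id, levels = ids))
  Zl <- list(); dtl <- list(); grpl <- list()
  from_v <- integer(0); to_v <- integer(0)
  g <- 0L; n_trans <- 0L

  for (p in ids) {
    o <- obs[o_idx[[as.character(p)]], , drop = FALSE]
    o <- o[order(o$day), , drop = FALSE]
    if (nrow(o) < 2L) next
    cov_row <- panel$covariates[match(p, panel$covariates$patient_id), , drop = FALSE]
    base_z <- panel_design_demog(cov_row)
    if (length(extra)) base_z <- c(base_z, unlist(cov_row[extra]))
    tl <- panel$timelines[[as.character(p)]]
    E <- t(vapply(seq_len(nrow(tl)),
                  function(i) exposure_design(tl[i, , drop = FALSE]),
                  numeric(length(WMT_COLS))))
    colnames(E) <- WMT_COLS

    for (i in seq_len(nrow(o) - 1L)) {
      t0 <- o$day[i]; t1 <- o$day[i + 1L]
      g <- g + 1L
      from_v[g] <- o$state[i]; to_v[g] <- o$state[i + 1L]
      if (o$state[i] != o$state[i + 1L]) n_trans <- n_trans + 1L
      if (timing == "changepoint") {
        cps <- tl$start[tl$start > t0 & tl$start < t1]
        starts <- c(t0, cps)
      } else {
        starts <- t0
      }
      idx <- pmax(findInterval(starts, tl$start), 1L)
      full <- cbind(matrix(base_z, nrow = length(starts),
                           ncol = length(base_z), byrow = TRUE,
                           dimnames = list(NULL, names(base_z))),
                    E[idx, , drop = FALSE])
      Zl[[g]] <- full[, covs, drop = FALSE]
      dtl[[g]] <- diff(c(starts, t1))
      grpl[[g]] <- rep(g, length(starts))
    }
  }
  if (g == 0L) wt_stop("wtmsm_data_error", "panel contains no observation intervals")

  Z <- do.call(rbind, Zl)
  if (length(covs) == 0L) Z <- matrix(0, nrow(Z), 0L)
  structure(list(
    Z = Z, seg_dt = unlist(dtl), seg_group = unlist(grpl),
    obs_from = from_v, obs_to = to_v, n_intervals = g,
    from = structure$from, to = structure$to,
    beta_idx = beta_index(structure), n_states = structure$n_states,
    n_patients = length(ids), n_obs = nrow(obs), n_transitions = n_trans,
    structure = structure, timing = timing
  ), class = "msm_data")
}

#' Log-likelihood of the panel data under the multistate model
#'
#' Sum over patients and consecutive observation pairs of
#' `log P[s_i -> s_{i+1}]`, where the interval probability is the
#' time-ordered product of matrix exponentials over exposure-constant
#' segments.  A zero transition probability yields `-Inf`, not an error.
#'
#' @param params an [msm_params()] object.
#' @param panel a `panel_dataset` or a prebuilt [msm_data()] object.
#' @param timing covariate-timing convention (ignored for prebuilt data).
#' @return scalar log-likelihood.
#' @export
panel_log_likelihood <- function(params, panel,
                                 timing = c("changepoint", "start")) {
  d <- if (inherits(panel, "msm_data")) panel
       else msm_data(panel, params$structure, match.arg(timing))
  -cpp_panel_nll(pack_theta(params), d$from, d$to, d$beta_idx, d$Z,
                 d$seg_dt, d$seg_group, d$obs_from, d$obs_to, d$n_states)
}

#' Crude initial intensity estimates from observed interval transitions
#'
#' Initialises each baseline intensity as the number of observed `r -> s`
#' interval transitions divided by the total observation time spent starting
#' in state `r`, floored at 1e-6/day; all coefficients start at zero.
#'
#' @param panel a `panel_dataset` or [msm_data()] object.
#' @param structure a [transition_structure()] (taken from prebuilt data when
#'   omitted).
#' @return an [msm_params()] object.
#' @export
crude_initial_estimates <- function(panel, structure = NULL) {
  d <- if (inherits(panel, "msm_data")) panel
       else {
         if (is.null(structure))
           wt_stop("wtmsm_input_error", "structure required with a raw panel")
         msm_data(panel, structure)
       }
  if (is.null(structure)) structure <- d$structure
  if (d$n_intervals == 0L) wt_stop("wtmsm_data_error", "empty panel")
  # interval lengths by group (seg_group ids are 1..n_intervals)
  len <- numeric(d$n_intervals)
  tmp <- rowsum(d$seg_dt, d$seg_group)
  len[as.integer(rownames(tmp))] <- tmp[, 1]
  counts <- numeric(8); risk <- numeric(8)
  for (k in 1:8) {
    fr <- structure$from[k]; to <- structure$to[k]
    counts[k] <- sum(d$obs_from == fr & d$obs_to == to)
    risk[k] <- sum(len[d$obs_from == fr])
  }
  q0 <- ifelse(risk > 0, counts / risk, 0)
  q0 <- pmin(pmax(q0, 1e-6), 0.5)
  msm_params(log(q0), structure = structure)
}
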