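#' Configuration for the synthetic EHR generator
#'
#' Defaults emulate a primary-care obesity cohort: panel observation at
#' roughly six visits per year, two years of follow-up, WMT uptake rates of a
#' few percent (nutrition counseling most common, meal replacement least),
#' and confounded treatment selection (uptake increases with BMI and
#' weight-related comorbidity), which the matching stage must remove.
#'
#' @param n_patients number of patients (>= 1).
#' @param followup_days follow-up horizon per patient, days.
#' @param visit_rate expected weight-measurement visits per year (Poisson
#'   panel observation process).
#' @param exposure_uptake named list of per-WMT uptake probabilities
#'   (`nutrition`, `mr`, `aom`, `surgery`), each in `[0, 1]`.
#' @param true_params ground-truth [msm_params()] driving the latent weight
#'   process; defaults to [default_true_params()].
#' @param baseline_bmi list with `mean`, `sd`, `min`, `max` of baseline BMI.
#' @param covariate_dists list: `age_mean`, `age_sd`, `p_female`, `p_white`,
#'   `p_hispanic`, and `conditions` (named prevalence vector).
#' @param confounding_strength scale of the logistic treatment-selection
#'   score (0 = uptake independent of covariates).
#' @param p_truncation probability of a truncation event (death, pregnancy,
#'   metastatic cancer) during follow-up.
#' @param p_ineligible probability a patient fails the prior-visit
#'   eligibility rule (only one prior primary-care visit).
#' @param calendar_start entry dates are drawn uniformly from the 180 days
#'   after this date.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000,
                       followup_days = 730,
                       visit_rate = 6,
                       exposure_uptake = list(nutrition = 0.063, mr = 0.004,
                                              aom = 0.026, surgery = 0.010),
                       true_params = default_true_params(),
                       baseline_bmi = list(mean = 36, sd = 5.7,
                                           min = 30.1, max = 65),
                       covariate_dists = list(
                         age_mean = 50, age_sd = 14, p_female = 0.57,
                         p_white = 0.79, p_hispanic = 0.031,
                         conditions = c(t2d = 0.041, hyperlipidemia = 0.076,
                                        hypertension = 0.137, nafld = 0.013,
                                        osa = 0.004)),
                       confounding_strength = 1,
                       p_truncation = 0.01,
                       p_ineligible = 0.02,
                       calendar_start = as.Date("2016-01-01"),
                       seed = NULL) {
  if (n_patients < 1) wt_stop("wtmsm_config_error", "n_patients must be >= 1")
  if (visit_rate <= 0) wt_stop("wtmsm_config_error", "visit_rate must be > 0")
  pr <- c(unlist(exposure_uptake), covariate_dists$p_female,
          covariate_dists$p_white, covariate_dists$p_hispanic,
          covariate_dists$conditions, p_truncation, p_ineligible)
  if (any(pr < 0 | pr > 1))
    wt_stop("wtmsm_config_error", "all probabilities must be in [0, 1]")
  structure(list(
    n_patients = as.integer(n_patients), followup_days = followup_days,
    visit_rate = visit_rate, exposure_uptake = exposure_uptake,
    true_params = true_params, baseline_bmi = baseline_bmi,
    covariate_dists = covariate_dists,
    confounding_strength = confounding_strength,
    p_truncation = p_truncation, p_ineligible = p_ineligible,
    calendar_start = as.Date(calendar_start), seed = seed
  ), class = "sim_config")
}

#' Ground-truth model parameters for the generator
#'
#' Baseline intensities are calibrated so that a reference patient without
#' WMT exposure has one-year state-occupancy probabilities close to those
#' observed in primary-care obesity cohorts (about 16% at >=5% loss, 68%
#' stable, 16% at >=5% gain).  WMT effects raise loss-direction intensities
#' (meal replacement and surgery strongly, nutrition counseling and
#' medication moderately) and damp gain-direction intensities.
#'
#' @return an [msm_params()] object.
#' @export
default_true_params <- function() {
  covs <- c("male", "age10", "nutrition_90d", "mr_early", "mr_late",
            "aom_any", "surg_0_90", "surg_gt90")
  st <- transition_structure(covs)
  # per-day baseline intensities (calibrated, see package vignette)
  q0 <- c(`1-2` = 0.00773, `2-1` = 0.00427, `2-3` = 0.00851, `3-2` = 0.00148,
          `3-4` = 0.00154, `4-3` = 0.00815, `4-5` = 0.00394, `5-4` = 0.00823)
  hr_loss <- c(male = 0.90, age10 = 0.95, nutrition_90d = 1.35, mr_early = 6.0,
               mr_late = 1.5, aom_any = 1.6, surg_0_90 = 15.0, surg_gt90 = 3.0)
  hr_gain <- c(male = 1.05, age10 = 1.00, nutrition_90d = 0.80, mr_early = 0.60,
               mr_late = 0.70, aom_any = 0.70, surg_0_90 = 0.30, surg_gt90 = 0.50)
  beta <- matrix(NA_real_, 8, length(covs), dimnames = list(st$labels, covs))
  for (k in 1:8) beta[k, ] <- log(if (st$loss[k]) hr_loss else hr_gain)
  msm_params(log(q0), beta, st)
}

#' Ground truth for parameter-recovery experiments
#'
#' A single pooled binary exposure (`wmt_any`) with one hazard ratio on the
#' four loss-direction and one on the four gain-direction transitions.
#'
#' @param hr_loss,hr_gain hazard ratios on loss / gain transitions.
#' @return an [msm_params()] object.
#' @export
recovery_true_params <- function(hr_loss = 2.0, hr_gain = 0.7) {
  st <- transition_structure("wmt_any")
  q0 <- c(0.00773, 0.00427, 0.00851, 0.00148, 0.00154, 0.00815, 0.00394,
          0.00823)
  beta <- matrix(log(ifelse(st$loss, hr_loss, hr_gain)), 8, 1,
                 dimnames = list(st$labels, "wmt_any"))
  msm_params(log(q0), beta, st)
}

#' Simulate a continuous-time Markov path under piecewise-constant intensities
#'
#' Exact Gillespie-style simulation: within a segment, sojourn times in state
#' `s` are exponential with rate `-Q[s, s]`; at segment boundaries the clock
#' restarts with the new matrix, which is exact by memorylessness.
#'
#' @param segments list of `list(duration =, Q =)` in time order; each `Q`
#'   must have nonnegative off-diagonals and rows summing to zero.
#' @param init_state starting state (1..5).
#' @return an object of class `state_path`: list with `jump_times` (starting
#'   at 0) and `states` (state occupied from each jump time), plus a
#'   `horizon` attribute.
#' @export
simulate_ctmc_path <- function(segments, init_state) {
  for (sg in segments) {
    Q <- sg$Q
    offdiag <- Q; diag(offdiag) <- 0
    if (any(offdiag < 0) || any(abs(rowSums(Q)) > 1e-8))
      wt_stop("wtmsm_intensity_error",
              "intensity matrix must have nonnegative off-diagonals and zero row sums")
    if (sg$duration <= 0)
      wt_stop("wtmsm_input_error", "segment durations must be > 0")
  }
  t_abs <- 0
  state <- as.integer(init_state)
  jump_times <- 0
  states <- state
  for (sg in segments) {
    t_end <- t_abs + sg$duration
    Q <- sg$Q
    repeat {
      rate <- -Q[state, state]
      if (rate <= 0) { t_abs <- t_end; break }
      dt <- rexp(1, rate)
      if (t_abs + dt >= t_end) { t_abs <- t_end; break }
      t_abs <- t_abs + dt
      probs <- Q[state, ]; probs[state] <- 0
      state <- sample.int(length(probs), 1L, prob = probs)
      jump_times <- c(jump_times, t_abs)
      states <- c(states, state)
    }
  }
  structure(list(jump_times = jump_times, states = states),
            horizon = t_abs, class = "state_path")
}

#' State occupied by a path at given times
#'
#' @param path a `state_path`.
#' @param t times in `[0, horizon]`.
#' @return integer states.
#' @export
path_state_at <- function(path, t) {
  horizon <- attr(path, "horizon")
  if (any(t < 0 | t > horizon))
    wt_stop("wtmsm_input_error", "time outside simulated horizon [0, %g]", horizon)
  path$states[pmax(findInterval(t, path$jump_times), 1L)]
}

#' Emit observed weights consistent with a latent state path
#'
#' Each emitted weight is drawn uniformly on the open relative-weight band of
#' the state occupied at the visit date (open-ended bands truncated at
#' +/-20%), so [derive_weight_states()] round-trips to the latent state.
#'
#' @param path a `state_path`.
#' @param baseline_weight baseline weight in kg (> 0).
#' @param visit_dates days within the path horizon.
#' @return numeric weights (kg).
#' @export
emit_weights <- function(path, baseline_weight, visit_dates) {
  if (baseline_weight <= 0)
    wt_stop("wtmsm_data_error", "baseline weight must be positive")
  s <- path_state_at(path, visit_dates)
  bands <- rbind(c(0.80, 0.90), c(0.90, 0.95), c(0.95, 1.05),
                 c(1.05, 1.10), c(1.10, 1.20))
  eps <- 1e-9
  lo <- bands[s, 1] + eps
  hi <- bands[s, 2] - eps
  baseline_weight * runif(length(s), lo, hi)
}

#' Simulate a linked raw EHR bundle with known ground truth
#'
#' Generates patients, primary-care visits, weight measurements, WMT event
#' streams and condition flags.  The latent weight process of each patient is
#' a continuous-time Markov chain under the configured ground-truth
#' parameters, with intensities changing at the patient's WMT exposure
#' changepoints; weights observed at visit dates are back-calculated from the
#' latent state.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `raw_ehr_bundle`: list of data.frames
#'   `patients`, `visits`, `weights`, `wmt_events`, `conditions`, with the
#'   generator's ground truth (latent paths, timelines, true parameters)
#'   attached as attribute `"truth"`.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    wt_stop("wtmsm_config_error", "config must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  Tf <- config$followup_days
  cd <- config$covariate_dists
  up <- config$exposure_uptake
  tp <- config$true_params
  covs_needed <- tp$structure$covariates

  # vector accumulators (per-patient data.frame construction is too slow)
  p_age <- p_h <- p_bw <- numeric(n); p_sex <- p_race <- p_eth <- character(n)
  p_entry <- numeric(n)
  vis_id <- list(); vis_day <- list()
  wt_id <- list(); wt_day <- list(); wt_kg <- list()
  cond_id <- integer(0); cond_nm <- character(0); cond_day <- numeric(0)
  wmt_events <- list()
  paths <- vector("list", n)
  timelines <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- i
    age <- min(max(rnorm(1, cd$age_mean, cd$age_sd), 18), 90)
    female <- rbinom(1, 1, cd$p_female)
    white <- rbinom(1, 1, cd$p_white)
    hispanic <- rbinom(1, 1, cd$p_hispanic)
    cond <- rbinom(length(cd$conditions), 1, cd$conditions)
    names(cond) <- names(cd$conditions)
    height <- rnorm(1, if (female) 1.63 else 1.77, 0.07)
    bmi <- min(max(rnorm(1, config$baseline_bmi$mean, config$baseline_bmi$sd),
                   config$baseline_bmi$min), config$baseline_bmi$max)
    bw <- bmi * height^2
    entry <- config$calendar_start + floor(runif(1, 0, 180))

    # prior primary-care visits and BMI history (eligibility plumbing)
    ineligible <- runif(1) < config$p_ineligible
    gap <- floor(runif(1, 360, 900))
    prior_days <- if (ineligible) -10 else c(-10 - gap, -10)
    # pre-baseline weights below the obesity threshold, so the first
    # qualifying obese weight (the trajectory baseline) is the day-0 weight
    prior_w <- pmin(runif(length(prior_days), 26, 29.5),
                    bmi - 0.5) * height^2

    # truncation event
    trunc_day <- Inf
    if (runif(1) < config$p_truncation) {
      trunc_day <- floor(runif(1, 30, Tf))
      cond_id <- c(cond_id, pid)
      cond_nm <- c(cond_nm, sample(c("death", "pregnancy",
                                     "metastatic_cancer"), 1))
      cond_day <- c(cond_day, as.numeric(entry) + trunc_day)
    }
    for (cn in names(cond)[cond == 1]) {
      cond_id <- c(cond_id, pid); cond_nm <- c(cond_nm, cn)
      cond_day <- c(cond_day, as.numeric(entry) - floor(runif(1, 30, 700)))
    }

    # confounded WMT uptake (logistic in baseline covariates)
    score <- config$confounding_strength *
      (0.5 * (bmi - config$baseline_bmi$mean) / max(config$baseline_bmi$sd, 1e-8) +
         0.4 * as.numeric(any(cond == 1)) + 0.2 * female - 0.2 * (age - 50) / 14)
    ev <- list()
    if (runif(1) < plogis(qlogis(pmin(pmax(up$nutrition, 1e-12), 1 - 1e-12)) + score) &&
        up$nutrition > 0) {
      d0 <- floor(runif(1, 30, Tf * 0.6))
      nv <- 1 + rpois(1, 2)
      dd <- d0 + cumsum(c(0, floor(rexp(nv - 1, 1 / 60))))
      dd <- dd[dd < Tf]
      ev[[length(ev) + 1L]] <- data.frame(type = "dietitian", day = dd,
                                          day_end = NA_real_, drug = NA_character_)
    }
    if (runif(1) < plogis(qlogis(pmin(pmax(up$mr, 1e-12), 1 - 1e-12)) + score) &&
        up$mr > 0) {
      d0 <- floor(runif(1, 30, Tf * 0.5))
      span <- runif(1, 90, 540)
      dd <- d0 + seq(0, span, by = 21)
      dd <- floor(dd[dd < Tf])
      ev[[length(ev) + 1L]] <- data.frame(type = "mr_visit", day = dd,
                                          day_end = NA_real_, drug = NA_character_)
    }
    if (runif(1) < plogis(qlogis(pmin(pmax(up$aom, 1e-12), 1 - 1e-12)) + score) &&
        up$aom > 0) {
      drug <- sample(c("glp1ra", "orlistat", "liraglutide", "phen_top", "bup_nal"),
                     1, prob = c(0.5, 0.15, 0.15, 0.1, 0.1))
      d0 <- floor(runif(1, 30, Tf * 0.7))
      d1 <- min(d0 + floor(runif(1, 60, 400)), Tf)
      ev[[length(ev) + 1L]] <- data.frame(type = "aom_order", day = d0,
                                          day_end = d1, drug = drug)
    }
    if (runif(1) < plogis(qlogis(pmin(pmax(up$surgery, 1e-12), 1 - 1e-12)) + score) &&
        up$surgery > 0) {
      d0 <- floor(runif(1, 60, Tf * 0.6))
      ev[[length(ev) + 1L]] <- data.frame(type = "surgery", day = d0,
                                          day_end = NA_real_, drug = NA_character_)
    }
    events <- if (length(ev)) do.call(rbind, ev) else NULL
    tl <- build_exposure_segments(events, followup = c(0, Tf))
    timelines[[i]] <- tl

    # latent path under the ground-truth model
    demog <- c(male = 1 - female, age10 = (age - 50) / 10,
               nonwhite = 1 - white, hispanic = hispanic,
               bmi5 = (bmi - 35) / 5, pcvisits = 0)
    starts <- tl$start
    ends <- c(starts[-1], Tf)
    segs <- lapply(seq_along(starts), function(k) {
      z <- c(demog, exposure_design(tl[k, , drop = FALSE]))
      list(duration = ends[k] - starts[k],
           Q = build_intensity_matrix(tp, z))
    })
    segs <- segs[vapply(segs, function(s) s$duration > 0, logical(1))]
    path <- simulate_ctmc_path(segs, 3L)
    paths[[i]] <- path

    # panel observation: homogeneous Poisson visit process
    nv <- rpois(1, config$visit_rate * Tf / 365.25)
    vdays <- sort(floor(runif(nv, 1, Tf)))
    vdays <- unique(vdays[vdays <= min(trunc_day, Tf)])
    w_obs <- if (length(vdays)) emit_weights(path, bw, vdays) else numeric(0)

    p_age[i] <- age; p_h[i] <- height; p_bw[i] <- bw
    p_sex[i] <- if (female) "female" else "male"
    p_race[i] <- if (white) "White" else
      sample(c("Black", "Asian", "Other"), 1, prob = c(0.5, 0.3, 0.2))
    p_eth[i] <- if (hispanic) "Hispanic" else "Non-Hispanic"
    p_entry[i] <- as.numeric(entry)
    dd <- c(prior_days, 0, vdays)
    vis_id[[i]] <- rep(pid, length(dd))
    vis_day[[i]] <- as.numeric(entry) + dd
    wt_id[[i]] <- rep(pid, length(dd))
    wt_day[[i]] <- as.numeric(entry) + dd
    wt_kg[[i]] <- c(prior_w, bw, w_obs)
    if (!is.null(events)) {
      wmt_events[[length(wmt_events) + 1L]] <- data.frame(
        patient_id = pid, type = events$type, event_date = entry + events$day,
        end_date = entry + events$day_end, drug = events$drug)
    }
  }

  as_date <- function(x) as.Date(x, origin = "1970-01-01")
  bundle <- structure(list(
    patients = data.frame(patient_id = seq_len(n), age = p_age, sex = p_sex,
                          race = p_race, ethnicity = p_eth, height_m = p_h,
                          entry_date = as_date(p_entry)),
    visits = data.frame(patient_id = unlist(vis_id),
                        visit_date = as_date(unlist(vis_day))),
    weights = data.frame(patient_id = unlist(wt_id),
                         measure_date = as_date(unlist(wt_day)),
                         weight_kg = unlist(wt_kg)),
    wmt_events = if (length(wmt_events)) {
      we <- do.call(rbind, wmt_events); rownames(we) <- NULL; we
    } else
      data.frame(patient_id = integer(), type = character(),
                 event_date = as.Date(character()),
                 end_date = as.Date(character()), drug = character()),
    conditions = data.frame(patient_id = cond_id, condition = cond_nm,
                            onset_date = as_date(cond_day))
  ), class = "raw_ehr_bundle")
  attr(bundle, "truth") <- list(paths = paths, timelines = timelines,
                                true_params = tp, config = config,
                                baseline_weights = p_bw)
  bundle
}

#' @export
print.raw_ehr_bundle <- function(x, ...) {
  cat("Synthetic raw EHR bundle\n")
  cat(sprintf("  patients: %d, visits: %d, weights: %d, WMT events: %d\n",
              nrow(x$patients), nrow(x$visits), nrow(x$weights),
              nrow(x$wmt_events)))
  invisible(x)
}

#' Write / read the raw tables as CSV
#'
#' Five CSV files (`patients.csv`, `visits.csv`, `weights.csv`,
#' `wmt_events.csv`, `conditions.csv`) with ISO-8601 dates and weights in kg.
#'
#' @param bundle a `raw_ehr_bundle`.
#' @param dir directory (created if needed).
#' @return `write_ehr_tables`: the directory, invisibly.
#' @export
write_ehr_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle)) {
    df <- bundle[[nm]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ehr_tables
#' @export
read_ehr_tables <- function(dir) {
  nms <- c("patients", "visits", "weights", "wmt_events", "conditions")
  out <- lapply(nms, function(nm) {
    df <- read.csv(file.path(dir, paste0(nm, ".csv")), stringsAsFactors = FALSE)
    for (cl in grep("date$", names(df), value = TRUE))
      df[[cl]] <- as.Date(df[[cl]])
    if ("drug" %in% names(df)) df$drug <- as.character(df$drug)
    df
  })
  names(out) <- nms
  structure(out, class = "raw_ehr_bundle")
}
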