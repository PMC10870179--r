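#' Apply eligibility, truncation and BMI-cleaning rules
#'
#' A patient is eligible when, at their first weight measurement (the entry
#' date), they have two or more primary-care visits 358 or more days apart
#' within the prior 3 years, and at least two BMI measurements between 12 and
#' 100 overall.  Follow-up is truncated at the first of death, pregnancy or
#' metastatic-cancer onset.
#'
#' @param raw a `raw_ehr_bundle`.
#' @param index_window optional length-2 `Date` vector; only entries inside
#'   the window are retained.
#' @return data.frame with `patient_id`, `entry_date`, `end_date`.
#' @export
apply_eligibility <- function(raw, index_window = NULL) {
  if (is.null(raw$visits) || nrow(raw$visits) == 0)
    wt_stop("wtmsm_input_error", "visits table missing or empty")
  if (is.null(raw$weights) || nrow(raw$weights) == 0)
    wt_stop("wtmsm_input_error", "weights table missing or empty")

  pts <- raw$patients
  h <- setNames(pts$height_m, pts$patient_id)
  trunc_ev <- raw$conditions[raw$conditions$condition %in%
                               c("death", "pregnancy", "metastatic_cancer"), ,
                             drop = FALSE]
  w_split <- split(raw$weights[c("measure_date", "weight_kg")],
                   raw$weights$patient_id)
  v_split <- split(raw$visits$visit_date, raw$visits$patient_id)
  out_id <- integer(0); out_entry <- out_end <- as.Date(character(0))
  for (pid in pts$patient_id) {
    w <- w_split[[as.character(pid)]]
    if (is.null(w) || nrow(w) == 0) next
    vall <- v_split[[as.character(pid)]]
    if (is.null(vall)) vall <- as.Date(character(0))
    # entry = first weight at which the prior-visit rule is satisfied
    wd <- sort(w$measure_date)
    entry <- as.Date(NA)
    for (dte in wd) {
      dte <- as.Date(dte, origin = "1970-01-01")
      v <- vall[vall >= dte - 1095 & vall <= dte]
      if (length(v) >= 2 && as.numeric(max(v) - min(v)) >= 358) {
        entry <- dte
        break
      }
    }
    if (is.na(entry)) next
    if (!is.null(index_window) &&
        (entry < index_window[1] || entry > index_window[2])) next
    bmi <- w$weight_kg / h[[as.character(pid)]]^2
    if (sum(bmi >= 12 & bmi <= 100) < 2) next
    te <- trunc_ev$onset_date[trunc_ev$patient_id == pid]
    te <- te[te >= entry]
    end <- if (length(te)) min(te) else max(w$measure_date)
    out_id <- c(out_id, pid); out_entry <- c(out_entry, entry)
    out_end <- c(out_end, end)
  }
  data.frame(patient_id = out_id, entry_date = out_entry, end_date = out_end)
}

#' Build the trajectory-analysis panel dataset
#'
#' For each eligible patient, the baseline is the first qualifying weight
#' (with obesity, BMI >= 30, when `require_obesity = TRUE`); observations are
#' the weight measurements from baseline to the (possibly truncated) end of
#' follow-up, deduplicated to the first measurement per day and categorised
#' into the five-state ladder.  Patients with WMT exposure before baseline
#' are excluded.  Each patient carries baseline covariates (age, sex, race,
#' ethnicity, baseline BMI, prior-year visit count, condition flags), a
#' time-varying WMT exposure timeline, a `wmt_exposed` flag (any prospective
#' exposure) and `followup_days`.
#'
#' @param raw a `raw_ehr_bundle`.
#' @param eligibility result of [apply_eligibility()]; computed when `NULL`.
#' @param require_obesity require BMI >= 30 at baseline.
#' @param min_obs minimum number of observations (including baseline).
#' @return an object of class `panel_dataset`: list with `obs` (patient_id,
#'   day, state), `covariates`, `timelines` (named list of
#'   [build_exposure_segments()] results), `baseline`.
#' @export
build_panel <- function(raw, eligibility = NULL, require_obesity = TRUE,
                        min_obs = 2L) {
  if (is.null(eligibility)) eligibility <- apply_eligibility(raw)
  pts <- raw$patients
  w_split <- split(raw$weights[c("measure_date", "weight_kg")],
                   raw$weights$patient_id)
  v_split <- split(raw$visits$visit_date, raw$visits$patient_id)
  e_split <- split(raw$wmt_events, raw$wmt_events$patient_id)
  c_split <- split(raw$conditions[c("condition", "onset_date")],
                   raw$conditions$patient_id)

  obs_id <- integer(0); obs_day <- numeric(0); obs_state <- integer(0)
  cov <- list(); tls <- list()
  b_id <- integer(0); b_dates <- as.Date(character(0)); b_wt <- numeric(0)
  for (r in seq_len(nrow(eligibility))) {
    pid <- eligibility$patient_id[r]
    key <- as.character(pid)
    end <- eligibility$end_date[r]
    p <- pts[match(pid, pts$patient_id), , drop = FALSE]
    w <- w_split[[key]]
    w <- w[order(w$measure_date), , drop = FALSE]
    w <- w[!duplicated(w$measure_date), , drop = FALSE] # first of day
    w$bmi <- w$weight_kg / p$height_m^2
    w <- w[w$bmi >= 12 & w$bmi <= 100, , drop = FALSE]

    cand <- if (require_obesity) which(w$bmi >= 30) else seq_len(nrow(w))
    cand <- cand[w$measure_date[cand] >= eligibility$entry_date[r]]
    if (length(cand) == 0) next
    b <- cand[1]
    b_date <- w$measure_date[b]
    bw <- w$weight_kg[b]

    ev <- e_split[[key]]
    if (!is.null(ev) && any(ev$event_date <= b_date)) next # prior WMT exposure
    wk <- w[w$measure_date >= b_date & w$measure_date <= end, , drop = FALSE]
    if (nrow(wk) < min_obs) next

    state <- derive_weight_states(wk$weight_kg, bw)
    state[1] <- 3L # baseline is its own reference
    obs_id <- c(obs_id, rep(pid, nrow(wk)))
    obs_day <- c(obs_day, as.numeric(wk$measure_date - b_date))
    obs_state <- c(obs_state, state)

    fu <- as.numeric(end - b_date)
    ev_days <- NULL
    if (!is.null(ev) && nrow(ev)) {
      ev_days <- data.frame(type = ev$type,
                            day = as.numeric(ev$event_date - b_date),
                            day_end = as.numeric(ev$end_date - b_date),
                            drug = ev$drug)
      ev_days <- ev_days[ev_days$day <= fu, , drop = FALSE]
      ev_days$day_end <- pmin(ev_days$day_end, fu)
    }
    tls[[key]] <- build_exposure_segments(ev_days, followup = c(0, fu))

    pc <- v_split[[key]]
    cf <- c_split[[key]]
    cfl <- if (is.null(cf)) character(0) else
      cf$condition[cf$onset_date <= b_date]
    cov[[length(cov) + 1L]] <- c(
      patient_id = pid, age = p$age,
      female = as.numeric(p$sex == "female"),
      white = as.numeric(p$race == "White"),
      hispanic = as.numeric(p$ethnicity == "Hispanic"),
      baseline_bmi = w$bmi[b],
      prior_visits = sum(pc >= b_date - 364 & pc < b_date),
      t2d = as.numeric("t2d" %in% cfl),
      hyperlipidemia = as.numeric("hyperlipidemia" %in% cfl),
      hypertension = as.numeric("hypertension" %in% cfl),
      nafld = as.numeric("nafld" %in% cfl),
      osa = as.numeric("osa" %in% cfl),
      wmt_exposed = as.numeric(!is.null(ev) &&
                                 any(ev$event_date > b_date & ev$event_date <= end)),
      followup_days = fu)
    b_id <- c(b_id, pid); b_dates <- c(b_dates, b_date); b_wt <- c(b_wt, bw)
  }
  if (length(obs_id) == 0)
    wt_stop("wtmsm_data_error", "no patients satisfy the panel criteria")
  covariates <- as.data.frame(do.call(rbind, cov))
  structure(list(obs = data.frame(patient_id = obs_id, day = obs_day,
                                  state = obs_state),
                 covariates = covariates,
                 timelines = tls,
                 baseline = data.frame(patient_id = b_id,
                                       baseline_date = b_dates,
                                       baseline_weight = b_wt)),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Panel dataset\n")
  cat(sprintf("  patients: %d, observations: %d, WMT-exposed: %d\n",
              nrow(x$covariates), nrow(x$obs), sum(x$covariates$wmt_exposed)))
  invisible(x)
}

#' Restrict a panel dataset to a subset of patients
#'
#' @param panel a `panel_dataset`.
#' @param ids patient identifiers to keep.
#' @return a `panel_dataset` with only those patients.
#' @export
panel_subset <- function(panel, ids) {
  structure(list(
    obs = panel$obs[panel$obs$patient_id %in% ids, , drop = FALSE],
    covariates = panel$covariates[panel$covariates$patient_id %in% ids, , drop = FALSE],
    timelines = panel$timelines[as.character(ids)],
    baseline = panel$baseline[panel$baseline$patient_id %in% ids, , drop = FALSE]
  ), class = "panel_dataset")
}

#' Extract a yearly cross-section (first weight per patient in the year)
#'
#' @param raw a `raw_ehr_bundle`.
#' @param year calendar year.
#' @return data.frame with one row per patient having a weight in the year:
#'   `patient_id`, `year`, `date`, `weight_kg`, `bmi`, `obese` (BMI >= 30),
#'   plus demographics.
#' @export
extract_cross_section <- function(raw, year) {
  w <- raw$weights
  w <- w[format(w$measure_date, "%Y") == as.character(year), , drop = FALSE]
  if (nrow(w) == 0)
    return(data.frame(patient_id = integer(), year = integer(),
                      date = as.Date(character()), weight_kg = numeric(),
                      bmi = numeric(), obese = numeric()))
  w <- w[order(w$patient_id, w$measure_date), , drop = FALSE]
  w <- w[!duplicated(w$patient_id), , drop = FALSE]
  p <- raw$patients[match(w$patient_id, raw$patients$patient_id), , drop = FALSE]
  data.frame(patient_id = w$patient_id, year = as.integer(year),
             date = w$measure_date, weight_kg = w$weight_kg,
             bmi = w$weight_kg / p$height_m^2,
             obese = as.numeric(w$weight_kg / p$height_m^2 >= 30),
             age = p$age, female = as.numeric(p$sex == "female"),
             white = as.numeric(p$race == "White"),
             hispanic = as.numeric(p$ethnicity == "Hispanic"),
             row.names = NULL)
}

#' Share of patients with obesity achieving >=5% loss two years later
#'
#' Among patients with obesity at their first weight in `year1`, reports the
#' fraction whose first weight in `year2` is at least 5% below the `year1`
#' index weight.  The exact denominator of such a share is ambiguous, so
#' both candidates are reported: all patients with obesity in `year1`
#' (`pct_of_all`, patients without a `year2` weight counted as not
#' achieving) and only those with follow-up weight data in `year2`
#' (`pct_of_followed`).
#'
#' @param raw a `raw_ehr_bundle`.
#' @param year1,year2 index and follow-up calendar years.
#' @return one-row data.frame: `n_obese`, `n_followed`, `n_loss`,
#'   `pct_of_followed`, `pct_of_all`.
#' @export
two_year_loss_share <- function(raw, year1, year2) {
  cs1 <- extract_cross_section(raw, year1)
  cs1 <- cs1[cs1$obese == 1, , drop = FALSE]
  cs2 <- extract_cross_section(raw, year2)
  i <- match(cs1$patient_id, cs2$patient_id)
  followed <- !is.na(i)
  loss <- followed & cs2$weight_kg[i] <= 0.95 * cs1$weight_kg
  data.frame(n_obese = nrow(cs1), n_followed = sum(followed),
             n_loss = sum(loss),
             pct_of_followed = 100 * sum(loss) / max(sum(followed), 1L),
             pct_of_all = 100 * sum(loss) / max(nrow(cs1), 1L))
}

#' Prospective WMT utilization after the index weight
#'
#' Restricted to patients with at least `horizon` days of recorded follow-up
#' both preceding and following the index weight (first weight in the year).
#' Reports the percentage using each WMT in the year after the index weight;
#' patients with prior bariatric surgery are excluded from the surgery
#' denominator; "any WMT" excludes GLP1RA.
#'
#' @param raw a `raw_ehr_bundle`.
#' @param cross_section result of [extract_cross_section()].
#' @param horizon days of required and assessed follow-up (default 364).
#' @return data.frame with columns `wmt`, `year`, `n`, `users`, `pct`.
#' @export
compute_utilization <- function(raw, cross_section, horizon = 364) {
  if (nrow(cross_section) == 0)
    return(data.frame(wmt = character(), year = integer(), n = integer(),
                      users = integer(), pct = numeric()))
  contact <- rbind(
    data.frame(patient_id = raw$visits$patient_id, date = raw$visits$visit_date),
    data.frame(patient_id = raw$weights$patient_id, date = raw$weights$measure_date))
  first_c <- aggregate(date ~ patient_id, contact, min)
  last_c <- aggregate(date ~ patient_id, contact, max)
  cs <- cross_section
  cs$first <- first_c$date[match(cs$patient_id, first_c$patient_id)]
  cs$last <- last_c$date[match(cs$patient_id, last_c$patient_id)]
  cs <- cs[as.numeric(cs$date - cs$first) >= horizon &
             as.numeric(cs$last - cs$date) >= horizon, , drop = FALSE]
  if (nrow(cs) == 0)
    return(data.frame(wmt = character(), year = integer(), n = integer(),
                      users = integer(), pct = numeric()))

  ev <- raw$wmt_events
  used <- function(pid, idx_date, types, drugs = NULL) {
    e <- ev[ev$patient_id == pid & ev$type %in% types, , drop = FALSE]
    if (!is.null(drugs)) e <- e[e$drug %in% drugs, , drop = FALSE]
    any(e$event_date > idx_date & e$event_date <= idx_date + horizon)
  }
  prior_surg <- vapply(seq_len(nrow(cs)), function(i) {
    e <- ev[ev$patient_id == cs$patient_id[i] & ev$type == "surgery", , drop = FALSE]
    any(e$event_date <= cs$date[i])
  }, logical(1))

  aom_drugs <- c("orlistat", "liraglutide", "phen_top", "bup_nal",
                 "phentermine", "topiramate", "bupropion", "naltrexone")
  flags <- data.frame(
    nutrition = vapply(seq_len(nrow(cs)), function(i)
      used(cs$patient_id[i], cs$date[i], "dietitian"), logical(1)),
    mr = vapply(seq_len(nrow(cs)), function(i)
      used(cs$patient_id[i], cs$date[i], "mr_visit"), logical(1)),
    aom = vapply(seq_len(nrow(cs)), function(i)
      used(cs$patient_id[i], cs$date[i], "aom_order", aom_drugs), logical(1)),
    glp1ra = vapply(seq_len(nrow(cs)), function(i)
      used(cs$patient_id[i], cs$date[i], "aom_order", "glp1ra"), logical(1)),
    surgery = vapply(seq_len(nrow(cs)), function(i)
      used(cs$patient_id[i], cs$date[i], "surgery"), logical(1)))
  flags$any_wmt <- flags$nutrition | flags$mr | flags$aom | flags$surgery

  yr <- unique(cs$year)[1]
  row <- function(wmt, keep) {
    u <- sum(flags[[wmt]][keep])
    data.frame(wmt = wmt, year = yr, n = sum(keep), users = u,
               pct = 100 * u / max(sum(keep), 1L))
  }
  all <- rep(TRUE, nrow(cs))
  out <- rbind(row("nutrition", all), row("mr", all), row("aom", all),
               row("glp1ra", all), row("surgery", !prior_surg),
               row("any_wmt", all))
  rownames(out) <- NULL
  # per-patient flags, e.g. to feed the utilization outcome of the GEE stage
  attr(out, "flags") <- data.frame(patient_id = cs$patient_id, year = cs$year,
                                   flags, wmt_any = as.numeric(flags$any_wmt))
  out
}
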