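# Population counterfactuals: patient-level probabilities, AME, PAF,
# fold-increase scenarios and the tipping point.

test_that("patient-level probabilities are consistent with profile predictions", {
  fit <- fixture_recovery_fit()
  panel <- fixture_recovery_panel()
  cov <- panel$covariates
  elig <- cov$patient_id[cov$followup_days >= 364]
  never <- intersect(elig, cov$patient_id[cov$wmt_exposed == 0])[1]
  # a never-exposed patient equals the no-WMT profile for their covariates
  p_pat <- patient_level_prob(fit, panel, never)
  cr <- cov[match(never, cov$patient_id), ]
  demog <- c(male = 1 - cr$female, age10 = (cr$age - 50) / 10,
             nonwhite = 1 - cr$white, hispanic = cr$hispanic,
             bmi5 = (cr$baseline_bmi - 35) / 5, pcvisits = cr$prior_visits - 1)
  p_prof <- state_probabilities(fit, reference_profile("none", demographics = demog))
  expect_equal(p_pat, p_prof$collapsed$loss, tolerance = 1e-8)
  # exposure over the whole year equals the idealized computation
  tl_full <- build_exposure_segments(
    data.frame(type = "aom_order", day = 0, day_end = 364, drug = "glp1ra"),
    followup = c(0, 364))
  panel2 <- panel
  panel2$timelines[[as.character(never)]] <- tl_full
  p_always <- patient_level_prob(fit, panel2, never)
  p_ideal <- state_probabilities(fit, reference_profile("aom",
                                                        demographics = demog))
  expect_equal(p_always, p_ideal$collapsed$loss, tolerance = 1e-8)
  # half-year exposure lies strictly between (loss HRs > 1 fitted here)
  tl_half <- build_exposure_segments(
    data.frame(type = "aom_order", day = 0, day_end = 182, drug = "glp1ra"),
    followup = c(0, 364))
  panel3 <- panel
  panel3$timelines[[as.character(never)]] <- tl_half
  p_half <- patient_level_prob(fit, panel3, never)
  lohi <- sort(c(p_pat, p_always))
  expect_gt(p_half, lohi[1])
  expect_lt(p_half, lohi[2])
  # a too-short timeline is an error
  shortid <- cov$patient_id[cov$followup_days < 364][1]
  if (!is.na(shortid))
    expect_error(patient_level_prob(fit, panel, shortid),
                 class = "wtmsm_input_error")
})

test_that("the AME vanishes without exposure and under null effects", {
  fit <- fixture_recovery_fit()
  panel <- fixture_recovery_panel()
  # cohort with zero exposed patients: AME exactly 0
  ids0 <- panel$covariates$patient_id[panel$covariates$wmt_exposed == 0 &
                                        panel$covariates$followup_days >= 364]
  p0 <- wtmsm:::panel_subset(panel, ids0)
  a0 <- population_ame(fit, p0)
  expect_identical(a0$ame, 0)
  # all hazard ratios forced to 1: AME 0 to numerical tolerance
  par1 <- fit$params
  par1$beta[, "wmt_any"] <- 0
  a1 <- population_ame(par1, panel)
  expect_lt(abs(a1$ame), 1e-12)
  # PAF round-trip: paf * observed = 100 * ame
  a <- population_ame(fit, panel)
  expect_gt(a$ame, 0)
  expect_equal(a$paf * a$observed_mean, 100 * a$ame, tolerance = 1e-12)
  expect_equal(attributable_fraction(a$ame, a$observed_mean), a$paf,
               tolerance = 1e-12)
})

test_that("attributable-fraction arithmetic matches the definition", {
  expect_equal(round(attributable_fraction(0.50, 17.6), 1), 2.8)
  expect_identical(attributable_fraction(0, 10), 0)
  expect_identical(attributable_fraction(0.2, 0.2), 100)
  expect_error(attributable_fraction(0.1, 0), class = "wtmsm_input_error")
})

test_that("per-WMT AMEs add up when exposures never co-occur", {
  # build a small panel where each exposed patient has exactly one WMT
  b <- simulate_population(
    sim_config(n_patients = 500, seed = 303,
               true_params = default_true_params(),
               exposure_uptake = list(nutrition = 0.08, mr = 0, aom = 0.08,
                                      surgery = 0),
               confounding_strength = 0))
  panel <- build_panel(b)
  # drop the rare patients holding both exposures
  both <- vapply(panel$timelines, function(tl)
    any(tl$nutrition_90d == 1) && any(tl$aom_any == 1), logical(1))
  keep <- panel$covariates$patient_id[!both[as.character(panel$covariates$patient_id)]]
  panel <- wtmsm:::panel_subset(panel, keep)
  par <- attr(b, "truth")$true_params
  a_all <- population_ame(par, panel, which = "all")
  a_nut <- population_ame(par, panel, which = "nutrition")
  a_aom <- population_ame(par, panel, which = "aom")
  expect_equal(a_all$ame, a_nut$ame + a_aom$ame, tolerance = 1e-10)
})

test_that("the model AME matches Monte-Carlo simulation of both scenarios", {
  b <- fixture_recovery_bundle()
  panel <- fixture_recovery_panel()
  par <- recovery_true_params()
  a <- population_ame(par, panel)
  # Monte-Carlo: resimulate each eligible patient's year under observed and
  # zeroed exposures
  cov <- panel$covariates
  ids <- cov$patient_id[cov$followup_days >= 364]
  ids <- head(ids[cov$wmt_exposed[match(ids, cov$patient_id)] == 1], 60)
  ids0 <- head(setdiff(cov$patient_id[cov$followup_days >= 364], ids), 60)
  sim_loss <- function(pid, zero, nrep = 60) {
    tl <- panel$timelines[[as.character(pid)]]
    if (zero) tl <- wtmsm:::zero_timeline(tl, "all")
    keep <- tl$start < 364
    tl <- tl[keep, , drop = FALSE]
    starts <- tl$start; ends <- c(starts[-1], 364)
    segs <- lapply(seq_along(starts), function(k) {
      z <- wtmsm:::exposure_design(tl[k, , drop = FALSE])
      list(duration = ends[k] - starts[k],
           Q = build_intensity_matrix(par, z))
    })
    segs <- segs[vapply(segs, function(s) s$duration > 0, logical(1))]
    mean(replicate(nrep, path_state_at(simulate_ctmc_path(segs, 3L), 364) <= 2))
  }
  set.seed(304)
  use <- c(ids, ids0)
  mc_obs <- mean(vapply(use, sim_loss, numeric(1), zero = FALSE))
  mc_cf <- mean(vapply(use, sim_loss, numeric(1), zero = TRUE))
  # model-based means over the same patients
  sub <- wtmsm:::panel_subset(panel, use)
  am <- population_ame(par, sub)
  nrep_tot <- length(use) * 60
  se <- sqrt(2 * 0.25 / nrep_tot) # conservative binomial bound on the diff
  expect_lt(abs((mc_obs - mc_cf) - am$ame), 3 * se)
})

test_that("linear scenarios reproduce the endpoints and constant increments", {
  fit <- fixture_recovery_fit()
  panel <- fixture_recovery_panel()
  sc <- fold_increase_scenarios(fit, panel, multipliers = c(0, 1, 2, 3, 4, 5))
  a <- population_ame(fit, panel)
  # m = 0 reproduces the no-WMT mean; m = 1 the observed mean
  expect_equal(sc$mean_loss[sc$multiplier == 0], a$counterfactual_mean,
               tolerance = 1e-10)
  expect_equal(sc$mean_loss[sc$multiplier == 1][1], a$observed_mean,
               tolerance = 1e-10)
  # per-fold increment is constant and equals the AME
  incr <- diff(sc$mean_loss[match(1:5, sc$multiplier)])
  expect_equal(incr, rep(a$ame, 4), tolerance = 1e-10)
  expect_equal(attr(sc, "ame"), a$ame, tolerance = 1e-12)
  # risk ratio is exactly 1 where the difference is 0
  expect_equal(sc$risk_ratio[abs(sc$diff) < 1e-14],
               rep(1, sum(abs(sc$diff) < 1e-14)))
  expect_error(fold_increase_scenarios(fit, panel, multipliers = -1),
               class = "wtmsm_input_error")
  # the increase-by convention shifts multipliers by one
  sc2 <- fold_increase_scenarios(fit, panel, multipliers = 2,
                                 fold_means = "increase-by")
  expect_identical(sc2$multiplier, c(1, 3))
})

test_that("linear and resampling scenario means agree at the status quo", {
  fit <- fixture_recovery_fit()
  panel <- fixture_recovery_panel()
  lin <- fold_increase_scenarios(fit, panel, multipliers = c(2, 3))
  res <- fold_increase_scenarios(fit, panel, multipliers = c(2, 3),
                                 mode = "resample", seed = 5)
  expect_equal(lin$mean_loss[1], res$mean_loss[1], tolerance = 1e-12)
  # both raise the loss share as utilization grows
  expect_true(all(diff(res$mean_loss) > -0.02))
  expect_true(all(diff(lin$mean_loss) > 0))
})

test_that("the tipping point flags the smallest multiplier with a clear excess", {
  # constructed crossing: loss and gain cross between m = 1 and m = 2
  tab <- data.frame(fold = c(1, 2, 3), multiplier = c(1, 2, 3),
                    mean_loss = c(0.15, 0.17, 0.19),
                    mean_gain = c(0.16, 0.16, 0.16))
  tab$diff <- tab$mean_loss - tab$mean_gain
  tab$risk_ratio <- tab$mean_loss / tab$mean_gain
  tab$diff_lo <- tab$diff - 0.005
  tab$diff_hi <- tab$diff + 0.005
  class(tab) <- c("scenario_table", "data.frame")
  tp <- tipping_point_summary(tab)
  expect_identical(tp$tipping_multiplier, 2)
  # loss == gain everywhere: nothing flagged
  tab2 <- tab
  tab2$diff <- rep(0, 3); tab2$diff_lo <- -0.01; tab2$diff_hi <- 0.01
  expect_true(is.na(tipping_point_summary(tab2)$tipping_multiplier))
  expect_error(tipping_point_summary(tab[1, ]), class = "wtmsm_input_error")
})
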