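# The multistate model core: intensity construction, interval probabilities
# (closed-form and Monte-Carlo oracles), the panel likelihood, and the
# maximum-likelihood fitter.

test_that("intensity matrices obey the proportional-intensity form", {
  st <- transition_structure("x")
  beta <- matrix(log(2), 8, 1)
  par <- msm_params(log(rep(0.1, 8)), beta, st)
  # zero covariate: baseline intensities regardless of beta
  Q0 <- build_intensity_matrix(par, c(x = 0))
  expect_equal(Q0[3, 4], 0.1)
  # x = 1 doubles every allowed rate: q = 0.1 * exp(log 2) = 0.2
  Q1 <- build_intensity_matrix(par, c(x = 1))
  expect_equal(Q1[3, 4], 0.2)
  expect_equal(rowSums(Q1), rep(0, 5))          # conservation, exact
  expect_true(all(Q1[upper.tri(Q1) | lower.tri(Q1)] >= 0))
  # disallowed (non-adjacent) entries stay zero
  expect_identical(Q1[1, 3], 0); expect_identical(Q1[3, 5], 0)
  # non-finite linear predictor is a structured error; absurd finite
  # predictors saturate with a warning instead of overflowing
  expect_error(build_intensity_matrix(par, c(x = NA_real_)),
               class = "wtmsm_numeric_error")
  par2 <- msm_params(log(rep(0.1, 8)), matrix(700, 8, 1), st)
  expect_warning(Qs <- build_intensity_matrix(par2, c(x = 2)), "saturated")
  expect_true(all(is.finite(Qs)))
})

test_that("interval probabilities match the two-state closed form to 1e-10", {
  lam <- 0.01; mu <- 0.005; tt <- 100
  st <- transition_structure()
  q0 <- rep(1e-15, 8); q0[5] <- lam; q0[6] <- mu  # only 3->4 and 4->3
  par <- msm_params(log(q0), structure = st)
  P <- interval_probability(par, data.frame(duration = tt))
  p33 <- mu / (lam + mu) + (lam / (lam + mu)) * exp(-(lam + mu) * tt)
  expect_lt(abs(P[3, 3] - p33), 1e-10)
  expect_lt(abs(P[3, 4] - (1 - p33)), 1e-10)
  # zero duration: identity
  expect_equal(interval_probability(par, data.frame(duration = 0)), diag(5))
  expect_error(interval_probability(par, data.frame(duration = -1)),
               class = "wtmsm_input_error")
})

test_that("interval probabilities agree with Gillespie simulation", {
  par <- recovery_true_params()
  P <- interval_probability(par, data.frame(duration = 364, wmt_any = 0))
  Q <- build_intensity_matrix(par, c(wmt_any = 0))
  set.seed(61)
  nrep <- 20000
  cnt <- integer(5)
  for (i in seq_len(nrep)) {
    p <- simulate_ctmc_path(list(list(duration = 364, Q = Q)), 3L)
    s <- path_state_at(p, 364)
    cnt[s] <- cnt[s] + 1L
  }
  emp <- cnt / nrep
  se <- sqrt(P[3, ] * (1 - P[3, ]) / nrep)
  expect_true(all(abs(emp - P[3, ]) <= 3 * se + 1e-12))
})

test_that("interval probabilities are row-stochastic and satisfy the semigroup law", {
  par <- default_true_params()
  z <- c(male = 1, age10 = 0.5, nutrition_90d = 1, mr_early = 0, mr_late = 0,
         aom_any = 1, surg_0_90 = 0, surg_gt90 = 0)
  seg <- function(d) data.frame(duration = d, as.list(z), check.names = FALSE)
  P364 <- interval_probability(par, seg(364))
  expect_true(all(abs(rowSums(P364) - 1) < 1e-10))
  expect_true(all(P364 >= 0))
  P182 <- interval_probability(par, seg(182))
  expect_lt(max(abs(P364 - P182 %*% P182)), 1e-10)
  # Chapman-Kolmogorov: splitting at an arbitrary interior point is exact
  Psplit <- interval_probability(par, rbind(seg(123.4), seg(364 - 123.4)))
  expect_lt(max(abs(P364 - Psplit)), 1e-10)
})

test_that("the panel log-likelihood matches hand-computed interval products", {
  st <- transition_structure("wmt_any")
  par <- recovery_true_params()
  # two-interval toy patient: 3 -> 4 over 100 d (exposed), 4 -> 4 over 50 d
  tl <- build_exposure_segments(
    data.frame(type = "aom_order", day = 0, day_end = 150, drug = "glp1ra"),
    followup = c(0, 150))
  panel <- structure(list(
    obs = data.frame(patient_id = 1, day = c(0, 100, 150), state = c(3, 4, 4)),
    covariates = data.frame(patient_id = 1, age = 50, female = 1, white = 1,
                            hispanic = 0, baseline_bmi = 35, prior_visits = 1,
                            t2d = 0, hyperlipidemia = 0, hypertension = 0,
                            nafld = 0, osa = 0, wmt_exposed = 1,
                            followup_days = 150),
    timelines = list(`1` = tl),
    baseline = data.frame(patient_id = 1, baseline_date = as.Date("2016-01-01"),
                          baseline_weight = 100)), class = "panel_dataset")
  ll <- panel_log_likelihood(par, panel)
  P1 <- interval_probability(par, data.frame(duration = 100, wmt_any = 1))
  P2 <- interval_probability(par, data.frame(duration = 50, wmt_any = 1))
  expect_equal(ll, log(P1[3, 4]) + log(P2[4, 4]), tolerance = 1e-8)

  # a zero-length interval in the same state contributes log 1 = 0
  panel2 <- panel
  panel2$obs <- data.frame(patient_id = 1, day = c(0, 100, 100, 150),
                           state = c(3, 4, 4, 4))
  expect_equal(panel_log_likelihood(par, panel2), ll, tolerance = 1e-8)
  # an impossible instantaneous jump has zero probability: -Inf, no error
  panel3 <- panel
  panel3$obs <- data.frame(patient_id = 1, day = c(0, 100, 100),
                           state = c(3, 4, 5))
  expect_identical(panel_log_likelihood(par, panel3), -Inf)
  panel4 <- panel
  panel4$obs$state[2] <- 7
  expect_error(panel_log_likelihood(par, panel4), class = "wtmsm_data_error")
})

test_that("the likelihood peaks near the truth on simulated data", {
  panel <- fixture_recovery_panel()
  st <- transition_structure("wmt_any")
  d <- msm_data(panel, st)
  par <- recovery_true_params()
  ll0 <- panel_log_likelihood(par, d)
  set.seed(71)
  for (i in 1:20) {
    pp <- par
    pp$log_q0 <- par$log_q0 + rnorm(8, 0, 0.4)
    pp$beta <- par$beta + rnorm(8, 0, 0.4)
    expect_gt(ll0, panel_log_likelihood(pp, d))
  }
})

test_that("analytic and numeric likelihood gradients agree", {
  panel <- fixture_recovery_panel()
  d <- msm_data(panel, transition_structure("wmt_any"))
  th <- wtmsm:::pack_theta(recovery_true_params())
  nll <- function(t) wtmsm:::cpp_panel_nll(t, d$from, d$to, d$beta_idx, d$Z,
                                           d$seg_dt, d$seg_group, d$obs_from,
                                           d$obs_to, d$n_states)
  g <- wtmsm:::cpp_panel_nll_grad(th, d$from, d$to, d$beta_idx, d$Z,
                                  d$seg_dt, d$seg_group, d$obs_from,
                                  d$obs_to, d$n_states)
  expect_true(g$success)
  expect_equal(g$nll, nll(th), tolerance = 1e-10)
  gn <- wtmsm:::num_gradient(nll, th)
  expect_lt(max(abs(g$grad - gn)), 1e-4 * max(1, max(abs(gn))))
})

test_that("crude initial estimates use counts over time at risk", {
  st <- transition_structure()
  mk_panel <- function(obs) structure(list(
    obs = obs,
    covariates = data.frame(patient_id = unique(obs$patient_id), age = 50,
                            female = 1, white = 1, hispanic = 0,
                            baseline_bmi = 35, prior_visits = 1, t2d = 0,
                            hyperlipidemia = 0, hypertension = 0, nafld = 0,
                            osa = 0, wmt_exposed = 0,
                            followup_days = max(obs$day)),
    timelines = setNames(lapply(unique(obs$patient_id), function(p)
      build_exposure_segments(NULL, c(0, max(obs$day)))),
      unique(obs$patient_id)),
    baseline = NULL), class = "panel_dataset")
  # single patient observed 3 -> 4 over 100 days: q34 = 1/100
  p1 <- mk_panel(data.frame(patient_id = 1, day = c(0, 100), state = c(3, 4)))
  init <- crude_initial_estimates(p1, st)
  expect_equal(unname(exp(init$log_q0["3-4"])), 0.01)
  # no observed changes: all intensities at the floor
  p2 <- mk_panel(data.frame(patient_id = 1, day = c(0, 100, 200),
                            state = c(3, 3, 3)))
  init2 <- crude_initial_estimates(p2, st)
  expect_equal(unname(exp(init2$log_q0)), rep(1e-6, 8), tolerance = 1e-12)
})

test_that("the fitter is stable across jittered starting values", {
  panel <- fixture_recovery_panel()
  ids <- head(panel$covariates$patient_id, 300)
  small <- wtmsm:::panel_subset(panel, ids)
  st <- transition_structure("wmt_any")
  d <- msm_data(small, st)
  f0 <- fit_msm(d)
  expect_true(f0$convergence)
  set.seed(81)
  for (i in 1:3) {
    init <- crude_initial_estimates(d)
    init$log_q0 <- init$log_q0 + rnorm(8, 0, 0.3)
    fi <- suppressWarnings(fit_msm(d, init = init))
    expect_lt(abs(fi$loglik - f0$loglik), 1e-4)
  }
})

test_that("hazard-ratio tables respect masks and Wald arithmetic", {
  fit <- fixture_recovery_fit()
  expect_true(fit$convergence)
  hr <- hazard_ratios(fit)
  expect_identical(nrow(hr), 8L)
  expect_true(all(is.finite(hr$hr)))
  expect_true(all(hr$lo <= hr$hr & hr$hr <= hr$hi))
  # masked cells are reported as NA: mask out one transition and refit shape
  st <- transition_structure("wmt_any",
                             masks = matrix(c(rep(TRUE, 7), FALSE), 8, 1))
  panel <- fixture_recovery_panel()
  ids <- head(panel$covariates$patient_id, 250)
  fit2 <- suppressWarnings(fit_msm(wtmsm:::panel_subset(panel, ids), st))
  hr2 <- hazard_ratios(fit2)
  expect_true(is.na(hr2$hr[hr2$transition == "5-4"]))
  # beta = 0, SE = 0.1: HR 1.00 (0.82-1.22)
  expect_equal(round(exp(0 + c(-1, 0, 1) * qnorm(0.975) * 0.1), 2),
               c(0.82, 1.00, 1.22))
})

test_that("raising a loss-direction hazard raises the one-year loss probability", {
  par <- recovery_true_params()
  base <- state_probabilities(par, reference_profile("none"))
  par2 <- par
  par2$beta["3-2", "wmt_any"] <- par$beta["3-2", "wmt_any"] + 0.5
  # the covariate must be active for the effect to show
  up <- state_probabilities(par2,
                            reference_profile("nutrition")) # nutrition: wmt_any = 1
  base_exp <- state_probabilities(par, reference_profile("nutrition"))
  expect_gt(up$collapsed$loss, base_exp$collapsed$loss)
  expect_equal(base$collapsed$loss + base$collapsed$stable +
                 base$collapsed$gain, 1, tolerance = 1e-10)
})
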