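# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# default-configuration bundle: moderate size, confounded uptake
fixture_bundle <- function() {
  memo("bundle", simulate_population(sim_config(n_patients = 350, seed = 101)))
}

fixture_panel <- function() {
  memo("panel", build_panel(fixture_bundle()))
}

# pooled-exposure recovery world: known HRs 2.0 (loss) / 0.7 (gain)
fixture_recovery_bundle <- function() {
  memo("rec_bundle", simulate_population(
    sim_config(n_patients = 900, visit_rate = 4, seed = 202,
               true_params = recovery_true_params(),
               exposure_uptake = list(nutrition = 0.10, mr = 0.02,
                                      aom = 0.06, surgery = 0.02))))
}

fixture_recovery_panel <- function() {
  memo("rec_panel", build_panel(fixture_recovery_bundle()))
}

fixture_recovery_fit <- function() {
  memo("rec_fit", fit_msm(fixture_recovery_panel(),
                          transition_structure("wmt_any")))
}

# hand-built raw bundle for rule-edge tests
make_mini_bundle <- function(patients, visits, weights,
                             wmt_events = NULL, conditions = NULL) {
  if (is.null(wmt_events))
    wmt_events <- data.frame(patient_id = integer(), type = character(),
                             event_date = as.Date(character()),
                             end_date = as.Date(character()),
                             drug = character())
  if (is.null(conditions))
    conditions <- data.frame(patient_id = integer(), condition = character(),
                             onset_date = as.Date(character()))
  structure(list(patients = patients, visits = visits, weights = weights,
                 wmt_events = wmt_events, conditions = conditions),
            class = "raw_ehr_bundle")
}

# greedy nearest-neighbour matching, as an oracle lower bound on quality
greedy_match_total <- function(D) {
  used <- rep(FALSE, ncol(D))
  tot <- 0
  for (i in seq_len(nrow(D))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    tot <- tot + D[i, j]
    used[j] <- TRUE
  }
  tot
}
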