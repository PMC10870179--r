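#' Propensity model for WMT exposure
#'
#' Logistic regression of the exposure indicator on follow-up time and
#' baseline covariates (age, BMI, sex and weight-related condition flags).
#' Constant covariate columns are dropped with a warning; complete
#' separation raises a convergence error with a diagnostic.
#'
#' @param cohort data.frame (typically `panel$covariates`) containing the
#'   exposure column and covariates.
#' @param covariates covariate column names.
#' @param exposure_col name of the 0/1 exposure column.
#' @return list with `scores` (fitted exposure probability per row, named by
#'   `patient_id` when present), `model` (the glm), `dropped` (removed
#'   constant columns).
#' @export
fit_propensity <- function(cohort,
                           covariates = c("followup_days", "age",
                                          "baseline_bmi", "female",
                                          "hyperlipidemia", "hypertension",
                                          "nafld", "osa", "t2d"),
                           exposure_col = "wmt_exposed") {
  if (!exposure_col %in% names(cohort))
    wt_stop("wtmsm_input_error", "exposure column '%s' not present", exposure_col)
  covariates <- intersect(covariates, names(cohort))
  const <- covariates[vapply(cohort[covariates],
                             function(v) length(unique(v)) == 1L, logical(1))]
  if (length(const)) {
    warning("dropping constant covariate(s): ", paste(const, collapse = ", "))
    covariates <- setdiff(covariates, const)
  }
  form <- stats::as.formula(paste(exposure_col, "~",
                                  paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(form, data = cohort, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE))
    wt_stop("wtmsm_convergence_error",
            "propensity model did not converge (possible complete separation); largest |coef| = %.1f",
            max(abs(coef(fit)), na.rm = TRUE))
  scores <- unname(fitted(fit))
  if ("patient_id" %in% names(cohort)) names(scores) <- cohort$patient_id
  list(scores = scores, model = fit, dropped = const)
}

#' Optimal 1:1 matching within demographic strata
#'
#' Within each stratum (by default the 16 cells of sex x race (majority /
#' nonmajority) x ethnicity (Hispanic / non-Hispanic) x any weight-related
#' condition), exposed patients are paired 1:1 to distinct unexposed controls
#' by minimum-total-distance bipartite assignment, with distance
#' `|logit(score_exposed) - logit(score_control)|` and no caliper.
#'
#' @param cohort data.frame with `patient_id`, the exposure column and the
#'   stratum-defining columns (`female`, `white`, `hispanic` and condition
#'   flags).
#' @param scores propensity scores aligned with `cohort` rows (e.g.
#'   `fit_propensity(cohort)$scores`).
#' @param strata optional factor of stratum labels (overrides the default).
#' @param exposure_col name of the 0/1 exposure column.
#' @param on_unmatchable `"error"` (default) raises a structured error
#'   listing strata with more exposed than controls; `"report"` skips them
#'   and lists them in the result.
#' @return object of class `match_result`: `pairs` (exposed_id, control_id,
#'   stratum, distance, score_exposed, score_control), `unmatchable`,
#'   `total_distance`.
#' @export
match_stratified <- function(cohort, scores, strata = NULL,
                             exposure_col = "wmt_exposed",
                             on_unmatchable = c("error", "report")) {
  on_unmatchable <- match.arg(on_unmatchable)
  if (is.null(strata)) {
    anycond <- as.numeric(rowSums(cohort[, intersect(
      c("t2d", "hyperlipidemia", "hypertension", "nafld", "osa"),
      names(cohort)), drop = FALSE]) > 0)
    strata <- interaction(
      ifelse(cohort$female == 1, "F", "M"),
      ifelse(cohort$white == 1, "maj", "nonmaj"),
      ifelse(cohort$hispanic == 1, "hisp", "nonhisp"),
      ifelse(anycond == 1, "cond", "nocond"), drop = TRUE)
  }
  scores <- as.numeric(scores)
  lg <- qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  exposed <- cohort[[exposure_col]] == 1

  pairs <- list(); unmatch <- list()
  for (s in levels(strata)) {
    ie <- which(strata == s & exposed)
    ic <- which(strata == s & !exposed)
    if (length(ie) == 0) next
    if (length(ic) < length(ie)) {
      unmatch[[length(unmatch) + 1L]] <- data.frame(
        stratum = s, n_exposed = length(ie), n_controls = length(ic))
      next
    }
    D <- abs(outer(lg[ie], lg[ic], "-"))
    asg <- cpp_assignment(matrix(D, nrow = length(ie)))
    pairs[[length(pairs) + 1L]] <- data.frame(
      exposed_id = cohort$patient_id[ie],
      control_id = cohort$patient_id[ic[asg]],
      stratum = s,
      distance = D[cbind(seq_along(ie), asg)],
      score_exposed = scores[ie],
      score_control = scores[ic[asg]])
  }
  unmatch <- if (length(unmatch)) do.call(rbind, unmatch) else
    data.frame(stratum = character(), n_exposed = integer(),
               n_controls = integer())
  if (nrow(unmatch) && on_unmatchable == "error")
    wt_stop("wtmsm_unmatchable_error",
            "stratum(s) with more exposed than controls: %s",
            paste(sprintf("%s (%d exposed, %d controls)", unmatch$stratum,
                          unmatch$n_exposed, unmatch$n_controls),
                  collapse = "; "))
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(exposed_id = integer(), control_id = integer(),
               stratum = character(), distance = numeric(),
               score_exposed = numeric(), score_control = numeric())
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatchable = unmatch,
                 total_distance = sum(pairs$distance)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Optimal 1:1 match: %d pairs in %d strata, total distance %.4f\n",
              nrow(x$pairs), length(unique(x$pairs$stratum)), x$total_distance))
  if (nrow(x$unmatchable))
    cat(sprintf("  unmatchable strata: %d\n", nrow(x$unmatchable)))
  invisible(x)
}

#' Standardized mean differences between exposure groups
#'
#' For continuous covariates, `SMD = (mean_exposed - mean_control) /
#' sqrt((var_exposed + var_control) / 2)`; for binary covariates the
#' proportion analogue.  A zero pooled SD yields SMD 0 with a warning.
#'
#' @param cohort data.frame with `patient_id` and the covariates.
#' @param covariates covariate columns to assess.
#' @param pairs optional `match_result$pairs`; when supplied the comparison
#'   is matched exposed vs matched controls, otherwise all exposed vs all
#'   unexposed.
#' @param exposure_col name of the 0/1 exposure column.
#' @return data.frame (covariate, mean_exposed, mean_control, smd) with the
#'   maximum `|SMD|` as attribute `"max_abs_smd"`.
#' @export
balance_table <- function(cohort,
                          covariates = c("age", "baseline_bmi", "female",
                                         "followup_days", "hyperlipidemia",
                                         "hypertension", "nafld", "osa",
                                         "t2d"),
                          pairs = NULL, exposure_col = "wmt_exposed") {
  covariates <- intersect(covariates, names(cohort))
  if (is.null(pairs)) {
    g1 <- cohort[cohort[[exposure_col]] == 1, , drop = FALSE]
    g0 <- cohort[cohort[[exposure_col]] == 0, , drop = FALSE]
  } else {
    g1 <- cohort[match(pairs$exposed_id, cohort$patient_id), , drop = FALSE]
    g0 <- cohort[match(pairs$control_id, cohort$patient_id), , drop = FALSE]
  }
  if (nrow(g1) == 0 || nrow(g0) == 0)
    wt_stop("wtmsm_input_error", "both exposure groups must be non-empty")
  smd1 <- function(v1, v0) {
    binary <- all(c(v1, v0) %in% c(0, 1))
    m1 <- mean(v1); m0 <- mean(v0)
    s <- if (binary) sqrt((m1 * (1 - m1) + m0 * (1 - m0)) / 2)
         else sqrt((var(v1) + var(v0)) / 2)
    if (!is.finite(s) || s == 0) {
      if (m1 != m0) warning("zero pooled SD with unequal means; SMD set to 0")
      return(0)
    }
    (m1 - m0) / s
  }
  out <- data.frame(
    covariate = covariates,
    mean_exposed = vapply(covariates, function(cv) mean(g1[[cv]]), numeric(1)),
    mean_control = vapply(covariates, function(cv) mean(g0[[cv]]), numeric(1)),
    smd = vapply(covariates, function(cv) smd1(g1[[cv]], g0[[cv]]), numeric(1)),
    row.names = NULL)
  attr(out, "max_abs_smd") <- max(abs(out$smd))
  out
}
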