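#' The five-state weight-status ladder
#'
#' States are defined by weight relative to baseline: state 1 = 10% or
#' greater loss, state 2 = 5-10% loss, state 3 = within +/-5% of baseline,
#' state 4 = 5-10% gain, state 5 = 10% or greater gain.
#'
#' @param thresholds relative-weight cut points (strictly increasing,
#'   length 4).
#' @return list with `thresholds` and `labels`.
#' @export
state_ladder <- function(thresholds = c(0.90, 0.95, 1.05, 1.10)) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    wt_stop("wtmsm_input_error", "thresholds must be 4 strictly increasing cut points")
  list(thresholds = thresholds,
       labels = c(">=10% loss", "5-10% loss", "baseline +/-5%",
                  "5-10% gain", ">=10% gain"))
}

#' Categorise weights into the five-state ladder
#'
#' Boundary convention: loss cut points are inclusive on the loss side and
#' gain cut points inclusive on the gain side, matching "10% or greater loss"
#' / "5% or greater gain" phrasing; the stable state is the open interval.
#' With baseline `b`: `w <= 0.90 b` is state 1, `0.90 b < w <= 0.95 b` state
#' 2, `0.95 b < w < 1.05 b` state 3, `1.05 b <= w < 1.10 b` state 4 and
#' `w >= 1.10 b` state 5.
#'
#' @param weights numeric vector of weights (kg), all positive.
#' @param baseline_weight baseline weight (kg), positive scalar.
#' @param ladder a [state_ladder()].
#' @return integer vector of states in 1..5.
#' @export
derive_weight_states <- function(weights, baseline_weight,
                                 ladder = state_ladder()) {
  if (!is.finite(baseline_weight) || baseline_weight <= 0)
    wt_stop("wtmsm_data_error", "baseline weight must be positive")
  if (any(!is.finite(weights)) || any(weights <= 0))
    wt_stop("wtmsm_data_error", "weights must be positive and finite")
  r <- weights / baseline_weight
  th <- ladder$thresholds
  ifelse(r <= th[1], 1L,
  ifelse(r <= th[2], 2L,
  ifelse(r <  th[3], 3L,
  ifelse(r <  th[4], 4L, 5L))))
}
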