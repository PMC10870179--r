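#' Time-varying WMT exposure coding
#'
#' Converts a patient's raw treatment event stream into a piecewise-constant
#' exposure timeline over follow-up.  Definitions:
#' \itemize{
#'   \item `nutrition_90d(t)` = 1 iff a dietitian visit occurred in the prior
#'     90 days (an event on day `e` keeps the flag on over `[e, e+90)`).
#'   \item `mr_early(t)` / `mr_late(t)` = 1 iff a meal-replacement visit
#'     occurred in the prior 90 days AND the program phase at `t` is early
#'     (days 0-183 since the first program visit) or late (days 184-730).
#'   \item `aom_any(t)` = 1 iff an anti-obesity-medication order interval
#'     covers `t`.  Single-agent orlistat, liraglutide, GLP1RA and the fixed
#'     combinations count directly; overlapping single-agent phentermine +
#'     topiramate or bupropion + naltrexone count over the overlap (off-label
#'     combination use).
#'   \item `surgery_bin(t)`: days since bariatric surgery binned as
#'     `none`, `0-90`, `91-180`, `181-364`, `>=365`.
#' }
#' All intervals are treated as left-closed, right-open at day resolution.
#'
#' @param events data.frame of the patient's WMT events with columns `type`
#'   (one of `"dietitian"`, `"mr_visit"`, `"aom_order"`, `"surgery"`), `day`
#'   (days from baseline), `day_end` (order end for `"aom_order"`, else `NA`)
#'   and `drug` (for orders: `"orlistat"`, `"liraglutide"`, `"glp1ra"`,
#'   `"phen_top"`, `"bup_nal"`, `"phentermine"`, `"topiramate"`,
#'   `"bupropion"`, `"naltrexone"`).
#' @param followup numeric length-2: follow-up window `[start, end]` in days.
#' @param mr_program_start optional program start day; defaults to the first
#'   meal-replacement visit.  A visit before the program start is a data
#'   error.
#' @return an object of class `exposure_timeline`: a data.frame with columns
#'   `start`, `nutrition_90d`, `mr_early`, `mr_late`, `aom_any`,
#'   `surgery_bin`; each row holds from its `start` to the next row's.
#' @export
build_exposure_segments <- function(events, followup = c(0, 730),
                                    mr_program_start = NULL) {
  t0 <- followup[1]; t1 <- followup[2]
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(type = character(), day = numeric(),
                         day_end = numeric(), drug = character())
  }
  if (is.null(events$day_end)) events$day_end <- NA_real_
  if (is.null(events$drug)) events$drug <- NA_character_

  # component intervals, each [a, b)
  iv <- function(a, b) if (length(a)) cbind(a, b) else matrix(0, 0, 2)

  diet <- events[events$type == "dietitian", , drop = FALSE]
  nut_iv <- iv(diet$day, diet$day + 90)

  mrv <- events[events$type == "mr_visit", , drop = FALSE]
  mr_early_iv <- mr_late_iv <- iv(numeric(0), numeric(0))
  if (nrow(mrv)) {
    ps <- if (!is.null(mr_program_start)) mr_program_start else min(mrv$day)
    if (any(mrv$day < ps))
      wt_stop("wtmsm_data_error", "meal-replacement visit before program start")
    act <- iv(mrv$day, mrv$day + 90)
    mr_early_iv <- interval_intersect(act, cbind(ps, ps + 184))
    mr_late_iv  <- interval_intersect(act, cbind(ps + 184, ps + 731))
  }

  aom <- events[events$type == "aom_order", , drop = FALSE]
  aom_iv <- iv(numeric(0), numeric(0))
  if (nrow(aom)) {
    if (any(is.na(aom$day_end)) || any(aom$day_end < aom$day))
      wt_stop("wtmsm_data_error", "AOM order interval needs day_end >= day")
    direct <- aom$drug %in% c("orlistat", "liraglutide", "glp1ra",
                              "phen_top", "bup_nal")
    aom_iv <- iv(aom$day[direct], aom$day_end[direct])
    for (pair in list(c("phentermine", "topiramate"),
                      c("bupropion", "naltrexone"))) {
      a <- aom[aom$drug == pair[1], , drop = FALSE]
      b <- aom[aom$drug == pair[2], , drop = FALSE]
      if (nrow(a) && nrow(b)) {
        ov <- interval_intersect(iv(a$day, a$day_end), iv(b$day, b$day_end))
        aom_iv <- rbind(aom_iv, ov)
      }
    }
  }

  surg <- events[events$type == "surgery", , drop = FALSE]
  if (nrow(surg) > 1)
    wt_stop("wtmsm_data_error", "at most one bariatric surgery per patient")
  surg_day <- if (nrow(surg)) surg$day[1] else NA_real_

  cuts <- c(t0, nut_iv, mr_early_iv, mr_late_iv, aom_iv)
  if (!is.na(surg_day)) cuts <- c(cuts, surg_day + c(0, 91, 181, 365))
  cuts <- sort(unique(pmin(pmax(cuts, t0), t1)))
  cuts <- cuts[cuts < t1]

  in_iv <- function(t, m) if (nrow(m) == 0) FALSE else any(t >= m[, 1] & t < m[, 2])
  sbin <- function(t) {
    if (is.na(surg_day) || t < surg_day) return("none")
    d <- t - surg_day
    if (d < 91) "0-90" else if (d < 181) "91-180"
    else if (d < 365) "181-364" else ">=365"
  }
  tl <- data.frame(
    start = cuts,
    nutrition_90d = vapply(cuts, in_iv, logical(1), m = nut_iv) * 1L,
    mr_early = vapply(cuts, in_iv, logical(1), m = mr_early_iv) * 1L,
    mr_late = vapply(cuts, in_iv, logical(1), m = mr_late_iv) * 1L,
    aom_any = vapply(cuts, in_iv, logical(1), m = aom_iv) * 1L,
    surgery_bin = vapply(cuts, sbin, character(1)),
    stringsAsFactors = FALSE
  )
  # drop redundant changepoints (no component actually changes)
  if (nrow(tl) > 1) {
    keep <- c(TRUE, rowSums(abs(tl[-1, 2:5, drop = FALSE] -
                                tl[-nrow(tl), 2:5, drop = FALSE])) > 0 |
                    tl$surgery_bin[-1] != tl$surgery_bin[-nrow(tl)])
    tl <- tl[keep, , drop = FALSE]
    rownames(tl) <- NULL
  }
  attr(tl, "followup") <- c(t0, t1)
  class(tl) <- c("exposure_timeline", "data.frame")
  tl
}

# pairwise intersection of two sets of [a,b) intervals
interval_intersect <- function(A, B) {
  out <- matrix(0, 0, 2)
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    lo <- max(A[i, 1], B[j, 1]); hi <- min(A[i, 2], B[j, 2])
    if (hi > lo) out <- rbind(out, c(lo, hi))
  }
  out
}

#' Exposure state at a time point
#'
#' @param timeline an [build_exposure_segments()] result.
#' @param t time in days from baseline.
#' @return one-row data.frame with the component values at `t`.
#' @export
exposure_at <- function(timeline, t) {
  fu <- attr(timeline, "followup")
  if (t < fu[1] || t > fu[2])
    wt_stop("wtmsm_input_error", "t = %g outside follow-up [%g, %g]", t, fu[1], fu[2])
  i <- findInterval(t, timeline$start)
  if (i < 1L) i <- 1L
  timeline[i, , drop = FALSE]
}

# expand one timeline row into the WMT design columns
exposure_design <- function(row) {
  sb <- row$surgery_bin
  c(nutrition_90d = as.numeric(row$nutrition_90d),
    mr_early = as.numeric(row$mr_early),
    mr_late = as.numeric(row$mr_late),
    aom_any = as.numeric(row$aom_any),
    surg_0_90 = as.numeric(sb == "0-90"),
    surg_91_180 = as.numeric(sb == "91-180"),
    surg_181_364 = as.numeric(sb == "181-364"),
    surg_ge365 = as.numeric(sb == ">=365"),
    surg_gt90 = as.numeric(sb %in% c("91-180", "181-364", ">=365")),
    wmt_any = as.numeric(row$nutrition_90d | row$mr_early | row$mr_late |
                           row$aom_any | sb != "none"))
}
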