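#' Allowed transitions and per-transition covariate masks
#'
#' The five weight states form a ladder; only adjacent transitions are
#' allowed, giving eight directed transitions.  A `transition_structure`
#' records which covariates carry a coefficient on which transition (the
#' mask), mirroring the convention that some exposures are not estimable, or
#' are pooled, on particular transitions (for example, fine time-since-surgery
#' bins on transitions out of loss states but a single pooled ">90 days" level
#' on transitions out of the baseline state).
#'
#' @param covariates character vector of design-column names.
#' @param masks logical matrix (8 transitions x covariates). `TRUE` means the
#'   covariate has a coefficient on that transition. Default: all `TRUE`.
#' @return an object of class `transition_structure` with elements `from`,
#'   `to`, `labels`, `covariates`, `masks`, and `loss` (logical, `TRUE` for
#'   loss-direction transitions).
#' @export
transition_structure <- function(covariates = character(), masks = NULL) {
  from <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L)
  to   <- c(2L, 1L, 3L, 2L, 4L, 3L, 5L, 4L)
  labels <- paste(from, to, sep = "-")
  P <- length(covariates)
  if (is.null(masks)) masks <- matrix(TRUE, 8L, P)
  masks <- as.matrix(masks)
  if (!identical(dim(masks), c(8L, P)))
    wt_stop("wtmsm_structure_error", "masks must be 8 x %d", P)
  storage.mode(masks) <- "logical"
  dimnames(masks) <- list(labels, covariates)
  structure(
    list(from = from, to = to, labels = labels, n_states = 5L,
         covariates = covariates, masks = masks, loss = to < from),
    class = "transition_structure"
  )
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure: 8 adjacent transitions among 5 states\n")
  cat("Covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  if (length(x$covariates)) {
    cat("Coefficients per transition:\n")
    print(x$masks)
  }
  invisible(x)
}

# demographic design columns, centred so the reference patient
# (female, age 50, BMI 35, White, non-Hispanic, 1 prior-year visit) is zero
DEMOG_COLS <- c("male", "age10", "nonwhite", "hispanic", "bmi5", "pcvisits")

# WMT design columns produced from an exposure timeline
WMT_COLS <- c("nutrition_90d", "mr_early", "mr_late", "aom_any",
              "surg_0_90", "surg_91_180", "surg_181_364", "surg_ge365",
              "surg_gt90", "wmt_any")

#' Default covariate masks for WMT effects
#'
#' Builds a `transition_structure` in which demographic covariates act on all
#' eight transitions while WMT exposures follow the estimability pattern used
#' in practice: full fine surgery bins on transitions out of the loss states,
#' a first bin plus pooled ">90 days" level on transitions out of the baseline
#' state, only the first bin on transitions out of the gain states, and
#' late-phase meal-replacement only on transitions out of loss states.
#'
#' @param demographics demographic design columns to include on every
#'   transition (subset of `c("male","age10","nonwhite","hispanic","bmi5",
#'   "pcvisits")`).
#' @return a [transition_structure()].
#' @export
default_wmt_structure <- function(demographics = DEMOG_COLS) {
  wmt <- c("nutrition_90d", "mr_early", "mr_late", "aom_any",
           "surg_0_90", "surg_91_180", "surg_181_364", "surg_ge365",
           "surg_gt90")
  covs <- c(demographics, wmt)
  st <- transition_structure(covs)
  M <- st$masks
  from_loss <- st$from %in% c(1L, 2L)
  from_base <- st$from == 3L
  from_gain <- st$from %in% c(4L, 5L)
  M[, wmt] <- FALSE
  M[, c("nutrition_90d", "mr_early", "aom_any", "surg_0_90")] <- TRUE
  M[from_loss, c("mr_late", "surg_91_180", "surg_181_364", "surg_ge365")] <- TRUE
  M[from_base, "surg_gt90"] <- TRUE
  st$masks <- M
  st
}

#' Model parameters: log baseline intensities and covariate coefficients
#'
#' @param log_q0 numeric vector of length 8: log baseline intensity (per day)
#'   for each allowed transition, in the order of `structure$labels`.
#' @param beta 8 x P matrix of log hazard-ratio coefficients; entries at
#'   masked-out cells must be `NA` (they carry no parameter).  May be omitted
#'   when the structure has no covariates.
#' @param structure a [transition_structure()].
#' @return an object of class `msm_params`.
#' @export
msm_params <- function(log_q0, beta = NULL, structure = transition_structure()) {
  if (length(log_q0) != 8L || any(!is.finite(log_q0)))
    wt_stop("wtmsm_params_error", "log_q0 must be 8 finite values")
  P <- length(structure$covariates)
  if (is.null(beta)) beta <- matrix(NA_real_, 8L, P)
  beta <- as.matrix(beta)
  if (!identical(dim(beta), c(8L, P)))
    wt_stop("wtmsm_params_error", "beta must be 8 x %d", P)
  beta[!structure$masks] <- NA_real_
  if (any(is.na(beta[structure$masks])))
    beta[structure$masks][is.na(beta[structure$masks])] <- 0
  dimnames(beta) <- dimnames(structure$masks)
  names(log_q0) <- structure$labels
  structure(list(log_q0 = log_q0, beta = beta, structure = structure),
            class = "msm_params")
}

#' @export
print.msm_params <- function(x, ...) {
  cat("Multistate model parameters\n")
  cat("Baseline intensities (per day):\n")
  print(round(exp(x$log_q0), 6))
  if (length(x$structure$covariates)) {
    cat("Hazard ratios exp(beta):\n")
    print(round(exp(x$beta), 3))
  }
  invisible(x)
}

# theta packing: log_q0 first, then unmasked betas in row-major
# (transition-by-transition) order -- must match beta_index() and the C++ code
beta_index <- function(structure) {
  M <- structure$masks
  idx <- matrix(0L, nrow(M), ncol(M), dimnames = dimnames(M))
  n <- 0L
  for (k in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[k, j]) { n <- n + 1L; idx[k, j] <- n }
  }
  idx
}

pack_theta <- function(params) {
  st <- params$structure
  M <- st$masks
  bv <- numeric(0)
  labs <- character(0)
  for (k in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    if (M[k, j]) {
      bv <- c(bv, params$beta[k, j])
      labs <- c(labs, paste0("b.", st$labels[k], ".", st$covariates[j]))
    }
  }
  setNames(c(unname(params$log_q0), bv), c(paste0("logq.", st$labels), labs))
}

unpack_theta <- function(theta, structure) {
  idx <- beta_index(structure)
  log_q0 <- theta[1:8]
  beta <- matrix(NA_real_, 8L, length(structure$covariates))
  if (max(idx) > 0L) beta[idx > 0L] <- theta[8L + idx[idx > 0L]]
  msm_params(log_q0, beta, structure)
}

#' Build the 5x5 transition intensity matrix for a covariate vector
#'
#' Off-diagonal allowed entries are \eqn{q^0_{rs} \exp(\beta_{rs}' z)} with
#' masked covariates excluded; disallowed entries are zero; each diagonal
#' entry is minus its row sum, so rows sum to zero exactly.
#'
#' @param params an [msm_params()] object.
#' @param z named numeric vector of covariate values (must cover the
#'   structure's covariates; extra names are ignored).
#' @return a 5x5 numeric matrix.
#' @export
build_intensity_matrix <- function(params, z = NULL) {
  st <- params$structure
  P <- length(st$covariates)
  lp <- params$log_q0
  if (P > 0L) {
    if (is.null(z) || !all(st$covariates %in% names(z)))
      wt_stop("wtmsm_params_error", "z must supply covariates: %s",
              paste(st$covariates, collapse = ", "))
    zz <- as.numeric(z[st$covariates])
    B <- params$beta
    B[is.na(B)] <- 0
    lp <- lp + as.numeric(B %*% zz)
  }
  if (any(!is.finite(lp)))
    wt_stop("wtmsm_numeric_error", "non-finite linear predictor on transition(s): %s",
            paste(st$labels[!is.finite(lp)], collapse = ", "))
  if (any(lp > 6)) {
    # same saturation as the compiled likelihood: exp(6)/day is beyond any
    # plausible weight-transition rate and signals a degenerate coefficient
    warning("transition intensity saturated at exp(6)/day on: ",
            paste(st$labels[lp > 6], collapse = ", "))
    lp <- pmin(lp, 6)
  }
  q <- exp(lp)
  Q <- matrix(0, 5L, 5L)
  for (k in seq_along(st$from)) {
    Q[st$from[k], st$to[k]] <- Q[st$from[k], st$to[k]] + q[k]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Interval transition probabilities over piecewise-constant exposure segments
#'
#' Multiplies matrix exponentials `expm(Q(z_j) * dt_j)` in time order.
#' Splitting an interval at exposure changepoints is exact under
#' piecewise-constant intensities.
#'
#' @param params an [msm_params()] object.
#' @param segments a data.frame with a `duration` column (days, >= 0) and one
#'   column per structure covariate, one row per exposure-constant segment in
#'   time order.
#' @return a 5x5 row-stochastic probability matrix.
#' @export
interval_probability <- function(params, segments) {
  if (!is.data.frame(segments) || is.null(segments$duration))
    wt_stop("wtmsm_input_error", "segments must be a data.frame with a duration column")
  if (any(segments$duration < 0))
    wt_stop("wtmsm_input_error", "segment durations must be >= 0")
  P <- diag(5)
  for (i in seq_len(nrow(segments))) {
    dt <- segments$duration[i]
    if (dt == 0) next
    Q <- build_intensity_matrix(params, unlist(segments[i, , drop = FALSE]))
    P <- P %*% as.matrix(Matrix::expm(Q * dt))
  }
  unname(P)
}
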