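# Exponential-survival milestone treatment-effect calculator.
#
# A constant-hazard (exponential) model links a milestone survival probability
# S at time t to the hazard h = -ln(S)/t. A hazard ratio HR scales the hazard,
# so the treated milestone probability is S^HR, and the absolute risk
# reduction (ARR) at the milestone is 100 * (S^HR - S) percentage points.
# All arithmetic is done at full precision; rounding happens only at display.

check_fraction <- function(x, what) {
  if (!is_prob_fraction(x))
    abort2(paste0(what, " must be a single probability strictly between 0 and 1"),
           "oncocausal_domain_error")
  x
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort2(paste0(what, " must be a single positive number"),
           "oncocausal_domain_error")
  x
}

#' Constant-hazard (exponential) survival model
#'
#' @param hazard event rate per month, > 0. Survival beyond time t is
#'   `exp(-hazard * t)`; mean survival is `1/hazard`, median `log(2)/hazard`.
#' @return Object of class `exp_model`.
#' @examples
#' m <- exp_model(0.04)
#' mean(m)    # 25 months
#' median(m)  # 17.3 months
#' @export
exp_model <- function(hazard) {
  check_positive(hazard, "hazard")
  structure(list(hazard = hazard), class = "exp_model")
}

#' Recover the constant hazard implied by a milestone survival probability
#'
#' Under the exponential model, `S(t) = exp(-h t)`, so
#' `h = -ln(S)/t`.
#'
#' @param prob milestone survival probability, a fraction strictly in (0, 1).
#' @param months milestone time in months, > 0.
#' @return An [exp_model()].
#' @examples
#' hazard_from_milestone(0.414, 24)  # hazard 0.03675 per month
#' @export
hazard_from_milestone <- function(prob, months) {
  check_fraction(prob, "milestone probability")
  check_positive(months, "milestone time")
  exp_model(-log(prob) / months)
}

#' Milestone survival probability of an exponential model
#'
#' @param model an [exp_model()].
#' @param months milestone time(s) in months, >= 0.
#' @return `exp(-h * months)`; 1 at `months = 0`.
#' @export
milestone_probability <- function(model, months) {
  stopifnot(inherits(model, "exp_model"))
  if (!is.numeric(months) || any(!is.finite(months)) || any(months < 0))
    abort2("months must be non-negative", "oncocausal_domain_error")
  exp(-model$hazard * months)
}

#' @export
predict.exp_model <- function(object, months, ...) {
  milestone_probability(object, months)
}

#' @export
mean.exp_model <- function(x, ...) 1 / x$hazard

#' @importFrom stats median
#' @export
median.exp_model <- function(x, na.rm = FALSE, ...) log(2) / x$hazard

#' @export
simulate.exp_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(nsim, rate = object$hazard)
}

#' @export
print.exp_model <- function(x, ...) {
  cat(sprintf("Exponential survival model: hazard %.5g per month\n", x$hazard))
  cat(sprintf("  mean %.1f months, median %.1f months\n", mean(x), median(x)))
  invisible(x)
}

#' Milestone treatment effect under a hazard ratio
#'
#' Converts a control-arm milestone survival probability to the treated-arm
#' probability implied by a hazard ratio under the exponential model
#' (`S1 = S0^HR`, algebraically identical to rescaling the hazard and
#' re-exponentiating) and reports the absolute risk reduction in percentage
#' points. An optional hazard-ratio confidence interval is propagated naively
#' by plugging in its endpoints; the resulting range is a plug-in range, not a
#' delta-method confidence interval.
#'
#' @param baseline control milestone survival probability, fraction in (0, 1).
#' @param months milestone time in months, > 0.
#' @param hr hazard ratio (treated vs control), > 0.
#' @param hr_ci optional length-2 vector `c(low, high)` of hazard-ratio
#'   interval endpoints.
#' @return Object of class `milestone_estimate` with components `months`,
#'   `baseline`, `hr`, `treated` (fraction) and `arr` (percentage points),
#'   plus `treated_range`/`arr_range` when `hr_ci` is supplied.
#' @examples
#' treated_milestone(0.414, 24, 0.68)  # treated 54.9%, ARR 13.5 points
#' @export
treated_milestone <- function(baseline, months, hr, hr_ci = NULL) {
  check_fraction(baseline, "baseline probability")
  check_positive(months, "milestone time")
  check_positive(hr, "hazard ratio")
  treated <- baseline^hr
  out <- list(months = months, baseline = baseline, hr = hr,
              treated = treated, arr = 100 * (treated - baseline))
  if (!is.null(hr_ci)) {
    if (length(hr_ci) != 2L || any(hr_ci <= 0) || hr_ci[1L] > hr_ci[2L])
      abort2("hr_ci must be c(low, high) with 0 < low <= high",
             "oncocausal_domain_error")
    tr <- baseline^hr_ci           # lower HR -> higher treated probability
    out$hr_ci <- hr_ci
    out$treated_range <- sort(tr)
    out$arr_range <- sort(100 * (tr - baseline))
  }
  structure(out, class = "milestone_estimate")
}

#' @export
print.milestone_estimate <- function(x, ...) {
  cat(sprintf("%g-month milestone: control %.1f%%, treated %.1f%% (HR %g)\n",
              x$months, 100 * x$baseline, 100 * x$treated, x$hr))
  cat(sprintf("  absolute risk reduction: %.1f percentage points\n", x$arr))
  if (!is.null(x$arr_range))
    cat(sprintf("  HR %g-%g plug-in range (naive, not a CI): treated %.1f%%-%.1f%%, ARR %.1f to %.1f points\n",
                x$hr_ci[1L], x$hr_ci[2L],
                100 * x$treated_range[1L], 100 * x$treated_range[2L],
                x$arr_range[1L], x$arr_range[2L]))
  invisible(x)
}

#' Hazard-ratio sensitivity grid for a milestone effect
#'
#' Evaluates [treated_milestone()] over a grid of hypothetical hazard ratios,
#' the sensitivity-analysis device used when no trial estimate exists for a
#' patient's subgroup.
#'
#' @inheritParams treated_milestone
#' @param hr_grid non-empty vector of positive hazard ratios.
#' @return Data frame with one row per grid value (order preserved):
#'   `hr`, `treated` (fraction), `arr` (percentage points).
#' @examples
#' hr_sensitivity(0.414, 24, c(0.68, 0.72, 0.76, 0.80, 0.84))
#' @export
hr_sensitivity <- function(baseline, months, hr_grid) {
  if (length(hr_grid) == 0L)
    abort2("hr_grid must be non-empty", "oncocausal_argument_error")
  rows <- lapply(hr_grid, function(hr) {
    est <- treated_milestone(baseline, months, hr)
    data.frame(hr = hr, treated = est$treated, arr = est$arr)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  attr(out, "months") <- months
  out
}

# ---- linear predictors ------------------------------------------------------

#' Linear predictor of a (log-)hazard regression
#'
#' Represents the linear term of an exponential (or Cox) regression:
#' additive ("risk modeling") form `b0 + b1 X + a'Z`, or interactive
#' ("effect modeling") form `b0 + b1 X + a'Z + (c'Z) X`. Only coefficients
#' multiplying the treatment indicator contribute to the hazard ratio.
#'
#' @param treatment treatment main-effect coefficient (b1).
#' @param intercept intercept (b0).
#' @param covariate named numeric vector of covariate main effects (a).
#' @param interaction named numeric vector of treatment-covariate interaction
#'   coefficients (c); empty for the additive form.
#' @return Object of class `linear_predictor`.
#' @examples
#' lp <- linear_predictor(treatment = -0.3857)
#' hr_from_linear(lp)  # additive model: exp(b1) = 0.68 for every patient
#' @export
linear_predictor <- function(treatment, intercept = 0,
                             covariate = numeric(0),
                             interaction = numeric(0)) {
  stopifnot(is.numeric(treatment), length(treatment) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (length(covariate) && is.null(names(covariate)))
    abort2("covariate coefficients must be named", "oncocausal_argument_error")
  if (length(interaction) && is.null(names(interaction)))
    abort2("interaction coefficients must be named", "oncocausal_argument_error")
  structure(list(intercept = intercept, treatment = treatment,
                 covariate = covariate, interaction = interaction),
            class = "linear_predictor")
}

#' @export
print.linear_predictor <- function(x, ...) {
  form <- "b0 + b1*X"
  if (length(x$covariate)) form <- paste0(form, " + a'Z")
  if (length(x$interaction)) form <- paste0(form, " + (c'Z)*X")
  cat("Linear predictor:", form, "\n")
  cat(sprintf("  b0 = %g, b1 = %g\n", x$intercept, x$treatment))
  if (length(x$covariate))
    cat("  a:", paste(names(x$covariate), "=", x$covariate, collapse = ", "), "\n")
  if (length(x$interaction))
    cat("  c:", paste(names(x$interaction), "=", x$interaction, collapse = ", "), "\n")
  invisible(x)
}

#' Hazard ratio implied by a linear predictor
#'
#' The hazard ratio for a patient is the exponential of the sum of all
#' coefficients multiplying the treatment indicator:
#' `exp(b1)` under the additive form (identical for every patient), or
#' `exp(b1 + c'z)` under the interactive form evaluated at the patient's
#' covariates z.
#'
#' @param lp a [linear_predictor()].
#' @param covariates named numeric vector of patient covariate values; must
#'   supply a value for every named interaction coefficient.
#' @return The hazard ratio, a positive number.
#' @examples
#' lp <- linear_predictor(treatment = -0.3857, interaction = c(B = -0.2))
#' hr_from_linear(lp, covariates = c(B = 1))
#' @export
hr_from_linear <- function(lp, covariates = numeric(0)) {
  stopifnot(inherits(lp, "linear_predictor"))
  if (length(lp$interaction) == 0L) return(exp(lp$treatment))
  need <- names(lp$interaction)
  missing <- setdiff(need, names(covariates))
  if (length(missing))
    abort2(paste0("missing covariate value(s) for interaction term(s): ",
                  paste(missing, collapse = ", ")),
           "oncocausal_argument_error")
  exp(lp$treatment + sum(lp$interaction * covariates[need]))
}

# ---- calibration ------------------------------------------------------------

#' Calibrate the calculator against reported trial milestones
#'
#' For each row (an adjuvant-trial arm summary), computes the treated-arm
#' milestone probability implied by the control probability and the hazard
#' ratio, and the signed difference from the trial's reported treated-arm
#' probability. Estimates are displayed at one decimal, and the difference is
#' taken between the one-decimal displays to match how such tables are read.
#'
#' @param rows data frame with columns `label`, `milestone_months`,
#'   `control_prob` (fraction), `hr`, `reported_treated_prob` (fraction).
#' @return Data frame with added columns `estimated_pct`, `reported_pct`
#'   (one-decimal percentages) and `difference_pct` (estimated minus reported,
#'   percentage points, signed).
#' @examples
#' calibration_table(data.frame(label = "ICI vs placebo", milestone_months = 12,
#'   control_prob = 0.762, hr = 0.68, reported_treated_prob = 0.857))
#' @export
calibration_table <- function(rows) {
  need <- c("label", "milestone_months", "control_prob", "hr",
            "reported_treated_prob")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    abort2(paste0("calibration rows lack column(s): ",
                  paste(missing, collapse = ", ")),
           "oncocausal_argument_error")
  est <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    est[i] <- tryCatch(
      treated_milestone(rows$control_prob[i], rows$milestone_months[i],
                        rows$hr[i])$treated,
      oncocausal_error = function(e)
        abort2(paste0("row '", rows$label[i], "': ", conditionMessage(e)),
               "oncocausal_domain_error"))
  }
  out <- rows
  out$estimated_pct <- round(100 * est, 1)
  out$reported_pct <- round(100 * rows$reported_treated_prob, 1)
  out$difference_pct <- round(out$estimated_pct - out$reported_pct, 1)
  out
}

#' Bundled adjuvant-trial calibration rows
#'
#' Reads the packaged CSV of published adjuvant-trial milestone summaries
#' (control milestone probability, hazard ratio, reported treated-arm
#' probability) and runs [calibration_table()] on it.
#'
#' @return The calibration data frame.
#' @export
adjuvant_calibration <- function() {
  path <- system.file("extdata", "calibration_trials.csv",
                      package = "oncocausal", mustWork = TRUE)
  calibration_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
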