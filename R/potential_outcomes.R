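# Potential-outcomes cohort simulator and causal estimators.
#
# Cohorts carry, per subject, the covariates Z, the true propensity
# e(Z) = Pr(X = 1 | Z), both potential outcomes Y^1 and Y^0, the assigned
# treatment X and the observed outcome Y. Consistency (Y equals the potential
# outcome of the received treatment) holds by construction, positivity is
# enforced (0 < e < 1 for every subject), and SUTVA is encoded as independent
# draws across subjects.

# ---- scenarios --------------------------------------------------------------

shipped_scenarios <- function() {
  list(
    # fair RCT: coin-flip assignment, prognostic covariate, HR-0.68-sized
    # shift in log DFS time
    rct = list(
      covariates = list(Z = list(dist = "normal", mean = 0, sd = 1)),
      propensity = list(type = "constant", p = 0.5),
      outcome = list(type = "gaussian", mu0 = 3.3, slopes = c(Z = 0.5),
                     tau = 0.3857, sd = 0.8)),
    # unbalanced randomization 2:1 experimental:control
    rct_unbalanced = list(
      covariates = list(Z = list(dist = "normal", mean = 0, sd = 1)),
      propensity = list(type = "constant", p = 2 / 3),
      outcome = list(type = "gaussian", mu0 = 3.3, slopes = c(Z = 0.5),
                     tau = 0.3857, sd = 0.8)),
    # observational: good-prognosis patients (Z = 1) more often treated, and
    # prognosis strongly drives outcome -> confounded naive comparison
    confounded = list(
      covariates = list(Z = list(dist = "bernoulli", p = 0.5)),
      propensity = list(type = "logistic",
                        intercept = stats::qlogis(0.3),
                        slopes = c(Z = stats::qlogis(0.7) - stats::qlogis(0.3))),
      outcome = list(type = "gaussian", mu0 = 3.0, slopes = c(Z = 0.9),
                     tau = 0.3857, sd = 0.8)),
    # inert agent given preferentially to good-prognosis patients: the naive
    # difference in means is biased upward while the true effect is zero
    innocent_bystander = list(
      covariates = list(Z = list(dist = "bernoulli", p = 0.5)),
      propensity = list(type = "logistic",
                        intercept = stats::qlogis(0.25),
                        slopes = c(Z = stats::qlogis(0.75) - stats::qlogis(0.25))),
      outcome = list(type = "gaussian", mu0 = 3.0, slopes = c(Z = 1.0),
                     tau = 0, sd = 0.8)),
    # binary 24-month DFS indicator tied to the exponential calculator:
    # per-stratum baseline hazards, hazard ratio 0.68
    milestone = list(
      covariates = list(Z = list(dist = "bernoulli", p = 0.5)),
      propensity = list(type = "constant", p = 0.5),
      outcome = list(type = "milestone", t = 24,
                     log_hazard = c(intercept = log(0.03675),
                                    Z = log(0.0167 / 0.03675)),
                     hr = 0.68))
  )
}

#' Define a potential-outcomes simulation scenario
#'
#' A scenario specifies covariate distributions, a propensity function
#' (constant for randomized designs, logistic-form for observational ones)
#' and an outcome mechanism. The true causal effect (the difference in
#' expected potential outcomes) is computed in closed form from the
#' configuration, so estimators can be validated against it.
#'
#' Shipped scenarios: `"rct"` (fair coin-flip randomization),
#' `"rct_unbalanced"` (2:1 randomization), `"confounded"` (good prognosis
#' favours treatment and drives the outcome), `"innocent_bystander"`
#' (treatment inert, assignment prognosis-driven) and `"milestone"` (binary
#' 24-month disease-free-survival indicator with hazard ratio 0.68).
#'
#' @param name one of the shipped scenario names, or `NULL` to build a custom
#'   scenario from the remaining arguments.
#' @param covariates named list; each element `list(dist = "normal", mean, sd)`
#'   or `list(dist = "bernoulli", p)`.
#' @param propensity `list(type = "constant", p)` or
#'   `list(type = "logistic", intercept, slopes)` (named slopes on covariates).
#' @param outcome `list(type = "gaussian", mu0, slopes, tau, sd)` for a
#'   continuous outcome (e.g. log survival time) with constant additive
#'   treatment effect `tau`, or `list(type = "milestone", t, log_hazard, hr)`
#'   for a binary event-free-at-t indicator under per-stratum exponential
#'   hazards (`log_hazard` has an `intercept` entry plus named covariate
#'   slopes; requires Bernoulli covariates).
#' @return Object of class `po_scenario` with the configuration plus `psi`
#'   (the true causal effect) and, for Bernoulli-covariate gaussian scenarios,
#'   `naive_bias` (the closed-form confounding bias of the unadjusted
#'   difference in means).
#' @examples
#' sc <- po_scenario("confounded")
#' sc$psi         # true effect
#' sc$naive_bias  # bias of the naive comparison
#' @export
po_scenario <- function(name = NULL, covariates = NULL, propensity = NULL,
                        outcome = NULL) {
  if (!is.null(name)) {
    shipped <- shipped_scenarios()
    if (!is_string(name) || !name %in% names(shipped))
      abort2(paste0("unknown scenario '", name, "'; shipped scenarios: ",
                    paste(names(shipped), collapse = ", ")),
             "oncocausal_argument_error")
    cfg <- shipped[[name]]
    covariates <- cfg$covariates; propensity <- cfg$propensity
    outcome <- cfg$outcome
  } else {
    name <- "custom"
    if (is.null(covariates) || is.null(propensity) || is.null(outcome))
      abort2("custom scenarios need covariates, propensity and outcome",
             "oncocausal_argument_error")
  }
  sc <- structure(list(name = name, covariates = covariates,
                       propensity = propensity, outcome = outcome),
                  class = "po_scenario")
  sc$psi <- true_psi(sc)
  if (outcome$type == "gaussian" && all_bernoulli(covariates))
    sc$naive_bias <- naive_bias(sc)
  sc
}

all_bernoulli <- function(covariates)
  all(vapply(covariates, function(cv) cv$dist == "bernoulli", TRUE))

# enumerate the joint support of Bernoulli covariates with probabilities
bernoulli_support <- function(covariates) {
  grids <- lapply(covariates, function(cv) c(0, 1))
  support <- expand.grid(grids)
  probs <- rep(1, nrow(support))
  for (nm in names(covariates)) {
    p <- covariates[[nm]]$p
    probs <- probs * ifelse(support[[nm]] == 1, p, 1 - p)
  }
  list(support = support, probs = probs)
}

propensity_at <- function(propensity, z_row) {
  if (propensity$type == "constant") return(propensity$p)
  eta <- propensity$intercept
  for (nm in names(propensity$slopes))
    eta <- eta + propensity$slopes[[nm]] * z_row[[nm]]
  stats::plogis(eta)
}

true_psi <- function(sc) {
  out <- sc$outcome
  if (out$type == "gaussian") return(out$tau)
  if (out$type == "milestone") {
    if (!all_bernoulli(sc$covariates))
      abort2("milestone outcomes require Bernoulli covariates (closed-form effect)",
             "oncocausal_argument_error")
    bs <- bernoulli_support(sc$covariates)
    psi <- 0
    for (i in seq_len(nrow(bs$support))) {
      lh <- out$log_hazard[["intercept"]]
      for (nm in names(sc$covariates))
        lh <- lh + (out$log_hazard[[nm]] %||% 0) * bs$support[[nm]][i]
      h0 <- exp(lh)
      psi <- psi + bs$probs[i] *
        (exp(-out$t * h0 * out$hr) - exp(-out$t * h0))
    }
    return(psi)
  }
  abort2(paste0("unknown outcome type: ", out$type),
         "oncocausal_argument_error")
}

# closed-form bias of the naive difference in arm means:
# sum_j beta_j * (E[Z_j | X = 1] - E[Z_j | X = 0]) for discrete covariates
naive_bias <- function(sc) {
  bs <- bernoulli_support(sc$covariates)
  e <- vapply(seq_len(nrow(bs$support)), function(i)
    propensity_at(sc$propensity, bs$support[i, , drop = FALSE]), 0)
  p1 <- sum(bs$probs * e)
  bias <- 0
  for (nm in names(sc$outcome$slopes)) {
    z <- bs$support[[nm]]
    ez1 <- sum(bs$probs * e * z) / p1
    ez0 <- sum(bs$probs * (1 - e) * z) / (1 - p1)
    bias <- bias + sc$outcome$slopes[[nm]] * (ez1 - ez0)
  }
  bias
}

#' @export
print.po_scenario <- function(x, ...) {
  cat(sprintf("Potential-outcomes scenario '%s'\n", x$name))
  cat(sprintf("  propensity: %s; outcome: %s; true effect psi = %.4g\n",
              x$propensity$type, x$outcome$type, x$psi))
  if (!is.null(x$naive_bias))
    cat(sprintf("  closed-form naive difference-in-means bias: %.4g\n",
                x$naive_bias))
  invisible(x)
}

# ---- simulation -------------------------------------------------------------

#' Simulate a potential-outcomes cohort
#'
#' Draws `n` exchangeable subjects from a scenario: covariates, true
#' propensities, both potential outcomes, the assigned treatment and the
#' observed outcome. The observed outcome always equals the potential outcome
#' of the assigned treatment (consistency by construction); any propensity of
#' exactly 0 or 1 raises a positivity error. A single integer seed drives
#' three fixed substreams (covariates, assignment, outcome noise) so cohorts
#' replay exactly.
#'
#' @param scenario a [po_scenario()] or a shipped scenario name.
#' @param n number of subjects, >= 1.
#' @param seed integer seed (kept below 2^31 - 10 to leave room for the
#'   substream offsets).
#' @return Object of class `po_cohort`: a data frame with the covariate
#'   columns plus `e`, `y1`, `y0`, `x`, `y`, and attributes `scenario` and
#'   `psi` (the scenario's true effect).
#' @examples
#' co <- simulate_cohort("rct", n = 100, seed = 1)
#' mean(co$x)  # close to 1/2
#' @export
simulate_cohort <- function(scenario, n, seed) {
  if (is.character(scenario)) scenario <- po_scenario(scenario)
  stopifnot(inherits(scenario, "po_scenario"))
  if (!is_count(n))
    abort2("n must be a positive integer", "oncocausal_argument_error")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      abs(seed) > 2^31 - 10)
    abort2("seed must be a single integer below 2^31 - 10",
           "oncocausal_argument_error")
  seed <- as.integer(seed)

  set.seed(seed)                       # substream 1: covariates
  z <- as.data.frame(lapply(scenario$covariates, function(cv) {
    switch(cv$dist,
           normal = stats::rnorm(n, cv$mean, cv$sd),
           bernoulli = stats::rbinom(n, 1L, cv$p),
           abort2(paste0("unknown covariate distribution: ", cv$dist),
                  "oncocausal_argument_error"))
  }))
  names(z) <- names(scenario$covariates)

  pr <- scenario$propensity
  e <- if (pr$type == "constant") {
    rep(pr$p, n)
  } else if (pr$type == "logistic") {
    eta <- rep(pr$intercept, n)
    for (nm in names(pr$slopes)) eta <- eta + pr$slopes[[nm]] * z[[nm]]
    stats::plogis(eta)
  } else {
    abort2(paste0("unknown propensity type: ", pr$type),
           "oncocausal_argument_error")
  }
  if (any(e <= 0 | e >= 1))
    abort2("propensity function produced 0 or 1: positivity violated",
           "oncocausal_positivity_error")

  set.seed(seed + 1L)                  # substream 2: treatment assignment
  x <- stats::rbinom(n, 1L, e)

  set.seed(seed + 2L)                  # substream 3: outcomes
  out <- scenario$outcome
  if (out$type == "gaussian") {
    y0 <- rep(out$mu0, n)
    for (nm in names(out$slopes)) y0 <- y0 + out$slopes[[nm]] * z[[nm]]
    y0 <- y0 + stats::rnorm(n, 0, out$sd)
    y1 <- y0 + out$tau
  } else {                             # milestone indicator
    lh <- rep(out$log_hazard[["intercept"]], n)
    for (nm in names(z)) lh <- lh + (out$log_hazard[[nm]] %||% 0) * z[[nm]]
    h0 <- exp(lh)
    y0 <- stats::rbinom(n, 1L, exp(-out$t * h0))
    y1 <- stats::rbinom(n, 1L, exp(-out$t * h0 * out$hr))
  }

  co <- cbind(z, data.frame(e = e, y1 = y1, y0 = y0, x = x))
  co$y <- ifelse(co$x == 1L, co$y1, co$y0)
  structure(co, class = c("po_cohort", "data.frame"),
            scenario = scenario, psi = scenario$psi)
}

#' @export
print.po_cohort <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Potential-outcomes cohort: %d subjects (scenario '%s', true psi %.4g)\n",
              nrow(x), sc$name, attr(x, "psi")))
  cat(sprintf("  treated fraction %.3f\n", mean(x$x)))
  NextMethod()
}

# ---- estimators -------------------------------------------------------------

new_causal_effect <- function(estimate, se, estimator, n) {
  structure(list(estimate = estimate, se = se, estimator = estimator, n = n),
            class = "causal_effect")
}

#' @export
print.causal_effect <- function(x, ...) {
  cat(sprintf("Causal effect estimate (%s): %.4f (SE %.4f, n = %d)\n",
              x$estimator, x$estimate, x$se, x$n))
  invisible(x)
}

#' @export
coef.causal_effect <- function(object, ...) {
  stats::setNames(object$estimate, object$estimator)
}

#' Inverse-probability-of-treatment-weighted effect estimate
#'
#' Estimates the average causal effect by weighting each observed outcome by
#' the inverse probability of the treatment actually received:
#' `Y X / e(Z) - Y (1 - X) / (1 - e(Z))`, averaged over subjects
#' (Horvitz-Thompson variant `"ht"`), or with the weights normalized within
#' each arm (Hajek variant `"hajek"`, the default, which is exactly the
#' difference of arm means whenever the propensity is constant). Standard
#' errors come from the empirical variance of the per-subject contributions;
#' the Hajek variant also offers a seeded nonparametric bootstrap.
#'
#' @param cohort a [simulate_cohort()] result (or any data frame with columns
#'   `x`, `y`).
#' @param propensities per-subject treatment probabilities, strictly in
#'   (0, 1); defaults to the cohort's true propensities `cohort$e`.
#' @param variant `"hajek"` or `"ht"`.
#' @param bootstrap number of bootstrap replicates for the Hajek standard
#'   error (0 = use the analytic contribution variance).
#' @param seed seed for the bootstrap resampling.
#' @return A `causal_effect` object.
#' @examples
#' co <- simulate_cohort("confounded", n = 500, seed = 7)
#' ipw_estimate(co)             # weighted by the true propensities
#' diff_means(co)               # naive, confounded comparison
#' @export
ipw_estimate <- function(cohort, propensities = NULL,
                         variant = c("hajek", "ht"),
                         bootstrap = 0, seed = NULL) {
  variant <- match.arg(variant)
  e <- propensities %||% cohort$e
  if (is.null(e))
    abort2("no propensities supplied and cohort carries none",
           "oncocausal_argument_error")
  if (length(e) != nrow(cohort))
    abort2("propensities must have one value per subject",
           "oncocausal_argument_error")
  if (any(e <= 0 | e >= 1))
    abort2("propensities must lie strictly in (0, 1)",
           "oncocausal_positivity_error")
  x <- cohort$x; y <- cohort$y; n <- nrow(cohort)
  if (variant == "ht") {
    contrib <- y * x / e - y * (1 - x) / (1 - e)
    return(new_causal_effect(mean(contrib),
                             stats::sd(contrib) / sqrt(n), "ipw_ht", n))
  }
  if (!any(x == 1L) || !any(x == 0L))
    abort2("Hajek weighting needs at least one subject in each arm",
           "oncocausal_degenerate_error")
  w1 <- x / e
  w0 <- (1 - x) / (1 - e)
  mu1 <- sum(w1 * y) / sum(w1)
  mu0 <- sum(w0 * y) / sum(w0)
  est <- mu1 - mu0
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]; eb <- e[idx]
      if (!any(xb == 1L) || !any(xb == 0L)) return(NA_real_)
      sum(xb * yb / eb) / sum(xb / eb) -
        sum((1 - xb) * yb / (1 - eb)) / sum((1 - xb) / (1 - eb))
    }, 0)
    se <- stats::sd(boots, na.rm = TRUE)
  } else {
    phi <- w1 * (y - mu1) / mean(w1) - w0 * (y - mu0) / mean(w0)
    se <- stats::sd(phi) / sqrt(n)
  }
  new_causal_effect(est, se, "ipw_hajek", n)
}

#' Naive difference of arm means
#'
#' The unadjusted comparison `mean(Y | X = 1) - mean(Y | X = 0)` with a
#' pooled-variance standard error. Unbiased for the causal effect only when
#' assignment is unconfounded; serves as the comparator the weighting
#' estimators are judged against.
#'
#' @inheritParams ipw_estimate
#' @return A `causal_effect` object.
#' @export
diff_means <- function(cohort) {
  x <- cohort$x; y <- cohort$y
  n1 <- sum(x == 1L); n0 <- sum(x == 0L)
  if (n1 == 0L || n0 == 0L)
    abort2("both arms must be non-empty", "oncocausal_degenerate_error")
  m1 <- mean(y[x == 1L]); m0 <- mean(y[x == 0L])
  v1 <- if (n1 > 1L) stats::var(y[x == 1L]) else 0
  v0 <- if (n0 > 1L) stats::var(y[x == 0L]) else 0
  pooled <- ((n1 - 1) * v1 + (n0 - 1) * v0) / max(n1 + n0 - 2, 1)
  new_causal_effect(m1 - m0, sqrt(pooled * (1 / n1 + 1 / n0)),
                    "diff_means", n1 + n0)
}

#' Estimate propensity scores with a logistic regression
#'
#' Fits `Pr(X = 1 | Z)` by maximum-likelihood logistic regression on the
#' named covariates and returns per-subject fitted probabilities, clipped to
#' a configurable floor/ceiling as a pragmatic positivity guard. Perfect or
#' quasi-perfect separation (fitted probabilities collapsing to 0/1, or
#' non-convergence) raises a convergence error advising a tighter clip or a
#' penalized fit.
#'
#' @param cohort a [simulate_cohort()] result (needs columns `x` and the
#'   covariates).
#' @param covariates character vector of covariate column names; defaults to
#'   the scenario's covariates when the cohort carries them.
#' @param clip length-2 vector: floor and ceiling applied to the fitted
#'   probabilities (default `c(0.01, 0.99)`).
#' @return Numeric vector of fitted probabilities in (0, 1), with attributes
#'   `coefficients` and `se` (the logistic fit) and `clipped_fraction`.
#' @export
estimate_propensity <- function(cohort, covariates = NULL,
                                clip = c(0.01, 0.99)) {
  if (is.null(covariates)) {
    sc <- attr(cohort, "scenario")
    covariates <- if (!is.null(sc)) names(sc$covariates)
  }
  if (is.null(covariates) || !length(covariates))
    abort2("covariate names are required", "oncocausal_argument_error")
  missing <- setdiff(covariates, names(cohort))
  if (length(missing))
    abort2(paste0("covariate column(s) not in cohort: ",
                  paste(missing, collapse = ", ")),
           "oncocausal_argument_error")
  if (!any(cohort$x == 1L) || !any(cohort$x == 0L))
    abort2("both arms must be non-empty to fit a propensity model",
           "oncocausal_degenerate_error")
  if (length(clip) != 2L || clip[1L] <= 0 || clip[2L] >= 1 ||
      clip[1L] >= clip[2L])
    abort2("clip must be c(floor, ceiling) with 0 < floor < ceiling < 1",
           "oncocausal_argument_error")
  fml <- stats::as.formula(paste("x ~", paste(covariates, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = as.data.frame(cohort)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged)
    abort2(paste0("propensity model did not identify probabilities away from ",
                  "0/1 (perfect separation or non-convergence); tighten the ",
                  "'clip' bounds on an external estimate or use a penalized fit"),
           "oncocausal_convergence_error")
  p <- stats::fitted(fit)
  clipped <- p < clip[1L] | p > clip[2L]
  p <- pmin(pmax(p, clip[1L]), clip[2L])
  attr(p, "coefficients") <- stats::coef(fit)
  attr(p, "se") <- sqrt(diag(stats::vcov(fit)))
  attr(p, "clipped_fraction") <- mean(clipped)
  p
}
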