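# Potential-outcomes simulator and causal estimators: structural assumptions
# hold by construction, weighting estimators recover the closed-form truth,
# and the naive comparison exhibits the designed confounding bias.

test_that("cohorts enforce consistency, positivity and exact replay", {
  for (nm in c("rct", "confounded", "milestone")) {
    co <- simulate_cohort(nm, n = 400, seed = 5)
    expect_true(all(co$y == ifelse(co$x == 1, co$y1, co$y0)),
                label = paste("consistency in", nm))
    expect_true(all(co$e > 0 & co$e < 1))
  }
  # same seed, same cohort; different seed, different cohort
  a <- simulate_cohort("rct", n = 200, seed = 9)
  b <- simulate_cohort("rct", n = 200, seed = 9)
  expect_identical(a$y, b$y)
  c <- simulate_cohort("rct", n = 200, seed = 10)
  expect_false(identical(a$y, c$y))
  # a degenerate propensity violates positivity
  bad <- po_scenario(covariates = list(Z = list(dist = "bernoulli", p = 0.5)),
                     propensity = list(type = "constant", p = 1),
                     outcome = list(type = "gaussian", mu0 = 0,
                                    slopes = c(Z = 1), tau = 0, sd = 1))
  expect_error(simulate_cohort(bad, n = 10, seed = 1),
               class = "oncocausal_positivity_error")
})

test_that("randomized assignment hits its target allocation", {
  co <- simulate_cohort("rct", n = 4000, seed = 21)
  expect_lt(abs(mean(co$x) - 0.5), 3 * sqrt(0.25 / 4000))
  co2 <- simulate_cohort("rct_unbalanced", n = 4000, seed = 21)
  expect_lt(abs(mean(co2$x) - 2 / 3), 3 * sqrt(2 / 9 / 4000))
})

test_that("a null scenario has zero true effect", {
  null_sc <- po_scenario(
    covariates = list(Z = list(dist = "normal", mean = 0, sd = 1)),
    propensity = list(type = "constant", p = 0.5),
    outcome = list(type = "gaussian", mu0 = 3, slopes = c(Z = 0.5),
                   tau = 0, sd = 1))
  expect_identical(null_sc$psi, 0)
  expect_identical(po_scenario("innocent_bystander")$psi, 0)
})

test_that("Hajek weighting equals the difference of arm means under constant propensity", {
  for (nm in c("rct", "rct_unbalanced")) {
    co <- simulate_cohort(nm, n = 501, seed = 3)   # odd n: arms unbalanced
    haj <- ipw_estimate(co, variant = "hajek")
    dm <- diff_means(co)
    expect_equal(haj$estimate, dm$estimate, tolerance = 1e-12)
  }
})

test_that("Horvitz-Thompson weighting equals the arm-mean difference when arms balance exactly", {
  co <- data.frame(x = rep(c(1L, 0L), each = 10),
                   y = c(rnorm(10, 5), rnorm(10, 3)))
  ht <- ipw_estimate(co, propensities = rep(0.5, 20), variant = "ht")
  dm <- diff_means(co)
  expect_equal(ht$estimate, dm$estimate, tolerance = 1e-12)
})

test_that("estimator guards: positivity, degenerate arms", {
  co <- simulate_cohort("rct", n = 50, seed = 2)
  expect_error(ipw_estimate(co, propensities = c(rep(0.5, 49), 1)),
               class = "oncocausal_positivity_error")
  allt <- data.frame(x = rep(1L, 10), y = rnorm(10))
  expect_error(ipw_estimate(allt, propensities = rep(0.5, 10),
                            variant = "hajek"),
               class = "oncocausal_degenerate_error")
  expect_error(diff_means(allt), class = "oncocausal_degenerate_error")
})

test_that("the confounded scenario biases the naive comparison as designed", {
  sc <- po_scenario("confounded")
  # closed-form naive bias: slope * (E[Z|X=1] - E[Z|X=0]) = 0.9 * 0.4
  expect_equal(sc$naive_bias, 0.9 * (0.7 - 0.3), tolerance = 1e-12)
  co <- simulate_cohort(sc, n = 20000, seed = 31)
  dm <- diff_means(co)
  expect_equal(dm$estimate, sc$psi + sc$naive_bias, tolerance = 0.05)
  # weighting by the true propensities removes the bias
  ipw <- ipw_estimate(co, variant = "hajek")
  expect_lt(abs(ipw$estimate - sc$psi), 3 * ipw$se)
})

test_that("the innocent-bystander scenario shows spurious benefit that weighting removes", {
  sc <- po_scenario("innocent_bystander")
  expect_equal(sc$naive_bias, 1.0 * (0.75 - 0.25), tolerance = 1e-12)
  co <- simulate_cohort(sc, n = 10000, seed = 41)
  expect_gt(diff_means(co)$estimate, 0.4)          # looks strongly beneficial
  ipw <- ipw_estimate(co, variant = "ht")
  expect_lt(abs(ipw$estimate), 3 * ipw$se)          # truth: no effect
  # within prognosis strata the arms are exchangeable: estimates centre at 0
  for (z in 0:1) {
    stratum <- co[co$Z == z, ]
    dmz <- diff_means(stratum)
    expect_lt(abs(dmz$estimate), 4 * dmz$se)
  }
})

test_that("weighting with known propensities is unbiased across replicates", {
  sc <- po_scenario("confounded")
  ests <- vapply(1:200, function(r)
    ipw_estimate(simulate_cohort(sc, n = 500, seed = 1000 + r),
                 variant = "ht")$estimate, 0)
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - sc$psi), 2 * mc_se)
})

test_that("propensity estimation recovers the generating model", {
  sc <- po_scenario("confounded")
  co <- simulate_cohort(sc, n = 5000, seed = 51)
  p <- estimate_propensity(co)
  cf <- attr(p, "coefficients")
  se <- attr(p, "se")
  truth <- c(stats::qlogis(0.3), stats::qlogis(0.7) - stats::qlogis(0.3))
  expect_lt(abs(cf[["(Intercept)"]] - truth[1]), 3 * se[["(Intercept)"]])
  expect_lt(abs(cf[["Z"]] - truth[2]), 3 * se[["Z"]])
  expect_true(all(p >= 0.01 & p <= 0.99))

  # no signal: near-zero coefficients under coin-flip assignment
  co2 <- simulate_cohort("rct", n = 5000, seed = 52)
  p2 <- estimate_propensity(co2)
  cf2 <- attr(p2, "coefficients")
  se2 <- attr(p2, "se")
  expect_lt(abs(cf2[["(Intercept)"]]), 3 * se2[["(Intercept)"]])
  expect_lt(abs(cf2[["Z"]]), 3 * se2[["Z"]])
})

test_that("perfect separation raises a convergence error with advice", {
  z <- c(rnorm(100, -2), rnorm(100, 2))
  sep <- data.frame(Z = z, x = as.integer(z > 0), y = rnorm(200))
  expect_error(estimate_propensity(sep, covariates = "Z"),
               class = "oncocausal_convergence_error")
  expect_error(estimate_propensity(sep, covariates = "Z"),
               regexp = "clip|penal")
})

test_that("weighting with estimated propensities beats the naive comparison", {
  sc <- po_scenario("confounded")
  reps <- 120
  est_ipw <- numeric(reps); est_dm <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(sc, n = 500, seed = 3000 + r)
    p <- estimate_propensity(co)
    est_ipw[r] <- ipw_estimate(co, propensities = as.numeric(p),
                               variant = "hajek")$estimate
    est_dm[r] <- diff_means(co)$estimate
  }
  expect_lt(abs(mean(est_ipw) - sc$psi), abs(mean(est_dm) - sc$psi))
})

test_that("the milestone scenario's closed-form effect matches simulation", {
  sc <- po_scenario("milestone")
  # truth by direct enumeration of the two prognosis strata
  s_lo <- exp(-24 * 0.03675); s_hi <- exp(-24 * 0.0167)
  psi <- 0.5 * (s_lo^0.68 - s_lo) + 0.5 * (s_hi^0.68 - s_hi)
  expect_equal(sc$psi, psi, tolerance = 1e-12)
  co <- simulate_cohort(sc, n = 20000, seed = 61)
  ipw <- ipw_estimate(co, variant = "hajek")
  expect_lt(abs(ipw$estimate - psi), 3 * ipw$se)
})

test_that("bootstrap standard errors are reproducible and sane", {
  co <- simulate_cohort("confounded", n = 400, seed = 71)
  e1 <- ipw_estimate(co, variant = "hajek", bootstrap = 100, seed = 8)
  e2 <- ipw_estimate(co, variant = "hajek", bootstrap = 100, seed = 8)
  expect_identical(e1$se, e2$se)
  analytic <- ipw_estimate(co, variant = "hajek")
  expect_lt(abs(e1$se - analytic$se) / analytic$se, 0.5)
})
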