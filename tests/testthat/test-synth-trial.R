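test_that("baseline generation honours point-mass and general probability tables", {
  L <- 3L
  p1 <- matrix(0, 5, L, dimnames = list(EQ5D_DIMENSIONS, NULL)); p1[, 1] <- 1
  probs <- new_baseline_probs("3L", p1)
  bl <- generate_baseline(probs, 20L, seed = 1L)
  expect_true(all(bl$control == "11111"))
  expect_true(all(bl$intervention == "11111"))

  # large-sample empirical frequencies match the table (goodness of fit)
  tbl <- baseline_probabilities("depression", "severe", "3L")
  bl2 <- generate_baseline(tbl, 50000L, seed = 2L)
  lv <- states_to_levels(bl2$control, "3L")
  for (d in EQ5D_DIMENSIONS) {
    obs <- tabulate(lv[, d], nbins = 3L)
    p <- stats::chisq.test(obs, p = tbl$control[d, ])$p.value
    expect_gt(p, 0.001)
  }

  expect_error(new_baseline_probs("3L", p1 * 0.98), "sum to 1")
})

test_that("follow-up transitions reproduce identity, absorption, and matrix rows", {
  ident <- stats::setNames(replicate(5, diag(3), simplify = FALSE),
                           EQ5D_DIMENSIONS)
  tm <- new_transition_model("3L", ident, ident)
  bl <- list(control = c("21232", "33311"), intervention = c("12321", "11111"))
  fu <- generate_followup(bl, tm, seed = 5L)
  expect_identical(fu$control, bl$control)
  expect_identical(fu$intervention, bl$intervention)

  cure <- matrix(0, 3, 3); cure[, 1] <- 1
  tm2 <- new_transition_model("3L",
                              stats::setNames(replicate(5, cure, simplify = FALSE),
                                              EQ5D_DIMENSIONS),
                              stats::setNames(replicate(5, cure, simplify = FALSE),
                                              EQ5D_DIMENSIONS))
  fu2 <- generate_followup(bl, tm2, seed = 5L)
  expect_true(all(unlist(fu2) == "11111"))

  # empirical transition frequencies from a fixed baseline level match the row
  tm3 <- control_transitions("3L")
  bl3 <- list(control = rep("22222", 50000L), intervention = character(0))
  fu3 <- generate_followup(bl3[1], tm3, seed = 9L)
  lv <- states_to_levels(fu3$control, "3L")
  for (d in c("MO", "AD")) {
    obs <- tabulate(lv[, d], nbins = 3L)
    p <- stats::chisq.test(obs, p = tm3$control[[d]][2, ])$p.value
    expect_gt(p, 0.001)
  }
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- quick_config(n = 30L, seed = 77L)
  d1 <- simulate_trial(cfg, "3L")
  d2 <- simulate_trial(cfg, "3L")
  expect_identical(d1, d2)
  d3 <- simulate_trial(scenario_config("low_back_pain", "moderate", "medium",
                                       n_per_arm = 30L, seed = 78L), "3L")
  expect_false(identical(d1$state_baseline, d3$state_baseline))
})

test_that("zero tilt leaves matrices unchanged and d = 0; tilt is monotone", {
  probs <- baseline_probabilities("osteoarthritis", "moderate", "3L")
  trans <- control_transitions("3L")
  tf <- builtin_tariff("NL", "3L")
  expect_equal(tilt_matrix(trans$control$MO, 0), trans$control$MO)
  expect_equal(cohens_d_population(trans, probs, tf)$d, 0, tolerance = 1e-12)

  shifts <- seq(0, 3, by = 0.25)
  ds <- vapply(shifts, function(s) {
    tm <- new_transition_model("3L", trans$control,
                               lapply(trans$control, tilt_matrix, shift = s))
    cohens_d_population(tm, probs, tf)$d
  }, numeric(1))
  expect_true(all(diff(ds) > -1e-9))
})

test_that("two-level single-dimension system matches the closed-form d", {
  # one informative dimension with two effective levels; the other four are
  # frozen at level 1. Follow-up utility is Bernoulli: u1 with prob p, u2
  # with prob 1-p, so d has a closed form in the tilted probability.
  L <- 3L
  p1 <- matrix(0, 5, L, dimnames = list(EQ5D_DIMENSIONS, NULL))
  p1[, 1] <- 1
  p1["PD", ] <- c(0, 1, 0) # everyone starts at PD level 2
  probs <- new_baseline_probs("3L", p1)

  frozen <- diag(3)
  m_pd <- matrix(c(1, 0, 0,
                   0.6, 0.4, 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  mats <- stats::setNames(replicate(5, frozen, simplify = FALSE),
                          EQ5D_DIMENSIONS)
  mats$PD <- m_pd
  trans <- new_transition_model("3L", mats, mats)
  tf <- new_tariff("PD2", "3L", data.frame(
    dimension = "PD", level = 2L, indicator = "level_dummy",
    coefficient = 0.3, offset = 0L))

  closed_form_d <- function(shift) {
    # tilted improvement probability from PD2: w1 = 0.6 e^shift, w2 = 0.4
    pI <- 0.6 * exp(shift) / (0.6 * exp(shift) + 0.4)
    pC <- 0.6
    mean_arm <- function(p) p * 1 + (1 - p) * 0.7
    var_arm <- function(p) p * (1 - p) * 0.3^2
    (mean_arm(pI) - mean_arm(pC)) / sqrt((var_arm(pI) + var_arm(pC)) / 2)
  }
  for (s in c(0, 0.4, 1.1)) {
    tm <- new_transition_model("3L", mats,
                               lapply(mats, tilt_matrix, shift = s))
    expect_equal(cohens_d_population(tm, probs, tf)$d, closed_form_d(s),
                 tolerance = 1e-10)
  }

  # bisection lands where the closed form says it should
  cal <- calibrate_effect_size(trans, probs, "small", tf)
  expect_equal(attr(cal, "d"), 0.2, tolerance = 0.005)
  expect_equal(closed_form_d(cal$shift), 0.2, tolerance = 0.005)
})

test_that("calibration reaches each band and reports unreachable targets", {
  probs <- baseline_probabilities("depression", "mild", "3L")
  trans <- control_transitions("3L")
  tf <- builtin_tariff("NL", "3L")
  for (band in c("small", "medium", "large")) {
    cal <- calibrate_effect_size(trans, probs, band, tf)
    b <- effect_band(band)
    expect_gte(attr(cal, "d"), b$lower)
    expect_lte(attr(cal, "d"), min(b$upper, b$target + 0.05))
    # control matrices untouched
    expect_identical(cal$control, trans$control)
  }

  # a system whose improvement mass is zero cannot move: unreachable band
  stuck <- stats::setNames(replicate(5, diag(3), simplify = FALSE),
                           EQ5D_DIMENSIONS)
  trans_stuck <- new_transition_model("3L", stuck, stuck)
  expect_error(
    calibrate_effect_size(trans_stuck, probs, "large", tf),
    "unreachable")
})

test_that("covariates have the designed marginals and are reproducible", {
  cov <- generate_covariates(100000L, seed = 4L)
  expect_true(all(cov$age >= 25L & cov$age <= 75L))
  expect_true(is.integer(cov$age) || all(cov$age == round(cov$age)))
  expect_equal(mean(cov$male), 0.19, tolerance = 0.01)
  expect_identical(cov, generate_covariates(100000L, seed = 4L))
})

test_that("costs are gamma with arm-specific means and QALY coupling", {
  set.seed(1)
  n <- 100000L
  qalys <- stats::rbeta(n, 8, 3)
  arm <- rep(c("control", "intervention"), each = n / 2)

  c0 <- generate_costs(qalys, arm, target_correlation = 0, seed = 21L)
  expect_true(all(c0 >= 0))
  expect_lt(abs(stats::cor(c0, qalys)), 0.02)
  expect_equal(mean(c0[arm == "control"]), 2000, tolerance = 0.02 * 2000)
  expect_equal(mean(c0[arm == "intervention"]), 2250, tolerance = 0.02 * 2250)

  c1 <- generate_costs(qalys, arm, target_correlation = -0.10, seed = 21L)
  expect_equal(stats::cor(c1, qalys), -0.10, tolerance = 0.02)

  # copula coupling conserves the gamma marginal (same substream draws)
  ks <- stats::ks.test(c1[arm == "control"], c0[arm == "control"])
  expect_gt(ks$p.value, 0.001)

  expect_error(generate_costs(qalys, arm, cost_mean = -5), "cost_mean > 0")
})

test_that("the factorial enumerates 36 scenarios", {
  sc <- enumerate_scenarios()
  expect_identical(nrow(sc), 36L)
  expect_identical(length(unique(sc$scenario)), 36L)
  expect_identical(
    nrow(unique(sc[, c("condition", "severity", "effect_size")])), 36L)
  expect_identical(nrow(unique(sc[, c("condition", "severity")])), 12L)
})

test_that("simulated trials have valid structure and share baselines across bands", {
  cfg_small <- scenario_config("cancer", "severe", "small", n_per_arm = 40L,
                               seed = 100L, population_seed = 55L)
  cfg_large <- scenario_config("cancer", "severe", "large", n_per_arm = 40L,
                               seed = 101L, population_seed = 55L)
  d1 <- simulate_trial(cfg_small, "5L")
  d2 <- simulate_trial(cfg_large, "5L")
  expect_identical(nrow(d1), 80L)
  expect_identical(as.vector(table(d1$arm)), c(40L, 40L))
  expect_true(all(d1$cost >= 0))
  expect_silent(states_to_levels(d1$state_baseline, "5L"))
  expect_silent(states_to_levels(d1$state_followup, "5L"))
  # same population seed -> same baseline states and covariates,
  # different effect band -> different follow-up
  expect_identical(d1$state_baseline, d2$state_baseline)
  expect_identical(d1$age, d2$age)
  expect_false(identical(d1$state_followup, d2$state_followup))
})
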