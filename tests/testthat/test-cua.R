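test_that("trapezoid QALYs follow the area-under-the-curve rule", {
  expect_identical(qaly_auc(1, 1), 1)
  expect_identical(qaly_auc(0.4, 0.6), 0.5)
  expect_identical(qaly_auc(0.8, 0.8, horizon = 0.5), 0.4)
  expect_equal(qaly_auc(c(0, 1), c(1, 0)), c(0.5, 0.5))
})

test_that("SUR with identical regressors collapses to per-equation OLS", {
  d <- hand_dataset()
  fit <- sur_fit(d, adjust_qaly_baseline = FALSE)
  ols_c <- stats::lm(cost ~ arm, data = d)
  ols_q <- stats::lm(qaly ~ arm, data = d)
  expect_equal(fit$delta_cost, unname(stats::coef(ols_c)[2]), tolerance = 1e-10)
  expect_equal(fit$delta_qaly, unname(stats::coef(ols_q)[2]), tolerance = 1e-10)
  # and with balanced arms the treatment coefficient is the mean difference
  dm <- tapply(d$qaly, d$arm, mean)
  expect_equal(fit$delta_qaly, unname(dm[2] - dm[1]), tolerance = 1e-10)
})

test_that("FGLS matches an explicit stacked Kronecker-GLS oracle", {
  d <- hand_dataset()
  fit <- sur_fit(d, adjust_qaly_baseline = TRUE)

  # oracle: literal stacked system with Omega = S x I
  n <- nrow(d)
  trt <- as.numeric(d$arm == "intervention")
  X1 <- cbind(1, trt)
  X2 <- cbind(1, trt, d$utility_baseline)
  e1 <- stats::residuals(stats::lm(d$cost ~ trt))
  e2 <- stats::residuals(stats::lm(d$qaly ~ trt + d$utility_baseline))
  S <- crossprod(cbind(e1, e2)) / n
  X <- rbind(cbind(X1, matrix(0, n, 3)), cbind(matrix(0, n, 2), X2))
  y <- c(d$cost, d$qaly)
  Oinv <- kronecker(solve(S), diag(n))
  beta <- solve(t(X) %*% Oinv %*% X, t(X) %*% Oinv %*% y)
  V <- solve(t(X) %*% Oinv %*% X)

  expect_equal(fit$delta_cost, beta[2], tolerance = 1e-8)
  expect_equal(fit$delta_qaly, beta[4], tolerance = 1e-8)
  expect_equal(fit$se_cost, sqrt(V[2, 2]), tolerance = 1e-8)
  expect_equal(fit$se_qaly, sqrt(V[4, 4]), tolerance = 1e-8)
  expect_equal(fit$cov[1, 2], V[2, 4], tolerance = 1e-8)
})

test_that("SUR estimation errors are explicit", {
  d <- hand_dataset()
  d$utility_baseline <- 1 # collinear with the intercept
  expect_error(sur_fit(d), "rank-deficient")
  d2 <- hand_dataset()[c(1, 5), ]
  expect_error(sur_fit(d2), "2 subjects per arm")
})

test_that("constant statistics collapse the BCa interval to a point", {
  d <- data.frame(x = rnorm(20))
  expect_warning(
    bs <- bca_bootstrap(d, function(dd) c(s = 1), B = 200L, seed = 1L),
    "degenerate")
  expect_equal(unname(bs$ci[1, ]), c(1, 1))
})

test_that("BCa endpoints match the textbook formulas on a fixed 10-point sample", {
  x <- c(2.1, 3.4, 1.9, 5.6, 4.2, 3.3, 2.8, 6.1, 3.9, 4.4)
  d <- data.frame(x = x)
  stat <- function(dd) c(m = mean(dd$x))
  bs <- bca_bootstrap(d, stat, B = 2000L, conf = 0.95, seed = 7L)

  # textbook recomputation from the replicate set
  t0 <- mean(x)
  tb <- bs$replicates[, 1]
  z0 <- stats::qnorm(mean(tb < t0))
  jk <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  dj <- mean(jk) - jk
  a <- sum(dj^3) / (6 * sum(dj^2)^1.5)
  za <- stats::qnorm(0.025)
  a1 <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  a2 <- stats::pnorm(z0 + (z0 - za) / (1 - a * (z0 - za)))
  want <- stats::quantile(tb, c(a1, a2), names = FALSE, type = 6)

  expect_equal(bs$z0[1], z0, tolerance = 1e-12)
  expect_equal(bs$a[1], a, tolerance = 1e-12)
  expect_equal(unname(bs$ci[1, ]), want, tolerance = 1e-12)

  # independent cross-check against boot's BCa machinery
  skip_if_not_installed("boot")
  set.seed(7)
  bo <- boot::boot(x, function(xx, ix) mean(xx[ix]), R = 2000L)
  bci <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  expect_equal(unname(bs$ci[1, ]), bci, tolerance = 0.15)
})

test_that("for near-symmetric statistics BCa is close to the percentile interval", {
  shifts <- numeric(10)
  for (s in 1:10) {
    set.seed(1000 + s)
    d <- data.frame(x = rnorm(60))
    bs <- bca_bootstrap(d, function(dd) c(m = mean(dd$x)), B = 1000L,
                        seed = s)
    expect_lt(abs(bs$z0[1]), 0.15)
    perc <- stats::quantile(bs$replicates[, 1], c(0.025, 0.975),
                            names = FALSE, type = 6)
    # endpoint shift measured in percentile units of the replicate set
    ecdf_b <- stats::ecdf(bs$replicates[, 1])
    shifts[s] <- max(abs(ecdf_b(bs$ci[1, ]) - ecdf_b(perc))) * 100
  }
  expect_lt(stats::median(shifts), 2)
})

test_that("bootstrap is deterministic in the seed and stratified by arm", {
  cfg <- quick_config(n = 25L, seed = 12L)
  d <- score_dataset(simulate_trial(cfg, "3L"),
                     scoring_value_set(builtin_tariff("NL", "3L")))
  stat <- function(dd) c(n_int = sum(dd$arm == "intervention"))
  bs <- bca_bootstrap(d, function(dd) {
    f <- sur_fit(dd)
    c(delta_cost = f$delta_cost, delta_qaly = f$delta_qaly)
  }, B = 150L, seed = 5L, strata = d$arm)
  bs2 <- bca_bootstrap(d, function(dd) {
    f <- sur_fit(dd)
    c(delta_cost = f$delta_cost, delta_qaly = f$delta_qaly)
  }, B = 150L, seed = 5L, strata = d$arm)
  expect_identical(bs$replicates, bs2$replicates)
  expect_identical(bs$ci, bs2$ci)
  # strata preserve arm sizes on every replicate
  expect_warning(
    bsn <- bca_bootstrap(d, stat, B = 120L, seed = 2L, strata = d$arm),
    "degenerate")
  expect_true(all(bsn$replicates == 25L))
})

test_that("ICER division, undefined flag, and quadrants behave as specified", {
  r <- compute_icer(250, 0.05)
  expect_equal(r$icer, 5000)
  expect_identical(r$quadrant, "NE")
  r0 <- compute_icer(250, 0)
  expect_true(is.na(r0$icer))
  expect_false(r0$defined)
  expect_identical(r0$quadrant, "NE") # tie on the effect axis -> positive side
  rd <- compute_icer(-100, 0.1)
  expect_equal(rd$icer, -1000)
  expect_identical(rd$quadrant, "SE")
  expect_identical(compute_icer(100, -0.1)$quadrant, "NW")
  expect_identical(compute_icer(-100, -0.1)$quadrant, "SW")
})

test_that("CEAC equals a brute-force count of positive net benefit", {
  cloud <- data.frame(delta_cost = c(100, -50, 200, 10, -5),
                      delta_qaly = c(0.01, 0.02, -0.01, 0.005, 0))
  got <- ceac(cloud, wtp = 20000)
  # direct count: INB = 20000*dQ - dC > 0 for rows 1 (100), 2 (450),
  # 4 (90), 5 (5); row 3 (-400) fails -> 4/5
  inb <- 20000 * cloud$delta_qaly - cloud$delta_cost
  expect_identical(unname(got), mean(inb > 0))
  expect_identical(unname(got), 0.8)
  # pCE at lambda 0 is the fraction of cost-saving replicates
  expect_identical(unname(ceac(cloud, wtp = 0)),
                   mean(cloud$delta_cost < 0))
  # all-dominant cloud is certain at every threshold
  dom <- data.frame(delta_cost = c(-10, -20), delta_qaly = c(0.1, 0.2))
  expect_identical(unname(ceac(dom)), rep(1, 4))
  expect_error(ceac(dom[0, ]), "empty")

  # randomized clouds: vectorized CEAC equals an explicit loop
  set.seed(42)
  for (i in 1:5) {
    cl <- data.frame(delta_cost = rnorm(200, 100, 400),
                     delta_qaly = rnorm(200, 0.02, 0.05))
    for (l in c(0, 20000, 30000, 50000)) {
      cnt <- 0L
      for (j in 1:200) {
        if (l * cl$delta_qaly[j] - cl$delta_cost[j] > 0) cnt <- cnt + 1L
      }
      expect_identical(unname(ceac(cl, wtp = l)), cnt / 200)
    }
  }
})

test_that("the 0.80 decision threshold is inclusive", {
  expect_true(decide(0.80))
  expect_false(decide(0.79))
  expect_true(decide(1.0))
  expect_identical(decide(c(0.5, 0.9)), c(FALSE, TRUE))
  expect_error(decide(1.2), "pce")
})

test_that("a full cost-utility run is deterministic and internally coherent", {
  cfg <- quick_config(n = 40L, seed = 9L)
  d <- score_dataset(simulate_trial(cfg, "3L"),
                     scoring_value_set(builtin_tariff("NL", "3L")))
  r1 <- run_cua(d, B = 200L, seed = 31L)
  r2 <- run_cua(d, B = 200L, seed = 31L)
  expect_identical(r1$cloud, r2$cloud)
  expect_identical(r1$ceac, r2$ceac)
  expect_identical(nrow(r1$cloud), 200L)
  expect_true(all(r1$ceac >= 0 & r1$ceac <= 1))
  expect_identical(unname(r1$decisions), unname(r1$ceac >= 0.80))
  expect_equal(sum(r1$quadrant_proportions), 1)
  # CEAC recomputed from the serialized cloud matches
  expect_identical(ceac(r1$cloud, r1$wtp), r1$ceac)
})

test_that("SUR recovers the true cost difference over repeated trials", {
  # parameter recovery at reduced scale: the generator's true arm cost
  # difference is 250
  nsim <- 60L
  est <- numeric(nsim)
  probs <- baseline_probabilities("depression", "moderate", "3L")
  tf <- builtin_tariff("NL", "3L")
  trans <- calibrate_effect_size(control_transitions("3L"), probs, "medium", tf)
  for (i in seq_len(nsim)) {
    bl <- generate_baseline(probs, 150L, seed = 4000L + i)
    fu <- generate_followup(bl, trans, seed = 8000L + i)
    st0 <- c(bl$control, bl$intervention)
    st1 <- c(fu$control, fu$intervention)
    arm <- rep(c("control", "intervention"), each = 150L)
    u0 <- score_states(st0, tf); u1 <- score_states(st1, tf)
    q <- qaly_auc(u0, u1)
    cost <- generate_costs(q, arm, seed = 12000L + i)
    dd <- data.frame(arm = factor(arm, c("control", "intervention")),
                     cost = cost, qaly = q, utility_baseline = u0)
    est[i] <- sur_fit(dd)$delta_cost
  }
  mc_se <- stats::sd(est) / sqrt(nsim)
  expect_lt(abs(mean(est) - 250), 2 * mc_se + 1e-9)
})
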