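#' Derive a named substream seed
#'
#' All randomness in a simulated trial flows from one master seed through
#' named substreams, so that changing one stage (e.g. the number of
#' bootstrap replications) never perturbs the draws of another.
#'
#' @param seed Master integer seed.
#' @param name Substream name.
#' @return An integer in \[1, 2^31 - 2\].
#' @export
substream <- function(seed, name) {
  b <- utf8ToInt(name)
  h <- sum(b * seq_along(b)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621 + 1) %% 2147483646 + 1)
}

.sample_levels <- function(prob_rows, lv_from = NULL, n = NULL) {
  # draw one level per subject for one dimension; prob_rows is either a
  # single probability vector (baseline) or an L x L matrix indexed by the
  # subject's baseline level (follow-up)
  if (is.null(lv_from)) {
    sample.int(length(prob_rows), n, replace = TRUE, prob = prob_rows)
  } else {
    out <- integer(length(lv_from))
    for (b in sort(unique(lv_from))) {
      idx <- which(lv_from == b)
      out[idx] <- sample.int(ncol(prob_rows), length(idx), replace = TRUE,
                             prob = prob_rows[b, ])
    }
    out
  }
}

#' Generate baseline health-state profiles
#'
#' Each subject's level on each dimension is drawn independently from the
#' arm's response-level probability vector for that dimension.
#'
#' @param probs A [baseline_probs][new_baseline_probs] table.
#' @param n_per_arm Subjects per arm.
#' @param seed Integer seed.
#' @return List with character vectors `control` and `intervention` of
#'   state strings.
#' @export
generate_baseline <- function(probs, n_per_arm, seed) {
  stopifnot(inherits(probs, "baseline_probs"))
  out <- list()
  for (arm in c("control", "intervention")) {
    set.seed(substream(seed, paste0("baseline:", arm)))
    lv <- vapply(EQ5D_DIMENSIONS,
                 function(d) .sample_levels(probs[[arm]][d, ], n = n_per_arm),
                 integer(n_per_arm))
    out[[arm]] <- levels_to_states(matrix(lv, ncol = 5L,
                                          dimnames = list(NULL, EQ5D_DIMENSIONS)))
  }
  out
}

#' Generate follow-up profiles from baseline states
#'
#' Each dimension's follow-up level is drawn from the transition-matrix row
#' indexed by that dimension's baseline level, independently across
#' dimensions and subjects.
#'
#' @param baseline List with `control` and `intervention` state vectors (as
#'   returned by [generate_baseline()]).
#' @param transitions A [transition_model][new_transition_model].
#' @param seed Integer seed.
#' @return List with `control` and `intervention` follow-up state vectors.
#' @export
generate_followup <- function(baseline, transitions, seed) {
  stopifnot(inherits(transitions, "transition_model"))
  out <- list()
  for (arm in intersect(c("control", "intervention"), names(baseline))) {
    lv <- states_to_levels(baseline[[arm]], transitions$version)
    set.seed(substream(seed, paste0("followup:", arm)))
    lv2 <- vapply(EQ5D_DIMENSIONS,
                  function(d) .sample_levels(transitions[[arm]][[d]],
                                             lv_from = lv[, d]),
                  integer(nrow(lv)))
    out[[arm]] <- levels_to_states(matrix(lv2, ncol = 5L))
  }
  out
}

#' Tilt a transition matrix toward improvement
#'
#' Multiplies the probability of moving from baseline level `b` to a better
#' follow-up level `t < b` by `exp(shift * (b - t))` and renormalizes each
#' row. `shift = 0` leaves the matrix unchanged; increasing `shift` moves
#' mass monotonically toward larger improvements.
#'
#' @param m Row-stochastic L x L matrix.
#' @param shift Non-negative tilt.
#' @return Tilted row-stochastic matrix.
#' @export
tilt_matrix <- function(m, shift) {
  L <- nrow(m)
  steps <- pmax(0, outer(seq_len(L), seq_len(L), "-")) # b - t when improving
  w <- m * exp(shift * steps)
  sw <- rowSums(w)
  sw[sw == 0] <- 1
  w / sw
}

.tilted <- function(transitions, shift) {
  new_transition_model(
    transitions$version, control = transitions$control,
    intervention = lapply(transitions$control, tilt_matrix, shift = shift),
    shift = shift
  )
}

#' Population Cohen's d of follow-up utilities between arms
#'
#' Because baseline levels and transitions are independent across
#' dimensions, the follow-up state distribution of each arm is an exact
#' product measure: per dimension, the follow-up level distribution is the
#' baseline probability vector times the transition matrix. The mean and
#' variance of the follow-up utility are then computed by enumerating all
#' 243/3125 states, and Cohen's d is the standardized mean difference with
#' the pooled (average-variance) SD. No Monte Carlo error is involved.
#'
#' @param transitions A [transition_model][new_transition_model].
#' @param probs A [baseline_probs][new_baseline_probs] table.
#' @param tariff Tariff of the same version used to value follow-up states.
#' @return List with `d`, and per-arm `mean` and `sd` of follow-up utility.
#' @export
cohens_d_population <- function(transitions, probs, tariff) {
  stopifnot(inherits(transitions, "transition_model"),
            inherits(probs, "baseline_probs"),
            identical(transitions$version, probs$version),
            identical(tariff$version, probs$version))
  u <- score_states(enumerate_states(probs$version), tariff)
  moments <- function(arm) {
    p <- 1
    for (d in EQ5D_DIMENSIONS) {
      pd <- as.numeric(probs[[arm]][d, ] %*% transitions[[arm]][[d]])
      p <- kronecker(p, pd)
    }
    mu <- sum(p * u)
    c(mean = mu, var = sum(p * u^2) - mu^2)
  }
  mc <- moments("control"); mi <- moments("intervention")
  sd_pooled <- sqrt((mc[["var"]] + mi[["var"]]) / 2)
  list(d = (mi[["mean"]] - mc[["mean"]]) / sd_pooled,
       mean = c(control = mc[["mean"]], intervention = mi[["mean"]]),
       sd = c(control = sqrt(mc[["var"]]), intervention = sqrt(mi[["var"]])))
}

#' Calibrate the intervention-arm tilt to an effect-size band
#'
#' Finds by bisection the improvement tilt (see [tilt_matrix()]) for which
#' the population Cohen's d of follow-up utilities (computed exactly by
#' state enumeration, see [cohens_d_population()]) equals the band's target
#' midpoint. The control matrices are left untouched.
#'
#' @param transitions A [transition_model][new_transition_model] whose
#'   control matrices define both arms before tilting.
#' @param probs A [baseline_probs][new_baseline_probs] table.
#' @param band `"small"`, `"medium"`, or `"large"`.
#' @param tariff Calibration tariff (NL value set of the generated version
#'   by convention).
#' @param tol Absolute tolerance on the achieved d (0.005).
#' @return The calibrated `transition_model` with `shift` set; its achieved
#'   d is stored in attribute `"d"`.
#' @export
calibrate_effect_size <- function(transitions, probs, band, tariff,
                                  tol = 0.005) {
  target <- effect_band(band)$target
  d_at <- function(shift) {
    cohens_d_population(.tilted(transitions, shift), probs, tariff)$d
  }
  hi <- 1
  d_hi <- d_at(hi)
  while (d_hi < target && hi < 64) {
    hi <- hi * 2
    d_new <- d_at(hi)
    if (abs(d_new - d_hi) < 1e-8 && d_new < target) {
      stop(sprintf(
        "effect-size band '%s' (target d = %.2f) is unreachable: d plateaus at %.3f",
        band, target, d_new))
    }
    d_hi <- d_new
  }
  if (d_hi < target - tol) {
    stop(sprintf(
      "effect-size band '%s' (target d = %.2f) is unreachable: max achievable d = %.3f",
      band, target, d_hi))
  }
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (d_at(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  shift <- (lo + hi) / 2
  out <- .tilted(transitions, shift)
  attr(out, "d") <- d_at(shift)
  if (abs(attr(out, "d") - target) > tol) {
    stop("calibration failed to reach the target within tolerance")
  }
  out
}

#' Generate subject covariates
#'
#' Ages are uniform integers on 25..75 inclusive; the male indicator is
#' Bernoulli with probability 0.19.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param age_range Inclusive integer age bounds.
#' @param p_male Probability of the male indicator.
#' @return Data frame with columns `age` and `male`.
#' @export
generate_covariates <- function(n, seed, age_range = c(25L, 75L),
                                p_male = 0.19) {
  stopifnot(n >= 1)
  set.seed(substream(seed, "covariates"))
  data.frame(
    age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
    male = stats::rbinom(n, 1L, p_male)
  )
}

# correlation between a gamma variate and its own normal score,
# cor(qgamma(pnorm(Z), shape), Z); used to de-attenuate the copula parameter
.gamma_normal_score_cor <- function(shape) {
  f <- function(z) stats::qgamma(stats::pnorm(z), shape = shape) * z * stats::dnorm(z)
  cov <- stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  cov / sqrt(shape)
}

#' Generate follow-up costs coupled to QALYs
#'
#' Costs are marginally gamma with dispersion `nu` (`Var = nu * mean^2`),
#' mean `cost_mean` in the control arm and `cost_mean +
#' cost_true_difference` in the intervention arm. Dependence on QALYs is
#' induced with a Gaussian copula on the within-arm QALY ranks, which
#' leaves the gamma marginals untouched. The copula correlation is chosen
#' so that the *pooled* Pearson correlation between costs and QALYs lands
#' on `target_correlation`: the first-order Hermite attenuation of both
#' margins (the gamma normal-score correlation, computed by numerical
#' integration, and the empirical QALY normal-score correlation) is
#' inverted, and the positive between-arm covariance contributed by the
#' arm mean differences in both costs and QALYs is subtracted from the
#' targeted covariance before solving for the within-arm correlation. A
#' target of exactly 0 disables the coupling entirely.
#'
#' @param qalys Numeric vector of per-subject QALYs.
#' @param arm Character/factor vector (`"control"`/`"intervention"`),
#'   same length.
#' @param cost_mean,cost_true_difference,cost_dispersion,target_correlation
#'   See [scenario_config()].
#' @param seed Integer seed.
#' @return Numeric vector of non-negative costs.
#' @export
generate_costs <- function(qalys, arm, cost_mean = 2000,
                           cost_true_difference = 250, cost_dispersion = 1,
                           target_correlation = -0.10, seed = 1L) {
  stopifnot(length(qalys) == length(arm), cost_mean > 0, cost_dispersion > 0)
  arm <- as.character(arm)
  arms_present <- intersect(c("control", "intervention"), unique(arm))
  n_all <- length(qalys)
  shape <- 1 / cost_dispersion
  mu_arm <- c(control = cost_mean,
              intervention = cost_mean + cost_true_difference)

  r_within <- 0
  if (target_correlation != 0 && stats::sd(qalys) > 0) {
    # moments of the pooled cost distribution are known by design;
    # QALY moments are taken from the supplied stream
    w <- vapply(arms_present, function(a) mean(arm == a), numeric(1))
    mu_c <- mu_arm[arms_present]
    sd_c <- mu_c * sqrt(cost_dispersion)
    mu_q <- vapply(arms_present, function(a) mean(qalys[arm == a]), numeric(1))
    sd_q <- vapply(arms_present, function(a) stats::sd(qalys[arm == a]),
                   numeric(1))
    mbar_c <- sum(w * mu_c); mbar_q <- sum(w * mu_q)
    var_c_pooled <- sum(w * (sd_c^2 + (mu_c - mbar_c)^2))
    var_q_pooled <- sum(w * (sd_q^2 + (mu_q - mbar_q)^2))
    cov_between <- sum(w * (mu_c - mbar_c) * (mu_q - mbar_q))
    cov_target <- target_correlation * sqrt(var_c_pooled * var_q_pooled)
    denom <- sum(w * sd_c * sd_q)
    r_within <- if (denom > 0) (cov_target - cov_between) / denom else 0
  }

  a_cost <- .gamma_normal_score_cor(shape)
  costs <- numeric(n_all)
  for (a in arms_present) {
    idx <- which(arm == a)
    n <- length(idx)
    set.seed(substream(seed, paste0("costs:", a)))
    eps <- stats::rnorm(n)
    q <- qalys[idx]
    if (r_within != 0 && stats::sd(q) > 0) {
      z_q <- stats::qnorm((rank(q, ties.method = "average") - 0.5) / n)
      a_q <- stats::cor(q, z_q)
      rho <- max(-0.99, min(0.99, r_within / (a_cost * a_q)))
      z_c <- rho * z_q + sqrt(1 - rho^2) * eps
    } else {
      z_c <- eps
    }
    costs[idx] <- stats::qgamma(stats::pnorm(z_c), shape = shape,
                                scale = mu_arm[[a]] * cost_dispersion)
  }
  costs
}

#' Simulate one two-arm trial dataset
#'
#' Runs the full generator for one scenario: baseline profiles from the
#' population's response-level probabilities, follow-up profiles from
#' control-arm transitions tilted in the intervention arm to the scenario's
#' effect-size band, uniform ages 25-75 and a 0.19 male proportion, and
#' gamma follow-up costs negatively coupled to QALYs. The QALY stream used
#' for cost coupling and effect-size calibration is valued with
#' `calibration_tariff` (the NL value set of the generated version by
#' default).
#'
#' @param config A [scenario_config()].
#' @param version `"3L"` or `"5L"`.
#' @param calibration_tariff Optional tariff of the same version.
#' @return Data frame with one row per subject: `id`, `arm`, `age`, `male`,
#'   `state_baseline`, `state_followup`, `cost`. The version, config, the
#'   calibrated transition model, and the achieved Cohen's d are attached
#'   as attributes.
#' @export
simulate_trial <- function(config, version = c("3L", "5L"),
                           calibration_tariff = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  version <- match.arg(version)
  tariff <- calibration_tariff %||% builtin_tariff("NL", version)
  stopifnot(identical(tariff$version, version))

  probs <- baseline_probabilities(config$condition, config$severity, version)
  trans <- calibrate_effect_size(control_transitions(version), probs,
                                 config$effect_size, tariff)

  bl <- generate_baseline(probs, config$n_per_arm,
                          substream(config$population_seed,
                                    paste0("states:", version)))
  fu <- generate_followup(bl, trans,
                          substream(config$seed, paste0("followup:", version)))

  n <- 2L * config$n_per_arm
  arm <- rep(c("control", "intervention"), each = config$n_per_arm)
  cov <- generate_covariates(n, substream(config$population_seed,
                                          paste0("covariates:", version)))
  st0 <- c(bl$control, bl$intervention)
  st1 <- c(fu$control, fu$intervention)
  u0 <- score_states(st0, tariff)
  u1 <- score_states(st1, tariff)
  qaly <- qaly_auc(u0, u1)
  cost <- generate_costs(qaly, arm, config$cost_mean,
                         config$cost_true_difference, config$cost_dispersion,
                         config$target_correlation,
                         substream(config$seed, paste0("costs:", version)))

  out <- data.frame(id = seq_len(n),
                    arm = factor(arm, levels = c("control", "intervention")),
                    age = cov$age, male = cov$male,
                    state_baseline = st0, state_followup = st1,
                    cost = cost, stringsAsFactors = FALSE)
  attr(out, "version") <- version
  attr(out, "config") <- config
  attr(out, "transitions") <- trans
  attr(out, "cohens_d") <- attr(trans, "d")
  out
}
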