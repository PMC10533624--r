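#' @title Simulated scenario factorial
#'
#' @description The simulation study crosses four health conditions
#' (depression, low back pain, osteoarthritis, cancer), three severity
#' levels (mild, moderate, severe), and three treatment effect-size bands
#' (small, medium, large on Cohen's d), giving 36 scenarios. A scenario's
#' condition and severity determine the baseline response-level
#' probabilities and the control-arm transition matrices; the effect-size
#' band determines how far the intervention arm's transitions are tilted
#' toward improvement.
#'
#' @name scenarios
NULL

CONDITIONS <- c("depression", "low_back_pain", "osteoarthritis", "cancer")
SEVERITIES <- c("mild", "moderate", "severe")
EFFECT_BANDS <- c("small", "medium", "large")

#' Cohen's d band for an effect-size label
#'
#' Small is d in \[0.1, 0.3\], medium \[0.5, 0.7\], large at least 0.8; the
#' calibration targets the band midpoint (0.2, 0.6) or 0.9 for large.
#'
#' @param band `"small"`, `"medium"`, or `"large"`.
#' @return List with `lower`, `upper` (may be `Inf`), and `target`.
#' @export
effect_band <- function(band = EFFECT_BANDS) {
  band <- match.arg(band)
  switch(band,
    small  = list(lower = 0.1, upper = 0.3, target = 0.2),
    medium = list(lower = 0.5, upper = 0.7, target = 0.6),
    large  = list(lower = 0.8, upper = Inf, target = 0.9)
  )
}

#' Enumerate the full scenario factorial
#'
#' @return Data frame with 36 rows: `scenario` (1..36), `condition`,
#'   `severity`, `effect_size`, ordered condition-major as in the study
#'   design table.
#' @export
enumerate_scenarios <- function() {
  g <- expand.grid(effect_size = EFFECT_BANDS, severity = SEVERITIES,
                   condition = CONDITIONS, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)[, 3:1]
  data.frame(scenario = seq_len(nrow(g)), g, stringsAsFactors = FALSE)
}

#' Build a scenario configuration
#'
#' Bundles the design parameters of one simulated trial: the patient
#' population (condition x severity), the targeted treatment effect-size
#' band, arm size, and the cost-generator parameters (gamma mean, true
#' between-arm difference, dispersion, and the targeted cost-QALY
#' correlation).
#'
#' @param condition One of `"depression"`, `"low_back_pain"`,
#'   `"osteoarthritis"`, `"cancer"`.
#' @param severity `"mild"`, `"moderate"`, or `"severe"`.
#' @param effect_size `"small"`, `"medium"`, or `"large"`.
#' @param n_per_arm Subjects per arm (150 by default).
#' @param cost_mean Mean follow-up cost in the control arm (currency units;
#'   2000 by default).
#' @param cost_true_difference True mean cost difference between arms (250).
#' @param cost_dispersion Gamma dispersion nu with `Var = nu * mean^2`, so
#'   the default 1 makes the cost SD equal its mean.
#' @param target_correlation Targeted Pearson correlation between follow-up
#'   costs and QALYs (-0.10: higher costs go with lower QALYs).
#' @param seed Integer seed; all stage-specific randomness is derived from
#'   it through named substreams.
#' @param population_seed Optional separate seed for the baseline population
#'   (states and covariates). Scenarios sharing a condition x severity
#'   population can share this seed so that effect-size bands differ only in
#'   the follow-up tilt, as in the study design. Defaults to `seed`.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(condition, severity, effect_size,
                            n_per_arm = 150L, cost_mean = 2000,
                            cost_true_difference = 250,
                            cost_dispersion = 1,
                            target_correlation = -0.10,
                            seed = 1L, population_seed = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  severity <- match.arg(severity, SEVERITIES)
  effect_size <- match.arg(effect_size, EFFECT_BANDS)
  stopifnot(n_per_arm >= 1, cost_mean > 0, cost_dispersion > 0,
            abs(target_correlation) < 1)
  structure(
    list(condition = condition, severity = severity,
         effect_size = effect_size, n_per_arm = as.integer(n_per_arm),
         cost_mean = cost_mean, cost_true_difference = cost_true_difference,
         cost_dispersion = cost_dispersion,
         target_correlation = target_correlation,
         seed = as.integer(seed),
         population_seed = as.integer(population_seed %||% seed)),
    class = "scenario_config"
  )
}

# severity pressure on the latent dysfunction scale
.severity_score <- c(mild = 0.9, moderate = 1.6, severe = 2.6)

# how strongly each condition loads on each EQ-5D dimension; these profiles
# are synthetic stand-ins shaped after the clinical picture (depression loads
# on anxiety/depression, low back pain on pain and mobility, osteoarthritis
# on mobility/pain, cancer diffusely), not estimates from any trial
.condition_weights <- rbind(
  depression     = c(MO = 0.15, SC = 0.25, UA = 0.55, PD = 0.35, AD = 0.95),
  low_back_pain  = c(MO = 0.60, SC = 0.35, UA = 0.65, PD = 0.95, AD = 0.30),
  osteoarthritis = c(MO = 0.85, SC = 0.45, UA = 0.60, PD = 0.80, AD = 0.25),
  cancer         = c(MO = 0.35, SC = 0.30, UA = 0.55, PD = 0.50, AD = 0.45)
)

#' Baseline response-level probabilities for a patient population
#'
#' Deterministic synthetic recipe: for each dimension the response level
#' minus one follows a binomial over the available levels whose success
#' probability increases with the condition's loading on that dimension and
#' with severity. Both arms share the same baseline distribution (no
#' treatment effect is simulated at baseline).
#'
#' @inheritParams scenario_config
#' @param version `"3L"` or `"5L"`.
#' @return A `baseline_probs` object: per-arm list of 5 x L probability
#'   matrices (dimensions in rows, levels in columns).
#' @export
baseline_probabilities <- function(condition, severity, version) {
  condition <- match.arg(condition, CONDITIONS)
  severity <- match.arg(severity, SEVERITIES)
  L <- n_levels(version)
  w <- .condition_weights[condition, ]
  p_dys <- stats::plogis(-2.2 + .severity_score[[severity]] * w)
  probs <- t(vapply(p_dys, function(p) stats::dbinom(0:(L - 1), L - 1, p),
                    numeric(L)))
  rownames(probs) <- EQ5D_DIMENSIONS
  new_baseline_probs(version, control = probs, intervention = probs)
}

#' Construct a baseline probability table
#'
#' @param version `"3L"` or `"5L"`.
#' @param control,intervention 5 x L matrices of response-level
#'   probabilities (rows MO..AD, each row summing to 1).
#' @return A `baseline_probs` object.
#' @export
new_baseline_probs <- function(version, control, intervention = control) {
  L <- n_levels(version)
  check <- function(m, arm) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(5L, L))) {
      stop(sprintf("%s table must be 5x%d for EQ-5D-%s", arm, L, version))
    }
    if (any(m < 0)) stop("negative probability in ", arm, " table")
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      stop(sprintf("rows of the %s table must sum to 1", arm))
    }
    rownames(m) <- EQ5D_DIMENSIONS
    m
  }
  structure(list(version = version, control = check(control, "control"),
                 intervention = check(intervention, "intervention")),
            class = "baseline_probs")
}

#' Control-arm follow-up transition matrices for a patient population
#'
#' Deterministic synthetic recipe: from baseline level `b`, the follow-up
#' level minus one is binomial over the available levels with success
#' probability `0.9 * (b - 1) / (L - 1)` clamped to (0.02, 0.98) — strong
#' persistence with a mild drift toward health, and strictly positive mass
#' on every level so that effect-size tilting can reach any band.
#'
#' @param version `"3L"` or `"5L"`.
#' @return A `transition_model` with identical control and intervention
#'   matrices (tilt not yet applied) and `shift = 0`.
#' @export
control_transitions <- function(version) {
  L <- n_levels(version)
  m <- t(vapply(1:L, function(b) {
    p <- min(0.98, max(0.02, 0.9 * (b - 1) / (L - 1)))
    stats::dbinom(0:(L - 1), L - 1, p)
  }, numeric(L)))
  mats <- stats::setNames(rep(list(m), 5L), EQ5D_DIMENSIONS)
  new_transition_model(version, control = mats, intervention = mats, shift = 0)
}

#' Construct a transition model
#'
#' @param version `"3L"` or `"5L"`.
#' @param control,intervention Named lists (MO..AD) of L x L row-stochastic
#'   matrices (baseline level in rows, follow-up level in columns).
#' @param shift Non-negative improvement tilt applied to the intervention
#'   arm (see [calibrate_effect_size()]).
#' @return A `transition_model` object.
#' @export
new_transition_model <- function(version, control, intervention, shift = 0) {
  L <- n_levels(version)
  check <- function(mats, arm) {
    if (!is.list(mats) || !setequal(names(mats), EQ5D_DIMENSIONS)) {
      stop(arm, " matrices must be a named list over ",
           paste(EQ5D_DIMENSIONS, collapse = ", "))
    }
    mats <- mats[EQ5D_DIMENSIONS]
    for (d in EQ5D_DIMENSIONS) {
      m <- as.matrix(mats[[d]])
      if (!all(dim(m) == c(L, L))) {
        stop(sprintf("%s matrix for %s must be %dx%d", arm, d, L, L))
      }
      if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
        stop(sprintf("%s matrix for %s must be row-stochastic", arm, d))
      }
      mats[[d]] <- m
    }
    mats
  }
  stopifnot(shift >= 0)
  structure(list(version = version, control = check(control, "control"),
                 intervention = check(intervention, "intervention"),
                 shift = shift),
            class = "transition_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
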