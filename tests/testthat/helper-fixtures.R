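# shared fixtures, built in code

# toy 3L tariff: any-dysfunction constant 0.07, MO2 0.05, UA2 0.03, PD3 0.20,
# AD2 0.06, extreme-level constant 0.10
fixture_tariff <- function(country = "FIX") {
  new_tariff(country, "3L", data.frame(
    dimension = c("MO", "UA", "PD", "AD", NA, NA),
    level = c(2L, 2L, 3L, 2L, 2L, 3L),
    indicator = c(rep("level_dummy", 4), "any_level_ge", "any_level_ge"),
    coefficient = c(0.05, 0.03, 0.20, 0.06, 0.07, 0.10),
    offset = 0L
  ))
}

# single-term 3L tariff (MO3 only), used for hand-computable crosswalks
mo3_tariff <- function(coef = 0.4, country = "MO3") {
  new_tariff(country, "3L", data.frame(
    dimension = "MO", level = 3L, indicator = "level_dummy",
    coefficient = coef, offset = 0L
  ))
}

# point-mass crosswalk matrices: source level k -> min(k, target max)
identity_like_matrices <- function(Ls, Lt) {
  mk <- function() {
    m <- matrix(0, Ls, Lt)
    m[cbind(seq_len(Ls), pmin(seq_len(Ls), Lt))] <- 1
    m
  }
  stats::setNames(replicate(5, mk(), simplify = FALSE), EQ5D_DIMENSIONS)
}

# random row-stochastic matrices
random_stochastic <- function(Ls, Lt) {
  mk <- function() {
    m <- matrix(stats::rexp(Ls * Lt), Ls, Lt)
    m / rowSums(m)
  }
  stats::setNames(replicate(5, mk(), simplify = FALSE), EQ5D_DIMENSIONS)
}

# brute-force expected crosswalked utility: explicit loop over every target
# state, probability as the product of the per-dimension transition entries
brute_force_crosswalk <- function(state, matrices, target_tariff) {
  src <- as.integer(strsplit(state, "")[[1]])
  targets <- enumerate_states(target_tariff$version)
  tl <- states_to_levels(targets, target_tariff$version)
  u <- score_states(targets, target_tariff)
  total <- 0
  for (i in seq_along(targets)) {
    p <- 1
    for (d in 1:5) p <- p * matrices[[d]][src[d], tl[i, d]]
    total <- total + p * u[i]
  }
  total
}

# small deterministic trial data frame for SUR tests
hand_dataset <- function() {
  data.frame(
    arm = factor(rep(c("control", "intervention"), each = 4),
                 levels = c("control", "intervention")),
    cost = c(1800, 2400, 2100, 1500, 2600, 2300, 1900, 2700),
    qaly = c(0.61, 0.55, 0.70, 0.64, 0.72, 0.69, 0.58, 0.77),
    utility_baseline = c(0.60, 0.52, 0.71, 0.66, 0.68, 0.71, 0.55, 0.74)
  )
}

quick_config <- function(n = 40L, seed = 42L, band = "medium") {
  scenario_config("low_back_pain", "moderate", band, n_per_arm = n,
                  seed = seed)
}
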