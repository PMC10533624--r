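#' Area-under-the-curve QALYs from two measurement points
#'
#' Two-point trapezoid: `horizon * (u0 + u1) / 2` quality-adjusted life
#' years over a horizon of `horizon` years (1 by default).
#'
#' @param u0,u1 Baseline and follow-up utilities.
#' @param horizon Years between the measurement points.
#' @return Numeric vector of QALYs.
#' @export
qaly_auc <- function(u0, u1, horizon = 1) {
  stopifnot(horizon > 0, length(u0) == length(u1))
  horizon * (u0 + u1) / 2
}

#' Scoring methods: value set or crosswalk
#'
#' A scoring method turns health-state strings into utilities. Two kinds
#' exist: direct valuation under a tariff of the states' own version, and
#' crosswalked valuation under a tariff of the other version through a
#' crosswalk model.
#'
#' @param tariff An [eq5d_tariff][new_tariff].
#' @param model An [eq5d_crosswalk][new_crosswalk] whose source version
#'   matches the states to be scored and whose target version matches
#'   `tariff`.
#' @return A `scoring_method` object with a `label`.
#' @export
scoring_value_set <- function(tariff) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  structure(list(type = "value_set", tariff = tariff,
                 version = tariff$version,
                 label = sprintf("%s %s value set", tariff$country,
                                 tariff$version)),
            class = "scoring_method")
}

#' @rdname scoring_value_set
#' @export
scoring_crosswalk <- function(model, tariff) {
  stopifnot(inherits(model, "eq5d_crosswalk"),
            inherits(tariff, "eq5d_tariff"),
            identical(model$target_version, tariff$version))
  structure(list(type = "crosswalk", model = model, tariff = tariff,
                 version = model$source_version,
                 label = sprintf("%s %s crosswalk", tariff$country,
                                 gsub("_", " ", model$direction))),
            class = "scoring_method")
}

#' Score states under a scoring method
#'
#' @param states Character vector of state strings (the method's source
#'   version).
#' @param method A [scoring_value_set()] or [scoring_crosswalk()].
#' @return Numeric utilities.
#' @export
method_utilities <- function(states, method) {
  stopifnot(inherits(method, "scoring_method"))
  if (method$type == "value_set") {
    score_states(states, method$tariff)
  } else {
    crosswalk_utilities(states, method$model, method$tariff)
  }
}

#' Add per-method utilities and QALYs to a trial dataset
#'
#' @param dataset A [simulate_trial()] data frame (or any data frame with
#'   `state_baseline` and `state_followup` columns of the method's version).
#' @param method A [scoring_value_set()] or [scoring_crosswalk()].
#' @param horizon Follow-up horizon in years.
#' @return The dataset with columns `utility_baseline`, `utility_followup`,
#'   and `qaly` added.
#' @export
score_dataset <- function(dataset, method, horizon = 1) {
  dataset$utility_baseline <- method_utilities(dataset$state_baseline, method)
  dataset$utility_followup <- method_utilities(dataset$state_followup, method)
  dataset$qaly <- qaly_auc(dataset$utility_baseline, dataset$utility_followup,
                           horizon)
  dataset
}

#' Seemingly unrelated regression of costs and QALYs on treatment
#'
#' Two-equation feasible-GLS system accounting for the residual correlation
#' between costs and effects: the cost equation regresses cost on an
#' intercept and the treatment indicator; the QALY equation regresses QALY
#' on an intercept, treatment, and (by default) baseline utility. The
#' treatment coefficients are the incremental cost and incremental QALY,
#' returned with their joint covariance.
#'
#' When both equations have identical regressors, the FGLS estimates
#' coincide algebraically with per-equation least squares.
#'
#' @param dataset Data frame with `cost`, `qaly`, `arm`, and (if adjusting)
#'   `utility_baseline`.
#' @param adjust_qaly_baseline Include baseline utility in the QALY
#'   equation (default `TRUE`).
#' @return List with `delta_cost`, `delta_qaly`, `se_cost`, `se_qaly`,
#'   `cov` (2x2 joint covariance of the treatment coefficients),
#'   `coefficients` (per equation), and `sigma` (2x2 residual covariance).
#' @export
sur_fit <- function(dataset, adjust_qaly_baseline = TRUE) {
  n <- nrow(dataset)
  trt <- as.numeric(dataset$arm == "intervention")
  if (min(table(dataset$arm)) < 2L) stop("need at least 2 subjects per arm")
  X1 <- cbind(`(Intercept)` = 1, treatment = trt)
  X2 <- if (adjust_qaly_baseline) {
    cbind(`(Intercept)` = 1, treatment = trt,
          utility_baseline = dataset$utility_baseline)
  } else {
    X1
  }
  y1 <- dataset$cost
  y2 <- dataset$qaly
  if (qr(X1)$rank < ncol(X1) || qr(X2)$rank < ncol(X2)) {
    stop("rank-deficient design matrix in the SUR system")
  }
  b1 <- qr.solve(X1, y1)
  b2 <- qr.solve(X2, y2)
  E <- cbind(y1 - X1 %*% b1, y2 - X2 %*% b2)
  S <- crossprod(E) / n
  if (any(diag(S) <= 0)) stop("zero residual variance in the SUR system")
  W <- solve(S)
  k1 <- ncol(X1); k2 <- ncol(X2)
  A <- rbind(cbind(W[1, 1] * crossprod(X1), W[1, 2] * crossprod(X1, X2)),
             cbind(W[2, 1] * crossprod(X2, X1), W[2, 2] * crossprod(X2)))
  b <- c(W[1, 1] * crossprod(X1, y1) + W[1, 2] * crossprod(X1, y2),
         W[2, 1] * crossprod(X2, y1) + W[2, 2] * crossprod(X2, y2))
  beta <- solve(A, b)
  V <- solve(A)
  i_c <- 2L            # treatment coefficient, cost equation
  i_q <- k1 + 2L       # treatment coefficient, QALY equation
  list(
    delta_cost = unname(beta[i_c]), delta_qaly = unname(beta[i_q]),
    se_cost = sqrt(V[i_c, i_c]), se_qaly = sqrt(V[i_q, i_q]),
    cov = V[c(i_c, i_q), c(i_c, i_q)],
    coefficients = list(cost = stats::setNames(beta[seq_len(k1)], colnames(X1)),
                        qaly = stats::setNames(beta[k1 + seq_len(k2)],
                                               colnames(X2))),
    sigma = S
  )
}

#' Bias-corrected and accelerated (BCa) bootstrap
#'
#' Nonparametric bootstrap of an arbitrary statistic of a dataset, with BCa
#' confidence intervals: the bias constant `z0` is the normal quantile of
#' the fraction of replicates below the point estimate, and the
#' acceleration `a` comes from the skewness of leave-one-out jackknife
#' values. Resampling is with replacement within strata when `strata` is
#' given (subjects are resampled within treatment arm in the cost-utility
#' analysis, preserving arm sizes).
#'
#' @param dataset Data frame of subjects.
#' @param statistic Function `dataset -> numeric vector` (possibly named).
#' @param B Number of replications (2000 by default).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @param strata Optional factor/vector defining resampling strata.
#' @return List with `t0`, `replicates` (B x k matrix), `ci` (k x 2),
#'   `z0`, `a`.
#' @export
bca_bootstrap <- function(dataset, statistic, B = 2000L, conf = 0.95,
                          seed = 1L, strata = NULL) {
  if (B < 100L) warning("fewer than 100 bootstrap replications")
  t0 <- statistic(dataset)
  k <- length(t0)
  n <- nrow(dataset)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), strata)

  set.seed(substream(seed, "bootstrap"))
  reps <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_stratum,
                          function(ix) ix[sample.int(length(ix),
                                                     length(ix),
                                                     replace = TRUE)]),
                   use.names = FALSE)
    reps[b, ] <- statistic(dataset[take, , drop = FALSE])
  }
  colnames(reps) <- names(t0)

  jack <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) jack[i, ] <- statistic(dataset[-i, , drop = FALSE])

  alpha <- (1 - conf) / 2
  ci <- matrix(NA_real_, k, 2, dimnames = list(names(t0), c("lower", "upper")))
  z0 <- a <- numeric(k)
  for (j in seq_len(k)) {
    t_b <- reps[, j]
    if (max(t_b) - min(t_b) < .Machine$double.eps * max(1, abs(t0[j]))) {
      warning("degenerate bootstrap distribution; interval collapses to a point")
      ci[j, ] <- c(t_b[1], t_b[1]); z0[j] <- 0; a[j] <- 0
      next
    }
    p <- mean(t_b < t0[j])
    p <- min(max(p, 1 / (2 * B)), 1 - 1 / (2 * B))
    z0[j] <- stats::qnorm(p)
    dj <- mean(jack[, j]) - jack[, j]
    denom <- sum(dj^2)^1.5
    a[j] <- if (denom == 0) 0 else sum(dj^3) / (6 * denom)
    zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
    a1 <- stats::pnorm(z0[j] + (z0[j] + zlo) / (1 - a[j] * (z0[j] + zlo)))
    a2 <- stats::pnorm(z0[j] + (z0[j] + zhi) / (1 - a[j] * (z0[j] + zhi)))
    ci[j, ] <- stats::quantile(t_b, c(a1, a2), names = FALSE, type = 6)
  }
  list(t0 = t0, replicates = reps, ci = ci, z0 = z0, a = a, conf = conf)
}

#' Incremental cost-effectiveness ratio with CE-plane quadrant
#'
#' ICER = incremental cost / incremental QALYs. When the incremental QALY
#' is within `epsilon` of zero the ratio is flagged undefined rather than
#' raising an error. Quadrants follow the cost-effectiveness plane
#' convention (effect on the east-west axis, cost on the north-south axis);
#' values exactly on an axis count as the positive side.
#'
#' @param delta_cost,delta_qaly Incremental estimates.
#' @param epsilon Threshold below which `|delta_qaly|` makes the ICER
#'   undefined.
#' @return List with `icer` (`NA` when undefined), `defined`, `quadrant`
#'   (`"NE"`, `"SE"` dominant, `"NW"` dominated, `"SW"`).
#' @export
compute_icer <- function(delta_cost, delta_qaly, epsilon = 1e-6) {
  east <- delta_qaly >= 0
  north <- delta_cost >= 0
  quadrant <- if (north && east) "NE" else if (!north && east) "SE"
    else if (north) "NW" else "SW"
  defined <- abs(delta_qaly) >= epsilon
  list(icer = if (defined) delta_cost / delta_qaly else NA_real_,
       defined = defined, quadrant = quadrant)
}

#' Probability of cost-effectiveness from a bootstrap cloud
#'
#' For each willingness-to-pay threshold `lambda`, the probability of
#' cost-effectiveness is the fraction of bootstrap replicates with positive
#' incremental net benefit, `lambda * delta_qaly - delta_cost > 0` (strict
#' inequality).
#'
#' @param cloud Data frame or matrix with columns `delta_cost` and
#'   `delta_qaly` (one bootstrap replicate per row).
#' @param wtp Numeric vector of willingness-to-pay thresholds per QALY
#'   (0, 20000, 30000, 50000 by default).
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
ceac <- function(cloud, wtp = c(0, 20000, 30000, 50000)) {
  cloud <- as.data.frame(cloud)
  if (nrow(cloud) == 0L) stop("empty bootstrap cloud")
  stats::setNames(
    vapply(wtp,
           function(l) mean(l * cloud$delta_qaly - cloud$delta_cost > 0),
           numeric(1)),
    as.character(wtp))
}

#' Cost-effectiveness decision rule
#'
#' An intervention is deemed cost-effective at a threshold when the
#' probability of cost-effectiveness is at least 0.80 (inclusive).
#'
#' @param pce Numeric vector of probabilities in \[0, 1\].
#' @param threshold Decision threshold (0.80).
#' @return Logical vector.
#' @export
decide <- function(pce, threshold = 0.80) {
  stopifnot(all(pce >= 0 & pce <= 1))
  pce >= threshold
}

#' Run one full cost-utility analysis
#'
#' Point estimates from [sur_fit()], BCa bootstrap (stratified by arm, SUR
#' refitted on every replicate) for uncertainty, ICER and CE-plane
#' quadrant, CEAC over the willingness-to-pay grid, and the 0.80-threshold
#' decisions.
#'
#' @param dataset A scored dataset (see [score_dataset()]).
#' @param B Bootstrap replications (2000).
#' @param seed Integer seed for the bootstrap.
#' @param wtp Willingness-to-pay grid.
#' @param conf Confidence level for intervals.
#' @param adjust_qaly_baseline Passed to [sur_fit()].
#' @return A `cua_result` list: `delta_cost`/`delta_qaly` (each with point
#'   estimate, model-based CI, and BCa CI), `icer`, `quadrant`,
#'   `quadrant_proportions`, `cloud`, `ceac`, `decisions`, `B`, `wtp`.
#' @export
run_cua <- function(dataset, B = 2000L, seed = 1L,
                    wtp = c(0, 20000, 30000, 50000), conf = 0.95,
                    adjust_qaly_baseline = TRUE) {
  fit <- sur_fit(dataset, adjust_qaly_baseline)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  stat <- function(d) {
    f <- sur_fit(d, adjust_qaly_baseline)
    c(delta_cost = f$delta_cost, delta_qaly = f$delta_qaly)
  }
  bs <- bca_bootstrap(dataset, stat, B = B, conf = conf, seed = seed,
                      strata = dataset$arm)
  cloud <- as.data.frame(bs$replicates)
  ic <- compute_icer(fit$delta_cost, fit$delta_qaly)
  qprop <- c(
    NE = mean(cloud$delta_cost >= 0 & cloud$delta_qaly >= 0),
    SE = mean(cloud$delta_cost < 0 & cloud$delta_qaly >= 0),
    NW = mean(cloud$delta_cost >= 0 & cloud$delta_qaly < 0),
    SW = mean(cloud$delta_cost < 0 & cloud$delta_qaly < 0)
  )
  pce <- ceac(cloud, wtp)
  structure(list(
    delta_cost = list(estimate = fit$delta_cost,
                      ci_model = fit$delta_cost + c(-1, 1) * zc * fit$se_cost,
                      ci_bca = bs$ci["delta_cost", ]),
    delta_qaly = list(estimate = fit$delta_qaly,
                      ci_model = fit$delta_qaly + c(-1, 1) * zc * fit$se_qaly,
                      ci_bca = bs$ci["delta_qaly", ]),
    icer = ic$icer, icer_defined = ic$defined, quadrant = ic$quadrant,
    quadrant_proportions = qprop, cloud = cloud,
    ceac = pce, decisions = decide(pce), B = B, wtp = wtp, conf = conf
  ), class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat(sprintf("<cua_result> dCost %.1f [%.1f, %.1f]; dQALY %.4f [%.4f, %.4f]; ICER %s (%s)\n",
              x$delta_cost$estimate, x$delta_cost$ci_bca[1], x$delta_cost$ci_bca[2],
              x$delta_qaly$estimate, x$delta_qaly$ci_bca[1], x$delta_qaly$ci_bca[2],
              if (x$icer_defined) sprintf("%.0f", x$icer) else "undefined",
              x$quadrant))
  cat("  pCE:", paste(sprintf("%s: %.3f", names(x$ceac), x$ceac),
                      collapse = "; "), "\n")
  invisible(x)
}
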