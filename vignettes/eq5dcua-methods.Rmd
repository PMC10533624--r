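---
title: "Simulating the impact of EQ-5D scoring methods on cost-utility results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the impact of EQ-5D scoring methods on cost-utility results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eq5dcua)
```

## The question the pipeline answers

The EQ-5D describes health on five dimensions — mobility, self-care,
usual activities, pain/discomfort, anxiety/depression — with three (3L)
or five (5L) response levels, giving 243 or 3125 possible health states.
A *value set* (tariff) converts a state into a utility anchored at 1
(full health) and 0 (dead); utilities below zero describe states judged
worse than dead. When a trial collected one version of the instrument but
the jurisdiction's accepted value set belongs to the other, analysts fall
back on *crosswalks* that map states of one version onto utilities of the
other. Because the two routes assign different utilities to the same
answers, everything downstream — QALYs, incremental QALYs, ICERs, the
probability of cost-effectiveness — can shift, and with it the
reimbursement decision.

`eq5dcua` makes that shift measurable under controlled conditions: it
simulates two-arm trial data whose EQ-5D structure, treatment effect
size, and cost structure are all set by design, scores the same simulated
patients under a value set and under the paired crosswalk, and carries
both utility streams through an identical cost-utility analysis.

## Tariffs as data

Published value sets are additive decrement models. Utility is

$$u(s) = u_{\text{full}} - \sum_j \beta_j \, g_j(s),$$

where each indicator $g_j$ is one of four primitives: a level dummy
(ordinary main effect), an "any dimension at level $\ge k$" constant
(any-dysfunction and N3-style terms), a count of dimensions at level
$\ge k$ beyond an offset, or the square of that count (the interaction
structure of count-based models). This mini-language expresses the model
families behind the Dutch (N3), US (count/interaction), and Japanese
published sets without per-country code, so tariffs are shipped and
exchanged as CSV files.

The six embedded NL/US/JP tables are **synthetic stand-ins**, anchored
exactly at the one published decrement each country is commonly cited
for (3L mobility-3: 0.161/0.490/0.418; 5L anxiety-depression-5:
0.421/0.340/0.197) and filled out with plausible coefficients of the
same structure. Their file names and metadata say so. Analyses meant to
reproduce published numbers should load the real published tables as
tariff CSVs; every function accepts them interchangeably.

A "decrement" in `get_decrement()` means the main-effect coefficient for
a (dimension, level) pair — not the total utility drop from full health,
which can additionally involve constants or interaction terms. That is
the sense in which single per-level numbers are quoted for published
tariffs.

## Crosswalks

A crosswalk model carries one row-stochastic matrix per dimension
(source level × target level). Under cross-dimension independence the
crosswalked utility of source state $s$ is the expectation

$$\tilde u(s) = \sum_{t} \Big[\prod_{d=1}^{5} P_d(t_d \mid s_d)\Big]\,
u_{\text{target}}(t)$$

over all 243 or 3125 target states, computed by direct enumeration (a
Kronecker product of the five transition rows). At this size brute force
is the clearest correct implementation; no sparsity tricks are used, and
the unit tests check the vectorised path against an explicit five-fold
loop. Published crosswalks are sometimes distributed as full
state-to-index lookup tables rather than transition matrices; a lookup
can therefore be attached to a model and, when present for the tariff's
country, takes precedence bit-exactly. `consistency_check()` reports the
per-state discrepancy between the two representations without asserting
anything — useful when probing whether a published lookup is consistent
with an independence-product reconstruction.

## The synthetic trial generator

The generator emulates a two-arm trial with two measurement points
(baseline and follow-up) and these design quantities:

| parameter | default | meaning |
|---|---|---|
| `n_per_arm` | 150 | subjects per arm |
| age | uniform integers 25–75 | years |
| male proportion | 0.19 | Bernoulli indicator |
| `cost_mean` | 2000 | control-arm mean follow-up cost (currency) |
| `cost_true_difference` | 250 | true between-arm mean cost difference |
| `cost_dispersion` ν | 1 | gamma dispersion, Var = ν·mean² (SD = mean) |
| `target_correlation` | −0.10 | pooled Pearson r between costs and QALYs |
| effect-size bands | d ∈ [0.1,0.3] / [0.5,0.7] / ≥0.8 | small / medium / large |

Baseline response levels are drawn independently per dimension from
per-arm probability vectors; follow-up levels are drawn from transition
matrices indexed by the baseline level. Both recipes shipped with the
package (`baseline_probabilities()`, `control_transitions()`) are
deterministic synthetic constructions: condition profiles load each
dimension according to the clinical picture (depression on
anxiety/depression, low back pain on pain and mobility, osteoarthritis
on mobility/pain, cancer diffusely), severity shifts mass toward worse
levels through a binomial family, and control transitions mix strong
persistence with a mild drift toward health while keeping strictly
positive mass everywhere. They are *not* estimates from any patient
data; studies with empirical tables can supply them as CSVs.

The gamma "dispersion 1" convention deserves a note: with Var = ν·mean²
and ν = 1, the cost SD equals its mean (an exponential-shaped
distribution), which is the convention of common simulation packages; a
literal variance of one squared currency unit would be degenerate at a
mean of 2000.

### Effect-size calibration

The intervention arm's transition matrices are the control matrices
tilted toward improvement: the probability of moving from baseline level
$b$ to a better level $t<b$ is multiplied by $e^{\gamma\,(b-t)}$ and the
row renormalised. The tilt $\gamma$ is found by bisection so that the
population Cohen's *d* of follow-up utilities between arms hits the
band's midpoint target (0.2, 0.6, or 0.9 for the open-ended large band).
Because dimensions are independent at baseline and in transition, the
follow-up state distribution is an exact product measure, so the mean
and variance of follow-up utility — and hence *d*, standardised by the
pooled (average-variance) SD — are computed exactly by enumerating all
states. No Monte Carlo error enters the calibration, the achieved *d* is
reproducible to 10 decimal places, and unreachable bands (e.g. identity
transitions with no improvement mass to tilt) are reported with the
achievable maximum. Calibration utilities are valued with a single
designated tariff, by convention the Dutch set of the generated version.
Exponential tilting is one admissible formalisation of "tweaking
transition probabilities"; it is monotone in $\gamma$ (tested as a
property), touches only the intervention arm, and reaches any target for
which some improvement mass exists.

### Costs and the cost–QALY coupling

Costs are marginally gamma per arm (means 2000 and 2250). Dependence
with QALYs uses a Gaussian copula on the within-arm QALY ranks, which
leaves the gamma marginals exactly intact (tested by a two-sample
Kolmogorov–Smirnov comparison against the uncoupled stream at
n = 100,000). Two corrections make the *pooled* Pearson correlation land
on the −0.10 target rather than merely near it: (i) first-order Hermite
de-attenuation, dividing the target by the product of the gamma
normal-score correlation (computed by numerical integration) and the
empirical QALY normal-score correlation; and (ii) subtraction of the
between-arm covariance that the design itself induces (the intervention
arm has both higher mean costs, +250, and higher mean QALYs) from the
targeted covariance before solving for the within-arm copula
correlation. A target of exactly 0 disables the coupling so that
independence means independence.

### Seeding

All randomness flows from one master seed through named substreams
(`substream(seed, name)`), so changing the number of bootstrap
replications never perturbs the simulated data, and scenarios that share
a condition × severity population share their baseline profiles and
covariates (`population_seed`), differing only in the follow-up tilt —
mirroring a design in which the effect size is a property of follow-up,
not of the recruited population. The full factorial therefore
yields exactly 12 baseline comparison populations (4 conditions × 3
severities) per country per pairing, alongside 36 full scenarios.

## The cost-utility analysis

QALYs use the two-point trapezoid over a 1-year horizon (the horizon is
configurable; one year with linear interpolation is the conventional
choice when the measurement schedule is not otherwise specified).
Incremental costs and QALYs come from a two-equation feasible-GLS
seemingly-unrelated-regression system: cost on intercept + treatment;
QALY on intercept + treatment + baseline utility (baseline adjustment of
utilities is standard practice and is configurable; with identical
regressors the system provably collapses to per-equation least squares,
which the tests assert). Uncertainty uses a nonparametric bootstrap with
2000 replications, resampling subjects with replacement *within arm* so
every replicate keeps 150 subjects per arm, refitting the SUR system each
time. Confidence intervals are bias-corrected and accelerated: the bias
constant is $z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$ and
the acceleration comes from jackknife skewness; endpoints are read from
the replicate distribution with a type-6 quantile. Model-based (normal)
SUR intervals are emitted alongside the BCa intervals, labelled, since
both conventions exist in applied work.

The ICER is ΔC/ΔE with an explicit undefined flag when |ΔE| < 10⁻⁶
(division is not an exception). CE-plane quadrants put ties on an axis
on the positive side. The CEAC evaluates the strict rule
pCE(λ) = P(λ·ΔE − ΔC > 0) on the bootstrap cloud at λ ∈ {0; 20,000;
30,000; 50,000}, and the decision rule is inclusive: cost-effective iff
pCE ≥ 0.80.

## Method comparison

Pairings follow the version of the collected data: a 3L value set is
compared with the 3L→5L crosswalk, a 5L value set with the 5L→3L
crosswalk — both members of a pair score the *same* simulated states.
Baseline utilities are compared on pooled arms (no treatment effect
exists at baseline) with paired *t* tests; differences at or above the
0.074 MCID are flagged (inclusive). ΔpCE is reported as value-set minus
crosswalk. No multiplicity correction is applied to the *t* tests; their
p-values are descriptive. Kernel-density summaries use the
normal-reference bandwidth on a fixed 512-point grid so that identical
inputs give identical output files.

A structural safeguard is tested end to end: if the crosswalk is rigged
(via its lookup) to return exactly the value-set utility for every
state, every difference column in every output table is exactly zero and
no decision changes at any threshold — the pipeline itself introduces no
spurious method effects.

## Numerical choices and degenerate inputs

* Utilities are compared at a 1e-9 tolerance; row-stochasticity likewise.
* Tariff files store coefficients at printed precision and round-trip
  through read/write exactly.
* Paired *t* on zero-variance differences reports the mean difference
  without a test instead of erroring mid-pipeline.
* A constant bootstrap statistic collapses the interval to a point with
  a warning; `z0` proportions of 0 or 1 are clipped to 1/(2B).
* Bisection for the effect-size tilt runs to an interval of 1e-10 and
  verifies the achieved *d* within 0.005 of the target.

## What passing tests do and do not show

The generator reproduces the *designed* statistical structure: coverage
of the cost-difference CI (≈95%), the pooled cost–QALY correlation
(≈−0.10), covariate marginals, and calibrated effect sizes inside their
bands — all verified in the test suite at reduced but adequate problem
sizes (500 simulated trials for coverage; samples of 100,000 for
marginals; a 36-scenario structural run at 15 subjects per arm and 40
bootstrap replications; full-scale defaults remain 150 per arm and
B = 2000). What no test can show is fidelity to any real patient
population: the shipped probability tables and transition recipes are
synthetic, cross-dimension dependence (present in real EQ-5D data) is
deliberately absent, there is no missing data, and the two-point,
one-year design abstracts from real measurement schedules. Conclusions
about *specific* conditions or countries require replacing the synthetic
tables with empirical ones; the pipeline's comparisons of scoring
methods are conditional on whatever tables it is given.

## Known limitations

* No copula or regression-based mapping models — only crosswalks of the
  transition-matrix/lookup form.
* No valuation-study estimation: tariffs are inputs, never fitted.
* No discounting (single-year horizon) and no Fieller or parametric ICER
  intervals.
* The embedded tariffs and crosswalks are synthetic stand-ins anchored
  at six published decrements; results under them are illustrative, not
  reproductions of published country results.
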