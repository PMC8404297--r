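---
title: "Joint Bayesian mapping of multiple diseases with coregionalized Leroux-CAR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian mapping of multiple diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Disease mapping estimates area-level relative risks from counts of
incident cases, smoothing the raw rates through a spatial prior so that
small-population areas borrow strength from their neighbours. Mapping
several diseases *jointly* adds a second source of strength — shared
geography between diseases — and yields a quantity single-disease maps
cannot give: the between-disease correlation of area effects, which
separates shared from disease-specific environmental risk.

`mcarmap` implements that joint analysis end to end for the canonical
setting of three cardiovascular outcomes (acute myocardial infarction,
stroke, atrial fibrillation) observed on 98 municipalities over a
two-year window, but every component is generic in the number of areas
and takes arbitrary disease labels.

## The model

Let $Y_{ij}$ be incident cases of disease $j = 1,\dots,J$ in area
$i = 1,\dots,n$ and $E_{ij}$ the expected count under internal
standardization. The likelihood is

$$Y_{ij} \sim \text{Poisson}\!\left(E_{ij}\,
  e^{\beta_j + \varphi_{ij}}\right),$$

with disease intercepts $\beta_j$ and disease-specific area effects
$\varphi_{ij}$. The effects are built by a linear model of
coregionalization: latent unit-scale fields $u_j$ are mixed through the
lower Cholesky factor $A$ of a $J \times J$ covariance $\Sigma = AA'$,

$$\varphi = (A \otimes I_n)\, u, \qquad
  u_j \sim N\!\left(0,\, Q(\rho_j)^{-1}\right),$$

where $Q(\rho) = \rho (D - W) + (1-\rho) I$ is the Leroux CAR
precision on the binary adjacency matrix $W$ with degree matrix $D$.
$Q$ interpolates between independence ($\rho = 0$) and the intrinsic
CAR ($\rho \to 1$) and is proper for all $\rho \in [0, 1)$, which is
why degree-0 areas are tolerated (flagged, but valid) and why islands
are ferry-linked rather than dropped.

Three variants are fitted and compared by DIC:

* **M1** — disease-specific $\rho_j$, correlated diseases;
* **M2** — one shared $\rho$, correlated diseases (the separable
  model);
* **M3** — no between-disease correlation: equivalent to univariate
  Leroux models per disease.

All marginal scale lives in $\Sigma$ and the latent fields carry unit
conditional scale. This is the standard identifiable split for
coregionalization when priors are placed on the elements of $\Sigma$,
which is what we do: uniform$(0, 10)$ on the standard deviations
(uniform$(0, 100)$ in the sensitivity analysis), uniform$(0, 1)$ on the
pairwise correlations, uniform$(0, 1)$ on $\rho$, and a weakly
informative $N(0, \text{precision } 0.1)$ prior on each intercept. The
uniform$(0,1)$ correlation prior restricts between-disease correlations
to be nonnegative; it is implemented verbatim, with
`mcarModelSpec(allowNegativeCorr = TRUE)` available as an off-by-default
extension. Positive definiteness of $\Sigma$ under these marginals is
enforced by rejection (a log-posterior of $-\infty$), not by
reparameterization. No sum-to-zero constraint is placed on $u$: the
Leroux prior with $\rho < 1$ is proper and the intercept prior resolves
the soft confounding between $\beta_j$ and the field mean.

## From records to expected counts

The cohort module mirrors register-based study practice:

* **Closed cohorts.** Each disease's study population is fixed at the
  index date: alive, resident, aged $\geq$ 30 there, with no prior
  diagnosis of that disease (incident exclusion). Persons turning 30
  later are not enrolled.
* **Follow-up** runs to the first of incident diagnosis, death,
  emigration or the administrative end; on same-day ties the event wins
  (outcomes are captured from cause-of-death data too), then death,
  then emigration. Intervals are half-open $[\text{entry},
  \text{exit} + 1\,\text{day})$ and person-years are days/365.25, which
  makes fragments exactly additive; events on the index date itself
  count as incident.
* **Splitting.** Follow-up is cut at every 1 January (area and income
  are per-calendar-year assignments consumed from the input, not
  recomputed), at every age-group boundary birthday (60, 70, 80) and at
  exit. The 24 strata are sexes $\times$ age groups (30–59, 60–69,
  70–79, 80+) $\times$ income groups (Low/Medium/High) in fixed nested
  order.
* **Standardization.** National stratum rates $R_j^k$ are cases over
  person-years; $E_{ij} = \sum_k R_j^k T_{ij}^k$. Because rates come
  from the same data, $\sum_i E_{ij} = \sum_i Y_{ij}$ holds exactly —
  this identity is asserted in the tests on every simulated dataset.

## The sampler

`fitMcmc` is a Metropolis-within-Gibbs sampler written in C++:
single-site random walks on each $u_{ij}$ (a site update touches only
the neighbour sum and the $J - j + 1$ likelihood cells its column of
$A$ reaches), random walks on $\beta_j$, and random walks on the
log-$\sigma_j$, logit-correlation and logit-$\rho$ scales with the
corresponding Jacobians. The log-determinant
$\log |Q(\rho)| = \sum_i \log(\rho \lambda_i + 1 - \rho)$ uses the
eigenvalues $\lambda_i$ of $D - W$, computed once per fit. Step sizes
adapt toward 0.44 acceptance during burn-in only and are frozen
afterwards, so the retained chain is a fixed-kernel Markov chain. Each
chain runs on its own `mt19937_64` stream: output is a pure function of
the seed, and reruns are bit-identical.

For M3 each disease is sampled on its own derived stream
(`seed + j - 1`), which makes a joint M3 fit equal, draw for draw, to
three univariate fits — asserted in the tests and useful for validating
the multivariate machinery against the univariate special case.

Two further test harnesses are built into the sampler because they give
closed-form oracles: `updateHyper = FALSE` holds the hyperparameters at
their initial values (so a single-area fit can be checked against 2-D
quadrature of the Poisson–Gaussian posterior), and
`likelihood = "gaussian"` replaces the Poisson likelihood with
$Y_{ij} \sim N(\beta_j + \varphi_{ij}, \sigma_g^2)$, making the
$(\beta, u)$ posterior exactly Gaussian so the sampler's long-run
moments can be compared with the analytic mean and covariance.

Default protocol: 2 chains $\times$ 20,000 iterations, burn-in 10,000,
thin 10 — 2,000 retained draws. This is a deliberate scaling-down of
the classical WinBUGS-era protocol (10,000 retained draws from two
chains after 10,000 burn-in with thinning 100); the package's own
convergence checks (Geweke, ESS, acceptance rates in $[0.1, 0.6]$) are
computed on every fit, and all problem sizes used by the tests and the
acceptance script are stated there explicitly. Chain 1 starts at a null
state ($\beta_j = \log \sum_i Y_{ij} / \sum_i E_{ij}$, $u = 0$,
$\sigma = 0.5$, corr $= 0.1$, $\rho = 0.5$); further chains get seeded
overdispersed jitter, redrawn until $\Sigma$ is positive definite.

## Outputs

* `sirSurface`: per draw $\text{SIR}_{ij} = \mu_{ij}/E_{ij} =
  e^{\beta_j + \varphi_{ij}}$ — the fitted mean, not a
  posterior-predictive count draw, which would add Poisson noise that
  smoothed maps should not contain. Summaries are the posterior median
  and a central 95% interval; "significantly above/below 1" is
  operationalized as the interval excluding 1 (the level is
  configurable, and widening it can only lose significance — a tested
  monotonicity).
* `conditionalCorrelation`: the between-disease conditional correlation
  at collocation, read per draw from $\Sigma$ as
  $\Sigma_{jk}/\sqrt{\Sigma_{jj}\Sigma_{kk}}$. For M1 the same
  $\Sigma$-summary is reported; the per-area M1 correlation is behind
  an experimental flag and deliberately outside the reference path.
* `percentDeviation`: $(\text{SIR} - 1) \times 100$, rounded to the
  nearest integer for presentation.
* `dic`: $\bar D + p_D$ with $p_D = \bar D - D(\bar\mu)$, the plug-in
  at the posterior mean of $\mu_{ij}$ (the WinBUGS convention), cells
  with $E = Y = 0$ dropped.

## The synthetic study conditions

The generator exists so that every downstream stage is testable without
the restricted register extract; its defaults *are* the study
conditions and are not tuned per test:

* **Map**: a 7 $\times$ 14 rook lattice — 98 areas like the real
  municipal map — with 7 designated islands whose lattice edges are
  removed and which are then ferry-linked to a single neighbour,
  reproducing the island mechanics of the real adjacency matrix.
* **Ground truth**: shared $\rho = 0.67$ and pairwise correlations
  $(0.47, 0.42, 0.65)$ — the posterior medians reported for the real
  data, used as generating truth so recovery tests exercise a realistic
  regime. The conditional scale is $0.2$ for all three diseases: on
  this lattice the mean diagonal of $Q(0.67)^{-1}$ is $\approx 0.64$,
  so $0.2$ gives marginal field standard deviations $\approx 0.16$ and
  SIR surfaces spanning roughly 0.7–1.45 across 98 areas, matching the
  spread of the published maps (0.76–1.38). Expected counts are flat at
  $E = 200$ per cell for aggregated runs.
* **Cohorts**: the individual-level generator draws piecewise-
  exponential event, death and emigration times whose hazards are
  constant exactly on the segments the cohort module later splits on
  (calendar years, decade birthdays), with age/sex/income rate
  structure shaped like the published national cohort, 1 January moves
  between areas, yearly income reassignment, and a configurable
  prevalence of pre-study diagnoses so the incident-exclusion rule is
  exercised.

What the generator does **not** emulate — diagnostic misclassification,
underreporting, competing-risks structure between the diseases, income
quintile construction on the full national population, and real border
geometry — bounds what passing tests show: they validate the
statistical machinery under the model's own assumptions, not robustness
to the data pathologies a real register carries.

## Numerical choices and edge cases

* Dense base-R linear algebra throughout ($n = 98$; eigen and Cholesky
  are microseconds at this size).
* Exact field draws via Cholesky back-substitution of $Q$.
* Geweke standard errors use a simple 4%-lag-window autocovariance sum
  (configurable); ESS uses initial-positive-sequence truncation and is
  capped at $N$; both flag degenerate (zero-variance) chains instead of
  erroring.
* Cells with $E_{ij} = 0, Y_{ij} = 0$ contribute nothing to likelihood
  or deviance; $E = 0$ with $Y > 0$ is rejected up front.
* DIC ties within 1 are broken toward M2, then M1, then M3 — a fixed,
  documented preference so model selection is deterministic.
* Rook contiguity (shared boundary of nonzero length) is the polygon
  convention: corner contact is not a border. "Share a common border"
  admits either reading; rook is adopted and stated.

## Worked example

```{r example}
library(mcarmap)

map <- syntheticMunicipalityMap()
truth <- makeGroundTruth(map, "M2", seed = 101)
E <- uniformExpectedCounts(map, value = 200)
Y <- simulateCounts(truth, E, seed = 201)

fit <- fitMcmc(mcarModelSpec("M2"), Y, E, map, mcmcControl(seed = 11))
conditionalCorrelation(fit)
dic(fit, Y, E)$DIC

surface <- sirSurface(fit, E)
head(surfaceTable(surface))
exportMaps(surface, "maps")
```

Or config-driven, end to end:

```{r pipeline}
cfg <- runConfig("synthetic", outdir = "run1", seed = 11)
manifest <- runPipeline(cfg)
manifest$selected          # DIC-minimizing variant
sensitivityRerun(cfg, list(priorSdUpper = 100))$maxAbsDeltaSIR
```

## Limitations

* The between-disease correlation prior is nonnegative by default (as
  specified); genuinely negatively correlated diseases need the
  extension switch.
* Single-site field updates mix adequately at the package's problem
  sizes but would be the first thing to block-update for much larger
  maps.
* The per-area correlation structure implied by M1 is exposed only
  experimentally; its reference summaries are the $\Sigma$-based ones.
* The pipeline's full-scale protocol reproduces the classical two-chain
  setup but is, like any MCMC result, subject to Monte Carlo error;
  the diagnostics report should be consulted before reading maps.
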