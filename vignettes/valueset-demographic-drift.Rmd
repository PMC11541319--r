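---
title: "Demographic drift in EQ-5D-3L value sets: model, sampler, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic drift in EQ-5D-3L value sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuesetdrift)
```

## The question and the model

Value sets for the EQ-5D-3L are estimated once from a time trade-off
(TTO) valuation study and then used for decades. If preferences differ
systematically between demographic groups, the population-weighted
average preference — which is what a value set encodes — can drift as
the population's sex and age composition changes, even if every group's
preferences stay fixed. `valuesetdrift` isolates exactly this mechanism:
it estimates group-specific preference scales from valuation data and
then compares the value set weighted by the study-year composition with
the same fitted preference structure weighted by a recent composition.
Everything except the weights is held constant, so the posterior of the
difference measures the pure demographic-change effect.

An observed TTO value for respondent *i* in task *t* is modelled as a
latent normal variable censored at −1 (the conventional floor for
worse-than-dead states; observed −1's are the censoring mass point):

$$
\mathrm{TTO}_{it} = \begin{cases}
\mathrm{TTO}^*_{it} & \mathrm{TTO}^*_{it} > -1\\
-1 & \mathrm{TTO}^*_{it} \le -1
\end{cases},
\qquad \mathrm{TTO}^*_{it} \sim \mathrm{Normal}(\mu_{it}, \sigma_{it}).
$$

The latent mean is an additive decrement model with multiplicative
demographic scales. With dummy indicators $I_{d2}, I_{d3}$ for each of
the five dimensions (MO, SC, UA, PD, AD) at levels 2 and 3, and the
respondent's demographic cell $c$ (sex × age band, 8 cells by default):

$$
\mu_{it} = \beta_0 + \sum_{d=1}^5
 \left(\beta_{d2} I_{d2,it} + \beta_{d3} I_{d3,it}\right)\varphi_{d,c(i)} .
$$

Each $\varphi_{d,c} > 0$ scales the whole dimension-$d$ decrement pair
for cell $c$; each dimension's scales average exactly 1 over cells, so
$\beta$ carries the cell-average decrements and $\varphi$ the relative
preference differences. The latent SD is a log-quartic polynomial in the
mean, $\sigma_{it} = \exp(\gamma_0 + \gamma_1\mu_{it} + \cdots +
\gamma_4\mu_{it}^4)$, which lets response noise grow (or shrink) with
state severity — empirically TTO responses for severe states are far
noisier than for mild ones. Because $\sigma$ depends on $\mu$, and $\mu$
on $\varphi$, the variance is parameter-dependent and is recomputed at
every likelihood evaluation.

Priors are vague Normal(0, 10) on $\beta_0$, $\beta$ and all five
$\gamma$ (the same SD for $\gamma$ as for $\beta$ is adopted
deliberately; nothing in the data analyses here is sensitive to it), and
log-normal with log-SD $\sigma = 0.4$ and log-mean $-\sigma^2/2 = -0.08$
on the scale parameters, so the prior expectation of every
$\varphi_{d,c}$ is exactly 1. $\beta_0$ is estimated, not fixed: it
appears in the mean model as an ordinary parameter, and the data
identify it sharply.

A value set under a demographic composition $w$ (shares over the cells,
summing to 1) has decrements

$$
D_{dl}(w) = \beta_{dl} \sum_c w_c\, \varphi_{d,c},
$$

computed per posterior draw under an *original* and an *updated*
composition, together with their difference (reported as updated −
original, the orientation of the package's comparison tables; note a
*negative* difference on a negative decrement means the decrement grew
in magnitude). Summaries are posterior means with equal-tailed 95%
credible intervals; a difference is flagged when its interval excludes
0.

## Respondent quality filters

Two sequential rules precede modelling, with an auditable report.
First, respondents with fewer than 10 observations are excluded (10
exactly is kept). Second, respondents whose values *rise* with the
misery index (the sum of the five levels, 5–15) are excluded: valuing
worse states higher indicates task misunderstanding. The slope is plain
unweighted OLS of value on misery over the respondent's tasks — the
estimator is isolated in `respondent_slope()` so a rank-based variant is
a drop-in substitution. A slope of exactly zero is not positive and is
retained; an undefined slope (no misery variation, impossible under the
shipped designs but possible in user data) retains the respondent with a
warning, since it carries no evidence of inconsistent responding.
Because the rules are applied in order and each respondent is charged to
at most one rule, `n_retained = n_input − n_min_obs − n_positive_slope`
always holds.

## Sampler design

The posterior is explored by a systematic-scan Gibbs sampler:

* $\beta_0$, $\beta_{1..10}$, $\gamma_{0..4}$: univariate Gaussian
  random-walk Metropolis. Step sizes adapt by Robbins–Monro towards a
  0.44 acceptance rate during burn-in only, so the retained chain is a
  time-homogeneous, valid sampler.
* $\varphi$: each dimension has $G-1$ free coordinates; the last cell is
  derived as $G - \sum(\text{free})$, keeping the mean-one constraint
  *exact* at every draw (not merely penalized). Free coordinates are
  updated by stepping-out-and-shrinkage slice sampling, with the support
  truncated wherever the coordinate or the implied derived cell would
  become non-positive. Priors are evaluated on the free coordinates.
* Scan order is fixed (β₀, β₁…β₁₀, γ₀…γ₄, then φ by dimension) for
  reproducibility. All randomness flows from one master seed that spawns
  per-chain streams; the same seed reproduces every draw bit for bit.

Default run lengths are 3 chains × (10,000 burn-in + 20,000 retained).
The test suite and the acceptance script use scaled-down runs — 3 chains
× (1,000 + 2,000) on studies of 1,000 respondents, and smaller still for
unit tests — chosen as the smallest sizes at which the distributional
checks have useful power. Convergence is summarized by split-chain
potential scale reduction factors for every parameter
(`gelman_rubin()`, `rhat_table()`); the pipeline treats R-hat > 1.05 as
a warning, not an error, leaving judgement to the analyst.

For speed, the likelihood is evaluated on unique (state × cell) groups
using Gaussian sufficient statistics — within a group all observations
share $(\mu, \sigma)$, and the Tobit likelihood depends on the
uncensored values only through their count, sum, and sum of squares,
plus the censored count. This is exact, not an approximation, and makes
a full likelihood evaluation O(number of groups) ≤ 360 rather than
O(observations). Each parameter block additionally touches only the
groups it can affect, with a per-group cache. The group scan lives in
C++ (Rcpp); a vectorized R implementation (`total_loglik()`) is the
reference the C++ path is tested against, and both are tested against an
independent scalar-loop oracle.

### Antithetic proposals: why the flag is off by default

The sampler exposes an antithetic mode that reuses the negated proposal
innovation of the previous scan for each Metropolis block (mirrored
pairs). It is off by default. Validation runs sampling from the prior
alone showed the naive mirrored-pair scheme measurably distorts the
stationary distribution: the innovation used at the odd scan is
dependent on the even scan's acceptance outcome, so the two-scan
composite does not satisfy detailed balance — in the extreme of a
locally flat target with acceptance near 1, accepted pairs cancel
exactly and the chain stops moving. With adapted steps the distortion is
smaller but still detectable (a prior marginal SD of 7.6 instead of 10
at 50,000 draws). Since no variant of the device is needed for
correctness, the package keeps it available for comparison but never
relies on it; every validity test runs with the flag off.

## Numerical choices

* Censoring status is inferred on read as `value == -1` within 1e-9:
  the model maps all latent values ≤ −1 to exactly −1, so an observed
  −1 is the mass point.
* `log Φ` in the censored-likelihood term uses `erfc` with an asymptotic
  expansion below z = −37, accurate in the far tail; the R path uses
  `pnorm(log.p = TRUE)`. They agree to ~1e-12 in all tested regimes.
* Credible intervals are equal-tailed 2.5/97.5 percentile intervals with
  linear interpolation between order statistics (R quantile type 7),
  fixed and documented so summaries are reproducible and order-invariant.
* Initial values: OLS of uncensored values on the state dummies,
  log-residual-SD for $\gamma_0$, scales at 1 with a small seed-specific
  jitter on the free coordinates (the derived cell restores the
  constraint exactly) — overdispersed but not absurd starting points.
* Proposals that would overflow `exp` in the SD polynomial, or make any
  scale parameter non-positive, are rejected (Metropolis) or excluded
  from the slice support.
* Degenerate inputs: an empty dataset has likelihood 0 (prior
  sampling); a dataset with no uncensored observations cannot be
  initialized and is rejected with a clear message; an all-censored
  *group* is handled naturally by the CDF term.

## What the synthetic generator does and does not emulate

`simulate_study()` draws respondents' demographic cells i.i.d. from a
specified composition, assigns task lists per design dialect, draws
latent values from the model at the true parameters, and censors at −1.
Two dialects mirror the source studies: every respondent valuing the
same 17 states (the Japanese design) and each respondent valuing 12
states sampled without replacement from a 45-state pool (the UK/US
design). The exact state lists of the historical designs are not public
in a citable form here, so the pools are deterministic synthetic
stand-ins with matched cardinalities, spanning misery 6–15 and
including 33333; users with the real designs can inject them.
Contamination is planted explicitly: low completers receive 3–9 tasks;
positive-slope responders are generated with sign-flipped decrements,
which guarantees a positive expected value–misery slope and makes the QC
filter's target unambiguous.

`default_truth()` encodes one fixed scenario per country style: true
decrements at the published country value-set magnitudes, intercept
0.95, $\gamma = (-1.0, -0.61, 0.05, 0, 0)$ so the latent SD runs from
about 0.2 at full health to about 0.5 for severe states (the realistic
noise ordering for TTO), scales varying up to ±25% across cells via
smooth age and sex contrasts with exact mean 1, the national
study-year composition, and contamination rates matching the source
studies' reported exclusion counts. These defaults are the package's
study conditions and are not tuned per run.

Deliberately not emulated: the iterative TTO elicitation procedure
itself (responses are continuous, not grid-valued), within-respondent
correlation beyond the shared mean/variance structure (no random
effects), quota or household sampling structure, and any upper
censoring — the latent-normal model is unbounded above 1, so simulated
datasets contain values above 1 where real elicitation data cannot.
Consequently, passing recovery tests demonstrate that the estimation
machinery is correct *for data generated by the assumed model*; they do
not validate the model against genuine TTO response behaviour
(digit preferences, heaping at 0 and −1, panel effects).

## Open design choices resolved here

* *Mean-one constraint*: read as the unweighted arithmetic mean over
  cells per dimension; the predicate is isolated in one internal
  function so a sample-weighted variant is a one-line change.
* *Mean model parenthesization*: the PD terms are treated symmetrically
  with the other four dimensions (the alternative reading is a clear
  typographical slip in the source presentation).
* *σ's argument*: the variance polynomial is evaluated at the
  scale-adjusted mean $\mu_{it}$ (including $\varphi$), as written.
* *Run-length convention*: "30,000 total iterations" is read as 10,000
  burn-in + 20,000 retained per chain.
* *β sign*: decrements are expected negative but unconstrained, matching
  the vague priors.
* *Slope estimator for QC*: OLS (see above), isolated for substitution.
* *Difference orientation*: updated − original, with the raw signed
  difference reported; consumers who prefer a magnitude-change reading
  can negate it, and the report prints the signed value.

## Limitations

The ceteris-paribus design answers only the demographic-composition
question: it cannot detect preference *change within* groups over time,
which confounds any real old-vs-new comparison. The scale parameters
shift whole dimensions, not individual levels, so level-specific
demographic effects are out of reach. Group cells are a fixed finite
partition; continuous-age preference gradients are approximated by four
bands. And the G−1 free-coordinate parameterization, while exact,
makes the derived cell's marginal prior differ slightly from the free
cells' (the free coordinates carry the log-normal prior); with 8 cells
and data-dominated posteriors this asymmetry is negligible, but it is a
documented asymmetry, not an oversight.
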