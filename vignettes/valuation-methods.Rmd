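---
title: "Valuing the ASCOT-Carer by best-worst scaling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing the ASCOT-Carer by best-worst scaling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carerbws)
```

## The valuation problem

The ASCOT-Carer instrument measures the long-term-care-related quality of
life of informal carers over seven domains (occupation, control over daily
life, looking after yourself, personal safety, social participation, space
and time to be yourself, feeling supported and encouraged), each reported at
one of four levels: 1 *ideal state*, 2 *no needs*, 3 *some needs*, 4 *high
needs*. A raw sum over domains treats all domains and level steps as equally
important; preference weights replace that assumption with empirically
elicited values, so that a total score reflects how (un)desirable the
population actually finds each state.

This package implements the full valuation pipeline around a profile-case
(case 2) best-worst scaling (BWS) experiment: each choice task displays one
statement from every domain, and the respondent picks, in sequence, the
*best*, the *worst*, the *second best* and the *second worst* statement.
Because a profile task compares individual domain-levels rather than whole
profiles, 28 items (7 × 4) can be valued with modest cognitive burden and
sample size. The raw choice data of the original Austrian survey are not
publicly available, so the package ships a first-class synthetic-data
generator that emulates the study conditions; every downstream stage is
exercised and validated against the published estimates through parameter
recovery.

## Experimental design

The full factorial over eight 4-level factors (seven domains plus one
blocking factor) has 4^8 scenarios; an orthogonal main-effects plan (OMEP)
reduces it to 32. `build_design()` constructs an OA(32, 8, 4, 2): the runs
are the 32 vectors of GF(2)^5, the 31 non-zero linear forms give a
Hadamard-derived two-level array, and eight disjoint XOR-closed triples of
forms (lines of PG(4,2), found by a seeded greedy search with restarts) are
collapsed into eight 4-level factors. Disjointness of the lines makes the
four defining bits of any two factors linearly independent, which yields the
strength-2 property: every pair of columns shows each of the 16 symbol pairs
exactly twice. `verify_design()` checks this exhaustively rather than by
sampling, and a vetted copy of the array ships as a plain-text fixture
(`design_fixture()`) so the pipeline never depends on the stochastic search.
Within every block of the shipped array each domain shows all four levels
(twice each), comfortably exceeding the minimum variation needed to estimate
level effects inside blocks.

The published description states the 4^8 factorial and 32 scenarios grouped
into blocks of 8, but not what the eighth factor was or how blocks were
formed. We interpret the eighth factor as the blocking factor: it is the
reading under which 32/8 = 4 randomly assigned blocks drop out of the design
automatically, and it keeps the blocks orthogonal to every domain. Design
symbols map to levels as level = symbol + 1, recorded in the design file
header. Statement positioning is randomised *per respondent* — one
permutation drawn per person and held constant over their eight tasks —
reading the study's "randomised across individuals" literally; a per-task
switch (`per_task_display`) is available.

## The choice model

Stage-level choices follow a multinomial logit on a common latent utility
scale. Writing $\beta_{dl}$ for the utility of domain $d$ at level $l$,
$\delta_p$ for the positioning effect of display position $p$, and
$\lambda_r$ for respondent $r$'s scale, the probability that item $i$ (at
position $p_i$) is picked from available set $A$ is

$$P(i \mid A) = \frac{\exp\{\lambda_r(\beta_i + \delta_{p_i})\}}
  {\sum_{j \in A}\exp\{\lambda_r(\beta_j + \delta_{p_j})\}}$$

for best-type stages, and with $-\lambda_r \beta_i$ and no positioning term
for worst-type stages (position effects on worst picks were found null in
the source study and are excluded from the model). The four picks of a task
form an exploded (sequential) likelihood: the task probability is the
product of stage probabilities over the shrinking available sets
(sizes 7, 6, 5, 4), in the order best → worst → second best → second worst.
The on-screen stage order of the original survey is not documented; this
sequential order follows the order in which the picks are described, and all
four stages carry equal weight in the likelihood. Softmaxes are computed
with max-subtraction, so utilities up to |λβ| ≈ 700 cannot overflow.

Scale heterogeneity enters as a multiplicative group effect, inversely
related to error variance. Three groups depart from the reference
(λ fixed at 1): respondents who did not, or only sometimes, understood the
tasks; respondents aged 35 and over; and respondents with completion times
at or above the first quartile (7 minutes). A respondent in several groups
gets the *product* of the multipliers; the composition rule is not stated in
the source and the product is the natural choice for a log-linear scale
model (membership effects add on the log scale). It also makes the
single-group published values directly interpretable.

### Identification

Utility location, the joint utility/scale product, and position effects are
not separately identified without constraints. The model pins: the reference
item (space-and-time, level 4, the least-valued state) at $\beta = 0$; the
encouragement-and-support levels 1 and 2 to one joint coefficient (their
valuations are empirically indistinguishable and level 2 would otherwise
rank above level 1); position 1 at $\delta = 0$; and the reference group at
$\lambda = 1$. The free vector has 26 utilities + 6 position effects + 3
log-scale parameters = 35 entries. Multiplying all $\beta,\delta$ by $c$ and
dividing scales by $c$ leaves the likelihood unchanged *only* through the
group multipliers; fixing the reference group's scale removes that ridge.

### Estimation and inference

`fit_smnl()` maximises the exploded likelihood with BFGS using the analytic
gradient (verified against central finite differences at 1e-6), followed by
Newton polishing steps (finite-difference Hessian of the analytic gradient)
until the gradient max-norm is below 1e-5, within at most 500 iterations;
non-convergence is flagged, never silent. Scales are optimised on the log
scale to enforce positivity. Degenerate inputs fail loudly: a never-shown
attribute-level raises an identification error naming the level, and
available sets that do not shrink by exactly the previous pick raise a
data-integrity error.

Because each respondent contributes eight tasks, observations are not
independent across tasks. The covariance is the cluster-robust sandwich
$A^{-1} B A^{-1}$ with $A$ the observed information and $B$ the sum of outer
products of per-respondent score sums. Coefficient-vs-zero tests are
two-sided; pairwise level comparisons (`pairwise_level_test()`) report
one-sided $p = 1 - \Phi(|z|)$, the convention under which the published
adjacent-level comparisons reproduce (z = 0.46 ↦ p = 0.32).

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 1001 respondents, each
randomly assigned one of the 4 blocks, answering 8 tasks with 4 sequential
picks (32 choices), choices sampled exactly from the stage model above at
the published Austrian parameter values (`austria_parameters()`). Covariate
defaults: 73.7% aged 35+ (the published sample share); 15% who did not or
only sometimes understood the tasks — the published tables do not report
this share, so a realistic online-panel value was fixed once; completion
times log-normal (sdlog 0.5) with the first quartile at the 7-minute
threshold that defines the "slower" group. A configurable 5% of respondents
are planted "speeders" below the 4.5-minute cleaning cut (non-speeder times
are truncated above it, so the speeder share is exact), exercising the
respondent-level exclusion filter `clean_dataset()` — the original survey
dropped such respondents during collection and re-sampled; post-hoc
filtering is the testable equivalent and is what the package does.

The generator reproduces the *structure* of the survey data, not its
behavioural quirks: no item non-response, no attrition, no learning or
fatigue over tasks, no taste heterogeneity beyond the scale groups, and
respondents follow the S-MNL exactly. Passing recovery tests therefore
demonstrate the estimator is correct and calibrated under the model, not
that the model is true of real respondents.

## From coefficients to preference weights

`reweight_by_population()` combines group-specific coefficient vectors as a
population-proportion-weighted entrywise average (the correction the source
study applied for the under-represented education and income groups; the
grouping is generic). `rescale_weights()` maps utilities to the deliverable
weights,

$$w_{dl} = \frac{\beta_{dl} - \min_l \beta_{dl}}
  {\sum_{d'} (\max_l \beta_{d'l} - \min_l \beta_{d'l})},$$

the unique per-domain affine map with a shared positive denominator under
which the total score $\sum_d w_{d,s_d}$ of the all-worst state is exactly 0
and of the all-best state exactly 1 (the published account states the 0-1
range but not the formula). `score_state()` evaluates states against the
table; `rank_items()` orders the 28 items and flags ties (the joint pair is
always tied by construction).

## Numerical and testing choices

* Tolerances: probability conservation over all 840 ordered pick sequences
  of a task is checked to 1e-10; the vectorised likelihood matches a naive
  double-loop oracle to 1e-10; optimiser gradient tolerance 1e-5.
* Problem sizes: recovery experiments use 20 replicates at the study size
  (n = 1001, ~8008 tasks); distributional simulator checks use 50,000 to
  100,000 draws; design checks are exhaustive.
* Recovery behaviour at the study size, measured over 20 seeded replicates:
  pooled 95% robust-CI coverage ≈ 0.94, mean absolute error of the 26 free
  utilities ≈ 0.03-0.13, within-domain monotone ordering recovered in all
  replicates, and the least-valued state always recovered. The *single*
  most-valued state is not stable across replicates: the two top generating
  utilities (occupation level 1 at 3.53, space-and-time level 1 at 3.50)
  differ by 0.03, below sampling noise at n = 1001, so either may come out
  on top — a property of the published values, not of the estimator.
* Ties in sampling are impossible almost surely; ties in ranking are broken
  by instrument order and reported.
* All randomness flows from explicit seeds (design search, respondent
  draws, choice draws derive from one master seed per run); identical seeds
  give byte-identical datasets and CSV outputs.

## Limitations

Exact reproduction of the published Austrian weight table is impossible
from public information alone: the final figure's numeric weights are not
printed, and the survey data are unavailable. The package therefore
reproduces the *construction* — design, model, estimator, reweighting,
rescaling — and validates it by recovering the published coefficient table
from data generated at those values. Mixed-logit/latent-class taste
heterogeneity, utility anchoring to QALY scales, and cross-country pooling
are out of scope.
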