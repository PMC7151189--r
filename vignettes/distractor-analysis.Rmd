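---
title: "Detecting ability-related distractor discrimination: models and methods"
author: "distractr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ability-related distractor discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distractr)
```

## The problem

Multiple-choice items carry information beyond right/wrong: *which* wrong
option a non-solver picks can itself depend on ability. Nested logit IRT
models exploit this by modelling solution behaviour with a binary logistic
model and, conditional on non-solution, distractor choice with Bock's nominal
response model (NRM). Fitting such models needs large samples, but item
pre-selection happens in pilot studies with N between roughly 100 and 500.
`distractr` implements descriptive effect sizes that screen candidate items
for *ability-related distractor discrimination* at pilot-study scale, a
simulator for the data-generating model, and a Monte-Carlo harness that
quantifies how reliably the effect sizes detect (or falsely flag)
discriminating distractors.

## The data-generating model (2PNL)

A person with ability $\theta \sim N(0,1)$ solves item $i$ with 2PL
probability

$$P(x_{ij} = u \mid \theta_j) = \frac{1}{1 + e^{-(\beta_i + \alpha_i\theta_j)}},$$

where $u$ is the correct option, $\beta_i$ the easiness intercept (larger =
easier) and $\alpha_i > 0$ the discrimination slope. Given non-solution,
distractor $v$ among the $m_i$ distractors is chosen with NRM probability

$$P(x_{ij} = v \mid \theta_j) = \bigl[1 - P(x_{ij}=u\mid\theta_j)\bigr]\,
\frac{e^{\zeta_{iv} + \lambda_{iv}\theta_j}}
     {\sum_{k=1}^{m_i} e^{\zeta_{ik} + \lambda_{ik}\theta_j}}.$$

The $\lambda_{iv}$ are the quantity of interest: when they differ across
distractors, distractor choice carries ability information. The standard
normal ability distribution is an assumption of this package's simulator —
it is the universal default in IRT simulation; nothing in the analysis side
depends on it, since all statistics use raw number-correct scores.

`p_correct()` and `p_options()` expose the model; `simulate_responses()`
draws datasets; probability mass is conserved to $10^{-12}$ by construction
(softmax with row-max centring).

### Simulated parameter ranges

`sample_item_bank()` draws, per design cell,

* easiness $\beta_i$: moderate $U(-0.15, 0.15)$, difficult $U(-1.15, -0.85)$,
  very difficult $U(-2.25, -1.85)$ (slope–intercept form, so negative values
  mean hard items);
* discrimination $\alpha_i$: low $U(0.25, 0.55)$, moderate $U(0.85, 1.15)$,
  high $U(1.60, 1.90)$;
* NRM intercepts $\zeta_{iv} \sim U(-1, 1)$ i.i.d.;
* NRM slopes $\lambda_{i\cdot}$: a fixed ladder symmetric around zero with
  step size 0 / 0.40 / 1.00 / 1.75 for the levels zero / moderate / high /
  very high (`nrm_lambda()`), e.g. $(-3,-2,-1,0,1,2,3)$ for high with seven
  distractors. The ladder is assigned to distractor slots in ascending
  order; because the $\zeta$ are i.i.d., any permutation is distributionally
  equivalent, and the fixed order keeps runs reproducible.

Option codes follow the convention correct = `"0"`, distractors `"1"`..`"m"`
in ladder order.

## The effect sizes

All statistics operate on raw number-correct scores. Writing $N_D$ for the
non-solvers of an item, the two item-level detection effect sizes are:

**Cohen's $\omega_G$.** Build the $K \times G$ contingency table of retained
distractor (rows) by ability group (columns) over the non-solvers; then
$\omega_G = \sqrt{\chi^2_G / n}$ with $n$ the table total and $\chi^2_G$ the
Pearson statistic (no continuity correction — this is an effect size, not a
test). Ability groups are score quantiles; $G = 2$ and $G = 5$ are the
supported defaults.

**Canonical correlation $R_{CC}$.** Among non-solvers choosing a retained
distractor, code the $K$ choices as indicator variables, drop one (the $K$
indicators sum to 1, which would make the Cholesky step singular), and with
$\mathbf r_{12}$ the indicator–score correlations and $\mathbf H_1$ the
Cholesky factor of the indicator correlation matrix,
$R_{CC}$ is the single singular value of
$\mathbf W = \mathbf r_{12}' \mathbf H_1^{-1}$. $R_{CC}$ is mathematically
the correlation ratio $\eta$ of the one-way layout of scores over distractor
groups; the test suite enforces both this identity (to $10^{-10}$) and
invariance to which indicator is dropped.

The traditional per-distractor indices are included for the boundary
conditions and for complete item-analysis reports:

* $PB_D = \frac{M_D - M}{S}\sqrt{\frac{P_D}{1-P_D}}$ — the point-biserial of
  choosing distractor $D$ against everyone, equal to the Pearson correlation
  between the choice indicator and the total score (the package uses the
  population SD, which makes the identity exact);
* $PB_{DC}$ — the same contrast restricted to the $D$-choosers plus solvers;
  well-functioning distractors give clearly negative values;
* $\omega_D$ — the Haladyna–Downing per-distractor omega: a goodness-of-fit
  $\chi^2$ of $D$'s choice counts across the realized ability groups against
  uniformity, scaled as $\sqrt{\chi^2 / n_D}$;
* Goodman–Kruskal $\gamma$ for *rising selection ratios*: over persons who
  solved the item or chose $D$, the probability of solving is estimated per
  rest-score level from the $2 \times J$ table; $\gamma$ counts concordant
  versus discordant level pairs (ties dropped). $\gamma = 1$ means the odds
  of solving versus choosing $D$ rise monotonically with ability. The
  default compares score levels unweighted; a frequency-weighted variant is
  available (`weighted = TRUE`).

### The 5% screen and NA taxonomy

A distractor must be chosen by at least 5% of *all* participants to be
retained (`min_rel_freq`, boundary inclusive); screened-out distractors are
excluded from every subsequent statistic. When fewer than two distractors
survive, $\omega_G$ and $R_{CC}$ are `NA` with reason
`insufficient_distractors`. The other reasons are `no_nonsolvers` (everyone
solved the item), `degenerate_groups` (fewer than two realized rows or
columns in the $\omega$ table) and `zero_variance` (no score spread among the
table's persons). Monte-Carlo summaries count `NA`s as missing effect sizes
rather than dropping them silently.

### Ability grouping with integer scores

Number-correct scores are small integers with heavy ties, so
interpolation-based quantiles are ill-defined. `ability_groups()` uses a
deterministic rule: breakpoint $k$ is the smallest observed score whose
empirical CDF reaches $k/G$, and each person joins the first group whose
upper breakpoint is at least their score. Ties are never split, which means
groups can fail to occur (this is deliberately visible: the study harness
reports group realization rates, and $\omega_5$ loses realized groups first).
For $\omega_G$ the quantiles are computed on the non-solver score
distribution by default — the contingency table contains only non-solvers,
so this keeps columns balanced; a flag (`grouping = "all"`) switches to
all-person quantiles, and the two differ little in practice.

## The Monte-Carlo study

`build_design()` crosses sample size {100, 200, 500} × items {10, 20, 50} ×
distractors {3, 7} × difficulty × discrimination × NRM level
(3·3·2·3·3·4 = 648 cells). Per replicate, `run_cell()` samples a bank,
simulates, and analyzes every item; per cell it pools item × replicate
records into

1. detection rates: the proportion of non-missing effect sizes strictly
   exceeding each threshold (0.10 / 0.30 / 0.50), with and without the
   boundary conditions (item mean $\gamma > 0.30$; item mean
   $PB_{DC} < -0.30$);
2. the proportion of distractors below the 5% screen;
3. missing effect-size rates (overall and attributable to the screen);
4. ability-group realization rates for $G = 2$ and $G = 5$.

`summarize_type1()` reports, over the zero-NRM cells, the percentage with
detection rate ≤ 0.05 per measure × threshold, plus an "all" row counting
cell × threshold combinations over {0.30, 0.50}. `summarize_power()` first
removes measure × threshold × facet combinations whose paired null cell was
unacceptable (matched on the non-NRM facets), then reports the percentage of
cells with power ≥ 0.80. `substance_summary()` averages the substance rates
with equal cell weights.

Reproducibility: every (cell, replicate) pair derives its own seed from the
master seed and the cell's position in the full cross (`derive_seed()`), so
cells can run in any order — or resume after interruption via the per-cell
CSVs that `cmd_study()` writes — with bit-identical output.

## Problem sizes used by the checks

The packaged checks are desk-scale versions of the full study:

* the worked-example datasets use N = 10,000 persons, 10 difficult items,
  three distractors, moderate 2PL discrimination, with zero versus high NRM
  discrimination — both banks share the same $\alpha, \beta, \zeta$ draws so
  the two examples differ only in $\lambda$;
* type-I summaries run all 162 null cells at 60–100 replicates (the
  percentages are pooled over items × replicates, so cell rates are already
  stable there);
* substance summaries run the 10-item stratum (216 cells) at 50 replicates:
  the sparse-distractor and missing rates are per-item quantities whose
  distribution does not depend on test length (items are i.i.d. given the
  cell), so the stratum mean estimates each NRM level's full-design mean
  without bias — this was verified empirically across test lengths.

## Numerical and design choices

* Inclusive boundaries throughout: retained at exactly 5% choice frequency;
  acceptable at exactly 0.05 type-I; adequate at exactly 0.80 power; strict
  `>` for threshold exceedance.
* $PB$ statistics use the population (divide-by-$n$) standard deviation so
  that the indicator-correlation identity is exact; the $PB_{DC}$ radical is
  $\sqrt{P_D/P_C}$ with both proportions inside the $D \cup C$ subgroup,
  which is precisely what makes $PB_{DC}$ the within-subgroup point-biserial.
* $R_{CC}$ caps at 1 (guarding $\eta$'s floating-point edge) and drops the
  last retained indicator; the $\eta$ identity guarantees coding invariance.
* $\gamma$ compares distinct score levels unweighted by default. With very
  large samples, sparse extreme score levels can still produce an occasional
  discordant pair, so empirical $\gamma$ can sit just below 1 even when the
  population satisfies rising selection ratios.
* Rising selection ratios is *not* implied by the 2PNL for strongly
  discriminating distractors: for a distractor with slope $\lambda_v$, the
  derivative of the log-odds of solving versus choosing $v$ is
  $\alpha - (\lambda_v - \sum_k w_k(\theta) \lambda_k)$, which is negative at
  low $\theta$ whenever the $\lambda$ span exceeds $\alpha$. High-NRM items
  can therefore legitimately show $\gamma < 1$ for their top-slope
  distractor.

## What the simulator does and does not emulate

The generator reproduces the study conditions: unidimensional normal
ability, items independent given ability, no guessing (the 3PNL/4PNL
extensions are out of scope), no missing data, and fixed $\lambda$ ladders.
Real pilot data bring multidimensionality, guessing on hard items,
position/speededness effects and non-normal ability — a green test suite
here shows the statistics behave as designed under the stated model, not
that they are robust to those violations. Parameter estimation for nested
logit models (and 2PL estimation for empirical tables) is deliberately not
included; the package is a screening tool upstream of such modelling.

## Known limitations

* Detection rates pool items and replicates within a cell; per-item power
  curves would need the retained item records (`retain_items = TRUE`).
* The worked-example statistics are single-item quantities and inherit one
  bank draw's luck; the package publishes the seed-derivation rule so any
  draw is exactly reproducible, but different seeds move the item-level
  values by a few hundredths.
* $\omega_5$ loses realized groups for short tests and small samples; its
  use is narrow, and the harness surfaces this through the group-realization
  rates rather than hiding it.
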