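---
title: "Dynamic feature-ratio networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic feature-ratio networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynratio)
```

## The problem

Repeated-measures omics time courses — the same subjects sampled at a handful
of time points while a disease progresses through stages — are awkward for
two-way methods: a sample-by-feature analysis at each time point ignores the
trajectory, while classical longitudinal models need more time points and
more subjects than a typical animal study provides (here: 7 model and 10
control rats over 7 time points). `dynratio` analyzes such data through the
*dynamics of pairwise feature ratios*. A ratio of two metabolite abundances
is a crude proxy for the net conversion between them, and — crucially for
small cohorts — it cancels any sample-level scaling (dilution, loading,
global inter-individual level shifts) that inflates the variance of single
abundances.

## The model

### Effective range

For an ordered feature pair $(i, j)$, $i < j$ in the canonical (input column)
order, the per-sample ratio at time $t$ is $r_{ijt} = f_{it} / f_{jt}$. Its
*effective range* at time $t$ is the interval

$$[\,u_{ijt} - 2 p_t \gamma \sigma_{ijt},\; u_{ijt} + 2 p_t \gamma
\sigma_{ijt}\,]$$

with $u$ and $\sigma$ the sample mean and standard deviation over the $n_t$
samples at that point, $\gamma = \sqrt 3 \approx 1.732$, and $p_t = n_t /
(n_t + n_{t+1})$ the point's *sample probability* in the network being built
from points $t$ and $t+1$. With equal samples at both points, $p_t = 1/2$ and
the range reduces to $u \pm \gamma\sigma$; by Chebyshev's inequality it then
contains at least $1 - 1/\gamma^2 = 2/3$ of the population. For normally
distributed ratios the expected coverage is $2\Phi(\sqrt 3) - 1 \approx
0.917$, which the test suite verifies empirically.

Numerical conventions: $\sigma$ uses the divisor $n$ (population form,
matching a definition that sums over the $n$ repeated measures without a
Bessel correction; `sd_divisor = "n-1"` switches it). $p_t$ is applied
symmetrically to both sides of the interval — the only choice that keeps the
range centred on $u$.

### The non-overlapping ratio (NOR)

Between adjacent time points a range can (1) shift up — floor and ceiling
both strictly increase, (2) shift down — both strictly decrease, or (3) be
nested in (or identical to) the other range. Only the first two cases carry a
direction; nested/identical ranges are excluded. For a directed change with
range lengths $L_1$, $L_2$ and overlap $O = \max(0, \min(\text{ceilings}) -
\max(\text{floors}))$,

$$|\mathrm{NOR}| = \frac{L_1 + L_2 - 2O}{L_1 + L_2}, \qquad
\mathrm{sign} = \begin{cases} + & \text{upshift} \\ - &
\text{downshift.} \end{cases}$$

$|\mathrm{NOR}| \in [0, 1]$, equals 1 exactly when the ranges are disjoint,
is antisymmetric under time reversal, and is invariant to rescaling either
feature (ranges scale linearly). Degenerate ranges ($\sigma = 0$, a point)
follow the same geometry: two separated points are disjoint ($|\mathrm{NOR}|
= 1$); a point inside the other range is nested and undefined. These
conventions are isolated in `classify_change()` / `nor_value()` so an
alternative closed form would be a one-function change.

### Dynamic networks and their analysis

`network_series()` builds $N - 1$ graphs: in network $DN\!-\!t$ features $i$
and $j$ are linked when the NOR of $r_{ij}$ between $t$ and $t+1$ satisfies
$\mathrm{NOR} \ge \tau$ (red edge, ratio rising) or $\mathrm{NOR} \le -\tau$
(green, falling), default $\tau = 0.85$ — i.e. nearly disjoint ranges. Every
retained feature is a node in every network, so degree tables are comparable.

Two analyses extract early-warning candidates ahead of the onset point $T_s$
(the typical time point of the final disease stage):

* **Dynamic concentration** (`dynamic_concentration()`): keep ratios whose
  edge persists *with the same sign* in every network $DN\!-\!i$, $s - N_e
  \le i < s - 1$. The upper bound is exclusive at $s - 1$, so for $s = 7$,
  $N_e = 3$ the window is $\{DN\!-\!4, DN\!-\!5\}$ — the window ends with the
  network that spans the onset transition, which is the semantics that makes
  a three-point look-back examine exactly the two transitions leading into
  the onset.
* **Topological structure** (`topological_structure()`): take the network
  with the most edges (the key transition), rank its nodes by degree, and
  return all ratios incident to the top $k$ nodes (default $k = 1$). Degree
  ties break by larger accumulated degree across all networks (a node that is
  busy throughout the course outranks one busy only at the key transition),
  then by canonical feature order for determinism. Ties for the max-edge network resolve to the
  earliest, with a warning; small synthetic cohorts hit this tie regularly
  (every post-onset transition links the planted features to everything),
  which is why the warning is informative rather than an error.

`combine_subsets()` intersects (default) or unites the two subsets.

### Static filter

Before any ratio is formed, non-informative features are removed by linear
SVM-RFE on every stage-pair sub-problem ($N_s (N_s - 1)/2$ of them), using
the model-group samples at the two stages' *typical* (last) time points. Each
RFE iteration fits a linear SVM (cost 1), ranks features by squared
hyperplane weight on standardized data, and removes the lowest
`ceiling(elim_fraction * current)` features (default `elim_fraction = 0.1`,
minimum 1, a common RFE step size; the step fraction is a free parameter of
the filter). The best subset of a run is the one with maximal 5-fold CV
accuracy, ties to the smaller subset. Because the elimination path is fitted
on the full sub-problem data it is deterministic; repeated runs (default 50)
differ only in fold assignment, and the per-sub-problem selection is the set
of features appearing in at least half of the runs' best subsets (an
unstated aggregation; selection frequency is deterministic given the seed and
robust to fold noise). The union over sub-problems, in canonical order, feeds
the network stage.

### Evaluation

Candidates are screened univariately: Welch two-sample t-tests model vs
control at every disease-stage time point, and paired t-tests between the
pre-onset reference point and every disease-stage point (model group).
"Significant at any disease-stage point" is read as *every* comparison
passing $p < 0.05$ simultaneously — the conservative rule, under which every
reported p-value is itself evidence. No multiplicity
correction is applied by default, keeping the screen a plain per-test rule; a
`p.adjust` method can be switched on. ROC analysis labels model-group
samples at the disease-stage points positive and all earlier model samples
negative; the AUC is the Mann–Whitney pair-counting estimator (ties one
half), its standard error Hanley–McNeil, and the operating point the Youden-J
maximizer with ties broken toward specificity ("best cut-off" is otherwise
undefined). PCA summaries are autoscaled and report the variance captured by
the first two components.

## The synthetic cohort generator

No public cohort of this design is available, so `generate_cohort()`
emulates the study layout the method targets: 10 control + 7 model subjects, 7 time points, stages
H (T1), CIR (T2–T4), HCC (T5–T7) — 119 samples — plus a validation variant
(6 model subjects, 6 points, 36 samples). Abundances are log-normal:

$$\log f_{sit} = \beta_i + b_s + \delta_{it} \cdot [\text{model}] +
\varepsilon_{sit}$$

* $\beta_i \sim U(1, 3)$: per-feature baseline.
* $b_s \sim N(0, \texttt{subject\_sd}^2)$, default 1.2: a subject-level
  offset *shared across features* (global level/dilution differences). It
  cancels exactly in every ratio — the core argument for ratio markers —
  while making single abundances poor classifiers, as in real serum
  lipidomics where inter-individual variation dwarfs technical noise. With a
  small value here the planted features would separate the stage sub-problems
  perfectly on their own, and the RFE rule "max CV accuracy, ties to the
  smaller subset" would collapse every best subset to a single feature — a
  degenerate regime real cohorts are not in.
* $\delta_{it}$: the planted signal. For the planted pair the numerator
  gains `log_fold_shift` (default 0.6) *per time point* from `shift_onset`
  (default 5, the HCC onset) onward, and the denominator loses the same;
  a cumulative ramp rather than a single step, because a level change
  produces only one shifted transition whereas persistence across the
  post-onset networks (what the concentration analysis detects) requires the
  ratio to keep moving. One pair is planted by default: with several, any
  up-numerator/down-denominator cross combination is an equally shifted
  ratio and "the planted pair" stops being identifiable.
* $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$, default 0.1 (~10% CV,
  typical post-normalization technical + short-term biological noise).

The default effect size follows from the NOR geometry, not from tuning: the
log ratio has scale $\sqrt 2 \cdot \texttt{noise\_sd}$, adjacent ranges at
$p = 0.5$ extend $\gamma\sigma$ to each side, and $|\mathrm{NOR}| \ge 0.85$
requires near-disjointness, i.e. a per-step log shift of roughly $2 \times
0.925 \times \gamma \times \sqrt 2 \times \texttt{noise\_sd} \approx 4.5
\times \texttt{noise\_sd}$. The default $0.6 = 6 \times \texttt{noise\_sd}$
clears this with margin; a "3×noise" shift, sometimes quoted as a strong
effect for mean-difference statistics, is *below* the detection boundary of
an interval-disjointness statistic.

What the generator does not emulate: chromatographic drift, batch effects,
missing values, correlated lipid families, heavy-tailed noise. Passing
recovery tests therefore demonstrates internal consistency of the pipeline
under its own assumptions, not performance on real LC-MS data.

```{r generator, eval = FALSE}
sim <- generate_cohort(generator_config(seed = 1))
design <- stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7,
                       lookback = 3)
run <- run_pipeline(sim$dataset, design, seed = 1)
glance(run)
```

## Degenerate inputs and numerical choices

* Abundances must be strictly positive; missing values are rejected at
  load time (ratios and standard deviations are undefined with them, and
  imputation policy belongs upstream).
* Zero-variance ratios give point ranges, handled by the degenerate-range
  conventions above; a network over a constant dataset is empty and the
  topology stage reports it as an error rather than inventing a hub.
* Unbalanced designs are accepted with a warning; each time point uses
  whichever samples exist, and $p_t$ absorbs the imbalance.
* Paired tests with fewer than two complete pairs, or zero-variance
  differences, report `NA` and fail the conservative screen.
* All randomness (fold splits, simulation) is seed-controlled through
  `withr::with_seed`, so identical inputs and seeds give bit-identical
  outputs.

## Problem sizes in the test suite

The suite exercises the full pipeline at the emulated study design (119
samples, 40 features) with 15 RFE repeats per sub-problem in the recovery
experiments and 8 elsewhere — enough for stable selection frequencies at
these sample sizes while keeping a full 10-seed recovery run in the
low minutes on a single core; the packaged default of 50 repeats is
recommended for real analyses. Property suites use
200–1000 randomized cases per invariant.

## Known limitations

* The NOR compares *interval geometry*, so it is sensitive to the standard
  deviation estimate at each point; with 7 samples per point the ranges are
  noisy, and $\tau = 0.85$ deliberately demands near-disjointness.
* Degree is the only centrality considered, by design.
* The concentration window semantics are fixed to the literal reading
  $s - N_e \le i < s - 1$; a window that excludes the onset-spanning network
  would need a different bound.
* The filter's best-subset rule favours minimal subsets; on perfectly
  separable data it legitimately returns very few features, and the ratio
  stage then has few pairs to work with.
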