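---
title: "Adaptive randomization: the boundary model, its weights, and what the simulator shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive randomization: the boundary model, its weights, and what the simulator shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrand)
```

## The allocation model

`adaptrand` implements a dynamic (covariate-adaptive) allocation scheme
for sequentially recruited trials.  Each time a participant arrives, the
probability of assigning them to each treatment group is recomputed from
the allocations made so far, so that groups that have drifted away from
the target ratio — overall, within the participant's level of each
stratification variable, or within their stratum (the cell of the full
cross-classification of all stratification variables) — become more
likely to receive the new participant.  A single uniform draw against
the resulting cumulative boundaries then decides the assignment, so
every allocation remains genuinely random.

For two groups A and B with target ratio $r_A : r_B$, the boundary for
an arriving participant is built in four steps:

1. **Odds.** The allocation odds are $o = r_A / r_B$ (2:1 gives $o=2$,
   1:1 gives $o=1$).

2. **Differences.** At every relevant level $\ell$ — overall, the
   participant's level of each stratification variable, and the
   participant's stratum — with current counts $n_A^{(\ell)}$ and
   $n_B^{(\ell)}$, compute
   $$d_\ell = \frac{o\,n_B^{(\ell)} - n_A^{(\ell)}}{o}.$$
   $d_\ell$ is positive exactly when A holds fewer allocations at that
   level than the ratio warrants.

3. **Weighted signed squares.** Each difference enters the total through
   $$t_\ell = w_\ell \, \mathrm{sign}(q_\ell)\, \frac{q_\ell^2}{o},
   \qquad q_\ell = o\,n_B^{(\ell)} - n_A^{(\ell)},$$
   i.e. $w_\ell\,\mathrm{sign}(d_\ell)\, o\, d_\ell^2$, and the total
   imbalance is $a = \sum_\ell t_\ell$.

4. **Logistic.** The probability of assigning the participant to A is
   $$p_A = \frac{o\,e^{a}}{1 + o\,e^{a}},$$
   which equals the ratio proportion $r_A/(r_A+r_B)$ at $a = 0$ and
   increases strictly with $a$.

Squaring makes large imbalances count disproportionately more than
small ones; the sign keeps the direction of the correction; the weights
decide how much each level matters.

### Two readings of the squaring step

Step 3 can be read two ways: square the step-2 difference itself
($w\,\mathrm{sign}(d)\,d^2$) or square the numerator and rescale by the
odds ($w\,\mathrm{sign}(q)\,q^2/o = w\,\mathrm{sign}(d)\,o\,d^2$).  The
two coincide whenever $o = 1$, which covers every equal-allocation
trial, and differ by the factor $o$ otherwise.  The engine's default is
the odds-scaled form, because it is the form whose arithmetic the
canonical worked boundary values of this method follow (a 2:1 example
with totals $-1.1$, $-11$ and $-0.11$ across weight scales, reproduced
exactly in this package's test suite).  The plain-difference form
remains available for sensitivity analysis through
`squaring = "difference"` on `imbalance_term()`, `total_imbalance()`,
`group_probabilities()`, `allocate_participant()` and the simulator
functions.

### More than two groups

The four steps define a two-group boundary.  For $k > 2$ groups the
engine computes each group's probability **one-vs-rest**: group $g$
plays the role of A with odds $o_g = r_g / (R - r_g)$, where
$R = \sum_j r_j$, and the pooled counts of all other groups play the
role of B; the $k$ resulting probabilities are then renormalized to sum
to one and turned into cumulative boundaries in declared group order.
Two properties motivated this choice over alternatives (e.g. pairwise
tournaments):

* at $k = 2$ it reduces *exactly* to the base method —
  $o_A = r_A/r_B$, and the pooled "rest" is just B, with the identity
  $p_B = 1 - p_A$ holding analytically (property-tested to $10^{-12}$);
* at zero imbalance $o_g/(1+o_g) = r_g/R$, so every group receives
  exactly its ratio proportion and the renormalization is a no-op.

The one-vs-rest construction is nevertheless one consistent choice
among several that the two-group definition does not pin down, which is
why split probabilities quoted for three-group set-ups elsewhere are
treated as soft checks rather than reproduction targets.

## Choosing weights

All weights are non-negative multipliers, one for the overall level,
one per stratification variable, one for the stratum level; they have
no units.  Two exact limits frame their interpretation:

* **All weights 0** — every boundary is the fixed ratio proportion:
  simple randomization.  The implementation returns the exact ratio
  proportion (not a rounded logistic evaluation) whenever the total
  imbalance is exactly zero, so this limit holds bit-exactly.
* **Very large weights (≈ 10) on a 1:1 unstratified trial** — any
  deficit of one allocation drives $|a|$ to 10 and the probability of
  the over-represented group below $5 \times 10^{-5}$: the sequence
  behaves like permuted blocks of size two.  (With stratification
  variables present, imbalances at different levels can pull in
  opposite directions, so even extreme weights do not guarantee an
  exact final split.)

Between the limits, the stratum weight is usually chosen largest and
the overall weight smallest, because the stratum holds the fewest
participants and a given absolute imbalance is most damaging there.
The bundled `scenario_spec(1:4)` regimes (strong 1/2/2/5, medium
0.1/0.2/0.2/0.5, weak 0.01/0.02/0.02/0.05, and all-zero) span the
practical range: the strong regime buys near-certain final balance at
the cost of predictability (roughly two-thirds of its computed
boundaries are below 0.10 or above 0.90, and with integer weights the
imbalance total is an integer, so four interior probability intervals
are structurally empty), while the weak regime leaves the boundaries
near the ratio proportion almost always and still prevents the extreme
splits that simple randomization permits.  `summarize_trials()` exists
precisely so that these trade-offs can be quantified for a candidate
weight set before recruitment starts.

## Numerical and interface choices

* **Assignment rule.** Intervals are half-open and lower-inclusive: a
  draw $u$ assigns the first group $g$ with $u < \text{cumulative}_g$.
  The top boundary is pinned to 1 so a draw of $0.999\ldots$ cannot
  fall off the end.
* **Zero imbalance.** When $a = 0$ the probabilities are returned as
  exact ratio proportions `ratio/sum(ratio)`, avoiding the one-ulp
  round-off of evaluating the logistic and its renormalization.
* **Saturation.** The exponent is clamped at $\pm 700$; beyond it the
  probability is exactly 0 or 1.  All internal comparisons use full
  double precision; equality checks on invariants use $10^{-12}$.
* **State and audit.** The allocation state caches counts at every
  level; the durable record is the CSV allocation log (one row per
  participant with the probabilities at full 17-digit precision, the
  uniform draw and the assignment).  `replay_log()` rebuilds the state
  from the log and, by default, verifies that every recorded
  probability and assignment agrees with a fresh recomputation, so a
  truncated or hand-edited log, or a log replayed against the wrong
  configuration, fails loudly.  Duplicate participant identifiers are
  rejected: no participant can be randomized twice.
* **Configuration.** Trial set-ups are YAML documents (groups, ratio,
  variables, weights, optional seed) read by `read_trial_config()`;
  unknown keys — including misspelled weight names — are rejected
  rather than ignored.  Weights are serialized at 17 significant
  digits so configurations round-trip losslessly.
* **Seeding.** `simulate_trials()` derives one sub-seed per replicate
  from the master seed, so replicate $r$ can be reproduced in
  isolation; every interactive allocation records its uniform draw, so
  a trial is replayable without knowing the generator state.

## What the simulator emulates — and what it does not

`simulate_trials()` allocates streams of synthetic participants whose
stratification profiles are drawn independently per participant and per
variable from a `covariate_model()` (uniform over levels by default,
overridable per variable).  This emulates the idealized recruitment
that the method's published operating characteristics assume.  It does
**not** emulate several features of real recruitment: covariate
dependence (e.g. center and age correlated), unequal center sizes
unless configured, time trends in the covariate mix, or variables whose
levels arrive *sequentially* rather than randomly (recruitment cohorts
— one reason the bundled three-group `swad_spec()` is a soft check).
Passing the distributional checks therefore shows that the engine
reproduces the method's operating characteristics under the stated
covariate model, not that any particular real trial will achieve them.

The package's own verification uses problem sizes chosen to make
sampling error small relative to the quantities checked: 1,000
replicates of 50-participant trials for the four weighting scenarios
(50,000 boundaries per scenario), 1,000 replicates of the
549-participant equal-allocation fixture, an exhaustive enumeration of
all $2^6$ allocation sequences of a six-participant trial checked
against 100,000 simulated replicates, and 3-binomial-SE acceptance
bands throughout.  These sizes match the scale at which the method's
published summaries were produced, and at desk scale they complete in
well under a minute.

## Known limitations

* Weights are fixed for the life of the trial; the engine is
  covariate-adaptive, not response-adaptive.
* Stratification variables must be discrete; continuous covariates
  (age, time since diagnosis) must be banded before the trial starts.
* The $k>2$ construction is a consistent generalization, not the only
  one; cross-package comparisons of multi-group boundary values should
  expect differences in the third decimal place and beyond.
* The imbalance total weighs levels only through their weights: two
  stratification variables with very different numbers of levels
  receive no automatic compensation, which is why simulation before
  recruitment (and weight adjustment in response) is part of the
  intended workflow.
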