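# adaptrand

Covariate-adaptive dynamic randomization for clinical trials.

Trials that recruit sequentially face a tension: simple randomization is
unpredictable but can leave the treatment arms badly unbalanced —
overall, within a stratification variable such as gender or center, or
within a stratum (one cell of the cross-classification of all
stratification variables) — while deterministic schemes keep balance
but let an unblinded recruiter anticipate the next assignment.
`adaptrand` implements a dynamic allocation engine that recomputes the
assignment probabilities for *every arriving participant* from the
imbalances accumulated so far, at all of those levels simultaneously,
and then assigns by a single uniform draw.  It is aimed at trial
statisticians and randomization-service developers who need a
configurable, auditable allocation engine plus a simulator for choosing
its weights before recruitment starts.

## The method

For two groups with target allocation ratio $r_A : r_B$ and odds
$o = r_A/r_B$, the probability of assigning an arriving participant to
group A is

$$p_A = \frac{o\,e^{a}}{1 + o\,e^{a}}, \qquad
  a = \sum_{\ell} w_\ell \,\mathrm{sign}(q_\ell)\,\frac{q_\ell^2}{o},
  \qquad q_\ell = o\,n_B^{(\ell)} - n_A^{(\ell)},$$

where $\ell$ runs over the levels relevant to that participant — the
overall totals, their level of each stratification variable, and their
stratum — $n_A^{(\ell)}, n_B^{(\ell)}$ are the current counts at level
$\ell$, and $w_\ell \ge 0$ are user-chosen weights.  At perfect balance
($a=0$) the participant gets exactly the ratio proportion
$r_A/(r_A+r_B)$; a deficit of A at any weighted level raises $p_A$.
With all weights 0 the engine *is* simple randomization; with very
large weights on an unstratified 1:1 trial it behaves like permuted
blocks of size two.  For $k>2$ groups each group's probability is
computed one-vs-rest with odds $r_g/(R-r_g)$ and renormalized; at
$k=2$ this reduces exactly to the formula above.  The methods vignette
(`vignettes/adaptive-randomization.Rmd`) derives and discusses all of
this.

## A worked allocation

Twelve participants are already allocated 8:4 in a 2:1 trial stratified
by gender and center; the 13th participant is female and from center Z:

```r
library(adaptrand)

spec <- trial_spec(
  groups    = c("A", "B"),
  ratio     = c(2, 1),
  variables = list(gender = c("M", "F"), center = c("X", "Y", "Z")),
  weights   = list(overall = 0.1,
                   variables = c(gender = 0.2, center = 0.2),
                   stratum = 0.5))

state <- state_from_counts(spec, example_counts_12())
total_imbalance(c(gender = "F", center = "Z"), state, spec)
#>     level  at n_a n_b weight difference term
#> 1 overall       8   4    0.1        0.0  0.0
#> 2  gender   F   4   2    0.2        0.0  0.0
#> 3  center   Z   3   1    0.2       -0.5 -0.1
#> 4 stratum F/Z   2   0    0.5       -1.0 -1.0
```

The trial is on-ratio overall (8:4) and within gender (4:2), but center
Z (3:1) and especially the stratum female–Z (2:0) are over-allocated to
A, so the total imbalance is $-1.1$ and the boundary shifts towards B:

```r
group_probabilities(c(gender = "F", center = "Z"), state, spec)
#> Allocation probabilities:
#>      A      B
#> 0.3997 0.6003
#> cumulative boundaries: 0.3997 | 1.0000

set.seed(2026)
allocate_participant(c(gender = "F", center = "Z"), state, spec, id = "P13")$record
#>   seq  id gender center      p_A      p_B         u group
#> 1  13 P13      F      Z 0.399667 0.600333 0.6986735     B
```

The participant's chance of A has dropped from the unconditional 2/3 to
0.40; the uniform draw 0.699 falls above the 0.3997 boundary, so P13
goes to B.  Every draw, probability and assignment is recorded, and
`append_log()` / `replay_log()` give a durable CSV audit trail that
replays to the identical state.

## Simulating a weight choice

```r
sims <- simulate_trials(scenario_spec(2), n = 50, replicates = 1000, seed = 1)
head(summarize_trials(sims, checkpoint = 12)$final_split)
#>   A  B trials
#>  23 27      8
#>  24 26    235
#>  25 25    538
#>  26 24    200
#>  27 23     19
```

Under the medium weighting regime, 538 of 1,000 simulated
50-participant 1:1 trials end exactly 25:25 and none strays beyond
23:27.  `summarize_trials()` also reports within-level imbalance
histograms, the distribution of every computed boundary (a
predictability diagnostic), longest same-group runs, and interim splits
at a checkpoint.  Ready-made specifications are bundled: the four
weighting scenarios (`scenario_spec(1:4)`), a 549-participant 1:1
multi-variable trial (`folated_spec()`), a 2:1 unequal-allocation trial
(`epic_spec()`) and a three-group 2:2:1 trial (`swad_spec()`), plus
their YAML configuration files under `inst/extdata/`.

A command-line front end (`inst/cli/adaptrand`) wraps the same
functions: `init` writes a template configuration, `randomize` allocates
one participant against a config and CSV log (with `--blind` printing
only a confirmation token), `simulate` writes the summary tables as CSV
files, and `report` tabulates the current splits from a log.

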