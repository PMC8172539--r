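---
title: "Models and methods behind impulscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind impulscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impulscreen)
```

`impulscreen` implements two connected analyses: a single-cell screen that
prioritises GPCR genes by selective expression in a target cortical cell
population, and the scoring and drug statistics of the 5-choice serial
reaction time task (5-CSRTT). This vignette describes the models, the
parameters that matter, and the design decisions behind them.

## The differential-expression screen

### Cell sets

A comparison opposes a target set (Set-T) to a contrast set (Set-C). Set-T
is either the reporter-positive glutamatergic cells (the fluorescence pull
used to label layer-5 projection neurons) or all cells of the layer-4/5 IT
transcriptomic clusters. Set-C grows in three levels of conservativeness:
GABAergic cells only; plus non-neuronal cells and layer-6 glutamatergic
clusters; plus layer-2/3 glutamatergic clusters. A cell eligible for both
pools — a reporter-positive layer-2/3 cell at level 3, say — is kept in
Set-T and removed from Set-C, because the contrast population is meant to
exclude the target class by construction. The full grid is
2 modes × 3 levels = 6 comparisons; `screen_grid()` runs them all. The
human-data variant of the analysis is pure configuration: cluster-name
regular expressions are arguments of `build_comparison()`, and sensory GPCRs
can be excluded in `rank_candidates()`.

### Per-gene measures

With `GE_S` the arithmetic mean CPM of a gene over set S:

* `expr_S = log2(1 + GE_S)` — the pseudocount makes a fully silent gene score
  exactly 0.
* `Diff_Mean = expr_T − expr_C`. The fold criterion is evaluated as
  `(1 + GE_T)/(1 + GE_C) ≥ fold_min` (`fold_min = 3` by default,
  `tenfold = 10` for the secondary flag). A plain ratio of means
  `GE_T/GE_C` and the pseudocounted ratio disagree only near zero
  expression, where the plain ratio is unstable or undefined; using the
  pseudocounted form everywhere gives one definition that is finite for
  `GE_C = 0` and converges to the plain ratio (and to the familiar
  `log2(fold-change) > 1.58` threshold for threefold) as expression grows.
* Detection fractions `pct_S`: the share of cells at CPM ≥ 1. Note that
  `log2(1 + CPM) ≥ 1` selects exactly the same cells, so the choice of scale
  for thresholding is immaterial; the threshold is applied on CPM.
* `Beta = sign(Diff_Mean)·|pct_T − pct_C|`, with `sign(0) = 0`. Beta is kept
  as a fraction in `[−1, 1]` internally; report writers may scale to
  percentage points.

### Testing

Significance comes from a two-sided Wilcoxon rank-sum test per gene on the
per-cell values (rank-based, hence identical on CPM and on log-transformed
CPM). Implementation details that matter numerically:

* ties are handled with midranks and the tie-corrected normal approximation
  with continuity correction;
* when the smaller set has ≤ 8 cells and the gene has no tied values, the
  exact U null distribution is used instead;
* a gene that is constant across both sets is assigned p = 1 directly — no
  degenerate statistic is computed;
* Bonferroni correction defaults to the number of genes in the matrix
  (matching a transcriptome-wide export); the family size is configurable,
  e.g. 402 for a GPCR-only family. Which family the original viewer export
  used is not stated anywhere, so both are legitimate configurations.

The test suite pins the implementation to an exhaustive-permutation oracle on
all set sizes from 2 to 6 (to 12 decimal places) and to
`stats::wilcox.test` on tied data; the normal approximation is required to
track the exact oracle within 0.02 on 5-vs-5 instances.

### Candidate ranking

`rank_candidates()` keeps GPCR genes passing the primary criteria in every
required comparison and matching the coupling filter (Gi by default: the
cascade whose activation in the target cells is the therapeutic direction).
The sort key is descending minimum `Diff_Mean` across required comparisons,
then descending minimum `Beta`, then ascending maximum contrast expression
(a good target is silent off-target), with an alphabetical tie-break for
determinism.

## The 5-CSRTT engine

### Trial cycle

A trial starts at ITI onset. Any hole poke during the ITI is premature and
triggers a timeout; at ITI end the stimulus lights one pseudo-randomly chosen
hole for the stimulus duration (SD), and the first poke inside the half-open
response window `[stim_on, stim_on + SD + LH)` is correct or incorrect; no
poke is an omission. Correct trials deliver a reward; the next ITI starts at
receptacle exit, otherwise at timeout end. Premature trials count toward the
trial total — the denominator of `%premature` includes them.

Boundary conventions are deliberately strict: the response window is
half-open, so a poke exactly at `SD + LH` is an omission; the premature
window is `[iti_start, stim_on)`. Pokes during timeouts belong to no trial
and are tallied in a separate counter; receptacle pokes during the ITI are
ignored (neither restarts the trial — the acquisition systems this engine
abstracts differ on such details and none is printed, so the simplest
deterministic rule wins). Perseverative pokes are a per-trial flag only and
never trigger a timeout of their own.

### The simulated agent

`agent_params()` defines a competing-risks generative model: premature pokes
as a Poisson process (rate `premature_hazard`, so
`P(premature) = 1 − exp(−hazard · ITI)`), detection/omission coin flips,
log-normal response latency truncated at the response window, accuracy as a
choice between the lit hole and a uniform other hole, log-normal reward
latency, and a perseveration probability. Latency distributions are
log-normal by default; any positive distribution matching the
location/scale contract could be substituted. Reward collection always
succeeds (collection failure is out of scope). Drug conditions act through
multiplicative factors on the hazard, the omission probability and the
latency locations — a Gi-like anti-impulsive manipulation is a hazard
multiplier below 1, a Gq-like pro-impulsive one above 1.

Defaults (hazard 0.05/s, detect 0.95, omit 0.15, accuracy 0.8, latencies
around 0.8 s and 1.2 s) yield ~30–40% premature trials in a 9-s fixed-ITI
challenge and accuracies near 80%, i.e. a plausibly challenged but engaged
animal. The variable-ITI preset draws from {2, 5, 7.5, 12.5} s with equal
weights — an explicit stand-in, since no actual duration set is printed.

The simulator emits a timestamped event log in the package's minimal CSV
dialect (`time_s, event, arg`) and carries hidden per-trial ground truth;
`classify_trials()` replays the state machine over the log with no access to
that truth. Their agreement is required to be exact: over 1000 seeded
sessions spanning random agents and all protocol presets, every classified
outcome must equal the simulator's. A session ends at `session_length`
(default 1800 s); a trial whose outcome is undecided at that point is
dropped by both sides of the comparison.

### Challenge statistics

Per subject and parameter, the drug value is normalised to the same
subject's vehicle value and log10-transformed. The two parameters that can
legitimately be 0% (`%premature`, `%perseverative`) are first floored to the
next full integer — `floor(x) + 1`, so `0.5 → 1` and `1.0 → 2`; the
published band definitions force the integer-input case upward, which is why
this is not `ceiling()`. Flooring is applied to drug and vehicle values
symmetrically, as the transform is defined for all analyses of those
parameters. Group-level inference is a one-sample t-test of the log-ratios
against 0 with a t-based 95% confidence interval (the interval level is an
assumption — figures in this literature display unlabelled C.I.s — and is
configurable). Sidak adjustment (`1 − (1 − p)^m`) is provided as a
function; which comparisons form a family follows the omnibus ANOVA
structure, which is out of scope here, so family composition is the
caller's decision. Pearson correlations between the premature log-ratio and
the other parameters' log-ratios screen for confounds (sedation would show
up as correlated omission/latency changes). Whether latency parameters
should enter as per-subject medians or means is not specified anywhere;
both are computed and carried.

## Synthetic data

### Expression

The generator draws per-gene baseline mean CPM log-normally
(`meanlog 0.5, sdlog 1.2`), links detection probability to expression via
`d = m/(m + 3)` jittered on the logit scale, and gives detected cells
log-normal values whose conditional mean preserves the gene's unconditional
mean — a dropout-with-amplification caricature of SmartSeq-style single-cell
data. CPM is the input contract of the screen, so no read-depth or count
layer is modelled; a negative-binomial count layer would be an extension,
not a correction. Non-planted GPCR genes share the background distribution —
there is no GPCR-specific background to emulate.

The default cluster roster totals 5190 cells with 1238 L4/5-IT cells and a
676-cell reporter pull overlapping in 502 cells — the printed set sizes of
the reference dataset. The printed contrast-pool size (3514) cannot be
reproduced simultaneously with those constraints, because the ~440
non-target, non-contrast glutamatergic cells must live somewhere; the
roster's level-3 contrast pool comes out at 3714. Planted markers are
implanted in the union of target-cluster and reporter cells with configured
detection fractions and a conditional mean chosen so the target/contrast
mean ratio equals the requested fold in expectation.

What the generator does **not** emulate: cluster substructure and
between-cluster expression correlations, batch effects, library-size
variation, and the real taxonomy's label granularity. Passing the screen's
calibration and recovery tests on this model therefore demonstrates that the
statistics behave as designed — not that the screen's published gene counts
would be reproduced on the real data, which would require the external
dataset itself.

### Cohorts

`make_cohort()` applies log-normal subject random effects (sd 0.3 on the log
scale) to the premature hazard and to both latency locations, shared across
conditions so the within-subject design is honest, then simulates each
subject × condition session. Ground truth records each subject's realised
parameters. Probability parameters are left at their group values: random
effects compose multiplicatively only where the scale is unbounded.

## Problem sizes and determinism

Every stochastic entry point takes a seed, and pipeline stages derive their
seeds from one global seed by label hashing (`derive_seed()`), so any stage
can be reproduced in isolation and `run_discovery_demo()` is bit-identical
under a fixed seed; outputs are stamped with a configuration hash that
`verify_bundle()` checks. The shipped validation suite uses: the full
2000-gene, 200 + 200-cell null screen over 100 seeds for calibration; 50
replicates of a 1000-gene planted-marker recovery at ≥ 100 cells per set;
1000 sessions for simulator/classifier agreement; and 100 + 100 simulated
cohorts (n = 12) for effect-direction recovery and type-I control — sizes
chosen to keep the binomial confidence bands tight while the whole suite
runs comfortably on a laptop. The demo defaults (2000 genes, quarter-scale
roster) are similarly demo-sized; generator defaults are the full study
scale.

## Known limitations

* The screen consumes CPM and cluster labels as given: no normalisation from
  raw counts, no clustering, no embedding computation, no cross-species
  ortholog mapping.
* The omnibus repeated-measures ANOVA/ANCOVA layer around the challenge
  statistics is intentionally not implemented; standard mixed-design tools
  exist, and only the bespoke normalisation feeding them lives here.
* Training-stage curricula, video-tracking assays and dose-response
  modelling are out of scope.
* The event-log dialect is the package's own minimal CSV; adapters for
  vendor formats are an extension point, not core.
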