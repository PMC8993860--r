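---
title: "Models and methods: simulating conditioned value learning and its behavioral use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating conditioned value learning and its behavioral use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condval)
```

`condval` implements a generative model of children performing a
probabilistic Pavlovian conditioning task and an instrumental
approach–avoid task, together with the inference chain a study of
value-based learning would run on the resulting data. This vignette is the
package's account of the models, their assumptions, the tunable parameters,
and the design decisions taken where the underlying paradigm leaves the
mechanism open.

## The task design

A session pairs five geometric cues with five outcome conditions: points
and a positive image (appetitive, valence +1), an aversive noise and a
negative image (aversive, −1), and a neutral condition (0). Each condition
contributes 14 trials, 70 per session, in uniform-random order within
participant. A non-neutral trial delivers its reinforcer with probability
0.8 and a scrambled neutral image otherwise; neutral trials always show the
scrambled image. Trial timing is a 1.5 s cue window, a 6 s delay, a 1.5 s
outcome, and a uniform 2.5–5.5 s inter-trial interval; onsets accumulate
from t = 0. Cue–condition pairings are counterbalanced across participants
by the deterministic cyclic Latin square (`build_latin_square()`), row
`participant mod 5`; any Latin square satisfies the counterbalance, and the
cyclic one makes the assignment reproducible.

Two reinforcement modes are supported because the paradigm's "probability
of 0.8" can be read either way: independent Bernoulli draws per trial (the
default, matching the probabilistic wording) or a fixed
`round(0.8 × 14) = 11`-of-14 ratio per condition (`exact_ratio = TRUE`),
useful when a test fixture needs exact counts. Outcome bookkeeping uses the
full 1.5 s cue window for onset arithmetic; the agent's RT (capped at the
window) is a response latency, not a schedule perturbation.

## The agent

Learning is the Rescorla–Wagner delta rule, `V ← V + α(r − V)`, with reward
coding `r = +1` for a delivered appetitive reinforcer, `−1` for a delivered
aversive reinforcer, and `0` for the scrambled image. This is the minimal
model consistent with a single learning-rate parameter; values start at 0
per cue and remain in [−1, 1].

Each behavioral read-out has its own expression parameters:

| parameter | units | default | role |
|---|---|---|---|
| `alpha` | — | 0.2 | learning rate (speed of integration of recent outcomes) |
| `rt_base_ms` | ms | 650 | baseline simple RT to the cue |
| `rt_gain_ms` | ms | 200 | RT speeding per unit salience \|V\| |
| `rt_sd_ms` | ms | 60 | Gaussian RT noise |
| `vas_gain` | points | 30 | rating change per unit value on the 0–100 scale |
| `vas_sd` | points | 8 | rating noise |
| `beta_choice` | — | 6 | softmax inverse temperature for approach/avoid |
| `p_recall` | — | 0.8 | probability a pairing is retrieved on a 4AFC item |
| `ibi_base_ms` | ms | 800 | baseline inter-beat interval |
| `ibi_react_ms` | ms | 50 | anticipatory IBI lengthening for salient cues |

The RT linkage is linear in unsigned value (salience): conditioning speeds
cue detection regardless of valence, so `RT = rt_base − rt_gain·|V| + ε`,
truncated to [150 ms, cue window]. The choice linkage is a two-action
softmax on signed value, `P(approach) = 1/(1 + e^{−β·V})`. Ratings map
value linearly onto the scale around a baseline drawn near the midpoint,
clipped to [0, 100]. On a recall retrieval failure the agent guesses
uniformly among the 3 distractors by default; a variant
(`recall_guess_all4`) guesses among all 4 options, giving the familiar
`p + (1 − p)/4` accuracy and a 0.25 chance floor at `p = 0`. The cardiac
generator lengthens the local IBI by `ibi_react_ms·|valence|` inside each
trial's 6 s anticipation window — cardiac orienting to motivationally
salient cues of either valence — plus beat-to-beat noise; a 250 ms floor
keeps beat times strictly increasing.

During the choice task the agent can either express the values carried over
from conditioning unchanged (default) or keep learning from the outcomes it
observes (`continue_learning = TRUE`; avoided trials reveal nothing and
never update). The default is the simpler account and keeps the planted
phenotypes interpretable; the flag exists to emulate re-learning accounts
of task dissociations.

## The planted phenotype mixture

The cohort generator (`sample_cohort()`, default n = 72) draws each agent
from an equal-weight 2 × 2 mixture in which learning itself is shared
(α = 0.2 for everyone) but its *expression* differs: `vas_gain` ∈ {2, 30}
controls how much conditioning shows up in ratings, and `beta_choice`
∈ {0.3, 6} controls how much it shows up in choice. A dissociation between
tasks is thus a property of expression gains, not of learning — the
simplest generative account that produces all four learn × use quadrants.
Nuisance parameters vary between subjects within fixed uniform bands
(RT base 600–700 ms, gain 170–230 ms, noise 50–70 ms; rating noise 5–10
points; recall 0.6–0.95; IBI base 700–900 ms, reactivity 40–60 ms).

The RT bands deserve a note: the package's central validation is that the
pooled learning-rate estimator recovers the generating α = 0.2 to within
one 0.01 grid step in the large majority of 72-subject cohorts, so the
default RT signal-to-noise ratio was calibrated once, by a one-time
sensitivity sweep of the estimator's pooled-argmin precision, to a regime
(gain ≈ 200 ms, noise ≈ 60 ms, gain/noise ≳ 3) where that identifiability
holds with margin. Slower or noisier linkages (e.g. gain 150/noise 80)
leave the pooled argmin wandering ±0.02 and are a useful stress case, but
they are not the default study condition.

Every participant's data descend from one master seed via a documented
spawning scheme (a single `sample.int` draw per level, Mersenne–Twister
throughout), so cohorts are bit-reproducible across machines, and
`write_dataset()`/`read_dataset()` round-trip the full study through plain
CSV plus a YAML manifest.

## Learning-rate inference from RTs

`fit_subject()` profiles the delta-rule/RT model over the fixed grid
α ∈ {0.01, 0.02, …, 1.00}: for each candidate α the realized outcome
sequence is forward-simulated to a per-trial salience series, RT is
regressed on salience by closed-form OLS (intercept + slope), and the SSE
is recorded; the estimate is the grid argmin. Numerical choices:

* **Grid, not continuous optimization.** A fixed grid makes the argmin
  reproducible and the profile inspectable; 0.01 resolution is finer than
  the estimator's sampling error at n = 72.
* **Tie-break**: smallest α among exact SSE ties (deterministic).
* **Missing RTs** (no keypress) are excluded from the regression but still
  drive value updates — the outcome was displayed regardless.
* **Identifiability**: a profile whose relative range
  `(max SSE − min SSE)/min SSE` falls below 1e−6 is flagged and the subject
  assigned the grid midpoint, excluded from pooling. This catches exactly
  flat profiles (e.g. constant RTs); subjects whose RTs are pure noise
  still show chance-level profile variation and are better diagnosed by a
  near-zero fitted slope.
* **Slope sign is unconstrained.** The generative linkage is negative
  (speeding); constraining the OLS sign would only affect noise-dominated
  subjects and would bias the profile, so the fit reports the slope as-is.
* The pooled estimate is the argmin of the **summed SSE** across
  identifiable subjects (fixed-effects pooling); the median of per-subject
  argmins is reported alongside, since a single group value could be
  operationalized either way.

## The behavioral analysis chain

**Learning score.** Unstandardized residualized change: the rating change
`post − pre` is regressed on `pre` (simple OLS) and the residuals keep the
rating-point scale. Residuals sum to zero and are uncorrelated with
baseline by the normal equations; both identities are asserted to 1e−10 in
the tests. A constant baseline makes the regression degenerate; the
centered change is returned with a warning. Before clustering, the score is
multiplied by the condition's valence (`sign_align`) so that "higher =
more learning" on every axis: positive change indicates learning for
appetitive reinforcers, negative change for aversive ones.

**Use score.** Fraction of expected responses — approach appetitive, avoid
aversive — over the first five qualifying choice trials, because the choice
task affords further learning and early trials are the cleanest read-out of
what was brought into it. "First five trials of the task" is ambiguous
between per-condition and whole-task counting; the default is
`per_condition` (clusters are built per condition, and five trials of one
condition span the early task), with `whole_task` available. Neither is
asserted as the paradigm's intent.

**Clustering.** k-means (Lloyd, 25 random restarts keeping the lowest
inertia, via `stats::kmeans`) on the within-condition z-standardized
learn × use plane, run separately per reinforcer condition, with k = 4 for
the headline analysis. Clusters are labeled by centroid quadrant; at k = 4
the labels are made bijective by assigning centroids to the four quadrant
prototypes with the minimum-cost permutation, which coincides with the raw
sign labels whenever the solution is quadrant-like. `select_k()` provides
the sensitivity analysis: mean silhouette width (`cluster::silhouette`)
over k = 2…6, with a `no_structure` flag when the best silhouette is below
0.25. That threshold is deliberately conservative; note that k-means
partitions of even a single Gaussian blob reach mean silhouettes near 0.4,
so the flag marks only grossly unclustered data and silhouette *comparisons*
(planted vs. null) are the more informative diagnostic.

**Concordance and tests.** The 2 × 2 learn/use agreement table uses a
median split with ties assigned to "low" (deterministic); Cohen's kappa
`(p_o − p_e)/(1 − p_e)` and an uncorrected chi-square statistic are
computed from the table, with degenerate margins flagged rather than
propagated as NaN. On cohorts where a score saturates (half the subjects at
a use score of exactly 1.0) the median split degenerates by construction —
a real property of median splits on bounded scores, reported via the flag.
Group-level conditioning effects on ratings are tested with a sign-flip
permutation test on paired changes (two-sided
`p = (1 + #{|perm| ≥ |obs|})/(n_perm + 1)`), the desk-scale substitute for
mixed-model fits, which require the original data at scale.

## The cardiac pipeline

Beat times become an instantaneous IBI series (interval assigned to the
*later* beat's timestamp; the paradigm is silent on alignment, and
right-alignment means every sample uses only past beats). Beats implying an
IBI outside 300–2000 ms are screened out as artifacts — an automated stand-in
for manual visual inspection. The remaining points are linearly interpolated
onto an exact 4 Hz grid spanning the observed IBI timestamps, never
extrapolating; linear interpolation cannot overshoot its neighbors, so
resampled values stay within the local raw range. Epochs are half-open
`[start, end)` windows — the 6 s anticipation period from cue onset, and the
reinforcer period from outcome onset to the next cue onset (1.5 s outcome +
2.5–5.5 s ITI, hence 4–7 s under the default design) — so consecutive
epochs never share a grid sample. Epochs with fewer than two samples, or
outside the series span, are flagged with missing means.

## What the synthetic data do and do not show

The generator emulates the *structure* of a real study — trial counts,
probabilistic reinforcement, counterbalancing, bounded rating scales,
choice saturation, cardiac epochs — and plants known effects at
field-plausible magnitudes. Passing tests therefore demonstrate that the
pipeline recovers what the generative model put in: they validate the
estimators and the analysis chain, not the psychological claims. Real data
differ in ways the model deliberately omits: RT distributions are skewed
and attention-lapse-contaminated rather than truncated-Gaussian; learning
rates, not just expression gains, vary across children; ratings cluster on
round numbers; ECG requires R-peak detection and artifact inspection before
any beat series exists; and missingness is nonrandom. None of these enter
the generative model, so none are claimed to be handled.

## Problem sizes and runtime choices

The validation suite simulates at the study's own scale — 72-subject
cohorts, 70-trial sessions — and uses replicate counts chosen to make the
Monte-Carlo assertions stable at their stated thresholds: 50 replicate
cohorts for learning-rate recovery, 10 cohorts for quadrant coverage, 500
replicates for the permutation-null uniformity check, 200-seed loops for
within-session Monte-Carlo properties. The whole suite runs in about a
minute on one CPU; `scripts/acceptance.R` reruns the two headline
computations from scratch in under a minute.

## Known limitations

* The delta rule with a single α cannot express valence-asymmetric or
  decaying learning rates; the fit inherits that restriction.
* Pooled-argmin estimation is a fixed-effects device; it has no shrinkage
  and no uncertainty quantification (a hierarchical model is out of scope).
* Quadrant labels at k ≠ 4 are sign-based and may repeat; they are
  descriptive, not a partition of the plane.
* The median-split concordance degenerates on saturated scores (flagged).
* The IBI generator plants equal orienting for both valences; it cannot, by
  construction, test valence-*specific* cardiac signatures.
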