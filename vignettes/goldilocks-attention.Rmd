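---
title: "Ideal-observer surprisal and the U-shaped attention pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal-observer surprisal and the U-shaped attention pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeobserver)
```

## The scientific problem

A learner watching a stream of events cannot attend to everything. Adaptive
accounts of attention predict that engagement should peak for events of
*intermediate* surprisingness: highly predictable events offer nothing to
learn, highly unpredictable ones exceed what the learner can integrate. On
gaze data this "Goldilocks" pattern shows up as a U shape — probability of
disengaging (looking away) is lowest, and orienting is fastest, at
intermediate surprisal.

`gazeobserver` implements the full analysis chain for a free-viewing
paradigm that tests this prediction: an animated display shows three boxes
at fixed random screen locations; each box conceals one unique object; at
each 1.5 s event (750 ms up, 750 ms down, no gap) one object pops out of
its box. A session presents 80 such sequences to each subject, every
subject seeing every sequence in its own random order, while gaze is
recorded at 1000 Hz.

## The ideal observer

The normative yardstick for "how surprising was this event?" is a
Dirichlet-multinomial ideal observer. With $K = 3$ objects and a symmetric
Dirichlet prior $\alpha$, after observing counts $c_1, \dots, c_K$ the
posterior-predictive probability of object $i$ is

$$p_i = \frac{c_i + \alpha_i}{\sum_j c_j + \sum_j \alpha_j},$$

and the surprisal of the event that actually occurs is $-\log_2 p$ (bits).
Two observers are tracked per sequence:

* **unigram** — events are exchangeable; the counts are marginal object
  counts, so only *how often* each object has popped up matters;
* **transitional (bigram)** — the observer keeps a $K \times K$
  transition-count matrix and conditions on the immediately preceding
  event; the first event of a sequence, which has no predecessor, is
  scored by the marginal prior (the only well-defined choice).

Belief state resets at every sequence boundary: objects are unique within
a trial and drawn fresh across trials, so counts cannot meaningfully carry
over.

Two conventions are deliberately fixed and exposed as parameters:

* **Prior**: the uninformative add-one (Laplace) choice $\alpha = 1$,
  representing a learner with no prior observations (`alpha` argument
  everywhere).
* **Log base**: base 2. Since surprisal is standardized before entering
  any regression, the base is cosmetic — an affine rescaling that leaves
  every z-scored coefficient, statistic and p-value unchanged (this
  invariance is verified in the test suite) — but it must be fixed for
  traces to be comparable.

## Stimulus sequences

`generate_sequence_set()` draws a pool of uniform random candidate
sequences (default 2× the requested set size), summarizes each candidate's
unigram surprisal trace as (mean, SD, max), and greedily selects the
requested number by maximin: each step adds the candidate with the largest
minimum Euclidean distance to the already-selected summaries, ties broken
by lowest candidate index. This is a concrete, reproducible way to "spread
the sequences' information properties as far as possible", so that pop-up
probabilities differ markedly across sequences; the set's
`dispersion_score` (mean pairwise distance between selected summaries) is
reliably higher than that of a size-matched random subset of the same
pool. Other constructions could serve the same goal (spread of
information properties); this one was chosen for being deterministic
given the pool, cheap, and easy to audit, and it should be read as a
well-defined stand-in for any particular lab's stimulus-generation
recipe rather than a reconstruction of one.

Sequence length is likewise configurable (default 30 events): long enough
for posterior beliefs to differentiate between sequences, short enough for
desk-scale simulation.

Geometry: box centers are placed on a 3×3 virtual grid over a
1920×1080 px screen with uniform jitter, rejected until all pairwise
separations reach `2 * aoi_radius + 1` px — the +1 makes the
boundary-inclusive AOI test provably exclusive, so no gaze sample can ever
sit in two AOIs. Coordinates are screen pixels, origin top-left. Surprisal
is a function of object order only; permuting box locations changes
nothing downstream of the geometry (verified as a property test).

## Behavioural measures

`build_event_table()` reduces each trial's 1000 Hz stream to one row per
event:

* **RT** — latency from pop-up onset to the first sample inside the
  event's circular AOI (default radius 150 px, boundary inclusive), within
  the event window; 0 if already inside at onset; missing if the AOI is
  never entered. No fixation parsing is applied — sample-level AOI entry
  is the minimal assumption — but a minimum-dwell variant is available
  (`min_dwell_ms`).
* **Predictive looking** — defined only on an object's *first* appearance:
  was the subject already fixating the to-be-active box just before
  pop-up? Operationalized as the last pre-onset sample (onset − 1 ms)
  lying in the AOI, with a configurable pre-onset window. The very first
  event of a trial has no pre-onset sample and is undefined.
* **Look-away** — the first maximal run of ≥ 750 ms (50% of the event
  duration) of samples that are off-screen or track-lost, attributed to
  the event whose window contains the run's start. Track loss counts as
  off-screen by default (`count_invalid`) because losing the pupil during
  a head turn away from the screen is behaviourally a look-away. Every
  event after the look-away is flagged `included = FALSE` and carries no
  outcomes, mirroring the trial-terminating convention of the infant
  paradigm.

Covariates for the controlled models: `is_repeat` (same object as the
previous event; FALSE at event 0), `distance_px` (Euclidean distance
between consecutive pop-up box centers; undefined at event 0, so
controlled fits drop first events), and `trial_number` (presentation
order).

## The synthetic-agent generator

The package ships a generative counterpart of the analysis model, so the
entire chain is testable by parameter recovery without any recorded gaze
data. For standardized surprisal $z$ and subject
intercept $u_s \sim N(0, \sigma_u)$:

$$\log \mathrm{RT} \sim N(a_0 + u_s + a_1 z + a_2 z^2,\ \sigma_{rt}),$$
$$\mathrm{lookaway} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(b_0 + u_s + b_1 z + b_2 z^2))
\ \text{per event, censored after the first success},$$
$$\mathrm{predictive} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(c_0 + u_s + c_1 z))
\ \text{on first appearances}.$$

Defaults — $a = (5.5, -0.05, 0.04)$, $\sigma_{rt} = 0.25$;
$b = (-2.2, -0.6, 0.35)$; $c = (-1.0, -0.5)$; $\sigma_u = 0.3$ — were
chosen once to mimic the qualitative U-shape regime (negative linear,
positive quadratic for RT and look-away; negative linear for predictive
looking) with effects detectable but not saturated at the design scale of
5 subjects × 80 sequences × 30 events. The baseline hazard
$\mathrm{logit}^{-1}(-2.2) \approx 0.10$ per event gives a realistic
spread of trial lengths under censoring.

`render_gaze_streams()` then emits 1000 Hz sample streams that realize the
drawn outcomes *exactly*: AOI entry at onset + RT with a dwell that ends
before a reserved 100 ms pre-onset slot (which carries the next event's
predictive look, when drawn); one off-screen run starting 50 ms into the
drawn look-away event and running to the end of the trial; neutral filler
gaze (an unused grid cell, clamped jitter) everywhere else. Round-trip
equality of extracted and drawn outcomes is exact by construction and
asserted at the full benchmark scale. Two bookkeeping consequences of
exactness: a drawn RT that would land inside the reserved slot
(≥ 1400 ms, a > 4σ tail under the defaults) is recorded as "never
fixated", and the look-away event's own RT is undefined (the agent is
disengaging, not orienting).

What the generator does *not* emulate: saccade kinematics and oculomotor
noise, fixation microstructure, calibration drift, pupillometry,
perceptual salience, or any reward contingency. Passing round-trip and
recovery tests therefore certifies the *pipeline* — measure definitions,
joins, censoring, model code — not the realism of monkey gaze; on real
data the AOI radius, dwell and window parameters matter and are exposed.

## Inference

`run_analysis()` fits the full 3 outcomes × 2 observers × raw/controlled
grid:

* log-RT: linear mixed model with subject random intercepts
  (`lme4::lmer`, ML), terms $z + z^2$ (+ covariates). RT = 0 rows are
  excluded: the log transform is undefined there and a zero RT is
  predictive rather than reactive behaviour, analysed separately.
* look-away and predictive looking: mixed logistic regression
  (`lme4::glmer`, Laplace). The look-away model is a discrete-time hazard:
  one row per included event, outcome TRUE exactly at the look-away
  event — the likelihood of the censored per-event Bernoulli process.
  Predictive-look models carry the linear surprisal term only.
* z and z² are raw (non-orthogonalized) polynomials of surprisal
  standardized *pooled across subjects and all events* (see below);
  covariates are z-scored, repeat status is 0/1. The repeat covariate is
  omitted from predictive models, where it is structurally constant.

Numerical and reporting choices: p-values for the linear mixed model use
the normal approximation to t (consistent with large-sample t reporting;
with thousands of events the approximation is accurate for the surprisal
terms — see limitations for intercepts); if `glmer` fails outright the
package falls back to an ordinary logistic fit with by-subject
cluster-robust standard errors and flags `converged = FALSE`; degenerate
outcomes (no variation) are flagged with no estimates rather than fitted.

**Standardization scope.** The default standardizes surprisal over *all*
event rows rather than only rows surviving the look-away censoring.
Sequences are always displayed in full, so the surprisal scale is a
property of the stimulus set, not of behaviour; pooling over all events
also makes the analysis-side z identical to the generator's z, so
recovered coefficients are directly comparable to the generating ones,
and keeps the predictor deterministic under censoring.
`scope = "included"` is available for sensitivity analyses, as is
within-subject standardization by splitting the table.

`fit_gam()` provides the model-free visualization: a penalized-spline
smooth of the outcome on raw surprisal bits (identity link for log RT,
logit link for the binary outcomes), smoothing parameter by GCV,
covariates as linear terms in the controlled variant. It returns the
curve with both a pointwise 95% band and a ±1 SE band (plots default to
the 95% band), plus raw means of three evenly spaced surprisal bins with
standard errors, and reports whether the curve's minimum is interior to
the attained surprisal range — the model-free signature of the U shape.

## Verification strategy and problem sizes

The package is verified at three levels, all seeded and generated in code:

1. **Exactness** — observer traces for 1,000 random sequences are compared
   to an independent brute-force implementation that recounts the full
   prefix at every event (tolerance 1e-12 bits); measure extraction from
   rendered streams must equal the drawn truth for 100% of the 12,000
   events of a full 5 × 80 × 30 benchmark.
2. **Recovery** — across 100 replicate simulations at the design scale,
   the surprisal coefficients of the raw RT and look-away models must fall
   within ±3 SE of truth with correct signs, and the look-away terms must
   have small median absolute error. With only 5 subjects the *intercept*
   error is t-distributed with ~4 degrees of freedom (its SE leans on a
   variance component estimated from 5 clusters), so intercepts are
   checked for sign per replicate and unbiasedness across replicates — a
   ±3 SE normal band is the wrong yardstick for them at this design size,
   and that limitation applies equally to real data with 5 subjects.
3. **Calibration and concordance** — with the quadratic truth set to zero,
   the z² term's rejection rate at α = 0.05 must sit inside the 95%
   binomial interval over 200 replicates; on U-shaped simulations, GAM
   interior minima must accompany significantly positive quadratic terms
   in ≥ 90% of replicates; maximin-selected sets must beat random subsets
   on dispersion over 100 seeds.

`scripts/acceptance.R` recomputes the same quantities from a fresh seed
at slightly reduced replicate counts (50 recovery / 100 calibration / 30
dispersion / 20 concordance replicates) and writes them as JSON.

## Known limitations

* The maximin stimulus generator is a stated stand-in (above), and the
  predictive-look window and look-away operationalizations are the
  closest literal readings of their definitions; both are configurable so
  they can be aligned with a specific lab's coding rules.
* Random intercepts only, matching the target analysis; no random slopes
  or model comparison machinery.
* The observer has no forgetting, learned hyperparameters, or capacity
  limits; it is the normative yardstick, not a process model.
* GAM smooths are a visualization aid; inferential claims rest on the
  mixed models.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- make_benchmark_dataset(seed = 1)              # 5 x 80 x 30 events
tab <- build_event_table(ds$trials, ds$traces)      # measures + surprisal
bundle <- run_analysis(tab)                         # 12 fits + GAMs
bundle$fits$lookaway_unigram_raw                    # U-shape coefficients
plot(bundle$gams$lookaway_unigram_raw)              # smooth + binned means
```
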