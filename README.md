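# gazeobserver

Ideal-observer surprisal and gaze-based attention analysis for sequential
visual events.

## What this is for

Adaptive accounts of attention predict a "Goldilocks" pattern: engagement
peaks for events of *intermediate* surprisingness and falls off for both
highly predictable and highly unpredictable events. `gazeobserver` is a
tested, reusable pipeline for testing that prediction on free-viewing
eye-tracking experiments in which three objects pop out of three boxes in
statistically structured sequences (80 sequences × 30 events of 1.5 s,
gaze sampled at 1000 Hz). It is aimed at researchers in comparative and
developmental cognition who need the full chain — stimulus statistics,
normative surprisal, gaze reduction, mixed-effects inference — to be
reproducible and verifiable without access to any particular lab's raw
recordings.

## The model at its core

A Dirichlet-multinomial ideal observer assigns each event a surprisal.
With counts $c_1,\dots,c_K$ of previously observed events and symmetric
prior $\alpha$ (default 1), the posterior-predictive probability of object
$i$ is

$$p_i = \frac{c_i + \alpha}{\sum_j c_j + K\alpha},$$

and the event's surprisal is $s = -\log_2 p$ bits. The **unigram**
observer tracks marginal counts; the **transitional** observer tracks a
$K\times K$ transition matrix and conditions on the preceding event
(first event scored by the marginal prior). Beliefs reset at each
sequence boundary.

Three per-event measures are extracted from gaze — reaction time to
fixate the active object's AOI, predictive looking at first appearances,
and the trial-terminating look-away (first ≥ 750 ms off-screen run) — and
modelled with mixed-effects regressions carrying standardized linear and
quadratic surprisal terms ($z$, $z^2$) and subject random intercepts,
plus GAM smooths for model-free visualization. The U shape is detected as
a negative linear plus positive quadratic coefficient.

A synthetic-agent module generates gaze streams whose RT, look-away
hazard and predictive looking depend on surprisal with known ground-truth
coefficients, so the entire chain is verifiable by exact round trips and
parameter recovery.

## Worked example

```r
library(gazeobserver)

ds  <- make_benchmark_dataset(seed = 1)         # 5 subjects x 80 sequences x 30 events
tab <- build_event_table(ds$trials, ds$traces)  # measures joined with surprisal
tab <- standardize_surprisal(tab)               # adds z and z^2

fit_mixed_logistic(tab, "lookaway")
#> <model_fit_result> lookaway ~ unigram (raw)  [glmer]
#>          term estimate      se statistic         p
#> 1 (Intercept)  -2.1015 0.11059   -19.003 1.620e-80
#> 2           z  -0.5730 0.05838    -9.814 9.753e-23
#> 3          z2   0.3572 0.03648     9.791 1.228e-22
#> random-intercept variance 0.03318;  n = 2473, groups = 5

fit_mixed_linear(tab)
#> <model_fit_result> rt ~ unigram (raw)  [lmer]
#>          term estimate       se statistic         p
#> 1 (Intercept)  5.52561 0.121409    45.512 0.000e+00
#> 2           z -0.04453 0.006564    -6.784 1.167e-11
#> 3          z2  0.04221 0.004838     8.724 2.678e-18
#> random-intercept variance 0.07348;  n = 2076, groups = 5

fit_gam(tab, "lookaway")
#> <gam_fit> lookaway ~ s(unigram surprisal) (raw): minimum at 2.2 bits (interior)
```

Reading the output: the simulated agents were generated with look-away
coefficients $(b_1, b_2) = (-0.6, 0.35)$ and log-RT coefficients
$(a_1, a_2) = (-0.05, 0.04)$; the fitted negative linear and positive
quadratic terms recover them within sampling error. The negative linear
term means disengagement falls (and orienting speeds up) as events become
less predictable at first; the positive quadratic term bends both back up
at high surprisal — the U shape. The GAM's interior minimum says the same
thing without assuming a quadratic.

One call runs everything (all 12 regression fits, GAM smooths, CSV
artifacts, and a manifest with config hash and seed):

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "results"))
res$bundle$coefficients
```

`vignettes/goldilocks-attention.Rmd` documents the model, the measure
definitions, the generator, and every numerical choice.

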