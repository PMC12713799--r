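# dreamcue

Timer-based targeted dream incubation (TDI) sessions, and the statistics
for analysing what people report afterwards.

## The problem

Hypnagogia — the N1 transition between wakefulness and sleep — produces
spontaneous, dream-like imagery, and auditory cues presented around sleep
onset can steer that imagery toward a chosen theme ("targeted dream
incubation"). Classic TDI needs physiological sensing to detect sleep
onset. `dreamcue` implements the sensor-free alternative: a purely
timer-driven protocol in which a participant picks their own sleep-latency
window, an incubation message naming an everyday object (Fork or Tree)
plays at a random time inside that window, and four rounds of a 3-minute
dwell followed by a 60-second thought report are scheduled, with 7-minute
return periods in between. The same protocol, run sitting up with
instructions not to sleep, cues wakeful freely moving thought (FMT, a form
of mind-wandering), allowing a within-subject comparison of the two
states.

The package is for sleep and mind-wandering researchers who want to run
this protocol (or simulate it), and to analyse the resulting data the way
such studies are analysed:

* **Session engine** — deterministic scheduling and (real-time or
  simulated) execution of sessions, plus the vigilance-based inclusion
  screen (keep a participant only if they slept at least "halfway" during
  the hypnagogia condition and not at all during FMT).
* **Corpus preparation** — rule-based sentence segmentation of typed
  thought reports and removal of literal prompt words.
* **Incorporation scoring** — cue-by-content-by-type tallies of rater
  annotations, inter-rater agreement (Pearson *r*, Cohen's κ, paired *t*),
  one-sample and two-sample Pearson χ² tests of incorporation rates
  (no continuity correction), and per-contrast within-subject factorial
  ANOVA where every effect's *F* is exactly the squared paired *t* on its
  contrast.
* **Semantic measures** — over a pluggable sentence embedder:
  *prompt centrality* (mean cosine similarity of each report sentence to
  the cue word, after prompt-word filtering) and *temporal coherence*
  (mean cosine similarity of consecutive sentences; defined only for
  reports with ≥ 2 sentences), with random-intercept linear mixed models
  (ML) compared by likelihood-ratio tests. A deterministic hashed
  token-count embedder ships as the offline default; any external
  encoder (e.g. a 512-dimensional transformer sentence encoder) plugs in
  through `custom_embedder()`.
* **Thought probes** — the 13-item phenomenology battery (11 Likert items,
  a binary intentionality item, a 4-category temporality item): paired
  *t* contrasts, binomial and baseline-category multinomial logistic
  contrasts, Benjamini–Hochberg correction across the 13-test family,
  precision-matrix partial correlations, Horn's parallel analysis with a
  common-factors (SMC-reduced) model, and maximum-likelihood exploratory
  factor analysis with oblimin (quartimin) rotation and an inclusive
  |loading| ≥ 0.40 "substantial" threshold.
* **Synthetic cohorts** — `generate_cohort()` emits sessions, vigilance
  responses, template-based reports with planted incorporations,
  annotations, and probe responses drawn from a planted latent-factor
  model, together with the ground truth, so the whole pipeline is
  testable offline.

## Worked example

```r
library(dreamcue)

cohort   <- generate_cohort(cohort_params(), seed = 1)
screened <- screen_cohort(cohort$vigilance)
sum(screened$included)                      # 88 of 132 pass the screen

rate <- any_incorporation_rate(cohort$annotations, condition = "hypnagogia")
chi  <- chisq_vs_chance(rate$k, rate$n)
```

This prints (via `sprintf`): `83 of 88 (94%) reported a cued
incorporation; chi2(1) = 69.1, p = 9.2e-17` — i.e. far more participants
incorporated their cued object than the 50% chance level, as expected
when the generator plants a 0.91 per-session incorporation probability.

```r
probe_contrasts(cohort$probes)
#> Hypnagogia vs FMT item-level contrasts (BH-corrected family of 13 tests):
#>              item estimate    raw_p    bh_p
#>       bizarreness   0.5227 0.000539 0.00701
#>   freedom_of_flow   0.2273 0.098100 0.35000
#>            images  -0.2386 0.100000 0.35000
#>    intentionality       NA 0.131000 0.35000
#>  current_concerns  -0.2273 0.135000 0.35000
#>             words  -0.1705 0.170000 0.35400
#>  positive_valence   0.1705 0.215000 0.35400
#>    topical_shifts   0.1705 0.242000 0.35400
#>           novelty   0.1705 0.245000 0.35400
#>    meaningfulness  -0.1250 0.281000 0.36500
#>       temporality       NA 0.378000 0.44700
#>      emotionality  -0.0909 0.545000 0.59000
#>  negative_valence  -0.0227 0.867000 0.86700
```

Estimates are hypnagogia-minus-FMT mean differences on the 1–5 scale; the
two categorical items report model likelihood-ratio p-values. The factor
pipeline on the hypnagogia condition:

```r
items <- cohort$probes[cohort$probes$condition == "hypnagogia", probe_items()]
pa    <- parallel_analysis(items, n_iter = 200, seed = 2)
pa$n_factors                                # 4
fit   <- efa(items, pa$n_factors)
#> Warning: Heywood case: communality at or above 1
summary(fit)
#> 4-factor solution over 11 items; 10 substantial loadings (|loading| >= 0.40)
#> no cross-loading items
```

Parallel analysis recovers the generator's planted 4-factor structure,
and the oblimin-rotated loadings delineate the planted item groupings.
(The Heywood warning is expected here: ML extraction on a factor marked
by only two coarse Likert items can push one communality to the
boundary — the same improper-solution signature that real probe
batteries of this size show — and the fit flags it rather than hiding
it.)

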