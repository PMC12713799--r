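---
title: "Timer-based dream incubation and its analysis model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timer-based dream incubation and its analysis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamcue)
```

## The protocol model

A targeted dream incubation (TDI) session in this package is a purely
timer-driven schedule. The participant supplies a latency window — their
own estimate of how long they need to fall toward sleep (hypnagogia) or
to settle into freely moving thought (FMT) — and the engine draws the
realized latency uniformly, as an integer number of seconds, over that
closed interval. After the latency an incubation cue naming the session's
object (Fork or Tree) plays, and each of the `n_trials` rounds consists
of a dwell period (default 180 s), a report prompt, and a report window
(default 60 s). Between rounds a return period (default 420 s) lets the
participant fall back toward the target state, and is opened by another
incubation cue so that every dwell is preceded by a cue. The session
ends immediately after the last report window; a trailing return period
would serve no trial, so none is scheduled. With the defaults and a
13-minute latency this gives 780 + 4·(180 + 60) + 3·420 = 3000 s.

Two timing choices deserve a note. First, the protocol's incubation
message is described in the field as playing "intermittently"; we fix
that to exactly one cue per dwell (at the end of latency, and at each
return start). One cue per entry into the target state matches the
per-trial structure of the protocol and keeps the schedule a
deterministic function of `(config, latency)` — identical inputs produce
bit-identical timelines, which the tests rely on. How often a
within-dwell repeat would help is an empirical question the engine does
not prejudge. Second, all scheduling is in whole seconds; in real-time
execution sub-second jitter is recorded in the event log but never fed
back into the schedule.

The inclusion screen mirrors the protocol's logic rather than any
physiology: a participant is analysed only if they report having slept
"fully" or "halfway" during the hypnagogia condition *and* not at all
during FMT. Both criteria are applied symmetrically by
`inclusion_filter()`; everything downstream sees only the screened
cohort.

## Report preparation

Typed reports are segmented into sentences by a deterministic rule
(split at `.`, `!`, `?` with an abbreviation guard) rather than by a
learned model: the sentence is only the unit of averaging, and
reproducibility across machines matters more here than edge-case
accuracy. Removal of meta-commentary addressed to the experimenter
("sorry, I fell asleep late") is a manual cleaning step that belongs to
the caller; the package deliberately does not guess at it.

Before prompt centrality is computed, every token equal to the cue word
or its simple plural is removed, case-insensitively. The filter is
literal by design — "forked" survives a Fork session — because the
measure being protected is similarity *to the literal prompt word*;
derivational stemming is available behind a flag but off by default.
Sentences emptied by the filter are dropped, which is why a report's
sentence count can shrink between segmentation and scoring.

## Semantic measures

Both measures are averages of cosine similarities between sentence
embeddings and are agnostic to the embedding model:

* **prompt centrality** — mean similarity of each (filtered) sentence to
  the bare lowercase cue word;
* **temporal coherence** — mean similarity of consecutive sentence pairs
  (width 2, stride 1). A single-sentence report has no consecutive pair,
  so the value is *missing*, not zero, and missing values are excluded
  listwise from regressions.

The default embedder hashes lowercased tokens into a fixed number of
buckets and counts them. It is deterministic, offline, non-negative (so
similarities lie in [0, 1]), and bit-reproducible across platforms —
which is what the test suite needs. What it does not have is semantics:
two sentences are similar only insofar as they share (or hash-collide
on) tokens. Consequently, with the default backend, *indirect*
incorporations ("watering big plants" in a Tree session) do not raise
prompt centrality, and the centrality–incorporation relation that a
transformer encoder reveals on real data is only visible here for
unfiltered direct mentions. Passing tests with the hash backend
therefore validates the *measures and their plumbing* — bounds, order
invariance, missingness, filtering — not the semantic sensitivity of any
particular encoder; for real analyses a sentence encoder should be
plugged in via `custom_embedder()`.

Relations among centrality, coherence, condition and incorporation
counts are fit with random-intercept linear mixed models, estimated by
maximum likelihood (`REML = FALSE`). ML rather than REML is forced by
the inference contract: each effect is judged by a likelihood-ratio test
of the full model against the model with that effect removed, and
nested fixed-effect comparisons are only valid under ML. One subtlety
surfaced by the tests: duplicating every observation does *not* in
general leave mixed-model fixed effects unchanged (the implied GLS
weighting changes with cluster size whenever the intercept variance is
positive); the invariance holds exactly where GLS reduces to OLS, e.g.
balanced designs with cluster-constant covariates, and that is the case
the suite asserts.

## Incorporation statistics

Rater annotations count direct (object named) and indirect (associate
evoked) incorporations of each object per report. The tally classifies
counts as cued or uncued relative to each session's own cue, and the
cue-specificity question — do people incorporate the cued object and not
the other one? — is answered by a within-subject factorial ANOVA in
which every factor has two levels. Each effect is computed from its
signed per-participant contrast, making `F = t²` an exact algebraic
identity rather than an approximation, and partial eta squared is
`F / (F + df_error)`.

Rate statistics use the Pearson chi-square with no continuity
correction, both against a fixed chance level (`p0 = 0.5` by default)
and between two independent samples; the one-sample statistic for 73 of
80 participants against chance is 54.45, and the comparison of 73/80
with 34/37 gives 0.013 — reproducing the published values of 54 and 0.01
at their printed precision, which is what fixed the no-correction
choice.

Agreement between two raters is reported three ways on matched
report units: Pearson correlation of total counts, a paired *t* for a
systematic scoring difference, and Cohen's κ on a categorical unit rule.
The unit of the κ computation is not standardized in this literature; we
default to per-report presence/absence of any cued incorporation and
keep the rule pluggable (any function from annotations to labels). This
combination reproduces the familiar pattern in which near-perfect count
correlation coexists with modest κ whenever one rater scores
systematically more than the other.

## Thought-probe statistics

The 13-item battery is analysed as one family: 11 two-sided paired
*t*-tests on the Likert items (treated as continuous, as is standard for
these scales), a binomial logistic regression for intentionality, and a
baseline-category multinomial logit for temporality with the atemporal
"none" response as reference, each categorical model assessed by a
likelihood-ratio test against its intercept-only null. All 13 p-values
enter a single Benjamini–Hochberg step-up adjustment. Complete
separation in the binomial model is flagged and the odds ratio replaced
by the Haldane–Anscombe (add-0.5) table estimate rather than reported at
an infinite value.

Partial correlations come from the precision matrix
(`-P_ij / sqrt(P_ii P_jj)`), which is algebraically identical to
correlating the residuals of each pair regressed on all remaining
variables — the test suite holds the two routes together at 1e-8.
Degrees of freedom are `n - 2 - g` with `g` controls.

Factor retention uses Horn's parallel analysis under a common-factors
model: eigenvalues of the correlation matrix with squared multiple
correlations on the diagonal, compared against the same quantity from
random normal data of identical shape, counting the leading run of
observed eigenvalues above their reference. The reference is the *mean*
random eigenvalue by default, with an optional upper quantile. The two
criteria behave differently at the null: because observed and random
eigenvalues share a distribution when there is no structure, the mean
criterion suggests one factor for pure noise about half the time (and
two occasionally) — that is a property of the method, not a bug — while
the 0.95-quantile criterion is conservative, and it is the quantile
version the null-behaviour test pins down. On planted structure at
realistic sizes (4 factors, loadings 0.7, n = 300) both criteria recover
the truth in essentially every seed.

Extraction is maximum likelihood (via `factanal`); rotation is oblimin
with γ = 0 (quartimin), implemented by gradient projection on the
oblique rotation manifold. The rotation is a pure reparameterization —
`L Φ Lᵀ` equals the unrotated common covariance to machine precision —
and two conventions make output deterministic and comparable: factors
are ordered by descending sum-of-squares loadings
(`diag(Φ Lᵀ L)`, whose total equals the sum of communalities), and each
factor's largest-magnitude loading is made positive. Loadings with
magnitude at or above 0.40 (inclusive) are flagged as substantial, and
items substantial on more than one factor are reported as
cross-loadings. Communalities above 1 (Heywood cases) are flagged, not
silently truncated; with two-item factors measured on coarse 5-point
scales they occur legitimately.

## The synthetic cohort

`generate_cohort()` is first-class, tested code, and its defaults *are*
the study conditions the analysis stack is meant to face: 132 recruited
participants with pass probability 80/132 on the vigilance screen;
condition order and cue object counterbalanced within subject;
per-session probability 0.91 of at least one cued incorporation, with
counts Poisson around means 2.85 (direct) and 1.68 (indirect)
conditional on any, and uncued counts exactly zero by default (an
optional leak rate exists because real uncued means are near zero, not
provably zero). Reports are built from fixed sentence templates: direct
mentions use the cue word verbatim, indirect mentions draw from a
shipped associate lexicon (Tree → branches, leaves, ...; Fork → spoon,
cutlery, ...), and distractor sentences avoid both — so planted counts
can be recovered from the text by exact token lookup, giving a
human-free "rater" for synthetic data. Probe items are Likert
discretizations (fixed thresholds −1.5, −0.5, 0.5, 1.5 on the
standardized latent scale) of a planted factor model, with per-item
hypnagogia-minus-FMT latent shifts defaulting to the small observed-scale
contrasts typical of this paradigm (e.g. +0.31 for freedom of thought
flow), applied ±δ/2 per condition. Discretization attenuates a latent
shift by the factor Σφ(thresholds) ≈ 0.96, which the recovery test
accounts for. A participant's factor scores correlate 0.3 across their
two conditions — a deliberate, realistic trait-consistency choice with
no analogue printed in the literature. One master seed is stream-split
into per-product sub-seeds, so regenerating one table never perturbs the
others.

What the generator does not emulate: linguistically realistic
narratives, rater disagreement structure beyond a simple
extra-count noise term, item-specific response styles, and any semantic
relation between associates and cue that only a real embedding model
would see. Tests passing on synthetic data therefore certify the
statistical machinery and its contracts, not field validity of the
protocol.

## Problem sizes and numerical choices

The recovery studies run at the sizes stated in their tests: 200
simulated cohorts of 80 participants × 2 reports for mixed-model slope
coverage (planted β = 0.20, matching the scale of the published
centrality–incorporation estimate); 20 seeds of n = 300, loadings 0.7
for parallel-analysis and EFA loading recovery; 100–200 random datasets
per parallel analysis. These sizes give stable pass/fail behaviour at
the asserted thresholds while keeping a full run of suite plus
acceptance script under a minute. Other numerical conventions:
chi-square tests are never continuity-corrected; cosine similarity
clamps to [−1, 1] against rounding; a zero embedding vector is an error
(a degenerate embedding should fail loudly), whereas an empty sentence
set yields a missing score; the oblimin gradient projection iterates to
a 1e-6 projected-gradient norm with step halving; and `factanal`'s
uniqueness floor (0.005) is treated as the Heywood boundary.

## Known limitations

The default embedder has no semantics (see above). The multinomial
temporality model is fit without covariates; published analyses of such
items sometimes adjust for order or demographics, and the
parameterization here (condition → category, reference "none") is the
minimal one consistent with reporting per-category relative-risk
ratios. Likert items are treated as continuous throughout; a polychoric
EFA would be the ordinal-faithful alternative and is out of scope. The
session engine trusts self-reported vigilance; it has, by construction,
no access to sleep physiology.
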