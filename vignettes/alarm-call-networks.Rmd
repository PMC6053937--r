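---
title: "Information content and interspecific alarm-call networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information content and interspecific alarm-call networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In species-rich prey communities, an individual that overhears another
species' alarm call faces an inference problem: how much does that call say
about *its own* predation risk? The answer depends on the signaller–receiver
relationship — whether the two species share predators, how consistently the
signaller calls when the receiver's predators appear, how often its calls
denote carnivores irrelevant to the receiver, how familiar and how
acoustically similar its calls are. `alarmnet` implements a complete
analysis pipeline for this question: information-content indices, acoustic
similarity, behavioural response coding, a suite of mixed models testing the
competing hypotheses, and the resulting directed communication network. A
synthetic-community generator with known ground truth makes every stage
testable by simulation.

## Information-content indices

Vulnerability of receiver $i$ to predator $x$ is taken from a Jacobs
selectivity index $D \in [-1, 1]$ and mapped to
$\varepsilon_{ix} = (D + 1)/2 \in [0, 1]$. The affine map is the unique
affine bijection between the two ranges; because the literature states only
that the index is rescaled into $[0,1]$ with high values meaning high
vulnerability, the transform is exposed as a pluggable function
(`jacobs_transform()`).

**Caller consistency** (sensitivity to *false negatives*): with
$I_{xj}$ the probability that species $j$ alarm-calls to predator $x$
(estimated as a per-cell trial proportion), $a_x$ the normalised predator
encounter weight, the default form is

$$L(i,j) \;=\; \frac{\sum_x I_{xj}\, \varepsilon_{ix}\, a_x}
                     {\sum_x \varepsilon_{ix}\, a_x}.$$

The normalising denominator is forced by the interpretation that a perfect
informant — a species that always calls, whatever the predator — should
score exactly 1 for every receiver. The raw weighted sum
$\sum_x I_{xj}\varepsilon_{ix}a_x$ is retained behind
`normalize = FALSE` for sensitivity analysis; the two variants always rank
callers identically within a receiver (they differ by a receiver-specific
positive factor), which the test suite asserts on random communities.

**Call reliability** (sensitivity to *false positives*): with $C_{xj}$ the
proportion of $j$'s calls elicited by predator $x$ under equal presentation
frequency,

$$V(i,j) \;=\; \sum_x C_{xj}\, \varepsilon_{ix},$$

a convex combination of vulnerabilities, hence in $[0,1]$ by construction.
$C$ is estimated by normalising per-predator alarm *rates* rather than raw
call counts: with exactly balanced trial counts the two coincide, and the
rate form removes sampling-frequency bias when realised counts are slightly
unbalanced (field totals rarely match the balanced-design arithmetic
exactly). A caller with no alarms anywhere has no call profile: its column
is flagged undefined, never silently zero-filled, because an observed zero
propensity (a species that genuinely never alarms) is information, while an
empty cell is not.

**Body-size ratio** (proxy for predator overlap) uses the asymmetric
Lovich–Gibbons form: receiver:caller mass when the receiver is larger,
$2 - \text{caller:receiver}$ when smaller. The two branches meet at 1 for
equal masses, giving a continuous measure whose quadratic term can capture
peak responsiveness near size parity.

## Acoustic similarity

Seven per-call features (duration, harmonics visibility, number of
structural components, pulse presence, 25% energy quartile, 25–75%
bandwidth, third dominant frequency) are max-standardised — each column
divided by its maximum, guaranteeing equal weighting and invariance to the
units each feature is measured in. Similarity between species $a$ and $b$
is $1 - d(a,b)/\sqrt{7}$ where $d$ is the Euclidean distance between
species centroids (per-feature means over that species' analysed calls).
The $\sqrt{7}$ divisor is the diameter of the unit feature box; it
guarantees similarity in $[0,1]$, consistent with presenting the covariate
on a 0–1 scale. Both choices are open in the source literature, so the
unscaled distance (`scale = FALSE`) and a call-pair-averaged aggregation
(`method = "pairwise"`) are provided as alternatives.

## Response coding

Playback videos are assumed transcribed to tidy event logs (one timestamped
behavioural event per row). Coding rules:

* **Binary response** — any qualifying event (head-lift, scratch, other
  coded behaviour change; vocabulary configurable) in the window
  $(t_0, t_0 + 10\,\mathrm{s}]$ after playback onset $t_0$. The window is
  closed on the right; an event at exactly $t_0 + 10$ counts. The boundary
  is tested explicitly.
* **Latency** — time from onset to the first qualifying event.
* **Duration** — time from onset to the start of the first foraging bout of
  at least 10 s that begins after onset. Trials where foraging never
  resumes within the log are flagged censored and excluded from duration
  models rather than imputed.
* **Counts** — head-lift starts and scratches after onset.
* **Pre-trial filter** — a single foraging interval must cover the 20 s
  before onset.

All rules are pure interval arithmetic on time differences, so coding is
invariant to shifting the log's clock. The generator can render simulated
trials as event logs (`playback_event_logs()`); coding those logs recovers
the latent response variables exactly, which pins down every coding rule
against the generative definitions.

## The model suite

* A preliminary binomial model with call type (control / conspecific /
  heterospecific) contrasts; control trials are then removed from all
  downstream models, mirroring the design in which the control sound exists
  only to establish a response floor.
* An alarm-production logistic model on predator-simulation trials: focal
  species, own vulnerability to the presented predator, their interaction,
  distance to the model, standardised group size, presence of young. The
  vulnerability coefficient tests whether alarm propensity tracks
  vulnerability.
* Six playback response models sharing one fixed-effect vocabulary —
  receiver body size, size ratio (linear + quadratic), their interactions,
  caller consistency, call reliability, acoustic similarity, caller
  abundance, and five environmental covariates — plus a per-receiver random
  intercept: binomial (response probability), log-linear (latency, time to
  resumed foraging, head-lift speed) and negative-binomial (head-up and
  scratch counts). Heterospecific trials only by default
  (`include_conspecific = TRUE` to widen); receivers lacking a conspecific
  alarm call have undefined acoustic similarity and drop from these models.

Covariate scales: consistency, reliability, similarity, abundance,
size-ratio and receiver size are affinely rescaled to $[0,1]$ **over the
heterospecific pair grid**, so the scaling is a property of the community
rather than of a particular trial sample; environmental covariates and the
integer group size are standardised to mean 0, SD 1 over the modelled
trials. Fitting is delegated to `stats::glm`, `lme4` and `glmmTMB`
(negative binomial with ML-estimated dispersion); linear mixed models are
fitted by maximum likelihood so that AICc comparisons are valid.

**Inference.** Term p-values for the log-linear mixed models are
likelihood-ratio tests (single-term deletions refitted by ML); binomial and
negative-binomial mixed models report Wald $z$ statistics, with LRT
available through `fit_model(..., pvalues = "lrt")`. Kenward–Roger degrees
of freedom are deliberately out of scope. A caution that the simulations
make quantitative (see the test suite): covariates whose variation is
mostly *between receivers* — call reliability is the clearest case, since
$V(i,j)$ is dominated by the receiver's vulnerability row — are effectively
tested against the number of receiver species (12), and their nominal-5%
tests reject at roughly 10–15% under a true null. Tests on trial-level and
caller-level covariates are accurately calibrated. Inference on
receiver-dominated covariates in communities of this size should therefore
be treated conservatively.

**AICc selection.** $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$.
`build_candidate_set()` enumerates all subsets of the full fixed-term list
that respect marginality (interactions require their main effects,
quadratics their linear terms; the random intercept is always retained),
with an optional complexity cap; `select_model()` fits every candidate and
ranks by AICc, breaking ties by fewer parameters and then by deterministic
term order — a reproducibility choice the selection literature leaves open.

## What the synthetic generator emulates

`generate_community()` draws a 12-herbivore, 5-predator community:
log-uniform body masses (15–900 kg, the span from small gazelle to
giraffe-class species), lognormal relative abundances, uniform Jacobs
indices, and per-species alarm propensities on the logit scale
(baseline $-0.8$, species SD 0.5, cell SD 1, optional coupling slope on own
vulnerability). One species is non-vocal by default: it never calls, has no
acoustic features, and never appears as a playback caller — exercising every
undefined-index path. Default trial sizes follow the balanced-design
arithmetic of the emulated field study: 9 presentations per species ×
(5 predators + control) = 648, and 17 playbacks per receiver × (11 callers
+ control) cell ≈ 2 450.

Playback responses are drawn from the exact logistic model the analysis
fits — linear predictor over the prepared covariates, per-receiver normal
random intercept (SD 0.5 on the logit scale; no field value exists, 0.5 is
a moderate between-species heterogeneity) — so parameter recovery is exact
by construction up to sampling noise. Latency, duration and head-lift speed
are lognormal conditional on a response (latency truncated to the 10-s
window, where it is defined); head-up and scratch counts are negative
binomial; 5% of durations are censored. All effect coefficients default to
zero: effects are injected explicitly per analysis, so that null
calibration and power are both measurable against known truth. Control
playbacks use a $-2.4$ logit offset and conspecific calls a $+0.96$ offset,
magnitudes typical of field playback contrasts. The predator-simulation
control alarm rate defaults to 0.05 (no field value is stated anywhere for
it; it only needs to be clearly below predator-elicited rates).

What the generator does **not** emulate: spatial structure and movement,
audio (features are abstract nonnegative vectors), observation error in
event logs, overdispersion beyond the negative binomial, imbalance in
realised trial counts (the field total of 649 against a balanced 648 is not
reproduced), and any correlation between acoustic similarity and ecology.
Passing simulation tests therefore demonstrates correctness of the
estimators and machinery under the assumed generative model, not robustness
to the many ways field data deviate from it.

## Numerical and scale choices

* Replicate simulation sweeps (parameter recovery, null calibration) fit
  the binomial GLMM with `nAGQ = 0`; at these sizes (≈1 900 trials, 12
  groups) fixed-effect estimates agree with adaptive quadrature to well
  under 1% and fitting is ~25× faster. Interactive analysis defaults to
  `nAGQ = 1`.
* Boundary (singular) random-effect fits are valid ML estimates and are not
  flagged as convergence failures; binomial fits with any |coefficient|
  > 10 are flagged as likely separation.
* Problem sizes used by the validation suite: 1 000 random communities for
  index-oracle equivalence, 100 replicates for recovery/coverage sweeps,
  200 for null calibration, full-design (648 / 2 448-trial) datasets for
  the end-to-end runs.
* Degenerate inputs fail loudly and specifically: constant vectors cannot
  be unit-scaled, all-zero feature columns cannot be max-standardised,
  receivers with zero encounter-weighted vulnerability have undefined
  consistency, and zero-trial index cells stay `NA`.

## Known limitations

* Anticonservative tests for receiver-dominated covariates with 12
  receiver species (quantified above) — a property of the design, not of
  the implementation.
* The all-subsets candidate space grows exponentially; enumeration refuses
  more than 20 terms and `max_terms` provides a dredge-style cap.
* Real-data mode consumes already-measured acoustic feature tables and
  coded or loggable behavioural data; no audio or video processing.
* The exact field model lists behind the published selection tables are not
  reconstructable; the machinery reproduces the selection mechanism, not
  the specific selected term sets.
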