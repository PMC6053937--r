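# alarmnet

Analysis of heterospecific alarm-call communication in multi-species animal
communities, written for behavioural ecologists working with
predator-simulation and playback experiments across a guild of prey species
(the motivating setting is a savannah herbivore community of 12 species and
5 shared predators).

Prey species eavesdrop on each other's alarm calls, but a heterospecific
call is only as useful as the signaller–receiver relationship behind it.
`alarmnet` quantifies that relationship and models its behavioural
consequences:

* **Vulnerability weights** ε<sub>ix</sub> ∈ [0, 1] from Jacobs predator-preference
  indices (affine transform of D ∈ [−1, 1]).
* **Caller consistency** — how reliably caller *j* informs receiver *i*
  (penalising false negatives):
  L(i, j) = Σ<sub>x</sub> I<sub>xj</sub> ε<sub>ix</sub> a<sub>x</sub> / Σ<sub>x</sub> ε<sub>ix</sub> a<sub>x</sub>,
  with I<sub>xj</sub> the propensity of *j* to alarm at predator *x* and
  a<sub>x</sub> the normalised predator encounter weight.
* **Call reliability** — how likely a single call of *j* denotes a predator
  of *i* (penalising false positives):
  V(i, j) = Σ<sub>x</sub> C<sub>xj</sub> ε<sub>ix</sub>,
  with C<sub>xj</sub> the caller's call profile over predators.
* **Acoustic similarity** 1 − d/√7 between species centroids of seven
  max-standardised call features.
* **Response coding** of playback event logs: binary 10-s-window response,
  latency, time to resumed foraging (≥ 10 s rule, censoring-aware),
  head-up and scratch counts, pre-trial relaxation filter.
* **Model suite**: alarm-production logistic model; preliminary call-type
  model with control exclusion; binomial / log-linear / negative-binomial
  mixed models for six response variables with a per-receiver random
  intercept; AICc all-subsets selection under marginality constraints.
* **Directed communication network** from caller → receiver response
  probabilities with a configurable cut-off (0.72 by default), exported as
  GraphML and edge-list CSV.

A synthetic-community generator reproduces the full statistical structure
of both experiments (balanced Bernoulli predator-simulation trials;
playback responses from a logistic mixed model with known coefficients), so
every stage of the pipeline is validated by parameter recovery against
ground truth. See the methods vignette
(`vignettes/alarm-call-networks.Rmd`) for the model details and design
choices.

## Worked example

```r
library(alarmnet)

# a community whose alarm propensity is coupled to own vulnerability
cm <- generate_community(seed = 7,
                         propensity_coupling = list(slope = 1.76, cell_sd = 0))
trials <- simulate_predator_trials(cm, n_per_combination = 9, seed = 8)
idx <- derive_indices(cm, trials)
print(idx)
#> Alarm information-content indices
#>   receivers: 12  callers: 12  ( 11 vocal )
#>   mean consistency L: 0.519   mean reliability V: 0.51

# does alarm propensity track vulnerability? (true slope 1.76)
m1 <- fit_alarm_model(trials, idx$epsilon, include_interaction = FALSE)
m1$vulnerability_coef
#>             term estimate    se statistic  p_value
#> 13 vulnerability     1.67 0.412      4.06 4.87e-05

# playback experiment, call-type contrasts against the control sound
playbacks <- simulate_playbacks(cm, idx, seed = 9)
pre <- preliminary_calltype_model(playbacks, include_interaction = FALSE)
pre$contrasts
#>                       term estimate    se statistic  p_value
#> 13    call_kindconspecific     3.13 0.273      11.5 1.79e-30
#> 14 call_kindheterospecific     2.36 0.215      10.9 7.87e-28

# directed communication network
P <- response_probability_matrix(playbacks)
net <- build_network(P, threshold = 0.72)
igraph::ecount(net)
#> [1] 26
```

The recovered vulnerability slope (1.67 ± 0.41) brackets the injected truth
of 1.76; both alarm-call types elicit far more responses than the control
sound (logit contrasts 3.13 and 2.36, the generator's true offsets being
3.36 and 2.40); and 26 caller → receiver pairs exceed the 0.72
response-probability cut-off in this community.

The six-stage pipeline (generate → indices → acoustics → responses →
models → network) runs in one call and writes CSV/YAML/GraphML artefacts
plus a manifest:

```r
run_pipeline(pipeline_config("out/", synthetic = list(seed = 7)))
```

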