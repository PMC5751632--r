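# eatbn

Eating-activity recognition from low-power wearable and smartphone sensors
with a modular, tree-structured Bayesian network.

## The problem

Detecting *when someone is eating* from everyday sensors matters for
dietary monitoring, diabetes management and elder care — but eating is a
complex activity whose raw sensor signature varies wildly with utensils,
place, time and person. Classifiers trained directly on window statistics
of the available low-power channels (wrist three-axis accelerometer at
20 Hz; wrist illuminance, temperature, humidity at 1 Hz; phone three-axis
accelerometer) overfit those surface patterns.

`eatbn` routes the decision through a hierarchy of interpretable context
variables instead. A binary query node (eating / not eating) roots a tree
of 88 nodes: four submodules — subject, object, spatial and temporal
context — attach to the main module through shared root nodes, 23
intermediate nodes carry low-level contexts such as *dinnerware use*,
*posture*, *indoor/outdoor* or *eating time*, and 64 evidence leaves are
set per one-second window by decision stumps over sensor features.

With joint distribution $P(N_1,\dots,N_n) = \prod_i P(N_i \mid Pa(N_i))$
and evidence $e$ on (any subset of) the leaves, the eating posterior
$P(Q = \text{eating} \mid e)$ is computed exactly by belief propagation on
the tree; missing evidence is marginalized out, so the recognizer keeps
answering when a sensor is absent. CPTs are learned by counting with
Laplace smoothing, $\hat p = (c + \alpha)/(c_{\mathrm{row}} + \alpha K)$;
a window is called *eating* when the posterior reaches the decision
threshold (default 0.6). Every posterior comes with the four shared-node
marginals, so a decision is explainable per context group.

A seed-deterministic simulator generates the nine-channel stream with
subject heterogeneity (handedness, age, gain/offset, dropout), activity
bouts with a configurable eating share, and per-window ground-truth
context states — so the full stack is trainable and testable without any
external data.

## Worked example

```r
library(eatbn)

ds  <- generate_dataset(n_subjects = 4, minutes_per_subject = 5, seed = 42)
w   <- segment_windows(ds$records)                      # 1-s feature windows
ctx <- ds$contexts[match(w$window_start, ds$contexts$window_start), ]

model <- train_model(w, ctx)                            # stumps + CPTs
model
#> Modular tree-structured Bayesian network
#>   nodes: 88 (1 query, 23 inference, 64 evidence)
#>   edges: 87   modules: main, subject, object, spatial, temporal (main: main)
#>   CPTs: 88 nodes (alpha = 1)   stumps: 64   threshold: 0.60

pred <- predict_windows(model, w)
compute_metrics(confusion_matrix(w$is_eating, decision = pred$decision))
#> accuracy 88.86%  precision 90.34%  sensitivity 82.72%  specificity 93.43%

infer_posterior(model, list())       # no evidence: the learned class prior
#> P(eating | evidence) = 0.4264 -> non-eating (threshold 0.60)
#> shared-node posteriors:
#>   subject_property   0.8155
#>   object_property    0.4317
#>   spatial_property   0.6058
#>   temporal_property  0.6564
```

The training-data accuracy (88.86 % here, on 1,140 windows whose eating
share is 42.6 %) measures how well the stump bank plus counted CPTs fit
the simulated cohort; the no-evidence posterior equals the empirical
eating prior, and the shared-node marginals show how much each context
group would, on average, speak for eating.

A YAML-configured command-line wrapper covers the same pipeline
(`simulate`, `train`, `recognize`, `evaluate`):

```sh
Rscript inst/cli/eatbn simulate --config run.yaml
```

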