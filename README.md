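# eventsem

Event comprehension by a library of recurrent event schemas with gated
Bayesian schema inference.

## The problem

People experience continuous activity but remember and predict it in
*events*. A long-standing account holds that the mind maintains an active
*event model* — a working representation of the current situation drawn
from learned *event schemas* — and that comprehension hinges on knowing
when to hand off from one model to the next: segment too rarely and
predictions go stale, too often and nothing accumulates. `eventsem` is for
computational cognitive scientists who want to simulate this process at
desk scale: it learns a library of small recurrent predictor networks from
a single online pass over activity streams, segments and categorizes the
stream as a side effect of prediction, and ships the statistics needed to
compare model behavior with (real or simulated) human segmentation.

## The model

Activity arrives as scene vectors $v(t) \in \mathbb{R}^{30}$ every 1/3 s.
Each schema $j$ is a four-layer GRU network $f_j$ predicting
$\hat v_j(t)$ from the recent context window. At each timestep the model
picks among **keep / switch / reset / spawn** by local MAP over

$$
P(j \mid v(t)) \;\propto\; \pi_j \cdot
  \mathcal N\!\left(\lVert v(t) - \hat v_j(t)\rVert;\, 0, \sigma\right),
$$

where the sticky uniform-process prior $\pi$ gives the active schema mass
$1+\lambda$, every other schema and the reset candidate mass $1$, and the
spawn candidate mass $\alpha$ (spawned schemas copy a continuously trained
generic network). An *event boundary* is a hand-off from one network to
another.

Three variants differ only in *when* this inference runs:

| variant | trigger |
|---|---|
| `sem2` | every timestep |
| `pe`   | prediction error $\lVert v(t)-\hat v(t)\rVert$ exceeds the active schema's running baseline by a margin |
| `unc`  | Monte Carlo dropout uncertainty $U(t)=\tfrac1{S-1}\sum_s \lVert v_{s,t}-\bar v_t\rVert^2$ exceeds its baseline |

Only the active schema (and the generic network) learn, one SGD step on
squared prediction error per timestep, in a single pass — each activity is
seen exactly once.

## Worked example

```r
library(eventsem)

corp <- generate_corpus(generator_config(seed = 1))   # 30 train / 6 validation
fit  <- event_sem(corp, variant = "unc", seed = 1)    # single-pass training
fit
#> Event-schema model (variant: unc )
#>   trained on 30 activities (single pass), seed 1
#>   schemas spawned: 4
#>   final validation PE: 10.65 | boundaries/activity: 6.33

vl    <- validation_labels(fit)                       # model event labels
truth <- unlist(lapply(vl$activity_ids,
                       function(id) corp$activities[[id]]$true_labels))
adjusted_mutual_information(vl$labels, truth)
#> [1] 0.3454472
```

The fit object answers the usual questions: `summary(fit)` (checkpoint
table, decision counts, schema spawn/reuse curves), `plot(fit)` (learning
and boundary-rate curves), `residuals(fit)` (per-timestep prediction
errors), `coef(fit)` (schema weights), `predict(fit, newdata)` (frozen
inference over new activities), `simulate(fit, schema = 1)` (generative
rollout of a learned schema). An AMI of ~0.35 against ground-truth labels —
with a 48-permutation chance level near 0.08 — says the spawned schemas
track the generator's event classes without ever seeing a label.

A thin CLI over the same functions lives at `inst/cli/eventsem.R`
(subcommands `simulate`, `train`, `evaluate`, `tune`, `permute`).

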