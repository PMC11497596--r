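---
title: "Event-schema models of activity comprehension: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-schema models of activity comprehension: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventsem)
```

## The model

`eventsem` implements an online model of event comprehension. The world
arrives as a stream of *scene vectors* — fixed-length real summaries of one
timestep of activity (by default 30 dimensions sampled every 1/3 s: 14
body-motion features, 13 object-semantic features, 2 object
appearance/disappearance flags, 1 luminance-change feature). The model
maintains a *library of event schemas*, each a small recurrent predictor
network, and at every moment exactly one schema is *active*: the active
schema plus its hidden state is the current event model. Comprehension is
cast as one-step prediction: the active schema predicts the next scene
vector from the recent past, and the stream of its successes and failures
drives both learning and segmentation.

At each timestep the model chooses among four outcomes:

* **keep** the active schema;
* **switch** to another schema in the library;
* **reset** the active schema's hidden state (same knowledge, fresh
  situation — e.g. washing a second plate right after the first);
* **spawn** a new schema, initialized from a continuously trained *generic*
  network.

The choice is a local maximum a posteriori decision. The prior over
candidates is a *sticky uniform process*: every existing schema has equal
prior mass (no rich-get-richer accumulation), the active schema gets a
stickiness bonus `1 + lambda`, the reset candidate counts like a non-active
schema, and the spawn candidate gets concentration mass `alpha`. Each
candidate's likelihood is an isotropic Gaussian density of its Euclidean
prediction error with a single global noise scale `sigma`; the spawn
candidate is evaluated through the generic network's prediction, so
spawning wins exactly when nothing in the library predicts well. All
posterior arithmetic is done in log space with log-sum-exp normalization.

An *event boundary* is a transition of the active schema from one network
to another. Hidden-state resets are event-model transitions but not, by
default, boundaries (`count_resets_as_boundaries` flips this); the
operational definition of a boundary is the hand-off between networks.

### Predictor networks

Each schema is a four-layer network: a fully connected input layer with
leaky-ReLU activation (slope 0.3), a gated recurrent unit (GRU) layer, a
second leaky-ReLU fully connected layer, and a linear read-out back to
scene space. Hidden size is 16 units per layer by default;
`hidden_multiplier` doubles or triples it for the generic-only baselines.
Every schema — active or not — predicts from the same context: the `k = 3`
most recent scene vectors, zero-padded at sequence start. Training is plain
stochastic gradient descent on squared prediction error with dropout
(probability 0.5) applied before every weight layer, one step per timestep,
for the active schema and the generic network only. The backward pass is
implemented directly (and verified against finite differences in the test
suite); the global gradient norm is clipped at 10 because raw squared-error
steps at event boundaries are occasionally violent enough to destabilize
networks this small.

Because predictions are recomputed from a short window, inactive schemas
need no persistent state. The active schema, however, carries *pre-window
memory*: a hidden state summarizing the scenes of its current tenure that
have aged out of the window, advanced by one GRU step as each scene leaves.
The keep candidate predicts from this carried state; the reset candidate
predicts from the same window with a re-initialized state. The two
therefore coincide during the first `k` steps of a tenure (ties prefer
keep), and diverge afterwards — which is precisely what gives the reset
outcome content. The window length `k` is not part of the architecture's
published description; 3 steps (1 s) was chosen as the shortest window that
spans the motion block's autocorrelation in the synthetic generator.

### Epistemic uncertainty

Prediction uncertainty is estimated by Monte Carlo dropout: the active
schema generates `S = 32` predictions, each under an independent
inverse-scaled dropout mask (masks held fixed across the window unroll
within a sample), and the uncertainty is the trace of the sample covariance

\[
U(t) = \frac{1}{S-1}\sum_{s=1}^{S}\lVert v_{s,t} - \bar v_t \rVert^2 .
\]

Training with dropout is what makes this quantity meaningful: the weights
adapt to predict well *under* dropout on inputs they have seen, so the
spread of dropout predictions is smaller on familiar input regions than on
unfamiliar ones. Aleatoric noise is treated as constant and ignored.

### Gated variants

The ungated model (`variant = "sem2"`) runs the full schema inference at
every timestep. The two gated variants monitor the active schema only and
trigger inference when its gating signal — prediction error for
`variant = "pe"`, dropout uncertainty for `variant = "unc"` — exceeds that
schema's running baseline by a margin `m`. The baseline is a per-schema
exponential moving average (decay 0.9) updated every timestep with the
post-decision active schema's signal, including on timesteps where
inference fired; a schema's baseline is initialized at its first observed
signal. `m = -Inf` makes the gate fire always, and the gated variants then
reproduce the ungated decision sequence exactly under shared seeds (this
equality is asserted in the test suite); `m = Inf` never fires, so the
model spawns once at the first step and never segments again.

Two points the architecture leaves open were resolved as follows: the gate
baseline *is* updated on timesteps where inference fires (using the
post-decision schema's signal), because a stale baseline otherwise makes
the firing rate drift after every transition; and candidate schemas during
inference are compared by likelihood only — uncertainty is never computed
for non-active candidates, keeping the gated variants' extra cost at one
Monte Carlo sample set per timestep.

## Training and evaluation protocol

Training is single-pass and online: each training activity is consumed
exactly once, whole, in a (seeded) shuffled order, and no scene is ever
revisited. The schema library persists across activities; hidden states and
tenure reset at each activity start. After every 10 training activities and
at the end, all validation activities are processed with learning disabled
— weights are bit-identical before and after a validation pass (asserted by
fingerprint in the tests). Gate baselines carry in from training, with each
validation activity starting from the same snapshot. A run of eight
simulations (shuffled orders, distinct seeds) gives eight data points per
metric per checkpoint.

Validation prediction error is the mean over activities of the mean over
timesteps of the squared Euclidean error of the active model's prediction.
Segmentation agreement is the scaled point-biserial correlation between the
model's binary boundary series and the normative series (per-timestep
proportion of raters marking a boundary): the raw Pearson correlation is
rescaled between the minimum and maximum achievable with the same boundary
count, placing the count's boundaries at the smallest and largest normative
values respectively — the correlation is monotone in the sum of normative
values at the boundary positions for a fixed count, which is what justifies
the sorting construction. Categorization agreement is adjusted mutual
information (hypergeometric-model expected MI, max normalization) between
the model's event labels and the true class labels, complemented by purity
and coverage. Chance levels come from length-preserving permutation nulls:
the runs of the concatenated validation label sequence are shuffled
(preserving the run-length multiset, hence the boundary count and event
length distribution), with rejection sampling keeping permuted boundaries
out of the between-activity gap intervals where no model or human boundary
can occur; 48 permutations form the null.

Model-to-rater comparisons use the full normative series; rater-to-group
agreement (`rater_agreement()`) excludes the rater under evaluation from
the series (leave-one-out), since otherwise each rater is correlated with
their own contribution.

## The synthetic generator

No activity corpus ships with the package; `generate_corpus()` produces
one with known ground truth. Each of `n_classes = 4` event classes is a
stable linear attractor on the motion block (a random rotation scaled to
spectral radius 0.6–0.85, so each class has distinct, learnable short-run
dynamics), a class offset on the motion and semantic blocks scaled by
`separation = 3`, and shared emission noise (`noise_sd = 0.05`). An
activity concatenates 6–7 scripted events of 5–9 timesteps each; the
semantic block is piecewise constant within an event (class offset plus a
small per-event instance jitter), the two object-change flags spike at
event onsets/offsets, and the luminance dimension follows a slow
autoregression. Actors contribute additive style offsets (SD 0.1), and
training and validation activities share classes and actors but not
scripts, so validation tests generalization across instances. Simulated
raters degrade the true boundaries with 0.5 s Gaussian jitter, a 20% miss
rate, and one false alarm per minute — 30 raters per activity.

The default corpus is 30 training and 6 validation activities — roughly
1,300 training timesteps. These sizes keep a full eight-simulation,
three-variant evaluation comfortably interactive on one core while leaving
the class structure recoverable; they are the sizes at which the shipped
evaluation suite runs. Event durations (5–9 steps, ~2–3 s) are an order of
magnitude shorter than naturalistic scripted actions; consequently
absolute numbers (prediction errors, boundary rates, mean event lengths)
are not comparable to those from full-scale corpora, and the evaluation
suite therefore checks *properties* — learning curves fall, agreement
beats its permutation null, modularity protects against interference —
rather than reproducing any published magnitudes.

What passing these tests does **not** show: the generator's linear
attractor dynamics are far simpler than naturalistic activity (no
hierarchy, no cross-class shared structure, no feature correlations beyond
the class offsets), rater noise is unbiased (real raters have systematic
reaction-time lag), and the semantic block's within-event constancy makes
class identity easier to read out than from real embeddings.

## Numerical choices and degenerate inputs

* Posteriors are computed in log space; if every candidate's likelihood
  underflows (a diverged predictor), the prior alone decides.
* Exact posterior ties are broken keep > reset > lowest-id switch > spawn,
  keeping traces deterministic.
* Non-finite gradients skip the update and flag the step; the global
  gradient norm is clipped at 10.
* The scaled point-biserial is undefined (NA with a warning) for zero or
  all boundaries or a constant normative series; boundary-interval
  statistics need at least two boundaries; the flurry threshold (1 s) uses
  strict inequality.
* Rater times are binned by `floor(time / dt)` and clipped into the
  activity span; timestep `t` covers `[t dt, (t+1) dt)`.
* The first timestep of a run forces a spawn (the library is empty). A
  frozen validation pass never grows the library: if spawn wins during
  validation, the best existing candidate is taken instead.
* `max_schemas` caps the library; at the cap, spawning is disabled and
  logged, and the spawn decision degrades to keep.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `stickiness` | 4 | prior mass | calibrated so the default generator yields boundary rates near the true ~5.5 events/activity without mid-event chatter |
| `concentration` | 0.3 | prior mass | new schemas must beat all existing ones decisively |
| `noise_scale` | 1 | scene units | likelihood scale of the same order as within-event prediction error after learning |
| `gate_margin` | 0 | signal units | fire on any excursion above the schema's own baseline |
| `ema_decay` | 0.9 | — | baseline memory of ~10 timesteps (~3 s) |
| `dropout_rate` | 0.5 | — | the architecture's stated regularization level |
| `dropout_samples` | 32 | — | the architecture's stated sample count |
| `context_window` | 3 | timesteps | 1 s of context; see above |
| `learning_rate` | 0.02 | — | small enough that learning is still visibly in progress at the first validation checkpoint of the default corpus |
| `hidden_size` | 16 | units/layer | smallest size that learns the generator's dynamics reliably |

`stickiness` and `learning_rate` were calibrated on the synthetic
generator's default conditions (the package's own boundary-rate matching,
`tune_boundary_rate()`, automates the same procedure); the dropout
constants are fixed by the architecture; the rest are round defaults in
the ranges above.

## Known limitations

* Pure-R networks: a full eight-simulation three-variant run takes a few
  minutes; scaling to corpora hundreds of times larger would require a
  compiled backend.
* The sticky uniform process has no event-to-event transition structure —
  the prior for the next schema ignores which schema is ending.
* Uncertainty gating inherits the weakness that a confidently wrong schema
  generates no gating signal; only the error-based gate or the full
  inference can recover quickly in that case.
* No memory of past scene-to-schema assignments: re-encountering a
  familiar situation still requires inference.

## A worked run

```{r, eval = FALSE}
corp <- generate_corpus(generator_config(seed = 1))
fit <- event_sem(corp, variant = "unc", seed = 1)
summary(fit)
plot(fit)

vl <- validation_labels(fit)
truth <- unlist(lapply(vl$activity_ids,
                       function(id) corp$activities[[id]]$true_labels))
adjusted_mutual_information(vl$labels, truth)
```
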