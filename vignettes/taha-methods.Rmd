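---
title: "Cross-species attention-head transfer and pruning: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species attention-head transfer and pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taha)
```

This vignette is the package's account of what it computes and why the
open design choices were made the way they were. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

The backbone is a pre-norm Vision Transformer: patch embedding with a
learned positional term and class token, `L` blocks of multi-head
self-attention plus a GELU MLP, residual connections, and a linear
classifier on the final class-token representation. Each head computes
`softmax(Q_h K_h' / sqrt(d_k)) V_h`; the concatenated head outputs are
mixed by an output projection `W_o` whose row blocks pair one-to-one with
heads. That pairing is what makes head surgery exact: deleting a head's
Q/K/V blocks together with its `W_o` rows is algebraically identical to
zeroing its output slice, a property the test suite verifies to 1e-6 on
hundreds of random instances.

Everything is plain R matrix code, including the reverse pass. The
gradients of the full computation graph — layer norms, attention softmax,
GELU, the KL alignment term injected at the attention maps, and the
consistency term injected at the head-output slices — are hand-derived
and pinned by finite-difference checks at tolerance 1e-6 in
`test-backbone.R`. This makes the package self-contained and keeps the
training loop inspectable, at the price of speed: the intended scale is
a few layers and tens of thousands of parameters, not ImageNet.

One initialization choice deserves a note. Query/key projections are
initialized with sd `3/sqrt(d)` rather than a width-independent constant.
With layer-normed inputs (token norm `sqrt(d)`), attention logits then
start at unit scale for any embedding width. A constant sd (the habit
inherited from full-size models, where `d` is large enough not to care)
leaves narrow research-scale models with logits of order 1e-3 — i.e.
uniform attention everywhere. Uniform attention can still classify
(through the value pathway), so nothing in training ever sharpens it, and
head-level analyses become vacuous: every head is the same average head.
Unit-scale logits give heads distinct, trainable attention patterns from
the start.

## Alignment

The adaptation state holds three players: the frozen source-pretrained
snapshot, the live model (initialized from the same weights), and the
phenotypic MLP. Each alignment step computes attention maps of both models
on the *same* target-domain batch and takes one Adam step of the live
model on

`mean_h DAL_h + lambda * PCC`.

Design choices made here, and why:

- **Row-wise KL.** The divergence between two attention maps is taken row
  by row (each query row is the only softmax-normalized distribution in
  the object) and averaged over rows and batch. Both arguments receive
  the additive smoothing `eps = 1e-8` *symmetrically*. The symmetric form
  matters numerically: with one-sided smoothing the gradient at
  `A^s = A^t` is not exactly zero, and an adaptive optimizer (Adam
  normalizes by gradient magnitude) amplifies that O(eps) residual into
  full-size parameter updates. With symmetric smoothing the minimum is
  exactly stationary.
- **Direction.** `KL(source ‖ target)`: the frozen source map is the
  reference distribution. The loss is asymmetric, and the tests pin the
  direction.
- **Which images.** Both maps are evaluated on target images — the source
  map through the frozen snapshot. Alignment toward the target species is
  only meaningful on target inputs; source images never enter the loop.
- **What updates.** By default only the per-head Q/K/V/O projections (and
  the phenotypic MLP) move during alignment; patch embedding and the MLP
  blocks stay fixed, with a config switch (`update_scope`) to free
  everything but the patch embedding. Head parameters are what is being
  aligned and scored; moving the rest would confound the per-head
  attribution.
- **PCC label encoding.** The consistency loss is a squared L2 norm, so
  classification labels enter as one-hot columns z-scored over the
  labeled subset (population sd). Cross-entropy is deliberately not used:
  the loss is specified as a squared distance, and standardized targets
  keep its scale comparable across class balances.
- **Per-head aggregation.** The total alignment objective averages DAL
  over currently retained heads, keeping the loss scale invariant to how
  many heads survive pruning.
- **Lambda schedule.** Linear from 0.1 to 1.0 over one alignment phase
  (`warmup_steps = steps_per_phase` by default), constant afterwards:
  early steps prioritize attention alignment, later steps phenotypic
  prediction.

## Scoring and pruning

`HTS_h = alpha * exp(-DAL_h) + (1-alpha) * Corr(Z_h, y)`, `alpha = 0.6`.

The correlation reduction for a multivariate head output against a
categorical label is not canonical, so it is isolated behind one function
(`head_label_correlation`) and defined as: token-mean pool the head
output per sample, Pearson-correlate every feature dimension with every
standardized one-hot label column, take the maximum absolute correlation
over classes per dimension, and average over dimensions. This lands in
[0, 1], matching the score's intended range; constant dimensions and
absent classes contribute zero. Raw signed Pearson would make the score
direction-dependent for features that happen to anti-correlate, which is
meaningless for a transferability ranking.

The threshold `tau = mean(HTS) - beta * sd(HTS)` uses the *population*
standard deviation — the scored heads are the entire population being
thresholded, not a sample — and `beta = 1.5` by default, which only
removes pronounced outliers (on a bimodal half/half score split, `tau`
goes negative and nothing is pruned; the tests exercise this). Ties at
`tau` are retained. HTS is pooled globally across layers by default,
which lets layers end up with different head counts (fractional per-layer
averages in the cost report); per-layer pooling is available via config.
Scoring uses the labeled target subset only, since the correlation term
needs labels. A per-layer floor (default 1 head) force-retains the
top-scoring heads of any layer the threshold would empty, and flags them.

## The pipeline

`run_taha()` executes, per outer iteration: one alignment phase, HTS
evaluation, threshold pruning, and one supervised fine-tuning phase
(cross-entropy on the labeled target fraction, updating attention, final
norm, and classifier). The loop stops after the first iteration that
prunes nothing, or at `max_outer_iters` (default 5). Two details:

- **Pruning is the only irreversible state change**, so "no heads pruned"
  is the convergence signal. Every iteration ends with fine-tuning —
  including the converging one — so the returned model is always in a
  supervised-recovered state, never freshly out of an alignment phase
  (alignment alone optimizes attention similarity, not classification,
  and a run that stopped there would hand back a degraded classifier).
- During the loop, pruned heads are *masked*, which the surgery
  equivalence theorem makes output-identical to removal; physical surgery
  produces the final compact model once. This keeps head indices stable
  across iterations for the score tables and trajectories. The optimizer
  state is reset at each pruning event (moment estimates for removed
  heads are meaningless).

Randomness: one master seed derives per-stage seeds (data generation,
initialization, batch sampling per phase) by fixed offsets; two runs with
the same config are bitwise-identical in score tables and masks.

## The synthetic benchmark

The generator emulates the structure of a cross-species transfer, not the
appearance of real plants. Each image has three channels: a morphology
channel (class signal: an elliptical leaf blob whose size distribution is
class-conditional, darkened by 2–4 vein-like lines), a texture channel
(species signal: background level plus noise), and their mixture. A
transfer pair shares the class-conditional shape distributions — the
shared-morphology assumption — while the target's texture statistics are
shifted by `shift_magnitude` (default 0.5): background level +0.2·m,
noise sd +0.05·m, plus a high-frequency speckle field of amplitude
0.25·m, so the band-pass energy of the texture channel separates the
domains monotonically in m (verified over seeds in `test-synthetic.R`).
Shape and texture use separate RNG streams, so texture randomness can be
redrawn without touching labels or morphology — which is how the tests
verify that the class signal lives entirely in the morphology channel.

The morphology signal is deliberately noisy (blob contrast 0.30 over a
0.15 background with pixel noise sd 0.12): classes remain separable by a
simple foreground-area statistic, but not so trivially that a classifier
never needs more than the first gradient step. Defaults: 3 classes, 32 px
images; the bundled experiment uses 240 source and 400 target images with
a 15% labeled target fraction (the top of the 10–15% semi-supervised
protocol, giving 60 labeled images for the correlation estimates).

**Planted structure.** With `glyph = TRUE`, source images carry a glyph
filling exactly the top-left corner patch (8 px at the default patch
size, so attention granularity matches) of the *texture channel*, with
brightness encoding the class; target images never do. Three design
points make this a working ground truth for transferability, each the
survivor of an alternative that fails:

- *Fixed corner with brightness code*, not a class-coded corner position:
  positional information survives token-mean pooling through any head's
  value pathway, so a position-coded glyph never forces specific heads to
  become non-transferable.
- *Texture channel only*: reading the glyph then requires texture-space
  value projections, and the texture channel is class-independent
  everywhere on the target — so a glyph head's pooled output is genuinely
  decorrelated from labels there, regardless of how much attention mass
  sits on the corner. A glyph drawn in the morphology channel lets glyph
  heads keep high label correlation through the class signal that leaks
  into every patch.
- *The blotch field*: without patch-level background noise, alignment can
  quietly "rescue" a glyph head by re-pointing its value projection at
  class features while its attention map stays put; with blotchy target
  texture, whatever a texture-space head reads is noise-dominated.

Heads whose mean attention mass on the glyph token exceeds twice the
uniform share `1/n_tokens` (measured on the frozen source model over
source images) are counted as glyph-attending in the recovery
experiment. Note that the ground truth is intentionally one-sided: a
*second-layer* head attending the corner position can be genuinely
transferable, because the residual stream at that position already
carries class information accumulated by the first layer — the
experiment therefore requires at least one glyph-attending head to be
pruned, not all of them.

What passing tests on this benchmark do *not* show: robustness to real
morphological variation (occlusion, pose, growth stage), to class
imbalance, or to label noise; the generator has none of these.

## Numerical and scale choices

- Softmax rows are stabilized by max subtraction; layer norm uses
  eps 1e-6; KL smoothing 1e-8.
- The reference optimizer settings are Adam at 3e-5 with batch 32 — the
  appropriate regime for fine-tuning a full-size pretrained backbone, and
  the package defaults (`run_config()`). The bundled experiments
  (`demo_run_config()`) train a 2-layer width-32 model *from scratch*,
  where 3e-5 is far below the useful range; they use 1e-3 for
  pretraining, alignment, and fine-tuning. This is a model-scale choice,
  documented here once, not a tuning knob.
- The phenotypic MLP uses hidden width 8 in the bundled experiments: with
  60 labeled samples, a wider MLP memorizes the consistency targets and
  the constraint stops exerting pressure on the heads it is supposed to
  probe.
- Experiment sizes: 300 pretraining steps, 60 steps per alignment and
  fine-tuning phase, at most 3 outer iterations, 10 seeds for the
  stochastic recovery experiment. These were chosen as the smallest sizes
  at which source pretraining saturates (accuracy ~1 on the source) and
  the loop completes its iterations; the vignette and acceptance script
  state them so runs are comparable.
- Cost accounting counts 1 MAC per reported "FLOP" (the vision-community
  convention), includes the patch-embedding projection, and excludes
  softmax, norms, GELU, and the classifier; this convention reproduces
  the standard 17.6 G figure for the full-size 12-layer, 12-head backbone
  at 224 px, which the acceptance suite checks to 3 significant figures.
  Percent reductions are rounded half-up to one decimal; head counts are
  reported as per-layer averages to one decimal.
- The printed pruned-model absolutes of the reference cost table (10.4 G,
  51.9 M) are not reachable from the full-size model by attention-head
  removal alone — the MLP blocks dominate and head surgery does not touch
  them — so the accounting module reproduces the table's arithmetic
  identities (the percent reductions from the printed inputs, and the
  full-model count from the architecture) and makes no claim to re-derive
  those pruned absolutes.

## Known limitations

- Pure-R training: wall-clock limits the backbone to research scale.
- The correlation term saturates in worlds where every head's pooled
  output correlates with the class (as in very low-dimensional synthetic
  tasks); there, DAL drift after fine-tuning does most of the
  discriminating between heads.
- Class labels must be categorical; continuous phenotypes would need a
  different PCC target encoding and correlation reduction.
- The per-layer floor guarantees architectural validity, not quality: a
  layer whose every head scores badly keeps its least-bad head.
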