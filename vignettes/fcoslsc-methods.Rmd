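---
title: "Methods: anchor-free green-fruit detection with level-space-channel attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-free green-fruit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter and their defaults,
the numerical choices, what the synthetic benchmark does and does not show,
and the known limitations.

## The detection model

The detector is a fully convolutional one-stage network. Every cell of a
five-level feature pyramid (strides 8, 16, 32, 64, 128) is an *anchor point*
at image coordinates `(s(col+0.5), s(row+0.5))` that predicts a class
confidence, the four distances `(l, t, r, b)` to the edges of the box it
belongs to, and a center-offset ("centerness") score. The final confidence
is the product of the class and center-offset probabilities; boxes are
decoded as `(x-l, y-t, x+r, y+b)` and clipped to the image.

Three architectural devices target the green-on-green regime:

**Modulated deformable convolutions** in backbone stages C3–C5. A 3x3
kernel point `p_n` samples the input at `p + p_n + Δp_n` (bilinearly
interpolated; out-of-map samples contribute zero) and is scaled by a
modulation coefficient `Δm_n = sigmoid(·) ∈ [0, 1]`, so irrelevant
background samples can be switched off. Offsets and modulation are predicted
per location by an auxiliary 3x3 convolution over the same input (27
channels: 2·9 offsets + 9 modulation logits). With zero offsets and unit
modulation the operator equals a standard convolution — a property the test
suite asserts exactly, and the initialization exploits: the offset branch
starts at zero with a large modulation bias (`sigmoid(12) ≈ 1`), so training
starts from plain-convolution behavior.

**The attention stack** on the pyramid tensor `X ∈ R^{L×S×C}` (L = 5
levels, S = H·W positions, C = 256 channels), applied `lsc_blocks` times as
a cascade:

* *Level/scale* (`M_L`): global-average pool each level, collapse channels by
  a shared 1x1 convolution, ReLU, then a hard sigmoid
  `hs(x) = clamp((x+3)/6, 0, 1)`; the resulting scalar in [0, 1] rescales
  its level. The hard-sigmoid form is the standard cheap approximation with
  `hs(0) = 0.5`.
* *Spatial* (`M_S`): for each target level, offsets and modulation are
  predicted from the level itself (the layer "not adjusted"); the level and
  its resized neighbors (bilinear up/down-sampling to the target grid) each
  pass through a modulated deformable 3x3 convolution sharing those offsets,
  and the results are averaged. Boundary levels average over their two
  existing members rather than dividing by a fixed L — zero-padding the sum
  would systematically dim the outermost levels.
* *Channel* (`M_C`): pool over levels and space, compress and restore through
  a two-layer bottleneck (reduction `r = 4`) emitting four values per
  channel, normalize them to [−1, 1] by `2·sigmoid(x) − 1`, and add them
  (gain 0.5) to base coefficients `(a1, a2, b1, b2) = (1, 0, 0, 0)`. The
  activation `max(a1 x + b1, a2 x + b2)` is then a *dynamic* ReLU: exactly
  ReLU at initialization (the restoring layer starts at zero), and a
  learned, per-channel piecewise-linear gate after training.

The whole attention stack initializes to a near-identity map: the scale
branch starts at a constant (zero weights), the spatial aggregation's
self-kernel is an identity delta with zero neighbor kernels and zero
offsets, and the channel activation starts as plain ReLU. A He-initialized
stack would scramble the pyramid through random cross-level mixtures before
training begins — measurably slowing short-budget training — whereas the
identity start lets the attentions grow from neutral. (The group-normalized
head makes the constant scale factors of the cascade irrelevant.)

The head consumes each level at its original resolution; resizing happens
only inside the spatial aggregation. Head towers (4 conv + group norm +
ReLU layers each) are shared across levels, with a per-level learnable
scalar on the exponentiated box distances.

## Dual-weighting label assignment

Candidate positives for a ground truth are the locations inside its box,
within `candidate_radius = 1.5` strides (Chebyshev distance) of its center,
and whose maximum regression distance falls in the level's range
(0–64–128–256–512–∞). A location claimed by several boxes goes to the
smallest. Each candidate receives **two** weights computed from the current
predictions:

* `w_pos = t·e^{μt}` with `t = s·IoU^β` — large when the classification
  score `s` and the localization quality IoU *agree*;
* `w_neg = P_neg·s^γ` with `P_neg = 1` below IoU 0.5, `0` above 0.95, and
  linear in between (`-20/9·IoU + 19/9`, the unique line through those
  endpoints, which are the COCO evaluation thresholds) — the probability of
  being a negative times its importance.

The loss is

```
L = Σ_bag (−w_pos ln s − w_neg ln(1−s)) + Σ_non-candidates FL(s, 0)
    + λ Σ_bag w_pos · (1 − GIoU(b, b′)),
```

normalized per image by `max(Σ w_pos, 1)` — the bare sums grow with image
area and would make the batch-size-2 regime scale-dependent. Two candidates
with equal `w_pos` but different IoU receive different `w_neg`, which is the
point: ambiguous predictions get a finer-grained supervision signal than a
single positive/negative bit.

Choices worth making explicit:

* `s` in the weighting functions is the *fused* score (class × centerness),
  the same quantity ranked at test time; a raw-class-score mode exists
  behind `score_mode = "cls"`.
* The weights are recomputed from the live predictions at every iteration
  but are *detached*: gradients flow through `ln s`, `ln(1−s)` and the GIoU
  term, not through the weights, which act as supervision strengths.
* Hyperparameters `μ = 5, β = 2, γ = 2, λ = 1`, focal `α = 0.25, η = 2`:
  standard dense-detector practice, all exposed in `detector_config()`.
* The interval endpoints of `P_neg` are tied to the COCO evaluation range
  [0.5, 0.95]; `k` and `b` of the linear segment are forced by continuity
  at both endpoints, not free parameters.

**Cold start.** Both weights are proportional to the predicted score, and
`w_pos` additionally to a power of the current box IoU. At random
initialization both are numerically zero, so from-scratch training receives
no positive supervision and the focal background term collapses all scores —
an effect we reproduced experimentally (the loss settles at ~1e-4 with zero
detections). Prediction-aware assigners in this family are therefore
conventionally warmed up with a static assigner; `assign_warmup_iters`
(default 500, inside the learning-rate warmup) supervises the first
iterations with the classic center-sampling focal/centerness losses before
switching to the dual weights. With a pretrained backbone the warm-up is
harmless; from scratch it is necessary.

## Training and inference

SGD with momentum 0.9 and weight decay 1e-4; batch size 2; base learning
rate 0.00125 reached by linear warmup from 0.001 over 1000 iterations;
tenfold drops at the start of the 8th and 11th of 12 epochs. Preprocessing:
resize to 600x400, random horizontal flip (p = 0.5, training only),
per-channel normalization with the ImageNet constants (the standard
pretraining statistics; the data never dictate others), zero-padding
right/bottom to multiples of 32. Normalization inside the network is group
norm (32 groups, fewer when channels require) — batch statistics are
meaningless at batch size 2.

Inference: drop fused scores below 0.4, keep the top 1000 per level, pool,
class-wise greedy NMS at IoU 0.6 (the family default; the threshold is not
part of the reference recipe), keep the top 100 per image.

Evaluation is COCO-style: greedy score-descending matching per image/class
at each IoU threshold in 0.5:0.05:0.95, 101-point interpolated precision,
AP the mean over thresholds, AR the mean recall at the detection cap, size
bins at 32² and 96² pixels with out-of-range ground truth ignored rather
than penalized. Metrics are reported in percent.

## Complexity accounting

`model_complexity()` counts trainable scalars and conv/linear
multiply-accumulates (1 MAC = 1 FLOP; normalization, activations and pooling
excluded) by a shape-only pass through *the same forward code* as the real
model, so counter and implementation cannot drift. Feature sizes follow the
exact convolution arithmetic at the stated input (600x400 by default, no
padding to /32). Deformable sampling operations are not instrumented — the
convention of the hook-based counters used across this architecture family,
and the only convention under which the reference figures for these
configurations are mutually consistent — while their offset-predictor
convolutions (standard convs) are counted. Under these conventions the
plain configuration counts 32.11M parameters / 47.50 GFLOPs and the full
default 38.73M / 42.03 GFLOPs.

The attention stack defaults to `lsc_blocks = 3` with unshared neighbor
kernels: the reference parameter budget of the attention module (+6.74M) is
several times one shared block, and three unshared blocks are the closest
consistent reading; the block count is exposed in the configuration.

## The synthetic orchard benchmark

The generator renders seeded HSV scenes: a textured green canopy field
(smoothed noise + vertical gradient), shaded ellipse fruits whose hue sits
`fruit_hue_offset` degrees from the canopy hue (the single hardness knob),
deliberate fruit-fruit overlap, elongated darker strokes as branch/leaf
occluders, four lighting regimes (soft, strong, backlight, low light), and
Gaussian distance blur. Ground truth annotates the *visible* extent of each
fruit — what a human annotator could draw — and fruits below
`min_visible_fraction = 0.25` visibility are left unannotated (heavily
occluded fruit is annotatable, invisible fruit is not). Defaults emulate
the working resolution (600x400) and plausible orchard statistics: 2–8
fruits of radius 18–50 px, hue offset 15° (hard), 1–4 occluders, overlap
probability 0.3. Per-image seeds are `seed + index`, so datasets extend
without reshuffling.

The desk-scale benchmark (`smoke_benchmark()`) trains on 64 easy scenes
(128x128, hue offset 40°, no occluders) for 300 iterations at batch 2 and
evaluates 16 held-out scenes. Model widths are reduced (backbone ×0.25,
64-channel pyramid/head, one attention block); both variants share one
recipe — learning rate 0.005 with a 50-iteration warmup (the highest
setting at which the deepest variant trains stably from scratch; a small
from-scratch model tolerates and needs a higher rate than the fine-tuning
recipe) and one tenfold drop late in the budget; the per-level delta scale
starts at 8 px so decoded boxes carry usable IoU immediately; the
dual-weighting losses take over from the static warm-up at iteration 250;
evaluation uses a 0.05 score threshold as in standard COCO protocol. These
sizes keep the benchmark in the minutes range on a single core.

What passing shows: the assignment, losses, gradients, optimizer and
post-processing are wired correctly end to end — a detector that learns
nothing, or an evaluator that miscounts, fails loudly. What it does not
show: performance on real orchard images. The generator's fruits are smooth
ellipses with an honest hue gap; real green fruit shares texture with
foliage, and real occluders are not dark strokes. Numbers from this
benchmark say nothing about AP on photographic data.

The benchmark also reports the AP gap between the full model and the plain
configuration as a matched ablation. A caution on reading it: the full
model's advantages are designed for fine-tuning pretrained features over
thousands of iterations. Under a 300-iteration from-scratch budget, added
capacity and plasticity (deformable offsets, cross-level attention,
prediction-aware weighting) cost optimization speed first and pay off
later, so at desk scale the gap can have either sign; the benchmark
computes and reports it rather than asserting it.

## Numerical choices and degenerate inputs

* Bilinear sampling uses half-pixel centers (`align_corners = FALSE`
  convention); out-of-map deformable samples contribute zero to value and
  gradient.
* Scores are clamped to `[1e-6, 1 − 1e-6]` before logs; regression logits
  are clamped at 12 before `exp`.
* Group-norm epsilon 1e-5; He initialization for convolutions; the
  classification bias starts at `−log((1−π)/π)` with π = 0.01.
* Zero-area boxes are rejected by the GIoU loss (error) and dropped with a
  warning by the preprocessing resize; images with no ground truth
  contribute only the background focal term.
* Ties in NMS and matching resolve by first index at equal score/IoU;
  the candidate-bag tie rule is smallest ground-truth area.
* The split rounding is half-up on the training count (1361 × 0.7 → 953);
  both subsets are forced non-empty.
* Evaluation with no ground truth and no detections returns `NA` ("undefined"),
  never 0.

## Known limitations

* Training is single-core CPU; the full-width model at 600x400 trains at
  desk scale only in principle — minutes per iteration. The reduced
  configuration is the practical training target; the full configuration is
  exercised symbolically (complexity) and by unit forward passes.
* No pretrained backbone weights are bundled, so the fine-tuning recipe the
  full-scale defaults describe (lr 0.00125, 12 epochs) is reproducible in
  shape but was validated here only on the reduced from-scratch benchmark.
* The evaluator implements the COCO definitions directly (101-point
  interpolation, greedy matching, area-range ignores) but not crowd
  annotations.
* `M_S` resizing happens inside the attention only; a reading in which the
  whole pyramid is resized to the middle level's grid and back is possible
  but conflicts with per-level head decoding, and was not adopted.
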