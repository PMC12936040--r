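---
title: "Detecting alveolar bone dehiscence and fenestration on sagittal CBCT slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alveolar bone dehiscence and fenestration on sagittal CBCT slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Alveolar bone **dehiscence** is a V-shaped defect that involves the
alveolar ridge crest (ARC): the bone margin recedes apically from the
cementoenamel junction (CEJ). A **fenestration** is a window-like
interruption of the bone plate apical to an intact crest, bounded by a
coronal border (CB) and an apical border (AB). Both are measured on
labio-lingual (sagittal) CBCT cross-sections of a tooth, on each of the
labial/buccal and lingual/palatal root surfaces — four defect classes in
total. The clinical decision rules implemented here are strict
inequalities: a dehiscence is diagnosed when the ARC–CEJ distance *exceeds
2 mm* and a fenestration when the CB–AB gap is *greater than 2.2 mm*. A
tooth receives a positive diagnosis for a class only when **all three**
consecutive sagittal slices of that tooth are positive (the three-slice
consensus rule); `fenestra` propagates a tooth-level confidence as the
minimum of the three slice confidences, mirroring the AND.

`fenestra` packages the full measurement chain — supervision encoding,
network, geometric decoding, diagnosis, evaluation — together with a
synthetic phantom generator so that every stage can be exercised and tested
without clinical data.

## Supervision encoding

Each slice annotation holds up to four landmark endpoint pairs (one per
class) in 0-based pixel coordinates (x = column, y = row, origin at the
top-left pixel centre; images are oriented crown-up). `build_target_stack()`
converts an annotation into the 12-channel supervision map. Channels come in
four groups of three, one group per class in `defect_classes()` order;
within a group:

* **channel 1 — mask**: the segment between the two endpoints rasterized at
  width 3 px with flat end caps. Flat caps keep the extreme mask pixels
  aligned with the true endpoints, which is what makes the geometric
  decode-from-mask accurate; width 3 px is thin enough to localize yet
  thick enough to survive the encoder's downsampling. A segment shorter
  than one pixel falls back to marking the pixels nearest each endpoint so
  the supervision is never empty.
* **channels 2–3 — direction field** (dx, dy): at every mask pixel, the
  unit vector from the apical-role endpoint toward the coronal-role
  endpoint (root apex toward crown); zero elsewhere. For fenestrations the
  apical endpoint is the stored AB role; for dehiscences it is the endpoint
  nearer the apical (bottom) side of the image, since role geometry — not
  annotation order — defines the sense. The field is spatially constant per
  group, and the MSE loss runs over all pixels so the zero background is
  supervised too.

An alternative **heatmap mode** replaces the mask channel with the Gaussian
sum `h(x, y) = Σ_i exp(−((x−x_i)² + (y−y_i)²)/(2σ²))` over the two
endpoints. The sum is literal — coincident landmarks stack to 2.0, and no
clipping is applied — because the decoder only looks for local maxima, so
the choice costs nothing and keeps the encoding analytically simple. σ
defaults to 2 px, a spread comparable to the rendered cortical rim at
native pitch; it is configurable. The supervision mode default is
`mask_direction`: both mask and heatmap heads are implemented, and the
mask/direction parameterization is the one whose decoding we found
geometrically self-sufficient (region + axis + extremes), so it is the
package default rather than a claim about which variant is canonical.

## Network

The predictor is a 2D Swin-UNETR: a four-stage hierarchical shifted-window
transformer encoder with patch merging between stages, and a convolutional
decoder with skip connections. Within a stage, blocks alternate between
unshifted and shifted windows (shift = half the window, cyclic, with masked
attention across the wrap-around boundary and across zero-padding);
relative-position bias tables are included per head, as is standard for
shifted-window attention. Feature maps whose extent is not a multiple of
the window are zero-padded and masked, deterministically.

The decoder upsamples with transposed convolutions implemented as linear
pixel-shuffle steps, concatenates the matching encoder skip, and applies a
3×3 convolution; the head emits the 12 output channels at the stage-1
resolution as 4×12 values per token and pixel-shuffles them to full
resolution — i.e. the final transposed convolution directly produces the
logit map. Mask channels are emitted as pre-activation logits; their head
biases are initialized to −3 so the initial predicted positive rate matches
the rarity of defect pixels (about half a percent of the image), which
removes a long plateau at the start of training.

No deep-learning framework is assumed: the package contains a small
reverse-mode automatic-differentiation engine (dense arrays, explicit
backward closures, RcppArmadillo kernels for batched window attention,
neighborhood gathering and pixel shuffling). Training uses AdamW (decoupled
weight decay, none on norms/biases) with a cosine-annealed learning rate,
following the training protocol the detector is built around (200 epochs
and initial rate 1e-4 at clinical scale; the bundled phantom study uses a
shorter schedule, below). Gradient correctness is pinned by tests against
numerical differentiation, and windowed attention is tested equal to a
brute-force global-attention oracle when the window covers the feature map.

Architecture hyperparameters (depths, widths, window size) are
configuration surface with defaults (patch 2, embed 24, depths 2/2/2/2,
window 7), a "tiny" preset for the tests, and a 0.54M-parameter
configuration used by the bundled study.

## Geometric decoding and diagnosis

`extract_endpoints()` turns one channel group into a detection:

* **mask mode** — pixels with sigmoid probability strictly above the
  threshold (default 0.5) form the candidate region; the largest
  8-connected component is kept (ties broken by scan order). The direction
  field averaged over the component gives an axis; member pixels are
  projected onto the axis through the component centroid, and the extreme
  projections give sub-pixel endpoint estimates: each extreme is extended
  outward to the point where the interpolated probability crosses the
  *measurement boundary level*. On a binary target that crossing lands half
  a pixel beyond the extreme pixel centre (undoing rasterization bias); on
  a smooth prediction it reads the learned contour. When the mask was
  trained with a positive-class weight `w`, the weighted cross-entropy
  places its 0.5-probability contour where the true posterior is only
  `1/(1+w)` — i.e. systematically outside the true endpoint — so the
  evaluation pipeline reads endpoints at the calibrated level `w/(1+w)`
  while detection presence keeps the 0.5 threshold. This decouples
  detection sensitivity from measurement bias: in development runs it
  removed a +0.8 mm length bias without costing recall. The apical/coronal
  extremes map back onto the class's ARC/CEJ or CB/AB roles. Score =
  maximum sigmoid probability in the component.
* **heatmap mode** — the two highest local maxima separated by more than
  the non-maximum-suppression radius (2σ) are the endpoints; score =
  normalized peak height.

An empty region, a single-pixel component, or fewer than two peaks is a
valid *absent* outcome. Length is the endpoint distance times the pixel
pitch; the slice label applies the strict 2 mm / 2.2 mm thresholds; teeth
are diagnosed by the three-slice AND with min-score propagation. The
continuous score that feeds ROC analysis is a documented package default
(maximum mask probability per slice, minimum over slices per tooth), since
a confidence definition is otherwise unspecified in this setting.

## The phantom generator

The phantom emulates the data regime the detector targets: sagittal slices
of 320 × 224 px at 0.25 mm/px, grouped as three consecutive slices per
tooth with patient-level grouping. Rendering is schematic rather than
photorealistic — an enamel crown, a linearly tapered root, a dark
periodontal-ligament line, trabecular bone below a physiologic crest, a
bright cortical rim along the root surface, and per-defect washout regions
that remove bone lateral to the root between the true endpoints. The
pipeline consumes intensity contrast at the root–bone rim, which schematic
rendering provides; what the phantom does *not* model is real CBCT texture,
beam-hardening artifacts, anatomical variation between tooth types, or
rater ambiguity, so passing tests demonstrate the correctness of the
machinery, not clinical performance.

Ground truth is exact by construction: endpoints lie on the (linear) root
surface, the second endpoint is placed at the requested Euclidean distance
from the first, and the stored millimetre length always equals the
endpoint distance times the pitch. Key generator choices:

* **Lengths** are drawn from 0.5–6.0 mm, spanning both decision
  thresholds. Tooth-level-positive defects sample lengths at least
  0.25 mm *above* the class threshold and sub-threshold defects at least
  0.25 mm *below* it, with slice-to-slice jitter (±0.12 mm) clamped inside
  the stratum, so the intended tooth label always matches the label derived
  from the stored lengths. The margin represents the clinical reality that
  borderline defects are rare relative to measurement noise, and it keeps
  generated labels well defined at every render scale.
* **Sub-threshold defects are annotated but diagnosis-negative**
  (annotation precedes threshold application), and some negative teeth are
  "2 slices positive, 1 negative" configurations that specifically
  exercise the consensus rule.
* **Prevalences** default to 0.35/0.30/0.25/0.20 for buccal dehiscence,
  lingual dehiscence, buccal fenestration and lingual fenestration —
  dehiscence more common than fenestration, buccal more than lingual, the
  ordering reported in clinical series.
* **Healthy sides** carry a 0.3 mm physiologic ARC–CEJ offset, well below
  the smallest annotated defect (0.5 mm), so "no defect" and "annotated
  sub-threshold defect" remain visually distinct and the supervision is
  consistent.
* Same-side fenestrations are placed clear of a coexisting dehiscence so
  the two gaps never merge into one ambiguous region.
* Intensities are rendered to the 8-bit range (with Gaussian blur σ 0.7 px
  and 3% additive noise by default) and standardized per image downstream,
  matching exported-image workflows.

Smaller render sizes keep the same field of view: the pitch scales as
`0.25 × 320 / height`, so anatomy and defect geometry in millimetres are
unchanged.

## Training protocol

* Patient-level 7:2:1 split (largest-remainder rounding, seeded shuffle);
  all slices of a patient stay in one subset.
* Augmentation: random similarity transform (scale ±10%, rotation ±10°,
  translation ±5% of extent) applied identically to pixels (bilinear,
  via an exact affine kernel) and landmark coordinates, plus photometric
  Gaussian blur (σ up to 1.5 px) and additive noise (up to 5% of range).
  Pairs pushed out of bounds are dropped with a logged count. Ranges
  contain the identity by construction.
* Per-image z-score standardization (mean 0, SD 1); constant images map to
  zeros with a warning.
* Loss: per group, BCE-with-logits on the mask channel plus MSE on the two
  direction channels (heatmap mode: MSE on all three), summed unweighted
  across groups by default; term weights and a BCE positive-class weight
  are exposed. The default positive weight 25 compensates the ~0.5%
  positive-pixel rate so that mask probabilities are decodable at the 0.5
  threshold.
* AdamW (β 0.9/0.999, weight decay 0.01 except on norms, biases and bias
  tables), cosine annealing from the initial rate to `lr_min`, per-epoch
  shuffled minibatches, best-validation-loss checkpointing (validation
  exists for model selection; the selection criterion is lowest validation
  loss).

## The bundled scaled study

`run_scaled_study()` is the package's self-contained end-to-end
demonstration: generate a phantom cohort, split by patient, train a small
network, decode and evaluate the held-out test patients. Its default
problem size — 150 teeth (50 patients × 3) rendered at 96 × 64 px
(0.833 mm/px, the native 320 × 224 field of view at a coarser pitch), a
0.54M-parameter network (embed 16, window 4), batch 14, 30 epochs of AdamW
at 1e-3 with a positive-class weight of 4 and the matching calibrated
measurement boundary — is chosen so the whole study runs in under twenty
minutes on a single CPU while keeping the defect geometry resolvable
around the 2 / 2.2 mm diagnostic thresholds; the schedule is the smallest
we found that reliably converges endpoint recognition on this cohort. All
randomness flows from one seed expanded per stage. The same entry point
backs `scripts/acceptance.R`, which recomputes the headline quantities
from scratch at every invocation.

## Evaluation suite

* **Keypoint localization** — a truth endpoint is *recognized* when a
  predicted endpoint of the same slice, class and role lies within the
  match tolerance (default 2 mm; the tolerance is a package default, made
  transparent by an accompanying tolerance-sweep curve in every report).
  Euclidean distances are summarized as AED (mean), SD (sample, n−1, by
  default; population available), and Q1/median/Q3 by linear interpolation.
  Distances are collected over recognized points only; the recognition rate
  is reported alongside so unmatched points stay visible.
* **Length accuracy** — MAE, RMSE, MRE (ground-truth denominator), Pearson
  correlation; pairs require a truth defect and a detection of the same
  class.
* **Agreement** — Bland–Altman bias and 95% limits of agreement
  (bias ± 1.96 × SD of differences).
* **Disease detection** — accuracy, recall, precision, specificity, F1
  from the confusion counts (zero denominators reported as missing, not
  zero), ROC curves and trapezoidal AUC (ties counted one half), per class
  and at both the individual-image and tooth level.

## Numerical choices and degenerate inputs

* Strict inequalities at both diagnostic thresholds ("exceeds" / "greater
  than"), including in the generator's label bookkeeping.
* Decoding treats mask channels as logits with a strict `> 0.5`
  probability cut, so an exactly-zero logit map stays empty rather than
  lighting up the whole image.
* Largest-component ties break toward the first component in scan order;
  a zero average direction falls back to the crown-up axis (0, −1).
* Quantile type 7 (linear interpolation), matching the quartile oracle in
  the tests.
* Pairs with zero true length cannot occur (annotation invariant
  `p1 ≠ p2`), so the MRE denominator is always positive.
* Non-divisible feature maps are zero-padded then cropped; the padding is
  masked out of attention so it cannot leak into real tokens.

## Known limitations

* The phantom's schematic appearance means reported phantom metrics
  overstate what any model would achieve on clinical CBCT; the package's
  claims are about the correctness and reproducibility of the pipeline.
* Only single-rooted, crown-up anatomy is rendered; the decoder's
  apical-side convention assumes crown-up orientation.
* Defect quantification is endpoint-to-endpoint length only — no area or
  severity grading.
* The training engine favors clarity over speed; it is adequate for the
  bundled study sizes, not for clinical-scale training.
* The scaled study's headline numbers vary by several points across phantom
  cohorts (different master seeds draw different mixes of near-threshold
  defects into the small test split); the bundled test pins one seed, and
  the acceptance script recomputes the quantities for whatever seed it is
  given.
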