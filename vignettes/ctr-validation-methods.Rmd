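---
title: "Models and methods behind ctrval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctrval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The cardiothoracic ratio (CTR) — the maximal transverse cardiac diameter
divided by the maximal internal thoracic diameter on a frontal (PA-upright)
chest radiograph — is the standard index for cardiomegaly, with CTR > 0.5
the conventional threshold. Measuring it by hand is observer-dependent and
slow; segmentation networks can do it automatically, and the clinical
question is not whether the AI *correlates* with human readings but whether
it *agrees* with them closely enough to stand in for a reader, or at least
to assist one.

`ctrval` re-implements the full validation apparatus for that question as a
tested pipeline: a synthetic-data stand-in for the clinical images, a small
trainable segmentation network, mask-based CTR extraction with clinical
failure screening, simulators for the three measurement workflows (manual,
AI-only, AI-assisted), and the agreement / correlation / classification
statistics suite.

# The phantom model

Real CXRs of this kind cannot be redistributed, so the package generates
phantoms whose ground truth is *exact by construction*:

- the thorax is a large ellipse; the two lung fields are lateral ellipses
  whose **outer edges coincide with the thoracic extremes**, so the
  lung-union horizontal span equals the thoracic span;
- the heart is a central, slightly off-midline ellipse whose horizontal
  pixel span is set directly from the designed CTR (`round(ctr × span)`),
  using half-integer centre alignment so the rasterised span is exact;
- lung masks exclude heart pixels, so the three classes are disjoint —
  convenient for the softmax segmentation head and harmless for CTR, since
  the heart never touches the lateral lung extremes.

Consequently `|extracted CTR − designed CTR| ≤ 0.5/span ≤ 2 px/span` for
every case, which the tests assert for all rendered phantoms. Intensities
(dark lung fields, brighter mediastinum, brightest heart, additive Gaussian
pixel noise) only matter to the segmentation module; masks are noise-free
rasterisations.

Tunable geometry (defaults): image 256 px square (tests use 64 px),
pixel spacing 0.7 mm/px (a typical downsampled-CXR scale; the source study
never states resolution), thoracic span 70–80% of image width,
mediastinal half-width 10% of the span, heart offset 5% of the span.

**Per-group CTR distributions** (the stated world): normal
`N(0.454, 0.043)`, cardiomegaly `N(0.569, 0.047)`, 4,933 and 2,517 cases —
the demographics of a large clinical PACS cohort. Draws are rejected
outside (0, 1) with bounded retries; cardiomegaly draws can optionally be
truncated at 0.5, appropriate when that group is *defined* by exceeding the
clinical threshold (classification experiments) and off for pure agreement
experiments. The cohort's reported cardiomegaly count is internally
inconsistent in its source (2,517 images in the population description,
2,571 in the outcome counts); the package uses 2,517.

# Measurement simulators and their calibration

All measurement noise is **multiplicative (relative)** on the true CTR,
because every clinical summary of interest is a percentage of the mean.

**Observers.** `measured = true × (1 + bias + ε)`, `ε ~ N(0, sd²)`. The
default pair is calibrated from two closed forms for independent relative
errors — intra-observer CV `= 100·√2·sd₁` and inter-observer CV
`= 100·√(sd₁² + sd₂²)` — to the clinically reported scales of ~1.5%
(intra) and ~2.1% (inter), giving `sd₁ = 0.0107`, `sd₂ = 0.0184`. The
defaults carry **no systematic observer bias**: clinical readers do show
inter-observer biases of order 1–2%, but a fixed observer-level bias makes
the assisted workflow's inter-observer differences bimodal (accepted pairs
agree exactly; adjusted pairs sit at the bias), which distorts the CV in a
way the observed clinical data (lower assisted bias *and* lower assisted
CV) contradicts. Bias is a per-observer parameter (`relative_bias`) for
experiments that need it, and its Bland–Altman recovery is tested with
explicit values.

**AI-only.** With group-specific probability the measurement *fails*
outright (no value); otherwise the relative error comes from a
two-component normal mixture. Two calibration anchors pin the defaults
jointly:

1. the method CV of manual-consensus vs AI-only of ≈ 5.8% fixes the total
   mixture variance (`0.9·core² + 0.1·outlier² ≈ 0.057²`);
2. the AI-assisted outcome grading of ≈ 40% excellent / 56% good / 4% poor
   at the ±1.8% acceptance tolerance requires roughly 40% of AI errors to
   land within ~1.8% of the observers' readings.

A single moderately wide component cannot satisfy both (at `sd = 0.045` it
reproduces the CV but yields only ~12% excellent); the anchors force a
**sharp core** (`core_sd = 0.012`), a **very heavy tail**
(`outlier_sd = 0.177`, probability 0.10) — phenomenologically, an AI that
is nearly reader-grade on most cases and badly wrong on a minority — plus
failure rates 290/4933 (normal) and 9/2517 (cardiomegaly), concentrating
failures in the normal group (short heart diameters). At n = 7,500 the
realised grading is 40/56/4 and the realised method CV ≈ 6%, about 2.8×
the inter-observer CV. The true error law of any clinical AI is unknown;
this mixture is a configurable stand-in constrained by those two
observables, not a claim.

**AI-assisted.** Each observer compares the AI value against their own
(simulated) manual reading; within the ±1.8% relative tolerance the AI
value is accepted unchanged, otherwise the observer adjusts (modelled as
their own manual draw), and on AI failure the default-line fallback makes
the assisted value the observer's manual value. The clinical ±1.8% band was
derived *post hoc* from the accepted cases; here it is the explicit
parameter of the decision rule. Grading: failure → poor; accepted by both
observers' first readings → excellent; otherwise good — a partition, which
the tests assert unconditionally. The simulator assumes the observers'
own readings are formed independently of the displayed AI lines (no
anchoring); that assumption is stated, not asserted as clinical truth, and
is the main reason the assisted intra-observer CV reduction here (~1.5%
vs ~1.54%) is weaker than clinically observed (~1.1% vs ~1.5%).

**Replication design** is 2+1 (observer 1 twice, observer 2 once) with the
per-case consensus being the mean of the three readings; any failed or
missing constituent excludes the case from consensus-based comparisons,
with exclusions counted.

# CTR extraction and failure rules

Diameters are horizontal extreme-point spans of the masks, inclusive
(`right − left + 1` columns, × pixel spacing), applied identically to heart
and lung-union, so a heart spanning exactly half the thoracic columns gives
CTR 0.5 exactly; the convention is a documented choice, as mask-based
pipelines differ at the one-pixel level. Failure screening mirrors clinical
practice for automatic segmentations: empty masks, heart diameter < 3 mm
(the clinical "unreasonable size" rule; `min_heart_mm` configurable), an
analogous lung minimum, and a heart span exceeding the thoracic span by
more than 2 px (segmentation bleed must produce a failure, never CTR > 1).
Shape mismatch is an input error, deliberately distinct from measurement
failure. Diameters are column-spans only — no rotation correction — matching
line-based clinical measurement software.

# The segmentation network

An encoder–decoder with stage-wise skip concatenation: per encoder stage,
two (VGG-style: two or three) 3×3 convolutions + ReLU then 2×2 max
pooling; a bottleneck block; per decoder stage, ×2 nearest-neighbour
upsampling, a 2×2 convolution, concatenation with the matching encoder
features and two 3×3 convolutions; a 1×1 softmax head over background /
lung / heart. Two presets: `vgg16_like` (64/128/256/512 channels, the
clinical-scale architecture) and the test-default `reduced` (3 stages, 8
base channels, ~121k parameters), because desk-scale CPU training must
finish in minutes and no clinical weights exist to load. The loss
(unstated in clinical descriptions, so chosen here) is per-pixel
cross-entropy plus soft Dice, optimised by Adam (1e-3), one image per
step, seeded shuffle; training is deterministic on a single thread and
`epochs = 0` is a no-op. Tensor primitives (im2col convolution
forward/backward, pooling, upsampling) are RcppArmadillo; there is no
torch in this stack, and implementing the primitives is part of keeping
the artifact self-contained. Checkpoints are self-describing JSON
(config + weight tensors).

Whether the clinical system used one multi-class model or separate heart
and lung models is unknowable from its description (its training data had
different sample counts per structure); this package uses one multi-class
model, and two single-class models can be emulated by `classes = 2`
configurations.

On phantoms, the reduced preset trained on 100 cases for 10 epochs reaches
held-out Dice ≈ 0.99 for both structures (the acceptance benchmark asserts
≥ 0.90 lung / ≥ 0.85 heart — thresholds defined by pilot runs of this
artifact, not clinical claims). A background-only image yields no credible
heart and engages the extractor's failure path.

# Statistics

- **Bland–Altman**: percent mode (default) uses
  `d = 100(a−b)/((a+b)/2)`; bias = mean(d), LoA = bias ± 1.96·SD(d)
  (normal-theory limits of agreement; clinical tables sometimes label this
  interval "95% CI"). Absolute mode uses raw differences.
- **CV**: `100 · SD(signed raw differences) / mean(all 2n values)` — the
  verbatim clinical definition — in both modes. The two scales cannot be
  reconciled against each clinical table simultaneously (a published LoA
  implying SD(diff%) ≈ 2.49 alongside a printed CV of 2.13 admits no
  single denominator), so both are computed and reported rather than
  resolved.
- **R²** from the least-squares fit, banded poor/moderate/good/excellent
  with boundary values assigned to the lower band, following the clinical
  banding text literally (0.75 → moderate, 0.9 → good).
- **Paired t**: two-sided; zero-variance differences are flagged
  `degenerate` and reported as t = 0, p = 1 (all-zero) or |t| = ∞, p = 0
  (constant nonzero) rather than erroring.
- **Classification**: positive iff value > cutoff (matching "more than
  0.5 indicates cardiomegaly"); AUC by the Mann–Whitney rank statistic
  with midrank ties, which the tests prove equal to trapezoidal ROC
  integration on exhaustive small instances. Cutoff candidates are
  midpoints of adjacent sorted unique values plus sentinels below the
  minimum and at the maximum; the Youden optimum breaks ties toward the
  lowest cutoff (favouring sensitivity) and the max-sensitivity cutoff is
  the largest candidate with sensitivity exactly 100%.

# What a green test establishes — and what it does not

The phantom world reproduces the *structure* of the clinical findings:
method CV of the AI ≈ 3× observer CV; assisted workflow at least as
concordant between observers as manual; R² dropping from good to
moderate/poor under range restriction to the cardiomegaly subset; excellent
standard-cutoff classification coexisting with a collapsed
maximum-sensitivity cutoff; grading proportions 40/56/4. These are
*directional calibration checks* of a stated world, not recomputations of
clinical values: phantom geometry is trivially segmentable, observer errors
are independent Gaussians without anchoring or fatigue, AI errors are a
two-component stand-in, and no pathology (effusion, pericardial fat),
pediatric anatomy, rotation or exposure variation exists here. Operating
time is out of scope entirely; the workflow reports
accepted/adjusted/fallback counts instead.

# Numerical and design choices

- Seeds are explicit everywhere (population, per-case render, observers,
  AI, training shuffle); per-case render seeds are drawn once from the
  population seed, so `render = FALSE` populations re-render any case
  bit-identically on demand.
- CTR draws outside (0,1) are rejected with bounded retries (sampling
  failure is an error, not a silent clamp); a designed heart span reaching
  the thoracic span is an invalid-geometry error (the heart must sit
  inside the lung fields).
- The +1.96 LoA multiplier, the 2 px bleed tolerance, the 3 mm heart
  minimum and the ±1.8% acceptance tolerance are parameters with those
  defaults, not constants.
- CSV outputs format numbers explicitly (`%.6f` / `%.6g`), making reruns
  byte-identical.
- The end-to-end replication config measures the reference from
  ground-truth masks (`truth_mask`) and does not train the network — the
  AI error model stands in for clinical AI error, keeping full replication
  around a minute of CPU; a trained-segmentation path
  (`measure_population(source = "predicted")`) exists and is exercised by
  the tests at reduced scale.

# Known limitations

Phantoms are radically simpler than radiographs; segmentation Dice here
says nothing about clinical Dice. The observer model has no anchoring,
learning or fatigue, so assisted-workflow gains are conservative. The AI
error mixture is identifiable only up to its two calibration anchors.
Inter-observer bias is configurable but not part of the default stated
world. Confidence intervals on CV are not provided (none are reported
clinically); mixed-effects repeated-measures agreement models are out of
scope.
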