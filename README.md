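# ctrval

Tools for studying how automatic (deep-segmentation-based) and manual
measurements of the **cardiothoracic ratio (CTR)** agree, and whether an AI
measurement is fit to assist — or replace — a human reader.

The CTR is read off a frontal chest radiograph as

```
CTR = maximal transverse cardiac diameter / maximal internal thoracic diameter
```

with CTR > 0.5 conventionally indicating cardiomegaly. Automatic pipelines
segment the lung fields and the heart with an encoder–decoder network
(U-Net; clinically, often with a VGG-16 encoder) and take the horizontal
extreme points of the masks as the diameters. Clinical validation of such a
pipeline asks three different statistical questions:

- **Agreement** — Bland–Altman bias, limits of agreement
  (bias ± 1.96·SD of differences) and the coefficient of variation
  CV = 100 · SD(differences) / mean, between methods and between observers;
- **Correlation** — R² of a linear fit, banded as poor (< 0.5), moderate
  (0.5–0.75), good (0.75–0.9), excellent (> 0.9);
- **Classification** — sensitivity/specificity/accuracy/F1/AUC at the
  standard cutoff (0.5), the Youden-optimal cutoff
  (max sensitivity + specificity − 1) and the maximum-sensitivity
  (rule-out) cutoff.

The sobering clinical finding this package lets you reproduce in silico is
that these three lenses disagree: an AI whose method CV is ~3× the
inter-observer CV (i.e. clearly not interchangeable with a human) can still
show "good" R² on a mixed population and excellent classification metrics
at the standard cutoff — while collapsing at the rule-out cutoff. Agreement
(CV), not correlation or classification, is the right lens.

Because clinical CXR datasets of this kind are not redistributable, the
package includes a **synthetic phantom module**: chest-like images (thorax,
lung fields and heart as rasterised ellipses) with exact ground-truth masks
and a *known, designed* CTR, plus calibrated simulators for manual
observers (relative noise ~1–2% CV), AI-only measurement (sharp core +
heavy-tailed error mixture, ~5–6% method CV, group-asymmetric failure
rates) and the AI-assisted accept-or-adjust workflow with
excellent/good/poor outcome grading at the ±1.8% acceptance tolerance.

## What's inside

| Module | Functions |
|---|---|
| phantom | `population_spec()`, `phantom_geometry()`, `render_phantom()`, `generate_population()`, `simulate_manual()`, `simulate_ai_only()`, `observer_model()`, `ai_error_model()` |
| segmentation | `unet_config()`, `build_unet()`, `unet_train()`, `unet_predict()`, `dice_coef()`, `save_checkpoint()`, `load_checkpoint()` |
| ctr | `compute_ctr()`, `measure_population()`, `measure_manifest()` |
| workflow | `run_assisted()`, `grade_outcomes()`, `consensus_values()`, `run_study()` |
| stats | `bland_altman()`, `cv_percent()`, `linear_fit_r2()`, `paired_t_test()`, `classification_eval()`, `find_cutoffs()`, `compare_methods()`, `plot_comparison()` |
| cli | `study_config()`, `read_study_config()`, `replicate_study()`, `ctrval_cli()` (also `exec/ctrval`) |

The segmentation network (VGG-16-style or reduced encoder, skip
concatenation, softmax head, cross-entropy + soft-Dice loss, Adam) is
implemented on RcppArmadillo primitives and trains on a CPU in minutes at
the reduced preset; there is no GPU/torch dependency.

## Worked example

```r
library(ctrval)

# one phantom: designed CTR 0.55, extracted back from the masks
ph <- render_phantom(0.55, phantom_geometry(image_size = 64), seed = 1)
compute_ctr(ph$heart_mask, ph$lung_mask, ph$pixel_spacing)
#> ctr_result: CTR 0.5556 (heart 17.5 mm / thorax 31.5 mm)

# a 750-case validation study: two observers (2+1 replicates), AI-only,
# and the AI-assisted accept-or-adjust workflow
pop <- generate_population(
  population_spec(n_normal = 500, n_cardiomegaly = 250, seed = 7),
  phantom_geometry(image_size = 64), render = FALSE)
study <- run_study(pop)
study$grading
#> AI outcome grading (n=750): excellent 297 (39.6%), good 415 (55.3%), poor 38 (5.1%)

compare_methods(study$measurements, "manual", "ai_only", cases = study$cases)
#>          comparison subset   n      bias loa_lower loa_upper       cv        r2
#> 1 manual vs ai_only    all 712 0.1519024 -12.01257  12.31638 6.111077 0.8375664
#>   r2_category          t         p n_excluded
#> 1        good -0.0630649 0.9497325         38
```

The AI's CV against the manual consensus (6.1%) is about three times the
manual inter-observer CV (~2.1%), yet its all-data R² is "good" — and on
the cardiomegaly subset alone the same comparison drops to "moderate"
(range restriction):

```r
compare_methods(study$measurements, "manual", "ai_only",
                cases = study$cases, subset = "cardiomegaly")$r2
#> [1] 0.5641031
```

Classification at the three cutoffs (AI-only consensus values):

```r
cons <- consensus_values(study$measurements, "ai_only")
grp <- study$cases$group[match(cons$values$case_id, study$cases$case_id)]
cuts <- find_cutoffs(cons$values$ctr, grp == "cardiomegaly")
cuts$standard
#> standard cutoff 0.500: sens 90.3%, spec 82.3%, acc 85.1%, F1 0.809, AUC 0.933
cuts$max_sensitivity
#> max_sensitivity cutoff 0.315: sens 100.0%, spec 0.6%, acc 35.3%, F1 0.518, AUC 0.933
```

Excellent-looking AUC at the standard cutoff; near-useless accuracy at the
rule-out cutoff — the heavy-tailed AI error forces the 100%-sensitivity
threshold far below the clinical range.

### End-to-end replication from the command line

```sh
./exec/ctrval replicate-study \
  --config=inst/configs/paper_like.json --outdir=study_out   # ~1 min CPU
```

writes `measurements.csv`, `grading.csv`, `comparisons.csv`,
`classification.csv`, `exclusions.csv`, a run log and an `outputs.json`
manifest; reruns are byte-identical. `inst/configs/smoke.json` is a
20-case variant that finishes in seconds. Other subcommands: `generate`,
`segment-train`, `segment-predict`, `measure`, `stats` (see
`?ctrval_cli`).

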