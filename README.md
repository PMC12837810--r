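# dmerwkv

Multitask deep learning for diabetic macular edema (DME): joint OCT lesion
segmentation and anti-VEGF treatment-response prediction, implemented as a
self-contained R package with its own compiled numerical kernels and a seeded
synthetic phantom generator, so the entire pipeline — data, training,
evaluation — runs end to end on a single CPU with no external data.

## Who this is for

Researchers in ophthalmic image analysis who want a fully inspectable,
dependency-light reference implementation of this family of architecture:
linear-complexity attention for high-resolution retinal images, a
topology-preserving loss for thin lesions, causal attention for
interpretability, and curriculum training — together with the exact
evaluation protocol (patient-grouped splits, DeLong comparisons, surface
distances) used in treatment-response studies.

## What is implemented

* **DME-RWKV network.** A weight-shared dual-modality encoder whose first two
  stages are Hadamard-product attention blocks, `y = x + DW(x) ⊙ σ(PW(x))`
  (parameter count `9C + C² + 2C`, below a dense 3×3 convolution's `9C²`),
  and whose last two stages are bidirectional-WKV token mixers with
  per-channel decay `w` and self-bonus `u`:

  `wkv_t = (Σ_{i≠t} e^{−(|t−i|−1)w/T + k_i} v_i + e^{u+k_t} v_t) / (same weights)`

  computed by a numerically stabilized O(T) scan (verified in the tests
  against the O(T²) double sum). Global-context attention (GCA) fuses the
  four pyramid levels per modality — pooled-context channel reweighting,
  multiplicative + residual fusion, parallel dilated 3×3 branches
  (d = 1, 2, 5, 7) — and a four-stage decoder over the OCT skips emits
  4-class lesion maps (background / ERM / IRC / SRF).
* **Causal attention (CAL).** The linear–ReLU–linear prediction head is scored
  as `Y_effect = softmax(Y − E[Ŷ])`, where `Ŷ` replaces the attention map by
  a renormalized i.i.d. uniform map (the do-operation), averaged over
  seeded draws.
* **GC topology loss.** Connected-component filtering, slim-region skeleton
  `SR = ReLU(M − maxpool(minpool(M, s), s))` (a differentiable white top-hat,
  s = 5 by default), and a soft-Dice skeleton difference that penalizes
  breaks in thin lesions. clDice is included as an optional comparison term.
* **Curriculum trainer.** Difficulty from ROI contrast, lesion area and image
  quality; tertile binning into easy/medium/hard; cumulative three-stage
  training with per-stage validation metrics.
* **Evaluation.** Dice / IOU / 95% Hausdorff distance, AUC with DeLong
  variance and test, bootstrap CIs for ACC/SEN/SPE/F1/PRE, patient-grouped
  4:1 split and 5-fold CV, and baseline-characteristics tables
  (Mann–Whitney, Yates-corrected chi-square).
* **Synthetic phantoms.** A seeded clinical cohort whose responder label is
  *derived* from generated CMT pairs via the ≥10%-decrease rule, layered
  retina B-scans with exact lesion masks, and UWF fundus phantoms with
  peripheral class signal. See `vignette("methods")` for what the phantoms
  do and do not emulate.

## Worked example

```r
library(dmerwkv)

# a 40-patient phantom cohort with paired OCT/UWF images at 64 px
samples <- make_dataset(n_eyes = 43, n_patients = 40, input_size = 64, seed = 1)
records <- attr(samples, "records")
head(records[, c("eye_id", "cmt_baseline", "cmt_3month", "responder")], 3)
#>     eye_id cmt_baseline cmt_3month responder
#> 1 P0001_OD     432.8115   308.5284      TRUE
#> 2 P0002_OD     616.0752   375.7660      TRUE
#> 3 P0003_OD     198.5801   186.3202     FALSE

sp <- split_grouped(records, seed = 1)        # whole patients, exact 4:1
model <- model_init(model_config(widths = c(12, 24, 36, 48),
                                 input_size = 64), seed = 1)
fit <- train_model(model, samples[sp$train],
                   trainer_config(epochs = 2, batch_size = 2, lr = 2e-3))
rep <- cmd_evaluate(fit$model, samples, eye_ids = sp$test, n_boot = 200)
c(dice = rep$dice, auc = rep$auc)
#>      dice       auc
#> 0.1055983 1.0000000
```

The response label is already perfectly separated after this two-epoch toy
run (AUC 1.0 — the phantom class signal is strong by design), while the
segmentation Dice of 0.11 shows that 34 training images and two epochs are
far too little for the dense task. On the shipped benchmark configuration (200 training phantoms at 64×64,
5 epochs, widths 16/32/48/64) the scaled-down model reaches a foreground
Dice around 0.7 on easy-tier validation phantoms and an AUC near 1.0 on the
synthetic response rule — numbers recomputed by the acceptance script below.
These quantify that the pipeline learns the phantom signals; they say
nothing about clinical data.

A command-line wrapper for the generate/train/evaluate cycle is installed at
`inst/cli/dmerwkv` (`dmerwkv generate --config run.yaml --seed 1`).

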