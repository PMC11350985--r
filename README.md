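# retinograde

Automated grading of diabetic retinopathy (DR) and diabetic macular edema
(DME) from retinal fundus photographs, implemented as a fully testable,
desk-scale R package.

Diabetic eyes accumulate microaneurysms, haemorrhages and hard/soft
exudates; the lesion load defines the DR grade (mild, moderate and severe
non-proliferative DR, then proliferative DR once neovascular growth
appears), while the distance between the hard exudates and the fovea
defines the DME grade (severe below `R/6` of the fundus radius, moderate
below `R/3`, mild beyond). The package implements a five-stage grading
pipeline around these rules:

1. **Preprocessing** — green-channel extraction, clip-limited histogram
   equalization, and multilevel 2D discrete wavelet denoising
   (`X = X_A^N + Σ_i (X_H^i + X_V^i + X_D^i)`; soft universal threshold on
   the detail sub-bands, exact orthogonal reconstruction).
2. **Segmentation** — a per-pixel feed-forward ANN over sliding patches
   whose multipliers are replaced by *shift-add quantized* weights: each
   weight becomes a signed sum of at most `S = 3` distinct power-of-two
   terms (`0.8735 ≅ 0.8750 = 2⁻¹ + 2⁻² + 2⁻³`), with cumulative error
   diffusion shrinking the average signed error, and a piecewise-linear
   tanh whose slopes are all powers of two.
3. **Feature extraction** — adaptive Gabor filtering
   (`G(x,y) = g_σ(x,y)·exp{2πjμ(x cosθ + y sinθ)}`), DC-removed for
   illumination invariance, with per-tile texture-adapted parameters plus
   a fixed orientation/frequency bank, and per-segmentation-class
   summaries (areas, counts, exudate–fovea distances, near-disc vessel
   density).
4. **Feature selection** — a penalized-Gini regularized random forest:
   stage 1 estimates normalized importances `Imp_norm`, stage 2 refits
   with `gain_G = λ_i · gain`, `λ_i = 1 − γ + γ·Imp_norm`, and returns the
   small informative subset.
5. **Classification** — a chicken-swarm-optimized neural classifier
   (roosters/hens/chicks moving by the swarm update rules, elitist
   archive) refining a gradient-trained fully-connected head, graded over
   8 joint DR/DME classes, reported as accuracy and macro
   sensitivity/specificity/precision/F1.

Real graded photograph collections cannot ship in a package, so a
first-class **synthetic fundus generator** renders labelled images —
circular field, vessel tree rooted at the optic disc, fovea, and
grade-consistent lesions — with per-structure ground-truth masks; every
stage is measured against that ground truth, and an independent
rule-based re-grader (`grade_from_masks()`) closes the loop on label
consistency.

## Worked example

```r
library(retinograde)

# the shift-add quantizer on a single weight
quantize_weight(0.8735, S = 3)
#> quantized weight: 2^-1 + 2^-2 + 2^-3 = 0.8750 (error -0.0015)

# error diffusion over a weight sequence
quantize_with_diffusion(c(0.8, 0.425, 0.405), S = 3)
#> shift-add quantization report (S = 3, diffusion on)
#>   original quantized  error
#> 1    0.800     0.750  0.050
#> 2    0.425     0.500 -0.075
#> 3    0.405     0.375  0.030
#> average signed error: +0.0017
```

Without diffusion the same sequence has average signed error +0.0433;
diffusion cuts it to +0.0017 while each individual error stays the same
size.

A full pipeline run on the default study (200 synthetic 96×96 images, 8
balanced DR/DME classes, 80/20 stratified split):

```r
rep <- run_pipeline(pipeline_config(n_samples = 200, seed = 1))
round(unlist(rep$metrics[1:5]), 3)
#>    accuracy sensitivity specificity   precision          f1
#>       0.775       0.775       0.968       0.796       0.781
rep$segmenter_agreement   # quantized vs float segmenter, pooled pixels
#> [1] 0.945
head(rep$selected_features)
#> [1] "seg_hard_exudate_minradial" "seg_optic_disc_area"
#> [3] "seg_hard_exudate_area"      "seg_haemorrhage_area"
#> [5] "segraw_soft_exudate_area"   "seg_soft_exudate_area"
```

Held-out accuracy 0.775 against a 0.125 chance level; the top selected
feature is the minimum hard-exudate-to-fovea distance — the DME grading
rule recovered from data. The report also carries preprocessing quality
(mean PSNR 24.7 dB, SSIM 0.75 of the denoised raster against the
equalized input), per-stage timings and the confusion matrix; a run takes
about two minutes on one CPU.

A thin command-line front end is installed at `inst/cli/retinograde`
(`generate`, `preprocess`, `run` subcommands sharing a YAML config).

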