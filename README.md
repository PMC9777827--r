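# ovaquant

Automated quantification of ovarian follicles in 2-D B-mode ultrasound.

Antral follicle count (AFC) — the number of 2–10 mm follicles seen on
transvaginal ultrasound — is a standard biomarker of ovarian reserve, and
measuring it by hand is slow and subjective. `ovaquant` implements a
three-stage pipeline for it: segment the ovary, segment the follicles, then
size and count the follicles. It is aimed at researchers studying
harmonic-convolution segmentation on ultrasound-like data and at anyone who
needs a deterministic, auditable follicle sizing/counting stage.

The package contains:

* **Harmonic convolution** — every convolution in the network is a learned
  linear combination of responses to a fixed orthonormal 2-D DCT-II filter
  bank: output channel *d* is
  `sum over n, u, v of w[d,n,u,v] * (γ(u,v) ⊛ x[n])`,
  where the `f²` kernels `γ(u,v)` are fixed, orthonormal, and carry no
  learned content (`dct_filter_bank()`, `harmonic_conv()`).
* **Harmonic attention (HA)** — a channel gate computed from globally pooled
  statistics through two 1×1 harmonic convolutions and a sigmoid,
  `O = T ⊙ attn(T′) + T`, used throughout the encoder and decoder.
* **The segmentation network** — a five-level encoder–decoder
  (`harmonic_unet()`) with 1-D factorized convolution pairs in the shallow
  levels, HA blocks, 2×2 max-pool / transpose-conv resampling, skip
  concatenations, and a sigmoid head thresholded at 0.5. A flag removes the
  HA blocks, giving the baseline model for the attention ablation.
* **Compound loss** — `L = L_BCE + 0.6 · L_focal(γ = 2)` plus the ablation
  variants (`bce`, `dice`, `bce+dice`), with analytic gradients.
* **Training** — Adam (β₁ = 0.5, β₂ = 0.999, lr 2e-4, batch 4), ±15°
  rotation / horizontal-flip augmentation, validation-Dice plateau decay,
  best-checkpoint selection (`train_network()`). Forward and backward passes
  are implemented in C++ (RcppArmadillo) and R — no deep-learning framework
  is required — and are verified against numerical differentiation and
  brute-force oracles in the test suite.
* **Counting** — connected components (8-connectivity) of the follicle mask
  are sized by their equivalent-ellipse axes,
  `diameter_mm = spacing · (major + minor) / 2`, filtered to the recruitable
  2–10 mm range, matched one-to-one to ground truth by descending Dice, and
  counted as correct when the match exceeds Dice 0.5
  (`extract_follicles()`, `counting_report()`).
* **Phantom generator** — seeded speckle phantoms with one hypoechoic ovary,
  0–12 anechoic follicles of known diameter, exact masks, optional shadow
  and contrast artifacts (`generate_phantom()`, `generate_dataset()`),
  standing in for clinical data so everything is reproducible offline.

## Worked example

```r
library(ovaquant)

sc <- generate_phantom(n_follicles = 5, size_px = 384, spacing_mm = 0.1,
                       seed = 7)
fs <- extract_follicles(sc$follicle_mask, pixel_spacing_mm = sc$spacing_mm)
fs$records[, c("label", "major_axis_px", "minor_axis_px",
               "diameter_mm", "recruitable")]
#>   label major_axis_px minor_axis_px diameter_mm recruitable
#> 1     1         55.05         38.70       4.687        TRUE
#> 2     2         43.25         37.65       4.045        TRUE
#> 3     3        169.46        122.86      14.616       FALSE
#> 4     4         47.30         39.48       4.339        TRUE
#> 5     5         68.34         68.13       6.824        TRUE
```

Five follicles were planted with true diameters 14.61, 6.82, 4.68, 4.34 and
4.04 mm; the moment-based measurements above recover them to within a pixel
spacing. The 14.6 mm component is a dominant follicle, outside the
recruitable 2–10 mm range, so the counting stage drops it from both masks:

```r
counting_report(sc$follicle_mask, sc$follicle_mask, sc$spacing_mm)
#> <quant_report> real 4, detected 4, correct 4 | precision 100.00%, recall 100.00%
```

The counting arithmetic itself is exposed directly; applied to aggregate
counts (correct = 344, detected = 448, real = 378) it gives

```r
counting_rates(344, 448, 378)
#> precision 76.79%  recall 91.01%
```

Training a pair of desk-scale models and running the chained pipeline:

```r
scenes <- lapply(1:280, function(i) generate_phantom(
  n_follicles = (i - 1) %% 13, size_px = 96, spacing_mm = 0.4,
  shadow = i %% 4 == 0, seed = 20000 + i))
cfg <- train_config(input_size = 96, epochs = 10, seed = 1)
fit_f <- train_network(harmonic_unet(base_width = 8, seed = 7),
                       phantom_pairs(scenes[1:200], "follicle"),
                       phantom_pairs(scenes[201:240], "follicle"), cfg)
fit_o <- train_network(harmonic_unet(base_width = 8, seed = 7),
                       phantom_pairs(scenes[1:200], "ovary"),
                       phantom_pairs(scenes[201:240], "ovary"), cfg)
out <- run_pipeline(scenes[[250]]$image, fit_o$net, fit_f$net,
                    pixel_spacing_mm = 0.4,
                    gt_follicle_mask = scenes[[250]]$follicle_mask)
```

Under these seeds the ovary model reaches a mean held-out Dice of about
0.91 and the follicle model about 0.73 (each run takes a few minutes on one
CPU; see the vignette for what these desk-scale numbers do and do not show).

## Command line

A thin front end over the same functions lives in `inst/cli/ovaquant.R`:

```sh
Rscript inst/cli/ovaquant.R simulate --n 100 --out data/ --seed 7
Rscript inst/cli/ovaquant.R train --data data/ --target follicle --out follicle.rds
Rscript inst/cli/ovaquant.R predict --model follicle.rds --image img.png --out mask.png
Rscript inst/cli/ovaquant.R quantify --pred mask.png --gt gt.png --spacing-mm 0.1
Rscript inst/cli/ovaquant.R evaluate --model follicle.rds --data data/ --target follicle
```

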