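# uvtcell

Label-free T cell characterization from deep-UV microscopy images and image
stacks — as a fully synthetic, ground-truthed R pipeline.

Deep-UV transmission imaging (255 nm, the nucleic-acid absorption peak) sees
live cells without stains: each frame is an attenuation map in which the
nucleus is dense and the cytoplasm dim. `uvtcell` implements the two analyses
that make this measurement useful for immune-cell work, for scientists who
want to study, extend or stress-test them without a microscope:

* **Static analysis** — segment cells, partition each into nucleus and
  cytoplasm, and extract morphology/texture features (area, circularity,
  equivalent diameter, eccentricity, intensity statistics, Shannon entropy,
  and eight box-counting fractal dimensions over the intensity octiles
  [(k−1)/8, k/8)). Features are chi-square ranked and embedded with UMAP;
  they drive a 3-class activated / quiescent / dead classifier and
  per-sample composition estimates (viability %, activation %).
* **Dynamic analysis** — treat every pixel of a stack (500 frames at ~8 Hz
  by default) as a time series. Its magnitude spectrum decays as a power law

      I(f) ∝ f^−β,   β ≈ 1 diffuse (Brownian) motion, β ≈ 2 advective motion,

  fitted by least squares in log–log over 0.1 Hz–Nyquist, and decomposed into
  first-harmonic phasor coordinates (g, s) of the spectral decay, whose
  distance from the origin is an activity scalar. Cytoplasmic activity —
  not nuclear — separates CD4-like from CD8-like activated cells, and the
  per-pixel maps feed a 4-channel (attenuation, g, s, β) subtype classifier.

Because no public data accompany the measurement, the package ships a seeded
synthetic-scene generator with complete ground truth (masks, classes,
compartment spectral exponents); every analysis is validated against it.

## Worked example

Simulate activated CD4-like and CD8-like cells (500-frame stacks at 8 Hz),
run the pixelwise frequency analysis on each, and compare compartments:

```r
library(uvtcell)

feats <- simulate_subtype_cells(n_per_class = 8, seed = 42, n_frames = 500)
aggregate(cbind(beta_cytoplasm, beta_nucleus, g_cytoplasm, s_cytoplasm)
          ~ class, feats, mean)
#>      class beta_cytoplasm beta_nucleus g_cytoplasm s_cytoplasm
#> 1 CD4-like           1.67         1.19       0.712       0.286
#> 2 CD8-like           1.32         1.16       0.553       0.304

compare_groups(feats$beta_cytoplasm[feats$class == "CD4-like"],
               feats$beta_cytoplasm[feats$class == "CD8-like"])
#> cytoplasm t = 14.55, p = 7.64e-10
compare_groups(feats$beta_nucleus[feats$class == "CD4-like"],
               feats$beta_nucleus[feats$class == "CD8-like"])
#> nucleus   t = 1.13, p = 0.28
```

The cytoplasmic power-law exponent separates the subtypes decisively (CD4-like
is the more active compartment, and maps further from the phasor origin),
while the nuclei are statistically indistinguishable — the spatial structure
the dynamic analysis is designed to expose. The exponent estimator itself
round-trips the generator exactly:

```r
tr <- synth_trace(beta = 2, amplitude = 0.02, n = 500, frame_rate = 8, seed = 1)
fit_power_law(pixel_spectrum(tr, 8))
#> fitted beta = 2.000 (r2 = 1.000)
```

An end-to-end run (simulate → segment → features → dynamics → classify),
writing TIFF masks and maps, CSV feature tables, pseudocolor PNGs and a
metrics JSON:

```r
cfg <- run_config(scene = scene_config(image_height = 256, image_width = 256,
                                       n_cells = 8,
                                       class_mix = c("CD4-like" = 0.5,
                                                     "CD8-like" = 0.5),
                                       seed = 5, n_frames = 500))
run_pipeline(cfg, "demo_run")
```

A thin CLI over the same functions lives at `inst/cli/uvtcell.R`
(`simulate`, `segment`, `features`, `dynamics`, `train`, `run`,
`sweep-frames`, `degrade`).

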