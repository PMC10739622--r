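# annhypr

Spatiotemporal denoising of reduced-count (low-dose) dynamic PET for
parametric imaging.

Lowering the injected dose of a PET tracer raises the Poisson noise of the
reconstructed dynamic frames (sigma proportional to 1/sqrt(counts)), and
that noise propagates into the voxel-wise kinetic parameter maps — the
uptake rate K1 and distribution volume VT of the one-tissue compartment
model C_T(t) = K1 (Cp ⊗ e^(−k2 t)), VT = K1/k2 — that carry the
quantitative result of a dynamic study.  This package is for imaging
scientists who want to evaluate, on a fully synthetic but statistically
faithful testbed, how much of that damage a denoising chain can undo.

It implements:

- **Patch ANN** — a 64→128(ReLU)→8 patch-to-patch network trained by SGD on
  one reduced/full-count frame pair (4×4×4 input patches, central 2×2×2
  labels, min-max row scaling), applied in cascade (default 3 passes) to
  every frame: `train_patch_denoiser()`, `denoise_series()`,
  `predict.ann_model()`.
- **HYPR** composite-ratio filtering — each frame becomes
  H_i = C · F(I_i)/F(C), with C the duration-weighted composite of all
  frames and F a 7³ box filter: `hypr_process()`; chained after the ANN by
  `ann_hypr()`.
- **Comparators** — 3D Gaussian filtering by FWHM (with matched-noise FWHM
  search) and 4D spatiotemporal non-local means (compiled kernel):
  `gaussian_filter_fwhm()`, `match_gaussian_fwhm()`, `nlm_st()`.
- **Kinetics** — voxel-wise basis-function fitting of the 1T model on a
  log-spaced k2 grid in [0.01, 1.0] min⁻¹ with NEC-style frame weights:
  `build_basis()`, `fit_parametric()`.
- **Evaluation** — ensemble normalized standard deviation (EnNSD), regional
  relative error (RE), noise reduction (NR), Poisson dose-equivalence
  1/(1−NR)², and the method-sweep table: `ennsd()`, `regional_re()`,
  `noise_reduction()`, `dose_equivalence_factor()`, `noise_bias_sweep()`.
- **Phantom** — a 6-region dynamic brain phantom driven by per-region
  (K1, k2) truth and a tri-exponential plasma input, with a calibrated
  count model that draws one full-count Poisson realization and partitions
  it into ten disjoint 1/10-count realizations by multinomial thinning:
  `brain_region_map()`, `render_phantom()`, `poisson_realizations()`.

## Worked example

```r
library(annhypr)

schedule <- default_schedule()          # 21 frames: 6x30s, 3x1, 2x2, 10x5 min
aif      <- feng_aif()                  # synthetic plasma input, Bq/mL
regions  <- brain_region_map(c(48, 48, 36))
phantom  <- render_phantom(regions, brain_kinetic_truth(), aif, schedule)

sens <- calibrate_sensitivity(phantom)  # 50 counts/voxel in 5-min frames
rs   <- poisson_realizations(phantom, count_model(sens, seed = 1))

# train on the highest-count frame of one reduced realization
model <- train_patch_denoiser(get_frame(rs$reduced[[1]], 15),
                              get_frame(rs$full, 15),
                              train_config(K = 20000, high_variance_count = 10000,
                                           iterations = 20000, seed = 1))
out <- ann_hypr(model, rs$reduced[[2]], passes = 3, box_size = 7)

roi <- which(regions$labels == 1)       # cortex
ennsd(lapply(rs$reduced, get_frame, i = 15), roi)
ennsd(lapply(rs$reduced, function(r) get_frame(ann_hypr(model, r), 15)), roi)
```

The whole study — all methods, ten realizations, parametric maps, the
EnNSD/RE/NR table — is one call:

```r
res <- run_study(seed = 1, profile = "demo")
aggregate(cbind(ennsd_pct, re_pct, nr_pct) ~ method + target, res$table, mean)
```

which on the demo profile (seed 1) prints, for the highest-count frame
(ROI-averaged):

```
  method   target ennsd_pct re_pct nr_pct
  raw      frame15     34.5    0.0    0.0
  ann3     frame15      5.8   -5.5   83.4
  hypr     frame15     10.7    0.0   69.1
  gauss    frame15      5.9   -7.7   82.8
  ann_hypr frame15      2.4   -5.6   92.9
```

Read: the raw 1/10-count frame has 34.5% ensemble noise; three cascade ANN
passes cut it to 5.8%, HYPR alone to 10.7%, and the combined ANN+HYPR chain
to 2.4% (a 92.9% noise reduction), at the cost of a few percent negative
regional bias (the piecewise-constant phantom makes that bias pessimistic —
see the methods vignette).  The same ordering holds for the K1 and VT
parametric maps.  A noise reduction of 75% is statistically equivalent to a
`dose_equivalence_factor(0.75)` = 16-fold dose increase; 70% to ~11-fold.

A thin command-line interface wraps the same functions
(`inst/cli/annhypr`): `simulate`, `train`, `denoise`, `hypr`, `annhypr`,
`gauss`, `nlmst`, `fit`, `evaluate`, `demo`; dynamic series travel as 4D
NIfTI plus a JSON frame-schedule sidecar, input functions as 2-column CSV.

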