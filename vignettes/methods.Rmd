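---
title: "Reduced-count dynamic PET denoising with a cascade patch ANN and HYPR: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-count dynamic PET denoising: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lowering the injected dose of a PET radioligand lowers the detected count
rate, and the Poisson noise of the reconstructed dynamic frames grows as
one over the square root of the counts.  For dynamic imaging the damage is
compounded: kinetic parameters (the uptake rate $K_1$ and the distribution
volume $V_T$ of the one-tissue compartment model) are estimated voxel by
voxel from the noisy frames, so frame noise propagates into the parametric
maps that carry the quantitative result.  This package implements a
spatiotemporal denoising chain for reduced-count dynamic series — a
patch-based neural network applied in cascade for spatial denoising,
followed by HYPR composite-ratio filtering for temporal denoising — plus
the comparator filters, the kinetic fitting, and the noise/bias evaluation
machinery needed to measure what the chain buys.  Because suitable human
scans are not publicly available, the package ships a synthetic dynamic
brain phantom with Poisson count noise that emulates a 60-minute,
21-frame acquisition at a full-count budget and ten disjoint 1/10-count
realizations.

## The patch ANN

The spatial denoiser is a patch-to-patch regression: a fully connected
network with a 64-unit input layer (a flattened $4^3$ patch of the
reduced-count frame, mean-removed), one ReLU hidden layer of 128 units,
and a linear 8-unit output layer (the central $2^3$ patch of the
co-located full-count frame, mean-removed).  Patch means are removed so
the network learns the relation between intensity *variations* at the two
dose levels, independently of the local mean; predicting only the central
core keeps regional means stable because each voxel's estimate averages
just 8 overlapping outputs.

Both vectors are centered on the *4x4x4 patch mean* of their source image:
the input subtracts its own patch mean, and the label subtracts the mean of
the co-located full-count patch.  Centering the label on the patch mean
(rather than on the central section's own mean) is what makes training
consistent with reconstruction — at test time the network output gets the
testing patch's mean added back, so with patch-mean centering the identity
map is exactly representable and regional means are preserved; with
own-mean centering every reconstructed voxel would be pulled toward its
4^3 local mean, an edge bias that compounds across cascade passes.

Training data come from one frame pair: one reduced-count noise
realization of the highest-count frame (the frame with the most counts has
the least noise, hence the least noise-induced bias between the two dose
levels; frame 12 in the original protocol, a late 5-min frame for the
decay-free phantom) and its full-count counterpart.  All stride-1 patches are extracted; pairs are ranked by
label-patch variance; the top 50% of the 100 000 retained pairs are the
highest-variance ones (edges and noise) and the rest are sampled uniformly
from the remainder.  Each row of the $64 \times K$ input matrix and
$8 \times K$ label matrix is min-max scaled to $[-1, 1]$, and the row
extrema are stored: at test time the *training* extrema are reused so that
testing patches are mapped through the same affine transform (values may
leave $[-1,1]$; we deliberately do not clip, since clipping would bias
the hottest voxels).  Degenerate rows (max = min) scale to 0 forward and
to the stored constant backward.

The loss is the mean squared recovery error over the $K$ pairs, minimized
by mini-batch SGD with the inverse-decay schedule
$\eta_t = 0.01\,(1 + 10^{-4}t)^{-3/4}$.  The decay constants, batch size
(64), and fan-in-scaled uniform initialization are conventional choices
for this optimizer family; "iteration" means one mini-batch parameter
update, with reshuffling each epoch.  The default budget is 150 000
iterations; the desk-scale demo profile uses 20 000, which is past the
loss plateau for the phantom's training set sizes.  All randomness
(selection, initialization, shuffling) flows from one seed through a
fixed stream-splitting scheme, so training is bit-reproducible.

At test time each frame is normalized by its own maximum, replicate-padded
by one voxel so that every voxel is covered (interior voxels by exactly 8
outputs), every patch is pushed through the network, outputs are
inverse-scaled, the testing patch's mean is added back, and overlapping
outputs are averaged by coverage count.  The *cascade* applies this whole
pass repeatedly (3 times by default): each pass trades a little more bias
for more noise reduction, and three passes is where the noise-reduction
gain flattens while the regional bias is still small.

Normalization of the label image is not uniquely determined by the
training recipe; we divide the full-count frame by the *reduced-count*
frame's maximum (shared constant), because the two dose levels are in the
same activity units after count normalization and a shared constant
preserves the scale of the identity mapping.  The alternative
(each image by its own maximum) is selectable.

## HYPR composite-ratio filtering

HYPR exploits the fact that the spatial structure of the tracer
distribution changes slowly across frames.  The composite
$C = \sum_i \Delta t_i I_i / \sum_i \Delta t_i$ (all 21 frames,
duration-weighted) has high SNR; each output frame is
$H_i = C \cdot F(I_i)/F(C)$ where $F$ is a cubic box filter (default
$7^3$).  The ratio restores each frame's temporal information at the
spatial scale passed by the box filter.  Two conventions are not dictated
by the method and are fixed here: the box filter uses replicate padding at
the borders (matching the patch denoiser's padding convention), and where
$|F(C)|$ falls below $10^{-9} \times \max C$ the weight is set to 1 so the
output falls back to the composite rather than amplifying empty-background
noise.  The full chain (ANN cascade, then HYPR) is `ann_hypr()`.

## Comparators

*Gaussian filtering* is parameterized by FWHM in mm
($\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$ per axis in voxel units,
sampled kernel truncated at $4\sigma$, replicate borders).  For fair
noise-versus-bias comparisons `match_gaussian_fwhm()` bisects on the FWHM
until the filtered ensemble noise equals a target (e.g. the ANN cascade's),
reproducing the matched-noise protocol.

*Spatiotemporal non-local means* (NLM-ST) averages, for every voxel of
every frame, the voxels of a 4D search window (default
$11 \times 11 \times 11 \times 7$) weighted by
$w = \exp(-d^2/h^2)$, with $d^2$ the mean squared difference of the two
$7 \times 7 \times 7 \times 7$ neighborhoods.  The original formulation
uses absolute smoothing constants (0.5/1.0/1.5) on an intensity scale that
is not recoverable; here $h$ is that constant times a robust noise
estimate $\hat\sigma$ (median absolute deviation of the first-difference
field divided by $\sqrt 2$, per frame, averaged over the temporal window;
differences between two zero voxels — empty background — are excluded,
since they carry no noise information and would drag the median to zero),
which makes the sweep values meaningful on any intensity scale — a
declared departure, documented rather than inferred.  The temporal window
defaults to a 7-frame window centered on the target frame and truncated at
the series ends; the fixed 7-frame block (frames 9–15) of the original
formulation is available as `temporal_window = "fixed-range"` (a fixed
block cannot sensibly denoise frames far outside it).  The kernel is
compiled code; the R-level quadruple-loop oracle in the test suite is the
reference for its correctness.

## Kinetics

The one-tissue compartment model
$C_T(t) = K_1\,(C_p \otimes e^{-k_2 t})$ is fitted voxel-wise by the basis
function method: $C_p \otimes e^{-k_2 t}$ is precomputed on a $k_2$ grid
(default 100 log-spaced points on $[0.01, 1.0]\ \mathrm{min}^{-1}$ —
log spacing is standard basis-function practice since $k_2$ acts
multiplicatively; count and range configurable), so each candidate fit is
weighted least squares in $K_1$ alone, through the origin, clipped at zero
because negative uptake is unphysical.  The grid point minimizing the
weighted residual sum of squares wins and $V_T = K_1/k_2$.  Frame weights
follow the noise-equivalent-count style $w_i \propto \Delta t_i^2 / C_i$
(total frame counts $C_i$), the inverse-variance weight for
count-normalized activity under Poisson statistics; true NEC requires
randoms and scatter rates that do not exist at image level, so total
counts stand in, and uniform weighting is available for purely synthetic
runs.  No blood-volume term is modelled — a stated limitation.  With the
default 100-point grid the worst-case $k_2$ quantization is ~2.4%
(half of the 4.8% grid ratio step), and the compensating $K_1$ refit
keeps noise-free $K_1$/$V_T$ recovery errors below 2%.

## The phantom

The synthetic study emulates the data-preparation protocol at count
level, not list-mode level.  A six-region brain-like geometry (cortex
shell, white matter, thalamus, caudate, putamen, cerebellum; nested
ellipsoids, scalable to any grid) carries per-region $(K_1, k_2)$ truth
spanning $K_1$ 0.05–0.3 mL·cm$^{-3}$·min$^{-1}$ and $k_2$
0.02–0.15 min$^{-1}$ — contrast typical of gray/white matter for a
high-uptake tracer, and enough regional diversity for noise-versus-bias
curves.  The plasma input is a tri-exponential bolus with a linear rise
(Feng form) peaking at ~0.5 min; tissue curves are the trapezoidal
convolution on a 1 s grid, frame-averaged exactly; an isotropic 3 mm FWHM
Gaussian emulates reconstructed resolution.

Counts: expected counts per voxel/frame are activity × sensitivity ×
duration.  Decay is ignored (decay-corrected images), so sensitivity is a
single scalar, calibrated so the full-count 5-min frames average 50
counts per in-brain voxel by default — this puts the 1/10-count frames in
the tens-of-percent ensemble-noise regime where the method is meant to
operate.  No count statistics are published for the original scans, so
this is an explicit calibration knob, not a reproduced value.  The ten
1/10-count realizations are produced by *partitioning* one full-count
Poisson draw via equal-probability multinomial thinning, which mirrors
sequential event redistribution in list mode: the subsets sum exactly to
the full draw, are marginally Poisson at $\lambda/10$, and carry the same
mild cross-realization correlation as disjoint list-mode subsets.
Independent draws are available as a mode flag.  What the phantom does
*not* emulate: scanner geometry, attenuation/scatter/randoms, head
motion, anatomical texture within regions, and reconstruction artifacts —
so passing tests demonstrate the pipeline's statistical behavior under
ideal Poisson imaging, not clinical image quality.

## Evaluation

Noise is the ensemble normalized standard deviation (EnNSD): the
per-voxel standard deviation across the $J = 10$ realizations (divisor
$J-1$) over the per-voxel mean, averaged over an ROI, in percent.  Voxels
whose across-realization mean is below $10^{-6}$ of the mean image
maximum are excluded (with the exclusion count reported) — near-zero
means make the ratio meaningless and the choice of guard is ours, since
brain-ROI analyses never face it.  Bias is the relative error (RE) of the
ROI mean against the *unprocessed* full-count reference, averaged over
realizations.  Noise reduction (NR) is the relative EnNSD drop against
the raw reduced-count data.  Because Poisson noise scales as
$1/\sqrt{\text{dose}}$, a fractional noise reduction $r$ is statistically
equivalent to a $1/(1-r)^2$-fold dose increase (`dose_equivalence_factor`).
`noise_bias_sweep()` applies each configured method to every realization,
optionally refits parametric maps, and tabulates EnNSD/RE/NR per ROI for
chosen frames and for $K_1$/$V_T$ — the phantom playing the role of a
single subject.

## Problem sizes and the demo profile

`run_study(seed, profile)` executes the whole workflow.  The `"full"`
profile uses the standard conditions: a $64 \times 64 \times 48$ phantom
(2 mm voxels), 100 000 training pairs, 150 000 SGD iterations, and the
$11 \times 11 \times 11 \times 7$ / $7^4$ NLM windows.  The `"demo"`
profile is the package's desk-scale choice for routine verification: a
$48 \times 48 \times 36$ phantom, 20 000 pairs, 20 000 iterations, and
reduced NLM windows ($5^3 \times 3$ search, $3^3 \times 3$ neighborhood).
The demo grid is the smallest at which the phantom brain keeps realistic
anatomical proportions relative to the fixed 4-voxel patch scale (at 2 mm
voxels a 48-voxel grid is a ~96 mm brain; shrinking further pushes the
subcortical structures below the patch size and distorts the method's
bias behavior); it keeps every structural property of the full run — same
schedule, same count calibration, same 10-realization thinning.  The
acceptance checks run on this profile.

## Numerical conventions collected

- Frame indices are 1-based in user-facing interfaces, 0-based in array
  code; activity is Bq/mL end-to-end.
- Patch vectors stack x fastest, then y, then z (R's column-major order).
- Replicate (edge-clamp) padding everywhere a border rule is needed:
  box filter, Gaussian, NLM neighborhoods, patch extraction at test time.
- The all-zero frame is returned unchanged by the denoiser
  (max-normalization is undefined on it).
- An all-zero TAC fits to $K_1 = 0$, $k_2 = $ grid minimum, $V_T = 0$.
- Grid-fit ties in the residual scan break toward the smaller $k_2$.
- Seeds: one user seed; sub-streams derived by a fixed integer-hash
  splitting scheme (`annhypr:::split_seed`), one stream per random
  component.

## Known limitations

The ANN is trained on a single frame pair of a single (synthetic)
subject, as in the original design; nothing in the package addresses
domain shift to very different tracers or scanners.  The cascade is
applied at test time only (cascade *training* is out of scope).  The 1T
model has no blood-volume term.  The phantom's regions are homogeneous,
so within-region texture preservation cannot be assessed with it — and
homogeneity also makes the denoiser's regional bias *pessimistic*: inside
a piecewise-constant region every within-patch variation is noise, so a
patch denoiser shrinks structure harder than on textured brain data, and
the smallest phantom structures (a few voxels across, against the fixed
4-voxel patch) lose the most contrast.  Regional biases measured on this
phantom should therefore be read as an upper bound on what the same chain
does to real dynamic brain data, not as a reproduction of clinical bias
levels.
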