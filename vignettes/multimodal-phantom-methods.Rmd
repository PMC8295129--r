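---
title: "Methods: co-registered multimodal synthetic abdomens for registration benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-registered multimodal synthetic abdomens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmsynth)
```

## The problem this package addresses

Ground truth for deformable, multimodal abdominal registration is almost
never available from patients: positioning cannot be reproduced between
scanners, and respiration, heartbeat, and bowel content move the anatomy
between acquisitions. `mmsynth` sidesteps the problem by *construction*: a
single digital phantom — an integer organ label map — is the common
ancestor of CT, cone-beam CT (CBCT), and T1-weighted MRI volumes, so all
modalities are voxel-for-voxel co-registered, every organ mask is exact,
and the respiratory deformation between motion states is known analytically.
Such data can score any deformable registration algorithm by organ-mask
overlap instead of manual landmarks.

## The phantom and its motion model

The phantom generator composites parameterized superellipsoids and tubes
(body outline, lungs, liver with intrahepatic vessels, kidneys, spleen,
stomach, spine, aorta, optional arms) back-to-front with fixed precedence
(vessels over liver over body). It is *not* an anatomically accurate atlas;
it is the minimal multi-organ geometry the downstream mathematics needs:
a large, mostly homogeneous liver, high-contrast interfaces (lung/liver,
bone/soft tissue), thin structures (vessels), and a body outline. Organ
semi-axes are jittered by a configurable fraction (default 5 %) per organ
so that different seeds give different "subjects". Arms are included only
when requested, mirroring the convention that MRI acquisitions show arms
while CT/CBCT do not.

Respiration exposes exactly two knobs: the amount of diaphragmatic motion
and the amount of chest expansion. Diaphragm displacement is a
superior–inferior translation weighted by a Gaussian axial window centered
on the diaphragm plane (estimated as the top of the liver) and forced to
zero at the inferior boundary; chest expansion is an anterior displacement
weighted by an anterior–posterior window that vanishes at the posterior
wall. The two components are blended additively and Gaussian-smoothed
(8 mm default). Because smoothing is an averaging operation, the peak
field magnitude never exceeds the configured amplitudes. The default
amplitudes (12 mm diaphragm, 4 mm chest) sit in the range reported for
quiet breathing in the abdomen; they are configuration, not a claim about
any specific dataset.

Displacement fields are stored in the pull-back (resampling) convention —
the inhaled volume samples the exhaled volume at `x + d(x)` — and the
inhaled phantom is *defined* as the warp of the exhaled labels through the
stored field. This guarantees exact ground-truth correspondence: no
regeneration step can drift out of sync with the field. The numerical
field inversion (fixed-point iteration) round-trips the liver mask with
Dice above 0.99 at the default amplitudes.

## Modality simulation

**CT and CBCT.** Each organ id maps to a linear attenuation coefficient
tabulated on the simulated tube-energy grid 90–120 keV in 5 keV steps (no
interpolation between energies — off-grid energies are an error), then
`HU = 1000 (mu - mu_water)/mu_water`. The shipped attenuation table is an
editable fixture with literature-plausible values: soft tissues near
water, bone falling faster with energy, and lung anchored near −760 HU, a
typical digital-phantom initialization. CBCT additionally applies a
cylindrical field-of-view mask (axial circle × z-extent) centered on the
liver centroid, emulating the narrow C-arm field of view; the cylinder is
our choice — the mask geometry of interventional systems varies and only
"liver-centered, narrow" matters downstream.

**MRI.** Each organ's T1, T2 and proton density feed the spoiled
gradient-echo (VIBE) steady-state signal

$$SI = \frac{\rho \sin\alpha\,(1 - e^{-TR/T1})}{1 - \cos\alpha\, e^{-TR/T1}}\, e^{-TE/T2}$$

with breath-hold protocol defaults TR = 7.25 ms, TE = 4.54 ms, flip angle
10°. To emulate inter-subject variability, each organ's (T1, T2, ρ) triple
is independently multiplied by Uniform(1 ± 5 %) draws — one triple per
organ per volume, which is the finer of the two plausible readings (per
volume vs per organ) and gives more texture variability across subjects.

**Windowing.** CT uses the fixed window [−1024, 1500] HU and CBCT
[−1024, 2000] HU; MRI, whose native scale is arbitrary, uses the 10th/90th
percentile of the *entire* 3D array, background included. Intensities are
clipped to the window and mapped affinely to [−1, 1] — the normalization
all networks and most metrics operate on. The mapping is affine and
order-preserving on the window, with the endpoints exactly at ±1.

**Textured noise.** Real scans differ from piecewise-constant phantoms
most visibly in noise. `inject_textured_noise()` adds zero-mean Gaussian
noise whose in-plane power spectrum is proportional to a chosen
`|H(f)|^2` (flat; a steep Gaussian low-pass; or a ramp-apodized band-pass
resembling CT reconstruction-kernel texture), scaled so the noise standard
deviation matches the requested magnitude. This makes the realism metrics
and the registration harness exercisable without trained networks.

## The CycleGAN stage

Synthesis from phantom to "realistic" appearance uses a CycleGAN: two
ResNet generators (encoder, residual blocks, decoder with
nearest-neighbour upsampling + convolution, tanh output) and two 70×70
PatchGAN discriminators trained with least-squares adversarial losses.
The generator objective extends the usual adversarial + cycle-consistency
combination with two structure-preserving terms:

* the **intensity loss** `||G(x) − x||_1 + ||F(y) − y||_1`, meaningful
  because the phantom is already initialized in the target modality's
  intensity range (the translation is monomodal), and
* the **gradient difference loss**, the squared difference of absolute
  forward-difference gradients of input and output along both in-plane
  axes, which counteracts blurring.

The total is `L_adv + λ_cyc L_cyc + λ_int L_int + λ_gdl (L_gdl(G,x) +
L_gdl(F,y))` with presets 10/10/5 (CT, CBCT) and 10/0.4/0.4 (MRI); pushing
the structural weights far above these thresholds drives the generators
toward an identity mapping, a regime the desk-scale smoke test verifies
directly. Image losses are normalized per pixel so the λ presets are
resolution-independent; the raw-sum variant is exposed for exact
small-grid verification, and both adversarial generator terms (one per
direction) are summed into `L_adv`.

Training follows Adam (β₁ = 0.5) at a constant learning rate of 0.0002,
batch size 4, with one random patch per axial slice (256 px at full
scale); slices smaller than the patch are reflect-padded. The framework is
implemented directly in R (im2col convolutions over BLAS, hand-derived
backward passes, all verified against numerical differentiation in the
test suite), which is entirely adequate at desk scale — width-16,
2-block networks on 64×64 patches, a few hundred steps — and makes
training bit-for-bit reproducible on CPU from a single seed. The
full-scale recipe (width 64, 9 blocks, 150 000 steps) is reachable through
the same arguments but is not a sensible CPU workload; reproducing
full-scale image-quality statistics additionally requires a clinical
patient-style domain, which is out of scope here.

## Evaluation metrics

Fidelity of a synthetic volume to its phantom is scored slice-wise on
axial slices: MAE (background excluded), SSIM (Gaussian-weighted, σ = 1.5,
K₁ = 0.01, K₂ = 0.03), FSIM (log-Gabor phase congruency over 4 scales ×
4 orientations combined with Scharr gradient magnitude), and Canny-based
edge ratios: EPR, the fraction of reference edges retained, and EGR, new
edges relative to the reference edge count (EGR may exceed 1). The Canny
parameters (σ = 1.4, hysteresis 0.1/0.2 of max gradient) are applied
identically to both images; edge-ratio definitions beyond "consistent
with EGR > 1" are a documented package choice.

Realism against a reference-style volume is scored on noise and intensity
statistics: the radial noise power spectrum of liver patches (16 px axial
patches fully inside the ROI, second-order polynomial detrending, Hann
window, averaged periodograms, annular binning), compared by Pearson
correlation (NCC); the noise magnitude (standard deviation of liver
voxels); and the histogram correlation (HistCC) over a common binning,
with an option to drop the dominant background bin, mirroring how such
histograms are usually displayed.

Two estimator properties deserve explicit mention because the tests
assert around them. First, polynomial detrending *suppresses the lowest
one or two frequency bins by construction* — a 16 px patch's lowest
nonzero frequency is partially absorbed by the quadratic trend — so
flatness of a white-noise spectrum holds away from those bins, and
spectra whose power is concentrated at DC (the steep low-pass preset) are
tracked in the log domain rather than by linear correlation. Second,
Hann-window leakage flattens extremely steep spectra; the band-pass
(ramp) texture is therefore the shape used to validate the estimator at
NCC > 0.95 in the linear domain.

A useful yardstick when reading MAE against noise magnitude: for
`X ~ N(0, σ)`, `E|X|/sd(X) = sqrt(2/π) ≈ 0.8` independent of σ. An
MAE/NM ratio well above 0.8 therefore indicates systematic synthesis
change, not noise. The package reproduces this constant by Monte Carlo
and applies the ratio arithmetic to the shipped full-scale reference
statistics (ratios 2.1 / 1.3 / 1.5 for CBCT / CT / MRI).

## Registration benchmark

The benchmark registers inhaled CT/CBCT/MRI to exhaled CT with a cubic
B-spline free-form deformation. Because no deformable-registration
toolkit is available to R here, the optimizer is implemented in the
package: tensor-product B-spline evaluation and its transpose (force
projection onto control points), three similarity metrics — mean squares,
normalized correlation, and Mattes mutual information (50 bins,
zeroth-order fixed / cubic Parzen moving windows, the standard analytic
derivative) — and step-adaptive gradient descent: the step starts at
`learning_rate` mm (default 1), grows 10 % on improvement, halves on a
worsening (rolled-back) step, and stops at the iteration cap (default
300) or when the step collapses. MS is refused for cross-modality pairs.
Full voxel sampling makes runs bit-for-bit deterministic; stochastic
sampling sits behind a seed. The optimization runs on a 2× downsampled
copy by default (a single-level coarse schedule — B-spline order, schedule
and sampling are package choices, since only the transform family, metric
set, learning rate, iteration cap and bin count are fixed by the study
design), and the resulting transform evaluates at any resolution.

The sweep crosses metric × control-point spacing (50–150 mm in 20 mm
steps): monomodal CT→CT uses all three metrics (18 settings), CBCT→CT and
MRI→CT use MMI and NC (12 settings each). Scoring uses liver masks closed
over the intrahepatic vessels (ball structuring element, default radius 3
voxels, applied to *both* fixed and moving masks) so vessels count as
liver; the closing radius and the both-sides choice are package decisions.
Pre-registration Dice is the direct overlap of inhaled and exhaled masks;
each setting reports post-registration Dice after nearest-neighbour mask
propagation, aggregated as mean and 10th/90th percentiles.

## Problem sizes, defaults, and what the tests do (and do not) show

The test and acceptance workloads use a 96³ phantom at 2.5 mm spacing
(240 mm cube — a plausible abdominal field of view) or a 48³/5 mm version
of the same physical geometry, a 12 mm + 4 mm breath, band-pass noise at
2 % of the normalized range, MMI at 50 mm spacing with 150 iterations,
and width-16 / 2-block CycleGANs trained for under 100 steps on 64×64 toy
domains. At these sizes the whole suite verifies: exact ground-truth
consistency of the motion model; recovery of injected noise spectra by
the NPS estimator; every loss formula against brute force; backward
passes against numerical gradients; registration improving liver Dice
over the unregistered baseline; and the identity-mapping regime of the
over-regularized CycleGAN.

What passing does *not* show: that the procedural phantom matches human
anatomy, that desk-scale GANs produce clinically realistic texture, or
that the benchmark's Dice values transfer to scanner data — those
require real patient domains and full-scale training by design. The
package's claim is the *harness*: co-registered, annotated, deformable
ground truth plus validated metrics around it.

## Numerical choices and degenerate inputs

Interpolation is trilinear for scalar volumes and nearest-neighbour for
labels and masks (labels are forced to nearest regardless of the caller's
request). Out-of-volume samples clamp to the edge. Percentile windowing
of a constant volume, an empty liver mask, an edgeless reference image,
a constant spectrum in NCC, a single-occupied-bin histogram, and Dice of
two empty masks are all errors, not silent values. The field inversion
iterates `d_inv(x) = -d(x + d_inv(x))` to 0.01 mm. Organ-size jitter,
MRI property jitter, noise, patch sampling and training are all driven by
explicit integer seeds; two runs with the same seed are identical.
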