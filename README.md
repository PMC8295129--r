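# mmsynth

Co-registered multimodal synthetic abdominal volumes for developing and
benchmarking deformable image registration.

## The problem

Deformable, multimodal registration of the abdomen (CT / cone-beam CT /
T1-weighted MRI around liver interventions) has essentially no patient
ground truth: positioning cannot be reproduced between scanners, and
respiration moves every organ between acquisitions. `mmsynth` builds the
ground truth instead of annotating it. A procedural digital phantom — a 3D
organ label map with liver, lungs, intrahepatic vessels, kidneys, spleen,
stomach, spine, aorta — is the single ancestor of all three modalities, so
the volumes are inherently co-registered, every organ mask is exact, and
the respiratory deformation between exhaled and inhaled states is known
analytically and stored as a displacement field.

On top of the generator, the package provides:

* **Modality simulation** — per-organ attenuation over a 90–120 keV tube
  energy grid converted to Hounsfield units (CT), a liver-centered
  cylindrical field-of-view mask (CBCT), and the spoiled gradient-echo
  (VIBE) steady-state signal
  `SI = ρ sin α (1 − e^(−TR/T1)) / (1 − cos α e^(−TR/T1)) · e^(−TE/T2)`
  with ±5 % tissue-property jitter (MRI), followed by windowing and affine
  normalization to [−1, 1].
* **A CycleGAN synthesis stage** (desk scale, pure R, fully seeded) whose
  generator objective extends adversarial + cycle losses with an intensity
  loss `‖G(x) − x‖₁ + ‖F(y) − y‖₁` and a gradient difference loss, with
  weight presets λ_cyc/λ_int/λ_gdl = 10/10/5 (CT, CBCT) and 10/0.4/0.4
  (MRI).
* **Image-quality metrics** — MAE (background excluded), SSIM, FSIM,
  edge preservation/generation ratios against the phantom; radial noise
  power spectrum + NPS correlation (NCC), noise magnitude (liver standard
  deviation), and histogram correlation against reference-style volumes.
* **A registration benchmark** — cubic B-spline free-form deformation with
  Mattes mutual information (50 bins), normalized correlation, or mean
  squares; learning rate 1, up to 300 iterations; swept over control-point
  spacings 50–150 mm (18 monomodal + 12 multimodal settings per pair) and
  scored by Dice overlap of vessel-closed liver masks,
  `DSC = 2|A∩B| / (|A|+|B|)`.

## Worked example

```r
library(mmsynth)

# 96^3 phantom pair (240 mm cube), 12 mm diaphragm / 4 mm chest breath
pair <- generate_phantom_pair(phantom_config(dim = c(96, 96, 96),
                                             spacing = c(2.5, 2.5, 2.5)),
                              seed = 1,
                              motion = motion_parameters(12, 4))
max(sqrt(apply(pair$field$vectors^2, 1:3, sum)))  # peak displacement, mm
#> [1] 12.37142

# simulate modalities and add CT-like textured noise
ct_ex <- inject_textured_noise(simulate_ct(pair$exhaled), "ramp",
                               magnitude = 0.02, seed = 11)
ct_in <- inject_textured_noise(simulate_ct(pair$inhaled), "ramp",
                               magnitude = 0.02, seed = 12)

# liver masks, closed over the intrahepatic vessels
m_ex <- close_liver_mask(extract_organ_mask(pair$exhaled, "liver"),
                         extract_organ_mask(pair$exhaled, "hepatic_vessel"))
m_in <- close_liver_mask(extract_organ_mask(pair$inhaled, "liver"),
                         extract_organ_mask(pair$inhaled, "hepatic_vessel"))
dice(m_in, m_ex)                       # pre-registration baseline
#> [1] 0.8946323

tr <- register_bspline(ct_ex, ct_in,
                       registration_config("MMI", grid_spacing_mm = 50,
                                           max_iterations = 150))
dice(propagate_mask(m_in, tr), m_ex)   # post-registration
#> [1] 0.9159801
```

The pre-registration Dice (~0.90) is the dashed-baseline overlap caused by
the simulated breath; Mattes-MI B-spline registration at 50 mm spacing
recovers part of the deformation (~0.92 here; the normalized-correlation
and mean-squares metrics reach ~0.97 on this monomodal pair). Warping the
inhaled liver mask through the numerically inverted ground-truth field
gives Dice ≈ 0.996 — the ceiling any registration could reach.

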