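# beamcascade

Beamformer source localization under forward-model simplification — a
simulation framework for EEG/MEG source analysis.

## What this is for

Localizing the generators of interictal epileptic spikes with LCMV
(linearly constrained minimum variance) beamformers requires a head volume
conductor model to compute the leadfield **L**(Q), and the model is always a
simplification of the real head. This package replays the resulting
methodological question at desk scale: *how does forward-model
simplification degrade beamformer localization, and how does the answer
depend on the filter normalization, the noise level, and the localization
statistic?*

It provides:

* analytic spherical forward models — a concentric multi-shell EEG
  conductor (brain/CSF/skull/skin analogue, conductivities 0.33 / 1.79 /
  0.01 / 0.43 S/m) solved by spherical-harmonic expansion, and the
  closed-form spherically symmetric MEG solution for axial gradiometers —
  plus a controlled model-simplification cascade (a 3-shell model without
  CSF, and exact-magnitude smooth leadfield perturbations);
* an interictal-spike simulator: a biphasic 530 ms / 636-sample template at
  1200 Hz fired twice in a 20 s (24,000 sample) recording at 100 nAm, with
  per-channel white noise rescaled to exact variance (EEG 10⁻³ / 1 µV²,
  MEG 1 / 10³ fT²) sharing one realization across scales;
* scalar LCMV beamformers under the three standard normalizations, with
  data-driven dipole orientation by generalized eigendecomposition:

  | constraint | identity | filter |
  |---|---|---|
  | unit gain | WᵀL = 1 | W = C⁻¹L/(LᵀC⁻¹L), Frobenius-normalized **L** |
  | unit array gain | WᵀL = ‖L‖ | W = ‖L‖C⁻¹L/(LᵀC⁻¹L) |
  | unit noise gain | WᵀW = 1, WᵀL > 0 | W = C⁻¹L/√(LᵀC⁻²L) |

* localization by output variance WᵀCW or by excess sample kurtosis
  g₂(WᵀB) = m₄/m₂² − 3 of the filtered waveform;
* an anti-inverse-crime source space (the node nearest each true source is
  displaced into a 0.5–0.6 mm offset band, so the best possible error is
  the 0.55 mm "grid floor"), Tukey-style error summaries with the
  median-anchored whisker rule and a 40 mm display cap, and a config-driven
  experiment driver.

## Worked example

The numbered scripts under `analysis/` run the study end to end
(`01_forward_models.R` … `05_report.R`), writing tables under `results/`.
The cascade step simulates every source with the reference model and scans
with progressively worse models; `analysis/04_cascade_experiment.R` prints,
for 12 EEG sources × 2 noise replicates at 300 inverse nodes:

```
== medians (mm, rounded) by model / noise / constraint, variance criterion ==
      constraint noise        model median_mm     q3 n_outliers max_outlier
 unit_array_gain  high           3C         1   0.55          4       13.89
 unit_array_gain  high  perturb_0.2         1   0.55          8        9.86
       unit_gain  high           3C        87 124.21          0          NA
       unit_gain  high  perturb_0.2        75 108.06          4        0.55
       unit_gain   low  perturb_0.2         1   0.55          4       54.33
 unit_noise_gain  high  perturb_0.2         1   0.55          4       9.86
 unit_noise_gain   low  perturb_0.2        82 118.89          0          NA
```

(excerpt). Read it as: array-gain localization stays at the 0.55 mm grid
floor in every condition, with mismatch surfacing as outliers (up to ~14 mm);
the Frobenius-normalized unit-gain filter collapses at high noise (median
75–87 mm — its data-driven orientation drifts to the weakest gain direction
and the variance map inherits a depth bias); the unit-noise-gain (neural
activity index) filter behaves like array gain at high noise but fails at
*low* noise once the model is misspecified (median 82 mm). The matched-model
run (`analysis/03_grid_floor.R`) localizes all 144 source/constraint/
criterion combinations inside the 0.5–0.6 mm band, and
`analysis/05_report.R` renders the per-condition Tukey boxplots.

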