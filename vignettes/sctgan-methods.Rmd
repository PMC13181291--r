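---
title: "Methods: SSIM-weighted CBCT-to-CT translation and its evaluation"
author: "sctgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSIM-weighted CBCT-to-CT translation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The translation model

`sctgan` trains a paired cycleGAN between the CBCT domain and the CT
domain. Two generators (`G`: CBCT→CT, `F`: CT→CBCT) and two patch
discriminators are optimized jointly. Slices enter the model after
in-plane resampling and an affine intensity map that takes the HU window
[−1000, 2000] onto [−1, 1] (values outside the window are clipped first —
the safe choice that keeps the map invertible on its range). The defaults
follow the clinical-scale recipe (256×256 pixels of 1.6 mm, 40 epochs of
Adam at learning rate 2·10⁻⁴, constant for the first 20 epochs and then
linearly decreased to exactly zero at the last, batch size 4); the test
suite and the acceptance script run a reduced configuration discussed
below.

## The SSIM-weighted L1 term

For a registered training pair — CBCT slice `x` and deformably registered
CT slice `y` — the local structural similarity is computed for every pixel
over a uniform (unweighted) 7×7 window with reflection padding at the
slice boundary:

$$\mathrm{SSIM}(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
{(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}$$

with population statistics and stability constants $C_1 = (0.01 L)^2$,
$C_2 = (0.03 L)^2$ for the dynamic range $L = 2$ of the normalized scale —
the universal defaults, since no other constants are standard. Values
below the threshold $\alpha = 0.5$ are set to zero; the surviving values
weight the paired L1 residual:

$$L_{\mathrm{SSIM}} = \overline{\; w \cdot |G(x) - y| \;}, \qquad
w = \mathrm{SSIM}(x,y)\cdot\mathbf{1}[\mathrm{SSIM}(x,y) \ge \alpha],$$

used symmetrically for both translation directions with the same weight
map (the SSIM formula is symmetric in its arguments). Two design points
deserve emphasis:

* **The weights are constants of the input pair.** No gradient flows
  through the weight map; it acts as a mask on the residual. A pixel whose
  weight is zero contributes nothing to the paired term no matter what the
  generator emits there — the property the acceptance suite verifies
  directly by perturbing the generator output inside a gas-pocket
  mismatch region and asserting the loss is bit-identical.
* **The threshold does not modulate the cycle term.** "Prioritizing
  cycle-consistency" is implemented purely by zeroing the paired weight;
  the cycle term keeps its global weight everywhere. A spatially varying
  cycle weight would be an alternative reading, but it adds a coupling
  with no testable benefit at this scale.

The remaining terms are the standard cycle consistency
$\overline{|F(G(x)) - x|} + \overline{|G(F(y)) - y|}$ and least-squares
adversarial losses (the formulation of the reference cycleGAN
discriminator). Term weights default to $\lambda_{cycle} = 10$,
$\lambda_{SSIM} = 10$, $\lambda_{adv} = 1$, the cycleGAN convention, and
are configurable in `lossConfig()`. No identity loss is used. Two-factor
SSIM, as used here, can be *positive* for anti-correlated patches (both
the luminance and covariance factors turn negative); the thresholding
behaviour should therefore be reasoned about via mean separation and
texture mismatch, not correlation sign.

## Architecture

The generator is a ResUnet: encoder levels connected by stride-2
convolutions with doubling channel width, residual blocks
(conv–IN–ReLU–conv–IN plus identity) on every level, a decoder of
nearest-neighbour upsampling and convolution, and Unet-style long skip
concatenations bridging the shallowest levels. Instance normalization and
ReLU follow the reference cycleGAN design; a final tanh bounds outputs to
[−1, 1], which after the inverse intensity map guarantees sCT values in
[−1000, 2000] HU. The discriminator is the reference patch design: 4×4
stride-2 convolutions with leaky ReLU (no normalization on the first
layer), then two stride-1 layers to a one-channel score map — a 256×256
input yields the familiar 30×30 patch map. All layers, the forward/backward
passes and Adam are implemented in the package (conv and instance-norm
kernels in compiled code); backpropagation is verified against central
finite differences to ~1e-9 relative error in the unit tests.

Toy scale, used by tests and the acceptance script: 2 levels, 8 base
channels, one residual block per level, one long skip (10 825 parameters),
on 64×64 slices of 3 mm pixels; discriminators with 2 stride-2 layers and
16 base channels. Five epochs over 150 slice pairs run in a few minutes on
one CPU. These sizes are the package's study conditions — large enough for
the mechanism to be observable, small enough for a desk.

## Update order and determinism

Per batch: both discriminators step first (on the current generator
outputs), then both generators step on the updated discriminators; no
image replay buffer is used. Adam runs with β₁ = 0.5, β₂ = 0.999. Every
stochastic choice (initialization, train/held-out split, shuffling)
derives from the seed in `trainConfig()`, so a repeated run is bitwise
identical; a training run whose any loss term becomes non-finite aborts
naming the offending term.

# The digital pelvis phantom

Patient CBCT/CT pairs are access-restricted, so the package generates its
own study cohort. The anatomy is deliberately an ellipsoid composite —
body (soft tissue, 30 HU), bladder (10 HU), prostate (45 HU), rectum
(20 HU) with a gas pocket (−800 HU), femoral heads (400 HU), sacrum
(300 HU), each with Gaussian HU texture and seeded jitter of centres and
radii — because only the statistical contrast structure matters for
exercising the loss and the metrics. Structures paint in priority order;
equal-priority overlap is an error naming the colliding pair. Organ masks
are clipped to the body, so containment holds by construction.

The CBCT degradation applies, in order: a radial cupping bias field
$-A(1 - r^2/R_{max}^2)$ (centre depressed by `cuppingHU` = 60 HU),
additive Gaussian noise (20 HU), streaks through gas voxels at random
in-plane angles with exponentially decaying amplitude (60 HU, 60 mm decay,
alternating sign — a cheap imitation of gas-motion streaks), and a global
HU shift of −30 HU. Zero-strength parameters reproduce the CT exactly, and
the mean absolute error grows monotonically in each strength — both tested
properties. The artifact magnitudes are plausible rather than calibrated:
no quantitative artifact characterization exists to calibrate against.

The "registered" CT emulates residual post-registration error: white
vector noise smoothed by a 9 mm Gaussian, rescaled so the maximum
displacement norm equals exactly `maxDisplacementMM` (4 mm), applied as a
backward warp. The structural mismatch replaces the gas pocket with
surrounding-tissue HU in the registered CT while the CBCT keeps it — the
day-to-day gas scenario that motivates the thresholded loss.

**Cohort composition.** `makeTrainingCohort()` applies the mismatch to a
seeded 30% of samples. This fraction is a modelling decision, not a tuning
knob: if *every* registered CT lacked gas, the target domain would contain
no gas at all and both the paired term and the discriminator would teach
the generator to erase it — the opposite of the clinical situation, where
most registered CTs match the CBCT and only a minority disagree locally.
Matched samples are what let the model learn to reproduce gas; the
mismatched minority is where the SSIM threshold must shield it from
contradictory supervision.

The dose model is analytic: each beam deposits
`entranceDose · exp(−μ · radiologicalDepth) · GaussianLateral`, with the
radiological depth accumulated by midpoint ray marching (2 mm step) of the
relative electron density along the beam axis and the lateral profile set
by the beam's FWHM. It replaces a Monte Carlo engine deliberately: it has
a closed-form oracle (exponential depth dose on a uniform phantom, exact
linearity in entrance dose, mirror symmetry for opposed beams) and costs
seconds. Default plan: a four-field 60 mm box of 20 Gy-scale beams with
μ = 0.005/mm, giving ~50 Gy at the prostate — clinically shaped, not
clinically accurate.

# Evaluation methodology

* **Contours.** DSC by voxel counting (`dice(∅,∅) = 1` by convention;
  metrics on a single empty mask raise). Surfaces are centres of mask
  voxels with a face-adjacent background or out-of-grid neighbour; MDA is
  the symmetric mean nearest-point distance, HD the 100th-percentile
  maximum (not HD95). Distances run through a compiled exact
  nearest-neighbour search, checked against all-pairs brute force at
  1e-9 mm including anisotropic spacing. Because surfaces are voxel
  centres rather than sub-voxel meshes, distance claims are
  spacing-limited. Pass flags are reported at DSC > 0.8 and MDA < 2 mm;
  the package reports, it does not assert clinical acceptability.
* **CT numbers.** Per-structure mean HU with reference-minus-test
  differences; trilinear line profiles (consistent with the resampling
  interpolation elsewhere); Spearman correlation via rank Pearson, with
  constant input an error rather than NA. The HU→rED curve is a
  three-knot water-anchored piecewise-linear default ((−1000, 0), (0, 1),
  (2000, 2.2)), clamped to the end knots; clinical curves are
  scanner-specific and configurable.
* **DVH.** Dx% uses the nearest-rank convention (descending sort, rank
  ⌈x/100·N⌉): exact and oracle-matched, diverging from DVH engines that
  interpolate between sorted doses. D2% is therefore a near-maximum and
  D98% a near-minimum dose — the conventional meaning.
* **Gamma.** 3D global gamma with the dose tolerance normalized to the
  reference maximum and the evaluation restricted to reference voxels at
  or above a 10% threshold of that maximum. The minimization is a dense
  search within 2×DTA of each voxel at step DTA/10 with trilinear
  interpolation of the test dose, sorted by distance with sound early
  termination. An independent exhaustive sweep at step DTA/20 serves as
  the oracle; pass rates agree within 0.5 percentage points on the test
  cohort. The pass criterion γ ≤ 1 carries a 1e-9 slack so exact-boundary
  constructions (a uniform field at exactly +3% under 3%/3mm) are not
  failed by floating-point rounding.

# Numerical choices and degenerate inputs

* Trilinear interpolation snaps coordinates within 1e-9 of the grid
  boundary inside it; without this, a beam at gantry 180° (where
  `sin(π) ≈ 1.2e-16` leaks into the direction vector) loses its boundary
  samples and opposed-beam symmetry breaks at the grid edge.
* Preprocessing resampling is centre-aligned; when the input grid already
  equals the target grid the resample is skipped exactly, making
  `postprocess(preprocess(v))` reproduce `clip(v, −1000, 2000)` to
  floating precision. With genuine resampling, the round trip equals two
  successive bilinear resamples; voxels within one pixel of the FOV
  border blend with the constant air fill, so border voxels are excluded
  from fidelity claims.
* Empty masks are errors everywhere (mean HU, DVH, surfaces, FOV crops
  that empty a structure): silent zeros would hide upstream failures.
* NIfTI support is deliberately restricted to axis-aligned, positively
  oriented affines; oblique volumes raise an explicit error.

# What the phantom does and does not show

Passing tests on this cohort demonstrate that the loss arithmetic, the
training dynamics, the preservation mechanism and every metric behave as
specified — on images whose artifacts are simple parametric fields and
whose anatomy is ellipsoidal. Real CBCT scatter is object-dependent and
non-radial; real registration error is correlated with anatomy; real
contours have sub-voxel detail; the dose model ignores scatter build-up
entirely. Quantities measured here (MAE improvements, gamma pass rates)
therefore characterize the implementation, not expected clinical
performance, and clinical-scale numbers from patient cohorts are not
reproducible in this package.

# Problem sizes used by the shipped runs

| Stage | Size |
|---|---|
| Training cohort | 10 phantoms of 64×64×16 @ 3 mm; 150 slice pairs, 10% held out |
| Training | 2-level/8-channel generators, 5 epochs, batch 4, seed-driven |
| Gamma validation | 20 seeded 16×16×8 pairs, 3%/3mm, 2%/2mm, 1%/2mm |
| Surface-metric validation | 30 seeded mask pairs up to 18³, anisotropic spacing |
| Degenerate full report | 5 phantoms at default size, test ≡ reference |

These sizes were chosen as the smallest at which each property is
meaningfully exercised; all are configurable upward.
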