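---
title: "Gaussian rocking-curve retrieval for analyzer-based imaging: model, simulator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian rocking-curve retrieval: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdei)
```

## The imaging model

Analyzer-based imaging (ABI) inserts a perfect-crystal analyzer between the
sample and the detector. Rocking the analyzer around the Bragg condition
traces its transmission versus angular offset — the rocking curve (RC) — and
this curve acts as a microradian-scale angular band-pass filter on the beam
leaving the sample. `gdei` models the RC as a unit-peak Gaussian,

$$R(\theta) = e^{-\theta^2 / 2\sigma^2},$$

with all working angles expressed as offsets $\theta$ from the RC peak in
µrad (the Bragg angle itself is metadata only and never enters any formula).

In each detector pixel the sample acts on the local RC in three ways:
attenuation (plus *extinction*, the rejection of scattered photons by the
analyzer) scales it by the apparent absorption $I_R$; refraction shifts it
by $\Delta\theta_R$; and ultra-small-angle scattering, described as a
zero-mean Gaussian of width $\sigma_S$, convolves it. Since a Gaussian
convolved with a Gaussian is Gaussian, the measured intensity at analyzer
offset $\theta_i$ has the closed form implemented by `forward_intensity()`:

$$I(\theta_i) = I_R\,\sqrt{\frac{\sigma^2}{\sigma_S^2+\sigma^2}}\;
 \exp\!\left(-\frac{(\theta_i+\Delta\theta_R)^2}
 {2(\sigma_S^2+\sigma^2)}\right).$$

The local curve keeps Gaussian shape with variance
$\sigma_m^2 = \sigma^2 + \sigma_S^2$ and amplitude reduced by
$\sqrt{\sigma^2/\sigma_m^2}$ (extinction). Three images at distinct offsets
$\theta_1, \theta_2, \theta_3$ therefore determine the three unknowns
exactly: log-ratios of image pairs give a linear system whose solution is
the closed-form inversion in `retrieve_refraction()`,
`retrieve_scatter_variance()` and `retrieve_apparent_absorption()`. Because
no Taylor expansion of the RC is involved, the inversion stays exact for
refraction and scattering angles *larger* than $\sigma$ — the regime (tens
of µrad) where slope-based two/three-image methods saturate.

When one effect is known to be absent, two images suffice; the
`retrieve_two_image_*()` functions implement the reduced formulas. Applied
outside their stated assumption they are biased — e.g. the no-scatter
refraction estimate shrinks by $\sigma^2/(\sigma^2+\sigma_S^2)$ — and the
test suite asserts that bias rather than hiding it.

## Normalization contract

All retrieval functions assume one shared normalization: every image is
divided by the *peak-position* object-free flat, so that background at
offset $\theta$ reads $R(\theta)$, not 1. Dividing each image by its own
per-angle flat would silently cancel the $R(\theta_i)$ factors the log-ratio
system relies on and is therefore only available behind an explicit,
loudly-warning flag in `correct_image()`. The simulator and the CLI both
honor the contract (simulated counts are divided by the photon budget,
manifests carry that normalization).

## Parameters that matter

* `sigma` (µrad) — RC width; defaults to 8.6 throughout examples, the width
  of a Si(111) analyzer at 17 keV. It is an *input*: computing it from
  dynamical diffraction theory is out of scope.
* Working points — canonical triad: both 50% half-slopes and the peak,
  i.e. $\theta = \mp\sigma\sqrt{2\ln 2} \approx \mp 10.13$ µrad and 0.
  `working_point_angle()` gives nominal positions;
  `working_point_from_samples()` interpolates the *measured* curve so
  off-nominal actual positions (e.g. 49%/55%) can be fed to the retrieval,
  which is triad-agnostic.
* `photons_per_pixel` (default 1e4) — Monte Carlo budget per pixel, the
  knob that sets counting noise.
* `pixel_pitch` (µm, default 14) and `intrinsic_resolution` (1 µm) — the
  detector grid and the sub-pixel grid on which photon positions and rod
  deflections are evaluated.

## The Monte Carlo simulator

`simulate_image()` shares no code path with the closed-form model: each
photon receives a uniform sub-pixel position, a Gaussian scattering draw
inside foils, Bernoulli absorption (foil transmission and
$e^{-\mu\,\mathrm{chord}}$ through the rod), a deterministic geometric
deflection $2\delta y/\sqrt{R^2-y^2}$, and a Bernoulli analyzer acceptance
with probability $R(\theta + \Delta\theta_R + \Delta\theta_S)$. Agreement
of Monte Carlo cell means with the closed form is therefore a genuine
cross-validation, asserted in the tests at the 3-standard-error level.

Numerical choices:

* The deflection diverges at the rod edge; it is capped at
  $\sigma\sqrt{2\ln 10^{12}} \approx 64$ µrad, beyond which the acceptance
  probability is below $10^{-12}$ at any in-range working point — the cap is
  physically invisible.
* Pure-background pixels (no geometry, no scattering, full transmission)
  aggregate their Bernoulli draws into one binomial draw; this is an exact
  shortcut, not an approximation.
* RNG substreams are derived per angle index from the master seed, so
  extending a working-point list never changes the images already in it.
  (Per-column substreams would need a counter-based generator base R does
  not provide; per-angle granularity achieves the stated goal.)
* Images are bit-identical for identical seed and configuration.

Two phantom factories reproduce the validation scenes: a 3.6 mm PMMA rod
crossed by 12 foils with $\sigma_S$ from 0 to 21.41 µrad (pure scatterers),
and a paper stairway of up to 6 layers whose width grows as $\sqrt{n}$ with
layer count and whose transmission decays geometrically. Quantities the scenes do not pin down were fixed once: the rod defaults to
$\mu = 0.0786\,$mm$^{-1}$ and $\delta = 9.2\times10^{-7}$ (tabulated PMMA
constants at 17 keV, both overridable — a quoted rod transmission of 0.79
for the 3.6 mm rod and the theoretical 0.66 for 5 mm PMMA imply *different*
$\mu$, so no single default reproduces both figures); one paper layer
scatters with $\sigma_S = 4.3$ µrad (placing the 6-step range astride
$\sigma$, the regime the stairway probes) and absorbs 2.7% (a realistic
single-sheet attenuation for 80 g/m² paper at 17 keV).

## What the synthetic data does and does not establish

The generator emulates monochromatic, parallel-beam illumination, Poisson
counting statistics, Gaussian scattering, and sub-pixel refraction-angle
gradients (which reproduce the single-pixel edge artifact at the rod
boundary). It does **not** emulate polychromaticity, detector read-out
noise, non-Gaussian rocking curves or scattering inside the rod material.
A green recovery test therefore establishes the *algorithm's* correctness
under its stated model, not robustness to those effects.

## Estimators and statistical conventions

* Per-pixel maps report the variance $\sigma_S^2$ *signed*; noise drives
  pixels negative and clamping them would bias ROI averages. The derived
  $\sigma_S$ display map clamps at 0 and flags clamped pixels.
* Quantitative ROI values invert the *ROI-averaged* intensities (with a
  delete-one-column jackknife for the uncertainty) instead of averaging
  per-pixel inversions: the inversion is nonlinear, so the mean of noisy
  inversions carries a Jensen bias of order $1/N_\mathrm{photons}$ that
  does not shrink with ROI size, while the uncertainty of a large-ROI mean
  does. Per-pixel averaging remains the right choice for *display* maps.
* All stochastic comparisons use a 3-standard-error criterion; "bias below
  the Monte Carlo error" is read in that conventional sense (a literal
  1-SE bound would be failed ~32% of the time per foil by a perfectly
  unbiased estimator).
* Property sweeps draw triads within $\pm3\sigma$ with pairwise separation
  $\ge 0.5$ µrad; unboundedly close working points make the linear system
  arbitrarily ill-conditioned, which probes conditioning, not correctness.
* $I_R > 1$ is physically impossible for passive samples but is *not*
  clipped (noise produces it); the affected fraction is reported.
* Degenerate denominators ($<10^{-12}$ relative) and non-positive
  intensities mask the pixel rather than raising errors on image paths.

## MIR reference

`mir_retrieve()` fits $A e^{-(\theta-c)^2/2s^2}$ per pixel along a
many-angle stack (a vectorized Levenberg–Marquardt; `stats::nls` cannot be
used because noiseless stacks — which must converge to machine precision —
have zero residual). The maps follow as $\Delta\theta_R = -c$,
$\sigma_S^2 = s^2 - \sigma^2$ and $I_R = A s/\sigma$; the last definition
(fitted-area ratio) makes an object-free pixel read exactly 1 and is the
package's own choice, as the reference technique's normalization is not
standardized. Pixels whose fitted center leaves the sampled range are
masked, not extrapolated. On noiseless closed-form stacks MIR and the
three-image inversion agree to fit tolerance; on simulated stairway data
they agree within combined error bars — the precision claim of the
three-image method.

## Scaling of the validation runs

Acceptance-level simulations keep the full phantom geometry and the
stated 1e4 photons/pixel but coarsen the pixel pitch to 56 µm (recovery,
background) or 112 µm (triad robustness, stairway + MIR) instead of the
native 14 µm, to fit single-CPU runtime budgets. The compared quantities
are ROI statistics and regression slopes, which are pitch-independent; the
one genuinely pitch-dependent effect — the single-pixel edge artifact — is
tested separately on a narrow crop at the native 14 µm pitch.

## Known limitations

* Gaussian RC and Gaussian scattering only (no Voigt/Pearson shapes, no
  multi-population scattering per pixel).
* No iterative/statistical retrieval; pixels are independent.
* The simulator treats foils as homogeneous scatterers; speckle from real
  paper texture (multiple refraction) is not reproduced.
* TIFF I/O is a minimal baseline codec (uncompressed, single-sample
  grayscale, 16-bit unsigned or 32-bit float) — sufficient for the
  package's own pipeline and cross-checked against an external decoder,
  but not a general TIFF library.
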