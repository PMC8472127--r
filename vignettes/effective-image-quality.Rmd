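---
title: "Effective image-quality metrology with effiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective image-quality metrology with effiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effiq)
```

## The model

Classical detective quantum efficiency characterises a detector in
isolation. The *effective* variants characterise the whole imaging chain
as deployed — phantom scatter, geometry, focal-spot and motion blur, and
the anti-scatter grid included. For a system measured behind a
patient-equivalent phantom, the package composes

$$eNEQ(f) = \frac{eMTF(f)^2\,(1-SF)^2}{eNNPS(f)},
\qquad
eDQE(f) = \frac{eNEQ(f)}{TF \cdot AK \cdot q},$$

where $f$ is spatial frequency rescaled to the object plane (mm$^{-1}$),
$eMTF$ is the slanted-edge modulation transfer function, $SF$ the
beam-stop scatter fraction, $eNNPS$ the normalised noise power spectrum
of phantom flat fields (mm$^2$), $TF = AK_+/AK_-$ the phantom
transmission factor, $AK$ the phantom-free air kerma corrected to the
detector plane (µGy), and $q$ the photon fluence per unit air kerma
(mm$^{-2}$µGy$^{-1}$), the ideal squared signal-to-noise ratio per
kerma. $eNEQ$ is the effective number of X-ray quanta contributing to
the image; $eDQE$ is the fraction of the ideal quanta the system
actually exploits.

Two geometric conventions matter:

* **Distance falloff.** A slot-scanned fan beam diverges in one
  direction only, so dosimeter readings are corrected linearly,
  $IAK = AK \cdot SDD/SID$; a cone beam follows the inverse square law.
  The detector-plane kerma is $DAK = IAK \cdot TF$.
* **Magnification.** Detector-plane frequencies map to the object plane
  through $m = SID/(SID - d)$, with $d$ the detector-to-object offset.
  The scan direction of a slot scanner has unit magnification
  (`magnificationAxis = "none"`).

In the $eDQE$ denominator, $AK$ is the phantom-free air kerma corrected
to the detector plane (that is the symbol's definition in the effective
formulation), not $DAK$; a measurement bundle built with $DAK$ instead
is possible for sensitivity runs by passing it as `akUGy`.

## Measurement chain

1. **Detector response** (`fitResponse`, `linearize`). Mean pixel value
   against detector air kerma over an exposure series (nominally 10
   levels), linear or fifth-order polynomial, constrained to be strictly
   monotone over the fitted range. Images are linearized by inverting
   the fitted curve; the inverse is a monotone piecewise-cubic (Hyman)
   interpolation of 1000 forward samples, which treats the linear and
   quintic kinds identically. Pixels outside the invertible range are
   clamped with a reported count; more than 1 % clamped aborts. The
   inversion method is a package choice: a response fit alone does not
   prescribe one.
2. **Slanted-edge eMTF** (`estimateEmtf`). Per-row sub-pixel edge
   crossings (gradient-magnitude centroids) give the edge angle by
   least squares — the nominal 3° tilt is only a generator default, the
   estimator never assumes it. Pixels are projected onto the edge
   normal and binned at 0.1 of the pixel pitch into a super-sampled
   ESF; empty interior bins are filled by linear interpolation, more
   than 10 % empty aborts (angle too shallow). The LSF is the central
   difference of the ESF; a Hann window centered on the LSF peak is on
   by default for measured (noisy) data and off in analytic oracle
   tests. The eMTF is the normalised Fourier modulus, reported to the
   detector Nyquist and averaged over the (nominally 5) edge images on
   a common 0.01 mm$^{-1}$ grid before object-plane projection.
3. **Flat-field eNNPS** (`nnps2d`, `nnps1dVertical`). A central
   1024×1024 ROI per image is tiled with 256×256 sub-ROIs overlapping
   by 128 pixels (49 per image, 196 over 4 images). Each sub-ROI is
   detrended by subtracting a fitted 2D quadratic surface (standard
   flat-field practice; a plain-mean fallback exists) before the
   squared Fourier modulus is averaged. The 2D spectrum is normalised
   by the squared mean linearized signal. The 1D vertical curve
   averages a band of ±7 frequency columns flanking the vertical axis,
   excluding the on-axis column (trend leakage concentrates there),
   then folds negative onto positive frequencies. Band width and axis
   exclusion are configuration, since the underlying 1D-extraction
   protocol admits both a thin and a thick band reading.
4. **Scatter fraction** (`measureScatterFraction`). Disk ROIs of 60 %
   of the cylinder diameter sample the signal behind the central 5×5
   lead cylinders of the beam-stop grid; equal-area ROIs at the
   midpoints between those cylinders sample the background in the same
   image. $SF$ is the ratio of the two means. The 60 % ROI stays clear
   of the penumbra; background ROIs are verified not to overlap any
   shadow. Grid auto-detection (threshold at half background, run-based
   connected-component labeling, centroid clustering) is available;
   synthetic tests pass the exact geometry for determinism.
5. **Fluence per air kerma** (`qValue`). For a tabulated spectrum,
   $K = \sum_E \Phi(E)\,E\,(\mu_{en}/\rho)_{air}(E)\,u$ with
   $u = 1.602\times10^{-5}$ µGy per keV·cm²·g$^{-1}$·mm$^{-2}$ the single
   documented unit conversion, and $q = \Phi_{tot}/K$ — scale-invariant
   in the fluence. The air $\mu_{en}/\rho$ table ships as a CSV fixture
   transcribed from the standard NIST tabulation, interpolated
   log-log. Externally computed spectra can be read from CSV, and
   published $q$ values can be entered directly (`qOverride`) — the
   package does not re-implement a full tube-spectrum code.
6. **Composition and comparison** (`eneq`, `edqe`, `pairwiseReport`).
   Curves are brought onto the 0.1 mm$^{-1}$ reporting grid: eMTF (and
   derived curves) by linear interpolation, eNNPS by *bin-averaging*
   the native-grid estimates within half a step of each reporting
   frequency. The distinction is deliberate: each native NNPS bin is a
   noisy periodogram estimate, and averaging the bins inside a
   reporting cell is the conventional coarse-grid NPS reduction,
   whereas interpolation would carry single-bin noise into every
   downstream point. The stratified comparison runs a Kruskal–Wallis
   test per frequency bin (low/high; defaults 0.00–1.00 and 1.15–2.15
   mm$^{-1}$ for eDQE, 0.00–1.25 and 1.35–2.55 for eNEQ) and, only
   when the global test is significant at 5 %, all pairwise
   Mann–Whitney tests, unadjusted. $U$ is reported as
   $\min(U_a, U_b)$ — the convention under which complete separation
   prints $U = 0$ — with the tie-corrected normal $Z$; an exact
   enumeration is available for pooled sizes ≤ 12. Adjacent frequency
   samples are correlated, so these tests are anti-conservative; the
   report prints that caveat.

## The synthetic generators

The study design this package targets deposits no raw images, so every
estimator is validated against synthetic radiographs with closed-form
ground truth:

* **Flat fields** — constant level + optional 2D quadratic trend +
  i.i.d. Gaussian noise; true NNPS plateau
  $\sigma^2\Delta x^2/\mu^2$. Gaussian noise is the default because
  every downstream formula consumes only second-order statistics, so
  the truth is exact; a Poisson option exists for dose-scaling sanity
  checks.
* **Edges** — a tilted step convolved with an isotropic Gaussian PSF
  and integrated *analytically* over each square pixel aperture
  (repeated integrals of the normal CDF), so no rasterization bias
  enters the MTF oracle: the pre-sampled truth is exactly
  $\exp(-2\pi^2\sigma^2 f^2)\,\mathrm{sinc}(\pi f a)$.
* **Beam-stop grids** — hard opaque disks (no penumbra): background
  $P+S$, shadow $P\,t_{Pb}+S$, so the true scatter fraction is the
  exact ratio the analyzer should recover.
* **Exposure series** — mean pixel value equal to the chosen response
  at each of 10 kerma levels, plus noise.
* **Spectra** — Kramers bremsstrahlung $(kVp-E)/E$ with Al/Cu
  filtration from shipped NIST attenuation tables, plus a default
  inherent tube filtration of 2.5 mm Al equivalent: clinical tubes
  always carry window/oil/collimator filtration, and without it the
  spectrum is unphysically soft and $q$ falls below the magnitude such
  beams show. Note that in the diagnostic range hardening *raises* q:
  kerma per photon $E(\mu_{en}/\rho)(E)$ bottoms out near 70 keV, which
  is why systems run at higher tube voltage show larger q values.

What the generators do **not** emulate: structured (fixed-pattern)
noise, detector lag, focal-spot blur, scatter point-spread tails,
anatomical texture, and vendor pre-processing. Passing tests therefore
demonstrate the correctness of the estimators and their composition,
not field performance on any physical detector.

The default three-system synthetic comparison
(`syntheticSystemDefaults`) places a slot scanner and two flat-panel DR
systems at the tube voltages, SIDs, scatter fractions, transmission
factors and air kermas typical of chest/knee protocol measurements on
such systems, with flat-field noise chosen so the eNNPS plateau implies
noise-equivalent-quanta magnitudes in the reported range. The slot
system's pixel pitch is set to 0.18 mm — a package choice, since slot
detectors' pitch varies by configuration — so that its Nyquist range
covers the full comparison band on all systems. Its exposure-series
dose levels span 0.02–15 µGy so that even deep beam-stop shadows stay
inside the invertible response range.

## Numerical choices

* ESF bin width 0.1 × pitch; bins are means of member pixels; the
  known transfer functions of the bin box and the central-difference
  kernel ($\mathrm{sinc}(\pi f h)\,\mathrm{sinc}(2\pi f h)$) are
  divided out in the high-level pipeline (`compensate = TRUE`) and left
  in place in the bare `lsfToMtf` operation.
* Edge angles below 0.5° degenerate the super-sampling and warn;
  above 45° the fit is rejected.
* The response inverse uses 1000 forward samples; monotonicity is
  enforced by rejection (with the turning point named), not by a
  constrained fit.
* Log-log interpolation for all attenuation/absorption tables.
* Kruskal–Wallis delegates to `stats::kruskal.test` (tie-corrected);
  fully tied data short-circuit to $H = 0$, $p = 1$. The Mann–Whitney
  $U/Z$ convention is implemented in-package and cross-checked against
  `stats::wilcox.test` and exhaustive enumeration in the tests.
* Ties in `maxPeak` resolve to the lowest frequency.

## Problem sizes

The default orchestration (`runProtocol`) uses a 50 mm edge ROI and a
512-pixel NNPS ROI per system — enough for stable curves while keeping
a three-system run in the seconds range. The validation suite runs the
full-scale analysis settings (80 mm ROI; 1024/256/128 NNPS tiling, 196
sub-ROIs) where the ground-truth recovery properties are asserted. At
those settings the eNNPS reporting-grid points retain roughly 2 %
relative sampling noise from the finite number of averaged periodogram
bins — the irreducible floor implied by 4 images and the overlapping
sub-ROI scheme — which is why unbiasedness checks of the composed eDQE
average a few independent replicates.

## Limitations

* The minimal DICOM reader/writer covers uncompressed explicit-VR
  little-endian monochrome files only; it exists because no DICOM
  package is otherwise available to the package's dependency set.
* The Kramers spectrum model has no characteristic lines and no anode
  self-absorption; $q$ from generated spectra is magnitude-realistic,
  not tube-accurate. Measured spectra or published $q$ values should
  be supplied when available.
* The rank-based comparison inherits the dependence problem of testing
  correlated frequency samples; it replicates the published procedure
  and is labelled exploratory.
* Slot-scan motion blur in the scan direction is not modelled; the
  per-axis magnification machinery is exposed rather than guessed at.
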