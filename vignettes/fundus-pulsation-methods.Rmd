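---
title: "Measuring ocular fundus pulsations and perfusion from repeated complex OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular fundus pulsations and perfusion from repeated complex OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octpulse)
```

## The measurement problem

The in- and outflow of blood deforms the posterior eye in synchrony with the
cardiac cycle. In the rodent eye these fundus pulsations are a relative axial
motion between the retina and the chorioscleral complex (choroid plus sclera)
on the order of tens to hundreds of nanometers — two to three orders of
magnitude below the axial pixel of an OCT system. They are nevertheless
measurable, because the *phase* of the complex OCT signal shifts by
$4\pi n\,\Delta d/\lambda_c$ when a scatterer moves axially by $\Delta d$
between two acquisitions. `octpulse` implements the full post-processing
chain that turns repeated complex-valued B-scans into (i) calibrated
chorioscleral velocity and displacement estimates, (ii) pulsatility spectra
with heart rate and harmonic amplitudes, (iii) perfusion maps and flux values
by OCT angiography, and (iv) cardiac-phase-gated velocity maps — together with
a speckle phantom generator that provides exact ground truth for every stage.

## Signal model and processing chain

Each pixel of a B-scan is a complex sample
$S_{b,i}(x,z) = A_{b,i}(x,z)\,e^{j\phi_{b,i}(x,z)}$, with $b$ the slow-axis
position, $i$ the repetition index ($M_B$ repeats per position), $x$ the
A-scan and $z$ depth. The chain is:

1. **Phase differencing.** For consecutive repetitions,
   $\Delta S_{b,i} = S_{b,i} \cdot S_{b,i+1}^{*}$ and
   $\Delta\phi_{b,i} = \arg \Delta S_{b,i}$. Only pixels whose pair-mean
   reflectivity exceeds a noise threshold contribute
   (`threshold_mask()`; default: twice the 0.99 quantile of the background
   amplitude, sampled from the shallowest depth rows).
2. **Bulk-motion correction.** Global axial drift between the two frames is
   estimated per A-scan as the argument of the complex sum of the masked
   $\Delta S$ over the retinal slab $[z_I, z_R]$ (ILM to RPE), the retina
   serving as the motion reference. The complex (phasor) sum — rather than
   an arithmetic mean of angles — is wrap-safe: two phasors at $\pm 2.9$ rad
   average to $\pi$, not $0$.
3. **Chorioscleral relative phase.** The bulk-corrected phasor average of
   the masked $\Delta S$ below the RPE gives $\Delta\phi_{RCS}(x)$, the phase
   shift of the chorioscleral complex relative to the retina.
4. **Velocity conversion.**
   $v = \Delta\phi_{RCS}\,\lambda_c / (4\pi n \tau_B)$. At
   $\lambda_c = 840$ nm, $n = 1.35$ and $\tau_B = 7.65$ ms the unambiguous
   range is $\pm 20.33\ \mu$m/s; larger velocities alias (no unwrapping is
   attempted, mirroring the hard instrument limit).
5. **Incidence-angle correction.** The RPE surface is smoothed by a 2-D
   least-squares polynomial (default degree 2, fitted volumetrically in
   physical coordinates since the normal needs both transverse derivatives);
   the angle $\alpha$ between the surface normal and the beam yields
   $v_{RCS} = v/\cos\alpha$, reconstructing motion perpendicular to the
   fundus. $\alpha$ is capped at 60°: beyond that, $1/\cos\alpha$ amplifies
   noise unboundedly, and a fundus inside a 30° field of view stays far from
   the cap; capped A-scans are flagged invalid instead of corrected.
6. **Outlier handling.** Frames whose retinal phase remains strongly
   decorrelated *after* bulk correction (weighted circular variance above
   0.5) indicate severe axial or transverse motion; their velocities are
   excluded and substituted by linear interpolation between the nearest valid
   frames (nearest-valid copy at the series boundaries). The 0.5 default is a
   package choice — on phantoms, genuine frames stay below ~0.1 and
   phase-scrambled frames approach 1, so the limit separates the two regimes
   with a wide margin. More than 50% excluded frames aborts the analysis.

### Segmentation

The ILM/RPE detector is deliberately simple and sits behind a small
interface (`layer_model()`), so a more elaborate segmenter can be dropped in
for difficult real data: the RPE is the brightest band of the
repetition-averaged amplitude (median-filtered along the fast axis only, so a
thin bright line in depth survives), the ILM the shallowest supra-threshold
pixel; invalid A-scans are in-filled transversally and both surfaces are
median-smoothed (windows of 9 A-scans and 5 positions).

### Spectral quantification

The per-frame mean of $v_{RCS}$ (over valid A-scans in the region of
interest) is analyzed by a short-time Fourier transform: windows of 256
frames with 75% overlap — a 1200-frame series yields exactly 15 windows whose
amplitude spectra are averaged. Each window is linearly detrended (residual
drift otherwise leaks into the lowest bins) and Hann-tapered, with the
amplitude rescaled by the taper's coherent gain so that a sinusoid of
velocity amplitude $V$ produces a spectral peak of height $V$. The
fundamental frequency $f_0$ is the highest mean-spectrum peak inside the
heart-rate search band (default 2–10 Hz, bracketing rodent heart rates);
harmonics are read off within ±1 bin of the integer multiples. Spectral
*amplitude* (not power) is reported, matching how the fundamental and first
harmonic of the pulsation are quantified. Heart rate is $60 f_0$; the
displacement amplitude is the mean peak-to-peak excursion of the integrated,
mean-removed velocity over five consecutive cardiac cycles (for
$v = V\sin 2\pi f t$ this equals $V/\pi f$ exactly).

**Frame timestamps.** B-scans are acquired uniformly at $\tau_B$, but only
$M_B - 1$ of every $M_B$ consecutive intervals produce a differential frame
(the last repetition of a position pairs with nothing), so the velocity
series has one missing $\tau_B$ slot per position boundary. Treating the
differential frames as gaplessly $\tau_B$-spaced would compress the time
axis by $M_B/(M_B-1)$ — a 25% frequency bias at $M_B = 5$, which would be
visible immediately in the heart rate. The package therefore keeps true
mid-interval timestamps on every frame and regrids onto the uniform $\tau_B$
grid (linear in-fill of the boundary slots) before any FFT, phase gating or
time integration. Plain numeric series are taken as already uniform.

### Angiography

Motion contrast is computed as pairwise amplitude decorrelation averaged over
the $M_B - 1$ repetition pairs,
$D = 1 - \frac{1}{M_B-1}\sum_i 2 A_i A_{i+1}/(A_i^2 + A_{i+1}^2) \in [0, 1]$,
insensitive to bulk phase by construction; sub-noise voxels are zeroed. Three
plexus slabs are defined relative to the segmented surfaces — SCP (upper 60%
of the retina), DCP (remainder down to the RPE), CS (40 px below the RPE by
default). The split fraction and CS depth are package choices: the anatomical
plexus boundaries (IPL, OPL) are not available from a two-surface segmenter.
En-face maps are maximum-intensity projections over the slabs. Retinal maps
are enhanced with a multi-scale Frangi vesselness filter (Hessian eigenvalue
ridge measure, scales 2/4/8 px, $\beta = 0.5$, structureness constant at half
the per-scale maximum Hessian norm); larger superficial vessels (vesselness
at scales 6–8 px above 0.25, dilated by 2 px) are excluded from the DCP and
CS flux to avoid shadowing artefacts, and a circular disk (default 150 px,
about 440 µm at the native 1.5 mm/512 sampling) removes the optic nerve
head. The **flux** of a plexus is the mean flow-signal intensity over its
detected blood-flow region — vesselness-defined for SCP/DCP, flow-defined
for CS, thresholded at the background median + 3 MAD. The averaged intensity
is the *raw* decorrelation value over that region (a switch selects the
enhanced values instead); raw values keep the flux interpretable as a mean
decorrelation.

### Cardiac gating

The velocity series is band-passed around $f_0$ (±30%, 2nd-order
Butterworth, zero-phase) and the instantaneous cardiac phase taken from the
analytic signal, with phase 0 at the positive-going zero crossing (a velocity
maximum maps to phase 0.25). Instantaneous phase rather than rigid folding at
a fixed $f_0$ tolerates heart-rate drift over a 15 s acquisition. The cycle
is divided into 20 equal sections and each section's map averages the frames
of three adjacent sections (cyclic); sections without frames at a position
are rendered missing, never interpolated. Gating is per frame, with
per-A-scan averaging — a whole B-scan shares one cardiac phase. Thresholding
gated maps at 12 µm/s isolates regions of locally increased deformation.

## The phantom generator

`generate_phantom()` produces complex volumes whose every property is known:

* **Speckle**: fully developed — one independent complex circular-Gaussian
  draw per voxel, scaled by tissue reflectivity (retina 1, a bright RPE line
  3, chorioscleral slab 0.8, background 0). This is the simplest model with
  the correct phase statistics for phase-difference testing.
* **Displacement as phase**: the chorioscleral waveform (sum of harmonics,
  `cardiac_waveform()`) and the bulk drift (0.5 Hz sinusoid plus white
  per-scan phase jitter by default, exercising the bulk correction without
  aliasing into the cardiac band) enter as pure phase ramps. Measured
  displacements (≤ 300 nm) are far below an axial pixel, so phase encoding
  is the dominant physical effect and keeps ground truth exact. The
  pulsation is directed along the local surface normal by default
  (`pulse_along_normal`), so its axial component is $d\cos\alpha$ and the
  angle correction is genuinely exercised on tilted geometry.
* **Flow**: vessel tubes decorrelate between repetitions through an AR(1)
  mixture with fresh speckle; the complex correlation between consecutive
  repetitions is exactly `1 - level`. The default level is 1 (full
  decorrelation): over a 7.65 ms inter-B-scan time blood speckle
  decorrelates completely (the flow signal saturates), which is the
  realistic regime for this frame rate.
* **Geometry**: the ILM is a 2-D polynomial over the field of view; presets
  include a flat quiet eye, a strongly pulsing eye (300 nm peak-to-peak, the
  largest displacement scale observed in vivo), a 10°-tilted and curved
  retina, a bulk-motion-heavy acquisition and a vascularized phantom.
* The axial pixel defaults to 2 µm, consistent with a 3.8 µm axial
  resolution system; it is metadata the container requires, not a quantity
  the method itself fixes.

What the phantom does **not** emulate: transverse or rotational motion (the
method corrects axial bulk motion only, and says so), multiple scattering,
depth-dependent signal roll-off, projection/tail artefacts under vessels, and
instrument phase noise beyond a white jitter. Passing phantom tests therefore
validates the *algorithms* — sign conventions, calibration factors, wrap
robustness, masks and bookkeeping — not robustness to every artefact of real
acquisitions.

## Numerical choices and degenerate inputs

* Depth averaging of phases is always amplitude-weighted phasor averaging,
  never an arithmetic mean of angles.
* The chorioscleral slab starts `cs_offset` (default 2) pixels below the
  segmented RPE: the RPE is bright and static, so a one-pixel segmentation
  quantization error — unavoidable on tilted geometry — would otherwise leak
  its reflectivity into the moving-slab phasor and bias velocities low by
  tens of percent at the affected A-scans.
* RPE argmax ties break to the shallowest pixel; A-scans with no
  supra-threshold pixel are invalid and in-filled; an entirely
  sub-threshold volume is an error ("no tissue found").
* The surface fit is refused when the design matrix is rank-deficient
  (e.g. polynomial degree too high for the grid).
* The fundamental search refuses a heart-rate band that reaches the Nyquist
  frequency; a spectrum whose in-band peak is below 3× the spectrum median
  sets a "no pulsation detected" flag (with a warning) instead of failing.
* An empty blood-flow region yields flux 0 with a warning, not an error.
* Simulation sizes: tests and examples run phantoms of 64–128 positions with
  96 depth pixels, which keeps every property measurable (≥ 256 differential
  frames, ≥ 10 cardiac cycles) at interactive runtimes.

## Known limitations

* The two-surface segmenter assumes the RPE is the brightest band and tissue
  occupies one contiguous depth range; pathology or strong vignetting breaks
  both assumptions (the interface accepts external segmentations).
* Velocities beyond ±20.33 µm/s alias; the package reports them wrapped.
* Whether the chorioscleral phase is averaged before or after bulk
  subtraction is ambiguous in principle; the phasor formulation used here
  commutes in the noiseless case and was chosen for wrap robustness.
* Flux values are comparative, not absolute flow: the decorrelation signal
  saturates for fast flow at this inter-B-scan time.
* The container dialect stores real and imaginary parts as separate HDF5
  datasets; complex HDF5 datatypes are not portable across language bindings.

## Package shape

The data objects are inherently array-valued (4-D complex volumes, depth
surfaces, en-face maps), so the package exposes them as light S3 containers
in the style of Bioconductor imaging packages rather than forcing tabular
frames; everything naturally tabular — frame series, spectra, flux tables —
is returned as a tibble, and `tidy()`/`glance()`/`autoplot()` methods cover
the fitted result objects.
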