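---
title: "Processing concurrent MR-optoacoustic brain data: models and methods"
author: "oatpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing concurrent MR-optoacoustic brain data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Volumetric optoacoustic tomography (OAT) acquired inside a high-field MR
scanner offers concurrent optical-contrast hemodynamics and MRI anatomy
from the same mouse brain, but the combination corrupts the acoustic data:
RF pulses of the echo-planar BOLD sequence couple into the transducer
cables and contaminate a substantial fraction of the recorded sinograms.
`oatpipe` implements the complete processing chain for such data —
corruption detection, sinogram restoration, reconstruction under a
two-region speed of sound, spectral unmixing into hemoglobin components,
rigid multimodal coregistration and oxygen-challenge statistics — together
with a fully seeded synthetic-data generator that produces every input the
chain needs, so all behaviour is testable on a desk without access to a
scanner.

## Acquisition model

The detection array carries 384 elements on a 40 mm-radius spherical cap
with 130° aperture (placed by a deterministic Fibonacci lattice; the real
array's exact element layout is not public, and a quasi-uniform lattice
preserves the aperture and density that drive the point-spread function).
Each laser shot produces a sinogram of 384 channels x 494 samples at
40 Msps. The laser sweeps five wavelengths (700, 730, 755, 800, 850 nm) on
a per-pulse basis at 50 Hz, so each wavelength is sampled at 10 Hz; a 900 s
protocol yields 45,000 frames, 9,000 per wavelength. The concurrent BOLD
sequence runs 11 slices per 995 ms TR for 900 repetitions.

The acquisition window covers 12.35 µs; a configurable pre-trigger delay
(default: the field-of-view centre arrival at the water sound speed sits at
mid-window) positions brain arrivals inside it.

## Forward model

Every spherical absorber emits the classical N-shaped transient of a
uniformly absorbing sphere: at distance $d$ the pressure is
$p(t) \propto \mu_a\, c\,(\tau - t)/(2d)$ for $|t - \tau| \le a/c$, with
$\tau$ the time of flight and $a$ the radius. Amplitudes scale linearly
with the absorption coefficient and pulse energy and fall off as $1/d$.
The transducer response is modelled as the stated 0.1–8 MHz detection band,
applied as a zero-phase order-4 Butterworth band-pass on a 4x temporally
oversampled axis before decimation to 40 Msps (the true element impulse
response is unpublished; a 40 µm sphere's raw N-wave is sub-sample at the
DAQ rate, so the band limit is what shapes the recorded wavelet).
Refraction, directivity, and full-wave propagation are not modelled.

## Interference model and corruption QC

RF interference is injected as additive bipolar bursts of configurable
amplitude on a uniformly random channel subset spanning a random sample
interval — the published material shows burst morphology but does not
parameterize it, so the injector exposes amplitude, channel fraction and
jitter as parameters rather than asserting fidelity. Slice-excitation
events are laid out at 11 equally spaced instants per 995 ms TR. Because
the physical 12.35 µs record is four orders of magnitude shorter than the
20 ms frame period, an instantaneous event would almost never overlap it;
the observable quantity is whether a *frame* is corrupted, so the injector
treats the full repetition period (1/PRF, configurable) as a frame's
acquisition window. This reproduces the corrupted-frame fraction
(≈ 11.06/50) and the 11 Hz corruption-spectrum peak.

Detection follows the residual rule: per frame, subtract the nominal
per-channel values and flag the frame when the L1 norm of the residual
exceeds a threshold. Two quantities the original description leaves open
are fixed as follows:

* *Nominal values* are the per-channel, per-sample **median** across all
  frames of the same wavelength — the median stays calibrated even when a
  fifth of the frames are contaminated, which a mean would not.
* *Threshold* defaults to median + 5 x scaled-MAD of the per-frame L1
  residuals, estimated **per wavelength** (whether the original threshold
  was global or per wavelength is unstated; per-wavelength is used because
  nominal sinograms differ across wavelengths). A fixed absolute threshold
  is accepted via configuration.

Frames with non-finite samples are flagged unconditionally. The corruption
spectrum is the DFT of the 0/1 indicator at the frame rate; the peak search
excludes DC, uses the one-sided spectrum, and breaks ties toward lower
frequency.

## Restoration

Per wavelength, non-overlapping blocks of 10 consecutive frames (1 s at
10 Hz, matching the 1 Hz fMRI volume rate) are collapsed pixel-wise:
values farther than 3 scaled-MADs from the block median are discarded and
the remainder averaged; if everything at a pixel is rejected the block
median is used and the event logged. "Ten adjacent measurements" is read
per wavelength, since that exactly yields the 1 Hz target rate.
QC-flagged frames are removed from blocks *before* the pixel statistics,
so gross corruption cannot inflate the block median. Blocks align to the
stream start; a trailing partial block is dropped. A min/max trimming rule
is selectable for users who prefer fixed trimming over the MAD rule.

## Reconstruction

Filtered back-projection with the universal term $b(t) = p(t) - t\,
\partial_t p(t)$, uniform element weights, and linear temporal
interpolation; out-of-window delays contribute zero and are counted.
Voxels map to mm by the voxel-centre convention, origin at the sphere
centre, z into the tissue; the default grid is the 8 x 8 x 4 mm field of
view at 100 µm.

The heavy-water coupling medium (1400 m/s) is acoustically slower than
brain tissue (1530 m/s), so a uniform-speed reconstruction defocuses deep
structures. The two-region model splits each straight voxel-element ray at
a single-valued surface $z = s(x, y)$ and sums the per-region travel
times; refraction is deliberately ignored (a delay correction along
straight rays, consistent with the two-speed description; Snell-corrected
ray bending is out of scope). The two-pass procedure is: reconstruct at
1400 m/s so superficial structures are sharp, segment the interface (first
crossing of 50% of each column's maximum, scanned from the water side,
then a least-squares plane — a quadratic surface is optional; the "simple
geometry" used originally is unstated and a plane is the default), then
reconstruct with the two-region model. Additional segmentation passes are
available but off by default.

Resolution is characterized by Gaussian fits to 1-D profiles through a
reconstructed microsphere; FWHM $= 2\sqrt{2\ln 2}\,\sigma$. A
non-convergent fit falls back to the direct half-maximum crossing width
and is flagged.

## Unmixing

Reconstructions are normalized to per-wavelength pulse energy, corrected
for fluence with a single exponential $\exp(+\mu_{\rm eff} d)$ in depth
$d$ below the segmented interface, and unmixed voxel-wise by least squares
against compiled literature extinction spectra of HbO and HbR at the five
wavelengths (the original coefficients and $\mu_{\rm eff}$ values are not
printed; $\mu_{\rm eff}$ defaults to a spectrally flat 0.6 mm⁻¹ and both
are configuration-exposed). Non-negativity is enforced by a clipped
active-set solve (the two-component problem admits a closed form);
unconstrained least squares is available for diagnostics, and the
per-voxel residual norm is kept for QC. Concentrations are relative: only
sO2 and fractional changes are interpreted. HbT = HbO + HbR and
sO2 = HbO/HbT, with sO2 masked where HbT is at or below a floor.

## Registration

All transforms are 6-DOF rigid: intrinsic z-y-x Euler angles about the
volume centre, then translation — the convention is stored with every
serialized transform so they are exchangeable. Registration maximizes
normalized mutual information (32 x 32 histogram on 1st–99th percentile
clipped intensities) for cross-modality pairs and normalized
cross-correlation for same-modality pairs, over a 4x/2x/1x
block-downsampled pyramid with Nelder-Mead descent per level and seeded
random restarts; the fixed image is subsampled to at most 30,000 voxels
per metric evaluation. Vessels act as landmarks implicitly through
intensity matching (landmark initialization can be supplied as `init`).
The coregistration chain OAT ← MRA ← T1-transverse ← T1-coronal ← BOLD is
composed from the pairwise transforms. Reslicing is trilinear (nearest
available) with NA masking outside the field.

## Synthetic paradigm and its limits

The oxygen-challenge generator drives per-compartment oxygen saturation
toward $s_0 + g\,(\mathrm{FiO_2}(t) - 0.36)$ through first-order kinetics
(τ = 10 s — transitions are smooth in the published traces but their
kinetics are unstated, and 10 s is a conventional hemodynamic time
constant), with the 15-min paradigm: 3 min baseline at FiO2 0.36, then
three cycles of 2 min normoxia (0.20) and 2 min hyperoxia (1.00). Total
hemoglobin is held exactly constant per compartment, so HbO + HbR is
conserved by construction — matching the observation of no significant
HbT change. Default baseline saturations (0.80 vessel/venous-weighted,
0.70 parenchyma) and gains (0.25 vs 0.10) encode the reported ordering
that vascular responses exceed parenchymal ones; noise is additive on the
saturation trace.

What the generator does **not** emulate: physiological drift and motion,
breathing/cardiac pulsation, wavelength-dependent fluence ("spectral
coloring") beyond the single exponential, skull aberration, transducer
directivity, and the true RF burst statistics. Passing tests therefore
demonstrate correctness of the algorithms under the stated models, not
performance on scanner data.

Simulated MRI volumes (MRA, two T1 views, 4-D BOLD) render one continuous
scene — phantom vessels plus a smooth brain-shaped background with fixed
internal features — on each sequence's grid under known rigid transforms,
so registration accuracy can be scored against ground truth. BOLD is
modulated opposite in sign to HbR with the parenchyma trace.

## Functional statistics

ROI time courses are means over 0.4 mm cubes. Fractional change is
$\Delta S/S = (S(t) - BL)/BL$ with $BL$ the mean of the first 3 min.
Display smoothing is a Butterworth low-pass with normalized half-power
frequency 0.15 (order 4 — the order is unstated; applied
forward-backward, with the single-pass cutoff pre-warped so the *net*
zero-phase response has its half-power point exactly at 0.15).
Response amplitudes are the maximum absolute fractional change per
stimulation cycle (normoxia + hyperoxia window; baseline excluded) and
are computed on unsmoothed series by default, since whether smoothing
preceded the original amplitude computation is ambiguous ("to display a
smooth response curve" suggests display only); a switch enables the other
reading. Group comparisons use the two-sample two-tailed t-test at
α = 0.05, pooled variance by default with Welch as an option (the variant
used originally is unstated).

## Numerical choices and problem sizes

* Zero-phase filtering uses odd-reflection end padding to suppress edge
  transients.
* The interface polynomial is evaluated exactly along each ray (plane and
  quadratic surfaces give a linear/quadratic equation in the ray
  parameter).
* Row-wise medians over large pixel blocks use a grouped-sort rather than
  per-row loops.
* Streams are serialized as R-native RDS with a tagged schema; volumes as
  NIfTI-1 with the grid in the qform/sform affine (voxel-centre
  convention); transforms and provenance as JSON; configuration as YAML.
* Test and acceptance runs use desk-scale problem sizes chosen to keep
  the full suite in the minutes range on a single core: timing-sensitive
  checks keep the full 900 s / 50 Hz protocol but shrink the per-frame
  matrix (the corruption statistics are independent of frame contents);
  reconstruction checks use reduced grids around the structures of
  interest; registration fixtures use 6–12 mm volumes at 0.15–0.4 mm.

## Known limitations

Straight-ray two-region delays ignore refraction; the exponential fluence
model ignores spectral coloring; uniform back-projection weights neglect
solid-angle variation (whether the original weighted by solid angle is
unstated); the N-wave forward model is valid for optically small, acoustically
homogeneous spheres only; registration is intensity-based rigid with no
distortion correction. These mirror the scope of the processing being
modelled rather than implementation shortcuts.
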