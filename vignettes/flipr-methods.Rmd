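---
title: "Models and methods behind flipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flipr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flipr)
```

## The problem

Camera-based voltage imaging needs sub-millisecond frames, which normally
confines it to a single focal plane. Flipped-image remote focusing (FLIPR)
sweeps a lightweight retroreflector in the image space of a remote objective
so that the heavy water-dipping objective stays still while the detection
focus races up and down through the tissue at 500 sweeps per second,
synchronized with a light sheet. A camera triggered at 8 kHz then collects
16 frames per sweep period: 8 planes on the downward (rising-z) stroke and
8 on the upward stroke, covering a 50 um deep volume.

Two geometric artifacts are intrinsic to this acquisition and must be
undone in software:

* **Tilted optical planes.** The focus moves continuously while the
  camera's rolling shutter staggers row exposure starts, so each row of a
  frame images a slightly different z. Within one frame the focal z spans
  roughly one per-plane z extent (`plane_z_extent(50, 8)` = 6.25 um), and
  the tilt direction flips between the down- and the up-stroke.
* **Stroke-dependent lateral offset.** The swept actuator follows a
  slightly ellipsoidal trajectory, displacing down-stroke images from
  up-stroke images by up to 6.5 um along the camera row (y) axis.

`flipr` provides (i) closed-form calculators for the optical design,
(ii) a forward simulator producing frame streams with exactly these
artifacts plus realistic noise and ground truth, (iii) the reconstruction
pipeline (jitter correction, motion correction, stroke-shift compensation,
tilted half-plane stitching, 3D segmentation, weighted trace extraction),
and (iv) bead/PSF characterization and light-sheet calibration analyses.

## Optical design calculators

All relations are closed-form and exact. With the 16x primary objective
(200 mm reference tube length) behind a 200 mm tube lens and the 20x remote
objective behind a 124 mm effective tube lens,

```{r}
tr <- optical_train()
lateral_magnification(tr)        # 1.2903 -> prints as 1.29
ideal_remote_magnification(1.333, 1.000) # 1.333, the water/air index ratio
sample_fov_x(tr)                 # 387.5 um from the 0.5 mm retroreflector
retroreflector_na_limit(1, 90)   # 0.7071: NA < 0.7 n along the folded axis
rayleigh_length(3.4, 0.532)      # 17.07 um for the light sheet
```

The remote objective's NA is quoted inconsistently in vendor/setup
descriptions (0.7 vs 0.75); the config stores a single value
(`na_primary` concerns the primary side only, so no derived quantity here
depends on the discrepancy). The Gaussian PSF used by the renderer,
`psf_sigmas()`, uses the standard approximation constants 0.21 (lateral)
and 0.75 (axial); it is a simulator device, not a claim about measured
optics. A green emission wavelength of 0.546 um is the default because it
reproduces the conventional 0.34 um diffraction-limited FWHM at NA 0.8;
it is an assumption, documented here, and freely overridable.

## The forward model

**Drive waveform.** A symmetric triangle at 500 Hz spanning 0..50 um,
passed through a causal second-order Butterworth low-pass at 2000 Hz
(order configurable) to emulate the analog filtering that protects the
voice-coil; the waveform is tabulated in filter steady state so its mean
over whole periods is exactly half the range. The actuator may lag the
drive clock by `phase_lag` radians; the light sheet follows the nominal
clock, which is what makes an uncorrected lag defocus the acquisition.

**Rolling shutter.** Row r of frame i starts exposing
`r * readout_row_stagger` after the frame trigger; the row images the
sweep z evaluated at its mid-exposure time. The default stagger spreads
the shutter over one full trigger period, reproducing the ~6.25 um
within-frame z span; zero stagger gives a global-shutter control.

**Emission.** Each soma is a Gaussian blob (PSF convolved with a Gaussian
soma profile of sigma = diameter/4), weighted axially by the detection
PSF and by the light-sheet profile centered at
`calibration_slope * z + calibration_intercept`. Intensity is modulated by
`(1 + polarity * dFF(t))`, multiplied by `exp(-t / bleach_tau)`
(tau = 72 s default), then Poisson shot noise, Gaussian read noise, and
the camera baseline are applied. The default response polarity is -1
(fluorescence dips on depolarization, as for negative-going chemigenetic
voltage indicators).

**Voltage dynamics.** Homogeneous Poisson spikes (default 3 Hz, the
elevated spontaneous rate of a convulsant-treated preparation; published
close-ups show several spikes per 2.5 s window) convolved with a 1 ms /
4 ms difference of exponentials at -15% dF/F; a configurable fraction
(default 0.4) of cells additionally carries 20 Hz sinusoidal bursts
(fictive-swimming-like rhythm, -8% dF/F, ~0.8 s bursts); subthreshold
fluctuations are an Ornstein-Uhlenbeck process with a 20 ms correlation
time and 1% dF/F sd — membrane filtering makes subthreshold voltage
band-limited, so white-at-Nyquist noise would be unphysical. Soma
brightness defaults to 3000 peak photons/pixel/frame, a photon budget at
which the ROI-mean per-spike SNR is about 10, consistent with
clearly resolvable single spikes.

**Exposure jitter.** Clock mismatch between trigger and camera is modelled
as piecewise-constant segments: at each change point all subsequent frames
scale multiplicatively above the camera baseline and every row gains a
persistent additive offset. Step-like segments mirror the correction the
artifact admits.

What the generator does **not** emulate: light scattering, aberrations
beyond the Gaussian PSF, non-rigid tissue motion, occlusion between
somata, neuropil background structure, and indicator kinetics beyond the
fixed spike kernel. Passing the round-trip tests therefore demonstrates
the correctness of the geometry and of the extraction machinery under the
stated noise model — not performance on real tissue.

## Reconstruction pipeline

1. **Jitter correction.** Detection works on the per-frame pixel
   *median*: an exposure step scales every pixel, while neural activity
   is spatially localized — a bursting cell can move the frame *mean* by
   more than a jitter step, and a mean-based detector then "corrects"
   biology away. Medians are normalized per frame-in-period (they also
   vary with sweep position, so detection must compare like with like — a
   requirement of correctness, not merely a choice). A split-window
   median statistic (window = two sweep periods, so both halves sample
   every plane equally) marks change points where the level steps by more
   than `min_step` (default 0.5%, raised adaptively to 6 robust sds of
   the statistic when the background is dim and the statistic noisy);
   candidates within one window merge to the strongest, and each event is
   then localized exactly with a short mean-difference statistic (the
   wide median statistic is flat within half a window of a step). Scales
   and per-row offsets are estimated from windows local to each event —
   within a window the bleaching trend is negligible, so the estimates
   are unbiased — with the per-row additive component removed by
   centering across planes before the scale ratio is taken. Correction
   subtracts the per-row offsets and divides the above-baseline signal by
   the segment scale, and is idempotent.
2. **Motion correction.** Per-plane rigid registration against the median
   of the first 50 frames, by FFT cross-correlation with single-step
   upsampled-DFT refinement (default 1/10 px). Translation uses separable
   Catmull-Rom interpolation with a recorded border-fill mask.
3. **Stroke-shift compensation.** The cross-power spectra of all
   z-matched down/up mean-plane pairs are pooled before peak finding: the
   common rigid shift adds coherently across pairs while spurious
   cross-cell matches (caused by the opposite tilt weighting each cell
   differently per stroke) do not. A per-pair median was measurably less
   robust at desk-scale cell densities, which is why the pooled estimator
   is the default. Compensation is symmetric — each stroke moves half the
   shift — so absolute y geometry stays unbiased; the time series are
   rolled by whole rows (no resampling of raw traces), the time-mean
   images used for stitching subpixel-translated.
4. **Stitching.** Each time-mean plane is split at the middle row (the
   row axis is forced by the rolling-shutter tilt); each half carries its
   mean z from the frame z-map. Top and bottom halves are paired by z
   rank — equivalently, each half joins the half of another plane closest
   in z, with exact ties resolved toward the same stroke by stable
   ordering — giving a 2-planes-per-sweep-deep stack with strictly
   increasing slice centers and full provenance. Both strokes are pooled
   into the reference volume (a config switch can restrict to one); no
   blending is applied. The provenance map inverts the stitching so 3D
   ROIs index raw per-plane movies.
5. **Segmentation.** Difference of Gaussians at FWHM `scale/2` and
   `scale` (per-axis sigmas honor anisotropic voxels), local-maxima seeds
   above median + 4 MAD with non-maximum suppression at 0.8 scale, then
   nearest-seed assignment of voxels above 0.25 of each seed's smoothed
   peak — the level at which a soma profile blurred by the detection PSF,
   the light-sheet thickness, and the pre-smoothing crosses its
   half-diameter (the ideal-Gaussian `exp(-2)` level over-extends masks
   under blur) — and a `[0.5, 2] x` nominal-volume size filter. Because
   the stitched slices are neither uniformly spaced nor at a single z per
   slice, every voxel is assigned its true focal z from the stitching
   provenance and the frame z-map.
6. **Trace extraction.** Per ROI: unweighted mean trace; background-shell
   (2-4 voxel annulus) regression and subtraction, with the regression
   coefficient clamped to [0, 1] — the shell inevitably carries part of
   the cell's own halo, and an unconstrained slope would regress the cell
   against itself; detrending by a
   running percentile over 1 s — the default percentile is the median
   because a low percentile hugs the dips of a negative-going sensor and
   subtracts signal; spike detection (running-median high-pass, MAD
   noise, k = 4, 3-sample refractory); a denoised reference built from
   the spike-triggered average waveform plus the 5-45 Hz band-passed
   component of the trace (spikes alone carry no information for
   oscillating cells); nonnegative per-pixel regression weights against
   the reference, shrunk halfway toward uniform (per-pixel regression on
   a short record is noisy and over-concentrated weights amplify shot
   noise) and normalized to sum 1; iterate detection and reweighting
   (default 3 iterations, early stop on an unchanged spike set). ROIs
   without spikes fall back to the background-subtracted mean with
   uniform weights and are flagged.
7. **Curation.** Automated proxies for a manual pass: `duplicate` when
   footprint IoU > 0.3 and trace correlation > 0.8 (lower-SNR member
   flagged), `no-activity` when spikes < 1 and 10-40 Hz band power is
   below 3x the noise. Flags never delete.

## Characterization and calibration

Bead stacks are analyzed exactly as a bench characterization would:
robust local-maxima detection with non-maximum suppression; per-bead 1D
Gaussian fits to the three axis projections (subvoxel centers, per-axis
sigmas, the x-profile amplitude as the intensity measure);
upsampled, center-aligned averaging of bead crops; FWHM
(`2.355 sigma`) and normalized intensity-vs-z curves per z-bin with bin
populations reported. The autofocus contrast metric is the normalized
variance of a band-passed image (1 px / 4 px difference of Gaussians,
variance over squared mean) — the upstream publication names its metric
only by citation, so this default is an explicit stand-in and the metric
argument is pluggable. Calibration sweeps take the contrast-argmax sheet
offset per focal plane (quadratic sub-sample refinement) and fit the
sheet-vs-focus line by least squares. The actuator phase lag is found by
scanning a correction-phase grid and maximizing summed plane contrast,
with quadratic refinement — an automated stand-in for the manual phase
adjustment used at the bench.

## Numerical choices and problem sizes

* Waveform tabulated at 4096 samples/period, linearly interpolated;
  20 warm-up periods guarantee filter steady state to double precision.
* Frame counts are truncated to whole sweep periods; frame i triggers at
  exactly `i / trigger_rate`.
* Registration refinement radius 1.5 px; shifts under 0.05 px are treated
  as zero to avoid pointless resampling.
* Degenerate inputs: constant traces raise errors in `zscore()` but yield
  a `no-bleach` flag (tau = Inf) in `fit_bleaching()`; empty segmentations
  warn and return zero ROIs; beads too close to a border error rather
  than silently truncating their fit window.
* The standard validation suite runs 20 neurons for 2.5 s on 48 x 96 px
  frames at the full 500 volumes/s, 16 frames/period geometry, and
  smaller fixtures elsewhere; these sizes keep a plain-R rendering loop
  comfortable in memory and time while leaving every geometric property
  (tilt span, stroke alternation, half-plane pairing) at its native
  scale.

## Known limitations

* The weighted extraction assumes somatic signals; dendrites/axons are
  out of scope, as is calibration of dF/F to millivolts.
* Registration is rigid translation per plane; non-rigid deformation is
  not modelled or corrected.
* The stitcher assigns halves exclusively (no blending), so a cell
  sitting exactly on a half boundary contributes through two different
  source planes — handled by the provenance-based pixel mapping, but
  visible as a seam in the mean volume if the stroke shift is
  miscompensated.
* With very few active cells per plane pair, the pooled stroke-shift
  estimator can still be biased by a few tenths of a micron by the
  tilt-weighted appearance differences; at realistic densities the bias
  is well under the 0.5 um validation tolerance.
* Axial localization is quantized by the per-stroke plane spacing
  (6.25 um by default, ~3 um effective after pooling strokes and
  halves). A soma whose true z falls between sample planes is weighted
  asymmetrically across slices, biasing its intensity-weighted z
  centroid by up to ~1.5 um — an undersampling property of the
  acquisition itself. Segmentation mitigates what it can by assigning
  every voxel its true focal z from the stitching provenance and the
  frame z-map rather than the slice center.
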