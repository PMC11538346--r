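# flipr

Simulation and analysis of **flipped-image remote-focusing (FLIPR)
volumetric voltage imaging**.

Voltage indicators report membrane potential as fast fluorescence changes,
but imaging them over a *volume* requires refocusing through the sample at
hundreds of sweeps per second. FLIPR does this with a miniature
retroreflector swept in the remote image space of the detection path: the
retroreflector both refocuses and flips the image across the field of view,
so incoming and refocused light separate geometrically instead of through a
polarizing beamsplitter — doubling light efficiency, which is decisive when
exposures are sub-millisecond. A light-sheet microscope built this way
records whole volumes of spiking and oscillating neurons (e.g. in the
larval zebrafish spinal cord) at 500 volumes/s.

This package is for microscopists and analysts working with (or evaluating)
such continuous-sweep rolling-shutter acquisitions. It provides:

* **Optical design calculators.** The remote relay magnification
  `M = (f_tube,1 / f_obj,1) x (f_obj,2 / f_tube,2)`, ideally `n1/n2` for
  aberration-free refocusing; the retroreflector NA limit
  `NA < n sin(theta/2)` (0.7 n for a 90 degree prism pair); the accessible
  field of view `aperture / M`; the light-sheet Rayleigh length
  `z_R = pi w0^2 / lambda`; trigger rates and per-plane z extents.
* **A forward simulator** of the acquisition: a filtered 500 Hz triangle
  focus sweep, rolling-shutter row timing (tilted optical planes with
  opposite tilt on the two strokes), the up/down-stroke lateral offset,
  neurons with Poisson spikes, fictive-swimming-like oscillations and
  Ornstein-Uhlenbeck subthreshold noise, photobleaching, shot and read
  noise — with complete ground truth, written as multi-page TIFF + JSON.
* **The reconstruction pipeline**: exposure-jitter detection/correction,
  rigid subpixel motion correction, stroke-shift compensation, stitching
  of tilted half-planes into a single 3D reference stack, 3D soma
  segmentation, and iterative weighted-sum trace extraction with spike
  detection, SNR, bleaching quantification, and automated curation flags.
* **Characterization tools**: bead detection and Gaussian PSF fitting,
  aligned upsampled PSF averaging, resolution/intensity-vs-z reports,
  autofocus contrast, light-sheet-to-focus calibration, and actuator
  phase-lag estimation.

## Worked example

The printed design numbers of the published instrument follow from the
optical train alone:

```r
library(flipr)
print(optics_report(optical_train()), row.names = FALSE, digits = 4)
#>                    quantity     value unit
#>               f_obj_primary   12.5000   mm
#>                f_obj_remote   10.0000   mm
#>       lateral_magnification    1.2903
#>  ideal_remote_magnification    1.3330
#>     retroreflector_na_limit    0.9426
#>                sample_fov_x  387.5000   um
#>             rayleigh_length   17.0662   um
#>                trigger_rate 8000.0000   Hz
#>              plane_z_extent    6.2500   um
#>           psf_sigma_lateral    0.1433   um
#>             psf_sigma_axial    0.8529   um
#>            psf_fwhm_lateral    0.3375   um
```

`lateral_magnification` is the near-ideal M = 1.29 (ideal 1.33 = water
over air); `sample_fov_x` is the 388 um field limited by the 0.5 mm
retroreflector; `rayleigh_length` the 17 um sheet confinement;
`retroreflector_na_limit` evaluates 0.7 n in the water immersion
(0.94 > 0.8, so the prism pair does not limit this objective).

A full round trip — simulate a small acquisition, reconstruct it, and
compare to the simulator's ground truth:

```r
sim <- simulate_acquisition(n_neurons = 6, duration = 1,
                            rows = 32, cols = 64, seed = 42)
res <- run_pipeline(sim$stream)
sprintf("stroke shift estimate: %.2f um", res$stroke_shift_um)
#> "stroke shift estimate: -6.75 um"
unlist(neuron_size_stats(res$rois)[c("mean", "sem")])
#>      mean       sem
#> 6.9425... 0.2731...
m <- match_to_truth(res, sim$truth)
sprintf("recovered %d/%d neurons, median trace correlation %.2f",
        sum(m$matched & m$trace_cor >= 0.8, na.rm = TRUE), nrow(m),
        median(m$trace_cor, na.rm = TRUE))
#> "recovered 5/6 neurons, median trace correlation 0.92"
res$traces$summary
#>   label n_pixels n_spikes       snr              flags    curation
#> 1     1       25        0        NA no-spikes-fallback no-activity
#> 2     2       21        3 12.905529                           keep
#> 3     3       28        2 13.256852                           keep
#> 4     4       20        1 16.541166                           keep
#> 5     5       39        2  5.363866                           keep
#> 6     6       18        2  3.369517                           keep
```

The estimated stroke shift recovers the simulator's 6.5 um offset (sign:
up-stroke relative to down-stroke); somata segment near their 7.7 um
nominal diameter (the mask level slightly under-reaches the true
boundary, see the vignette); five of six weighted traces correlate with
their true dF/F above 0.8 even at this deliberately small frame size.
Entry 1 is a purely oscillating cell: with no detected spikes the
extractor falls back to the background-subtracted mean trace and the
conservative automated curation flags it — flags annotate, they never
delete. At the standard validation scale (48 x 96 px, 2.5 s, 20 neurons)
recovery is 95-100%.

The methods vignette (`vignettes/flipr-methods.Rmd`) documents the
acquisition model, every default, and the known limitations.

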