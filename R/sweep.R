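#' Focus-sweep configuration
#'
#' Parameters of the triangle-wave focus sweep driving the remote-focusing
#' element and the light-sheet galvo. The drive is a symmetric triangle at
#' `volume_rate` spanning `[0, z_range]`, low-pass filtered to spare the
#' voice-coil motor; `frames_per_period` camera frames are exposed per
#' period, half on the rising (down) stroke and half on the falling (up)
#' stroke.
#'
#' @param volume_rate Sweep (volume) rate in Hz.
#' @param frames_per_period Camera frames per sweep period (even).
#' @param planes_per_sweep Frames per one-directional stroke; must equal
#'   `frames_per_period / 2`.
#' @param z_range Full axial sweep range in um.
#' @param lowpass_cutoff Cutoff (Hz) of the causal low-pass applied to the
#'   triangle drive; `Inf` for an ideal triangle. Must exceed `volume_rate`.
#' @param filter_order Order of the Butterworth low-pass (default 2).
#' @param phase_lag Phase lag (radians of one sweep period) of the focus
#'   actuator relative to the nominal drive clock.
#' @param stroke_y_shift Reproducible lateral (y) offset in um between images
#'   acquired on the down- vs the up-stroke, caused by the ellipsoidal
#'   trajectory of the moving retroreflector; >= 0.
#' @param waveform_sample_rate Internal sampling rate (Hz) used to tabulate
#'   the filtered waveform; defaults to 4096 samples per period.
#' @return An object of class `sweep_config`.
#' @examples
#' sw <- sweep_config()
#' trigger_rate(sw$volume_rate, sw$frames_per_period) # 8000 Hz
#' @export
sweep_config <- function(volume_rate = 500,
                         frames_per_period = 16,
                         planes_per_sweep = frames_per_period / 2,
                         z_range = 50,
                         lowpass_cutoff = 2000,
                         filter_order = 2,
                         phase_lag = 0,
                         stroke_y_shift = 6.5,
                         waveform_sample_rate = NULL) {
  if (frames_per_period %% 2 != 0) {
    stop("sweep_config: frames_per_period must be even")
  }
  if (planes_per_sweep != frames_per_period / 2) {
    stop("sweep_config: planes_per_sweep must equal frames_per_period / 2")
  }
  if (volume_rate <= 0 || z_range <= 0) {
    stop("sweep_config: volume_rate and z_range must be positive")
  }
  if (lowpass_cutoff <= volume_rate) {
    stop("sweep_config: lowpass_cutoff must exceed volume_rate")
  }
  if (stroke_y_shift < 0) stop("sweep_config: stroke_y_shift must be >= 0")
  if (is.null(waveform_sample_rate)) {
    waveform_sample_rate <- 4096 * volume_rate
  }
  structure(list(
    volume_rate = volume_rate,
    frames_per_period = frames_per_period,
    planes_per_sweep = planes_per_sweep,
    z_range = z_range,
    lowpass_cutoff = lowpass_cutoff,
    filter_order = filter_order,
    phase_lag = phase_lag,
    stroke_y_shift = stroke_y_shift,
    waveform_sample_rate = waveform_sample_rate
  ), class = "sweep_config")
}

#' Camera configuration
#'
#' Frame geometry and noise model of the rolling-shutter sCMOS camera run in
#' frame-overlap trigger mode (exposure follows the high state of the
#' external trigger, so every frame exposes during the same sweep phase).
#'
#' @param rows,cols Frame size in pixels; rows are the rolling-shutter /
#'   stroke-shift axis (y), columns the flip axis (x).
#' @param pixel_size_sample Pixel size referred to sample space, um.
#' @param frame_trigger_rate Frame trigger rate in Hz
#'   (`volume_rate * frames_per_period`).
#' @param exposure_fraction Fraction of the trigger period each row exposes.
#' @param readout_row_stagger Row-to-row exposure start stagger in seconds;
#'   defaults to `1 / frame_trigger_rate / rows` so the shutter rolls over
#'   the full frame within one trigger period. Set 0 for a global shutter.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param baseline Camera offset, counts.
#' @param gain Counts per detected photon.
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(rows = 48,
                          cols = 120,
                          pixel_size_sample = 1.5,
                          frame_trigger_rate = 8000,
                          exposure_fraction = 1,
                          readout_row_stagger = NULL,
                          read_noise_sd = 2,
                          baseline = 100,
                          gain = 1) {
  if (rows < 1 || cols < 1) stop("camera_config: rows, cols must be >= 1")
  if (exposure_fraction <= 0 || exposure_fraction > 1) {
    stop("camera_config: exposure_fraction must lie in (0, 1]")
  }
  if (is.null(readout_row_stagger)) {
    readout_row_stagger <- 1 / frame_trigger_rate / rows
  }
  if (readout_row_stagger * rows > 1 / frame_trigger_rate + 1e-12) {
    stop("camera_config: row stagger times rows exceeds the trigger period")
  }
  structure(list(
    rows = as.integer(rows),
    cols = as.integer(cols),
    pixel_size_sample = pixel_size_sample,
    frame_trigger_rate = frame_trigger_rate,
    exposure_fraction = exposure_fraction,
    readout_row_stagger = readout_row_stagger,
    read_noise_sd = read_noise_sd,
    baseline = baseline,
    gain = gain
  ), class = "camera_config")
}

# One steady-state period of the filtered triangle drive, tabulated at
# sweep$waveform_sample_rate. Warm-up periods are filtered and discarded so
# the returned period is the periodic steady state of the causal filter
# (DC gain 1 keeps the period mean at z_range / 2).
steady_state_period <- function(sweep) {
  fs <- sweep$waveform_sample_rate
  nps <- round(fs / sweep$volume_rate)
  warmup <- 20L
  n <- nps * (warmup + 1L)
  tt <- (seq_len(n) - 1) / fs
  phase <- (tt * sweep$volume_rate) %% 1
  tri <- sweep$z_range * ifelse(phase < 0.5, 2 * phase, 2 * (1 - phase))
  if (is.finite(sweep$lowpass_cutoff)) {
    bf <- signal::butter(sweep$filter_order,
                         sweep$lowpass_cutoff / (fs / 2), type = "low")
    tri <- as.numeric(signal::filter(bf, tri))
  }
  tri[(n - nps + 1L):n]
}

# Periodic focus-position function z(t) in um. phase_lag delays the actuator
# relative to the drive clock; `extra_phase` adds further delay (used when
# modelling a device that follows a phase-shifted copy of the drive).
make_z_function <- function(sweep, extra_phase = 0) {
  zp <- steady_state_period(sweep)
  nps <- length(zp)
  lag <- (sweep$phase_lag + extra_phase) / (2 * pi) / sweep$volume_rate
  period <- 1 / sweep$volume_rate
  function(t) {
    ph <- ((t - lag) / period) %% 1
    x <- ph * nps
    i0 <- floor(x)
    frac <- x - i0
    i1 <- (i0 %% nps) + 1L
    i2 <- ((i0 + 1) %% nps) + 1L
    zp[i1] * (1 - frac) + zp[i2] * frac
  }
}

# Stroke-direction y-offset function in um: +shift/2 on the down-stroke
# (z rising), -shift/2 on the up-stroke, based on the nominal triangle phase
# (including the actuator phase lag, since the offset is a property of the
# moving actuator).
make_y_function <- function(sweep, extra_phase = 0) {
  lag <- (sweep$phase_lag + extra_phase) / (2 * pi) / sweep$volume_rate
  period <- 1 / sweep$volume_rate
  half <- sweep$stroke_y_shift / 2
  function(t) {
    ph <- ((t - lag) / period) %% 1
    ifelse(ph < 0.5, half, -half)
  }
}

#' Sampled focus drive waveform
#'
#' Tabulates the focus position z(t): a symmetric triangle spanning
#' `[0, z_range]` at `volume_rate`, passed through a causal Butterworth
#' low-pass at `lowpass_cutoff` and delayed by `phase_lag`. The waveform is
#' returned in filter steady state, so its mean over any integer number of
#' periods equals `z_range / 2`.
#'
#' @param sweep A [sweep_config()].
#' @param duration Duration in seconds; at least one period.
#' @return A list with `t` (s), `z` (um), and `sample_rate` (Hz), of class
#'   `drive_waveform`.
#' @examples
#' w <- drive_waveform(sweep_config(), 0.004)
#' mean(w$z) # z_range / 2
#' @export
drive_waveform <- function(sweep, duration) {
  stopifnot(inherits(sweep, "sweep_config"))
  period <- 1 / sweep$volume_rate
  if (duration < period) {
    stop("drive_waveform: duration must cover at least one sweep period")
  }
  fs <- sweep$waveform_sample_rate
  n <- floor(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  zf <- make_z_function(sweep)
  structure(list(t = tt, z = zf(tt), sample_rate = fs, sweep = sweep),
            class = "drive_waveform")
}

#' Add the up/down-stroke lateral shift to a focus waveform
#'
#' The moving actuator follows an ellipsoidal rather than a purely axial
#' trajectory, displacing down-stroke images from up-stroke images by
#' `stroke_y_shift` um along the camera row (y) axis. The offset is modelled
#' as +shift/2 during the down-stroke and -shift/2 during the up-stroke, so
#' `mean(y | down) - mean(y | up)` equals the configured shift exactly.
#'
#' @param waveform A [drive_waveform()].
#' @param sweep The [sweep_config()] that produced it.
#' @return The waveform list with an added `y` component (um).
#' @export
trajectory_with_stroke_shift <- function(waveform, sweep) {
  stopifnot(inherits(waveform, "drive_waveform"),
            inherits(sweep, "sweep_config"))
  yf <- make_y_function(sweep)
  waveform$y <- yf(waveform$t)
  waveform
}

#' Continuous sweep trajectory for the renderer
#'
#' Packages the periodic steady-state focus position z(t), the light-sheet
#' position (which follows the nominal, un-lagged drive clock, optionally
#' advanced by a correction phase), and the stroke-direction y offset as
#' functions of time.
#'
#' @param sweep A [sweep_config()]. Its `phase_lag` applies to the focus
#'   actuator only; the light sheet follows the nominal clock.
#' @param sheet_phase Correction phase (radians) applied to the light-sheet
#'   drive; `sheet_phase = sweep$phase_lag` restores perfect synchrony.
#' @return A list of functions `zfun(t)`, `sheetfun(t)`, `yfun(t)` plus the
#'   config, of class `sweep_trajectory`.
#' @export
sweep_trajectory <- function(sweep, sheet_phase = 0) {
  stopifnot(inherits(sweep, "sweep_config"))
  zfun <- make_z_function(sweep)
  sheet_sweep <- sweep
  sheet_sweep$phase_lag <- 0
  sheetfun <- make_z_function(sheet_sweep, extra_phase = sheet_phase)
  yfun <- make_y_function(sweep)
  structure(list(zfun = zfun, sheetfun = sheetfun, yfun = yfun,
                 sweep = sweep, sheet_phase = sheet_phase),
            class = "sweep_trajectory")
}
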