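#' Render a synthetic acquisition
#'
#' Forward model of the continuous-sweep rolling-shutter acquisition. Frames
#' are triggered at the camera trigger rate; row `r` of a frame images the
#' focal plane at the z-position of the sweep evaluated at that row's
#' mid-exposure time (rows start staggered by `readout_row_stagger`), so the
#' focal z varies across rows within a frame by approximately one per-plane
#' z extent and the tilt direction flips between the down- and up-stroke.
#' Neurons are rendered as Gaussian blobs (detection PSF convolved with the
#' soma profile) weighted by the light-sheet axial profile centered at
#' `calibration_slope * z + calibration_intercept`, modulated by
#' `(1 + polarity * dFF(t))` and bleached as `exp(-t / bleach_tau)`.
#' Poisson shot noise, Gaussian read noise, and the camera baseline complete
#' the pixel model.
#'
#' @param scn A [scene()].
#' @param voltage Output of [generate_voltage_traces()] (its `traces` matrix
#'   must have one row per neuron and at least one column per sweep period).
#' @param trajectory A [sweep_trajectory()].
#' @param camera A [camera_config()].
#' @param optics An [optical_train()] supplying the PSF model.
#' @param duration Acquisition duration in seconds; truncated to an integer
#'   number of sweep periods.
#' @param seed RNG seed for the noise draws.
#' @param noise `"full"` (Poisson + read noise) or `"none"` (expected
#'   values, for geometric tests).
#' @return A list with `stream` (class `frame_stream`: `frames` array
#'   `[rows, cols, n_frames]`, per-frame `meta`, configs) and `truth`
#'   (class `ground_truth`: dF/F traces, per-(frame-in-period, row) focal z
#'   and y offset, scene, jitter log).
#' @export
render_frames <- function(scn, voltage, trajectory, camera, optics,
                          duration, seed = 1L, noise = c("full", "none")) {
  stopifnot(inherits(scn, "scene"), inherits(trajectory, "sweep_trajectory"),
            inherits(camera, "camera_config"),
            inherits(optics, "optical_train"))
  noise <- match.arg(noise)
  sweep <- trajectory$sweep
  fpp <- sweep$frames_per_period
  ftr <- camera$frame_trigger_rate
  if (abs(ftr - sweep$volume_rate * fpp) > 1e-6) {
    stop("render_frames: camera trigger rate must equal ",
         "volume_rate * frames_per_period")
  }
  n_periods <- floor(duration * sweep$volume_rate)
  if (n_periods < 1) stop("render_frames: duration shorter than one period")
  n_frames <- n_periods * fpp
  traces <- voltage$traces
  if (ncol(traces) < n_periods) {
    stop("render_frames: voltage traces shorter than the acquisition")
  }
  neurons <- scn$neurons
  n_neu <- nrow(neurons)
  rows <- camera$rows; cols <- camera$cols
  px <- camera$pixel_size_sample
  x_max <- cols * px; y_max <- rows * px
  out_of_vol <- neurons$x < 0 | neurons$x > x_max |
    neurons$y < 0 | neurons$y > y_max |
    neurons$z < 0 | neurons$z > sweep$z_range
  if (any(out_of_vol)) {
    warning("render_frames: ", sum(out_of_vol),
            " neuron(s) outside the imaged volume; rendered partially")
  }

  # per-(row, frame-in-period) mid-exposure times, periodic in the sweep
  exp_dur <- camera$exposure_fraction / ftr
  t_row <- (seq_len(rows) - 1) * camera$readout_row_stagger + exp_dur / 2
  t_mid <- outer(t_row, (seq_len(fpp) - 1) / ftr, "+") # [rows, fpp]
  z_rows <- matrix(trajectory$zfun(as.numeric(t_mid)), rows, fpp)
  y_rows <- matrix(trajectory$yfun(as.numeric(t_mid)), rows, fpp)
  sheet_z <- scn$calibration_slope *
    matrix(trajectory$sheetfun(as.numeric(t_mid)), rows, fpp) +
    scn$calibration_intercept

  sig <- psf_sigmas(optics$emission_wavelength, optics$na_primary,
                    optics$n_primary)
  blob <- neurons$diameter / 4 # Gaussian soma stand-in
  s_lat <- sqrt(sig[["lateral"]]^2 + blob^2)
  s_det <- sqrt(sig[["axial"]]^2 + blob^2)
  s_sheet <- sqrt((scn$lightsheet_width_1e2 / 4)^2 + blob^2)

  r_pos <- (seq_len(rows) - 0.5) * px
  c_pos <- (seq_len(cols) - 0.5) * px
  # column (x) profile per neuron, time-independent: [cols, n_neu]
  B <- vapply(seq_len(n_neu), function(i) {
    exp(-(c_pos - neurons$x[i])^2 / (2 * s_lat[i]^2))
  }, numeric(cols))
  B <- matrix(B, cols, n_neu)
  tB <- t(B)
  # row profile per neuron per frame-in-period: [rows, n_neu, fpp]
  A <- array(0, c(rows, n_neu, fpp))
  for (f in seq_len(fpp)) {
    for (i in seq_len(n_neu)) {
      gy <- exp(-(r_pos - neurons$y[i] - y_rows[, f])^2 / (2 * s_lat[i]^2))
      gz <- exp(-(neurons$z[i] - z_rows[, f])^2 / (2 * s_det[i]^2)) *
        exp(-(neurons$z[i] - sheet_z[, f])^2 / (2 * s_sheet[i]^2))
      A[, i, f] <- gy * gz
    }
  }

  set.seed(seed)
  frames <- array(0, c(rows, cols, n_frames))
  t_frame <- (seq_len(n_frames) - 1) / ftr
  bleach <- exp(-t_frame / scn$bleach_tau)
  amp <- neurons$brightness
  pol <- neurons$polarity
  npx <- rows * cols
  for (k in seq_len(n_frames)) {
    p <- ((k - 1) %/% fpp) + 1L
    f <- ((k - 1) %% fpp) + 1L
    w <- amp * (1 + pol * traces[, p])
    sig_img <- matrix(A[, , f], rows, n_neu) %*% (w * tB)
    expected <- (scn$background_level + sig_img) * bleach[k]
    expected[expected < 0] <- 0
    if (noise == "full") {
      counts <- camera$gain * stats::rpois(npx, expected) +
        camera$baseline + stats::rnorm(npx, 0, camera$read_noise_sd)
    } else {
      counts <- camera$gain * expected + camera$baseline
    }
    frames[, , k] <- counts
  }

  period_idx <- ((seq_len(n_frames) - 1) %/% fpp) + 1L
  fip <- ((seq_len(n_frames) - 1) %% fpp) + 1L
  zm <- frame_z_map(sweep, camera)
  meta <- data.frame(
    frame = seq_len(n_frames),
    time = t_frame,
    period = period_idx,
    frame_in_period = fip,
    stroke = zm$stroke[fip],
    plane = zm$plane[fip],
    stringsAsFactors = FALSE
  )
  stream <- structure(list(frames = frames, meta = meta,
                           sweep = sweep, camera = camera),
                      class = "frame_stream")
  truth <- structure(list(
    traces = traces[, seq_len(n_periods), drop = FALSE],
    spike_frames = voltage$spike_frames,
    trace_times = (seq_len(n_periods) - 1) / sweep$volume_rate,
    z_rows = z_rows, y_rows = y_rows, sheet_z = sheet_z,
    scene = scn, sweep = sweep, camera = camera,
    psf_sigma = sig, jitter_log = NULL, seed = seed
  ), class = "ground_truth")
  list(stream = stream, truth = truth)
}

#' Inject exposure-time jitter into a frame stream
#'
#' Emulates the clock-mismatch artifact of triggered rolling-shutter
#' acquisitions: at each event frame the effective exposure changes, scaling
#' all subsequent frames multiplicatively above the camera baseline until
#' the next event, and each pixel row acquires a persistent additive
#' baseline offset.
#'
#' @param stream A `frame_stream`.
#' @param n_events Number of jitter change points (>= 0).
#' @param scale_range Length-2 range the per-segment exposure scale is drawn
#'   from (used when `scales` is `NULL`).
#' @param row_baseline_sd Sd (counts) of the per-row additive offsets.
#' @param seed RNG seed.
#' @param events Optional explicit change-point frame indices (sorted,
#'   length `n_events`); drawn uniformly when `NULL`.
#' @param scales Optional explicit per-segment exposure scales for the
#'   `n_events` post-event segments.
#' @return The stream with modified frames and a `jitter_log` attribute-like
#'   element: a list with `events` (frame indices), `scales`, and
#'   `row_offsets` (`rows x n_segments` matrix; first segment is the
#'   unmodified reference).
#' @export
inject_exposure_jitter <- function(stream, n_events,
                                   scale_range = c(0.98, 1.02),
                                   row_baseline_sd = 1, seed = 1L,
                                   events = NULL, scales = NULL) {
  stopifnot(inherits(stream, "frame_stream"), n_events >= 0)
  n <- dim(stream$frames)[3]
  rows <- dim(stream$frames)[1]
  if (n_events == 0) {
    stream$jitter_log <- list(events = integer(0), scales = 1,
                              row_offsets = matrix(0, rows, 1))
    return(stream)
  }
  set.seed(seed)
  if (is.null(events)) events <- sort(sample(2:(n - 1), n_events))
  stopifnot(length(events) == n_events, !is.unsorted(events))
  n_seg <- n_events + 1L
  scales <- if (is.null(scales)) {
    c(1, stats::runif(n_events, scale_range[1], scale_range[2]))
  } else {
    stopifnot(length(scales) == n_events)
    c(1, scales)
  }
  offsets <- cbind(0, matrix(stats::rnorm(rows * n_events, 0, row_baseline_sd),
                             rows, n_events))
  base <- stream$camera$baseline
  bounds <- c(1L, events, n + 1L)
  for (s in 2:n_seg) {
    idx <- bounds[s]:(bounds[s + 1] - 1L)
    seg <- stream$frames[, , idx, drop = FALSE]
    seg <- base + scales[s] * (seg - base)
    seg <- seg + array(offsets[, s], dim(seg)) # recycles down rows
    stream$frames[, , idx] <- seg
  }
  stream$jitter_log <- list(events = events, scales = scales,
                            row_offsets = offsets)
  stream
}
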