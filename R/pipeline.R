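#' Simulate a complete volumetric voltage-imaging acquisition
#'
#' Convenience wrapper wiring the generator modules together with the
#' standard acquisition geometry: a triangle sweep at 500 volumes/s with
#' 16 frames per period (8 planes per stroke) over 50 um, neurons of
#' 7.7 um nominal diameter with Poisson spikes and fictive-swimming-like
#' oscillations, bleaching with tau = 72 s, and the rolling-shutter
#' camera model. Frame size and duration are free so callers can scale
#' the problem.
#'
#' @param n_neurons Number of neurons.
#' @param duration Acquisition duration, s.
#' @param rows,cols Frame size in pixels.
#' @param pixel_size_sample Pixel size, um.
#' @param sweep,camera Optional pre-built configs (defaults built from
#'   the other arguments).
#' @param voltage Optional [voltage_params()].
#' @param scene_args List of overrides for [scene()] fields.
#' @param neuron_args List of overrides for [random_neurons()].
#' @param optics An [optical_train()].
#' @param noise Passed to [render_frames()].
#' @param seed Master seed; independent sub-seeds are derived for neuron
#'   placement, voltage dynamics, and the pixel-noise draws.
#' @return As [render_frames()]: list with `stream` and `truth`.
#' @export
simulate_acquisition <- function(n_neurons = 20, duration = 4,
                                 rows = 48, cols = 120,
                                 pixel_size_sample = 1.5,
                                 sweep = NULL, camera = NULL,
                                 voltage = NULL,
                                 scene_args = list(),
                                 neuron_args = list(),
                                 optics = optical_train(),
                                 noise = "full", seed = 1L) {
  if (is.null(sweep)) sweep <- sweep_config()
  if (is.null(camera)) {
    camera <- camera_config(rows = rows, cols = cols,
                            pixel_size_sample = pixel_size_sample,
                            frame_trigger_rate = sweep$volume_rate *
                              sweep$frames_per_period)
  }
  seed <- as.integer(seed)
  x_max <- camera$cols * camera$pixel_size_sample
  y_max <- camera$rows * camera$pixel_size_sample
  margin <- 6
  na <- utils::modifyList(list(
    n = n_neurons,
    x_range = c(margin, x_max - margin),
    y_range = c(margin, y_max - margin),
    z_range = c(8, sweep$z_range - 8),
    seed = seed + 1000L
  ), neuron_args)
  neurons <- do.call(random_neurons, na)
  scn <- do.call(scene, utils::modifyList(list(neurons = neurons),
                                          scene_args))
  if (is.null(voltage)) voltage <- voltage_params(seed = seed + 2000L)
  n_periods <- ceiling(duration * sweep$volume_rate)
  vt <- generate_voltage_traces(voltage, n_neurons, n_periods,
                                sweep$volume_rate)
  traj <- sweep_trajectory(sweep)
  render_frames(scn, vt, traj, camera, optics, duration,
                seed = seed + 3000L, noise = noise)
}

#' Run the full reconstruction pipeline on a frame stream
#'
#' Applies, in order: exposure-jitter detection and correction; splitting
#' into down/up-stroke plane series; per-plane rigid motion correction;
#' stroke-shift estimation and compensation (symmetric: each stroke is
#' moved half the shift toward the common frame, subpixel for the
#' time-mean images used for stitching, whole-row for the raw series so
#' ROI coordinates transfer without resampling); stitching of tilted
#' half-planes into a 3D reference stack; 3D segmentation; and iterative
#' weighted trace extraction with automated curation.
#'
#' @param stream A `frame_stream`.
#' @param scale Expected soma diameter, um.
#' @param jitter_correction,motion_correction Logical switches.
#' @param segment_args,extract_args,curate_args Lists of extra arguments
#'   for [segment_3d()], [extract_traces()], [curate()].
#' @return A list with `traces` (`trace_set`), `rois` (`roi_set`),
#'   `volume` (`volume_stack`), `series` (`plane_series`),
#'   `stroke_shift_um`, `jitter_events`, `shifts` (per-plane shift
#'   tables).
#' @export
run_pipeline <- function(stream, scale = 7.7,
                         jitter_correction = TRUE,
                         motion_correction = TRUE,
                         segment_args = list(),
                         extract_args = list(),
                         curate_args = list()) {
  stopifnot(inherits(stream, "frame_stream"))
  events <- NULL
  if (jitter_correction) {
    events <- detect_jitter_changepoints(stream)
    stream <- correct_jitter(stream, events)
  }
  zmap <- frame_z_map(stream$sweep, stream$camera)
  series <- split_frames_by_stroke(stream, zmap)
  shifts <- list()
  if (motion_correction) {
    base <- stream$camera$baseline
    for (s in c("down", "up")) {
      arr <- series[[s]]
      planes <- dim(arr)[3]
      shifts[[s]] <- vector("list", planes)
      for (p in seq_len(planes)) {
        st <- estimate_shifts(arr[, , p, ], upsample = 10)
        shifts[[s]][[p]] <- st
        if (any(abs(st$dy) > 0.05 | abs(st$dx) > 0.05)) {
          arr[, , p, ] <- apply_shifts(arr[, , p, ], st, fill = base)$stack
        }
      }
      series[[s]] <- arr
    }
  }
  mp <- mean_planes(series)
  px <- stream$camera$pixel_size_sample
  dy_um <- estimate_stroke_shift(mp$down, mp$up, series$z_down, series$z_up,
                                 px)
  base <- stream$camera$baseline
  # symmetric compensation keeps absolute y geometry unbiased
  mp_up <- compensate_stroke_shift(mp$up, dy_um / 2, px, fill = base)
  mp_down <- compensate_stroke_shift(mp$down, -dy_um / 2, px, fill = base)
  up_c <- compensate_stroke_shift(series$up, dy_um / 2, px, fill = base,
                                  integer_shift = TRUE)
  down_c <- compensate_stroke_shift(series$down, -dy_um / 2, px, fill = base,
                                    integer_shift = TRUE)
  series$up <- up_c$images
  series$down <- down_c$images
  series$row_shift <- c(down = down_c$shift_rows, up = up_c$shift_rows)
  volume <- stitch_half_planes(mp_down$images, mp_up$images, zmap)
  rois <- do.call(segment_3d, c(list(volume = volume, scale = scale),
                                segment_args))
  if (nrow(rois$table) == 0) {
    return(list(traces = NULL, rois = rois, volume = volume,
                series = series, stroke_shift_um = dy_um,
                jitter_events = events, shifts = shifts))
  }
  traces <- do.call(extract_traces,
                    c(list(series = series, rois = rois, volume = volume),
                      extract_args))
  traces <- do.call(curate, c(list(traces = traces), curate_args))
  list(traces = traces, rois = rois, volume = volume, series = series,
       stroke_shift_um = dy_um, jitter_events = events, shifts = shifts)
}

#' Match recovered ROIs and traces to simulation ground truth
#'
#' Greedily pairs each true neuron with the nearest recovered ROI
#' centroid within `max_dist` um and computes the Pearson correlation of
#' the extracted (polarity-corrected) weighted trace with the true dF/F
#' trace.
#'
#' @param result A [run_pipeline()] result.
#' @param truth The simulator `ground_truth`.
#' @param max_dist Maximum centroid distance for a match, um.
#' @return Data.frame with one row per true neuron: `matched`, `roi`,
#'   `dist`, `trace_cor`.
#' @export
match_to_truth <- function(result, truth, max_dist = 6) {
  neurons <- truth$scene$neurons
  tab <- result$rois$table
  n <- nrow(neurons)
  out <- data.frame(neuron = seq_len(n), matched = FALSE, roi = NA_integer_,
                    dist = NA_real_, trace_cor = NA_real_)
  if (is.null(result$traces) || nrow(tab) == 0) return(out)
  taken <- logical(nrow(tab))
  pol <- neurons$polarity
  for (i in seq_len(n)) {
    d <- sqrt((tab$x - neurons$x[i])^2 + (tab$y - neurons$y[i])^2 +
                (tab$z - neurons$z[i])^2)
    d[taken] <- Inf
    j <- which.min(d)
    if (!length(j) || d[j] > max_dist) next
    taken[j] <- TRUE
    entry <- result$traces$entries[[which(result$traces$summary$label ==
                                            tab$label[j])]]
    tt <- truth$traces[i, ]
    cc <- suppressWarnings(stats::cor(pol[i] * entry$detrended, tt))
    out$matched[i] <- TRUE
    out$roi[i] <- tab$label[j]
    out$dist[i] <- d[j]
    out$trace_cor[i] <- cc
  }
  out
}
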