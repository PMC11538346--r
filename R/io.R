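#' Write an acquisition to disk
#'
#' Writes the frame stream as a 16-bit multi-page TIFF in trigger order, a
#' JSON sidecar with the sweep/camera configuration and per-frame metadata
#' (period, frame-in-period, stroke, plane), and, when given, the ground
#' truth as JSON (traces, scene, focal-z map, jitter log). Counts are
#' rounded and clamped to the 16-bit range. Re-running with the same
#' simulated stream produces byte-identical files.
#'
#' @param stream A `frame_stream`.
#' @param path Output directory (created if missing).
#' @param truth Optional `ground_truth`.
#' @return `path`, invisibly. Files: `frames.tif`, `meta.json`, and
#'   `truth.json` when truth is given.
#' @export
write_acquisition <- function(stream, path, truth = NULL) {
  stopifnot(inherits(stream, "frame_stream"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("write_acquisition: cannot create directory: ", path)
  n <- dim(stream$frames)[3]
  pages <- lapply(seq_len(n), function(i) {
    pmin(pmax(round(stream$frames[, , i]), 0), 65535) / 65535
  })
  tif <- file.path(path, "frames.tif")
  res <- tryCatch(
    tiff::writeTIFF(pages, tif, bits.per.sample = 16, compression = "none"),
    error = function(e) stop("write_acquisition: TIFF write failed for ",
                             tif, ": ", conditionMessage(e)))
  meta <- list(
    sweep = unclass(stream$sweep),
    camera = unclass(stream$camera),
    frames = stream$meta,
    jitter_log = stream$jitter_log
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) {
    tr <- list(
      traces = truth$traces,
      spike_frames = truth$spike_frames,
      trace_times = truth$trace_times,
      z_rows = truth$z_rows,
      y_rows = truth$y_rows,
      neurons = truth$scene$neurons,
      background_level = truth$scene$background_level,
      bleach_tau = truth$scene$bleach_tau,
      lightsheet_width_1e2 = truth$scene$lightsheet_width_1e2,
      calibration_slope = truth$scene$calibration_slope,
      calibration_intercept = truth$scene$calibration_intercept,
      psf_sigma = truth$psf_sigma,
      seed = truth$seed
    )
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an acquisition from disk
#'
#' Reads `frames.tif` + `meta.json` (and `truth.json` if present) written
#' by [write_acquisition()], or any externally produced pair following the
#' same schema, and reconstructs the `frame_stream`.
#'
#' @param path Directory containing the acquisition.
#' @return A list with `stream` (class `frame_stream`) and `truth` (list
#'   or `NULL`).
#' @export
read_acquisition <- function(path) {
  tif <- file.path(path, "frames.tif")
  mj <- file.path(path, "meta.json")
  if (!file.exists(tif) || !file.exists(mj)) {
    stop("read_acquisition: missing frames.tif or meta.json in ", path)
  }
  pages <- tiff::readTIFF(tif, all = TRUE)
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  n <- length(pages)
  if (n != nrow(meta$frames)) {
    stop("read_acquisition: sidecar frame count (", nrow(meta$frames),
         ") does not match TIFF page count (", n, ")")
  }
  rows <- nrow(pages[[1]]); cols <- ncol(pages[[1]])
  frames <- array(0, c(rows, cols, n))
  for (i in seq_len(n)) frames[, , i] <- round(pages[[i]] * 65535)
  sw <- meta$sweep
  sweep <- sweep_config(volume_rate = sw$volume_rate,
                        frames_per_period = sw$frames_per_period,
                        z_range = sw$z_range,
                        lowpass_cutoff = sw$lowpass_cutoff,
                        filter_order = sw$filter_order,
                        phase_lag = sw$phase_lag,
                        stroke_y_shift = sw$stroke_y_shift,
                        waveform_sample_rate = sw$waveform_sample_rate)
  cm <- meta$camera
  camera <- camera_config(rows = cm$rows, cols = cm$cols,
                          pixel_size_sample = cm$pixel_size_sample,
                          frame_trigger_rate = cm$frame_trigger_rate,
                          exposure_fraction = cm$exposure_fraction,
                          readout_row_stagger = cm$readout_row_stagger,
                          read_noise_sd = cm$read_noise_sd,
                          baseline = cm$baseline, gain = cm$gain)
  stream <- structure(list(frames = frames, meta = meta$frames,
                           sweep = sweep, camera = camera,
                           jitter_log = meta$jitter_log),
                      class = "frame_stream")
  truth <- NULL
  tj <- file.path(path, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  list(stream = stream, truth = truth)
}

#' Write a volume stack as TIFF + JSON
#'
#' @param volume A `volume_stack`.
#' @param path Output directory.
#' @return `path`, invisibly. Files: `volume.tif` (32-bit float pages) and
#'   `volume.json` (slice z centers and stitching provenance).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_stack"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("write_volume: cannot create directory: ", path)
  mx <- max(volume$data)
  pages <- lapply(seq_len(dim(volume$data)[3]), function(i) {
    volume$data[, , i] / max(mx, 1)
  })
  tiff::writeTIFF(pages, file.path(path, "volume.tif"),
                  bits.per.sample = 32, compression = "none")
  jsonlite::write_json(
    list(slice_z = volume$slice_z, provenance = volume$provenance,
         pixel_size = volume$pixel_size, scale_max = mx),
    file.path(path, "volume.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Write extracted traces as CSV + JSON
#'
#' @param traces A `trace_set`.
#' @param path Output directory.
#' @return `path`, invisibly. Files: `traces.csv` (one column per ROI,
#'   weighted traces), `zscored.csv`, and `traces.json` (spikes, SNR,
#'   flags, weights summary).
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("write_traces: cannot create directory: ", path)
  w <- vapply(traces$entries, function(e) e$weighted,
              numeric(length(traces$entries[[1]]$weighted)))
  colnames(w) <- paste0("roi_", traces$summary$label)
  utils::write.csv(w, file.path(path, "traces.csv"), row.names = FALSE)
  z <- vapply(traces$entries, function(e) e$zscored,
              numeric(length(traces$entries[[1]]$zscored)))
  colnames(z) <- colnames(w)
  utils::write.csv(z, file.path(path, "zscored.csv"), row.names = FALSE)
  js <- list(
    plane_rate = traces$plane_rate,
    summary = traces$summary,
    spikes = lapply(traces$entries, function(e) e$spikes)
  )
  jsonlite::write_json(js, file.path(path, "traces.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
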