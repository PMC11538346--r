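#' Map frames and rows to focal z
#'
#' Evaluates the steady-state sweep waveform at every row's mid-exposure
#' time for one sweep period, giving the focal z of each (frame-in-period,
#' row) pair, the stroke label of each frame (down = rising z, the first
#' half of the period; up = falling z), the nominal plane index within each
#' stroke (1 = lowest z), and the mean z of the top and bottom row-halves of
#' each frame (used by the stitcher).
#'
#' @param sweep A [sweep_config()].
#' @param camera A [camera_config()].
#' @return An object of class `z_map`: list with `z` (`rows x
#'   frames_per_period` matrix, um), `stroke` (character), `plane`
#'   (integer), `z_frame_mean`, `z_half` (`frames_per_period x 2`,
#'   top/bottom), `t_mid`, and the configs.
#' @export
frame_z_map <- function(sweep, camera) {
  stopifnot(inherits(sweep, "sweep_config"), inherits(camera, "camera_config"))
  fpp <- sweep$frames_per_period
  ftr <- camera$frame_trigger_rate
  rows <- camera$rows
  exp_dur <- camera$exposure_fraction / ftr
  t_row <- (seq_len(rows) - 1) * camera$readout_row_stagger + exp_dur / 2
  t_mid <- outer(t_row, (seq_len(fpp) - 1) / ftr, "+")
  traj <- sweep_trajectory(sweep)
  z <- matrix(traj$zfun(as.numeric(t_mid)), rows, fpp)
  # nominal stroke: frames triggered in the first half-period ride the
  # rising (down) stroke
  stroke <- ifelse(seq_len(fpp) <= fpp / 2, "down", "up")
  z_frame_mean <- colMeans(z)
  plane <- integer(fpp)
  for (s in c("down", "up")) {
    idx <- which(stroke == s)
    plane[idx] <- rank(z_frame_mean[idx], ties.method = "first")
  }
  half <- rows %/% 2
  z_half <- cbind(top = colMeans(z[seq_len(half), , drop = FALSE]),
                  bottom = colMeans(z[(half + 1):rows, , drop = FALSE]))
  structure(list(z = z, stroke = stroke, plane = as.integer(plane),
                 z_frame_mean = z_frame_mean, z_half = z_half,
                 t_mid = t_mid, sweep = sweep, camera = camera),
            class = "z_map")
}

#' Split a frame stream into down- and up-stroke plane series
#'
#' Reorders the interleaved frame stream into two plane-indexed time
#' series (one sample per sweep period each), ordered by nominal plane
#' index (ascending z). Counts are conserved: the two outputs together are
#' a permutation of the input frames.
#'
#' @param stream A `frame_stream`.
#' @param zmap A [frame_z_map()] for the same configs.
#' @return An object of class `plane_series`: arrays `down` and `up` of
#'   dimension `[rows, cols, planes, n_periods]`, plane mean z vectors
#'   `z_down`, `z_up`, the `zmap`, and bookkeeping of any integer row
#'   shift applied by [compensate_stroke_shift()].
#' @export
split_frames_by_stroke <- function(stream, zmap) {
  stopifnot(inherits(stream, "frame_stream"), inherits(zmap, "z_map"))
  meta <- stream$meta
  fpp <- zmap$sweep$frames_per_period
  planes <- zmap$sweep$planes_per_sweep
  n_periods <- nrow(meta) / fpp
  if (n_periods != floor(n_periods)) {
    stop("split_frames_by_stroke: stream length is not a whole number of periods")
  }
  rows <- dim(stream$frames)[1]; cols <- dim(stream$frames)[2]
  out <- list()
  zmean <- list()
  for (s in c("down", "up")) {
    arr <- array(0, c(rows, cols, planes, n_periods))
    zv <- numeric(planes)
    for (p in seq_len(planes)) {
      f <- which(zmap$stroke == s & zmap$plane == p)
      idx <- which(meta$frame_in_period == f)
      arr[, , p, ] <- stream$frames[, , idx]
      zv[p] <- zmap$z_frame_mean[f]
    }
    out[[s]] <- arr
    zmean[[s]] <- zv
  }
  structure(list(down = out$down, up = out$up,
                 z_down = zmean$down, z_up = zmean$up,
                 zmap = zmap, camera = stream$camera, sweep = stream$sweep,
                 row_shift = c(down = 0L, up = 0L)),
            class = "plane_series")
}

#' Time-mean plane images of a plane series
#'
#' @param series A `plane_series`.
#' @return List with `down` and `up` arrays `[rows, cols, planes]`.
#' @export
mean_planes <- function(series) {
  stopifnot(inherits(series, "plane_series"))
  list(down = apply(series$down, c(1, 2, 3), mean),
       up = apply(series$up, c(1, 2, 3), mean))
}

#' Estimate the up/down-stroke lateral shift
#'
#' Cross-correlates z-matched pairs of time-mean down- and up-stroke plane
#' images and returns the median rigid row (y) displacement of the
#' up-stroke images relative to the down-stroke images, in um. The estimate
#' is antisymmetric under swapping the arguments.
#'
#' @param mean_down,mean_up Arrays `[rows, cols, planes]` of time-mean
#'   plane images.
#' @param z_down,z_up Mean plane z vectors (um) used for pairing.
#' @param pixel_size_sample Pixel size, um.
#' @param upsample Subpixel refinement factor for the correlation peak.
#' @return Signed shift Delta-y in um (up relative to down).
#' @export
estimate_stroke_shift <- function(mean_down, mean_up, z_down, z_up,
                                  pixel_size_sample, upsample = 20) {
  planes <- dim(mean_down)[3]
  if (planes < 1) stop("estimate_stroke_shift: need at least one plane pair")
  # The opposite plane tilt weights each cell differently in the two
  # strokes, so a single pair can lock onto a spurious cross-cell match.
  # The cross-power spectra of all z-matched pairs are therefore pooled:
  # the common rigid shift adds coherently across pairs, spurious matches
  # do not. One joint peak is then refined to subpixel precision.
  cps <- NULL
  for (p in seq_len(planes)) {
    q <- which.min(abs(z_up - z_down[p]))
    a <- mean_up[, , q]; b <- mean_down[, , p]
    cp <- stats::fft(a - mean(a)) * Conj(stats::fft(b - mean(b)))
    cps <- if (is.null(cps)) cp else cps + cp
  }
  cc <- Re(stats::fft(cps, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  nr <- nrow(cc); nc <- ncol(cc)
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (upsample > 1) {
    res <- upsampled_xcorr_peak(cps / length(cps), dy, dx, upsample)
    dy <- res[1]
  }
  dy * pixel_size_sample
}

#' Compensate the up-stroke lateral shift
#'
#' Translates up-stroke images by minus the estimated shift along rows so
#' both strokes share one lateral frame of reference.
#'
#' @param images Array `[rows, cols, ...]` (mean planes or a full series).
#' @param dy_um Signed shift in um (as returned by
#'   [estimate_stroke_shift()]).
#' @param pixel_size_sample Pixel size, um.
#' @param fill Fill value for rows rolled in at the border.
#' @param integer_shift If `TRUE`, round the shift to whole rows and roll
#'   without interpolation (used for full time series, where subpixel
#'   resampling of every frame is unnecessary); otherwise translate with
#'   subpixel interpolation.
#' @return List with `images` (translated array), `mask` (logical rows x
#'   cols, `TRUE` where values are filled), and `shift_rows` (applied row
#'   shift in pixels).
#' @export
compensate_stroke_shift <- function(images, dy_um, pixel_size_sample,
                                    fill = 0, integer_shift = FALSE) {
  dy_px <- -dy_um / pixel_size_sample
  d <- dim(images)
  rows <- d[1]
  if (integer_shift) dy_px <- round(dy_px)
  flat <- array(images, c(d[1], d[2], prod(d[-(1:2)])))
  out <- array(0, dim(flat))
  for (k in seq_len(dim(flat)[3])) {
    out[, , k] <- translate_image(flat[, , k], dy_px, 0, fill = fill)
  }
  mask <- matrix(FALSE, rows, d[2])
  n_edge <- ceiling(abs(dy_px))
  if (n_edge > 0 && n_edge < rows) {
    if (dy_px > 0) mask[seq_len(n_edge), ] <- TRUE
    else mask[(rows - n_edge + 1):rows, ] <- TRUE
  }
  list(images = array(out, d), mask = mask, shift_rows = dy_px)
}

#' Stitch tilted half-planes into a single 3D stack
#'
#' Because the rolling shutter tilts each optical plane (in opposite
#' directions on the two strokes), the top row-half and the bottom row-half
#' of a frame sit at different z. Each time-mean plane image is split at
#' the middle row; every half carries its own mean z from the
#' [frame_z_map()]. Top halves and bottom halves are then paired by z rank
#' (equivalently, each half is paired with the half of another plane most
#' closely matching its z; exact ties resolve toward the same stroke via
#' stable ordering) and composed into one stack ordered by z.
#'
#' @param mean_down,mean_up Arrays `[rows, cols, planes]` of time-mean
#'   plane images, up-stroke images already stroke-shift compensated.
#' @param zmap The [frame_z_map()].
#' @return An object of class `volume_stack`: `data` array
#'   `[rows, cols, 2 * planes]`, `slice_z` (um), `provenance` data.frame
#'   (per slice: stroke and plane of the top and bottom half and their z),
#'   and pixel/voxel geometry.
#' @export
stitch_half_planes <- function(mean_down, mean_up, zmap) {
  stopifnot(inherits(zmap, "z_map"))
  rows <- dim(mean_down)[1]; cols <- dim(mean_down)[2]
  planes <- dim(mean_down)[3]
  half <- rows %/% 2
  if (rows %% 2 != 0) stop("stitch_half_planes: need an even number of rows")
  get_img <- function(stroke, p) {
    if (stroke == "down") mean_down[, , p] else mean_up[, , p]
  }
  halves <- data.frame(
    stroke = rep(rep(c("down", "up"), each = planes), times = 2),
    plane = rep(seq_len(planes), times = 4),
    half = rep(c("top", "bottom"), each = 2 * planes),
    stringsAsFactors = FALSE
  )
  halves$z <- mapply(function(s, p, h) {
    f <- which(zmap$stroke == s & zmap$plane == p)
    zmap$z_half[f, h]
  }, halves$stroke, halves$plane, halves$half)
  tops <- halves[halves$half == "top", ]
  bots <- halves[halves$half == "bottom", ]
  tops <- tops[order(tops$z), ]
  bots <- bots[order(bots$z), ]
  n_slices <- nrow(tops)
  data <- array(0, c(rows, cols, n_slices))
  prov <- data.frame(slice = seq_len(n_slices), z = NA_real_,
                     top_stroke = tops$stroke, top_plane = tops$plane,
                     top_z = tops$z,
                     bottom_stroke = bots$stroke, bottom_plane = bots$plane,
                     bottom_z = bots$z, stringsAsFactors = FALSE)
  for (i in seq_len(n_slices)) {
    data[seq_len(half), , i] <- get_img(tops$stroke[i], tops$plane[i])[seq_len(half), ]
    data[(half + 1):rows, , i] <- get_img(bots$stroke[i], bots$plane[i])[(half + 1):rows, ]
    prov$z[i] <- (tops$z[i] + bots$z[i]) / 2
  }
  ord <- order(prov$z)
  prov <- prov[ord, ]
  prov$slice <- seq_len(n_slices)
  rownames(prov) <- NULL
  structure(list(data = data[, , ord, drop = FALSE],
                 slice_z = prov$z,
                 provenance = prov,
                 pixel_size = zmap$camera$pixel_size_sample,
                 zmap = zmap),
            class = "volume_stack")
}

#' Map 3D ROI voxels back to raw plane-series pixels
#'
#' Inverts the stitching geometry: every voxel of a label defined on the
#' stitched stack belongs to one half-plane, whose provenance names the
#' stroke and plane of the raw time series it came from. This lets 3D ROIs
#' index the raw per-plane movies for trace extraction. Requires the raw
#' series to carry the same stroke-shift compensation as the stitched
#' means (see [compensate_stroke_shift()] with `integer_shift = TRUE`).
#'
#' @param voxels Integer matrix with columns `row`, `col`, `slice` (voxel
#'   coordinates in the stitched stack), e.g. from [roi_voxels()].
#' @param volume The `volume_stack` the labels were drawn on.
#' @return A data.frame with columns `stroke`, `plane`, `row`, `col` (one
#'   raw-pixel coordinate per voxel).
#' @export
map_roi_to_frames <- function(voxels, volume) {
  stopifnot(inherits(volume, "volume_stack"))
  rows <- dim(volume$data)[1]
  half <- rows %/% 2
  prov <- volume$provenance
  is_top <- voxels[, "row"] <= half
  s_idx <- voxels[, "slice"]
  data.frame(
    stroke = ifelse(is_top, prov$top_stroke[s_idx], prov$bottom_stroke[s_idx]),
    plane = ifelse(is_top, prov$top_plane[s_idx], prov$bottom_plane[s_idx]),
    row = voxels[, "row"],
    col = voxels[, "col"],
    stringsAsFactors = FALSE
  )
}
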