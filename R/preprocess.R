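# --- shared image primitives -------------------------------------------------

# Catmull-Rom cubic convolution kernel (a = -0.5)
cubic_kernel <- function(x) {
  a <- -0.5
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# n_out x n_in interpolation matrix evaluating a cubic interpolant of a
# length-n_in sequence at positions `at` (1-based, may be fractional).
# Out-of-range positions return `NA` rows (caller decides the fill).
interp_matrix <- function(n_in, at) {
  W <- matrix(0, length(at), n_in)
  oob <- at < 1 | at > n_in
  base <- floor(at)
  for (k in -1:2) {
    idx <- base + k
    w <- cubic_kernel(at - idx)
    idx_c <- pmin(pmax(idx, 1L), n_in) # clamp edge taps
    W[cbind(seq_along(at), idx_c)] <- W[cbind(seq_along(at), idx_c)] + w
  }
  W[oob, ] <- NA_real_
  W
}

#' Translate an image by a (possibly subpixel) rigid shift
#'
#' Shifts image content by `(dy, dx)` pixels (positive = toward larger
#' row/column indices) using separable cubic (Catmull-Rom) interpolation.
#' Pixels whose source coordinate falls outside the input are set to
#' `fill`.
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in pixels along rows / columns.
#' @param fill Fill value for rolled-in borders.
#' @return The translated matrix.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  if (dy == 0 && dx == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) { # fast integer roll
    out <- matrix(fill, nr, nc)
    sr <- seq_len(nr) - dy
    sc <- seq_len(nc) - dx
    okr <- sr >= 1 & sr <= nr
    okc <- sc >= 1 & sc <= nc
    out[okr, okc] <- img[sr[okr], sc[okc]]
    return(out)
  }
  Wr <- interp_matrix(nr, seq_len(nr) - dy)
  Wc <- interp_matrix(nc, seq_len(nc) - dx)
  badr <- is.na(Wr[, 1])
  badc <- is.na(Wc[, 1])
  Wr[badr, ] <- 0
  Wc[badc, ] <- 0
  out <- Wr %*% img %*% t(Wc)
  out[badr, ] <- fill
  out[, badc] <- fill
  out
}

# Upsampled cross-correlation in a small neighborhood of (dy0, dx0), via
# a matrix-multiply DFT of the cross-power spectrum (Guizar-Sicairos
# single-step upsampling).
upsampled_xcorr_peak <- function(cps, dy0, dx0, upsample, radius = 1.5) {
  nr <- nrow(cps); nc <- ncol(cps)
  nsteps <- ceiling(radius * upsample)
  offs <- seq(-nsteps, nsteps) / upsample
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  Er <- exp(2i * pi * outer(dy0 + offs, fr))       # [n_off, nr]
  Ec <- exp(2i * pi * outer(fc, dx0 + offs))       # [nc, n_off]
  cc <- Re(Er %*% cps %*% Ec)
  pk <- arrayInd(which.max(cc), dim(cc))
  c(dy0 + offs[pk[1]], dx0 + offs[pk[2]])
}

# Rigid displacement of `img` relative to `ref` by FFT cross-correlation
# with optional subpixel refinement. Returns c(dy, dx): translating `img`
# by -(dy, dx) aligns it to `ref`.
phase_corr_shift <- function(img, ref, upsample = 1) {
  nr <- nrow(img); nc <- ncol(img)
  F1 <- stats::fft(img - mean(img))
  F2 <- stats::fft(ref - mean(ref))
  cps <- F1 * Conj(F2)
  cc <- Re(stats::fft(cps, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (upsample > 1) {
    res <- upsampled_xcorr_peak(cps / length(cps), dy, dx, upsample)
    dy <- res[1]; dx <- res[2]
  }
  c(dy = dy, dx = dx)
}

# --- exposure-jitter correction ----------------------------------------------

#' Detect exposure-jitter change points
#'
#' Clock mismatch between the frame trigger and the camera steps the
#' effective exposure time at unpredictable frames, changing full-frame
#' counts multiplicatively (above the camera baseline) and per-row
#' baselines additively. The detector works on the per-frame pixel
#' *median*, which tracks the global exposure scale but is immune to
#' localized changes such as neural activity (a bursting cell can move the
#' frame *mean* by more than a jitter step). Medians also vary with sweep
#' position, so each frame is first normalized by the median of frames
#' sharing its frame-in-period (plane) index; the normalized series is
#' then scanned with a split window: a change point is a frame where the
#' right-half median departs from the left-half median by more than the
#' detection threshold — `min_step`, raised to `noise_k` robust sds of the
#' step statistic when the statistic itself is noisy. Candidates closer
#' than `merge_within` frames are merged to the strongest (never silently
#' dropped), and each event is finally localized with a short
#' mean-difference statistic (the wide median statistic is flat within
#' half a window of a step).
#'
#' @param stream A `frame_stream`.
#' @param min_step Minimum relative step to call an event (default 0.5%).
#' @param window Half-width (frames) of the split window; defaults to two
#'   sweep periods so every plane is represented on both sides.
#' @param merge_within Merge radius in frames.
#' @param noise_k Adaptive-threshold multiplier on the robust sd of the
#'   step statistic.
#' @return An object of class `jitter_events`: `events` (frame indices of
#'   segment starts), `scales` (per-segment exposure scale relative to the
#'   first segment), `row_offsets` (`rows x n_segments` additive counts).
#' @export
detect_jitter_changepoints <- function(stream, min_step = 0.005,
                                       window = NULL, merge_within = 2L,
                                       noise_k = 6) {
  stopifnot(inherits(stream, "frame_stream"))
  n <- dim(stream$frames)[3]
  if (n < 2) stop("detect_jitter_changepoints: need at least 2 frames")
  fpp <- stream$sweep$frames_per_period
  if (is.null(window)) window <- 2L * fpp
  base <- stream$camera$baseline
  m <- vapply(seq_len(n), function(i) stats::median(stream$frames[, , i]),
              numeric(1)) - base
  fip <- stream$meta$frame_in_period
  ref_level <- tapply(m, fip, stats::median)
  norm <- m / ref_level[fip]
  norm[!is.finite(norm)] <- 1

  # split-window step statistic
  stat <- rep(0, n)
  for (i in seq(window + 1L, n - window + 1L)) {
    L <- stats::median(norm[(i - window):(i - 1L)])
    R <- stats::median(norm[i:(i + window - 1L)])
    stat[i] <- (R - L) / L
  }
  inner <- stat[stat != 0]
  thr <- min_step
  if (length(inner) > 10) {
    thr <- max(min_step, noise_k * stats::mad(inner, center = 0))
  }
  cand <- which(abs(stat) > thr)
  events <- integer(0)
  if (length(cand)) {
    # group candidates separated by <= max(merge_within, window) frames and
    # keep the strongest per group; a wide step makes the whole window
    # region exceed threshold, so grouping must span the window
    gap <- max(merge_within, window)
    grp <- cumsum(c(1L, diff(cand) > gap))
    events <- vapply(split(cand, grp), function(ix) {
      ix[which.max(abs(stat[ix]))]
    }, integer(1))
    # the median statistic is flat within half a window around a step;
    # localize each event with a short mean-difference statistic, which
    # peaks exactly at the change point
    m <- max(4L, fpp %/% 2)
    events <- vapply(events, function(g) {
      lo <- max(m + 1L, g - window)
      hi <- min(n - m + 1L, g + window)
      ds <- vapply(lo:hi, function(i) {
        abs(mean(norm[i:(i + m - 1L)]) - mean(norm[(i - m):(i - 1L)]))
      }, numeric(1))
      (lo:hi)[which.max(ds)]
    }, integer(1))
    events <- sort(unname(events))
  }

  # scales and per-row offsets from windows local to each event: within a
  # window the slow bleaching trend is negligible, so the step estimates
  # are unbiased; per-segment values accumulate across events
  n_seg <- length(events) + 1L
  rows <- dim(stream$frames)[1]
  scales <- numeric(n_seg); scales[1] <- 1
  row_offsets <- matrix(0, rows, n_seg)
  rm_all <- apply(stream$frames, 3, rowMeans) # [rows, n]
  plane_med <- function(idx) {
    # per-(row, plane) medians over idx, averaged over planes
    out <- matrix(NA_real_, rows, fpp)
    for (f in seq_len(fpp)) {
      ix <- idx[fip[idx] == f]
      if (length(ix)) out[, f] <- apply(rm_all[, ix, drop = FALSE], 1,
                                        stats::median)
    }
    out
  }
  for (s in seq_along(events)) {
    e <- events[s]
    left <- max(1L, e - window):(e - 1L)
    right <- e:min(n, e + window - 1L)
    AL <- plane_med(left) - base
    AR <- plane_med(right) - base
    # center across planes per row: removes the per-row additive offsets,
    # leaving a pure scale relation between the two windows
    CL <- AL - rowMeans(AL, na.rm = TRUE)
    CR <- AR - rowMeans(AR, na.rm = TRUE)
    ok <- is.finite(CL) & is.finite(CR)
    r_i <- sum(CR[ok] * CL[ok]) / sum(CL[ok]^2)
    scales[s + 1L] <- scales[s] * r_i
    d_off <- rowMeans(AR, na.rm = TRUE) - r_i * rowMeans(AL, na.rm = TRUE)
    d_off[is.na(d_off)] <- 0
    # offsets accumulate through the event: x_new = base + r (x_old - base)
    # + d_off, and x_old already carried the previous offset
    row_offsets[, s + 1L] <- r_i * row_offsets[, s] + d_off
  }
  structure(list(events = events, scales = scales,
                 row_offsets = row_offsets, baseline = base),
            class = "jitter_events")
}

#' Correct exposure-time jitter
#'
#' Inverts the jitter model per segment: subtracts the per-row additive
#' baseline offsets, then divides the above-baseline signal by the segment
#' exposure scale. Correcting an already-corrected stream with its
#' (re-detected, empty) event set is the identity.
#'
#' @param stream A `frame_stream`.
#' @param events A [detect_jitter_changepoints()] result (or the
#'   simulator's truth log coerced to one).
#' @return The corrected `frame_stream`.
#' @export
correct_jitter <- function(stream, events) {
  stopifnot(inherits(stream, "frame_stream"))
  n <- dim(stream$frames)[3]
  bounds <- c(1L, events$events, n + 1L)
  base <- stream$camera$baseline
  for (s in seq_along(events$scales)) {
    if (bounds[s] > n) break
    idx <- bounds[s]:(bounds[s + 1L] - 1L)
    seg <- stream$frames[, , idx, drop = FALSE]
    seg <- seg - array(events$row_offsets[, s], dim(seg))
    seg <- base + (seg - base) / events$scales[s]
    stream$frames[, , idx] <- seg
  }
  stream
}

# --- rigid motion correction -------------------------------------------------

#' Estimate rigid shifts of a plane time series
#'
#' Registers every frame of a single-plane movie against a template (the
#' pixelwise median of the first `template_frames` frames) by FFT
#' cross-correlation with subpixel peak refinement at `1/upsample` pixel
#' resolution.
#'
#' @param stack Array `[rows, cols, time]`.
#' @param upsample Subpixel refinement factor (>= 1).
#' @param template_frames Frames used to build the template.
#' @param max_shift Shifts larger than this (pixels) are clipped to 0 and
#'   flagged.
#' @return A data.frame (`shift_table`) with columns `frame`, `dy`, `dx`,
#'   `clipped`.
#' @export
estimate_shifts <- function(stack, upsample = 10, template_frames = 50,
                            max_shift = Inf) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) stop("estimate_shifts: need >= 2 frames")
  if (upsample < 1) stop("estimate_shifts: upsample must be >= 1")
  k <- min(template_frames, d[3])
  template <- apply(stack[, , seq_len(k), drop = FALSE], c(1, 2), stats::median)
  out <- matrix(0, d[3], 2)
  for (i in seq_len(d[3])) {
    out[i, ] <- phase_corr_shift(stack[, , i], template, upsample = upsample)
  }
  clipped <- abs(out[, 1]) > max_shift | abs(out[, 2]) > max_shift
  out[clipped, ] <- 0
  data.frame(frame = seq_len(d[3]), dy = out[, 1], dx = out[, 2],
             clipped = clipped)
}

#' Apply rigid shifts to a plane time series
#'
#' Translates each frame by minus its estimated shift (cubic
#' interpolation for subpixel shifts), filling rolled-in borders with
#' `fill` and recording the fill mask.
#'
#' @param stack Array `[rows, cols, time]`.
#' @param shifts A [estimate_shifts()] table of matching length.
#' @param fill Border fill value (e.g. the camera baseline).
#' @param min_shift Shifts below this magnitude (pixels) are skipped.
#' @return List with `stack` (registered array) and `mask` (logical array,
#'   `TRUE` where filled).
#' @export
apply_shifts <- function(stack, shifts, fill = 0, min_shift = 0.01) {
  d <- dim(stack)
  if (nrow(shifts) != d[3]) stop("apply_shifts: length mismatch")
  mask <- array(FALSE, d)
  for (i in seq_len(d[3])) {
    dy <- shifts$dy[i]; dx <- shifts$dx[i]
    if (abs(dy) < min_shift && abs(dx) < min_shift) next
    stack[, , i] <- translate_image(stack[, , i], -dy, -dx, fill = fill)
    m <- matrix(FALSE, d[1], d[2])
    nr <- ceiling(abs(dy)); nc <- ceiling(abs(dx))
    if (nr >= d[1] || nc >= d[2]) {
      m[] <- TRUE
    } else {
      if (nr > 0) {
        if (dy > 0) m[(d[1] - nr + 1):d[1], ] <- TRUE else m[seq_len(nr), ] <- TRUE
      }
      if (nc > 0) {
        if (dx > 0) m[, (d[2] - nc + 1):d[2]] <- TRUE else m[, seq_len(nc)] <- TRUE
      }
    }
    mask[, , i] <- m
  }
  list(stack = stack, mask = mask)
}
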