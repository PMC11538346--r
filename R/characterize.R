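#' Simulate a 3D bead stack
#'
#' Renders sub-resolution fluorescent beads as 3D Gaussians of the given
#' per-axis sigmas at random subvoxel positions, with an optional axial
#' intensity profile and Poisson noise. Used to exercise the bead
#' characterization pipeline against known truth.
#'
#' @param n_beads Number of beads.
#' @param dims Stack dimensions (y, x, z) in voxels.
#' @param voxel_size Per-axis voxel size (y, x, z), um.
#' @param sigma Per-axis Gaussian sigma (y, x, z), um.
#' @param peak Peak amplitude, counts.
#' @param background Constant background, counts.
#' @param noise `"none"` or `"poisson"`.
#' @param intensity_profile Optional function of z (um) scaling each
#'   bead's amplitude (e.g. an axial falloff).
#' @param min_separation Minimum bead separation, um.
#' @param margin Margin from the stack borders, um (scalar or per-axis).
#' @param seed RNG seed.
#' @return List with `stack`, `centers` (um, columns y/x/z), `amplitudes`,
#'   `sigma`, `voxel_size`.
#' @export
simulate_bead_stack <- function(n_beads, dims = c(64, 64, 48),
                                voxel_size = c(0.2, 0.2, 0.4),
                                sigma = c(0.25, 0.25, 1.0),
                                peak = 1000, background = 10,
                                noise = c("none", "poisson"),
                                intensity_profile = NULL,
                                min_separation = 3, margin = 2,
                                seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  ext <- dims * voxel_size
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < n_beads) {
    p <- stats::runif(3, margin, ext - margin)
    ok <- nrow(centers) == 0 ||
      all(colSums((t(centers) - p)^2) >= min_separation^2)
    if (ok) centers <- rbind(centers, p)
    tries <- tries + 1L
    if (tries > 50000L) stop("simulate_bead_stack: placement failed")
  }
  colnames(centers) <- c("y", "x", "z")
  amps <- rep(peak, n_beads)
  if (!is.null(intensity_profile)) amps <- amps * intensity_profile(centers[, "z"])
  pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
  stack <- array(background, dims)
  for (i in seq_len(n_beads)) {
    gy <- exp(-(pos[[1]] - centers[i, 1])^2 / (2 * sigma[1]^2))
    gx <- exp(-(pos[[2]] - centers[i, 2])^2 / (2 * sigma[2]^2))
    gz <- exp(-(pos[[3]] - centers[i, 3])^2 / (2 * sigma[3]^2))
    blk <- outer(gy, gx) # [y, x]
    for (s in which(gz > 1e-6)) {
      stack[, , s] <- stack[, , s] + amps[i] * blk * gz[s]
    }
  }
  if (noise == "poisson") {
    stack <- array(stats::rpois(length(stack), stack), dims)
  }
  list(stack = stack, centers = centers, amplitudes = amps,
       sigma = sigma, voxel_size = voxel_size)
}

#' Detect bead candidates in a 3D stack
#'
#' Local maxima above a robust threshold, followed by non-maximum
#' suppression at `min_separation`.
#'
#' @param stack 3D array.
#' @param voxel_size Per-axis voxel size (y, x, z), um.
#' @param min_separation Suppression radius, um.
#' @param k Threshold in robust sds above the median.
#' @return Matrix of candidate centers in voxel indices (columns
#'   `row`, `col`, `slice`), ordered by decreasing intensity.
#' @export
detect_beads <- function(stack, voxel_size, min_separation = 2, k = 8) {
  thr <- stats::median(stack) + k * stats::mad(stack)
  cand <- local_maxima_3d(stack, thr)
  if (nrow(cand) == 0) return(cand)
  um <- t(t(cand - 0.5) * voxel_size)
  ord <- order(stack[cand], decreasing = TRUE)
  keep <- logical(nrow(cand))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(um[keep, , drop = FALSE]) - um[i, ])^2)
    if (all(d2 >= min_separation^2)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out[order(stack[out], decreasing = TRUE), , drop = FALSE]
}

# 1D Gaussian least-squares fit to a profile; returns amplitude, center
# (in the coordinate system of `pos`), sigma, offset.
fit_gauss_1d <- function(pos, y) {
  off0 <- min(y)
  a0 <- max(y) - off0
  mu0 <- pos[which.max(y)]
  w <- pmax(y - off0, 0)
  s0 <- sqrt(sum(w * (pos - mu0)^2) / max(sum(w), 1e-12))
  s0 <- max(s0, diff(pos[1:2]) / 4)
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-(pos - mu)^2 / (2 * s^2)) + c0,
    start = list(a = a0, mu = mu0, s = s0, c0 = off0),
    lower = c(0, min(pos), 1e-6, -Inf),
    upper = c(Inf, max(pos), diff(range(pos)), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(amplitude = cf[["a"]], center = cf[["mu"]], sigma = cf[["s"]],
       offset = cf[["c0"]], residual = sqrt(mean(stats::resid(fit)^2)))
}

#' Fit a 3D Gaussian to one bead
#'
#' Crops a window around the candidate center and fits a 1D Gaussian by
#' least squares to each of the three axis projections (mean over the
#' other two axes), refining the center to subvoxel precision.
#'
#' @param stack 3D array.
#' @param center Candidate center in voxel indices (row, col, slice).
#' @param voxel_size Per-axis voxel size (y, x, z), um.
#' @param window Crop half-widths per axis in um (lateral, lateral,
#'   axial); a bead whose window exceeds the stack errors out rather than
#'   being silently truncated.
#' @return An object of class `bead_fit`: `center` (um, y/x/z), `sigma`
#'   (um), `peak` (amplitude of the x-profile fit), `residual`,
#'   `center_vox`.
#' @export
fit_bead <- function(stack, center, voxel_size, window = c(2, 2, 4)) {
  d <- dim(stack)
  hw <- pmax(ceiling(window / voxel_size), 2L)
  lo <- center - hw
  hi <- center + hw
  if (any(lo < 1) || any(hi > d)) {
    stop("fit_bead: bead too close to the stack border for the fit window")
  }
  crop <- stack[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  fits <- vector("list", 3)
  for (a in 1:3) {
    prof <- apply(crop, a, mean)
    pos <- (lo[a]:hi[a] - 0.5) * voxel_size[a]
    fits[[a]] <- fit_gauss_1d(pos, prof)
  }
  structure(list(
    center = c(y = fits[[1]]$center, x = fits[[2]]$center,
               z = fits[[3]]$center),
    sigma = c(y = fits[[1]]$sigma, x = fits[[2]]$sigma,
              z = fits[[3]]$sigma),
    peak = fits[[2]]$amplitude,
    residual = mean(vapply(fits, function(f) f$residual, numeric(1))),
    center_vox = center
  ), class = "bead_fit")
}

#' Average aligned, upsampled bead images
#'
#' Crops each fitted bead, resamples the crop on an `upsample`-times finer
#' grid shifted so the fitted center lands on the grid center, and
#' averages, removing subvoxel smearing.
#'
#' @param stack 3D array.
#' @param fits List of [fit_bead()] results.
#' @param voxel_size Per-axis voxel size, um.
#' @param upsample Integer upsampling factor.
#' @param window Crop half-widths per axis, um.
#' @param align Center on the fitted positions (`TRUE`) or on the integer
#'   voxel centers (`FALSE`, for comparison).
#' @return List with `psf` (3D array on the upsampled grid), `n` beads
#'   averaged, `voxel_size` of the upsampled grid.
#' @export
average_psf <- function(stack, fits, voxel_size, upsample = 4,
                        window = c(2, 2, 4), align = TRUE) {
  if (length(fits) < 1) stop("average_psf: need at least one fit")
  d <- dim(stack)
  hw_um <- window
  n_out <- 2 * round(hw_um / (voxel_size / upsample)) + 1
  acc <- array(0, n_out)
  used <- 0L
  for (f in fits) {
    ctr_um <- if (align) {
      c(f$center[["y"]], f$center[["x"]], f$center[["z"]])
    } else {
      (f$center_vox - 0.5) * voxel_size
    }
    ok <- TRUE
    Ws <- vector("list", 3)
    for (a in 1:3) {
      at_um <- ctr_um[a] + seq(-hw_um[a], hw_um[a], length.out = n_out[a])
      at_vox <- at_um / voxel_size[a] + 0.5
      if (at_vox[1] < 1 || at_vox[n_out[a]] > d[a]) { ok <- FALSE; break }
      Ws[[a]] <- interp_matrix(d[a], at_vox)
    }
    if (!ok) next
    # separable resampling: y, then x, then z
    m <- Ws[[1]] %*% matrix(stack, d[1], d[2] * d[3])
    v <- array(m, c(n_out[1], d[2], d[3]))
    v <- aperm(v, c(2, 1, 3))
    m <- Ws[[2]] %*% matrix(v, d[2], n_out[1] * d[3])
    v <- aperm(array(m, c(n_out[2], n_out[1], d[3])), c(2, 1, 3))
    v <- aperm(v, c(3, 1, 2))
    m <- Ws[[3]] %*% matrix(v, d[3], n_out[1] * n_out[2])
    v <- aperm(array(m, c(n_out[3], n_out[1], n_out[2])), c(2, 3, 1))
    acc <- acc + v
    used <- used + 1L
  }
  if (used == 0L) stop("average_psf: no bead window fits inside the stack")
  list(psf = acc / used, n = used, voxel_size = voxel_size / upsample)
}

#' Resolution versus defocus from bead fits
#'
#' Median Gaussian FWHM (`2 sqrt(2 ln 2) sigma`, about `2.355 sigma`) per
#' z-bin, laterally (mean of y and x) and axially.
#'
#' @param fits List of [fit_bead()] results.
#' @param z_bin_width Bin width in um.
#' @return Data.frame with `z_center`, `n`, `fwhm_lateral`, `fwhm_axial`
#'   (um); empty bins are omitted with a warning.
#' @export
resolution_report <- function(fits, z_bin_width = 5) {
  if (length(fits) < 1) stop("resolution_report: no fits")
  z <- vapply(fits, function(f) f$center[["z"]], numeric(1))
  lat <- vapply(fits, function(f) mean(f$sigma[c("y", "x")]), numeric(1))
  axi <- vapply(fits, function(f) f$sigma[["z"]], numeric(1))
  bins <- floor(z / z_bin_width)
  fac <- 2 * sqrt(2 * log(2))
  all_bins <- seq(min(bins), max(bins))
  if (!all(all_bins %in% bins)) {
    warning("resolution_report: ", sum(!(all_bins %in% bins)),
            " empty z-bin(s) omitted")
  }
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(z_center = (b + 0.5) * z_bin_width, n = sum(sel),
               fwhm_lateral = fac * stats::median(lat[sel]),
               fwhm_axial = fac * stats::median(axi[sel]))
  }))
  out
}

#' Normalized bead intensity versus z
#'
#' Mean fitted peak amplitude per z-bin, normalized so the curve maximum
#' is exactly 1, with the standard error of the mean per bin.
#'
#' @param fits List of [fit_bead()] results.
#' @param z_bin_width Bin width in um.
#' @return Data.frame with `z_center`, `n`, `intensity`, `sem`.
#' @export
intensity_vs_z <- function(fits, z_bin_width = 5) {
  if (length(fits) < 1) stop("intensity_vs_z: no fits")
  z <- vapply(fits, function(f) f$center[["z"]], numeric(1))
  pk <- vapply(fits, function(f) f$peak, numeric(1))
  bins <- floor(z / z_bin_width)
  out <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(z_center = (b + 0.5) * z_bin_width, n = sum(sel),
               intensity = mean(pk[sel]),
               sem = if (sum(sel) > 1) stats::sd(pk[sel]) / sqrt(sum(sel)) else 0)
  }))
  top <- max(out$intensity)
  out$sem <- out$sem / top
  out$intensity <- out$intensity / top
  out
}

#' Image contrast metric for autofocus
#'
#' Normalized variance of the band-passed image: the image is band-passed
#' with a difference of Gaussians (1 and 4 px), and the variance of the
#' result is divided by the squared image mean, making the metric
#' invariant to global intensity scaling. A constant image scores 0.
#' In-focus structure scores strictly higher than defocused copies.
#'
#' @param image 2D numeric matrix.
#' @param sigma_low,sigma_high Band-pass sigmas in pixels.
#' @return Scalar contrast.
#' @export
contrast_metric <- function(image, sigma_low = 1, sigma_high = 4) {
  stopifnot(is.matrix(image))
  mu <- mean(image)
  if (mu == 0) return(0)
  Wr1 <- gauss_matrix(nrow(image), sigma_low)
  Wc1 <- gauss_matrix(ncol(image), sigma_low)
  Wr2 <- gauss_matrix(nrow(image), sigma_high)
  Wc2 <- gauss_matrix(ncol(image), sigma_high)
  bp <- Wr1 %*% image %*% t(Wc1) - Wr2 %*% image %*% t(Wc2)
  stats::var(as.numeric(bp)) / mu^2
}

# Quadratic (3-point) refinement of an argmax on a regular grid; returns
# the refined position in grid units relative to the integer peak.
quad_refine <- function(vals, i) {
  if (i <= 1 || i >= length(vals)) return(0)
  denom <- vals[i - 1] - 2 * vals[i] + vals[i + 1]
  if (denom >= 0) return(0)
  0.5 * (vals[i - 1] - vals[i + 1]) / denom
}

#' Calibrate the light-sheet-to-focus relationship
#'
#' For each focal plane of a calibration sweep (images acquired at several
#' light-sheet offsets around each focal position), the sheet position
#' maximizing the [contrast_metric()] is found (argmax with quadratic
#' sub-sample refinement), and the final linear map
#' `sheet = slope * focus + intercept` is obtained by least squares over
#' the (focal position, best offset) pairs.
#'
#' @param images List of lists: `images[[p]][[o]]` is the 2D image at
#'   focal plane `p` and sheet offset `o`.
#' @param focal_positions Focal plane positions, um (length >= 2).
#' @param sheet_offsets Sheet positions, um (length >= 3).
#' @param metric Contrast function of one image.
#' @return An object of class `calibration_result`: `slope`, `intercept`,
#'   `phase_lag` (NA here), `best_offset` table, `residuals`.
#' @export
calibrate_lightsheet <- function(images, focal_positions, sheet_offsets,
                                 metric = contrast_metric) {
  n_p <- length(focal_positions)
  n_o <- length(sheet_offsets)
  if (n_p < 2) stop("calibrate_lightsheet: need >= 2 focal planes")
  if (n_o < 3) stop("calibrate_lightsheet: need >= 3 sheet offsets")
  step <- stats::median(diff(sheet_offsets))
  best <- numeric(n_p)
  for (p in seq_len(n_p)) {
    cv <- vapply(seq_len(n_o), function(o) metric(images[[p]][[o]]),
                 numeric(1))
    i <- which.max(cv)
    best[p] <- sheet_offsets[i] + quad_refine(cv, i) * step
  }
  fit <- stats::lm(best ~ focal_positions)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    phase_lag = NA_real_,
    best_offset = data.frame(focal_position = focal_positions,
                             best_sheet = best),
    residuals = unname(stats::resid(fit))
  ), class = "calibration_result")
}

#' Simulate a light-sheet calibration sweep
#'
#' Renders a fixed 2D bead constellation at every (focal plane, sheet
#' offset) combination; beads blur and dim as the sheet departs from the
#' true focus `slope * focus + intercept`, emulating the contrast falloff
#' the calibration exploits.
#'
#' @param focal_positions,sheet_offsets Grids in um.
#' @param slope,intercept True sheet-vs-focus relation to recover.
#' @param dims Image size (rows, cols).
#' @param pixel_size Pixel size, um.
#' @param sheet_sigma Axial 1/e^2-derived Gaussian sigma of the sheet, um.
#' @param psf_sigma In-focus lateral PSF sigma, um.
#' @param n_beads Number of beads.
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed.
#' @return List of lists of images, `images[[p]][[o]]`.
#' @export
simulate_calibration_sweep <- function(focal_positions, sheet_offsets,
                                       slope = 1, intercept = 0,
                                       dims = c(48, 48), pixel_size = 1,
                                       sheet_sigma = 1.7, psf_sigma = 0.8,
                                       n_beads = 25, noise = c("none", "poisson"),
                                       seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  ext <- dims * pixel_size
  by <- stats::runif(n_beads, 2, ext[1] - 2)
  bx <- stats::runif(n_beads, 2, ext[2] - 2)
  amp <- stats::runif(n_beads, 500, 1000)
  ry <- (seq_len(dims[1]) - 0.5) * pixel_size
  rx <- (seq_len(dims[2]) - 0.5) * pixel_size
  out <- vector("list", length(focal_positions))
  for (p in seq_along(focal_positions)) {
    out[[p]] <- vector("list", length(sheet_offsets))
    true_sheet <- slope * focal_positions[p] + intercept
    for (o in seq_along(sheet_offsets)) {
      dz <- sheet_offsets[o] - true_sheet
      dim_f <- exp(-dz^2 / (2 * sheet_sigma^2))
      blur <- psf_sigma * sqrt(1 + (dz / (2 * sheet_sigma))^2)
      img <- matrix(10, dims[1], dims[2])
      for (b in seq_len(n_beads)) {
        gy <- exp(-(ry - by[b])^2 / (2 * blur^2))
        gx <- exp(-(rx - bx[b])^2 / (2 * blur^2))
        img <- img + amp[b] * dim_f * outer(gy, gx)
      }
      if (noise == "poisson") {
        img <- matrix(stats::rpois(length(img), img), dims[1], dims[2])
      }
      out[[p]][[o]] <- img
    }
  }
  out
}

#' Estimate the actuator phase lag
#'
#' Automated stand-in for the manual phase adjustment: scans a grid of
#' candidate correction phases, scores each by the summed
#' [contrast_metric()] of the resulting mean plane images of a bead
#' acquisition (the score peaks when the light sheet is back in synchrony
#' with the focus sweep), and refines the peak quadratically. The result
#' is reported modulo 2 pi in (-pi, pi].
#'
#' @param acquire Function taking a candidate correction phase (radians)
#'   and returning either a list of 2D mean plane images or a
#'   `frame_stream` (whose per-plane time means are then used).
#' @param phase_grid Candidate phases, radians.
#' @param metric Contrast function of one image.
#' @param refine Run a second, four-times-finer local grid around the
#'   coarse peak before the quadratic refinement.
#' @return List with `phase_lag` (radians), `grid`, `scores`.
#' @export
estimate_phase_lag <- function(acquire, phase_grid = seq(-0.3, 0.3, by = 0.05),
                               metric = contrast_metric, refine = TRUE) {
  score_one <- function(ph) {
    res <- acquire(ph)
    imgs <- if (inherits(res, "frame_stream")) {
      fip <- res$meta$frame_in_period
      lapply(sort(unique(fip)), function(f) {
        idx <- which(fip == f)
        rowMeans(array(res$frames[, , idx],
                       c(dim(res$frames)[1] * dim(res$frames)[2],
                         length(idx))), dims = 1) |>
          matrix(dim(res$frames)[1], dim(res$frames)[2])
      })
    } else {
      res
    }
    sum(vapply(imgs, metric, numeric(1)))
  }
  scores <- vapply(phase_grid, score_one, numeric(1))
  i <- which.max(scores)
  step <- stats::median(diff(phase_grid))
  grid <- phase_grid
  if (refine) {
    fine_step <- step / 4
    fine <- phase_grid[i] + fine_step * seq(-2, 2)
    fine_scores <- vapply(fine, score_one, numeric(1))
    j <- which.max(fine_scores)
    ph <- fine[j] + quad_refine(fine_scores, j) * fine_step
    grid <- c(phase_grid, fine)
    scores <- c(scores, fine_scores)
  } else {
    ph <- phase_grid[i] + quad_refine(scores, i) * step
  }
  ph <- ((ph + pi) %% (2 * pi)) - pi
  list(phase_lag = ph, grid = grid, scores = scores)
}
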