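# Rolling percentile via block quantiles + linear interpolation (the
# standard cheap detrender for slow baselines such as photobleaching).
running_percentile <- function(x, window, p = 0.2) {
  n <- length(x)
  window <- max(3L, min(window, n))
  block <- max(1L, floor(window / 4))
  centers <- unique(c(seq(1L, n, by = block), n))
  half <- window %/% 2
  vals <- vapply(centers, function(i) {
    stats::quantile(x[max(1, i - half):min(n, i + half)], p, names = FALSE)
  }, numeric(1))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect spikes in a fluorescence trace
#'
#' High-passes the trace (running-median subtraction), estimates the noise
#' sd robustly (`1.4826 * MAD`), and marks local extrema exceeding
#' `k * sd` in the configured polarity, enforcing a refractory minimum
#' separation (keeping the larger extremum).
#'
#' @param trace Numeric trace.
#' @param k Threshold in robust noise sds.
#' @param polarity -1 for negative-going spikes (fluorescence dips on
#'   depolarization), +1 for positive-going.
#' @param refractory Minimum spike separation in samples.
#' @param hp_window Running-median window (odd, samples) for the high-pass.
#' @return Integer vector of spike sample indices.
#' @export
detect_spikes <- function(trace, k = 4, polarity = -1, refractory = 3L,
                          hp_window = 25L) {
  n <- length(trace)
  hp_window <- min(hp_window, if (n %% 2 == 1) n else n - 1L)
  if (hp_window %% 2 == 0) hp_window <- hp_window - 1L
  if (n < max(5L, hp_window)) stop("detect_spikes: trace too short")
  hp <- trace - stats::runmed(trace, hp_window)
  s <- polarity * hp
  noise <- stats::mad(s)
  if (noise == 0) noise <- stats::sd(s)
  if (!is.finite(noise) || noise == 0) return(integer(0))
  cand <- which(s > k * noise)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[s[cand] >= s[cand - 1] & s[cand] >= s[cand + 1]]
  if (!length(cand)) return(integer(0))
  # refractory: greedy by amplitude
  ord <- cand[order(s[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refractory)) kept <- c(kept, i)
  }
  sort(kept)
}

#' z-score a trace
#'
#' @param trace Numeric trace with positive sd.
#' @return `(x - mean) / sd`.
#' @export
zscore <- function(trace) {
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0) {
    stop("zscore: trace has zero or undefined variance")
  }
  (trace - mean(trace)) / s
}

# Spike-triggered average waveform in a +/- window, and the denoised
# reference trace rebuilt from it at the detected spike times.
sta_reference <- function(trace, spikes, window = 10L) {
  n <- length(trace)
  sta <- numeric(2L * window + 1L)
  cnt <- numeric(2L * window + 1L)
  for (s in spikes) {
    idx <- (s - window):(s + window)
    ok <- idx >= 1 & idx <= n
    sta[ok] <- sta[ok] + trace[idx[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  sta <- sta / pmax(cnt, 1)
  sta <- sta - stats::median(sta[c(1:3, (2 * window - 1):(2 * window + 1))])
  ref <- numeric(n)
  for (s in spikes) {
    idx <- (s - window):(s + window)
    ok <- idx >= 1 & idx <= n
    ref[idx[ok]] <- ref[idx[ok]] + sta[ok]
  }
  list(sta = sta, reference = ref)
}

#' Extract one weighted fluorescence trace
#'
#' Iterative weighted-sum extraction for a 3D ROI on the raw plane series:
#' (1) the raw trace is the unweighted mean of the ROI pixels; (2) a
#' background trace from a surrounding shell is scaled by least squares
#' and subtracted; (3) the result is detrended with a slow running
#' percentile (removing bleaching; the default percentile is the median,
#' which is neutral to the sign of the voltage response); (4) spikes are
#' detected; (5) a denoised reference trace is built from the detected
#' spikes via the spike-triggered average waveform, plus the band-limited
#' oscillatory component of the trace (so rhythmic cells inform the
#' weights too); (6) each pixel receives a nonnegative regression
#' coefficient of its time series against the reference, regularized
#' toward uniform and normalized to sum 1; (7) the weighted pixel sum
#' replaces the raw trace, and steps 4-7 repeat until the spike set is
#' unchanged or `n_iter` is reached. If no spikes are found the
#' background-subtracted mean trace with uniform weights is returned and
#' flagged.
#'
#' @param pixels Matrix `[time, n_pixels]` of ROI pixel time series.
#' @param shell Matrix `[time, n_shell]` of background-shell pixel series.
#' @param plane_rate Sampling rate, Hz.
#' @param k,polarity,refractory Spike detection parameters
#'   (see [detect_spikes()]).
#' @param n_iter Maximum number of reweighting iterations.
#' @param sta_window Half-width (samples) of the spike-triggered average.
#' @param detrend_window Running-percentile window in seconds.
#' @param detrend_percentile Percentile used for detrending (0.5 =
#'   running median).
#' @param osc_band Frequency band (Hz) of the oscillatory reference
#'   component; `NULL` disables it.
#' @return A list (one `trace_set` entry): `raw`, `background`,
#'   `weighted`, `detrended`, `zscored`, `weights`, `spikes`, `snr`,
#'   `beta`, `flags`, `iterations`, `spike_history`.
#' @export
extract_trace <- function(pixels, shell, plane_rate,
                          k = 4, polarity = -1, refractory = 3L,
                          n_iter = 3L, sta_window = 10L,
                          detrend_window = 1, detrend_percentile = 0.5,
                          osc_band = c(5, 45)) {
  Tn <- nrow(pixels)
  win <- max(3L, round(detrend_window * plane_rate))
  raw <- rowMeans(pixels)
  bg <- if (!is.null(shell) && ncol(shell) > 0) rowMeans(shell) else numeric(Tn)
  beta <- 0
  if (any(bg != 0) && stats::var(bg) > 0) {
    beta <- stats::cov(raw, bg) / stats::var(bg)
    # the shell inevitably carries some of the cell's own halo; an
    # unconstrained slope then regresses the cell against itself and
    # subtracts its signal. A global background cannot exceed unit gain,
    # so the coefficient is clamped to [0, 1].
    beta <- min(max(beta, 0), 1)
  }
  sub <- raw - beta * (bg - mean(bg))
  detrend <- function(x) x - running_percentile(x, win, detrend_percentile)
  det <- detrend(sub)
  bandpass <- NULL
  if (!is.null(osc_band) && Tn >= 100 &&
      osc_band[1] < plane_rate / 2) {
    hi <- min(osc_band[2], 0.45 * plane_rate)
    bf <- signal::butter(2, c(osc_band[1], hi) / (plane_rate / 2),
                         type = "pass")
    bandpass <- function(x) as.numeric(signal::filtfilt(bf, x))
  }

  flags <- character(0)
  weights <- rep(1 / ncol(pixels), ncol(pixels))
  weighted <- sub
  det_w <- det
  spike_history <- list()
  spikes <- detect_spikes(det, k = k, polarity = polarity,
                          refractory = refractory)
  spike_history[[1]] <- spikes
  iterations <- 0L
  if (length(spikes) == 0) {
    flags <- c(flags, "no-spikes-fallback")
  } else {
    # detrended, background-regressed pixel series for the weighting
    P <- pixels
    if (beta != 0) P <- P - outer(bg - mean(bg), rep(beta, ncol(pixels)))
    Pd <- apply(P, 2, detrend)
    for (it in seq_len(n_iter)) {
      iterations <- it
      ref <- sta_reference(det_w, spikes, window = sta_window)$reference
      if (!is.null(bandpass)) ref <- ref + bandpass(det_w)
      denom <- sum(ref^2)
      if (denom <= 0) {
        flags <- c(flags, "degenerate-reference")
        break
      }
      b <- as.numeric(crossprod(Pd, ref)) / denom
      w <- pmax(b, 0)
      if (sum(w) <= 0) {
        flags <- c(flags, "degenerate-weights")
        break
      }
      # shrink toward uniform: per-pixel regression on a short record is
      # noisy, and over-concentrated weights amplify shot noise
      w <- w + mean(w)
      weights <- w / sum(w)
      weighted <- as.numeric(P %*% weights)
      det_w <- detrend(weighted)
      new_spikes <- detect_spikes(det_w, k = k, polarity = polarity,
                                  refractory = refractory)
      spike_history[[it + 1L]] <- new_spikes
      if (identical(new_spikes, spikes)) {
        spikes <- new_spikes
        break
      }
      spikes <- new_spikes
    }
  }
  snr <- if (length(spikes) > 0) {
    spike_snr(det_w, spikes, polarity = polarity)
  } else {
    NA_real_
  }
  zs <- if (stats::sd(det_w) > 0) zscore(det_w) else det_w
  list(raw = raw, background = bg, weighted = weighted, detrended = det_w,
       zscored = zs, weights = weights, spikes = spikes, snr = snr,
       beta = beta, flags = flags, iterations = iterations,
       spike_history = spike_history)
}

#' Extract traces for every ROI of a segmentation
#'
#' Maps each 3D ROI (and its background shell) to raw plane-series pixels
#' via the stitching provenance and runs [extract_trace()] on each.
#'
#' @param series A `plane_series` (stroke-shift compensated consistently
#'   with the stitched volume).
#' @param rois A `roi_set` segmented on `volume`.
#' @param volume The `volume_stack` carrying the stitching provenance.
#' @param ... Passed to [extract_trace()].
#' @return An object of class `trace_set`: list of per-ROI entries plus
#'   `summary` data.frame (label, n_pixels, n_spikes, snr, flags) and the
#'   sampling rate.
#' @export
extract_traces <- function(series, rois, volume, ...) {
  stopifnot(inherits(series, "plane_series"), inherits(rois, "roi_set"),
            inherits(volume, "volume_stack"))
  plane_rate <- series$sweep$volume_rate
  labels <- rois$table$label
  entries <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    coords <- map_roi_to_frames(roi_voxels(rois, labels[i]), volume)
    shell_vox <- background_shell(rois, labels[i])
    shell_coords <- if (nrow(shell_vox) > 0) {
      map_roi_to_frames(shell_vox, volume)
    } else {
      NULL
    }
    px <- gather_pixel_series(series, coords)
    sh <- if (!is.null(shell_coords)) gather_pixel_series(series, shell_coords) else NULL
    e <- extract_trace(px, sh, plane_rate, ...)
    e$label <- labels[i]
    e$coords <- coords
    entries[[i]] <- e
  }
  summary <- data.frame(
    label = labels,
    n_pixels = vapply(entries, function(e) length(e$weights), integer(1)),
    n_spikes = vapply(entries, function(e) length(e$spikes), integer(1)),
    snr = vapply(entries, function(e) e$snr, numeric(1)),
    flags = vapply(entries, function(e) paste(e$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries, summary = summary,
                 plane_rate = plane_rate), class = "trace_set")
}

#' Gather pixel time series from a plane series
#'
#' @param series A `plane_series`.
#' @param coords Data.frame with columns `stroke`, `plane`, `row`, `col`
#'   (e.g. from [map_roi_to_frames()]). Coordinates outside the frame are
#'   dropped.
#' @return Matrix `[time, n_pixels]`.
#' @export
gather_pixel_series <- function(series, coords) {
  stopifnot(inherits(series, "plane_series"))
  d <- dim(series$down)
  ok <- coords$row >= 1 & coords$row <= d[1] &
    coords$col >= 1 & coords$col <= d[2]
  coords <- coords[ok, , drop = FALSE]
  if (nrow(coords) == 0) stop("gather_pixel_series: no valid pixels")
  Tn <- d[4]
  out <- matrix(0, Tn, nrow(coords))
  for (i in seq_len(nrow(coords))) {
    arr <- if (coords$stroke[i] == "down") series$down else series$up
    out[, i] <- arr[coords$row[i], coords$col[i], coords$plane[i], ]
  }
  out
}

#' Spike signal-to-noise ratio
#'
#' Median spike peak amplitude (baseline-subtracted, in the spike
#' polarity) divided by the robust noise sd of the spike-free portion of
#' the trace. Invariant to scaling of the trace.
#'
#' @param trace Numeric trace (typically detrended).
#' @param spikes Spike sample indices (>= 1 spike required).
#' @param polarity Spike polarity (-1 or +1).
#' @param exclude Half-width (samples) removed around each spike for the
#'   noise estimate.
#' @return SNR (dimensionless).
#' @export
spike_snr <- function(trace, spikes, polarity = -1, exclude = 5L) {
  if (length(spikes) < 1) stop("spike_snr: need at least one spike")
  n <- length(trace)
  spike_free <- rep(TRUE, n)
  for (s in spikes) {
    spike_free[max(1, s - exclude):min(n, s + exclude)] <- FALSE
  }
  base <- stats::median(trace[spike_free])
  noise <- stats::mad(trace[spike_free])
  if (noise == 0) noise <- stats::sd(trace[spike_free])
  amp <- stats::median(polarity * (trace[spikes] - base))
  amp / noise
}

#' Automated curation of extracted traces
#'
#' Proxy for manual curation: flags `duplicate` when two footprints
#' overlap (intersection over union of weight supports above
#' `iou_thresh`) and their weighted traces correlate above `corr_thresh`
#' (the lower-SNR member is flagged); flags `no-activity` when a trace
#' has fewer than `min_spikes` spikes and its oscillation-band sd is
#' below `osc_k` times the noise. Flags never delete entries.
#'
#' @param traces A `trace_set`.
#' @param iou_thresh,corr_thresh,min_spikes,osc_band,osc_k Thresholds.
#' @return The `trace_set` with a `curation` column added to its summary
#'   and per-entry `flags` updated.
#' @export
curate <- function(traces, iou_thresh = 0.3, corr_thresh = 0.8,
                   min_spikes = 1L, osc_band = c(10, 40), osc_k = 3) {
  stopifnot(inherits(traces, "trace_set"))
  n <- length(traces$entries)
  flags <- rep("keep", n)
  support <- lapply(traces$entries, function(e) {
    sel <- e$weights > 0
    paste(e$coords$stroke[sel], e$coords$plane[sel], e$coords$row[sel],
          e$coords$col[sel], sep = ":")
  })
  snr <- vapply(traces$entries, function(e) {
    if (is.na(e$snr)) -Inf else e$snr
  }, numeric(1))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      iou <- length(intersect(support[[i]], support[[j]])) /
        length(union(support[[i]], support[[j]]))
      if (iou > iou_thresh) {
        cc <- suppressWarnings(stats::cor(traces$entries[[i]]$detrended,
                                          traces$entries[[j]]$detrended))
        if (is.finite(cc) && cc > corr_thresh) {
          loser <- if (snr[i] <= snr[j]) i else j
          flags[loser] <- "duplicate"
        }
      }
    }
  }
  fs <- traces$plane_rate
  for (i in seq_len(n)) {
    if (flags[i] != "keep") next
    e <- traces$entries[[i]]
    if (length(e$spikes) >= min_spikes) next
    x <- e$detrended
    nfft <- length(x)
    P <- Mod(stats::fft(x - mean(x)))^2 / nfft
    freq <- (seq_len(nfft) - 1) * fs / nfft
    band <- freq >= osc_band[1] & freq <= osc_band[2]
    osc_sd <- sqrt(2 * sum(P[band]) / nfft)
    noise <- stats::mad(diff(x)) / sqrt(2)
    if (noise == 0 || !is.finite(noise) || osc_sd < osc_k * noise) {
      flags[i] <- "no-activity"
    }
  }
  for (i in seq_len(n)) {
    traces$entries[[i]]$flags <- union(traces$entries[[i]]$flags,
                                       flags[i])
  }
  traces$summary$curation <- flags
  traces
}

#' Fit the photobleaching decay constant
#'
#' Fits `a + b * exp(-t / tau)` to each baseline trace by nonlinear least
#' squares (Levenberg-Marquardt), seeded from a log-linear fit, and pools
#' all cells by fitting their mean trace. Traces with negligible decay are
#' flagged `no-bleach` (tau = Inf) rather than erroring.
#'
#' @param baselines Matrix `[n_cells, time]` of baseline fluorescence
#'   traces (un-detrended).
#' @param time Time vector in seconds.
#' @return An object of class `bleach_fit`: per-cell data.frame
#'   (`tau`, `amplitude`, `offset`, `residual`, `flag`) and `pooled_tau`.
#' @export
fit_bleaching <- function(baselines, time) {
  if (is.vector(baselines)) baselines <- matrix(baselines, nrow = 1)
  if (ncol(baselines) != length(time)) stop("fit_bleaching: length mismatch")
  if (length(time) < 3) stop("fit_bleaching: trace too short")
  fit_one <- function(y) {
    rng <- diff(range(y))
    if (rng <= 0 || rng < 1e-9 * max(abs(y), 1)) {
      return(list(tau = Inf, amplitude = 0, offset = mean(y),
                  residual = 0, flag = "no-bleach"))
    }
    a0 <- min(y)
    b0 <- max(y[1], a0 + rng) - a0
    pos <- pmax(y - a0 + 0.05 * rng, 1e-12)
    sl <- unname(stats::coef(stats::lm(log(pos) ~ time))[2])
    tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else diff(range(time))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * exp(-time / tau),
                        start = list(a = a0, b = b0, tau = tau0),
                        lower = c(-Inf, 0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                  residual = NA_real_, flag = "fit-failed"))
    }
    cf <- stats::coef(fit)
    flag <- "ok"
    if (cf[["tau"]] > 100 * diff(range(time)) &&
        cf[["b"]] < 0.01 * max(abs(y))) {
      flag <- "no-bleach"
    }
    list(tau = cf[["tau"]], amplitude = cf[["b"]], offset = cf[["a"]],
         residual = sqrt(mean(stats::resid(fit)^2)), flag = flag)
  }
  per_cell <- do.call(rbind, lapply(seq_len(nrow(baselines)), function(i) {
    as.data.frame(fit_one(baselines[i, ]))
  }))
  pooled <- fit_one(colMeans(baselines))
  # per-cell median is the pooled estimate: on records much shorter than
  # tau the offset/tau degeneracy makes any single fit long-tailed, and
  # the median over cells is far more stable than the mean-trace fit
  ok <- per_cell$flag == "ok" & is.finite(per_cell$tau)
  pooled_tau <- if (any(ok)) stats::median(per_cell$tau[ok]) else pooled$tau
  structure(list(per_cell = per_cell, pooled_tau = pooled_tau,
                 mean_trace = pooled), class = "bleach_fit")
}
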