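test_that("the drive waveform has triangle geometry and unit-DC filtering", {
  sw <- sweep_config()
  w <- drive_waveform(sw, 0.004) # two periods
  expect_equal(mean(w$z), sw$z_range / 2, tolerance = 1e-6)
  # unfiltered limit: quarter-period value is half the range
  swi <- sweep_config(lowpass_cutoff = Inf)
  wi <- drive_waveform(swi, 0.002)
  i_quarter <- round(length(wi$z) / 4) + 1
  expect_equal(wi$z[i_quarter], swi$z_range / 2, tolerance = 1e-3)
  expect_equal(max(wi$z), swi$z_range, tolerance = 1e-6)
  expect_error(drive_waveform(sw, 0.001), "one sweep period")
})

test_that("the filtered waveform matches a direct convolution oracle", {
  sw <- sweep_config()
  fs <- sw$waveform_sample_rate
  nps <- round(fs / sw$volume_rate)
  # oracle: convolve a long triangle with the truncated impulse response
  bf <- signal::butter(sw$filter_order, sw$lowpass_cutoff / (fs / 2),
                       type = "low")
  h <- as.numeric(signal::filter(bf, c(1, rep(0, 30 * nps - 1))))
  n <- 40 * nps
  tt <- (seq_len(n) - 1) / fs
  phase <- (tt * sw$volume_rate) %% 1
  tri <- sw$z_range * ifelse(phase < 0.5, 2 * phase, 2 * (1 - phase))
  conv <- numeric(nps)
  last <- (n - nps + 1):n
  for (k in seq_along(last)) {
    i <- last[k]
    m <- min(i, length(h))
    conv[k] <- sum(h[1:m] * tri[i - (1:m) + 1])
  }
  w <- drive_waveform(sw, 1 / sw$volume_rate)
  expect_lt(max(abs(w$z - conv)), 1e-8 * sw$z_range)
})

test_that("the stroke shift separates down- and up-stroke by the configured offset", {
  sw <- sweep_config(stroke_y_shift = 6.5)
  w <- trajectory_with_stroke_shift(drive_waveform(sw, 0.004), sw)
  phase <- (w$t * sw$volume_rate) %% 1
  down <- phase < 0.5
  expect_equal(mean(w$y[down]) - mean(w$y[!down]), 6.5)
  # periodic with the volume period
  nps <- round(sw$waveform_sample_rate / sw$volume_rate)
  expect_equal(w$y[seq_len(nps)], w$y[nps + seq_len(nps)])
  sw0 <- sweep_config(stroke_y_shift = 0)
  w0 <- trajectory_with_stroke_shift(drive_waveform(sw0, 0.002), sw0)
  expect_true(all(w0$y == 0))
})

test_that("voltage traces are reproducible Poisson spiking plus oscillation", {
  vp0 <- voltage_params(spike_rate = 0, oscillation_amplitude = 0,
                        subthreshold_noise_sd = 0)
  flat <- generate_voltage_traces(vp0, 3, 200, 500)
  expect_true(all(flat$traces == 0))
  vp <- voltage_params(seed = 11)
  a <- generate_voltage_traces(vp, 4, 300, 500)
  b <- generate_voltage_traces(vp, 4, 300, 500)
  expect_identical(a$traces, b$traces)
  # Monte-Carlo spike count vs the Poisson mean over 100 seeds
  rate <- 5; dur <- 2
  counts <- vapply(1:100, function(s) {
    vt <- generate_voltage_traces(
      voltage_params(spike_rate = rate, oscillation_amplitude = 0,
                     subthreshold_noise_sd = 0, seed = s),
      1, dur * 500, 500)
    length(vt$spike_frames[[1]])
  }, numeric(1))
  mu <- rate * dur
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 100))
})

test_that("each row images the sweep z at its mid-exposure time", {
  # global shutter + ideal triangle: frame centers at (i + 0.5) * 6.25 um
  swi <- sweep_config(lowpass_cutoff = Inf)
  cam_g <- camera_config(rows = 16, cols = 16, readout_row_stagger = 0)
  zm <- frame_z_map(swi, cam_g)
  down <- which(zm$stroke == "down")
  expect_equal(zm$z_frame_mean[down],
               (seq_along(down) - 0.5) * 6.25, tolerance = 1e-3)
  expect_equal(max(apply(zm$z, 2, function(z) diff(range(z)))), 0)
  # rolling shutter: within-frame span ~ plane_z_extent in the linear regime
  sw <- sweep_config()
  cam <- camera_config(rows = 48, cols = 32)
  zmr <- frame_z_map(sw, cam)
  mid <- c(4, 12) # frames where the filtered drive is most linear
  spans <- apply(zmr$z[, mid], 2, function(z) diff(range(z)))
  expect_true(all(abs(spans - 6.25) / 6.25 < 0.02))
  # tilt sign flips between strokes
  slope <- apply(zmr$z, 2, function(z) sign(z[nrow(zmr$z)] - z[1]))
  expect_true(all(slope[c(3:7)] == 1))
  expect_true(all(slope[zmr$stroke == "up"] %in% c(-1, 1)))
  expect_equal(slope[4], -slope[12])
})

test_that("rendered frames obey timing, positivity, and bleaching", {
  sim <- tiny_sim()
  st <- sim$stream
  expect_true(min(st$frames) >= 0)
  expect_equal(st$meta$time,
               (seq_len(nrow(st$meta)) - 1) / st$camera$frame_trigger_rate)
  # noiseless static scene: frame means decay with the configured tau
  nn <- one_neuron_sim(duration = 1, spike_rate = 0, noise = "none")
  m <- colMeans(nn$stream$frames, dims = 2) - nn$stream$camera$baseline
  tt <- nn$stream$meta$time
  tau_fit <- -1 / coef(lm(log(m) ~ tt))[2]
  expect_lt(abs(tau_fit - 72) / 72, 0.02)
  # tilt signs recorded in ground truth flip between strokes
  zr <- nn$truth$z_rows
  s_down <- zr[nrow(zr), 4] - zr[1, 4]
  s_up <- zr[nrow(zr), 12] - zr[1, 12]
  expect_true(s_down > 0 && s_up < 0)
})

test_that("the brightest frame in each sweep tracks the emitter z", {
  sim <- one_neuron_sim(z = 30, spike_rate = 0, noise = "none",
                        stroke_y_shift = 0, duration = 0.05)
  st <- sim$stream
  zm <- frame_z_map(st$sweep, st$camera)
  m <- colMeans(st$frames, dims = 2)
  fip <- st$meta$frame_in_period
  down_f <- which(zm$stroke == "down")
  # brute-force argmax over frames of one sweep vs nearest mid-exposure z
  sweep1 <- which(st$meta$period == 2 & fip %in% down_f)
  brightest <- sweep1[which.max(m[sweep1])]
  nearest <- sweep1[which.min(abs(zm$z_frame_mean[fip[sweep1]] - 30))]
  expect_equal(brightest, nearest)
  # noiseless flat traces: same plane repeats across periods up to bleaching
  i1 <- which(fip == 5)[2]; i2 <- which(fip == 5)[4]
  b1 <- exp(-st$meta$time[i1] / 72); b2 <- exp(-st$meta$time[i2] / 72)
  f1 <- (st$frames[, , i1] - 100) / b1
  f2 <- (st$frames[, , i2] - 100) / b2
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("exposure jitter injection is piecewise, seeded, and logged", {
  sim <- one_neuron_sim(duration = 0.25, spike_rate = 0, noise = "none")
  st0 <- sim$stream
  same <- inject_exposure_jitter(st0, 0, seed = 5)
  expect_equal(same$frames, st0$frames)
  expect_length(same$jitter_log$events, 0)
  j1 <- inject_exposure_jitter(st0, 1, scale_range = c(1.02, 1.02),
                               row_baseline_sd = 0, seed = 5)
  ev <- j1$jitter_log$events
  base <- st0$camera$baseline
  pre <- mean(j1$frames[, , ev - 1] - base) / mean(st0$frames[, , ev - 1] - base)
  post <- mean(j1$frames[, , ev + 1] - base) / mean(st0$frames[, , ev + 1] - base)
  expect_equal(pre, 1)
  expect_equal(post, 1.02, tolerance = 1e-10)
  j2 <- inject_exposure_jitter(st0, 1, scale_range = c(1.02, 1.02),
                               row_baseline_sd = 0, seed = 5)
  expect_identical(j1$frames, j2$frames)
  expect_identical(j1$jitter_log, j2$jitter_log)
})

test_that("acquisitions round-trip through TIFF + JSON byte-identically", {
  sim <- one_neuron_sim(duration = 0.05, noise = "full")
  d1 <- file.path(tempdir(), "acq1"); d2 <- file.path(tempdir(), "acq2")
  write_acquisition(sim$stream, d1, truth = sim$truth)
  back <- read_acquisition(d1)
  expect_equal(back$stream$frames,
               array(pmin(pmax(round(sim$stream$frames), 0), 65535),
                     dim(sim$stream$frames)))
  expect_equal(nrow(back$stream$meta), dim(back$stream$frames)[3])
  # stroke labels alternate in blocks of planes_per_sweep
  r <- rle(back$stream$meta$stroke)
  expect_true(all(r$lengths == sim$stream$sweep$planes_per_sweep))
  expect_equal(r$values[1:2], c("down", "up"))
  # byte-identical rewrite
  write_acquisition(sim$stream, d2, truth = sim$truth)
  for (f in c("frames.tif", "meta.json", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
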