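test_that("3D segmentation finds well-separated somata with accurate centroids", {
  set.seed(12)
  dims <- c(48, 96, 16); vox <- c(1.5, 1.5, 3.125)
  ext <- dims * vox
  centers <- matrix(NA_real_, 0, 3)
  while (nrow(centers) < 30) {
    p <- runif(3, c(8, 8, 10), ext - c(8, 8, 10))
    if (nrow(centers) == 0 ||
        all(colSums((t(centers) - p)^2) >= 144)) centers <- rbind(centers, p)
  }
  sv <- sphere_volume(centers, diameter = 7.7, dims = dims, voxel_size = vox)
  rois <- segment_3d(sv$vol, scale = 7.7, voxel_size = vox)
  expect_equal(nrow(rois$table), 30)
  for (i in 1:30) {
    d <- sqrt((rois$table$y - centers[i, 1])^2 +
                (rois$table$x - centers[i, 2])^2 +
                (rois$table$z - centers[i, 3])^2)
    expect_lt(min(d), 1)
  }
  # empty volume segments to zero ROIs with a warning
  expect_warning(r0 <- segment_3d(array(10, c(16, 16, 8)), scale = 7.7,
                                  voxel_size = vox))
  expect_equal(nrow(r0$table), 0)
})

test_that("touching somata are split into two ROIs", {
  dims <- c(32, 32, 16); vox <- c(1.5, 1.5, 1.5)
  centers <- rbind(c(24, 20, 12), c(24, 28, 12)) # 8 um apart, touching
  sv <- sphere_volume(centers, diameter = 7.7, dims = dims, voxel_size = vox)
  rois <- segment_3d(sv$vol, scale = 7.7, voxel_size = vox)
  expect_equal(nrow(rois$table), 2)
  expect_true(abs(diff(sort(rois$table$x))) > 5)
})

test_that("neuron size statistics use the equivalent spherical diameter", {
  # single sphere: diameter recovered, sem 0
  one <- neuron_size_stats(8)
  expect_equal(one$mean, 8)
  expect_equal(one$sem, 0)
  # sampling oracle: N(7.7, 0.5^2), n = 100
  set.seed(5)
  diam <- rnorm(100, 7.7, 0.5)
  st <- neuron_size_stats(diam)
  expect_lt(abs(st$mean - 7.7), 2 * st$sem + 1e-12)
  expect_equal(st$sem, sd(diam) / 10)
  # a unit-voxel ROI has the closed-form equivalent diameter
  labs <- array(0L, c(5, 5, 5)); labs[3, 3, 3] <- 1L
  rs <- structure(list(labels = labs,
                       table = data.frame(label = 1L, n_vox = 1L, x = 0, y = 0,
                                          z = 0,
                                          equivalent_diameter = (6 / pi)^(1 / 3)),
                       voxel_size = c(1, 1, 1)), class = "roi_set")
  expect_equal(neuron_size_stats(rs)$mean, (6 / pi)^(1 / 3))
})

test_that("spike detection finds template spikes and respects polarity", {
  expect_error(detect_spikes(rep(0, 3)), "too short")
  flat <- rnorm(500, sd = 0) + 5
  expect_length(detect_spikes(flat, polarity = -1), 0)
  set.seed(9)
  n <- 1000
  spikes <- sort(sample(30:970, 10))
  kern <- exp(-(0:8) / 2) - exp(-(0:8) / 0.5); kern <- kern / max(kern)
  x <- rnorm(n, sd = 0.01)
  for (s in spikes) {
    idx <- s:(s + 8)
    x[idx] <- x[idx] - 0.2 * kern
  }
  det <- detect_spikes(x, k = 4, polarity = -1)
  expect_equal(spike_f1(det, spikes, tol = 1), 1)
  det_flip <- detect_spikes(-x, k = 4, polarity = 1)
  expect_identical(det, det_flip)
})

test_that("z-scoring is exact and affine-invariant", {
  expect_error(zscore(rep(3, 10)), "variance")
  set.seed(1)
  x <- rnorm(200)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(2.5 * x + 3), z)
  expect_equal(zscore(-2 * x + 1), -z)
})

test_that("a uniform ROI yields uniform weights and clean spike recovery", {
  fx <- synth_roi_pixels(n_pix = 30, Tn = 800, noise_sd = rep(0, 30),
                         seed = 2)
  P <- outer(1 - 0.15 * fx$dff, rep(300, 30)) # identical pixels, no noise
  e <- extract_trace(P, NULL, 500)
  expect_lt(diff(range(e$weights)), 1e-6)
  expect_equal(spike_f1(e$spikes, fx$spikes, tol = 1), 1)
  expect_true(all(e$weights >= 0))
  expect_equal(sum(e$weights), 1)
})

test_that("weighted extraction recovers a noiseless neuron almost perfectly", {
  sim <- one_neuron_sim(duration = 1, z = 25, spike_rate = 5, noise = "none",
                        stroke_y_shift = 0, seed = 13)
  res <- run_pipeline(sim$stream, jitter_correction = FALSE,
                      motion_correction = FALSE)
  expect_equal(nrow(res$rois$table), 1)
  e <- res$traces$entries[[1]]
  cc <- cor(-e$detrended, sim$truth$traces[1, ])
  expect_gte(cc, 0.99)
  expect_true(all(e$weights >= 0))
  expect_equal(sum(e$weights), 1)
})

test_that("overlapping neurons separate into their own spike trains", {
  # two somata 8 um apart with distinct spikes, moderate noise
  neurons <- data.frame(x = c(40, 48), y = c(24, 24), z = c(24, 26),
                        diameter = 7.7, brightness = 3000, polarity = -1)
  scn <- scene(neurons)
  sw <- sweep_config(stroke_y_shift = 0)
  cam <- camera_config(rows = 32, cols = 64)
  vp <- voltage_params(spike_rate = 4, oscillation_amplitude = 0,
                       subthreshold_noise_sd = 0.003, seed = 21)
  vt <- generate_voltage_traces(vp, 2, 1250, 500)
  sim <- render_frames(scn, vt, sweep_trajectory(sw), cam, optical_train(),
                       2.5, seed = 21, noise = "full")
  res <- run_pipeline(sim$stream, jitter_correction = FALSE,
                      motion_correction = FALSE)
  m <- match_to_truth(res, sim$truth)
  expect_true(all(m$matched))
  for (i in 1:2) {
    e <- res$traces$entries[[which(res$traces$summary$label == m$roi[i])]]
    own <- vt$spike_frames[[i]]
    other <- vt$spike_frames[[3 - i]]
    expect_gte(spike_f1(e$spikes, own, tol = 1), 0.9)
    cross <- sum(vapply(e$spikes, function(s) {
      min(abs(other - s)) <= 1 && min(abs(own - s)) > 1
    }, logical(1)))
    expect_lt(cross / max(length(e$spikes), 1), 0.1)
  }
})

test_that("reweighting iterations never degrade spike recovery", {
  # property over 10 seeds on a fast synthetic-ROI fixture
  for (seed in 1:10) {
    fx <- synth_roi_pixels(n_pix = 40, Tn = 1000, n_spikes = 8, seed = seed)
    e <- extract_trace(fx$pixels, NULL, 500)
    f1_first <- spike_f1(e$spike_history[[1]], fx$spikes, tol = 1)
    f1_final <- spike_f1(e$spikes, fx$spikes, tol = 1)
    expect_gte(f1_final, f1_first - 1e-9)
    expect_true(all(e$weights >= 0))
    expect_equal(sum(e$weights), 1)
  }
})

test_that("curation flags duplicates and silent ROIs but keeps the rest", {
  sim <- one_neuron_sim(duration = 1, z = 25, spike_rate = 5,
                        noise = "full", stroke_y_shift = 0, seed = 17)
  res <- run_pipeline(sim$stream, jitter_correction = FALSE,
                      motion_correction = FALSE)
  tr <- res$traces
  expect_true(all(tr$summary$curation == "keep"))
  # duplicate: clone the single entry
  tr2 <- tr
  tr2$entries[[2]] <- tr$entries[[1]]
  tr2$entries[[2]]$snr <- tr$entries[[1]]$snr - 1
  tr2$summary <- rbind(tr$summary, tr$summary)
  tr2$summary$label[2] <- 2L
  cur <- curate(tr2)
  expect_equal(sum(cur$summary$curation == "duplicate"), 1)
  expect_equal(cur$summary$curation[1], "keep")
  # a silent background ROI gets the no-activity flag
  tr3 <- tr
  silent <- tr$entries[[1]]
  set.seed(4)
  silent$detrended <- rnorm(length(silent$detrended), sd = 0.5)
  silent$spikes <- integer(0)
  silent$snr <- NA_real_
  silent$coords <- data.frame(stroke = "down", plane = 1L,
                              row = 1:3, col = 1L)
  silent$weights <- rep(1 / 3, 3)
  tr3$entries[[2]] <- silent
  tr3$summary <- rbind(tr$summary, tr$summary)
  tr3$summary$label[2] <- 2L
  cur3 <- curate(tr3)
  expect_equal(cur3$summary$curation[2], "no-activity")
})

test_that("spike SNR is scale-invariant and matches its construction", {
  set.seed(6)
  n <- 2000
  spikes <- sort(sample(50:1950, 12))
  x <- rnorm(n, sd = 1)
  x[spikes] <- x[spikes] - 5
  snr <- spike_snr(x, spikes, polarity = -1)
  expect_lt(abs(snr - 5), 0.5)
  expect_equal(spike_snr(3 * x, spikes, polarity = -1), snr)
  expect_error(spike_snr(x, integer(0)), "at least one spike")
})

test_that("bleaching fits recover the decay constant", {
  tt <- seq(0, 20, by = 0.02)
  y <- 50 + 200 * exp(-tt / 30)
  f <- fit_bleaching(y, tt)
  expect_lt(abs(f$pooled_tau - 30) / 30, 0.001)
  # noisy ensemble at tau = 72 s, sampled at the 500 Hz plane rate:
  # pooled estimate within 15%
  t5 <- seq(0, 20, by = 1 / 500)
  set.seed(8)
  Y <- t(vapply(1:50, function(i) {
    a <- runif(1, 40, 60); b <- runif(1, 150, 250)
    a + b * exp(-t5 / 72) + rnorm(length(t5), sd = 0.05 * b)
  }, numeric(length(t5))))
  fn <- fit_bleaching(Y, t5)
  expect_lt(abs(fn$pooled_tau - 72) / 72, 0.15)
  ok <- fn$per_cell$flag == "ok"
  expect_gt(mean(ok), 0.8)
  # constant trace: flagged, not an error
  fc <- fit_bleaching(rep(100, length(tt)), tt)
  expect_equal(fc$mean_trace$flag, "no-bleach")
  expect_equal(fc$pooled_tau, Inf)
})
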