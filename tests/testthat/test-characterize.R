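test_that("bead detection finds isolated beads and suppresses close pairs", {
  empty <- array(10, c(24, 24, 12))
  expect_equal(nrow(detect_beads(empty, c(0.2, 0.2, 0.4))), 0)
  bs <- simulate_bead_stack(50, dims = c(96, 96, 40),
                            voxel_size = c(0.2, 0.2, 0.4),
                            min_separation = 2.5, seed = 2)
  cand <- detect_beads(bs$stack, bs$voxel_size, min_separation = 2)
  expect_equal(nrow(cand), 50)
  cand_um <- t(t(cand - 0.5) * bs$voxel_size)
  for (i in 1:50) {
    d <- sqrt(colSums((t(cand_um) - bs$centers[i, ])^2))
    expect_lt(min(d), sqrt(sum(bs$voxel_size^2))) # within one voxel
  }
  # two beads closer than min_separation collapse to one candidate
  two <- simulate_bead_stack(1, dims = c(32, 32, 16),
                             voxel_size = c(0.2, 0.2, 0.4), seed = 3)
  st2 <- two$stack
  ctr <- two$centers[1, ]
  pos <- lapply(1:3, function(a) {
    (seq_len(dim(st2)[a]) - 0.5) * two$voxel_size[a]
  })
  for (k in seq_len(dim(st2)[3])) {
    st2[, , k] <- st2[, , k] + 800 *
      outer(exp(-(pos[[1]] - ctr[1] - 0.8)^2 / (2 * 0.25^2)),
            exp(-(pos[[2]] - ctr[2])^2 / (2 * 0.25^2))) *
      exp(-(pos[[3]] - ctr[3])^2 / (2 * 1^2))
  }
  c2 <- detect_beads(st2, two$voxel_size, min_separation = 2)
  expect_equal(nrow(c2), 1)
})

test_that("Gaussian bead fits recover sigma and error out at the border", {
  bs <- simulate_bead_stack(1, dims = c(48, 48, 32),
                            voxel_size = c(0.1, 0.1, 0.25),
                            sigma = c(0.25, 0.25, 1.0),
                            margin = c(1.4, 1.4, 3.3), seed = 4)
  cand <- detect_beads(bs$stack, bs$voxel_size, min_separation = 1)
  f <- fit_bead(bs$stack, cand[1, ], bs$voxel_size, window = c(1.2, 1.2, 3))
  expect_lt(abs(f$sigma[["y"]] - 0.25) / 0.25, 0.01)
  expect_lt(abs(f$sigma[["x"]] - 0.25) / 0.25, 0.01)
  expect_lt(abs(f$sigma[["z"]] - 1.0) / 1.0, 0.01)
  expect_lt(max(abs(f$center - bs$centers[1, ])), 0.05)
  expect_error(fit_bead(bs$stack, c(2L, 2L, 2L), bs$voxel_size),
               "border")
  # Poisson noise at moderate counts: sigma within 10% over 50 beads
  # separation 5 um guarantees no neighbor enters a (1.5, 1.5, 4) um
  # fit window (contamination needs a 3D distance under ~4.4 um)
  bn <- simulate_bead_stack(30, dims = c(160, 160, 64),
                            voxel_size = c(0.2, 0.2, 0.4),
                            sigma = c(0.3, 0.3, 1.0), peak = 2000,
                            noise = "poisson", min_separation = 5,
                            margin = c(2, 2, 4.5), seed = 5)
  cn <- detect_beads(bn$stack, bn$voxel_size, min_separation = 3)
  sig <- vapply(seq_len(nrow(cn)), function(i) {
    f <- tryCatch(fit_bead(bn$stack, cn[i, ], bn$voxel_size,
                           window = c(1.5, 1.5, 4)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else mean(f$sigma[c("y", "x")])
  }, numeric(1))
  expect_gt(sum(!is.na(sig)), 20)
  expect_lt(abs(mean(sig, na.rm = TRUE) - 0.3) / 0.3, 0.1)
})

test_that("aligned upsampled averaging removes subvoxel smearing", {
  vox <- c(0.4, 0.4, 0.4)
  dims <- c(28, 28, 28)
  sigma <- c(0.35, 0.35, 0.35)
  pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * vox[a])
  mk <- function(ctr) {
    v <- array(0, dims)
    gz <- exp(-(pos[[3]] - ctr[3])^2 / (2 * sigma[3]^2))
    blk <- outer(exp(-(pos[[1]] - ctr[1])^2 / (2 * sigma[1]^2)),
                 exp(-(pos[[2]] - ctr[2])^2 / (2 * sigma[2]^2)))
    for (k in which(gz > 1e-8)) v[, , k] <- 500 * blk * gz[k]
    v
  }
  width_of <- function(psf, vs) {
    prof <- apply(psf, 2, sum)
    p <- (seq_along(prof) - 0.5) * vs
    flipr:::fit_gauss_1d(p, prof)$sigma
  }
  # identical, voxel-centered beads: average equals any single crop
  ctr0 <- c(5.4, 5.4, 5.4) # voxel center (index 14)
  stack1 <- mk(ctr0)
  f0 <- fit_bead(stack1, round(ctr0 / vox + 0.5), vox, window = c(2, 2, 2))
  av1 <- average_psf(stack1, list(f0), vox, upsample = 4, window = c(2, 2, 2))
  expect_equal(av1$n, 1)
  w_single <- width_of(av1$psf, av1$voxel_size[2])
  # beads at uniform subvoxel offsets: aligned averaging keeps the width;
  # unaligned averaging smears it by the offset variance (analytic oracle)
  offsets <- seq(-0.45, 0.45, length.out = 7) * vox[2]
  stacks <- lapply(offsets, function(o) mk(ctr0 + c(0, o, 0)))
  fits <- lapply(stacks, function(s) {
    fit_bead(s, round(ctr0 / vox + 0.5), vox, window = c(2, 2, 2))
  })
  avg_of <- function(align) {
    Reduce(`+`, lapply(seq_along(stacks), function(i) {
      average_psf(stacks[[i]], fits[i], vox, upsample = 4,
                  window = c(2, 2, 2), align = align)$psf
    })) / length(stacks)
  }
  up_vs <- vox[2] / 4
  w_aligned <- width_of(avg_of(TRUE), up_vs)
  w_unaligned <- width_of(avg_of(FALSE), up_vs)
  expect_lt(abs(w_aligned - w_single) / w_single, 0.02)
  w_pred <- sqrt(w_single^2 + mean(offsets^2))
  expect_gt(w_unaligned, w_aligned)
  expect_lt(abs(w_unaligned - w_pred) / w_pred, 0.02)
})

test_that("resolution and intensity reports summarize fits per z-bin", {
  mkfit <- function(z, s, peak = 1) {
    structure(list(center = c(y = 1, x = 1, z = z),
                   sigma = c(y = s, x = s, z = 3 * s),
                   peak = peak, residual = 0,
                   center_vox = c(1L, 1L, 1L)), class = "bead_fit")
  }
  fits <- list(mkfit(2, 0.225), mkfit(3, 0.225), mkfit(7, 0.45))
  rep <- resolution_report(fits, z_bin_width = 5)
  expect_equal(rep$fwhm_lateral[1], 2 * sqrt(2 * log(2)) * 0.225)
  expect_equal(round_half_up(rep$fwhm_lateral[1], 2), 0.53)
  expect_equal(rep$fwhm_lateral[2] / rep$fwhm_lateral[1], 2)
  expect_warning(resolution_report(list(mkfit(2, 0.2), mkfit(12, 0.2)),
                                   z_bin_width = 5), "empty")
  # intensity: uniform peaks give a flat curve at exactly 1
  iu <- intensity_vs_z(list(mkfit(2, 0.2, 5), mkfit(7, 0.2, 5),
                            mkfit(12, 0.2, 5)), z_bin_width = 5)
  expect_true(all(iu$intensity == 1))
  expect_equal(max(iu$intensity), 1)
  # Gaussian axial falloff: recovered 80%-width within 5%
  sd_true <- 30
  zs <- rep(seq(2.5, 97.5, by = 5), each = 8)
  fits2 <- lapply(zs, function(z) {
    mkfit(z, 0.2, peak = exp(-(z - 50)^2 / (2 * sd_true^2)))
  })
  curve <- intensity_vs_z(fits2, z_bin_width = 5)
  above <- curve$z_center[curve$intensity >= 0.8]
  w80 <- max(above) - min(above) + 5
  w80_true <- 2 * sd_true * sqrt(-2 * log(0.8))
  expect_lt(abs(w80 - w80_true) / w80_true, 0.05)
})

test_that("the contrast metric prefers focus and ignores global scaling", {
  expect_equal(contrast_metric(matrix(7, 32, 32)), 0)
  set.seed(10)
  img <- matrix(10, 48, 48)
  for (k in 1:8) {
    cy <- runif(1, 10, 38); cx <- runif(1, 10, 38)
    img <- img + 300 * outer(exp(-((1:48) - cy)^2 / 2),
                             exp(-((1:48) - cx)^2 / 2))
  }
  c0 <- contrast_metric(img)
  W <- flipr:::gauss_matrix(48, 1)
  blur1 <- W %*% img %*% t(W)
  expect_gt(c0, contrast_metric(blur1))
  W3 <- flipr:::gauss_matrix(48, 3)
  expect_gt(contrast_metric(blur1), contrast_metric(W3 %*% img %*% t(W3)))
  expect_equal(contrast_metric(img * 5), c0, tolerance = 1e-10)
})

test_that("light-sheet calibration recovers the simulated linear map", {
  focal <- seq(5, 45, length.out = 10)
  offsets <- seq(0, 60, by = 2)
  imgs <- simulate_calibration_sweep(focal, offsets, slope = 1.1,
                                     intercept = 3, seed = 6)
  cal <- calibrate_lightsheet(imgs, focal, offsets)
  expect_lt(abs(cal$slope - 1.1) / 1.1, 0.02)
  expect_lt(abs(cal$intercept - 3), 0.5)
  # perfect calibration comes out as the identity map
  imgs0 <- simulate_calibration_sweep(focal, seq(0, 50, by = 2), slope = 1,
                                      intercept = 0, seed = 7)
  cal0 <- calibrate_lightsheet(imgs0, focal, seq(0, 50, by = 2))
  expect_lt(abs(cal0$slope - 1), 0.02)
  expect_lt(abs(cal0$intercept), 0.5)
  # residuals on a truly linear relation stay at sub-sample size
  expect_lt(max(abs(cal0$residuals)), 1)
  # two focal planes: exact line through both refined points
  cal2 <- calibrate_lightsheet(imgs[c(2, 9)], focal[c(2, 9)], offsets)
  expect_equal(cal2$slope * focal[2] + cal2$intercept,
               cal2$best_offset$best_sheet[1])
  expect_error(calibrate_lightsheet(imgs[1], focal[1], offsets), ">= 2")
})

test_that("the actuator phase lag is recovered by contrast maximization", {
  # beads spread throughout z: a sparse sample aligned to the plane grid
  # would bias the contrast optimum toward grid-concentrating phases
  set.seed(2)
  n <- 15
  neurons <- data.frame(x = runif(n, 10, 86), y = runif(n, 8, 52),
                        z = runif(n, 6, 44), diameter = 2,
                        brightness = 4000, polarity = -1)
  scn <- scene(neurons, bleach_tau = 1e6)
  cam <- camera_config(rows = 40, cols = 64)
  vp <- voltage_params(spike_rate = 0, oscillation_amplitude = 0,
                       subthreshold_noise_sd = 0)
  vt <- generate_voltage_traces(vp, n, 100, 500)
  acquire_with_lag <- function(true_lag) {
    sw <- sweep_config(phase_lag = true_lag, stroke_y_shift = 0)
    function(ph) {
      traj <- sweep_trajectory(sw, sheet_phase = ph)
      render_frames(scn, vt, traj, cam, optical_train(), 0.05,
                    noise = "none")$stream
    }
  }
  est <- estimate_phase_lag(acquire_with_lag(0.1),
                            phase_grid = seq(-0.25, 0.25, by = 0.05))
  expect_lt(abs(est$phase_lag - 0.1), 0.02)
  est0 <- estimate_phase_lag(acquire_with_lag(0),
                             phase_grid = seq(-0.25, 0.25, by = 0.05))
  expect_lt(abs(est0$phase_lag), 0.05)
  # the estimate is defined modulo 2 pi
  acq <- acquire_with_lag(0.1)
  est_wrap <- estimate_phase_lag(function(ph) acq(ph - 2 * pi),
                                 phase_grid = seq(-0.25, 0.25, by = 0.05) +
                                   2 * pi)
  expect_lt(abs(est_wrap$phase_lag - 0.1), 0.05)
})

test_that("bead characterization closes the loop with the renderer PSF model", {
  sig <- psf_sigmas(0.546, 0.8, 1.333)
  bs <- simulate_bead_stack(30, dims = c(128, 128, 60),
                            voxel_size = c(0.1, 0.1, 0.3),
                            sigma = c(sig[["lateral"]], sig[["lateral"]],
                                      sig[["axial"]]),
                            peak = 2000, noise = "poisson",
                            min_separation = 2, margin = c(1.2, 1.2, 4.3),
                            seed = 12)
  cand <- detect_beads(bs$stack, bs$voxel_size, min_separation = 1.5)
  fits <- list()
  for (i in seq_len(nrow(cand))) {
    f <- tryCatch(fit_bead(bs$stack, cand[i, ], bs$voxel_size,
                           window = c(1, 1, 4)),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  expect_gt(length(fits), 10)
  rep <- resolution_report(fits, z_bin_width = 20)
  fw <- 2 * sqrt(2 * log(2))
  expect_lt(abs(median(rep$fwhm_lateral) - fw * sig[["lateral"]]) /
              (fw * sig[["lateral"]]), 0.05)
})
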