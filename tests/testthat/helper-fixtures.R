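# Shared fixtures, built in code and memoized per test run.

# Small default acquisition with full noise (5 neurons, 1 s, 32 x 64 px).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_acquisition(n_neurons = 5, duration = 1,
                                     rows = 32, cols = 64, seed = 7)
    }
    cache
  }
})

# Noiseless single-neuron acquisition for geometric checks.
one_neuron_sim <- function(rows = 32, cols = 64, duration = 1,
                           stroke_y_shift = 6.5, z = 25, seed = 3,
                           spike_rate = 4, noise = "none") {
  neurons <- data.frame(x = cols * 1.5 / 2, y = rows * 1.5 / 2, z = z,
                        diameter = 7.7, brightness = 3000, polarity = -1)
  scn <- scene(neurons)
  sw <- sweep_config(stroke_y_shift = stroke_y_shift)
  cam <- camera_config(rows = rows, cols = cols)
  vp <- voltage_params(spike_rate = spike_rate, oscillation_amplitude = 0,
                       oscillating_fraction = 0, subthreshold_noise_sd = 0,
                       seed = seed)
  n_periods <- ceiling(duration * sw$volume_rate)
  vt <- generate_voltage_traces(vp, 1, n_periods, sw$volume_rate)
  sim <- render_frames(scn, vt, sweep_trajectory(sw), cam, optical_train(),
                       duration, seed = seed, noise = noise)
  sim$voltage <- vt
  sim
}

# Volume of Gaussian-profile spheres on a voxel grid (for segmentation).
sphere_volume <- function(centers, diameter = 7.7,
                          dims = c(48, 96, 16),
                          voxel_size = c(1.5, 1.5, 3.125),
                          peak = 500, background = 10) {
  vol <- array(background, dims)
  pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_size[a])
  s <- diameter / 4
  for (i in seq_len(nrow(centers))) {
    gy <- exp(-(pos[[1]] - centers[i, 1])^2 / (2 * s^2))
    gx <- exp(-(pos[[2]] - centers[i, 2])^2 / (2 * s^2))
    gz <- exp(-(pos[[3]] - centers[i, 3])^2 / (2 * s^2))
    for (k in which(gz > 1e-4)) {
      vol[, , k] <- vol[, , k] + peak * outer(gy, gx) * gz[k]
    }
  }
  list(vol = vol, voxel_size = voxel_size, centers = centers)
}

# Spike-train F1 with +/- tol frame matching (greedy).
spike_f1 <- function(detected, truth, tol = 1) {
  if (!length(truth)) return(if (!length(detected)) 1 else 0)
  if (!length(detected)) return(0)
  used <- logical(length(detected))
  tp <- 0
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) { tp <- tp + 1; used[j] <- TRUE }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Synthetic ROI pixel matrix: per-pixel amplitude profile times a spiking
# dF/F trace plus noise (fast extraction fixture, no rendering).
synth_roi_pixels <- function(n_pix = 40, Tn = 1000, rate = 500,
                             n_spikes = 8, amp = 0.15, base = 300,
                             noise_sd = NULL, polarity = -1, seed = 1) {
  set.seed(seed)
  spikes <- sort(sample(20:(Tn - 20), n_spikes))
  kern <- exp(-(0:10) / 2) - exp(-(0:10) / 0.5)
  kern <- kern / max(kern)
  dff <- numeric(Tn)
  for (s in spikes) {
    idx <- s:min(Tn, s + 10)
    dff[idx] <- dff[idx] + amp * kern[seq_along(idx)]
  }
  prof <- base * exp(-((seq_len(n_pix) - n_pix / 2)^2) / (2 * (n_pix / 4)^2))
  P <- outer(1 + polarity * dff, prof)
  if (is.null(noise_sd)) noise_sd <- sqrt(prof) # shot-like
  P <- P + matrix(rnorm(Tn * n_pix), Tn, n_pix) %*% diag(noise_sd)
  list(pixels = P, spikes = spikes, dff = dff, profile = prof)
}
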