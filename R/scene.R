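#' Synthetic imaging scene
#'
#' Describes the fluorescent content of the simulated volume: neuron somata
#' (Gaussian blobs of the given diameter), a uniform fluorescent background,
#' photobleaching, the light-sheet thickness, and the (possibly wrong)
#' linear calibration mapping the focus position to the light-sheet position.
#'
#' @param neurons A data.frame with columns `x`, `y`, `z` (um), `diameter`
#'   (um), `brightness` (expected peak photon counts per frame at t = 0), and
#'   `polarity` (+1 or -1; the sign of the fluorescence response to
#'   depolarization, -1 for negative-going voltage sensors).
#' @param background_level Uniform background fluorescence, photons per pixel
#'   per frame.
#' @param bleach_tau Photobleaching time constant in seconds (all
#'   fluorescence decays as `exp(-t / bleach_tau)`).
#' @param lightsheet_width_1e2 1/e^2 full width of the light sheet, um.
#' @param calibration_slope,calibration_intercept Linear map placing the
#'   light sheet at `slope * z_focus + intercept` um; (1, 0) is a perfect
#'   calibration.
#' @return An object of class `scene`.
#' @export
scene <- function(neurons,
                  background_level = 10,
                  bleach_tau = 72,
                  lightsheet_width_1e2 = 3.4,
                  calibration_slope = 1,
                  calibration_intercept = 0) {
  stopifnot(is.data.frame(neurons))
  need <- c("x", "y", "z", "diameter", "brightness", "polarity")
  missing <- setdiff(need, names(neurons))
  if (length(missing)) {
    stop("scene: neurons is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(neurons$diameter <= 0)) stop("scene: diameters must be positive")
  if (!all(neurons$polarity %in% c(-1, 1))) {
    stop("scene: polarity must be +1 or -1")
  }
  if (bleach_tau <= 0) stop("scene: bleach_tau must be positive")
  structure(list(
    neurons = neurons,
    background_level = background_level,
    bleach_tau = bleach_tau,
    lightsheet_width_1e2 = lightsheet_width_1e2,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept
  ), class = "scene")
}

#' Randomly placed neurons with a minimum separation
#'
#' Draws neuron centers uniformly inside the given bounds with a hard
#' minimum pairwise separation (dart throwing), diameters from a normal
#' distribution around the 7.7 um soma scale of larval zebrafish spinal
#' neurons, and constant brightness and polarity.
#'
#' @param n Number of neurons.
#' @param x_range,y_range,z_range Length-2 numeric bounds in um.
#' @param diameter_mean,diameter_sd Soma diameter distribution, um.
#' @param brightness Expected peak photon counts per frame.
#' @param polarity Fluorescence response sign (-1 default).
#' @param min_separation Minimum center-to-center distance, um.
#' @param seed Optional RNG seed.
#' @return A neurons data.frame suitable for [scene()].
#' @export
random_neurons <- function(n,
                           x_range, y_range, z_range,
                           diameter_mean = 7.7, diameter_sd = 0.5,
                           brightness = 3000, polarity = -1,
                           min_separation = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < n) {
    p <- c(stats::runif(1, x_range[1], x_range[2]),
           stats::runif(1, y_range[1], y_range[2]),
           stats::runif(1, z_range[1], z_range[2]))
    ok <- TRUE
    if (nrow(centers) > 0) {
      d2 <- colSums((t(centers) - p)^2)
      ok <- all(d2 >= min_separation^2)
    }
    if (ok) centers <- rbind(centers, p)
    tries <- tries + 1L
    if (tries > 20000L) {
      stop("random_neurons: could not place ", n, " neurons with separation ",
           min_separation, " um in the given bounds")
    }
  }
  data.frame(
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    diameter = pmax(3, stats::rnorm(n, diameter_mean, diameter_sd)),
    brightness = rep(brightness, n),
    polarity = rep(polarity, n)
  )
}

#' Voltage-dynamics parameters
#'
#' Phenomenological model of spinal-neuron membrane-voltage fluorescence:
#' Poisson spikes convolved with a fast difference-of-exponentials kernel, a
#' sinusoidal-burst oscillation (fictive-swimming-like rhythm) carried by a
#' fraction of neurons, and Gaussian subthreshold noise, all in dF/F units.
#'
#' @param spike_rate Spike rate per neuron, Hz.
#' @param spike_amplitude Peak spike amplitude, |dF/F|.
#' @param spike_rise,spike_decay Kernel rise/decay time constants, ms.
#' @param oscillation_freq Oscillation frequency, Hz.
#' @param oscillation_amplitude Oscillation amplitude, |dF/F|.
#' @param oscillating_fraction Fraction of neurons carrying the oscillation.
#' @param burst_rate Rate of oscillation bursts, Hz.
#' @param burst_duration Duration of each burst, s.
#' @param subthreshold_noise_sd Subthreshold fluctuation sd, dF/F. Modelled
#'   as an Ornstein-Uhlenbeck process with correlation time
#'   `subthreshold_tau` (membrane filtering makes subthreshold voltage
#'   band-limited, not white at the sampling rate).
#' @param subthreshold_tau Correlation time of the subthreshold process, s.
#' @param seed Integer RNG seed for reproducibility.
#' @return An object of class `voltage_params`.
#' @export
voltage_params <- function(spike_rate = 3,
                           spike_amplitude = 0.15,
                           spike_rise = 1,
                           spike_decay = 4,
                           oscillation_freq = 20,
                           oscillation_amplitude = 0.08,
                           oscillating_fraction = 0.4,
                           burst_rate = 0.5,
                           burst_duration = 0.8,
                           subthreshold_noise_sd = 0.01,
                           subthreshold_tau = 0.02,
                           seed = 1L) {
  if (spike_rate < 0 || oscillation_freq < 0 || burst_rate < 0) {
    stop("voltage_params: rates must be >= 0")
  }
  if (!all(is.finite(c(spike_amplitude, oscillation_amplitude,
                       subthreshold_noise_sd)))) {
    stop("voltage_params: amplitudes must be finite")
  }
  structure(list(
    spike_rate = spike_rate, spike_amplitude = spike_amplitude,
    spike_rise = spike_rise, spike_decay = spike_decay,
    oscillation_freq = oscillation_freq,
    oscillation_amplitude = oscillation_amplitude,
    oscillating_fraction = oscillating_fraction,
    burst_rate = burst_rate, burst_duration = burst_duration,
    subthreshold_noise_sd = subthreshold_noise_sd,
    subthreshold_tau = subthreshold_tau,
    seed = as.integer(seed)
  ), class = "voltage_params")
}

# Difference-of-exponentials spike kernel sampled at dt, peak-normalized.
spike_kernel <- function(rise_ms, decay_ms, dt) {
  tau_r <- rise_ms / 1000
  tau_d <- decay_ms / 1000
  tmax <- 6 * tau_d
  tt <- seq(0, tmax, by = dt)
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  if (max(k) <= 0) k <- exp(-tt / tau_d) # degenerate rise >= decay
  k / max(k)
}

#' Generate ground-truth voltage fluorescence traces
#'
#' @param params A [voltage_params()].
#' @param n_neurons Number of neurons.
#' @param n_frames_per_plane Samples per plane time series (one per sweep
#'   period).
#' @param plane_rate Sampling rate of each plane series, Hz (the volume
#'   rate).
#' @return A list with `traces` (`n_neurons x n_frames_per_plane` dF/F
#'   matrix), `spike_frames` (list of true spike sample indices), and
#'   `oscillating` (logical vector).
#' @export
generate_voltage_traces <- function(params, n_neurons,
                                    n_frames_per_plane, plane_rate) {
  stopifnot(inherits(params, "voltage_params"))
  if (plane_rate <= 0) stop("generate_voltage_traces: plane_rate must be > 0")
  set.seed(params$seed)
  dt <- 1 / plane_rate
  tt <- (seq_len(n_frames_per_plane) - 1) * dt
  kern <- spike_kernel(params$spike_rise, params$spike_decay, dt)
  nk <- length(kern)
  n_osc <- round(params$oscillating_fraction * n_neurons)
  oscillating <- seq_len(n_neurons) <= n_osc
  traces <- matrix(0, n_neurons, n_frames_per_plane)
  spike_frames <- vector("list", n_neurons)
  duration <- n_frames_per_plane * dt
  for (i in seq_len(n_neurons)) {
    x <- numeric(n_frames_per_plane)
    n_spk <- stats::rpois(1, params$spike_rate * duration)
    if (n_spk > 0 && params$spike_amplitude != 0) {
      at <- sort(sample.int(n_frames_per_plane, min(n_spk, n_frames_per_plane)))
      for (s in at) {
        idx <- s:min(n_frames_per_plane, s + nk - 1L)
        x[idx] <- x[idx] + params$spike_amplitude * kern[seq_along(idx)]
      }
      spike_frames[[i]] <- at
    } else {
      spike_frames[[i]] <- integer(0)
    }
    if (oscillating[i] && params$oscillation_amplitude != 0 &&
        params$oscillation_freq > 0) {
      env <- numeric(n_frames_per_plane)
      n_burst <- stats::rpois(1, max(params$burst_rate * duration, 0)) + 1L
      starts <- stats::runif(n_burst, 0, max(duration - params$burst_duration, 0))
      for (b in starts) {
        inb <- tt >= b & tt < b + params$burst_duration
        # raised-cosine ramped envelope
        u <- (tt[inb] - b) / params$burst_duration
        env[inb] <- pmax(env[inb], sin(pi * u)^2)
      }
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + params$oscillation_amplitude * env *
        sin(2 * pi * params$oscillation_freq * tt + phase)
    }
    if (params$subthreshold_noise_sd > 0) {
      a <- exp(-dt / max(params$subthreshold_tau, dt / 10))
      eps <- stats::rnorm(n_frames_per_plane)
      ou <- as.numeric(stats::filter(eps * sqrt(1 - a^2), a,
                                     method = "recursive"))
      x <- x + params$subthreshold_noise_sd * ou
    }
    traces[i, ] <- x
  }
  list(traces = traces, spike_frames = spike_frames,
       oscillating = oscillating, plane_rate = plane_rate, time = tt)
}
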