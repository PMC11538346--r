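#' Optical train of a flipped-image remote-focusing microscope
#'
#' Bundles the parameters of the detection / remote-focusing path: the primary
#' (sample-side) objective, the remote objective, their tube lenses, immersion
#' media, and the miniature retroreflector that folds the remote image.
#' Defaults reproduce a 16x/0.8 NA water-dipping primary objective with a
#' 200 mm tube lens, a 20x air remote objective behind a 124 mm effective tube
#' lens, and a retroreflector built from two 0.5 mm right-angle prisms.
#'
#' @param obj_mag_primary Nominal magnification of the primary objective.
#' @param reference_tube_length_primary Reference tube length (mm) the primary
#'   objective's magnification is specified against (manufacturer convention,
#'   200 mm for Nikon/Olympus infinity objectives).
#' @param f_tube_primary Focal length (mm) of the primary tube lens actually used.
#' @param obj_mag_remote,reference_tube_length_remote,f_tube_remote Same three
#'   quantities for the remote arm.
#' @param n_primary Refractive index of the primary immersion medium (water).
#' @param n_remote Refractive index of the remote immersion medium (air).
#' @param na_primary Numerical aperture of the primary objective.
#' @param retro_aperture Clear aperture (mm) of the retroreflector, i.e. the
#'   prism size; limits the usable field along the flip axis.
#' @param retro_opening_angle Opening angle (degrees) between the two mirror
#'   faces of the retroreflector (90 for right-angle prisms).
#' @param emission_wavelength Fluorescence emission wavelength (um).
#' @return An object of class `optical_train` (a validated list).
#' @examples
#' tr <- optical_train()
#' lateral_magnification(tr)
#' @export
optical_train <- function(obj_mag_primary = 16,
                          reference_tube_length_primary = 200,
                          f_tube_primary = 200,
                          obj_mag_remote = 20,
                          reference_tube_length_remote = 200,
                          f_tube_remote = 124,
                          n_primary = 1.333,
                          n_remote = 1.000,
                          na_primary = 0.8,
                          retro_aperture = 0.5,
                          retro_opening_angle = 90,
                          emission_wavelength = 0.546) {
  train <- list(
    obj_mag_primary = obj_mag_primary,
    reference_tube_length_primary = reference_tube_length_primary,
    f_tube_primary = f_tube_primary,
    obj_mag_remote = obj_mag_remote,
    reference_tube_length_remote = reference_tube_length_remote,
    f_tube_remote = f_tube_remote,
    n_primary = n_primary,
    n_remote = n_remote,
    na_primary = na_primary,
    retro_aperture = retro_aperture,
    retro_opening_angle = retro_opening_angle,
    emission_wavelength = emission_wavelength
  )
  lengths <- c("obj_mag_primary", "reference_tube_length_primary",
               "f_tube_primary", "obj_mag_remote",
               "reference_tube_length_remote", "f_tube_remote",
               "n_primary", "n_remote", "retro_aperture",
               "emission_wavelength")
  for (f in lengths) {
    v <- train[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("optical_train: field '", f, "' must be a positive finite scalar")
    }
  }
  if (na_primary <= 0 || na_primary > n_primary) {
    stop("optical_train: need 0 < na_primary <= n_primary")
  }
  if (retro_opening_angle <= 0 || retro_opening_angle >= 180) {
    stop("optical_train: retro_opening_angle must lie in (0, 180) degrees")
  }
  structure(train, class = "optical_train")
}

#' @export
print.optical_train <- function(x, ...) {
  cat("<optical_train>\n")
  cat(sprintf("  primary: %gx / ref %g mm, tube %g mm, n = %g, NA = %g\n",
              x$obj_mag_primary, x$reference_tube_length_primary,
              x$f_tube_primary, x$n_primary, x$na_primary))
  cat(sprintf("  remote:  %gx / ref %g mm, tube %g mm, n = %g\n",
              x$obj_mag_remote, x$reference_tube_length_remote,
              x$f_tube_remote, x$n_remote))
  cat(sprintf("  retroreflector: %g mm aperture, %g deg opening\n",
              x$retro_aperture, x$retro_opening_angle))
  cat(sprintf("  lateral magnification M = %.4f\n", lateral_magnification(x)))
  invisible(x)
}

#' Focal length of an infinity-corrected objective
#'
#' Standard convention: an objective labelled `mag`x against a reference tube
#' length of `reference_tube_length` mm has focal length
#' `reference_tube_length / mag`.
#'
#' @param mag Nominal magnification (> 0).
#' @param reference_tube_length Reference tube length in mm (> 0).
#' @return Focal length in mm.
#' @examples
#' objective_focal_length(16, 200) # 12.5 mm
#' @export
objective_focal_length <- function(mag, reference_tube_length) {
  if (any(mag <= 0) || any(reference_tube_length <= 0)) {
    stop("objective_focal_length: inputs must be positive")
  }
  reference_tube_length / mag
}

#' Lateral magnification of the remote-focusing relay
#'
#' The sample-to-remote-image magnification is the product of the primary
#' magnification (tube over objective focal length) and the inverse remote
#' magnification. Remote focusing is aberration-free when this equals the
#' refractive-index ratio of the two immersion media
#' (see [ideal_remote_magnification()]); a non-standard remote tube lens
#' focal length is the design knob used to approach it.
#'
#' @param train An [optical_train()].
#' @return Dimensionless magnification M.
#' @examples
#' lateral_magnification(optical_train()) # 1.2903, i.e. M = 1.29
#' @export
lateral_magnification <- function(train) {
  stopifnot(inherits(train, "optical_train"))
  f_obj_primary <- objective_focal_length(train$obj_mag_primary,
                                          train$reference_tube_length_primary)
  f_obj_remote <- objective_focal_length(train$obj_mag_remote,
                                         train$reference_tube_length_remote)
  (train$f_tube_primary / f_obj_primary) * (f_obj_remote / train$f_tube_remote)
}

#' Ideal remote-focusing magnification
#'
#' Aberration-free refocusing requires the angular magnification between
#' sample and remote space to equal `n1 / n2`, the ratio of the immersion
#' refractive indices of the primary and remote objectives.
#'
#' @param n1 Refractive index on the sample side (e.g. 1.333 for water).
#' @param n2 Refractive index on the remote side (e.g. 1.000 for air).
#' @return `n1 / n2`.
#' @examples
#' ideal_remote_magnification(1.333, 1.000) # 1.333, i.e. M = 1.33
#' @export
ideal_remote_magnification <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("ideal_remote_magnification: indices must be positive")
  }
  n1 / n2
}

#' Effective NA limit imposed by the retroreflector
#'
#' A retroreflector with opening angle `theta` only returns rays within
#' `theta / 2` of its symmetry axis, so with unit angular magnification the
#' usable NA of the primary objective along that axis is limited to
#' `n * sin(theta / 2)`. For the 90 degree prism pair this is `0.707 n`,
#' i.e. NA < 0.7 n.
#'
#' @param n Refractive index of the primary immersion medium.
#' @param opening_angle Opening angle of the retroreflector in degrees.
#' @return Maximum usable NA along the folded axis.
#' @examples
#' retroreflector_na_limit(1.0, 90) # 0.7071
#' @export
retroreflector_na_limit <- function(n, opening_angle) {
  if (any(n <= 0)) stop("retroreflector_na_limit: n must be positive")
  if (any(opening_angle <= 0) || any(opening_angle > 180)) {
    stop("retroreflector_na_limit: opening_angle must lie in (0, 180]")
  }
  n * sin(opening_angle / 2 * pi / 180)
}

#' Accessible field of view along the image-flip axis
#'
#' The retroreflector aperture, referred back to sample space by the lateral
#' magnification, limits the field of view along the axis across which the
#' image is flipped (x).
#'
#' @param train An [optical_train()].
#' @return Field of view in um at the sample.
#' @examples
#' sample_fov_x(optical_train()) # 387.5 um, i.e. ~388 um
#' @export
sample_fov_x <- function(train) {
  stopifnot(inherits(train, "optical_train"))
  train$retro_aperture / lateral_magnification(train) * 1000
}

#' Rayleigh length of a Gaussian light sheet
#'
#' For a Gaussian beam with 1/e^2 intensity full width `width_1e2` (waist
#' radius `w0 = width_1e2 / 2`), the Rayleigh length is `pi * w0^2 / lambda`.
#'
#' @param width_1e2 1/e^2 full width of the sheet at the waist, um.
#' @param wavelength Excitation wavelength, um.
#' @return Rayleigh length in um.
#' @examples
#' rayleigh_length(3.4, 0.532) # 17.07 um
#' @export
rayleigh_length <- function(width_1e2, wavelength) {
  if (any(width_1e2 <= 0) || any(wavelength <= 0)) {
    stop("rayleigh_length: inputs must be positive")
  }
  pi * (width_1e2 / 2)^2 / wavelength
}

#' Axial range swept by a single camera frame
#'
#' With the focus moving continuously, each frame integrates over
#' `z_range / planes_per_sweep` um of the volume (the rolling shutter spreads
#' this across rows, tilting the optical plane).
#'
#' @param z_range Full axial sweep range in um.
#' @param planes_per_sweep Number of frames per one-directional sweep.
#' @return z extent per plane in um.
#' @examples
#' plane_z_extent(50, 8) # 6.25 um
#' @export
plane_z_extent <- function(z_range, planes_per_sweep) {
  if (any(planes_per_sweep < 1)) {
    stop("plane_z_extent: planes_per_sweep must be >= 1")
  }
  z_range / planes_per_sweep
}

#' Camera trigger rate for a given volume rate
#'
#' @param volume_rate Volume sweep rate in Hz (one triangle period per volume).
#' @param frames_per_period Frames acquired per sweep period.
#' @return Frame trigger rate in Hz.
#' @examples
#' trigger_rate(500, 16) # 8000 Hz
#' @export
trigger_rate <- function(volume_rate, frames_per_period) {
  if (any(volume_rate <= 0) || any(frames_per_period <= 0)) {
    stop("trigger_rate: inputs must be positive")
  }
  volume_rate * frames_per_period
}

#' Gaussian approximation of the detection PSF
#'
#' Widely used Gaussian stand-in for the widefield PSF:
#' `sigma_lateral = 0.21 * lambda / NA` and
#' `sigma_axial = 0.75 * n * lambda / NA^2`. The constants are the standard
#' least-squares Gaussian matches to the paraxial Airy/axial profiles; they
#' parameterize the renderer only and make no claim about measured optics.
#'
#' @param wavelength Emission wavelength, um.
#' @param na Numerical aperture (0 < na <= n).
#' @param n Refractive index of the immersion medium.
#' @return Named vector `c(lateral = , axial = )` in um.
#' @examples
#' psf_sigmas(0.546, 0.8, 1.333)
#' @export
psf_sigmas <- function(wavelength, na, n) {
  if (any(wavelength <= 0)) stop("psf_sigmas: wavelength must be positive")
  if (any(na <= 0) || any(na > n)) stop("psf_sigmas: need 0 < na <= n")
  c(lateral = 0.21 * wavelength / na,
    axial = 0.75 * n * wavelength / na^2)
}

#' Round half away from zero
#'
#' Display rounding used for reported design numbers (round-half-up, unlike
#' base R's round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derived design quantities of an optical train
#'
#' Computes every closed-form design number for a given train and sweep
#' timing: objective focal lengths, lateral and ideal magnification, the
#' retroreflector NA limit, the accessible x field of view, the light-sheet
#' Rayleigh length, camera trigger rate, per-plane z extent, and the Gaussian
#' PSF widths used by the simulator.
#'
#' @param train An [optical_train()].
#' @param volume_rate Volume rate in Hz.
#' @param frames_per_period Frames per sweep period.
#' @param z_range Axial sweep range, um.
#' @param lightsheet_width_1e2 1/e^2 width of the light sheet, um.
#' @param excitation_wavelength Excitation wavelength, um.
#' @return A data.frame with columns `quantity`, `value`, `unit`.
#' @examples
#' optics_report(optical_train())
#' @export
optics_report <- function(train,
                          volume_rate = 500,
                          frames_per_period = 16,
                          z_range = 50,
                          lightsheet_width_1e2 = 3.4,
                          excitation_wavelength = 0.532) {
  stopifnot(inherits(train, "optical_train"))
  M <- lateral_magnification(train)
  sig <- psf_sigmas(train$emission_wavelength, train$na_primary,
                    train$n_primary)
  df <- data.frame(
    quantity = c(
      "f_obj_primary", "f_obj_remote",
      "lateral_magnification", "ideal_remote_magnification",
      "retroreflector_na_limit", "sample_fov_x",
      "rayleigh_length", "trigger_rate", "plane_z_extent",
      "psf_sigma_lateral", "psf_sigma_axial",
      "psf_fwhm_lateral"
    ),
    value = c(
      objective_focal_length(train$obj_mag_primary,
                             train$reference_tube_length_primary),
      objective_focal_length(train$obj_mag_remote,
                             train$reference_tube_length_remote),
      M,
      ideal_remote_magnification(train$n_primary, train$n_remote),
      retroreflector_na_limit(train$n_primary, train$retro_opening_angle),
      sample_fov_x(train),
      rayleigh_length(lightsheet_width_1e2, excitation_wavelength),
      trigger_rate(volume_rate, frames_per_period),
      plane_z_extent(z_range, frames_per_period / 2),
      sig[["lateral"]], sig[["axial"]],
      2 * sqrt(2 * log(2)) * sig[["lateral"]]
    ),
    unit = c("mm", "mm", "", "", "", "um", "um", "Hz", "um",
             "um", "um", "um"),
    stringsAsFactors = FALSE
  )
  df
}
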