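# Parameter containers for the instrument model. Plain validated lists with
# S3 classes, in the style of small config objects rather than S4 machinery.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Ultrasound transducer parameters
#'
#' Describes the focused detection transducer by its -6 dB center frequency
#' and fractional bandwidth. The absolute -6 dB bandwidth entering the axial
#' resolution formula is `B = bandwidth_frac * center_frequency_mhz`.
#'
#' @param center_frequency_mhz Center frequency in MHz (default 19).
#' @param bandwidth_frac Fractional -6 dB bandwidth, dimensionless
#'   (default 0.69).
#' @param focal_length_mm Focal length in mm (default 11.6); carried as
#'   metadata only, the forward model treats the transducer as ideally
#'   focused over the volume.
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(center_frequency_mhz = 19,
                            bandwidth_frac = 0.69,
                            focal_length_mm = 11.6) {
  stop_if(center_frequency_mhz <= 0, "center_frequency_mhz must be > 0")
  stop_if(bandwidth_frac <= 0 || bandwidth_frac >= 2,
          "bandwidth_frac must be in (0, 2)")
  structure(list(center_frequency_mhz = center_frequency_mhz,
                 bandwidth_frac = bandwidth_frac,
                 focal_length_mm = focal_length_mm),
            class = "transducer_spec")
}

#' Excitation optics parameters
#'
#' @param wavelength_nm Excitation wavelength in nm (default 532).
#' @param numerical_aperture Effective NA of the objective (default 0.12).
#' @param k_pam_um Single-pass optical attenuation coefficient for the
#'   photoacoustic channel, 1/um. The default 2/431 makes the fitted 1/e^2
#'   penetration depth (depth where intensity reaches `exp(-2)` of its
#'   surface value) equal 431 um.
#' @param k_lscm_um Attenuation for the confocal emulator, 1/um; default
#'   2/262 encodes the steeper effective attenuation of confocal detection.
#' @param psf_fwhm_um Optional lateral PSF full width at half maximum in um.
#'   `NULL` (default) uses the diffraction limit
#'   `0.51 * wavelength / NA` from [theoretical_lateral_resolution()]; the
#'   razor-edge characterization fixture overrides it with the bench-measured
#'   width.
#' @return An object of class `optical_spec`.
#' @export
optical_spec <- function(wavelength_nm = 532,
                         numerical_aperture = 0.12,
                         k_pam_um = 2 / 431,
                         k_lscm_um = 2 / 262,
                         psf_fwhm_um = NULL) {
  stop_if(wavelength_nm <= 0, "wavelength_nm must be > 0")
  stop_if(numerical_aperture <= 0 || numerical_aperture >= 1,
          "numerical_aperture must be in (0, 1)")
  stop_if(k_pam_um < 0 || k_lscm_um < 0, "attenuation must be >= 0")
  stop_if(!is.null(psf_fwhm_um) && psf_fwhm_um <= 0, "psf_fwhm_um must be > 0")
  structure(list(wavelength_nm = wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 k_pam_um = k_pam_um,
                 k_lscm_um = k_lscm_um,
                 psf_fwhm_um = psf_fwhm_um),
            class = "optical_spec")
}

#' Acquisition parameters
#'
#' @param sampling_rate_msps Digitizer rate in megasamples per second
#'   (default 500).
#' @param sound_speed_mps Speed of sound used for the time-to-depth
#'   conversion, m/s (default 1540).
#' @param lateral_step_um Raster scan pitch in um (default 2).
#' @param noise_sigma Additive white Gaussian RF noise, as a fraction of the
#'   peak RF amplitude of the frame (default 0.02); 0 gives a deterministic
#'   forward model.
#' @param rng_seed Integer seed for the noise stream.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate_msps = 500,
                             sound_speed_mps = 1540,
                             lateral_step_um = 2,
                             noise_sigma = 0.02,
                             rng_seed = 1L) {
  stop_if(sound_speed_mps <= 0, "sound_speed_mps must be > 0")
  stop_if(noise_sigma < 0, "noise_sigma must be >= 0")
  structure(list(sampling_rate_msps = sampling_rate_msps,
                 sound_speed_mps = sound_speed_mps,
                 lateral_step_um = lateral_step_um,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_spec")
}

# Nyquist guard shared by the waveform synthesizers.
check_nyquist <- function(transducer, acquisition) {
  need <- 2 * transducer$center_frequency_mhz *
    (1 + transducer$bandwidth_frac / 2)
  stop_if(acquisition$sampling_rate_msps <= need,
          "sampling rate violates Nyquist for the transducer passband (need > ",
          signif(need, 4), " MS/s)")
  invisible(TRUE)
}

#' Phantom generation parameters
#'
#' Defines a synthetic bioprinted hydrogel block with a self-assembled
#' capillary network. Per-day segment length defaults are log-normal with
#' medians 67.1 / 103.2 / 158.5 um (culture days 4 / 6 / 8) and a per-day
#' shape parameter chosen so that the 99.9th percentile matches the observed
#' maxima 602.5 / 410.4 / 1154.7 um.
#'
#' @param volume_size_um Physical (x, y, z) extent in um; z is depth below
#'   the hydrogel surface (z = 0). Default `c(600, 600, 600)` so the three
#'   standard 200-um depth bins are populated.
#' @param voxel_pitch_um Voxel pitch (x, y, z) in um, default `c(2, 2, 3)`.
#' @param culture_day One of 4, 6, 8.
#' @param condition One of `"control"`, `"TMZ"`, `"SU"`, `"combo"`.
#' @param rng_seed Integer seed; identical specs give bit-identical phantoms.
#' @param n_sprouts Number of seeded sprout points (default 12). 0 gives an
#'   empty phantom.
#' @param vessel_radius_um Range of tube radii in um, default `c(5, 15)`
#'   (capillary scale; not constrained by measurements).
#' @param branch_prob Per-day probability that a finished segment branches
#'   into two daughters; defaults 0.35 / 0.45 / 0.55 for days 4 / 6 / 8,
#'   emulating progressive interconnection.
#' @param max_generations Cap on branching generations (default 4).
#' @param include_spheroid If `TRUE`, stamp a static absorbing half-sphere at
#'   the surface center emulating a seeded tumor spheroid (default `FALSE`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_size_um = c(600, 600, 600),
                         voxel_pitch_um = c(2, 2, 3),
                         culture_day = 8,
                         condition = "control",
                         rng_seed = 1L,
                         n_sprouts = 12L,
                         vessel_radius_um = c(5, 15),
                         branch_prob = NULL,
                         max_generations = 4L,
                         include_spheroid = FALSE) {
  stop_if(length(volume_size_um) != 3 || any(volume_size_um <= 0),
          "volume_size_um must be 3 positive values")
  stop_if(length(voxel_pitch_um) != 3 || any(voxel_pitch_um <= 0),
          "voxel_pitch_um must be 3 positive values")
  stop_if(!culture_day %in% c(4, 6, 8), "culture_day must be 4, 6 or 8")
  stop_if(!condition %in% c("control", "TMZ", "SU", "combo"),
          "condition must be one of control, TMZ, SU, combo")
  stop_if(n_sprouts < 0, "n_sprouts must be >= 0")
  if (is.null(branch_prob))
    branch_prob <- c(`4` = 0.35, `6` = 0.45, `8` = 0.55)[[as.character(culture_day)]]
  structure(list(volume_size_um = as.numeric(volume_size_um),
                 voxel_pitch_um = as.numeric(voxel_pitch_um),
                 culture_day = as.integer(culture_day),
                 condition = condition,
                 rng_seed = as.integer(rng_seed),
                 n_sprouts = as.integer(n_sprouts),
                 vessel_radius_um = as.numeric(vessel_radius_um),
                 branch_prob = branch_prob,
                 max_generations = as.integer(max_generations),
                 include_spheroid = isTRUE(include_spheroid)),
            class = "phantom_spec")
}

# Per-day log-normal length parameters: median fixed at the observed medians,
# sdlog set so the 99.9th percentile equals the observed maxima (fit per day;
# the day-6 maximum is below day-4's so a shared shape would not work).
day_length_params <- function(culture_day) {
  med <- c(`4` = 67.1, `6` = 103.2, `8` = 158.5)[[as.character(culture_day)]]
  mx <- c(`4` = 602.5, `6` = 410.4, `8` = 1154.7)[[as.character(culture_day)]]
  list(meanlog = log(med), sdlog = log(mx / med) / stats::qnorm(0.999))
}
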