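# Instrument forward model: bandlimited transducer impulse response,
# per-column photoacoustic A-line synthesis (one-way time of flight),
# raster-scanned stacks, a confocal-stack emulator, and pulse-echo waveforms.
# Units: time in us, frequency in MHz, length in um, sound speed in m/s
# (1 um / (1 m/s) = 1 us, so depth_um / v_mps is directly a time in us).

`%||%` <- function(a, b) if (is.null(a)) b else a

lateral_psf_fwhm_um <- function(optics) {
  optics$psf_fwhm_um %||% theoretical_lateral_resolution(optics)
}

#' Transducer impulse response
#'
#' Zero-phase Gaussian-spectrum bandpass pulse: a carrier at the center
#' frequency under a Gaussian envelope whose spectral -6 dB full width equals
#' `bandwidth_frac * center_frequency`. Peak amplitude 1 at t = 0. Its
#' envelope FWHM, expressed as one-way depth, is `4 ln 2 / pi * v / B`
#' (~0.8825 v/B), the usual ~0.88 v/B axial-resolution figure.
#'
#' @param transducer A [transducer_spec()].
#' @param acquisition An [acquisition_spec()]; must satisfy Nyquist for the
#'   transducer passband.
#' @param n_sigma Support half-width in envelope standard deviations.
#' @return A list: `waveform` (sampled amplitudes), `t_us` (sample times,
#'   symmetric about 0), `center_index` (index of t = 0).
#' @export
transducer_impulse_response <- function(transducer, acquisition, n_sigma = 5) {
  check_nyquist(transducer, acquisition)
  fs <- acquisition$sampling_rate_msps
  fc <- transducer$center_frequency_mhz
  b_mhz <- transducer$bandwidth_frac * fc
  sigma_f <- b_mhz / (2 * sqrt(2 * log(2)))  # -6 dB amplitude = half max
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(n_sigma * sigma_t * fs)
  t <- (-half:half) / fs
  w <- cos(2 * pi * fc * t) * exp(-t^2 / (2 * sigma_t^2))
  list(waveform = w, t_us = t, center_index = half + 1L)
}

#' Pulse-echo waveform
#'
#' Two-way response: the impulse response convolved with itself (normalized
#' to unit peak). Its Gaussian spectrum is the square of the one-way
#' spectrum, so its fractional -6 dB bandwidth is narrower by 1/sqrt(2).
#'
#' @inheritParams transducer_impulse_response
#' @return A list with `waveform` and `t_us` as in
#'   [transducer_impulse_response()].
#' @export
simulate_pulse_echo <- function(transducer, acquisition) {
  ir <- transducer_impulse_response(transducer, acquisition)
  n <- length(ir$waveform)
  w <- conv_full(ir$waveform, ir$waveform)
  w <- w / max(abs(w))
  half <- n - 1L
  list(waveform = w, t_us = (-half:half) / acquisition$sampling_rate_msps,
       center_index = half + 1L)
}

# linear convolution via FFT
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nn <- stats::nextn(n, 2)
  re <- Re(fft(fft(c(a, numeric(nn - length(a)))) *
                 fft(c(b, numeric(nn - length(b)))), inverse = TRUE)) / nn
  re[seq_len(n)]
}

# Deposit depth profiles on the RF time grid and convolve with the impulse
# response. `p0` is a matrix (n_depth x n_columns); returns RF samples
# (n_t x n_columns) where sample i corresponds to t = (i - 1) / fs.
synthesize_rf <- function(p0, depth_um, acquisition, transducer) {
  fs <- acquisition$sampling_rate_msps
  v <- acquisition$sound_speed_mps
  si <- depth_um / v * fs                 # fractional sample index, 0-based
  n_t <- as.integer(ceiling(max(si, 0)) + 1L)
  ncol_ <- ncol(p0)
  dep <- matrix(0, n_t, ncol_)
  fl <- floor(si)
  fr <- si - fl
  for (k in seq_along(si)) {
    i0 <- fl[k] + 1L
    row <- p0[k, ]
    dep[i0, ] <- dep[i0, ] + row * (1 - fr[k])
    if (i0 + 1L <= n_t) dep[i0 + 1L, ] <- dep[i0 + 1L, ] + row * fr[k]
  }
  ir <- transducer_impulse_response(transducer, acquisition)
  h <- ir$waveform
  m <- length(h)
  nn <- stats::nextn(n_t + m - 1L, 2)
  H <- fft(c(h, numeric(nn - m)))
  rf <- matrix(0, n_t, ncol_)
  block <- max(1L, 2^22 %/% nn)  # bound working memory
  for (j0 in seq(1L, ncol_, by = block)) {
    j1 <- min(ncol_, j0 + block - 1L)
    D <- rbind(dep[, j0:j1, drop = FALSE],
               matrix(0, nn - n_t, j1 - j0 + 1L))
    R <- Re(stats::mvfft(stats::mvfft(D) * H, inverse = TRUE)) / nn
    # zero-phase kernel peaks at its centre: shift back by (center - 1)
    rf[, j0:j1] <- R[ir$center_index - 1L + seq_len(n_t), , drop = FALSE]
  }
  rf
}

add_rf_noise <- function(rf, acquisition) {
  if (acquisition$noise_sigma <= 0) return(rf)
  ref <- max(abs(rf))
  if (ref == 0) ref <- 1
  rf + rnorm(length(rf), sd = acquisition$noise_sigma * ref)
}

#' Simulate a single photoacoustic A-line
#'
#' Initial pressure is proportional to the absorber profile attenuated by
#' the single-pass optical decay `exp(-k_pam * z)`; each depth arrives at the
#' one-way time of flight `t = z / v` and is convolved with the transducer
#' impulse response. Additive white Gaussian noise of relative standard
#' deviation `acquisition$noise_sigma` is applied (seeded from
#' `acquisition$rng_seed`); with `noise_sigma = 0` the trace is
#' deterministic.
#'
#' @param absorber_line Absorption profile versus depth (nonnegative).
#' @param optics,transducer,acquisition Instrument specs.
#' @param depth_pitch_um Sampling pitch of `absorber_line` in um (default 3).
#' @return Numeric RF trace; sample i corresponds to `t = (i - 1) / fs`.
#' @export
simulate_pa_ascan <- function(absorber_line, optics, transducer, acquisition,
                              depth_pitch_um = 3) {
  if (!length(absorber_line)) return(numeric(0))
  z <- (seq_along(absorber_line) - 1) * depth_pitch_um
  p0 <- matrix(absorber_line * exp(-optics$k_pam_um * z), ncol = 1)
  rf <- synthesize_rf(p0, z, acquisition, transducer)
  if (acquisition$noise_sigma > 0) set.seed(acquisition$rng_seed)
  drop(add_rf_noise(rf, acquisition))
}

#' Simulate a raster-scanned photoacoustic acquisition
#'
#' Applies the lateral Gaussian excitation PSF (FWHM `0.51 lambda / NA`
#' unless overridden via `optics$psf_fwhm_um`) per depth slice of the
#' phantom absorber, then synthesizes one RF A-line per lateral voxel column
#' of the phantom grid (the phantom's lateral pitch is the scan pitch).
#'
#' @param phantom A `vascular_phantom`.
#' @param optics,transducer,acquisition Instrument specs.
#' @return An `rf_frameset`: `samples` array (scan_x, scan_y, time), the
#'   specs, and grid metadata.
#' @export
simulate_pam_stack <- function(phantom, optics, transducer, acquisition) {
  a <- phantom$absorber
  pitch <- phantom$voxel_pitch_um
  stop_if(dim(a)[1] * pitch[1] < acquisition$lateral_step_um ||
            dim(a)[2] * pitch[2] < acquisition$lateral_step_um,
          "phantom smaller than one scan step")
  d <- dim(a)
  blurred <- blur_lateral(a, lateral_psf_fwhm_um(optics), pitch)
  z <- (seq_len(d[3]) - 1) * pitch[3]
  att <- exp(-optics$k_pam_um * z)
  p0 <- matrix(aperm(blurred, c(3, 1, 2)), nrow = d[3]) * att
  rf <- synthesize_rf(p0, z, acquisition, transducer)
  if (acquisition$noise_sigma > 0) set.seed(acquisition$rng_seed)
  rf <- add_rf_noise(rf, acquisition)
  samples <- aperm(array(t(rf), dim = c(d[1], d[2], nrow(rf))), c(1, 2, 3))
  structure(list(samples = samples,
                 acquisition = acquisition,
                 transducer = transducer,
                 optics = optics,
                 scan_pitch_um = pitch[1:2],
                 depth_extent_um = (d[3] - 1) * pitch[3]),
            class = "rf_frameset")
}

#' @export
print.rf_frameset <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rf_frameset: %d x %d A-lines, %d samples at %g MS/s>\n",
              d[1], d[2], d[3], x$acquisition$sampling_rate_msps))
  invisible(x)
}

#' Simulate a confocal-style intensity stack
#'
#' Emulates laser-scanning confocal detection of the same specimen: the
#' laterally blurred absorber scaled by the steeper confocal attenuation
#' `exp(-k_lscm * z)` plus additive noise (negative values clipped to 0).
#' There is no acoustic stage; the output lives on the phantom voxel grid.
#'
#' @param phantom A `vascular_phantom`.
#' @param optics,acquisition Instrument specs (`noise_sigma` and `rng_seed`
#'   are taken from `acquisition`).
#' @return A `recon_volume` of intensities.
#' @export
simulate_confocal_stack <- function(phantom, optics, acquisition) {
  a <- phantom$absorber
  pitch <- phantom$voxel_pitch_um
  d <- dim(a)
  out <- blur_lateral(a, lateral_psf_fwhm_um(optics), pitch)
  z <- (seq_len(d[3]) - 1) * pitch[3]
  att <- exp(-optics$k_lscm_um * z)
  out <- sweep(out, 3, att, `*`)
  if (acquisition$noise_sigma > 0) {
    set.seed(acquisition$rng_seed)
    ref <- max(out)
    if (ref == 0) ref <- 1
    out <- out + rnorm(length(out), sd = acquisition$noise_sigma * ref)
    out[out < 0] <- 0
  }
  new_recon_volume(out, pitch,
                   provenance = list(modality = "confocal",
                                     k_lscm_um = optics$k_lscm_um))
}

# Separable lateral Gaussian blur (x and y), zero-padded borders.
blur_lateral <- function(arr, fwhm_um, pitch_um) {
  sigma <- fwhm_um / (2 * sqrt(2 * log(2)))
  out <- arr
  for (ax in 1:2) {
    s_px <- sigma / pitch_um[ax]
    if (s_px < 0.05) next
    half <- max(1L, ceiling(4 * s_px))
    k <- exp(-(-half:half)^2 / (2 * s_px^2))
    k <- k / sum(k)
    out <- shift_sum(out, k, half, ax)
  }
  out
}

shift_sum <- function(arr, k, half, ax) {
  d <- dim(arr)
  acc <- array(0, d)
  n <- d[ax]
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    if (ax == 1L) {
      acc[dst, , ] <- acc[dst, , , drop = FALSE] +
        k[j] * arr[src[ok], , , drop = FALSE]
    } else {
      acc[, dst, ] <- acc[, dst, , drop = FALSE] +
        k[j] * arr[, src[ok], , drop = FALSE]
    }
  }
  acc
}
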