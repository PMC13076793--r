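# Resolution formulas and measurements, bandwidth estimation, penetration
# depth fitting.

test_that("theoretical resolutions implement the diffraction and bandwidth limits", {
  expect_equal(theoretical_lateral_resolution(optical_spec()),
               0.51 * 532 / 1000 / 0.12)   # 2.261 um
  # coefficients cancel: lambda 532 nm at NA 0.51 gives exactly 532 nm
  expect_equal(theoretical_lateral_resolution(
    optical_spec(numerical_aperture = 0.51)), 0.532)
  expect_equal(theoretical_lateral_resolution(optical_spec()),
               2 * theoretical_lateral_resolution(
                 optical_spec(numerical_aperture = 0.24)))

  expect_lt(abs(theoretical_axial_resolution(transducer_spec()) - 103.4), 0.05)
  expect_equal(theoretical_axial_resolution(
    transducer_spec(center_frequency_mhz = 15, bandwidth_frac = 1), 1500),
    88.0)
  tra <- transducer_spec()
  expect_equal(theoretical_axial_resolution(tra),
               2 * theoretical_axial_resolution(
                 transducer_spec(bandwidth_frac = 2 * 0.69)))
})

test_that("esf_to_lsf_fwhm recovers Gaussian widths across scales", {
  # property sweep: erf edge of known sigma, >= 10 samples per FWHM
  for (sigma in c(1, 5, 20, 50)) {
    x <- seq(-6 * sigma, 6 * sigma, by = sigma / 8)
    esf <- pnorm(x / sigma)
    fwhm <- esf_to_lsf_fwhm(x, esf)
    expect_lt(abs(fwhm - 2.3548 * sigma) / (2.3548 * sigma), 0.02)
  }
  # ideal step: derivative is a near-impulse
  x <- seq(0, 20, by = 0.5)
  expect_lte(esf_to_lsf_fwhm(x, as.numeric(x > 10)), 2 * 0.5)
  expect_error(esf_to_lsf_fwhm(x, rep(1, length(x))), "flat|peak")
  expect_error(esf_to_lsf_fwhm(1:5, c(0, 0, 1, 1, 1)), "10 samples")
})

test_that("simulated razor-edge scan reproduces the bench lateral resolution", {
  es <- simulate_edge_scan()  # calibrated 2.42 um PSF, 0.2 um step
  fwhm <- esf_to_lsf_fwhm(es$position_um, es$intensity)
  expect_lt(abs(fwhm - 2.42) / 2.42, 0.05)
})

test_that("axial_fwhm_from_fiber fits Gaussian envelopes", {
  acq <- default_acq0()
  # exact Gaussian: self-fit to solver precision
  i <- 1:400
  sigma <- 22.5
  env <- exp(-(i - 180)^2 / (2 * sigma^2))
  expect_equal(axial_fwhm_from_fiber(env, acq),
               time_to_depth(2.3548 * sigma, acq), tolerance = 1e-4)

  # noise-free fiber simulation lands within 10% of the 103.4 um limit
  fib <- make_calibration_target("fiber")
  frames <- simulate_pam_stack(fib, optical_spec(), transducer_spec(), acq)
  mid <- ceiling(dim(frames$samples)[1:2] / 2)
  env <- extract_envelope(frames$samples[mid[1], mid[2], ])
  fwhm <- axial_fwhm_from_fiber(env, acq)
  expect_lt(abs(fwhm - 103.4) / 103.4, 0.10)

  # halving the bandwidth doubles the measured width
  tra2 <- transducer_spec(bandwidth_frac = 0.69 / 2)
  frames2 <- simulate_pam_stack(fib, optical_spec(), tra2, acq)
  env2 <- extract_envelope(frames2$samples[mid[1], mid[2], ])
  expect_lt(abs(axial_fwhm_from_fiber(env2, acq) / fwhm - 2), 0.2)

  expect_error(axial_fwhm_from_fiber(numeric(10), acq), "empty")
})

test_that("estimate_bandwidth round-trips configured transducers", {
  acq <- default_acq0()
  for (fc in c(15, 19, 25)) {
    for (bf in c(0.5, 0.69, 0.9)) {
      tra <- transducer_spec(center_frequency_mhz = fc, bandwidth_frac = bf)
      bw <- estimate_bandwidth(transducer_impulse_response(tra, acq)$waveform,
                               acq)
      expect_lt(abs(bw$center_frequency_mhz - fc) / fc, 0.02)
      expect_lt(abs(bw$bandwidth_frac - bf) / bf, 0.02)
    }
  }
  # amplitude scaling leaves both estimates unchanged
  tra <- transducer_spec()
  w <- transducer_impulse_response(tra, acq)$waveform
  b1 <- estimate_bandwidth(w, acq)
  b2 <- estimate_bandwidth(17 * w, acq)
  expect_equal(b1$bandwidth_frac, b2$bandwidth_frac)
  expect_error(estimate_bandwidth(w[1:32], acq), "64")
  # a long pure sinusoid never falls to -6 dB across... it does at the
  # window limit; instead: fractional bandwidth tends to zero
  t <- (0:8191) / 500
  bsin <- estimate_bandwidth(sin(2 * pi * 19 * t), acq)
  expect_lt(bsin$bandwidth_frac, 0.01)
})

test_that("depth_attenuation_profile + penetration_depth recover decay rates", {
  # exact profiles at the two calibrated attenuation rates
  z <- seq(0, 600, by = 3)
  for (d_true in c(431, 262)) {
    prof <- data.frame(depth_um = z,
                       median_intensity = 5 * exp(-2 / d_true * z))
    expect_lt(abs(penetration_depth(prof) - d_true) / d_true, 0.01)
  }
  # scale invariance
  prof <- data.frame(depth_um = z, median_intensity = exp(-0.004 * z))
  expect_equal(penetration_depth(prof),
               penetration_depth(transform(prof,
                                           median_intensity = 7 * median_intensity)))
  # constant profile: error
  expect_error(penetration_depth(
    data.frame(depth_um = z, median_intensity = rep(1, length(z)))), "decay")
  expect_error(penetration_depth(
    data.frame(depth_um = 1:3, median_intensity = exp(-(1:3)))), "5")

  # synthetic object stack: flat without attenuation, slope -k with it
  set.seed(8)
  mk_stack <- function(k) {
    a <- array(0, c(60, 60, 50))
    for (cell in 1:40) {
      cx <- sample(5:55, 1); cy <- sample(5:55, 1); cz <- sample(1:50, 1)
      a[cx + (-1:1), cy + (-1:1), cz] <- exp(-k * (cz - 1) * 3)
    }
    a + array(abs(rnorm(length(a), sd = 1e-3)), dim(a))
  }
  p0 <- depth_attenuation_profile(mk_stack(0), min_object_voxels = 4)
  ok <- is.finite(p0$median_intensity)
  expect_gt(sum(ok), 10)
  expect_lt(diff(range(p0$median_intensity[ok])), 0.05)

  k <- 2 / 431
  pk <- depth_attenuation_profile(mk_stack(k), min_object_voxels = 4)
  est <- penetration_depth(pk)
  expect_lt(abs(est - 431) / 431, 0.10)

  # a slice with no objects yields NA and is excluded
  a <- mk_stack(0)
  a[, , 25] <- 0
  p <- depth_attenuation_profile(a, min_object_voxels = 4)
  expect_true(is.na(p$median_intensity[25]))
})
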