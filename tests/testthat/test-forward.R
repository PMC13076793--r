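# Forward model: impulse response, A-line synthesis, stacks, pulse-echo.

test_that("impulse response has the configured Gaussian passband", {
  acq <- default_acq0()
  tra <- transducer_spec()
  ir <- transducer_impulse_response(tra, acq)
  n <- stats::nextn(16 * length(ir$waveform), 2)
  mag <- Mod(fft(c(ir$waveform, numeric(n - length(ir$waveform)))))
  f <- acq$sampling_rate_msps * (0:(n - 1)) / n
  at <- function(freq) mag[which.min(abs(f[1:(n / 2)] - freq))]
  # -6 dB definition: half the peak magnitude at fc +/- B/2
  b <- tra$bandwidth_frac * tra$center_frequency_mhz
  expect_lt(abs(at(19 + b / 2) / at(19) - 0.5), 0.02)
  expect_lt(abs(at(19 - b / 2) / at(19) - 0.5), 0.02)
  expect_equal(max(abs(ir$waveform)), 1)

  # envelope FWHM expressed as one-way depth ~ 0.88 v/B =~ 103.4 um
  env <- extract_envelope(ir$waveform)
  fwhm_um <- time_to_depth(pamvasc:::fwhm_of_peak(seq_along(env), env), acq)
  expect_lt(abs(fwhm_um - 103.4) / 103.4, 0.02)

  # doubling the fractional bandwidth halves the envelope duration
  ir2 <- transducer_impulse_response(transducer_spec(bandwidth_frac = 2 * 0.69),
                                     acq)
  env2 <- extract_envelope(ir2$waveform)
  fwhm2 <- time_to_depth(pamvasc:::fwhm_of_peak(seq_along(env2), env2), acq)
  expect_lt(abs(fwhm2 / fwhm_um - 0.5), 0.02)

  expect_error(
    transducer_impulse_response(tra, acquisition_spec(sampling_rate_msps = 40)),
    "Nyquist")
})

test_that("simulate_pa_ascan geometry, attenuation and degenerate cases", {
  acq <- default_acq0()
  tra <- transducer_spec()
  opt <- optical_spec(k_pam_um = 0)

  expect_length(simulate_pa_ascan(numeric(0), opt, tra, acq), 0)

  prof <- numeric(150)
  prof[101] <- 1  # z0 = 300 um
  rf <- simulate_pa_ascan(prof, opt, tra, acq)
  env <- extract_envelope(rf)
  expect_equal(which.max(env) - 1, round(300 * 500 / 1540))

  # two absorbers 200 um apart resolve; 20 um apart merge (103 um limit)
  prof2 <- numeric(200)
  prof2[c(34, 101)] <- 1  # 99 and 300 um
  env2 <- extract_envelope(simulate_pa_ascan(prof2, opt, tra, acq))
  peaks <- function(e) sum(diff(sign(diff(e))) == -2 & e[2:(length(e) - 1)] > 0.4 * max(e))
  expect_equal(peaks(env2), 2)
  prof3 <- numeric(200)
  prof3[c(101, 108)] <- 1  # 300 and 321 um
  env3 <- extract_envelope(simulate_pa_ascan(prof3, opt, tra, acq))
  expect_equal(peaks(env3), 1)

  # scatterer train with attenuation: envelope peaks decay at rate k
  # (a strictly uniform absorber has no content in the transducer passband,
  # so the decay is probed on well-separated point scatterers)
  k <- 2 / 431
  optk <- optical_spec(k_pam_um = k)
  depths_i <- seq(21, 281, by = 40)  # every 120 um
  proft <- numeric(300)
  proft[depths_i] <- 1
  envt <- extract_envelope(simulate_pa_ascan(proft, optk, tra, acq))
  zpk <- (depths_i - 1) * 3
  peaks_at <- vapply(zpk, function(z) {
    i0 <- round(z * 500 / 1540) + 1
    max(envt[max(1, i0 - 5):min(length(envt), i0 + 5)])
  }, numeric(1))
  fit <- lm(log(peaks_at) ~ zpk)
  expect_lt(abs(-coef(fit)[[2]] - k) / k, 0.1)

  # linearity at zero noise
  rf1 <- simulate_pa_ascan(prof, opt, tra, acq)
  rf3 <- simulate_pa_ascan(3 * prof, opt, tra, acq)
  expect_equal(rf3, 3 * rf1, tolerance = 1e-12)

  # shift covariance: each absorber peaks at its own rounded sample index
  prof_b <- numeric(150)
  prof_b[121] <- 1  # z = 360 um
  env_b <- extract_envelope(simulate_pa_ascan(prof_b, opt, tra, acq))
  expect_equal(which.max(env_b) - 1, round(360 * 500 / 1540))
})

test_that("simulate_pam_stack blurs laterally and is seed-reproducible", {
  tra <- transducer_spec()
  opt <- optical_spec(k_pam_um = 0)
  acq <- default_acq0()

  ph0 <- pamvasc:::new_phantom(array(0, c(6, 6, 20)), c(2, 2, 3))
  fr0 <- simulate_pam_stack(ph0, opt, tra, acq)
  expect_true(all(fr0$samples == 0))

  # noisy frames: identical seeds give identical samples
  acqn <- acquisition_spec(noise_sigma = 0.05, rng_seed = 33L)
  ph <- pamvasc:::new_phantom(array(0, c(6, 6, 20)), c(2, 2, 3))
  ph$absorber[3, 3, 10] <- 1
  f1 <- simulate_pam_stack(ph, opt, tra, acqn)
  f2 <- simulate_pam_stack(ph, opt, tra, acqn)
  expect_identical(f1$samples, f2$samples)
  f3 <- simulate_pam_stack(ph, opt, tra,
                           acquisition_spec(noise_sigma = 0.05, rng_seed = 34L))
  expect_false(identical(f1$samples, f3$samples))

  expect_error(simulate_pam_stack(
    pamvasc:::new_phantom(array(0, c(1, 1, 5)), c(1, 1, 3)), opt, tra,
    acquisition_spec(lateral_step_um = 50)), "scan step")

  # energy decay: statistically depth-uniform speckle phantom with
  # attenuation shows decaying per-depth envelope maxima at rate ~k
  # (a strictly uniform absorber is invisible to the bandpass transducer)
  k <- 2 / 431
  optk <- optical_spec(k_pam_um = k)
  set.seed(77)
  phu <- pamvasc:::new_phantom(array(runif(8 * 8 * 200), c(8, 8, 200)),
                               c(2, 2, 3))
  vol <- assemble_volume(simulate_pam_stack(phu, optk, tra, acq))
  prof <- apply(vol$amplitude, 3, max)
  z <- (seq_along(prof) - 1) * 3
  sel <- z > 60 & z < 540
  expect_lt(cor(z[sel], log(prof[sel]), method = "spearman"), -0.8)
  slope <- -coef(lm(log(prof[sel]) ~ z[sel]))[[2]]
  expect_lt(abs(slope - k) / k, 0.3)
})

test_that("fiber target produces a single band at its depth", {
  fib <- make_calibration_target("fiber", fiber_depth_um = 300)
  frames <- simulate_pam_stack(fib, optical_spec(k_pam_um = 0),
                               transducer_spec(), default_acq0())
  vol <- assemble_volume(frames)
  b <- extract_bscan(vol, max(1, dim(vol$amplitude)[2] %/% 2), axis = "x")
  depth_of_max <- (which.max(apply(b, 2, max)) - 1) * 3
  expect_lt(abs(depth_of_max - 300), 4)
})

test_that("confocal emulator attenuates faster than PAM", {
  acq <- default_acq0()
  opt0 <- optical_spec(k_lscm_um = 0)
  ph <- pamvasc:::new_phantom(array(1, c(5, 5, 60)), c(2, 2, 3))
  st <- simulate_confocal_stack(ph, opt0, acq)
  prof <- apply(st$amplitude, 3, median)
  expect_lt(diff(range(prof)), 1e-9)  # no depth dependence

  opt <- optical_spec()
  st_c <- simulate_confocal_stack(ph, opt, acq)
  prof_c <- apply(st_c$amplitude, 3, median)
  prof_pam <- exp(-opt$k_pam_um * (0:59) * 3)
  ratio_c <- prof_c / prof_c[1]
  expect_true(all(ratio_c <= prof_pam + 1e-9))
})

test_that("pulse-echo spectrum is the squared one-way response", {
  acq <- default_acq0()
  tra <- transducer_spec()
  pe <- simulate_pulse_echo(tra, acq)
  bw1 <- estimate_bandwidth(transducer_impulse_response(tra, acq)$waveform, acq)
  bw2 <- estimate_bandwidth(pe$waveform, acq)
  expect_lt(abs(bw2$center_frequency_mhz - 19) / 19, 0.02)
  # Gaussian spectra: two-way fractional bandwidth narrower by 1/sqrt(2)
  expect_lt(abs(bw2$bandwidth_frac / bw1$bandwidth_frac - 1 / sqrt(2)), 0.01)
})
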