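# Envelope extraction, time-depth conversion, volume assembly, filtering
# and projections.

test_that("extract_envelope reproduces known modulations", {
  t <- seq(0, 10, by = 0.002)
  s <- 0.7 * sin(2 * pi * 19 * t)
  env <- extract_envelope(s)
  inner <- env[500:(length(env) - 500)]
  expect_true(all(abs(inner - 0.7) < 0.02))

  expect_equal(extract_envelope(numeric(64)), numeric(64))
  expect_error(extract_envelope(numeric(0)), "empty")
  expect_error(extract_envelope(c(1, NA, 2)), "finite")

  # Gaussian-modulated carrier: envelope equals the modulator within 1%
  mod <- exp(-(t - 5)^2 / (2 * 0.5^2))
  env <- extract_envelope(mod * cos(2 * pi * 19 * t))
  core <- which(mod > 0.05)
  expect_lt(max(abs(env[core] - mod[core]) / max(mod)), 0.01)

  # envelope dominates the RF magnitude away from the edges
  rf <- mod * cos(2 * pi * 19 * t)
  expect_true(all(env[core] >= abs(rf[core]) - 1e-8))
})

test_that("time_to_depth implements one-way time of flight", {
  acq <- acquisition_spec()
  expect_equal(time_to_depth(0, acq), 0)
  expect_equal(time_to_depth(1, acq), 3.08)      # native pitch 1540/500
  expect_equal(round(time_to_depth(1, acq)), 3)  # printed axial pixel
  expect_equal(time_to_depth(100, acq), 308)
  expect_error(time_to_depth(-1, acq), ">= 0")
})

test_that("assemble_volume localizes absorbers and handles empty frames", {
  acq <- default_acq0()
  tra <- transducer_spec()
  opt <- optical_spec(k_pam_um = 0)
  ph <- pamvasc:::new_phantom(array(0, c(5, 4, 100)), c(2, 2, 3))
  ph$absorber[3, 2, 50] <- 1   # depth 49*3 = 147 um
  frames <- simulate_pam_stack(ph, opt, tra, acq)
  vol <- assemble_volume(frames)
  expect_s3_class(vol, "recon_volume")
  peak <- which(vol$amplitude == max(vol$amplitude), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1:2]), c(3, 2))
  expect_lt(abs((peak[1, 3] - 1) * 3 - 147), 3.1)

  # volume argmax equals RF envelope argmax mapped through time_to_depth
  env <- extract_envelope(frames$samples[3, 2, ])
  z_rf <- time_to_depth(which.max(env) - 1, acq)
  expect_lt(abs(z_rf - (peak[1, 3] - 1) * 3), 3.1)

  # empty frames give an all-zero volume
  ph0 <- pamvasc:::new_phantom(array(0, c(4, 4, 30)), c(2, 2, 3))
  vol0 <- assemble_volume(simulate_pam_stack(ph0, opt, tra, acq))
  expect_true(all(vol0$amplitude == 0))
})

test_that("median_filter_3d matches a brute-force oracle and its bounds", {
  expect_error(median_filter_3d(array(0, c(3, 3, 3)), window = 2), "odd")

  const <- array(4.2, c(5, 5, 5))
  expect_equal(median_filter_3d(const), const)

  # isolated hot voxel in zeros is removed (median of 27 values)
  a <- array(0, c(7, 7, 7))
  a[4, 4, 4] <- 100
  f <- median_filter_3d(a)
  expect_equal(f[4, 4, 4], 0)

  # pointwise within the local window's [min, max]; matches brute force
  set.seed(5)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  f <- median_filter_3d(a)
  brute <- function(x, y, z) {
    xs <- pmin(pmax((x - 1):(x + 1), 1), 6)
    ys <- pmin(pmax((y - 1):(y + 1), 1), 5)
    zs <- pmin(pmax((z - 1):(z + 1), 1), 4)
    median(a[xs, ys, zs])
  }
  for (x in c(1, 3, 6)) for (y in c(1, 5)) for (z in c(1, 2, 4)) {
    expect_equal(f[x, y, z], brute(x, y, z))
  }
  expect_gte(min(f), min(a))
  expect_lte(max(f), max(a))
})

test_that("map_projection and depth encoding obey their definitions", {
  expect_equal(map_projection(array(0, c(3, 3, 2))), matrix(0, 3, 3))

  set.seed(1)
  a <- array(runif(4 * 5 * 6), c(4, 5, 6))
  m <- map_projection(a)
  for (k in 1:6) expect_true(all(m >= a[, , k]))

  a <- array(0, c(6, 6, 10))
  a[2, 3, 5] <- 1  # depth (5-1)*3 = 12... pitch default (2,2,3)
  vol <- pamvasc:::new_recon_volume(a, c(2, 2, 3))
  expect_equal(map_projection(vol)[2, 3], 1)
  d <- depth_encoded_projection(vol, amplitude_floor = 0.5)
  expect_equal(d[2, 3], 12)
  expect_true(all(is.na(d[-2, ])))

  # shallow-but-brighter absorber wins the argmax
  a[2, 3, 2] <- 2
  vol$amplitude <- a
  d <- depth_encoded_projection(vol, amplitude_floor = 0.5)
  expect_equal(d[2, 3], 3)

  # raising the floor never unmasks a pixel
  d1 <- depth_encoded_projection(vol, amplitude_floor = 0.1)
  d2 <- depth_encoded_projection(vol, amplitude_floor = 1.5)
  expect_true(all(is.na(d1) <= is.na(d2)))
})

test_that("extract_bscan slices and commutes with MAP", {
  const <- array(2, c(4, 5, 6))
  expect_equal(extract_bscan(const, 3), matrix(2, 4, 6))
  expect_error(extract_bscan(const, 9), "range")

  set.seed(2)
  a <- array(runif(4 * 5 * 6), c(4, 5, 6))
  b <- extract_bscan(a, 2, axis = "y")
  expect_equal(apply(b, 1, max),
               apply(a, c(1, 2), max)[, 2])
  bx <- extract_bscan(a, 4, axis = "x")
  expect_equal(dim(bx), c(5, 6))
})

test_that("end-to-end localization of well-separated point absorbers", {
  acq <- default_acq0()
  tra <- transducer_spec()
  opt <- optical_spec(k_pam_um = 0)
  truth <- rbind(c(10, 10, 60), c(30, 40, 120), c(50, 20, 240), c(20, 50, 330))
  a <- array(0, c(40, 40, 150))
  for (i in seq_len(nrow(truth)))
    a[truth[i, 1] / 2 + 1, truth[i, 2] / 2 + 1, truth[i, 3] / 3 + 1] <- 1
  ph <- pamvasc:::new_phantom(a, c(2, 2, 3))
  vol <- assemble_volume(simulate_pam_stack(ph, opt, tra, acq))
  for (i in seq_len(nrow(truth))) {
    sub <- vol$amplitude[truth[i, 1] / 2 + 1, truth[i, 2] / 2 + 1, ]
    expect_lt(abs((which.max(sub) - 1) * 3 - truth[i, 3]), 3.1)
  }
})
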