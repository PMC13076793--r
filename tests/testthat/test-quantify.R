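# Segmentation, density, fractal dimension, skeleton tracing and length
# statistics.

test_that("otsu segmentation is exact on two-valued volumes and filters specks", {
  a <- array(0, c(20, 20, 10))
  a[5:10, 5:10, 3:6] <- 1
  m <- segment_vessels(a, min_component_voxels = 1)
  expect_identical(m$mask, a == 1)
  expect_error(segment_vessels(array(1, c(4, 4, 4))), "dynamic range")

  # small components removed; lowering the floor never removes kept voxels
  a[15, 15, 8] <- 1  # single speck
  m1 <- segment_vessels(a, min_component_voxels = 5)
  m2 <- segment_vessels(a, min_component_voxels = 1)
  expect_false(m1$mask[15, 15, 8])
  expect_true(m2$mask[15, 15, 8])
  expect_true(all(m2$mask >= m1$mask))
})

test_that("segmentation recovers phantom tubes at high SNR (Dice >= 0.9)", {
  ph <- grow_vascular_phantom(small_spec(culture_day = 6, rng_seed = 3))
  set.seed(1)
  noisy <- ph$absorber + array(rnorm(length(ph$absorber), sd = 0.05),
                               dim(ph$absorber))
  m <- segment_vessels(noisy, min_component_voxels = 50)
  truth <- ph$absorber > 0
  dice <- 2 * sum(m$mask & truth) / (sum(m$mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("depth_binned_density: definition, conservation, erosion monotonicity", {
  full <- pamvasc:::new_vessel_mask(array(TRUE, c(10, 10, 200)), c(2, 2, 3))
  d <- depth_binned_density(full)
  expect_equal(d$density, rep(1, 3))
  expect_error(depth_binned_density(full, bin_edges_um = c(0, 0)), "increasing")
  expect_error(depth_binned_density(full, bin_edges_um = c(900, 1200)),
               "no voxel layers")

  set.seed(4)
  m <- array(runif(10 * 10 * 200) < 0.1, c(10, 10, 200))
  vm <- pamvasc:::new_vessel_mask(m, c(2, 2, 3))
  d <- depth_binned_density(vm)
  # conservation: counts sum to the vessel voxels in [0, 600)
  z <- (seq_len(200) - 1) * 3
  expect_equal(sum(d$n_vessel), sum(m[, , z < 600]))

  # erosion (6-neighbourhood shrink) never increases any bin density
  er <- m
  er[-1, , ] <- er[-1, , ] & m[-10, , ]
  er[, -1, ] <- er[, -1, ] & m[, -10, ]
  er[1, , ] <- FALSE; er[, 1, ] <- FALSE
  de <- depth_binned_density(pamvasc:::new_vessel_mask(er, c(2, 2, 3)))
  expect_true(all(de$density <= d$density + 1e-12))
})

test_that("fractal_dimension matches line, plane and Sierpinski references", {
  n <- 243
  line <- matrix(FALSE, n, n)
  line[, 120] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.15)

  sq <- matrix(TRUE, n, n)
  expect_lt(abs(fractal_dimension(sq) - 2), 0.1)

  carpet <- sierpinski_carpet(5)
  expect_lt(abs(fractal_dimension(carpet) - log(8) / log(3)), 0.1)

  expect_error(fractal_dimension(matrix(FALSE, 64, 64)), "empty")
  expect_error(fractal_dimension(matrix(TRUE, 6, 6)), "small")
  # bounded in [0, 2] for arbitrary slab projections
  set.seed(9)
  r <- array(runif(64 * 64 * 5) < 0.2, c(64, 64, 5))
  fd <- fractal_dimension(r)
  expect_gte(fd, 0)
  expect_lte(fd, 2)
})

test_that("skeleton tracing recovers simple geometries", {
  pitch <- c(2, 2, 3)
  # straight axis-aligned tube, 300 um
  m <- tube_mask(list(rbind(c(50, 30, 45), c(350, 30, 45))), 8, c(200, 30, 30))
  g <- skeletonize_and_trace(m)
  expect_equal(nrow(g$segments), 1)
  expect_lt(abs(g$segments$length_um - 300), 3.1)

  # 45-degree oblique in x-y: within 3%
  L <- 250
  m2 <- tube_mask(list(rbind(c(40, 40, 45),
                             c(40 + L / sqrt(2), 40 + L / sqrt(2), 45))),
                  8, c(120, 120, 30))
  g2 <- skeletonize_and_trace(m2)
  expect_equal(nrow(g2$segments), 1)
  expect_lt(abs(g2$segments$length_um - L) / L, 0.03)

  # Y: three segments meeting at one junction
  polys <- list(rbind(c(30, 100, 45), c(150, 100, 45)),
                rbind(c(150, 100, 45), c(250, 160, 45)),
                rbind(c(150, 100, 45), c(250, 40, 45)))
  g3 <- skeletonize_and_trace(tube_mask(polys, rep(7, 3), c(150, 100, 30)))
  expect_equal(nrow(g3$segments), 3)
  expect_true(all(abs(sort(g3$segments$length_um) -
                        sort(c(120, 116.6, 116.6))) < 15))

  # empty mask: empty graph, not an error
  g0 <- skeletonize_and_trace(array(FALSE, c(10, 10, 10)))
  expect_equal(nrow(g0$segments), 0)
})

test_that("skeleton is contained in the mask", {
  ph <- grow_vascular_phantom(small_spec(rng_seed = 5))
  m <- segment_vessels(ph$absorber, min_component_voxels = 50)
  g <- skeletonize_and_trace(m, return_skeleton = TRUE)
  expect_true(all(m$mask[g$skeleton]))
})

test_that("random oriented cylinders: traced length error <= 5% + 2 pitches", {
  set.seed(12)
  for (i in 1:8) {
    L <- runif(1, 50, 600)
    r <- runif(1, 5, 15)
    dir <- pamvasc:::random_unit_vector()
    margin <- 25
    dims_um <- abs(dir) * L + 2 * margin + 20
    start <- margin + 10 * runif(3)
    start[dir < 0] <- (dims_um - margin - 10)[dir < 0]
    poly <- rbind(start, start + dir * L)
    m <- tube_mask(list(poly), r, ceiling(dims_um / c(2, 2, 3)))
    g <- skeletonize_and_trace(m)
    expect_equal(nrow(g$segments), 1)
    expect_lt(abs(g$segments$length_um - L), 0.05 * L + 2 * 3)
  }
})

test_that("length_statistics summarizes distributions", {
  g1 <- structure(list(segments = data.frame(length_um = 120),
                       voxel_pitch_um = c(2, 2, 3)), class = "vessel_graph")
  s <- length_statistics(g1)
  expect_equal(s$median_um, 120)
  expect_equal(s$max_um, 120)
  expect_error(length_statistics(numeric(0)), "segments")

  s2 <- length_statistics(c(10, 20, 30, 100))
  expect_equal(s2$median_um, 25)
  expect_equal(s2$max_um, 100)
  expect_s3_class(s2$density, "density")
})
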