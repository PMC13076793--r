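# Phantom generator: determinism, bookkeeping, growth and drug effects,
# calibration targets.

test_that("spec validation rejects invalid parameters", {
  expect_error(phantom_spec(culture_day = 5), "culture_day")
  expect_error(phantom_spec(condition = "DMSO"), "condition")
  expect_error(phantom_spec(volume_size_um = c(600, 600)), "positive")
  expect_error(phantom_spec(voxel_pitch_um = c(2, 2, 0)), "positive")
  expect_error(grow_vascular_phantom(phantom_spec(volume_size_um = c(30, 30, 30))),
               "too small")
})

test_that("generation is deterministic and bookkeeping is exact", {
  sp <- small_spec(rng_seed = 21L)
  p1 <- grow_vascular_phantom(sp)
  p2 <- grow_vascular_phantom(sp)
  expect_identical(p1$absorber, p2$absorber)
  expect_identical(p1$edges, p2$edges)

  # per-edge arc lengths equal independent polyline integration
  expect_equal(sum(p1$edges$length_um), total_centerline_length(p1),
               tolerance = 1e-9)
  for (i in seq_len(nrow(p1$edges))) {
    expect_equal(p1$edges$length_um[i],
                 pamvasc:::polyline_length(p1$polylines[[i]]),
                 tolerance = 1e-9)
  }
  expect_true(all(p1$edges$length_um > 0))
  # no self-loops
  expect_true(all(p1$edges$node_from != p1$edges$node_to))
})

test_that("zero sprouts give an empty phantom", {
  p <- grow_vascular_phantom(small_spec(n_sprouts = 0L))
  expect_equal(nrow(p$edges), 0)
  expect_true(all(p$absorber == 0))
  expect_equal(total_centerline_length(p), 0)
})

test_that("expected total vessel length grows with culture day", {
  totals <- sapply(c(4, 6, 8), function(day) {
    mean(sapply(1:20, function(s) {
      sum(grow_vascular_phantom(small_spec(culture_day = day,
                                           rng_seed = s))$edges$length_um)
    }))
  })
  expect_true(totals[1] < totals[2])
  expect_true(totals[2] < totals[3])
})

test_that("drug effects prune with the expected ordering and identities", {
  ph <- grow_vascular_phantom(small_spec(rng_seed = 2L))
  expect_identical(apply_drug_effect(ph, "control"), ph)
  expect_error(apply_drug_effect(ph, "dmso"), "unknown condition")

  combo <- apply_drug_effect(ph, "combo")
  expect_lt(nrow(combo$edges), nrow(ph$edges))
  expect_error(apply_drug_effect(combo, "TMZ"), "control-grown")

  # mean density ordering over 20 seeds, three 200-um depth bins
  dens <- function(p, edges = c(0, 200, 400, 600)) {
    depth_binned_density(pamvasc:::new_vessel_mask(p$absorber > 0,
                                                   p$voxel_pitch_um),
                         edges)$density
  }
  spec_of <- function(s) phantom_spec(volume_size_um = c(300, 300, 600),
                                      n_sprouts = 6L, rng_seed = s)
  acc <- matrix(0, 3, 3, dimnames = list(NULL, c("control", "SU", "combo")))
  for (s in 1:20) {
    ctrl <- grow_vascular_phantom(spec_of(s))
    acc[, "control"] <- acc[, "control"] + dens(ctrl)
    acc[, "SU"] <- acc[, "SU"] + dens(apply_drug_effect(ctrl, "SU"))
    acc[, "combo"] <- acc[, "combo"] + dens(apply_drug_effect(ctrl, "combo"))
  }
  expect_true(all(acc[, "combo"] < acc[, "SU"]))
  expect_true(all(acc[, "SU"] < acc[, "control"]))
})

test_that("combo suppression is strongest in the shallow bin", {
  # shallow-bin survival carries an extra 0.8 factor: the combo/control
  # density ratio is lower at 0-200 um than at 400-600 um (5-seed average)
  rs <- ru <- 0
  for (s in 101:105) {
    ctrl <- grow_vascular_phantom(phantom_spec(volume_size_um = c(300, 300, 600),
                                               n_sprouts = 8L, rng_seed = s))
    combo <- apply_drug_effect(ctrl, "combo")
    dc <- depth_binned_density(pamvasc:::new_vessel_mask(ctrl$absorber > 0,
                                                         ctrl$voxel_pitch_um))
    dx <- depth_binned_density(pamvasc:::new_vessel_mask(combo$absorber > 0,
                                                         combo$voxel_pitch_um))
    rs <- rs + dx$density[1] / dc$density[1]
    ru <- ru + dx$density[3] / dc$density[3]
  }
  expect_lt(rs, ru)
})

test_that("calibration targets implement their geometries", {
  edge <- make_calibration_target("edge", edge_x_um = 30)
  x <- (seq_len(dim(edge$absorber)[1]) - 1) * edge$voxel_pitch_um[1]
  expect_true(all(edge$absorber[x < 30, , ] == 1))
  expect_true(all(edge$absorber[x >= 30, , ] == 0))
  expect_error(make_calibration_target("edge", volume_size_um = c(-1, 10, 10)),
               "positive")

  # fiber: occupied cross-section ~ pi r^2 per unit length
  fib <- make_calibration_target("fiber", fiber_diameter_um = 10,
                                 voxel_pitch_um = c(2, 2, 1))
  vox_um3 <- prod(fib$voxel_pitch_um)
  # fiber axis spans the x extent
  area <- sum(fib$absorber) * vox_um3 / (dim(fib$absorber)[1] * 2)
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.25)
  expect_error(make_calibration_target("fiber", fiber_diameter_um = 0),
               "positive")

  # cell field: Poisson-distributed counts with mean density * volume
  counts <- sapply(1:15, function(s) {
    nrow(make_calibration_target("cell_field",
                                 volume_size_um = c(200, 200, 200),
                                 cell_density_mm3 = 5000,
                                 rng_seed = s)$cells)
  })
  lambda <- 5000 * prod(c(200, 200, 200)) * 1e-9
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.35)
  expect_error(make_calibration_target("cell_field", cell_density_mm3 = -2),
               "positive")
})
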