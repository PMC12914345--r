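test_that("depth-dose curve peaks at the nominal range and falls off", {
  for (R in c(50, 80, 120)) {
    z <- seq(0, R + 40, by = 0.1)
    dl <- depth_dose_let(R, z)
    # Bragg peak within 2% of the nominal range (dense-sweep oracle)
    expect_lt(abs(z[which.max(dl$dose)] - R) / R, 0.02)
    # distal falloff: negligible dose 20 mm past the range
    expect_lt(dl$dose[which.min(abs(z - (R + 20)))], 0.01 * max(dl$dose))
  }
  expect_error(depth_dose_let(-5, 10), class = "letplan_domain_error")
})

test_that("LET rises monotonically toward the Bragg peak", {
  R <- 100
  z <- seq(0, R + 10, by = 0.5)
  let <- depth_dose_let(R, z)$let
  expect_true(all(diff(let) >= -1e-12))
  expect_gt(depth_dose_let(R, 0.95 * R)$let,
            depth_dose_let(R, 0.30 * R)$let)
  # entrance and peak-region LET in physically sensible bands (keV/um)
  expect_gt(let[1], 0.3); expect_lt(let[1], 2)
  peak_let <- max(let)
  expect_gt(peak_let, 5); expect_lt(peak_let, 20)
})

test_that("radiological depth reproduces geometry in uniform water", {
  ph <- build_phantom(tiny_spec(
    densities = list(air = 1, tissue = 1, bone = 1)))
  ctv <- which(ph$masks$ctv)
  beam <- beam_config(0, 0)  # travels +y from the y = 0 grid face
  w <- radiological_depth(ph, beam, voxels = ctv)
  co <- letplan:::voxel_coordinates(dim(ph$density), ph$origin,
                                    ph$voxel_size)
  expect_lt(max(abs(w - co$y[ctv])), 1.5 + 1e-9)  # within half a voxel
})

test_that("radiological depth is linear in density and range scale", {
  ph <- tiny_phantom()
  half <- ph
  half$density <- ph$density / 2
  ctv <- which(ph$masks$ctv)
  beam <- beam_config(90, 0)
  w1 <- radiological_depth(ph, beam, voxels = ctv)
  expect_equal(radiological_depth(half, beam, voxels = ctv), w1 / 2)
  expect_equal(radiological_depth(ph, beam, range_scale = 1.035,
                                  voxels = ctv), 1.035 * w1)
  expect_error(radiological_depth(ph, beam, range_scale = 0),
               class = "letplan_domain_error")
})

test_that("spot placement covers the target depth interval at 5 mm", {
  ph <- tiny_phantom()
  spots <- place_spots(ph, tiny_beams())
  expect_s3_class(spots, "spot_grid")
  # adjacent lateral offsets differ by the 5 mm spacing
  for (b in unique(spots$beam)) {
    av <- sort(unique(spots$a[spots$beam == b]))
    expect_true(all(abs(diff(av) - 5) < 1e-9))
  }
  # spot ranges span the CTV's radiological-depth interval per beam
  ctv <- which(ph$masks$ctv)
  beams <- attr(spots, "beams")
  for (b in seq_along(beams)) {
    wepl <- radiological_depth(ph, beams[[b]], voxels = ctv)
    rng <- range(spots$range[spots$beam == b])
    expect_lte(rng[1], min(wepl) + 5)
    expect_gte(rng[2], max(wepl) - 5)
  }
  # empty target is rejected
  ph2 <- ph
  ph2$masks$ctv[] <- FALSE
  expect_error(place_spots(ph2, tiny_beams()),
               class = "letplan_placement_error")
})

test_that("influence entries are nonnegative with peaks at spot depths", {
  ph <- tiny_phantom()
  spots <- place_spots(ph, tiny_beams())
  inf <- compute_influence(ph, spots)
  expect_true(all(inf$D@x >= 0))
  expect_true(all(inf$L@x >= 0))
  # D and L share a sparsity pattern
  expect_identical(inf$D@i, inf$L@i)
  expect_identical(inf$D@p, inf$L@p)
  # every spot hitting the body deposits dose
  colsum <- Matrix::colSums(inf$D)
  expect_true(all(is.finite(colsum)))
  expect_gt(mean(colsum > 0), 0.95)
  # column maxima sit near each spot's radiological peak depth
  beams <- attr(spots, "beams")
  body <- which(ph$masks$body)
  set.seed(4)
  for (ci in sample(ncol(inf$D), 20)) {
    col <- inf$D[, ci]
    if (max(col) == 0) next
    imax <- which.max(col)
    wepl <- radiological_depth(ph, beams[[spots$beam[ci]]], voxels = imax)
    expect_lt(abs(wepl - spots$range[ci]), 6)
  }
})

test_that("dose is linear in spot weights (dense oracle)", {
  ph <- tiny_phantom()
  spots <- place_spots(ph, tiny_beams())
  inf <- compute_influence(ph, spots)
  set.seed(11)
  w <- runif(ncol(inf$D))
  sub <- sample(which(ph$masks$ctv), 40)
  Dd <- as.matrix(inf$D[sub, , drop = FALSE])
  dense <- as.numeric(Dd %*% w)
  expect_equal(as.numeric(inf$D[sub, ] %*% w), dense, tolerance = 1e-12)
  expect_equal(as.numeric(inf$D[sub, ] %*% (2 * w)), 2 * dense,
               tolerance = 1e-12)
})

test_that("nominal influence equals a zero-shift setup influence", {
  ph <- tiny_phantom()
  spots <- place_spots(ph, tiny_beams())
  a <- compute_influence(ph, spots, scenario_nominal())
  zero_shift <- scenario_nominal()
  zero_shift$shift <- c(0, 0, 0)
  b <- compute_influence(ph, spots, zero_shift)
  expect_equal(a$D, b$D)
  expect_equal(a$L, b$L)
})

test_that("shifting the patient equals shifting the beam the other way", {
  # on a translation-invariant (uniform water) phantom, a one-voxel
  # patient shift along x reproduces the dose field of the unshifted
  # patient sampled one voxel over (beam along +y, so x is purely lateral)
  ph <- build_phantom(tiny_spec(
    densities = list(air = 1, tissue = 1, bone = 1)))
  spots <- place_spots(ph, list(beam_config(0, 0)))
  nom <- compute_influence(ph, spots)
  sh <- compute_influence(ph, spots,
                          scenario("setup", shift = c(3, 0, 0)))
  w <- rep(1, ncol(nom$D))
  d_nom <- array(as.numeric(nom$D %*% w), dim = dim(ph$density))
  d_sh <- array(as.numeric(sh$D %*% w), dim = dim(ph$density))
  interior <- 5:(dim(ph$density)[1] - 5)
  # patient shifted +x: anatomy plane i sees what plane i+1 saw nominally
  a <- d_sh[interior, 10:20, 10:16]
  b <- d_nom[interior + 1, 10:20, 10:16]
  keep <- b > 0.05 * max(b)
  expect_lt(max(abs(a[keep] - b[keep]) / max(b)), 0.05)
})
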