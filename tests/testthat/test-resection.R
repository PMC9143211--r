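test_that("apply_resection partitions the mask exactly", {
  f <- unit_frame(c(30, 30, 40), spacing = 0.5)
  cube <- box_mask(f, c(1, 1, 1), c(13, 13, 18))
  mid <- resection_spec(resection_plane(c(7, 7, 9.5), c(0, 0, 1)))
  parts <- apply_resection(cube, mid)
  # exact voxel partition
  expect_equal(sum(parts$resected$mask) + sum(parts$residual$mask),
               sum(cube$mask))
  expect_equal(sum(parts$resected$mask & parts$residual$mask), 0)
  # symmetric cut: halves equal within one voxel layer
  layer <- max(apply(cube$mask, 3, sum))
  expect_lte(abs(sum(parts$resected$mask) - sum(parts$residual$mask)), layer)
  # plane entirely outside with normal pointing away: nothing resected
  away <- resection_spec(resection_plane(c(0, 0, 100), c(0, 0, 1)))
  expect_warning(p2 <- apply_resection(cube, away), "empty")
  expect_equal(sum(p2$resected$mask), 0)
})

test_that("volume conservation holds for random planes on the horseshoe", {
  ph <- make_phantom("horseshoe", spacing = 1)
  mandible <- segment_bone(ph$hu, ph$frame, 300)
  set.seed(31)
  for (i in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    p <- c(runif(1, -20, 20), runif(1, 0, 30), runif(1, -5, 5))
    parts <- suppressWarnings(
      apply_resection(mandible, resection_spec(resection_plane(p, n))))
    expect_identical(sum(parts$resected$mask) + sum(parts$residual$mask),
                     sum(mandible$mask))
    expect_identical(sum(parts$resected$mask & parts$residual$mask), 0L)
  }
})

test_that("two-plane slab volume matches a finer-grid oracle within 1%", {
  # plane offsets off the voxel lattice at every spacing tested
  spec <- resection_spec(list(resection_plane(c(0.13, 20, 0), c(1, 0, 0)),
                              resection_plane(c(20.13, 20, 0), c(-1, 0, 0))))
  vols <- vapply(c(1, 0.25), function(sp) {
    ph <- make_phantom("horseshoe", spacing = sp)
    mandible <- segment_bone(ph$hu, ph$frame, 300)
    volume_ml(apply_resection(mandible, spec)$resected)
  }, numeric(1))
  expect_lt(abs(vols[1] - vols[2]) / vols[2], 0.01)
})

test_that("seed-mode resection removes the connected segment holding the seed", {
  ph <- make_phantom("horseshoe", arch_radius = 30, tube_radius = 8,
                     arc_span_deg = 240, spacing = 1)
  mandible <- segment_bone(ph$hu, ph$frame, 300)
  planes <- list(resection_plane(c(0, 22, 0), c(1, 0, 0)),
                 resection_plane(c(14, 22, 0), c(-1, 0, 0)))
  seed_pt <- c(7, 29, 0)       # on the arch between the two planes
  parts <- apply_resection(mandible, resection_spec(planes, mode = "seed",
                                                    seed_point = seed_pt))
  hs <- apply_resection(mandible, resection_spec(planes))
  expect_equal(sum(parts$resected$mask), sum(hs$resected$mask))
  expect_identical(sum(parts$resected$mask) + sum(parts$residual$mask),
                   sum(mandible$mask))
})

test_that("fit_cut_planes recovers planted planes", {
  f <- unit_frame(c(60, 60, 80), spacing = 0.5)
  cube <- box_mask(f, c(2, 2, 2), c(27, 27, 37))
  spec0 <- resection_spec(list(resection_plane(c(15, 15, 15), c(0, 0, 1)),
                               resection_plane(c(15, 15, 25), c(0, 0, -1))))
  parts <- apply_resection(cube, spec0)
  rec <- fit_cut_planes(cube, parts$residual, 2)
  offs <- sort(vapply(rec$planes, function(pl) pl$point[3], numeric(1)))
  for (i in 1:2) {
    ang <- acos(pmin(1, abs(rec$planes[[i]]$normal[3]))) * 180 / pi
    expect_lt(ang, 1)
  }
  expect_lt(abs(offs[1] - 15), 0.5)
  expect_lt(abs(offs[2] - 25), 0.5)
  # normals point into the removed slab
  for (pl in rec$planes)
    expect_gt(plane_signed_distance(pl, c(15, 15, 20)), 0)
  expect_error(fit_cut_planes(cube, cube, 2), "no resection detected")
  # single oblique cut at 30 degrees
  n30 <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
  p1 <- apply_resection(cube, resection_spec(resection_plane(c(15, 15, 20), n30)))
  r1 <- fit_cut_planes(cube, p1$residual, 1)
  ang <- acos(pmin(1, abs(sum(r1$planes[[1]]$normal * n30)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("recovered planes reproduce the planted resection volume", {
  ph <- make_phantom("horseshoe", spacing = 0.8)
  mandible <- segment_bone(ph$hu, ph$frame, 300)
  spec0 <- resection_spec(list(resection_plane(c(-5, 25, 0), c(1, 0.2, 0)),
                               resection_plane(c(12, 25, 0), c(-1, 0.1, 0))))
  parts <- apply_resection(mandible, spec0)
  rec <- fit_cut_planes(mandible, parts$residual, 2)
  parts2 <- apply_resection(mandible, rec)
  expect_lt(abs(volume_ml(parts2$resected) - volume_ml(parts$resected)) /
              volume_ml(parts$resected), 0.02)
})
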