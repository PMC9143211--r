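test_that("volume_ml is voxel count times voxel volume", {
  f <- unit_frame(c(12, 12, 12))
  m <- box_mask(f, c(0.5, 0.5, 0.5), c(10.5, 10.5, 10.5))  # 10^3 voxel centers
  expect_equal(sum(m$mask), 1000)
  expect_equal(volume_ml(m), 1.0)
  empty <- binary_volume(f, array(FALSE, dim = f$shape))
  expect_equal(volume_ml(empty), 0)
})

test_that("sphere volume converges to the closed form as spacing shrinks", {
  analytic <- 4 / 3 * pi * 10^3 / 1000
  errs <- vapply(c(0.5, 0.25), function(sp) {
    ph <- make_phantom("sphere", radius = 10, spacing = sp)
    abs(volume_ml(binary_volume(ph$frame, ph$hu > 0)) - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1] / 2 + 1e-9)   # halving spacing at least halves error
})

test_that("segment_bone keeps the largest 26-connected component", {
  ph <- make_phantom("horseshoe", spacing = 1)
  seg <- segment_bone(ph$hu, ph$frame, 300)
  expect_equal(sum(seg$mask), sum(ph$hu > 0))   # two-level image: exact
  # two disjoint blobs: only the larger is retained
  f <- unit_frame(c(30, 12, 12))
  xyz <- voxel_centers(f)
  big <- xyz[, 1] < 10
  small <- xyz[, 1] > 24
  hu <- array(ifelse(big | small, 1200, -1000), dim = f$shape)
  seg2 <- segment_bone(hu, f, 300)
  expect_equal(sum(seg2$mask), sum(big))
  expect_error(segment_bone(hu, f, 2000), "no bone above threshold")
})

test_that("isodose regions are inclusive and nested", {
  # voxel centers at z = 0.5 .. 99.5 sample the 0-100 mm ramp D(z) = z
  f <- image_frame(c(0, 0, 0.5), c(1, 1, 1), c(10, 10, 100))
  zmm <- voxel_centers(f)[, 3]
  d <- dose_grid(f, array(zmm, dim = f$shape))
  # analytic fraction above 56 Gy on a 0-100 ramp is 44%, within half a voxel
  expect_equal(sum(isodose_region(d, 56)$region$mask) / prod(f$shape), 0.44,
               tolerance = 0.5 / 100 + 1e-9)
  full <- isodose_region(dose_grid(f, array(60, dim = f$shape)), 60)
  expect_true(all(full$region$mask))                 # inclusive >=
  # nesting across thresholds
  set.seed(5)
  dr <- dose_grid(f, array(runif(prod(f$shape), 0, 70), dim = f$shape))
  ts <- sort(runif(5, 5, 65))
  regions <- lapply(ts, function(t) isodose_region(dr, t)$region)
  for (i in seq_len(length(ts) - 1)) {
    expect_true(all(regions[[i + 1]]$mask <= regions[[i]]$mask))
    expect_lte(volume_ml(regions[[i + 1]]), volume_ml(regions[[i]]))
  }
})

test_that("intersection is exact voxelwise AND with frame checking", {
  f <- unit_frame(c(20, 20, 20))
  a <- box_mask(f, c(0, 0, 0), c(10, 19, 19))
  b <- box_mask(f, c(6, 0, 0), c(19, 19, 19))
  expect_equal(intersect_volumes(a, a)$mask, a$mask)
  empty <- binary_volume(f, array(FALSE, dim = f$shape))
  expect_equal(sum(intersect_volumes(a, empty)$mask), 0)
  # overlapping half-spaces: slab x in [6, 10] -> 5 voxel planes
  expect_equal(volume_ml(intersect_volumes(a, b)), 5 * 20 * 20 / 1000)
  expect_lte(volume_ml(intersect_volumes(a, b)),
             min(volume_ml(a), volume_ml(b)))
  g <- unit_frame(c(20, 20, 20), origin = c(1, 0, 0))
  expect_error(intersect_volumes(a, box_mask(g, c(0, 0, 0), c(5, 5, 5))),
               "resample")
})

test_that("dose resampling is exact on matching frames and affine fields", {
  f <- image_frame(c(0, 0, 0), c(1, 1, 1), c(10, 10, 20))
  zmm <- voxel_centers(f)[, 3]
  d <- dose_grid(f, array(2 * zmm + 5, dim = f$shape))
  expect_identical(resample_dose_to_frame(d, f)$values, d$values)
  # target offset by half a voxel: trilinear is exact for affine fields
  g <- image_frame(c(0, 0, 0.5), c(1, 1, 1), c(10, 10, 19))
  rz <- resample_dose_to_frame(d, g)
  expect_equal(rz$values, array(2 * voxel_centers(g)[, 3] + 5, dim = g$shape),
               tolerance = 1e-12)
  # voxels beyond the source support get 0 Gy
  h <- image_frame(c(0, 0, -10), c(1, 1, 1), c(10, 10, 40))
  rh <- resample_dose_to_frame(d, h)
  expect_true(all(rh$values[, , 1:9] == 0))
  expect_true(all(rh$values[, , 31:40] == 0))
})

test_that("contour rasterisation follows the center-in and even-odd rules", {
  f <- image_frame(c(0, 0, 0), c(1, 1, 2), c(30, 30, 5))
  sq <- cbind(c(4.5, 24.5, 24.5, 4.5), c(4.5, 4.5, 24.5, 24.5))
  cs <- contour_set("sq", lapply(0:4, function(k) list(z = 2 * k, xy = sq)))
  bv <- rasterize_contours(cs, f)
  for (k in 1:5) expect_equal(sum(bv$mask[, , k]), 400)   # 20x20 centers
  # annulus: inner square excluded by the even-odd rule
  inner <- cbind(c(9.5, 19.5, 19.5, 9.5), c(9.5, 9.5, 19.5, 19.5))
  ann <- contour_set("ann", list(list(z = 0, xy = sq), list(z = 0, xy = inner)))
  bva <- rasterize_contours(ann, f)
  expect_equal(sum(bva$mask[, , 1]), 400 - 100)
  # contour exactly midway between planes goes to the lower-index plane
  mid <- contour_set("mid", list(list(z = 1, xy = sq)))
  bvm <- rasterize_contours(mid, f)
  expect_equal(sum(bvm$mask[, , 1]), 400)
  expect_equal(sum(bvm$mask[, , 2]), 0)
  expect_error(rasterize_contours(contour_set("far",
    list(list(z = 500, xy = sq))), f), "overlap")
})

test_that("rasterised prism volume converges to area times height", {
  # convex polygon (diamond, 45-degree edges) so in-plane error is non-trivial
  r <- 10
  diam <- cbind(c(10.23 + r, 10.23, 10.23 - r, 10.23),
                c(10.41, 10.41 + r, 10.41, 10.41 - r))
  area <- 2 * r^2                      # shoelace area of the diamond
  analytic <- area * 10 / 1000         # 5 slices x 2 mm
  errs <- vapply(c(1, 0.25), function(sp) {
    n <- ceiling(26 / sp)
    f <- image_frame(c(-2, -2, 0), c(sp, sp, 2), c(n, n, 5))
    cs <- contour_set("d", lapply(0:4, function(k) list(z = 2 * k, xy = diam)))
    abs(volume_ml(rasterize_contours(cs, f)) - analytic)
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2 + 1e-9)
  expect_lt(errs[2] / analytic, 0.02)
})

test_that("mesh extraction is watertight and volume-accurate", {
  f <- unit_frame(c(5, 5, 5))
  single <- binary_volume(f, array(seq_len(125) == 63, dim = f$shape))
  ms <- mesh_from_mask(single)
  expect_true(mesh_is_watertight(ms))
  expect_lte(abs(mesh_volume_ml(ms) - 0.001) / 0.001, 0.5)
  ph <- make_phantom("sphere", radius = 10, spacing = 0.5)
  bv <- binary_volume(ph$frame, ph$hu > 0)
  mesh <- mesh_from_mask(bv)
  expect_true(mesh_is_watertight(mesh))
  expect_lt(abs(mesh_volume_ml(mesh) - ph$analytic_ml) / ph$analytic_ml, 0.02)
  # divergence-theorem volume vs voxel count volume
  expect_lt(abs(mesh_volume_ml(mesh) - volume_ml(bv)) / volume_ml(bv), 0.02)
  # mask touching the array border still closes (pad-by-one)
  g <- unit_frame(c(6, 6, 6))
  border <- binary_volume(g, array(TRUE, dim = g$shape))
  mb <- mesh_from_mask(border)
  expect_true(mesh_is_watertight(mb))
  expect_error(mesh_from_mask(binary_volume(g, array(FALSE, dim = g$shape))),
               "empty")
})
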