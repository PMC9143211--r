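test_that("the arch midline separates lingual from buccal points", {
  ph <- make_phantom("horseshoe", arch_radius = 30, tube_radius = 8,
                     arc_span_deg = 240, spacing = 1)
  mandible <- segment_bone(ph$hu, ph$frame, 300)
  ml <- mandible_midline(mandible)
  # points on the inner cortex are lingual, on the outer cortex buccal
  inner <- c(0, 24, 0)       # radius 24 < arch radius 30 at the apex
  outer <- c(0, 36, 0)
  expect_true(is_lingual(ml, inner))
  expect_false(is_lingual(ml, outer))
  th <- 150 * pi / 180       # near one arch end
  expect_true(is_lingual(ml, c(24 * cos(th), 24 * sin(th), 0)))
  expect_false(is_lingual(ml, c(36 * cos(th), 36 * sin(th), 0)))
})

test_that("constructed phantoms yield the planned cortical category", {
  for (kind in c("outside", "lingual", "bicortical")) {
    want <- switch(kind, outside = "outside", lingual = "lingual_only",
                   bicortical = "bicortical")
    for (seed in 1:3) {
      p <- make_classification_phantom(kind, seed)
      cl <- classify_osteotomy(p$plane, p$vm56, p$mandible)
      expect_identical(cl$category, want)
      # invariant table: outside iff both contact areas are zero
      if (cl$category == "outside") {
        expect_identical(cl$lingual_area_mm2 + cl$buccal_area_mm2, 0)
      } else if (cl$category == "lingual_only") {
        expect_gt(cl$lingual_area_mm2, 0)
        expect_identical(cl$buccal_area_mm2, 0)
      } else if (cl$category == "bicortical") {
        expect_gt(cl$lingual_area_mm2, 0)
        expect_gt(cl$buccal_area_mm2, 0)
      }
    }
  }
})

test_that("an empty high-dose region classifies as outside", {
  p <- make_classification_phantom("outside", 7)
  empty <- binary_volume(p$mandible$frame,
                         array(FALSE, dim = dim(p$mandible$mask)))
  cl <- classify_osteotomy(p$plane, empty, p$mandible)
  expect_identical(cl$category, "outside")
})

test_that("resections without a bone-cutting plane follow the residual rule", {
  p <- make_classification_phantom("bicortical", 3)
  # remove one arch end; irradiated bone remains -> counts as bicortical
  parts <- apply_resection(p$mandible,
                           resection_spec(resection_plane(c(-20, 10, 0),
                                                          c(-1, 0, 0))))
  cl <- classify_osteotomy(NULL, p$vm56, p$mandible, residual = parts$residual)
  expect_identical(cl$category, "bicortical")
  # nothing irradiated left -> outside
  gone <- binary_volume(p$mandible$frame,
                        array(FALSE, dim = dim(p$mandible$mask)))
  cl2 <- classify_osteotomy(NULL, gone, p$mandible, residual = parts$residual)
  expect_identical(cl2$category, "outside")
})

test_that("the cortical shell has the requested thickness", {
  ph <- make_phantom("horseshoe", spacing = 0.5)
  mandible <- segment_bone(ph$hu, ph$frame, 300)
  sh <- cortical_shell(mandible, 2)
  expect_true(all(sh$mask <= mandible$mask))
  # a tube of radius 8 with a 2 mm shell keeps roughly 1 - (6/8)^2 = 44%
  frac <- sum(sh$mask) / sum(mandible$mask)
  expect_gt(frac, 0.30)
  expect_lt(frac, 0.60)
})
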