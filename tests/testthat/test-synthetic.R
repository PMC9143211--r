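test_that("phantom volumes match their closed forms", {
  sp <- make_phantom("sphere", radius = 10, spacing = 0.5)
  expect_equal(sp$analytic_ml, 4.18879, tolerance = 1e-5)
  expect_equal(volume_ml(binary_volume(sp$frame, sp$hu > 0)), sp$analytic_ml,
               tolerance = 0.02 * sp$analytic_ml)
  hs <- make_phantom("horseshoe", arch_radius = 30, tube_radius = 8,
                     arc_span_deg = 180, spacing = 0.5)
  expect_equal(hs$analytic_ml, pi * 64 * pi * 30 / 1000, tolerance = 1e-9)
  expect_equal(volume_ml(binary_volume(hs$frame, hs$hu > 0)), hs$analytic_ml,
               tolerance = 0.02 * hs$analytic_ml)
  expect_error(make_phantom("horseshoe", arch_radius = 10, tube_radius = 12),
               "self-intersection")
  expect_error(make_phantom("horseshoe", arc_span_deg = 380), "arc span")
  f <- unit_frame(c(10, 10, 10))
  expect_warning(make_phantom("sphere", center = c(500, 0, 0), radius = 5,
                              frame = f), "outside")
})

test_that("dose fields sample their analytic models exactly", {
  f <- image_frame(c(0, 0, 0), c(2, 2, 1), c(10, 10, 60))
  ramp <- make_dose("linear_ramp", f, gradient = 1, offset = 0)
  expect_equal(ramp$values[1, 1, 57], 56)       # z = 56 mm exactly
  ps <- make_dose("point_source", f, focus = c(10, 10, 30), peak = 70,
                  sigma = 25)
  expect_equal(max(ps$values), 70)
  at25 <- attr(ps, "field_fn")(c(10, 10, 55))   # 25 mm from the focus
  expect_equal(at25, 70 * exp(-0.5), tolerance = 1e-9)
  expect_error(make_dose("point_source", f, peak = 55), "envelope")
  expect_error(make_dose("linear_ramp", f, gradient = 10), "envelope")
  expect_true(all(ps$values >= 0))
})

test_that("case generation is deterministic and honours its targets", {
  a <- make_case(77, fine_factor = 0)
  b <- make_case(77, fine_factor = 0)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$params, b$params)
  c2 <- make_case(78, fine_factor = 0)
  expect_false(identical(a$metrics, c2$metrics))
  # target mandible volume and irradiated fraction approximately realised
  t1 <- make_case(5, fine_factor = 0, vm_ml = 60, vm56_frac = 0.4)
  expect_lt(abs(t1$metrics$Vm - 60) / 60, 0.1)
  expect_lt(abs(t1$metrics$Vm56_over_Vm - 40), 5)
})

test_that("bracketing planes empty the hot region; interior planes do not", {
  base <- make_case(12, fine_factor = 0, vm56_frac = 0.15, resect_frac = 0.5)
  # hot region is small and central, resection wide: everything hot removed
  expect_lt(base$metrics$Vm56R, 0.05 * base$metrics$Vm56 + 0.2)
  narrow <- make_case(12, fine_factor = 0, vm56_frac = 0.6, resect_frac = 0.1)
  expect_gt(narrow$metrics$Vm56R, 0)
  vm56 <- intersect_volumes(narrow$mandible, narrow$isodose)
  cl <- classify_osteotomy(narrow$planes[[1]], vm56, narrow$mandible)
  expect_false(cl$category == "outside")
})

test_that("pipeline metrics agree with the fine-grid ground truth", {
  pct <- c("Vm56_over_Vm", "Vm_PTV_over_Vm", "VmR_over_Vm")
  for (seed in c(301, 302, 303, 304, 305)) {
    cs <- make_case(seed)
    m <- unlist(unclass(cs$metrics))
    tr <- unlist(unclass(cs$truth))
    for (f in names(m)) {
      floorv <- if (f %in% pct) 0.5 else 0.1
      expect_lt(abs(m[[f]] - tr[[f]]), max(0.02 * tr[[f]], floorv))
    }
  }
})

test_that("cohorts are reproducible and group-structured", {
  c1 <- make_cohort(n_nonrecurrent = 6, n_recurrent = 3, seed = 21,
                    mode = "geometry", spacing = 1.5)
  c2 <- make_cohort(n_nonrecurrent = 6, n_recurrent = 3, seed = 21,
                    mode = "geometry", spacing = 1.5)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$metrics), 9)
  expect_equal(nrow(c1$planes), 18)          # two planes per case
  expect_true(all(c1$metrics$Vm56 <= c1$metrics$Vm + 1e-9))
  expect_true(all(c1$metrics$Vm56R <= c1$metrics$Vm56 + 1e-9))
  expect_error(make_cohort(5, 2), "seed")
  # sample mode: group means follow the cohort distributions at large n
  big <- make_cohort(n_nonrecurrent = 2000, n_recurrent = 2000, seed = 3,
                     mode = "sample")
  vm_nr <- big$metrics$Vm[big$metrics$group == "non_recurrent"]
  vm_r <- big$metrics$Vm[big$metrics$group == "recurrent"]
  expect_lt(abs(mean(vm_nr) - 65.4), 2 * sd(vm_nr) / sqrt(length(vm_nr)) + 1)
  expect_lt(abs(mean(vm_r) - 47.8), 2 * sd(vm_r) / sqrt(length(vm_r)) + 1)
  expect_gt(mean(vm_nr), mean(vm_r))
})
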