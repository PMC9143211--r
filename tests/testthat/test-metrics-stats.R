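test_that("compute_metrics handles the containment and disjoint cases", {
  f <- unit_frame(c(30, 30, 30))
  mandible <- sphere_mask(f, c(14, 14, 14), 8)
  everywhere <- binary_volume(f, array(TRUE, dim = f$shape))
  m <- compute_metrics(mandible, everywhere, NULL, NULL)
  expect_equal(m$Vm56, m$Vm)
  expect_equal(m$Vm56_over_Vm, 100)
  expect_equal(m$VmR, 0)
  nowhere <- binary_volume(f, array(FALSE, dim = f$shape))
  spec <- resection_spec(resection_plane(c(14, 14, 14), c(0, 0, 1)))
  m2 <- compute_metrics(mandible, nowhere, NULL, spec)
  expect_equal(m2$Vm56, 0)
  expect_equal(m2$Vm56R, 0)
  g <- unit_frame(c(30, 30, 30), origin = c(0.5, 0, 0))
  expect_error(compute_metrics(mandible,
                               binary_volume(g, array(TRUE, dim = g$shape)),
                               NULL, NULL), "resample")
})

test_that("metrics on a sphere phantom match spherical-cap closed forms", {
  r <- 20
  f <- image_frame(c(-24, -24, -24), c(0.5, 0.5, 0.5), c(97, 97, 97))
  mandible <- sphere_mask(f, c(0, 0, 0), r)
  zmm <- voxel_centers(f)[, 3]
  # hot region z >= 0.13, cut plane z = 10.2: both off the voxel lattice so
  # half-open membership carries no systematic layer bias
  dose <- dose_grid(f, array(pmax(0, 56 + zmm - 0.13), dim = f$shape))
  iso <- isodose_region(dose, 56)
  ptv <- sphere_mask(f, c(0, 0, 0), 12)
  spec <- resection_spec(resection_plane(c(0, 0, 10.2), c(0, 0, 1)))
  m <- compute_metrics(mandible, iso, ptv, spec)
  vol_sphere <- 4 / 3 * pi * r^3 / 1000
  cap <- function(rr, h) pi * h^2 * (3 * rr - h) / 3 / 1000
  expect_equal(m$Vm, vol_sphere, tolerance = 0.02)
  expect_equal(m$Vm56, cap(r, r - 0.13), tolerance = 0.02)
  expect_equal(m$VmR, cap(r, r - 10.2), tolerance = 0.02)
  expect_equal(m$Vm56R, cap(r, r - 0.13) - cap(r, r - 10.2), tolerance = 0.02)
  expect_equal(m$Vm_PTV, 4 / 3 * pi * 12^3 / 1000, tolerance = 0.02)
  expect_equal(m$Vm_PTV_R, 4 / 3 * pi * 12^3 / 1000 - cap(12, 1.8),
               tolerance = 0.02)
  # percentages recompute from the mL fields
  expect_equal(m$Vm56_over_Vm, 100 * m$Vm56 / m$Vm, tolerance = 1e-9)
})

test_that("volume_metrics enforces containment invariants", {
  expect_error(volume_metrics(Vm = 10, V56 = 100, V_PTV = 5, Vm56 = 12,
                              Vm_PTV = 2, VmR = 3, Vm56R = 1, Vm_PTV_R = 0),
               "containment")
  expect_error(volume_metrics(Vm = 10, V56 = 100, V_PTV = 5, Vm56 = 8,
                              Vm_PTV = 2, VmR = 3, Vm56R = 9, Vm_PTV_R = 0),
               "containment")
})

test_that("the Lilliefors normality test separates normal from skewed data", {
  expect_error(normality_test(c(1, 2, 3)), "n >= 4")
  expect_error(normality_test(rep(5, 10)), "zero variance")
  set.seed(101)
  normal_p <- replicate(60, normality_test(rnorm(120))$p)
  exp_p <- replicate(60, normality_test(rexp(120))$p)
  expect_gte(mean(normal_p > 0.05), 0.90)
  expect_gte(mean(exp_p < 0.05), 0.95)
})

test_that("Lilliefors p-values track the reference implementation", {
  set.seed(7)
  for (x in list(rnorm(25), rexp(30), runif(40))) {
    ours <- normality_test(x)
    ref <- nortest::lillie.test(x)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_lt(abs(ours$p - ref$p.value), 0.05)
  }
})

test_that("compare_groups gates on normality and handles degenerate input", {
  set.seed(55)
  a <- rnorm(20, 10, 2); b <- rnorm(20, 10, 2)
  res <- compare_groups(a, b)
  expect_identical(res$test, "t")
  sk <- rexp(30); sk2 <- rexp(30)
  res2 <- compare_groups(sk^3, sk2^3)
  expect_identical(res2$test, "MWW")
  same <- rep(3.3, 5)
  res3 <- compare_groups(same, same)
  expect_equal(res3$p, 1)
  expect_equal(res3$statistic, 0)
  expect_error(compare_groups(1, 1:5), "n >= 2")
  ident <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p, 0.98)
})

test_that("small-sample Mann-Whitney p equals exhaustive enumeration", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$test, "MWW")
  expect_equal(unname(res$statistic), 0)    # U = 0
  expect_equal(res$p, 0.1)                  # 2/20 arrangements as extreme
  set.seed(77)
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- round(runif(na, 0, 100), 3)        # continuous: no ties
    b <- round(runif(nb, 0, 100), 3)
    res <- compare_groups(a, b)
    if (res$test == "MWW")
      expect_equal(res$p, mww_exact_enum(a, b), tolerance = 1e-9)
  }
})

test_that("osteotomy tabulation counts categories and groups", {
  df <- data.frame(
    category = c(rep("outside", 3), rep("lingual_only", 2), rep("bicortical", 5)),
    group = c(rep("non_recurrent", 7), rep("recurrent", 3)))
  tab <- tabulate_osteotomies(df)
  expect_equal(as.numeric(tab$total), c(3, 2, 0, 5))
  expect_equal(sum(tab$total), nrow(df))
  expect_equal(sum(tab$by_group), nrow(df))
  empty <- tabulate_osteotomies(data.frame(category = character(0)))
  expect_equal(sum(empty$total), 0)
})

test_that("cohort_summary produces per-group rows and flags inconsistencies", {
  set.seed(12)
  coh <- make_cohort(n_nonrecurrent = 10, n_recurrent = 5, seed = 9,
                     mode = "sample")
  res <- cohort_summary(coh$metrics)
  expect_true(all(c("group", "metric", "mean", "min", "max") %in%
                    names(res$summary)))
  expect_length(res$comparisons, 11)
  expect_length(res$percent_inconsistencies, 0)
  bad <- coh$metrics
  bad$Vm56_over_Vm <- bad$Vm56_over_Vm + 5
  expect_true("Vm56_over_Vm" %in%
                cohort_summary(bad)$percent_inconsistencies)
  expect_error(cohort_summary(coh$metrics, group_col = "nope"), "available")
  one <- coh$metrics[coh$metrics$group == "recurrent", ]
  expect_error(cohort_summary(one), "two groups")
})
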