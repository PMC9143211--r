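test_that("CT series round-trips frame and HU exactly", {
  td <- withr::local_tempdir()
  f <- image_frame(c(-10, -20, 5), c(1, 2, 2.5), c(12, 10, 6))
  set.seed(11)
  hu <- array(round(rnorm(prod(f$shape), 0, 300)), dim = f$shape)
  write_ct_series(file.path(td, "ct"), hu, f, "2.25.9001")
  ct <- read_ct_series(file.path(td, "ct"))
  expect_lt(max(abs(ct$frame$origin - f$origin)), 1e-6)
  expect_lt(max(abs(ct$frame$spacing - f$spacing)), 1e-6)
  expect_identical(dim(ct$hu), dim(hu))
  expect_equal(ct$hu, hu)
})

test_that("slice order on disk does not matter", {
  td <- withr::local_tempdir()
  f <- image_frame(c(0, 0, 0), c(1, 1, 2), c(6, 6, 5))
  hu <- array(seq_len(prod(f$shape)) %% 1000, dim = f$shape)
  paths <- write_ct_series(file.path(td, "ct"), hu, f, "2.25.9002")
  # shuffle by renaming so directory listing order changes
  tmp <- file.path(td, "ct", sprintf("z_%04d.dcm", rev(seq_along(paths))))
  file.rename(paths, tmp)
  ct <- read_ct_series(file.path(td, "ct"))
  expect_equal(ct$hu, hu)
  expect_equal(ct$frame$origin, f$origin)
})

test_that("mixed or inconsistent series are rejected with identifiers", {
  td <- withr::local_tempdir()
  f1 <- image_frame(c(0, 0, 0), c(1, 1, 2), c(6, 6, 3))
  f2 <- image_frame(c(0, 0, 6), c(2, 2, 2), c(6, 6, 3))
  hu <- array(0, dim = f1$shape)
  write_ct_series(file.path(td, "ct"), hu, f1, "2.25.9003")
  # second series with different UID root and spacing into the same directory
  p2 <- write_ct_series(file.path(td, "ct2"), hu, f2, "2.25.9004")
  file.copy(p2, file.path(td, "ct", paste0("b_", basename(p2))))
  expect_error(read_ct_series(file.path(td, "ct")),
               "mixed.*(9003|9004).*(9003|9004)")
})

test_that("RTDOSE values are stored integers times the scaling factor", {
  td <- withr::local_tempdir()
  f <- image_frame(c(0, 0, 0), c(2, 2, 2), c(8, 8, 4))
  uniform <- dose_grid(f, array(60, dim = f$shape))
  write_rtdose(file.path(td, "u.dcm"), uniform, "2.25.9005")
  expect_equal(unique(as.numeric(read_rtdose(file.path(td, "u.dcm"))$values)),
               60, tolerance = 1e-9)
  zmm <- voxel_centers(f)[, 3]
  ramp <- dose_grid(f, array(70 * zmm / max(zmm), dim = f$shape))
  write_rtdose(file.path(td, "r.dcm"), ramp, "2.25.9006")
  r2 <- read_rtdose(file.path(td, "r.dcm"))
  expect_equal(max(r2$values), 70, tolerance = 1e-3)
  expect_equal(min(r2$values), 0)
  # definition of scaling: stored 5600 at scaling 0.01 is 56 Gy
  write_rtdose(file.path(td, "s.dcm"), dose_grid(f, array(56, dim = f$shape)),
               "2.25.9007", scaling = 0.01)
  expect_equal(unique(as.numeric(read_rtdose(file.path(td, "s.dcm"))$values)), 56)
  # round trip quantum: error bounded by the scaling factor
  set.seed(2)
  noisy <- dose_grid(f, array(runif(prod(f$shape), 0, 66), dim = f$shape))
  write_rtdose(file.path(td, "n.dcm"), noisy, "2.25.9008")
  q <- max(noisy$values) / 60000
  expect_lt(max(abs(read_rtdose(file.path(td, "n.dcm"))$values - noisy$values)),
            q)
})

test_that("RTSTRUCT ROIs match case-insensitively and errors list names", {
  td <- withr::local_tempdir()
  sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
  cs <- contour_set("mandible",
                    lapply(1:5, function(k) list(z = 2 * k, xy = sq)))
  ptv <- contour_set("ptv", list(list(z = 4, xy = sq / 2)))
  write_rtstruct(file.path(td, "rs.dcm"), list(cs, ptv), "2.25.9009")
  got <- read_rtstruct(file.path(td, "rs.dcm"), c("Mandible", "PTV"))
  expect_named(got, c("Mandible", "PTV"))
  zs <- vapply(got$Mandible$contours, `[[`, numeric(1), "z")
  expect_equal(zs, c(2, 4, 6, 8, 10))   # sorted
  expect_error(read_rtstruct(file.path(td, "rs.dcm"), "maxilla"),
               "mandible, ptv")
})

test_that("written fixtures are readable by an independent DICOM parser", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  td <- withr::local_tempdir()
  f <- image_frame(c(-5, -5, 0), c(1, 1, 2), c(8, 6, 3))
  hu <- array(rep(c(-1000, 1200), length.out = prod(f$shape)), dim = f$shape)
  write_ct_series(file.path(td, "ct"), hu, f, "2.25.9010")
  write_rtdose(file.path(td, "d.dcm"),
               dose_grid(f, array(42, dim = f$shape)), "2.25.9010")
  script <- file.path(td, "check.py")
  writeLines(c(
    "import sys, glob, pydicom",
    sprintf("base = %s", shQuote(td)),
    "ct = pydicom.dcmread(sorted(glob.glob(base + '/ct/*.dcm'))[0])",
    "assert ct.Modality == 'CT' and int(ct.Rows) == 6 and int(ct.Columns) == 8",
    "assert [float(v) for v in ct.ImagePositionPatient] == [-5.0, -5.0, 0.0]",
    "d = pydicom.dcmread(base + '/d.dcm')",
    "v = d.pixel_array.astype(float) * float(d.DoseGridScaling)",
    "assert abs(v.max() - 42) < 1e-2 and abs(v.min() - 42) < 1e-2",
    "print('OK')"), script)
  out <- system2(py, script, stdout = TRUE, stderr = TRUE)
  expect_equal(tail(out, 1), "OK")
})
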