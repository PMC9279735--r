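# DICOM fixtures are generated at run time by the package's own writer; the
# reader is then exercised against them plus hand-constructed tag streams.

test_that("a CT series round-trips through write and read", {
  v <- tiny_volume(dim = c(12, 10, 5), spacing = c(1.5, 2, 3),
                   origin = c(-10, -8, 4))
  set.seed(21)
  v$voxels[] <- sample(-1000:1500, length(v$voxels), replace = TRUE)
  dir <- withr::local_tempdir()
  write_dicom_ct_series(v, dir)
  rv <- read_dicom_series(dir)
  expect_equal(rv$voxels, v$voxels)
  expect_equal(rv$spacing, v$spacing)
  expect_equal(rv$origin, v$origin)
})

test_that("non-uniform slice spacing in a series is a hard error", {
  v <- tiny_volume(dim = c(6, 6, 6), spacing = c(2, 2, 2))
  dir <- withr::local_tempdir()
  paths <- write_dicom_ct_series(v, dir)
  file.remove(paths[3])  # gap in the stack
  expect_error(read_dicom_series(dir), "non-uniform")
})

test_that("RT Dose honors DoseGridScaling: value = scaling * stored pixel", {
  d <- c(8, 6, 4)
  scaling <- 1.25e-3
  pixels <- array(sample(0:60000, prod(d), replace = TRUE), d)
  dose <- dose_grid(pixels * scaling, c(2.5, 2.5, 2), c(0, 0, -4))
  path <- file.path(withr::local_tempdir(), "rtdose.dcm")
  write_dicom_rtdose(dose, path, scaling = scaling)
  rd <- read_dicom_rtdose(path)
  expect_equal(rd$voxels, dose$voxels, tolerance = 1e-12)
  expect_equal(rd$spacing, dose$spacing)
  expect_equal(rd$origin, dose$origin)
})

test_that("RT Structure Set contours round-trip and rasterize like the originals", {
  grid <- tiny_volume(dim = c(24, 24, 6), spacing = c(1, 1, 3))
  sq <- function(cx, cy, half, z)
    cbind(c(cx - half, cx + half, cx + half, cx - half),
          c(cy - half, cy - half, cy + half, cy + half), z)
  contours <- list(
    ptv = list(sq(10, 10, 5, 0), sq(10, 10, 5, 3)),
    ring = list(sq(12, 12, 8, 6), sq(12, 12, 3, 6)))
  path <- file.path(withr::local_tempdir(), "rtstruct.dcm")
  write_dicom_rtstruct(contours, path)
  rc <- read_dicom_rtstruct(path)
  expect_named(rc, c("ptv", "ring"))
  expect_equal(rc$ptv[[1]], unname(contours$ptv[[1]]), tolerance = 1e-9)
  m1 <- rasterize_contours(rc$ring, grid)
  m2 <- rasterize_contours(contours$ring, grid)
  expect_identical(m1, m2)
  expect_true(any(m1))
})

test_that("the DICOM dialect assembles a full plan bundle on the CT grid", {
  v <- tiny_volume(dim = c(20, 20, 6), spacing = c(2, 2, 3), origin = c(-19, -19, 0))
  set.seed(3); v$voxels[] <- round(rnorm(length(v$voxels), 0, 100))
  dosef <- function(w) pmax(40 - 0.05 * (w[, 1]^2 + w[, 2]^2) / 10, 0)
  dose <- dose_grid(array(dosef(rtflow:::grid_world_coords(v)), c(20, 20, 6)),
                    v$spacing, v$origin)
  sq <- function(z) cbind(c(-8, 8, 8, -8), c(-8, -8, 8, 8), z)
  contours <- list(ptv_60 = list(sq(0), sq(3), sq(6)),
                   cord = list(cbind(c(-2, 2, 2, -2), c(10, 10, 14, 14), 3)))
  dir <- withr::local_tempdir()
  write_dicom_ct_series(v, file.path(dir, "ct"))
  write_dicom_rtdose(dose, file.path(dir, "dose.dcm"))
  write_dicom_rtstruct(contours, file.path(dir, "ss.dcm"))
  rb <- read_plan_bundle(list(ct = file.path(dir, "ct"),
                              rtdose = file.path(dir, "dose.dcm"),
                              rtstruct = file.path(dir, "ss.dcm")),
                         dialect = "dicom",
                         plan_meta = list(total_fractions = 30,
                                          prescriptions = list(ptv_60 = 60),
                                          roles = list(ptv_60 = "target")))
  expect_equal(rb$plan$total_fractions, 30L)
  expect_equal(rb$plan$structures$ptv_60$prescription, 60)
  expect_equal(rb$plan$structures$cord$role, "oar")
  expect_identical(rtflow:::vol_dim(rb$dose), rtflow:::vol_dim(rb$image))
  expect_equal(rb$image$voxels, v$voxels)
  # masks live on the CT grid
  expect_identical(dim(rb$plan$structures$ptv_60$mask), rtflow:::vol_dim(v))
  expect_true(sum(rb$plan$structures$ptv_60$mask) > 0)
})
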