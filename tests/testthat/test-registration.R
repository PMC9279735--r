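test_that("registering an image to itself yields a near-zero field", {
  b <- std_bundle()
  dvf <- register(b$image, b$image)
  expect_lt(max(dvf_magnitude(dvf)), 0.1)
  expect_true(attr(dvf, "converged"))
})

test_that("a 5 mm rigid shift is recovered within 1 mm median inside the body", {
  b <- std_bundle()
  daily <- shifted_volume(b$image, c(5, 0, 0))
  dvf <- register(b$image, daily)
  body <- b$plan$structures$body$mask
  expect_lt(abs(median(dvf$ux[body]) - 5), 1)
  expect_lt(abs(median(dvf$uy[body])), 1)
  expect_lt(abs(median(dvf$uz[body])), 1)
  # warping the daily image by the recovered field restores alignment over
  # the interior (the outermost slices sit at the field-of-view edge, where
  # no image gradient constrains the flow)
  w <- warp_image(daily, dvf, background = min(daily$voxels))
  nz <- dim(body)[3]
  interior <- body; interior[, , c(1, nz)] <- FALSE
  expect_gt(ncc(w$voxels, b$image$voxels, interior),
            ncc(daily$voxels, b$image$voxels, interior))
  expect_gt(ncc(w$voxels, b$image$voxels, interior), 0.95)
})

test_that("a prescribed 4 mm medial parotid drift is recovered within 1.5 mm", {
  # reference resolution (2 mm), the regime the tolerance is stated for
  cfg <- phantom_config(n_fractions = 8)
  b <- make_plan_phantom(cfg, seed = 11)
  # the gland ipsilateral to the target drifts; the contralateral one holds
  tr <- course_truth(cfg, n_fractions = 8, parotid_drift_mm = c(0.5, 0),
                     parotid_shrink_rate = 0, target_shrink_rate = 0,
                     body_shrink_rate = 0, setup_sd_mm = 0, setup_rot_sd_deg = 0,
                     noise_sd = 20, seed = 12)
  course <- simulate_course(b, tr)
  f <- 8  # 4 mm accumulated medial shift
  dvf <- register(b$image, course$daily[[f]])
  tru <- course$dvf[[f]]
  err <- sqrt((dvf$ux - tru$ux)^2 + (dvf$uy - tru$uy)^2 + (dvf$uz - tru$uz)^2)
  mask <- b$plan$structures$parotid_left$mask
  expect_gt(mean(dvf_magnitude(tru)[mask]), 3.5)  # the drift really is ~4 mm
  expect_lt(mean(err[mask]), 1.5)
  # the static gland stays put under registration too
  expect_lt(mean(err[b$plan$structures$parotid_right$mask]), 1.5)
})

test_that("registration needs physical overlap and is deterministic", {
  b <- std_bundle()
  far <- b$image
  far$origin <- far$origin + c(10000, 0, 0)
  expect_error(register(b$image, far), "overlap")
  daily <- shifted_volume(b$image, c(2, -1, 1))
  d1 <- register(b$image, daily)
  d2 <- register(b$image, daily)
  expect_identical(d1$ux, d2$ux)
  expect_identical(d1$uz, d2$uz)
})

test_that("warp_image shifts content by whole voxels exactly in the interior", {
  v <- tiny_volume(dim = c(14, 12, 9), spacing = c(2, 3, 4))
  set.seed(14); v$voxels[] <- rnorm(length(v$voxels))
  u <- dvf_zero(v); u$uy[] <- 3  # one voxel along y
  w <- warp_image(v, u, background = NA)
  expect_equal(w$voxels[, 1:11, ], v$voxels[, 2:12, ], tolerance = 1e-12)
  expect_error(warp_image(tiny_volume(dim = c(5, 5, 5)), u), "geometr")
})
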