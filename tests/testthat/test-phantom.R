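test_that("the phantom plan is a valid, reproducible baseline", {
  b1 <- make_plan_phantom(std_config(), seed = 11)
  b2 <- make_plan_phantom(std_config(), seed = 11)
  expect_identical(b1$image$voxels, b2$image$voxels)
  expect_identical(b1$dose$voxels, b2$dose$voxels)
  b3 <- make_plan_phantom(std_config(), seed = 12)
  expect_false(identical(b1$image$voxels, b3$image$voxels))
  pm <- plan_metrics(b1)
  # both targets fully covered by their prescription plateau
  expect_equal(pm$ptv_60$V95, 100)
  expect_equal(pm$ptv_54$V95, 100)
  # spared parotids planned below the 20 Gy mean-dose goal
  expect_lt(pm$parotid_left$Dmean, 20)
  expect_lt(pm$parotid_right$Dmean, 20)
  # analytic oracle for the parotid mean: dose model integrated over the mask
  cfg <- std_config()
  dosef <- phantom_dose_fun(cfg)
  w <- rtflow:::grid_world_coords(b1$image)
  oracle <- mean(dosef(w[as.vector(b1$plan$structures$parotid_left$mask), ]))
  expect_equal(pm$parotid_left$Dmean, oracle, tolerance = 1e-9)
})

test_that("infeasible geometry is rejected", {
  expect_error(make_plan_phantom(phantom_config(dim = c(24, 24, 16),
                                                spacing = c(2, 2, 2))),
               "exceeds the grid")
  expect_error(make_plan_phantom(std_config() |>
                                   modifyList(list(parotid_center_x = 85)) |>
                                   structure(class = "phantom_config")),
               "outside the body")
})

test_that("a zero-change truth reproduces the plan images exactly", {
  cfg <- std_config(3)
  b <- make_plan_phantom(cfg, seed = 11)
  tr <- course_truth(cfg, parotid_drift_mm = 0, parotid_shrink_rate = 0,
                     target_shrink_rate = 0, body_shrink_rate = 0,
                     setup_sd_mm = 0, setup_rot_sd_deg = 0, noise_sd = 0,
                     seed = 1)
  course <- simulate_course(b, tr)
  for (f in 1:3) {
    expect_equal(course$daily[[f]]$voxels, b$image$voxels)
    expect_equal(max(dvf_magnitude(course$dvf[[f]])), 0)
  }
})

test_that("a single rigid setup error gives a constant ground-truth field", {
  cfg <- std_config(2)
  b <- make_plan_phantom(cfg, seed = 11)
  tr <- course_truth(cfg, parotid_drift_mm = 0, parotid_shrink_rate = 0,
                     target_shrink_rate = 0, body_shrink_rate = 0,
                     setup_sd_mm = 0, setup_rot_sd_deg = 0, noise_sd = 0,
                     seed = 1)
  tr$rigid$tx[2] <- 5  # 5 mm lateral error at fraction 2 only
  course <- simulate_course(b, tr)
  expect_equal(max(dvf_magnitude(course$dvf[[1]])), 0)
  u2 <- course$dvf[[2]]
  expect_equal(range(u2$ux), c(5, 5))
  expect_equal(range(u2$uy), c(0, 0))
  expect_equal(range(u2$uz), c(0, 0))
  # and the daily image is the plan content shifted by +5 mm
  oracle <- shifted_volume(b$image, c(5, 0, 0))
  expect_equal(course$daily[[2]]$voxels, oracle$voxels, tolerance = 1e-9)
})

test_that("simulated courses are reproducible from (config, seed)", {
  cfg <- std_config(2)
  b <- make_plan_phantom(cfg, seed = 11)
  tr1 <- course_truth(cfg, parotid_drift_mm = 0.5, seed = 21)
  tr2 <- course_truth(cfg, parotid_drift_mm = 0.5, seed = 21)
  c1 <- simulate_course(b, tr1)
  c2 <- simulate_course(b, tr2)
  expect_identical(c1$daily[[2]]$voxels, c2$daily[[2]]$voxels)
  expect_identical(c1$dvf[[2]]$ux, c2$dvf[[2]]$ux)
})

test_that("a drifting gland sees monotonically rising dose matching the model", {
  # reference-resolution grid (2 mm): interpolation error stays well under
  # the 2% band of the analytic oracle
  cfg <- phantom_config(n_fractions = 10)
  b <- make_plan_phantom(cfg, seed = 11)
  tr <- course_truth(cfg, parotid_drift_mm = 0.5, setup_sd_mm = 0,
                     setup_rot_sd_deg = 0, noise_sd = 0, seed = 21)
  st <- b$plan$structures$parotid_left
  dvfs <- lapply(1:10, function(f) truth_dvf(tr, b$image, f))
  dmean <- vapply(1:10, function(f)
    mean(daily_dose(b$dose, dvfs[[f]], st)$dose_full_course), 0)
  expect_true(all(diff(dmean) > 0))
  dosef <- phantom_dose_fun(cfg)
  w <- rtflow:::grid_world_coords(b$image)[as.vector(st$mask), ]
  for (f in c(3, 7, 10)) {
    oracle <- mean(dosef(rtflow:::truth_forward(tr, w, f)))
    expect_lt(abs(dmean[f] - oracle) / oracle, 0.02)
  }
})

test_that("drift pushing structures off the grid names the failing fraction", {
  cfg <- std_config(4)
  b <- make_plan_phantom(cfg, seed = 11)
  tr <- course_truth(cfg, parotid_drift_mm = 0, setup_sd_mm = 0,
                     setup_rot_sd_deg = 0, noise_sd = 0, seed = 1)
  tr$rigid$tx[3] <- 500
  expect_error(simulate_course(b, tr), "fraction 3")
})

test_that("a full fixture course can be written to disk and read back", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(dim = c(28, 28, 18), spacing = c(6, 6, 6),
                        body_semiaxes = c(70, 60), ptv_high_r = 14,
                        ptv_low_r = 22, parotid_center_x = 42,
                        mandible_R = 34, mandible_tube = 5)
  tr <- course_truth(cfg, n_fractions = 2, seed = 3)
  write_phantom_course(dir, cfg, tr, seed = 3)
  rb <- read_plan_bundle(dir, "fixture")
  expect_equal(rb$plan$total_fractions, cfg$n_fractions)
  d1 <- read_daily_volume(file.path(dir, "daily_001.nii.gz"), "fixture")
  expect_identical(rtflow:::vol_dim(d1), rtflow:::vol_dim(rb$image))
})
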