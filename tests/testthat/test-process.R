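small_course_cfg <- function(nf)
  phantom_config(dim = c(48, 48, 28), spacing = c(4, 4, 4), n_fractions = nf)

test_that("a zero-change course is a fixed point of the whole pipeline", {
  cfg <- small_course_cfg(6)
  b <- make_plan_phantom(cfg, seed = 8)
  tr <- course_truth(cfg, parotid_drift_mm = 0, parotid_shrink_rate = 0,
                     target_shrink_rate = 0, body_shrink_rate = 0,
                     setup_sd_mm = 0, setup_rot_sd_deg = 0, noise_sd = 0,
                     seed = 8)
  course <- simulate_course(b, tr)
  # the simulated daily volumes equal the plan exactly
  for (dv in course$daily) expect_equal(dv$voxels, b$image$voxels)
  rep <- process_course(b, course$daily)
  expect_length(rep$failed_fractions, 0)
  # every DP_sum equals the planned DP at every fraction
  pm <- rep$plan_metrics
  for (i in seq_len(nrow(rep$fractions))) {
    row <- rep$fractions[i, ]
    # the identity-registration contract allows |u| <= 0.1 mm, hence ~0.1%
    # DP movement through the local dose gradient
    expect_equal(row$dp_sum, pm[[row$structure]][[row$metric]], tolerance = 2e-3,
                 label = paste(row$structure, row$metric, "fraction", row$fraction))
    expect_equal(row$dp_day, row$dp_sum, tolerance = 1e-8)
  }
  expect_equal(nrow(rep$violations), 0)
  expect_false(any(rep$qa$flagged))
  expect_true(all(rep$qa$ncc > 0.999, na.rm = TRUE))
  expect_true(all(rep$qa$max_displacement_mm < 0.1))
  expect_false(any(rep$cohort$eot_violation))
})

test_that("a failing fraction is recorded and the course continues", {
  cfg <- small_course_cfg(3)
  b <- make_plan_phantom(cfg, seed = 8)
  tr <- course_truth(cfg, parotid_drift_mm = 0, parotid_shrink_rate = 0,
                     target_shrink_rate = 0, body_shrink_rate = 0,
                     setup_sd_mm = 0, setup_rot_sd_deg = 0, noise_sd = 0,
                     seed = 8)
  course <- simulate_course(b, tr)
  # second daily volume placed outside the plan's physical extent
  broken <- course$daily[[2]]
  broken$origin <- broken$origin + c(5000, 0, 0)
  course$daily[[2]] <- broken
  expect_warning(rep <- process_course(b, course$daily), "fraction 2 failed")
  expect_equal(rep$failed_fractions, 2L)
  expect_setequal(unique(rep$fractions$fraction), c(1L, 3L))
})

test_that("course reports round-trip through JSON", {
  cfg <- small_course_cfg(6)
  b <- make_plan_phantom(cfg, seed = 8)
  tr <- course_truth(cfg, parotid_drift_mm = 1.5, setup_sd_mm = 0.5,
                     noise_sd = 10, seed = 9)
  course <- simulate_course(b, tr)
  # replay under ground-truth fields: fast and deterministic
  rep <- process_course(b, course$daily, dvf_list = course$dvf)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_course_report(rep, path)
  back <- read_course_report(path)
  expect_equal(as.data.frame(back$cohort), as.data.frame(rep$cohort))
  expect_equal(nrow(back$violations), nrow(rep$violations))
  if (nrow(rep$violations))
    expect_equal(as.data.frame(back$violations), as.data.frame(rep$violations))
  expect_equal(back$dose_per_fraction, rep$dose_per_fraction)
})

test_that("trend forecasts appear once five fractions are processed", {
  cfg <- small_course_cfg(7)
  b <- make_plan_phantom(cfg, seed = 8)
  tr <- course_truth(cfg, parotid_drift_mm = 1.0, setup_sd_mm = 0,
                     setup_rot_sd_deg = 0, noise_sd = 0, seed = 10)
  course <- simulate_course(b, tr)
  rep <- process_course(b, course$daily, dvf_list = course$dvf)
  expect_true(nrow(rep$predictions) > 0)
  expect_gte(min(rep$predictions$anchor_fraction), 5)
  # exactly 4 predictions per endpoint and anchor
  counts <- dplyr::count(rep$predictions, .data$structure, .data$metric,
                         .data$anchor_fraction)
  expect_true(all(counts$n == 4))
})
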