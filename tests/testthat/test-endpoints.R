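test_that("parotid endpoint resolution follows the plan-dependent rules", {
  # spared gland, planning goal met: monitored against 20 Gy
  e1 <- resolve_parotid_endpoint(19.54, "spared")
  expect_equal(e1$warning, 20); expect_equal(e1$adaptation, 22)
  # goal missed but planned mean < 21 Gy: monitored against 21 Gy
  e2 <- resolve_parotid_endpoint(20.76, "spared")
  expect_equal(e2$warning, 21); expect_equal(e2$adaptation, 1.10 * 21)
  # spared contralateral gland planned < 26 Gy: monitored against 26 Gy
  e3 <- resolve_parotid_endpoint(25.66, "contralateral_spared")
  expect_equal(e3$warning, 26); expect_equal(e3$adaptation, 28.6, tolerance = 1e-12)
  # outside all rule ranges: excluded with a notice
  expect_message(e4 <- resolve_parotid_endpoint(23.4, "spared"), "excluded")
  expect_null(e4)
  expect_message(e5 <- resolve_parotid_endpoint(27.0, "contralateral_spared"),
                 "excluded")
  expect_null(e5)
})

test_that("the endpoint set encodes targets, OARs and the 10% adaptation rule", {
  b <- std_bundle()
  eps <- build_endpoint_set(b$plan, plan_metrics(b))
  ptv <- eps[eps$structure == "ptv_60" & eps$metric == "V95", ]
  expect_equal(ptv$direction, "lower_bound")
  expect_equal(c(ptv$warning, ptv$adaptation), c(95, 93))
  hot <- eps[eps$structure == "ptv_54" & eps$metric == "hotspot", ]
  expect_equal(c(hot$warning, hot$adaptation), c(110, 110))
  expect_equal(hot$reference, 60)  # highest SIB level of the plan
  cord <- eps[eps$structure == "spinal_cord", ]
  expect_equal(cord$warning, 45)
  expect_equal(cord$adaptation, 49.5)
  mand <- eps[eps$structure == "mandible", ]
  expect_equal(mand$warning, mand$adaptation)  # planning goal at both levels
  # every relative ("10%") OAR endpoint: adaptation / warning = 1.10 exactly
  cfg <- hn_endpoint_config()
  rel <- eps$structure %in% cfg$structure[cfg$de10]
  expect_true(all(abs(eps$adaptation[rel] / eps$warning[rel] - 1.10) < 1e-12))
  expect_error(build_endpoint_set(b$plan, plan_metrics(b),
                                  config = tibble::tibble(structure = "spinal_cord",
                                                          metric = "Dfoo",
                                                          goal_gy = 45, de10 = TRUE,
                                                          parotid_role = NA)),
               "unknown metric")
})

test_that("crossing detection is strict and finds the first violating fraction", {
  spec_v95 <- rtflow:::endpoint_row("ptv", "V95", "lower_bound", 95, 93, "%")
  # exactly at threshold never violates
  none <- detect_crossings(rep(95, 10), spec_v95)
  expect_equal(nrow(none), 0)
  ev <- detect_crossings(c(96, 94.5, 92.8, 92.0, 91.5), spec_v95,
                         dose_per_fraction = 2)
  expect_equal(ev$fx[ev$level == "warning"], 2)
  expect_equal(ev$fx[ev$level == "adaptation"], 3)
  expect_equal(ev$cumulative_dose_gy[ev$level == "warning"], 4)
  expect_true(all(ev$eot_violation))
  # upper bound: a mean dose crossing 26 Gy between fractions 7 and 8
  spec_pg <- rtflow:::endpoint_row("pg", "Dmean", "upper_bound", 26, 28.6, "Gy")
  traj <- c(24.0, 24.6, 25.0, 25.3, 25.6, 25.8, 25.95, 26.3, 26.8, 27.2)
  ev2 <- detect_crossings(traj, spec_pg, dose_per_fraction = 2)
  expect_equal(ev2$fx[ev2$level == "warning"], 8)
  # crossing and receding is still reported, without an EOT violation
  ev3 <- detect_crossings(c(25, 26.5, 25.5, 25.0), spec_pg)
  expect_equal(ev3$fx[ev3$level == "warning"], 2)
  expect_false(any(ev3$eot_violation))
  expect_error(detect_crossings(numeric(0), spec_pg), "empty")
})

test_that("monotone trajectories yield ordered warning/adaptation crossings", {
  spec <- rtflow:::endpoint_row("ptv", "V95", "lower_bound", 95, 93, "%")
  set.seed(2)
  for (i in 1:10) {
    traj <- 99 - cumsum(runif(20, 0, 1.2))
    ev <- detect_crossings(traj, spec)
    w <- ev$fx[ev$level == "warning"]; a <- ev$fx[ev$level == "adaptation"]
    if (length(w) && length(a)) expect_lte(w, a)
    expect_lte(nrow(ev), 2)  # one crossing per level on a monotone trajectory
  }
})
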