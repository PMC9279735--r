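make_sphere_mask <- function(vol, center, r) {
  w <- rtflow:::grid_world_coords(vol)
  array((w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
          (w[, 3] - center[3])^2 <= r^2, rtflow:::vol_dim(vol))
}

test_that("a zero field leaves masks, images and structure doses unchanged", {
  v <- tiny_volume(dim = c(20, 20, 14))
  set.seed(6); v$voxels[] <- rnorm(length(v$voxels))
  z <- dvf_zero(v)
  expect_identical(warp_image(v, z)$voxels, v$voxels)
  m <- make_sphere_mask(v, c(19, 19, 13), 8)
  expect_identical(warp_structure(m, z), m)
  dose <- dose_grid(abs(v$voxels), v$spacing, v$origin)
  st <- rt_structure("s", "oar", m)
  s <- daily_dose(dose, z, st)
  expect_equal(s$dose_full_course, dose$voxels[m])
  expect_equal(s$n_out_of_grid, 0)
})

test_that("warp_structure tracks rigid shifts and volume change", {
  v <- tiny_volume(dim = c(30, 30, 20), spacing = c(2, 2, 2))
  m <- make_sphere_mask(v, c(29, 29, 19), 12)
  z <- dvf_zero(v)
  shift <- z; shift$ux[] <- 6
  ms <- warp_structure(m, shift)
  w <- rtflow:::grid_world_coords(v)
  centroid <- function(mask) colMeans(w[as.vector(mask), , drop = FALSE])
  d <- centroid(ms) - centroid(m)
  expect_lt(abs(d[1] - 6), 0.5)
  expect_lt(max(abs(d[2:3])), 0.5)
  # uniform contraction by 0.8 about the sphere center: volume ratio 0.8^3
  ctr <- c(29, 29, 19)
  contr <- z
  contr$ux <- array(-0.2 * (w[, 1] - ctr[1]), dim(m))
  contr$uy <- array(-0.2 * (w[, 2] - ctr[2]), dim(m))
  contr$uz <- array(-0.2 * (w[, 3] - ctr[3]), dim(m))
  mc <- warp_structure(m, contr)
  expect_lt(abs(sum(mc) / sum(m) - 0.8^3) / 0.8^3, 0.05)
  expect_warning(warp_structure(array(FALSE, dim(m)), z), "empty")
})

test_that("structure dose follows the planned dose along the displacement", {
  v <- tiny_volume(dim = c(24, 24, 16), spacing = c(2, 2, 2))
  w <- rtflow:::grid_world_coords(v)
  g <- 0.8  # Gy/mm linear gradient along x
  dose <- dose_grid(array(10 + g * w[, 1], c(24, 24, 16)), v$spacing, v$origin)
  m <- make_sphere_mask(v, c(16, 23, 15), 8)
  st <- rt_structure("s", "oar", m)
  u <- dvf_zero(v); u$ux[] <- 4
  s <- daily_dose(dose, u, st)
  base <- daily_dose(dose, dvf_zero(v), st)
  # trilinear sampling is exact on a linear dose: mean rises by exactly 4 g
  expect_equal(mean(s$dose_full_course) - mean(base$dose_full_course), 4 * g,
               tolerance = 1e-9)
})

test_that("out-of-grid sampling is counted and flagged beyond 10%", {
  v <- tiny_volume(dim = c(10, 10, 10), spacing = c(2, 2, 2))
  dose <- dose_grid(array(10, c(10, 10, 10)), v$spacing, v$origin)
  m <- array(FALSE, c(10, 10, 10)); m[8:10, 5, 5] <- TRUE
  st <- rt_structure("edge", "oar", m)
  u <- dvf_zero(v); u$ux[] <- 30  # push everything past the +x face
  s <- daily_dose(dose, u, st)
  expect_equal(s$n_out_of_grid, 3)
  expect_true(s$unreliable)
  expect_equal(s$dose_full_course, rep(0, 3))  # out-of-grid samples take 0 Gy
})

test_that("accumulation implements the projected-cumulative formula", {
  mk <- function(d) structure(list(structure = "s", voxel_ids = 1:2,
                                   dose_full_course = rep(d, 2),
                                   voxel_volume_cc = 1, n_out_of_grid = 0L,
                                   unreliable = FALSE),
                              class = "structure_dose_samples")
  # N = 30, constant 60 Gy for 10 fractions then 66 Gy at fraction 11
  acc <- accumulate(c(replicate(10, mk(60), simplify = FALSE), list(mk(66))), 30)
  expect_equal(acc$d_sum, rep((10 * 60 + 66) / 30 + (19 / 30) * 66, 2))
  expect_equal(acc$d_day, rep(66, 2))
  # k = N: plain mean of the per-fraction doses (projection term vanishes)
  series <- lapply(seq(50, 64, by = 2), mk)
  accN <- accumulate(series, length(series))
  expect_equal(accN$d_sum, rep(mean(seq(50, 64, by = 2)), 2))
  # all fractions at the plan: the projection is a fixed point for every k
  for (k in c(1, 5, 12)) {
    acck <- accumulate(replicate(k, mk(54), simplify = FALSE), 12)
    expect_equal(acck$d_sum, rep(54, 2))
  }
  bad <- mk(60); bad$voxel_ids <- 2:3
  expect_error(accumulate(list(mk(60), bad), 30), "voxel ids")
})

test_that("accumulation is linear in dose and bounded by the fraction extremes", {
  set.seed(8)
  mkv <- function(d) structure(list(structure = "s", voxel_ids = seq_along(d),
                                    dose_full_course = d, voxel_volume_cc = 1,
                                    n_out_of_grid = 0L, unreliable = FALSE),
                               class = "structure_dose_samples")
  doses <- replicate(7, runif(40, 10, 70), simplify = FALSE)
  acc <- accumulate(lapply(doses, mkv), 20)
  acc3 <- accumulate(lapply(doses, function(d) mkv(3 * d)), 20)
  expect_equal(acc3$d_sum, 3 * acc$d_sum, tolerance = 1e-12)
  expect_equal(acc3$d_day, 3 * acc$d_day, tolerance = 1e-12)
  mat <- do.call(cbind, doses)
  expect_true(all(acc$d_sum >= apply(mat, 1, min) - 1e-12))
  expect_true(all(acc$d_sum <= apply(mat, 1, max) + 1e-12))
})
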