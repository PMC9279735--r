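# Synthetic head-and-neck phantom: a planning bundle plus a simulated daily
# treatment course with exact, analytic ground truth (deformations, doses,
# trends), so the whole pipeline is testable without patient data.

#' Phantom geometry, intensity and dose-model configuration
#'
#' Defines a neck-like digital phantom: an elliptic soft-tissue body cylinder
#' in air containing a two-level simultaneous-integrated-boost target (nested
#' spheres), two parotid ellipsoids, a spinal cord cylinder inside a vertebral
#' column, and a mandible arc.  The dose model is analytic: each target
#' contributes its prescription as a plateau inside the target with Gaussian
#' falloff of scale `falloff_mm` outside, and the grid dose is the voxel-wise
#' maximum over targets — steep near the parotids by construction.
#'
#' @param dim grid size (voxels); default 96 x 96 x 64.
#' @param spacing voxel size mm.
#' @param n_fractions course length N.
#' @param rx_high,rx_low SIB prescription levels (Gy) of the nested targets.
#' @param falloff_mm Gaussian dose-falloff scale outside targets.
#' @param body_semiaxes x/y semi-axes (mm) of the body ellipse.
#' @param ptv_high_r,ptv_low_r target sphere radii (mm), common center
#'   `ptv_center`.
#' @param parotid_semiaxes,parotid_center_x,parotid_center parotid ellipsoid
#'   geometry; glands sit at `(+/- parotid_center_x, parotid_center[1],
#'   parotid_center[2])`.
#' @param cord_center_y,cord_r spinal cord cylinder (full z extent).
#' @param mandible_R,mandible_tube,mandible_z mandible arc: anterior half of a
#'   torus of major radius `mandible_R` around the target axis.
#' @param n_texture_blobs smooth intensity blobs giving the optical flow
#'   texture to grip on.
#' @param image_noise_sd Gaussian noise on the planning image (HU), matching
#'   the quantum noise of a real planning CT.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(96, 96, 64), spacing = c(2, 2, 2),
                           n_fractions = 30, rx_high = 60, rx_low = 54,
                           falloff_mm = 12,
                           body_semiaxes = c(75, 65),
                           ptv_high_r = 20, ptv_low_r = 30,
                           ptv_center = c(0, 10, 0),
                           parotid_semiaxes = c(11, 14, 18),
                           parotid_center_x = 48, parotid_center = c(0, 5),
                           cord_center_y = -40, cord_r = 5,
                           mandible_R = 40, mandible_tube = 6, mandible_z = 22,
                           n_texture_blobs = 25, image_noise_sd = 10) {
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              n_fractions = as.integer(n_fractions),
              rx_high = rx_high, rx_low = rx_low, falloff_mm = falloff_mm,
              body_semiaxes = body_semiaxes,
              ptv_high_r = ptv_high_r, ptv_low_r = ptv_low_r,
              ptv_center = ptv_center,
              parotid_semiaxes = parotid_semiaxes,
              parotid_center_x = parotid_center_x,
              parotid_center = parotid_center,
              cord_center_y = cord_center_y, cord_r = cord_r,
              mandible_R = mandible_R, mandible_tube = mandible_tube,
              mandible_z = mandible_z,
              n_texture_blobs = n_texture_blobs,
              image_noise_sd = image_noise_sd)
  cfg$origin <- -(cfg$dim - 1) * cfg$spacing / 2  # grid centered on the body axis
  structure(cfg, class = "phantom_config")
}

phantom_centers <- function(cfg) {
  list(ptv = cfg$ptv_center,
       parotid_left = c(-cfg$parotid_center_x, cfg$parotid_center),
       parotid_right = c(cfg$parotid_center_x, cfg$parotid_center))
}

#' Analytic dose model of the phantom
#'
#' @param cfg a [phantom_config()].
#' @return function mapping an n x 3 matrix of world mm points to dose in Gy.
#' @export
phantom_dose_fun <- function(cfg) {
  force(cfg)
  function(pts) {
    pts <- matrix(pts, ncol = 3)
    r <- sqrt((pts[, 1] - cfg$ptv_center[1])^2 +
                (pts[, 2] - cfg$ptv_center[2])^2 +
                (pts[, 3] - cfg$ptv_center[3])^2)
    lvl <- function(rx, rad) {
      d <- pmax(r - rad, 0)
      rx * exp(-(d / cfg$falloff_mm)^2)
    }
    pmax(lvl(cfg$rx_high, cfg$ptv_high_r), lvl(cfg$rx_low, cfg$ptv_low_r))
  }
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

phantom_body <- function(cfg, w) {
  (w[, 1] / cfg$body_semiaxes[1])^2 + (w[, 2] / cfg$body_semiaxes[2])^2 <= 1
}

phantom_masks <- function(cfg, w) {
  ctr <- phantom_centers(cfg)
  sphere <- function(c3, r)
    (w[, 1] - c3[1])^2 + (w[, 2] - c3[2])^2 + (w[, 3] - c3[3])^2 <= r^2
  ellipsoid <- function(c3, ax)
    ((w[, 1] - c3[1]) / ax[1])^2 + ((w[, 2] - c3[2]) / ax[2])^2 +
    ((w[, 3] - c3[3]) / ax[3])^2 <= 1
  planar_r <- sqrt(w[, 1]^2 + (w[, 2] - cfg$ptv_center[2])^2)
  list(body = phantom_body(cfg, w),
       ptv_high = sphere(ctr$ptv, cfg$ptv_high_r),
       ptv_low = sphere(ctr$ptv, cfg$ptv_low_r),
       parotid_left = ellipsoid(ctr$parotid_left, cfg$parotid_semiaxes),
       parotid_right = ellipsoid(ctr$parotid_right, cfg$parotid_semiaxes),
       spinal_cord = (w[, 1]^2 + (w[, 2] - cfg$cord_center_y)^2) <= cfg$cord_r^2,
       mandible = (planar_r - cfg$mandible_R)^2 + (w[, 3] - cfg$mandible_z)^2 <=
         cfg$mandible_tube^2 & w[, 2] > cfg$ptv_center[2])
}

#' Generate the phantom planning bundle
#'
#' Builds the planning image (HU-like intensities with reproducible smooth
#' texture), the structure set and the analytic full-course dose grid.
#' Deterministic given `(config, seed)`.  The generated plan is a valid
#' baseline: both targets sit entirely inside their prescription plateau
#' (V95 = 100%) and the spared parotids stay below a 20 Gy planned mean.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed driving the texture.
#' @return list with `image` ([image_volume()]), `plan` ([plan_context()]),
#'   `dose` ([dose_grid()]) and `config`.
#' @export
make_plan_phantom <- function(config = phantom_config(), seed = 1) {
  cfg <- config
  grid <- list(spacing = cfg$spacing, origin = cfg$origin)
  d <- cfg$dim
  w <- cbind(rep(cfg$origin[1] + (seq_len(d[1]) - 1) * cfg$spacing[1],
                 times = d[2] * d[3]),
             rep(rep(cfg$origin[2] + (seq_len(d[2]) - 1) * cfg$spacing[2],
                     each = d[1]), times = d[3]),
             rep(cfg$origin[3] + (seq_len(d[3]) - 1) * cfg$spacing[3],
                 each = d[1] * d[2]))
  half_extent <- -cfg$origin[1:2]
  if (any(cfg$body_semiaxes >= half_extent))
    stop("infeasible phantom geometry: body ellipse exceeds the grid extent; ",
         "enlarge the grid or shrink the body", call. = FALSE)
  m <- phantom_masks(cfg, w)
  if (any(m$ptv_low & m$spinal_cord))
    stop("infeasible phantom geometry: target overlaps the spinal cord",
         call. = FALSE)
  for (nm in c("ptv_high", "ptv_low", "parotid_left", "parotid_right",
               "spinal_cord", "mandible")) {
    if (!any(m[[nm]]))
      stop("infeasible phantom geometry: '", nm, "' catches no voxel centers ",
           "(grid too coarse for this structure)", call. = FALSE)
    if (any(m[[nm]] & !m$body))
      stop("infeasible phantom geometry: '", nm, "' extends outside the body",
           call. = FALSE)
  }

  # HU-like intensity model: air, soft tissue with smooth random texture,
  # bone-like vertebral column and mandible, gland/tumor contrast
  vert <- (w[, 1]^2 + (w[, 2] - cfg$cord_center_y)^2) <= (cfg$cord_r + 8)^2
  vox <- rep(-1000, nrow(w))
  vox[m$body] <- 40
  tex <- run_with_seed(seed, {
    noise <- stats::rnorm(nrow(w), 0, cfg$image_noise_sd)
    # two texture scales: broad anatomical variation plus finer structure so
    # similarity metrics see variance at the scale of a single organ
    nb <- 3L * cfg$n_texture_blobs
    cx <- stats::runif(nb, -cfg$body_semiaxes[1] * 0.85, cfg$body_semiaxes[1] * 0.85)
    cy <- stats::runif(nb, -cfg$body_semiaxes[2] * 0.85, cfg$body_semiaxes[2] * 0.85)
    cz <- stats::runif(nb, min(w[, 3]), max(w[, 3]))
    amp <- c(stats::runif(cfg$n_texture_blobs, -60, 60),
             stats::runif(2L * cfg$n_texture_blobs, -45, 45))
    sd <- c(stats::runif(cfg$n_texture_blobs, 8, 18),
            stats::runif(2L * cfg$n_texture_blobs, 4, 8))
    t <- numeric(nrow(w))
    for (b in seq_len(nb))
      t <- t + amp[b] * exp(-((w[, 1] - cx[b])^2 + (w[, 2] - cy[b])^2 +
                                (w[, 3] - cz[b])^2) / (2 * sd[b]^2))
    list(t = t, noise = noise)
  })
  vox[m$body] <- vox[m$body] + tex$t[m$body]
  vox[vert] <- 400
  vox[m$spinal_cord] <- 60
  vox[m$mandible] <- 700
  # glands and tumor keep the soft-tissue texture (offset, not overwritten),
  # so intensity-based registration has structure to grip on inside them
  par <- m$parotid_left | m$parotid_right
  vox[par] <- vox[par] - 70
  vox[m$ptv_high] <- vox[m$ptv_high] + 60
  # finite imaging point-spread: a real scanner never produces single-voxel
  # edges, and band-limited boundaries are what intensity-based registration
  # and histogram transfer assume; quantum noise added after the PSF
  vox <- cpp_gauss3d(array(vox, d), d, rep(0.6, 3)) + tex$noise
  image <- image_volume(array(vox, d), cfg$spacing, cfg$origin)

  dosef <- phantom_dose_fun(cfg)
  dose <- dose_grid(array(dosef(w), d), cfg$spacing, cfg$origin)

  shape <- function(v) array(v, d)
  structures <- list(
    rt_structure("body", "external", shape(m$body)),
    rt_structure(sprintf("ptv_%d", round(cfg$rx_high)), "target",
                 shape(m$ptv_high), prescription = cfg$rx_high),
    rt_structure(sprintf("ptv_%d", round(cfg$rx_low)), "target",
                 shape(m$ptv_low), prescription = cfg$rx_low),
    rt_structure("parotid_left", "oar", shape(m$parotid_left)),
    rt_structure("parotid_right", "oar", shape(m$parotid_right)),
    rt_structure("spinal_cord", "oar", shape(m$spinal_cord)),
    rt_structure("mandible", "oar", shape(m$mandible)))
  plan <- plan_context(cfg$n_fractions, structures)
  list(image = image, plan = plan, dose = dose, config = cfg)
}

#' Ground truth of a simulated treatment course
#'
#' Describes the per-fraction anatomy change as an analytic forward
#' deformation: smooth Gaussian-windowed drifts (medial parotid shift, parotid
#' and target shrinkage, global body-contour shrinkage in the axial plane)
#' composed with a random rigid setup error (translation + rotation about the
#' body axis), plus additive Gaussian image noise and optional streak
#' artifacts on the daily images.  Rigid errors are drawn once at
#' construction, so the whole course is reproducible from `(config, seed)`.
#'
#' Defaults emulate gradual radiotherapy response over a 30-fraction course:
#' parotid medial drift 0.2 mm/fraction, parotid volume loss 0.7%/fraction,
#' target regression 0.5%/fraction, body contour shrinkage 0.1%/fraction,
#' setup errors of 1.5 mm / 0.5 degrees SD, CBCT-like noise of 20 HU.
#'
#' @param config a [phantom_config()].
#' @param n_fractions number of simulated fractions (default full course).
#' @param parotid_drift_mm medial shift per fraction (mm); either one value
#'   for both glands or `c(left, right)` — clinically the gland ipsilateral
#'   to the target is the one that drifts.
#' @param parotid_shrink_rate,target_shrink_rate,body_shrink_rate fractional
#'   linear shrinkage per fraction (0.007 = 0.7%/fraction).
#' @param setup_sd_mm,setup_rot_sd_deg SD of the per-fraction rigid setup
#'   error (translation per axis, rotation about z).
#' @param noise_sd additive Gaussian noise SD on daily images (HU).
#' @param n_streaks number of bright random streak artifacts per daily image.
#' @param seed reproducibility seed.
#' @return a `course_truth` object.
#' @export
course_truth <- function(config, n_fractions = config$n_fractions,
                         parotid_drift_mm = 0.2,
                         parotid_shrink_rate = 0.007,
                         target_shrink_rate = 0.005,
                         body_shrink_rate = 0.001,
                         setup_sd_mm = 1.5, setup_rot_sd_deg = 0.5,
                         noise_sd = 20, n_streaks = 0, seed = 1) {
  stopifnot(inherits(config, "phantom_config"), n_fractions >= 1)
  rigid <- run_with_seed(seed, {
    tibble::tibble(fraction = seq_len(n_fractions),
                   tx = stats::rnorm(n_fractions, 0, setup_sd_mm),
                   ty = stats::rnorm(n_fractions, 0, setup_sd_mm),
                   tz = stats::rnorm(n_fractions, 0, setup_sd_mm),
                   rot_deg = stats::rnorm(n_fractions, 0, setup_rot_sd_deg))
  })
  structure(list(config = config, n_fractions = as.integer(n_fractions),
                 parotid_drift_mm = rep_len(parotid_drift_mm, 2L),
                 parotid_shrink_rate = parotid_shrink_rate,
                 target_shrink_rate = target_shrink_rate,
                 body_shrink_rate = body_shrink_rate,
                 setup_sd_mm = setup_sd_mm,
                 setup_rot_sd_deg = setup_rot_sd_deg,
                 noise_sd = noise_sd, n_streaks = n_streaks,
                 rigid = rigid, seed = as.integer(seed)),
            class = "course_truth")
}

# anatomical drift displacement (before the rigid error) at world points,
# fraction f; returns an n x 3 matrix of mm displacements
truth_drift_disp <- function(truth, pts, f) {
  cfg <- truth$config
  ctr <- phantom_centers(cfg)
  disp <- matrix(0, nrow(pts), 3)
  gauss_w <- function(c3, sd3) {
    exp(-(((pts[, 1] - c3[1]) / sd3[1])^2 + ((pts[, 2] - c3[2]) / sd3[2])^2 +
            ((pts[, 3] - c3[3]) / sd3[3])^2) / 2)
  }
  sides <- c("parotid_left", "parotid_right")
  for (si in seq_along(sides)) {
    c3 <- ctr[[sides[si]]]
    wnd <- gauss_w(c3, 2 * cfg$parotid_semiaxes)
    medial <- -sign(c3[1])
    shift <- truth$parotid_drift_mm[si] * f
    lam <- (1 - truth$parotid_shrink_rate)^f - 1
    disp[, 1] <- disp[, 1] + wnd * (medial * shift + lam * (pts[, 1] - c3[1]))
    disp[, 2] <- disp[, 2] + wnd * lam * (pts[, 2] - c3[2])
    disp[, 3] <- disp[, 3] + wnd * lam * (pts[, 3] - c3[3])
  }
  lam_t <- (1 - truth$target_shrink_rate)^f - 1
  wnd_t <- gauss_w(ctr$ptv, rep(2 * cfg$ptv_low_r, 3))
  disp <- disp + wnd_t * lam_t * sweep(pts, 2, ctr$ptv, "-")
  lam_b <- (1 - truth$body_shrink_rate)^f - 1
  disp[, 1] <- disp[, 1] + lam_b * pts[, 1]
  disp[, 2] <- disp[, 2] + lam_b * pts[, 2]
  disp
}

truth_rigid <- function(truth, f) {
  r <- truth$rigid[f, ]
  th <- r$rot_deg * pi / 180
  list(R = matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3),
       t = c(r$tx, r$ty, r$tz))
}

# forward map: phi(x) = R (x + d(x)) + t  (rotation about the grid center,
# which is the body axis)
truth_forward <- function(truth, pts, f) {
  d <- truth_drift_disp(truth, pts, f)
  rg <- truth_rigid(truth, f)
  (pts + d) %*% t(rg$R) + matrix(rg$t, nrow(pts), 3, byrow = TRUE)
}

#' Ground-truth deformation field of one fraction on the plan grid
#'
#' Evaluates the analytic forward map (drift composed with the rigid setup
#' error) at every plan-grid voxel center, in the same plan-to-daily
#' convention as [register()].
#'
#' @param truth a [course_truth()].
#' @param grid an [image_volume()] carrying the plan geometry.
#' @param f fraction index.
#' @return a [deformation_field()].
#' @export
truth_dvf <- function(truth, grid, f) {
  w <- grid_world_coords(grid)
  u <- truth_forward(truth, w, f) - w
  d <- vol_dim(grid)
  deformation_field(array(u[, 1], d), array(u[, 2], d), array(u[, 3], d),
                    grid$spacing, grid$origin)
}

# invert the forward map at world points y (daily grid): find x with
# phi(x) = y, by fixed-point iteration on x = R^-1 (y - t) - d(x)
truth_inverse <- function(truth, y, f, iters = 12) {
  rg <- truth_rigid(truth, f)
  z <- sweep(y, 2, rg$t, "-") %*% rg$R  # R^-1 = t(R)
  x <- z
  for (i in seq_len(iters)) x <- z - truth_drift_disp(truth, x, f)
  x
}

#' Simulate the daily image course of the phantom
#'
#' Produces one daily setup volume per fraction by resampling the planning
#' image through the inverse of the analytic ground-truth deformation (so
#' the daily anatomy really is the plan anatomy moved by the forward map),
#' then adding Gaussian noise and optional streak artifacts.  Ground-truth
#' deformation fields are returned in the registration module's convention
#' (plan to daily, on the plan grid).
#'
#' @param bundle plan bundle from [make_plan_phantom()].
#' @param truth a [course_truth()].
#' @return list with `daily` (list of [image_volume()]) and `dvf` (list of
#'   ground-truth [deformation_field()]s).
#' @export
simulate_course <- function(bundle, truth) {
  stopifnot(inherits(truth, "course_truth"))
  image <- bundle$image
  d <- vol_dim(image)
  w <- grid_world_coords(image)
  lo <- image$origin - image$spacing / 2
  hi <- image$origin + (d - 1 + 0.5) * image$spacing
  # the external body contour and through-FOV structures (the cord) run to
  # the z boundary by construction; the escape check watches the interior
  # voxels of the monitored structures
  monitored <- Filter(function(s) s$role != "external", bundle$plan$structures)
  union_mask <- Reduce(`|`, lapply(monitored, `[[`, "mask"))
  union_mask[, , c(1, dim(union_mask)[3])] <- FALSE
  struct_w <- w[as.vector(union_mask), , drop = FALSE]
  daily <- vector("list", truth$n_fractions)
  dvfs <- vector("list", truth$n_fractions)
  for (f in seq_len(truth$n_fractions)) {
    fwd <- truth_forward(truth, struct_w, f)
    if (any(fwd < matrix(lo, nrow(fwd), 3, byrow = TRUE)) ||
        any(fwd > matrix(hi, nrow(fwd), 3, byrow = TRUE)))
      stop("simulated drift pushes structures outside the grid at fraction ",
           f, call. = FALSE)
    src <- truth_inverse(truth, w, f)
    # edge extension: the phantom body runs through the z extent, so slices
    # displaced marginally past the boundary continue the anatomy
    vals <- sample_volume(image, src, clamp = TRUE)
    vals <- run_with_seed(truth$seed * 10000L + f, {
      v <- vals + stats::rnorm(length(vals), 0, truth$noise_sd)
      if (truth$n_streaks > 0) {
        for (s in seq_len(truth$n_streaks)) {
          k <- sample.int(d[3], 1)
          th <- stats::runif(1, 0, pi)
          off <- stats::runif(1, -30, 30)
          in_slice <- abs(w[, 3] - (image$origin[3] + (k - 1) * image$spacing[3])) <
            image$spacing[3] / 2
          pd <- w[, 1] * cos(th) + w[, 2] * sin(th) - off
          v <- v + ifelse(in_slice, 800 * exp(-(pd / 1.5)^2), 0)
        }
      }
      v
    })
    daily[[f]] <- image_volume(array(vals, d), image$spacing, image$origin)
    dvfs[[f]] <- truth_dvf(truth, image, f)
  }
  list(daily = daily, dvf = dvfs)
}

#' Write a complete phantom fixture course to disk
#'
#' Materialises a plan bundle and simulated daily volumes in the portable
#' fixture format (the CLI `phantom` verb).
#'
#' @param dir output directory.
#' @param config a [phantom_config()].
#' @param truth a [course_truth()]; defaults to the standard drift model.
#' @param seed seed for the plan texture (and truth, when defaulted).
#' @return `dir`, invisibly.
#' @export
write_phantom_course <- function(dir, config = phantom_config(),
                                 truth = course_truth(config, seed = seed),
                                 seed = 1) {
  bundle <- make_plan_phantom(config, seed = seed)
  write_plan_bundle(bundle$image, bundle$plan, bundle$dose, dir)
  course <- simulate_course(bundle, truth)
  for (f in seq_along(course$daily))
    write_daily_volume(course$daily[[f]],
                       file.path(dir, sprintf("daily_%03d.nii.gz", f)))
  invisible(dir)
}
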