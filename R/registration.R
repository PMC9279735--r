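#' Parameters of the deformable registration
#'
#' Controls the multi-resolution optical-flow algorithm: a brightness-
#' constancy force (intensity difference times local gradient, normalised by
#' gradient magnitude) drives per-voxel displacements, and a Gaussian
#' smoothing of the field after every update acts as the gradient-smoothness
#' regularizer.  A Gaussian image pyramid handles large displacements coarse
#' to fine.
#'
#' @param pyramid_levels number of resolution levels (>= 1); level `L` works
#'   at `2^(L-1)`-fold decimation.
#' @param iterations_per_level iteration cap at each level.
#' @param smoothness regularization strength: standard deviation (voxels) of
#'   the Gaussian applied to each displacement update (fluid-like
#'   regularization); larger is smoother.
#' @param smoothness_field additional diffusion-like smoothing of the
#'   accumulated field after every iteration (voxels; 0 disables).  Non-zero
#'   values resist localised deformation more strongly.
#' @param intensity_normalization `"histogram_match"` (default: foreground
#'   quantile transfer of the daily volume onto the plan intensities, with
#'   the air background of both images flattened to a common floor —
#'   appropriate for CBCT-to-CT where intensities are not calibrated),
#'   `"z_score"`, or `"none"`.
#' @param convergence_tol stop a level once the mean per-iteration update
#'   falls below this (mm).
#' @param max_step_mm cap on the per-iteration displacement update.
#' @return a `reg_params` list.
#' @export
reg_params <- function(pyramid_levels = 3, iterations_per_level = 100,
                       smoothness = 2.0, smoothness_field = 0.75,
                       intensity_normalization = c("histogram_match", "z_score", "none"),
                       convergence_tol = 0.02, max_step_mm = 2) {
  intensity_normalization <- match.arg(intensity_normalization)
  stopifnot(pyramid_levels >= 1, iterations_per_level >= 1, smoothness > 0,
            smoothness_field >= 0, convergence_tol > 0, max_step_mm > 0)
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 smoothness = smoothness, smoothness_field = smoothness_field,
                 intensity_normalization = intensity_normalization,
                 convergence_tol = convergence_tol,
                 max_step_mm = max_step_mm),
            class = "reg_params")
}

# Joint intensity normalisation of the (fixed, moving) pair before flow.
# Histogram matching transfers the moving foreground quantiles onto the fixed
# foreground quantiles (foreground = above each image's mean, which separates
# tissue from the dominant air peak); background voxels in BOTH images are
# then flattened to the common foreground floor.  The body outline stays
# visible to the flow while uncalibrated air values and the air-mass
# imbalance between CT and CBCT stop generating spurious forces.
normalize_pair <- function(fixed, moving, method) {
  if (method == "none") return(list(fixed = fixed, moving = moving))
  if (method == "z_score") {
    m <- (moving - mean(moving)) / max(stats::sd(moving), 1e-9) *
      stats::sd(fixed) + mean(fixed)
    return(list(fixed = fixed, moving = m))
  }
  fg_f <- fixed > mean(fixed); fg_m <- moving > mean(moving)
  if (!any(fg_f) || !any(fg_m)) return(list(fixed = fixed, moving = moving))
  sf <- sort(fixed[fg_f])
  sm <- sort(moving[fg_m])
  floor_val <- sf[1]
  mv <- moving
  if (sm[length(sm)] - sm[1] >= 1e-9) {
    # Smooth quantile transfer.  The raw empirical transfer (CDF of the
    # moving foreground chained with the fixed quantile function) is exact
    # but ill-conditioned: in sparsely populated intensity bands a tiny CDF
    # difference becomes a large value shift, which then perturbs every
    # structure sharing that band and drives spurious flow.  Detector
    # miscalibration is smooth in intensity, so a low-order (cubic) map
    # fitted through the transfer pairs, weighted by the local intensity
    # density, captures the genuine correction and suppresses the
    # sparse-band noise.  Identical distributions give the identity map
    # (a linear map is reproduced exactly by the cubic fit).
    n <- length(sm)
    vk <- seq(sm[1], sm[n], length.out = 257)
    rk <- findInterval(vk, sm)
    pk <- pmin(pmax((rk - 0.5) / n, 0), 1)
    Tk <- stats::quantile(sf, pk, names = FALSE, type = 7)
    wk <- diff(c(0, pk)) + 1e-6
    vs <- (vk - mean(vk)) / stats::sd(vk)
    fit <- stats::lm.wfit(cbind(1, vs, vs^2, vs^3), Tk, w = wk)
    ms <- (moving[fg_m] - mean(vk)) / stats::sd(vk)
    mv[fg_m] <- cbind(1, ms, ms^2, ms^3) %*% fit$coefficients
  }
  mv[!fg_m] <- floor_val
  fx <- fixed
  fx[!fg_f] <- floor_val
  list(fixed = fx, moving = mv)
}

downsample2 <- function(arr, times) {
  for (t in seq_len(times)) {
    arr <- cpp_gauss3d(arr, dim(arr), rep(0.85, 3))
    d <- dim(arr)
    arr <- arr[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2),
               drop = FALSE]
  }
  arr
}

#' Deformable registration of the planning anatomy to a daily image
#'
#' Estimates a dense deformation field `u` on the planning grid, stored in the
#' plan-to-daily direction: the tissue at plan position `x` lies at `x + u(x)`
#' in the daily anatomy.  The daily volume is resampled onto the planning grid
#' and intensity-normalised before the flow iterations.  The algorithm is
#' deterministic: identical inputs and parameters give an identical field.
#'
#' @param plan_image planning [image_volume()] (the fixed image).
#' @param daily_image daily setup [image_volume()] in physical coordinates;
#'   must overlap the plan volume in space.
#' @param params a [reg_params()].
#' @return a [deformation_field()] with attributes `converged` (logical) and
#'   `convergence` (per-level iteration counts and final mean updates).  A
#'   non-converged result is still returned, flagged.
#' @export
register <- function(plan_image, daily_image, params = reg_params()) {
  stopifnot(inherits(plan_image, "image_volume"), inherits(daily_image, "image_volume"))
  lo_p <- plan_image$origin
  hi_p <- plan_image$origin + (vol_dim(plan_image) - 1) * plan_image$spacing
  lo_d <- daily_image$origin
  hi_d <- daily_image$origin + (vol_dim(daily_image) - 1) * daily_image$spacing
  if (any(hi_d < lo_p) || any(lo_d > hi_p))
    stop("plan and daily volumes do not overlap in physical space", call. = FALSE)

  bg <- min(daily_image$voxels)
  daily_rs <- resample_to_grid(daily_image, plan_image, background = bg)
  np <- normalize_pair(plan_image$voxels, daily_rs$voxels,
                       params$intensity_normalization)
  fixed <- np$fixed
  moving <- np$moving

  levels <- params$pyramid_levels
  pyr_f <- vector("list", levels); pyr_m <- vector("list", levels)
  pyr_f[[1]] <- fixed; pyr_m[[1]] <- moving
  if (levels > 1) for (l in 2:levels) {
    pyr_f[[l]] <- downsample2(pyr_f[[l - 1]], 1)
    pyr_m[[l]] <- downsample2(pyr_m[[l - 1]], 1)
  }

  conv <- list()
  u <- NULL
  for (l in levels:1) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    d <- dim(f)
    sp <- plan_image$spacing * 2^(l - 1)
    if (is.null(u)) {
      u <- list(ux = array(0, d), uy = array(0, d), uz = array(0, d))
    } else {
      # upsample the coarser field (mm values unchanged) onto this level
      dc <- dim(u$ux)
      ix <- (seq_len(d[1]) - 1) / 2; iy <- (seq_len(d[2]) - 1) / 2
      iz <- (seq_len(d[3]) - 1) / 2
      pts <- cbind(rep(ix, times = d[2] * d[3]),
                   rep(rep(iy, each = d[1]), times = d[3]),
                   rep(iz, each = d[1] * d[2]))
      u <- lapply(u, function(comp)
        array(cpp_trilinear(comp, dc, pts[, 1], pts[, 2], pts[, 3], 0, TRUE), d))
    }
    res <- cpp_flow_level(f, m, d, sp, u$ux, u$uy, u$uz,
                          params$iterations_per_level,
                          rep(params$smoothness, 3),
                          rep(params$smoothness_field, 3),
                          params$convergence_tol, params$max_step_mm)
    u <- list(ux = res$ux, uy = res$uy, uz = res$uz)
    conv[[length(conv) + 1]] <- list(level = l, iterations = res$iterations,
                                     mean_update = res$mean_update,
                                     converged = res$converged)
  }
  dvf <- deformation_field(u$ux, u$uy, u$uz, plan_image$spacing, plan_image$origin)
  attr(dvf, "converged") <- conv[[length(conv)]]$converged
  attr(dvf, "convergence") <- conv
  dvf
}

#' Warp a volume by a deformation field (backward sampling)
#'
#' `output(x) = moving(x + u(x))`, trilinear.  With the plan-to-daily field
#' convention used here, warping the *daily* image reconstructs the anatomy on
#' the planning grid.
#'
#' @param moving volume to sample from; must share the field's grid.
#' @param dvf a [deformation_field()].
#' @param background value for samples falling outside the grid.
#' @param clamp extend edge values beyond the grid instead of `background`
#'   (appropriate when comparing anatomy whose extent continues past the
#'   field of view).
#' @return an [image_volume()] (or [dose_grid()] input class preserved).
#' @export
warp_image <- function(moving, dvf, background = 0, clamp = FALSE) {
  stopifnot(inherits(moving, "image_volume"), inherits(dvf, "deformation_field"))
  if (!same_geometry(moving, dvf))
    stop("volume and deformation field geometries do not match", call. = FALSE)
  d <- vol_dim(moving)
  w <- grid_world_coords(moving)
  w[, 1] <- w[, 1] + as.vector(dvf$ux)
  w[, 2] <- w[, 2] + as.vector(dvf$uy)
  w[, 3] <- w[, 3] + as.vector(dvf$uz)
  out <- moving
  out$voxels <- array(sample_volume(moving, w, background = background,
                                    clamp = clamp), d)
  out
}

#' Normalized cross-correlation of two volumes over a region
#'
#' @param a,b numeric arrays of identical dimension.
#' @param mask optional logical array restricting the region.
#' @return NCC in `[-1, 1]`, or `NA` when either region has zero variance.
#' @export
ncc <- function(a, b, mask = NULL) {
  x <- if (is.null(mask)) as.vector(a) else a[mask]
  y <- if (is.null(mask)) as.vector(b) else b[mask]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx < 1e-12 || sy < 1e-12)
    return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy) *
    length(x) / (length(x) - 1)
}
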