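#' Deform a structure mask to the daily anatomy
#'
#' Forward-maps the mask with the plan-to-daily field: every masked voxel
#' pushes trilinear weights to its displaced position, and the splatted
#' density is thresholded at 0.5.  Used for display and DIR-confidence
#' regions; dose estimation itself stays on the plan grid (Lagrangian
#' accumulation) and does not use this.
#'
#' @param mask logical 3D array on the plan grid.
#' @param dvf a [deformation_field()].
#' @return logical 3D array on the same raster, deformed.
#' @export
warp_structure <- function(mask, dvf) {
  stopifnot(inherits(dvf, "deformation_field"))
  if (!identical(dim(mask), dim(dvf$ux)))
    stop("mask and field dimensions differ", call. = FALSE)
  if (!any(mask)) {
    warning("empty input mask; returning an empty mask")
    return(array(FALSE, dim(mask)))
  }
  w <- cpp_splat(array(as.numeric(mask), dim(mask)), dim(mask), dvf$spacing,
                 dvf$ux, dvf$uy, dvf$uz)
  # density-adaptive threshold: under volume change the splatted density is
  # the inverse Jacobian, so a fixed 0.5 cut biases the surface; half the
  # interior density keeps the boundary at the half-voxel crossing
  interior <- stats::median(w[w > 0.05])
  array(w >= 0.5 * interior, dim(mask))
}

#' Per-fraction dose received by a structure's tissue elements
#'
#' For each plan-grid voxel `x` of the structure, samples the planned
#' full-course dose at the voxel's daily position `x + u(x)` (trilinear).
#' The planned dose distribution is held fixed in room coordinates while the
#' anatomy moves, so this is the full-course-equivalent dose the tissue
#' element receives on that day's anatomy.  Samples falling outside the dose
#' grid take 0 Gy and are counted; if more than 10% of the structure falls
#' outside, the result is flagged unreliable for the fraction.
#'
#' @param plan_dose full-course [dose_grid()] on the plan grid.
#' @param dvf plan-to-daily [deformation_field()] on the plan grid.
#' @param structure an [rt_structure()] with its mask on the plan grid.
#' @return a `structure_dose_samples` object: voxel ids (fixed across
#'   fractions — the Lagrangian identity), per-voxel full-course-equivalent
#'   dose in Gy, voxel volume in cm^3, out-of-grid count and reliability flag.
#' @export
daily_dose <- function(plan_dose, dvf, structure) {
  stopifnot(inherits(plan_dose, "dose_grid"), inherits(dvf, "deformation_field"),
            inherits(structure, "rt_structure"))
  if (!same_geometry(plan_dose, dvf))
    stop("dose grid and deformation field geometries differ", call. = FALSE)
  ids <- which(structure$mask)
  if (!length(ids)) stop("structure '", structure$name, "' has an empty mask",
                         call. = FALSE)
  d <- vol_dim(plan_dose)
  ijk <- arrayInd(ids, d) - 1
  world <- sweep(sweep(ijk, 2, plan_dose$spacing, "*"), 2, plan_dose$origin, "+")
  world[, 1] <- world[, 1] + dvf$ux[ids]
  world[, 2] <- world[, 2] + dvf$uy[ids]
  world[, 3] <- world[, 3] + dvf$uz[ids]
  idx <- world_to_index(plan_dose, world)
  eps <- 1e-6
  out_of_grid <- idx[, 1] < -eps | idx[, 2] < -eps | idx[, 3] < -eps |
    idx[, 1] > d[1] - 1 + eps | idx[, 2] > d[2] - 1 + eps | idx[, 3] > d[3] - 1 + eps
  dose <- cpp_trilinear(plan_dose$voxels, d, idx[, 1], idx[, 2], idx[, 3], 0, FALSE)
  structure(list(structure = structure$name,
                 voxel_ids = ids,
                 dose_full_course = dose,
                 voxel_volume_cc = voxel_volume_cc(plan_dose),
                 n_out_of_grid = sum(out_of_grid),
                 unreliable = mean(out_of_grid) > 0.10),
            class = "structure_dose_samples")
}

#' Accumulate per-fraction doses with projection to course end
#'
#' Combines the per-fraction full-course-equivalent doses of one structure
#' into the day dose and the projected cumulative dose after fraction `k` of
#' an `N`-fraction course.  Each fraction delivers `1/N` of the full-course
#' grid (simultaneous-integrated-boost plans scale uniformly), and the most
#' recent anatomy is assumed to hold for the remaining fractions:
#'
#' \deqn{D_{day,k}(x) = \hat d_k(x), \qquad
#'       D_{sum,k}(x) = \frac{1}{N}\sum_{f=1}^{k} \hat d_f(x)
#'                      + \frac{N-k}{N}\,\hat d_k(x)}
#'
#' At `k = N` the projection term vanishes and `D_sum` is the plain mean of
#' the per-fraction doses.
#'
#' @param samples_by_fraction list of `structure_dose_samples` for fractions
#'   `1..k`, sharing voxel ids.
#' @param total_fractions course length `N`.
#' @return an `accumulated_dose` object with per-voxel `d_day` and `d_sum`
#'   (Gy), the fraction index and voxel geometry.
#' @export
accumulate <- function(samples_by_fraction, total_fractions) {
  k <- length(samples_by_fraction)
  N <- as.integer(total_fractions)
  stopifnot(k >= 1, N >= k)
  ids <- samples_by_fraction[[1]]$voxel_ids
  for (s in samples_by_fraction)
    if (!identical(s$voxel_ids, ids))
      stop("mismatched voxel ids across fractions (Lagrangian identity broken)",
           call. = FALSE)
  doses <- vapply(samples_by_fraction, `[[`, numeric(length(ids)),
                  "dose_full_course")
  doses <- matrix(doses, nrow = length(ids))
  d_k <- doses[, k]
  d_sum <- rowSums(doses) / N + (N - k) / N * d_k
  structure(list(structure = samples_by_fraction[[1]]$structure,
                 fraction = k, total_fractions = N,
                 d_day = d_k, d_sum = d_sum,
                 voxel_ids = ids,
                 voxel_volume_cc = samples_by_fraction[[1]]$voxel_volume_cc),
            class = "accumulated_dose")
}
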