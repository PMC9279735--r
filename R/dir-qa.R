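#' Registration confidence metrics for one structure
#'
#' Two automated checks of the deformation quality, computed per structure:
#' the normalized cross-correlation between the daily image pulled onto the
#' planning grid by the recovered field and the planning image, evaluated
#' over the structure mask dilated by a margin (boundary mismatch shows up in
#' the margin); and the maximum displacement magnitude inside the structure.
#' A structure is flagged when NCC falls below 0.85 or any voxel displaces
#' more than 7 mm (both thresholds configurable; the displacement criterion
#' is conservative any-voxel).  A zero-variance region makes NCC undefined:
#' the structure is then flagged for review with a reason code.
#'
#' @param plan_image planning [image_volume()].
#' @param daily_image daily [image_volume()] in native coordinates.
#' @param dvf plan-to-daily [deformation_field()] from [register()].
#' @param structure an [rt_structure()].
#' @param thresholds list with `ncc` and `displacement_mm`.
#' @param margin_mm dilation margin of the NCC region.
#' @return one-row tibble: `structure`, `ncc`, `max_displacement_mm`,
#'   `low_ncc`, `large_displacement`, `flagged`, `note`.
#' @export
structure_qa <- function(plan_image, daily_image, dvf, structure,
                         thresholds = list(ncc = 0.85, displacement_mm = 7),
                         margin_mm = 5) {
  stopifnot(inherits(structure, "rt_structure"))
  if (!any(structure$mask))
    stop("structure '", structure$name, "' has an empty mask", call. = FALSE)
  region <- cpp_dilate(structure$mask, vol_dim(plan_image), plan_image$spacing,
                       margin_mm)
  daily_rs <- if (same_geometry(daily_image, plan_image)) daily_image
              else resample_to_grid(daily_image, plan_image,
                                    background = min(daily_image$voxels))
  # edge extension: the anatomy continues past the field of view, and a
  # boundary voxel displaced infinitesimally outward must not turn into air
  warped <- warp_image(daily_rs, dvf, clamp = TRUE)
  # mild smoothing before NCC suppresses uncorrelated image noise, which
  # would otherwise dominate the similarity of small low-contrast regions
  d <- vol_dim(plan_image)
  ncc_val <- ncc(cpp_gauss3d(warped$voxels, d, rep(1, 3)),
                 cpp_gauss3d(plan_image$voxels, d, rep(1, 3)), mask = region)
  maxdisp <- max(dvf_magnitude(dvf)[structure$mask])
  note <- NA_character_
  low_ncc <- FALSE
  if (is.na(ncc_val)) {
    note <- "ncc_undefined_zero_variance"
    low_ncc <- TRUE
  } else if (ncc_val < thresholds$ncc) {
    low_ncc <- TRUE
  }
  large <- maxdisp > thresholds$displacement_mm
  tibble::tibble(structure = structure$name, ncc = ncc_val,
                 max_displacement_mm = maxdisp,
                 low_ncc = low_ncc, large_displacement = large,
                 flagged = low_ncc | large, note = note)
}
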