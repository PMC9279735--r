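#' @importFrom jsonlite read_json write_json
NULL

geom_to_list <- function(x) list(dim = vol_dim(x), spacing = x$spacing,
                                 origin = x$origin, axes = "LPS")

require_fields <- function(lst, fields, where) {
  miss <- setdiff(fields, names(lst))
  if (length(miss))
    stop("missing geometry/metadata field(s) in ", where, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
}

write_nifti_raw <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Write a planning bundle in the portable fixture format
#'
#' The fixture dialect stores each raster as a NIfTI file and all plan
#' metadata (geometry, fractionation, structure roles and prescriptions) in a
#' single `plan.json` sidecar, which is the authoritative source of geometry.
#' Arrays are kept in the package's LPS voxel-center convention.
#'
#' @param image planning [image_volume()].
#' @param plan [plan_context()] with structures on the planning grid.
#' @param dose full-course [dose_grid()] (any grid; stored with its own
#'   geometry).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plan_bundle <- function(image, plan, dose, dir) {
  stopifnot(inherits(image, "image_volume"), inherits(plan, "plan_context"),
            inherits(dose, "dose_grid"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_nifti_raw(image$voxels, image$spacing, file.path(dir, "plan_image.nii.gz"))
  write_nifti_raw(dose$voxels, dose$spacing, file.path(dir, "plan_dose.nii.gz"))
  structs <- lapply(plan$structures, function(s) {
    f <- file.path("masks", paste0(gsub("[^A-Za-z0-9_.-]", "_", s$name), ".nii.gz"))
    m <- array(as.integer(s$mask), dim(s$mask))
    write_nifti_raw(m, image$spacing, file.path(dir, f))
    list(name = s$name, role = s$role,
         prescription = if (is.na(s$prescription)) NULL else s$prescription,
         file = f)
  })
  meta <- list(format = "rtflow-fixture", version = 1L,
               geometry = geom_to_list(image),
               dose_file = "plan_dose.nii.gz",
               dose_geometry = geom_to_list(dose),
               image_file = "plan_image.nii.gz",
               total_fractions = plan$total_fractions,
               structures = unname(structs))
  write_json(meta, file.path(dir, "plan.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(dir)
}

read_fixture_bundle <- function(dir, required_structures = NULL) {
  sidecar <- file.path(dir, "plan.json")
  if (!file.exists(sidecar)) stop("no plan.json in ", dir, call. = FALSE)
  meta <- read_json(sidecar, simplifyVector = TRUE)
  require_fields(meta, c("geometry", "image_file", "dose_file", "dose_geometry",
                         "total_fractions", "structures"), "plan.json")
  require_fields(meta$geometry, c("dim", "spacing", "origin"), "plan.json geometry")
  g <- meta$geometry
  image <- image_volume(read_nifti_raw(file.path(dir, meta$image_file)),
                        g$spacing, g$origin)
  dg <- meta$dose_geometry
  dose_native <- dose_grid(read_nifti_raw(file.path(dir, meta$dose_file)),
                           dg$spacing, dg$origin)
  dose <- if (same_geometry(dose_native, image)) dose_native else {
    r <- resample_to_grid(dose_native, image, background = 0)
    dose_grid(r$voxels, image$spacing, image$origin)
  }
  st <- meta$structures
  get_rx <- function(i) {
    # jsonlite may simplify the prescription column to a vector (with NA for
    # absent entries) or leave it as a list with NULLs
    p <- st$prescription
    if (is.null(p)) return(NULL)
    v <- if (is.list(p)) p[[i]] else p[i]
    if (is.null(v) || length(v) == 0 || is.na(v)) NULL else as.numeric(v)
  }
  structures <- lapply(seq_len(nrow(st)), function(i) {
    m <- read_nifti_raw(file.path(dir, st$file[i])) != 0
    rt_structure(st$name[i], st$role[i], m, prescription = get_rx(i))
  })
  plan <- plan_context(meta$total_fractions, structures)
  if (length(required_structures)) {
    miss <- setdiff(required_structures, names(plan$structures))
    if (length(miss))
      stop("structure(s) referenced in endpoint config but absent from bundle: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  list(image = image, plan = plan, dose = dose)
}

#' Read a planning bundle
#'
#' Returns the planning image, plan context and full-course dose with the dose
#' grid and all structure masks aligned on the planning image grid (dose:
#' trilinear; masks are stored on the plan grid in the fixture dialect and
#' rasterized onto it in the DICOM dialect).
#'
#' @param paths for `dialect = "fixture"`, the bundle directory; for
#'   `dialect = "dicom"`, a list with elements `ct` (directory or files of the
#'   CT series), `rtstruct` and `rtdose` (file paths).
#' @param dialect `"fixture"` or `"dicom"`.
#' @param plan_meta DICOM dialect only: list with `total_fractions`,
#'   `prescriptions` (named Gy per target) and `roles` (named role per
#'   structure; unlisted structures default to `"oar"`).
#' @param required_structures names that must be present (e.g. every structure
#'   referenced by the endpoint configuration); missing ones are a hard error.
#' @return list with elements `image`, `plan`, `dose`.
#' @export
read_plan_bundle <- function(paths, dialect = c("fixture", "dicom"),
                             plan_meta = NULL, required_structures = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         fixture = read_fixture_bundle(paths, required_structures),
         dicom = read_dicom_bundle(paths, plan_meta, required_structures))
}

#' Write a single volume in the fixture format
#' @param vol an [image_volume()].
#' @param path output path ending in `.nii.gz`; a `.json` sidecar with the
#'   authoritative geometry is written next to it.
#' @export
write_daily_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  write_nifti_raw(vol$voxels, vol$spacing, path)
  write_json(list(format = "rtflow-volume", version = 1L, geometry = geom_to_list(vol)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read one daily setup volume
#'
#' Returned in its native physical coordinates (never resampled); the
#' registration step brings it onto the planning grid.
#'
#' @param path fixture: the `.nii.gz` path (with its `.json` sidecar);
#'   dicom: directory or file vector of one CT/CBCT series.
#' @param dialect `"fixture"` or `"dicom"`.
#' @param spacing_tol tolerated relative non-uniformity of DICOM slice
#'   spacing before a hard error.
#' @return an [image_volume()].
#' @export
read_daily_volume <- function(path, dialect = c("fixture", "dicom"),
                              spacing_tol = 0.01) {
  dialect <- match.arg(dialect)
  vol <- if (dialect == "fixture") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("missing sidecar ", sidecar, call. = FALSE)
    meta <- read_json(sidecar, simplifyVector = TRUE)
    require_fields(meta$geometry, c("dim", "spacing", "origin"), "volume sidecar")
    image_volume(read_nifti_raw(path), meta$geometry$spacing, meta$geometry$origin)
  } else {
    read_dicom_series(path, spacing_tol = spacing_tol)
  }
  if (any(vol_dim(vol) < 2L))
    stop("a daily volume must be 3D (>= 2 voxels along every axis)", call. = FALSE)
  vol
}
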