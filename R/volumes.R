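#' 3D image volume with physical geometry
#'
#' The basic raster container used throughout the package: a 3D array of
#' scalar values plus the physical geometry that places voxel centers in
#' patient space.  World coordinates are in mm; the center of voxel
#' `[1, 1, 1]` sits at `origin`, and voxel `[i, j, k]` at
#' `origin + (c(i, j, k) - 1) * spacing`.  Axes follow the patient-based
#' LPS convention (x left, y posterior, z superior); only axis-aligned
#' volumes are supported.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   center.
#' @param axes orientation descriptor; only `"LPS"` is supported.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0), axes = "LPS") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 1L)) stop("`voxels` must contain at least one voxel", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  if (!identical(axes, "LPS")) stop("only the 'LPS' axes convention is supported", call. = FALSE)
  if (any(!is.finite(voxels))) stop("all voxel values must be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin, axes = axes),
            class = "image_volume")
}

#' Full-course absorbed dose on a raster grid
#'
#' Same geometry contract as [image_volume()]; values are absorbed dose in Gy
#' for the complete treatment course and must be non-negative.
#'
#' @inheritParams image_volume
#' @param values 3D numeric array of dose in Gy.
#' @return An object of class `dose_grid` (also an `image_volume`).
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0), axes = "LPS") {
  vol <- image_volume(values, spacing, origin, axes)
  if (any(vol$voxels < 0)) stop("dose values must be >= 0 Gy", call. = FALSE)
  class(vol) <- c("dose_grid", "image_volume")
  vol
}

#' A contoured structure on a reference grid
#'
#' @param name structure label.
#' @param role one of `"target"`, `"oar"`, `"external"`, `"other"`.
#' @param mask logical 3D array on the reference (planning) grid.
#' @param prescription prescription dose in Gy; required (> 0) for targets.
#'   For simultaneous-integrated-boost plans this is the SIB level of the
#'   target.
#' @return An object of class `rt_structure`.
#' @export
rt_structure <- function(name, role = c("oar", "target", "external", "other"),
                         mask, prescription = NULL) {
  role <- match.arg(role)
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D logical array", call. = FALSE)
  if (role == "target") {
    if (is.null(prescription) || !is.finite(prescription) || prescription <= 0)
      stop("target '", name, "' needs a positive prescription (Gy)", call. = FALSE)
  }
  structure(list(name = as.character(name), role = role, mask = mask,
                 prescription = if (is.null(prescription)) NA_real_ else as.numeric(prescription)),
            class = "rt_structure")
}

#' Treatment-plan context: fractionation, prescriptions and structures
#'
#' @param total_fractions number of fractions N in the course (>= 1).
#' @param structures named list of [rt_structure()] objects.
#' @return An object of class `plan_context`.
#' @export
plan_context <- function(total_fractions, structures) {
  total_fractions <- as.integer(total_fractions)
  if (is.na(total_fractions) || total_fractions < 1L)
    stop("`total_fractions` must be >= 1", call. = FALSE)
  if (!length(structures) || !all(vapply(structures, inherits, TRUE, "rt_structure")))
    stop("`structures` must be a non-empty list of rt_structure objects", call. = FALSE)
  names(structures) <- vapply(structures, `[[`, "", "name")
  rx <- vapply(structures, `[[`, 0, "prescription")
  prescriptions <- rx[!is.na(rx)]
  structure(list(total_fractions = total_fractions,
                 prescriptions = prescriptions,
                 structures = structures),
            class = "plan_context")
}

#' Dense deformation field on the planning grid
#'
#' Stores per-voxel displacement vectors `u` (mm) in the plan-to-daily
#' direction: the tissue element at plan-grid world position `x` is found at
#' `x + u(x)` in the daily anatomy.
#'
#' @param ux,uy,uz 3D arrays of displacement components in mm.
#' @param spacing,origin geometry of the planning grid (see [image_volume()]).
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(ux, uy, uz, spacing, origin = c(0, 0, 0)) {
  dims <- dim(as.array(ux))
  if (length(dims) != 3L) stop("displacement components must be 3D arrays", call. = FALSE)
  if (!identical(dims, dim(as.array(uy))) || !identical(dims, dim(as.array(uz))))
    stop("displacement components must share dimensions", call. = FALSE)
  if (any(!is.finite(ux)) || any(!is.finite(uy)) || any(!is.finite(uz)))
    stop("all displacement components must be finite", call. = FALSE)
  structure(list(ux = as.array(ux), uy = as.array(uy), uz = as.array(uz),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "deformation_field")
}

#' Per-voxel displacement magnitude of a deformation field
#' @param dvf a [deformation_field()].
#' @return 3D array of |u| in mm.
#' @export
dvf_magnitude <- function(dvf) {
  stopifnot(inherits(dvf, "deformation_field"))
  sqrt(dvf$ux^2 + dvf$uy^2 + dvf$uz^2)
}

#' Zero deformation field matching a volume's grid
#' @param vol an [image_volume()].
#' @export
dvf_zero <- function(vol) {
  z <- array(0, dim(vol$voxels))
  deformation_field(z, z, z, vol$spacing, vol$origin)
}

vol_dim <- function(x) dim(if (inherits(x, "deformation_field")) x$ux else x$voxels)

#' Voxel volume of a grid in cm^3
#' @param x an `image_volume`, `dose_grid` or `deformation_field`.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing) / 1000

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

# world coordinates (mm) of every voxel center, as an n x 3 matrix (x fastest)
grid_world_coords <- function(x) {
  d <- vol_dim(x)
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  cbind(rep(i, times = d[2] * d[3]) * x$spacing[1] + x$origin[1],
        rep(rep(j, each = d[1]), times = d[3]) * x$spacing[2] + x$origin[2],
        rep(k, each = d[1] * d[2]) * x$spacing[3] + x$origin[3])
}

# continuous 0-based voxel coordinates of world points on x's grid
world_to_index <- function(x, world) {
  sweep(sweep(world, 2, x$origin, "-"), 2, x$spacing, "/")
}

#' Sample a volume at world positions
#'
#' Trilinear interpolation at arbitrary world coordinates (mm).
#'
#' @param vol an [image_volume()] or [dose_grid()].
#' @param world n x 3 matrix of world coordinates in mm.
#' @param background value returned outside the grid (default 0); ignored
#'   when `clamp = TRUE`, which extends edge values instead.
#' @param clamp extend edge values beyond the grid instead of `background`.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(vol, world, background = 0, clamp = FALSE) {
  idx <- world_to_index(vol, world)
  cpp_trilinear(vol$voxels, dim(vol$voxels), idx[, 1], idx[, 2], idx[, 3],
                background, clamp)
}

#' Resample a volume onto a reference grid
#'
#' Used to bring dose grids and masks stored at a different resolution onto
#' the planning grid: trilinear for scalar data, threshold-0.5 trilinear for
#' masks.
#'
#' @param vol volume to resample.
#' @param ref volume (or any object with `spacing`/`origin`/voxels) whose grid
#'   defines the output.
#' @param method `"linear"` or `"mask"` (linear then `>= 0.5` threshold).
#' @param background fill value outside `vol`'s extent.
#' @return an object like `vol` on `ref`'s grid.
#' @export
resample_to_grid <- function(vol, ref, method = c("linear", "mask"), background = 0) {
  method <- match.arg(method)
  w <- grid_world_coords(ref)
  src <- if (method == "mask") {
    v <- vol; v$voxels <- array(as.numeric(vol$voxels), dim(vol$voxels)); v
  } else vol
  vals <- sample_volume(src, w, background = background)
  out <- array(vals, vol_dim(ref))
  if (method == "mask") return(array(out >= 0.5, vol_dim(ref)))
  res <- vol
  res$voxels <- out; res$spacing <- ref$spacing; res$origin <- ref$origin
  res
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  value range [%.3g, %.3g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.plan_context <- function(x, ...) {
  cat(sprintf("<plan_context> %d fractions, %d structures\n",
              x$total_fractions, length(x$structures)))
  for (s in x$structures)
    cat(sprintf("  %-20s %-9s %s\n", s$name, s$role,
                if (is.na(s$prescription)) "" else sprintf("Rx %.4g Gy", s$prescription)))
  invisible(x)
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$ux)
  m <- dvf_magnitude(x)
  cat(sprintf("<deformation_field> %d x %d x %d, |u| max %.2f mm, mean %.2f mm\n",
              d[1], d[2], d[3], max(m), mean(m)))
  invisible(x)
}
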