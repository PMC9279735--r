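#' Rasterize planar contours to a binary mask
#'
#' Converts RT Structure Set style contours (closed planar polygons on axial
#' slices, world mm coordinates) into a voxel mask on a reference grid.  A
#' voxel belongs to the structure iff its center is inside the polygon(s) of
#' its slice under the even-odd rule, evaluated with a crossing-number test;
#' several polygons on one slice combine by exclusive-or, so holes and rings
#' come out naturally.  Each contour is assigned to the nearest grid plane;
#' contours farther than half a slice spacing from every plane are skipped
#' with a warning.
#'
#' @param contours list of closed polygons, each an n x 3 matrix of world mm
#'   coordinates with constant z per polygon (the closing edge last-to-first
#'   vertex is implicit).
#' @param grid an [image_volume()] supplying the output geometry.
#' @return logical 3D array on `grid`'s raster.
#' @export
rasterize_contours <- function(contours, grid) {
  d <- vol_dim(grid)
  mask <- array(FALSE, d)
  if (!length(contours)) return(mask)
  xc <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  yc <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  for (poly in contours) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3) next
    z <- poly[1, 3]
    k <- round((z - grid$origin[3]) / grid$spacing[3]) + 1
    plane_z <- grid$origin[3] + (k - 1) * grid$spacing[3]
    if (k < 1 || k > d[3] || abs(z - plane_z) > grid$spacing[3] / 2 + 1e-9) {
      warning(sprintf("contour at z = %.3f mm is farther than half a slice spacing from any grid plane; skipped", z))
      next
    }
    inside <- poly_inside(poly[, 1], poly[, 2], xc, yc)
    mask[, , k] <- xor(mask[, , k], inside)
  }
  mask
}

# crossing-number (even-odd) test for a grid of points, vectorized over the
# grid; returns an nx x ny logical matrix
poly_inside <- function(px, py, xc, yc) {
  nx <- length(xc); ny <- length(yc)
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  inside <- matrix(FALSE, nx, ny)
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > Y) != (py[j] > Y)) &
      (X < (px[j] - px[i]) * (Y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
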