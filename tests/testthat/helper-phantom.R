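# Shared phantom fixtures, built once per test run.  The test grids keep the
# default anatomy's physical extent at coarser spacing so geometry stays
# clinically shaped while runs stay fast.

.fixtures <- new.env(parent = emptyenv())

std_config <- function(n_fractions = 30) {
  phantom_config(dim = c(64, 64, 40), spacing = c(3, 3, 3),
                 n_fractions = n_fractions)
}

std_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- make_plan_phantom(std_config(), seed = 11)
  .fixtures$bundle
}

# tiny geometric grid for cheap resampling / warping checks
tiny_volume <- function(fill = 0, dim = c(16, 16, 10), spacing = c(2, 2, 2),
                        origin = c(0, 0, 0)) {
  image_volume(array(fill, dim), spacing, origin)
}

# independent scalar point-in-polygon oracle (crossing number, textbook loop)
pip_oracle <- function(px, py, x, y) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# shift image content by t (mm): daily(y) = plan(y - t)
shifted_volume <- function(vol, t) {
  w <- sweep(rtflow:::grid_world_coords(vol), 2, t, "-")
  out <- vol
  out$voxels <- array(sample_volume(vol, w, clamp = TRUE), dim(vol$voxels))
  out
}
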