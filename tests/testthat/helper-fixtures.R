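# Small reusable fixtures; everything is generated in code.

# tiny cubic grid, voxel 1 mm, centred on the origin
tiny_grid <- function(n = 32L, voxel = 1) volume_grid(rep(n, 3L), voxel)

# single-projection line geometry whose central ray is the x axis
single_ray_geometry <- function(rows = 65L, cols = 65L, pitch = 0.5,
                                sod = 100, sdd = 1000) {
  lt_geometry(sod = sod, sdd = sdd, detector_shape = c(rows, cols),
              pixel_pitch = pitch, translations = 0)
}

# small circular-CT geometry fully covering a tiny grid
small_ct_geometry <- function(n_angles = 36L, rows = 40L, cols = 56L,
                              sod = 100, sdd = 200, pitch = 2) {
  default_ct_geometry(n_angles = n_angles, rows = rows, cols = cols,
                      sod = sod, sdd = sdd, pitch = pitch)
}

# random attenuation volume on a grid
random_volume <- function(grid, seed = 1L) {
  set.seed(seed)
  v <- array(runif(prod(grid$shape)), dim = grid$shape)
  attr(v, "grid") <- grid
  v
}

# concentric-ring phantom small enough for fast projection tests
small_phantom_spec <- function(tilt = 0, n = 48L, voxel = 1,
                               widths = c(3, 4, 2, 5, 3, 4),
                               pith_offset = c(0, 0)) {
  phantom_spec(ring_series(widths), tilt_alpha = tilt,
               pith_offset = pith_offset,
               grid = volume_grid(rep(n, 3L), voxel))
}

expect_series_equal <- function(x, y, tol = 1e-12) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
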