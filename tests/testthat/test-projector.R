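test_that("line integral through a uniform cube equals mu * L", {
  g <- tiny_grid(32)                       # 32 mm cube
  vol <- array(0.3, dim = g$shape); attr(vol, "grid") <- g
  geom <- single_ray_geometry()
  pr <- forward_project(vol, geom, g)$data
  central <- pr[33, 33, 1]                 # ray perpendicular to the face
  expect_lt(abs(central - 0.3 * 3.2) / (0.3 * 3.2), 0.005)
})

test_that("zero volume projects to zero and zero data backprojects to zero", {
  g <- tiny_grid(16)
  z <- array(0, dim = g$shape); attr(z, "grid") <- g
  geom <- small_ct_geometry(n_angles = 8, rows = 16, cols = 24, sod = 20,
                            sdd = 80, pitch = 2)
  expect_equal(max(abs(forward_project(z, geom, g)$data)), 0)
  pz <- projection_stack(array(0, c(16, 24, 8)), geom)
  expect_equal(max(abs(back_project(pz, g, geom))), 0)
})

test_that("projections are invariant under a joint object/geometry shift", {
  spec <- small_phantom_spec(n = 24L, widths = c(3, 4, 2))
  vol <- build_phantom(spec)
  geom <- lt_geometry(sod = 60, sdd = 200, detector_shape = c(32, 48),
                      pixel_pitch = 2, translations = c(-5, 0, 5))
  base <- forward_project(vol, geom, spec$grid)$data
  # translate the phantom by +t along y and the trajectory by +t as well
  t_shift <- 4
  g2 <- volume_grid(spec$grid$shape, spec$grid$voxel_size,
                    origin = spec$grid$origin + c(0, t_shift, 0))
  # the translation values are object positions relative to the trajectory,
  # so moving object and trajectory together lowers each value by the shift
  geom2 <- lt_geometry(sod = 60, sdd = 200, detector_shape = c(32, 48),
                       pixel_pitch = 2,
                       translations = geom$translations - t_shift)
  attr(vol, "grid") <- g2
  shifted <- forward_project(vol, geom2, g2)$data
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("backprojection is the exact adjoint of forward projection", {
  g <- tiny_grid(32)
  x <- random_volume(g, seed = 1)
  geom <- small_ct_geometry(n_angles = 12, rows = 40, cols = 48, sod = 30,
                            sdd = 120, pitch = 1.4)
  Ax <- forward_project(x, geom, g)$data
  set.seed(2)
  y <- array(runif(length(Ax)), dim = dim(Ax))
  Aty <- back_project(projection_stack(y, geom), g, geom)
  lhs <- sum(Ax * y); rhs <- sum(x * Aty)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
})

test_that("a single detector pixel backprojects onto one ray footprint", {
  g <- tiny_grid(24)
  geom <- single_ray_geometry(rows = 9, cols = 9, pitch = 4, sod = 50,
                              sdd = 300)
  pr <- array(0, c(9, 9, 1)); pr[3, 7, 1] <- 1
  vol <- back_project(projection_stack(pr, geom), g, geom)
  nz <- which(vol != 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  # oracle: distance from each touched voxel centre to the analytic ray
  fr <- dendrotomo:::geometry_frames(geom, centre_depth = 12)
  S <- fr$src[1, ]
  P <- fr$det[1, ] + (7 - 5) * 4 * fr$u[1, ] + (3 - 5) * 4 * fr$v[1, ]
  u <- (P - S) / sqrt(sum((P - S)^2))
  ctr <- cbind(g$origin[1] + (nz[, 1] - 1), g$origin[2] + (nz[, 2] - 1),
               g$origin[3] + (nz[, 3] - 1))
  rel <- sweep(ctr, 2, S)
  proj <- rel %*% u
  dist <- sqrt(rowSums((rel - proj %*% t(u))^2))
  expect_lt(max(dist), 1.5)            # bilinear footprint is one voxel wide
})

test_that("the projector is linear", {
  g <- tiny_grid(16)
  geom <- small_ct_geometry(n_angles = 6, rows = 16, cols = 24, sod = 20,
                            sdd = 80, pitch = 2)
  x <- random_volume(g, 3); y <- random_volume(g, 4)
  ax <- forward_project(x, geom, g)$data
  ay <- forward_project(y, geom, g)$data
  z <- 2.5 * x - 1.25 * y; attr(z, "grid") <- g
  az <- forward_project(z, geom, g)$data
  expect_equal(az, 2.5 * ax - 1.25 * ay, tolerance = 1e-10)
})

test_that("mirrored translations of a symmetric phantom mirror the projections", {
  spec <- small_phantom_spec(n = 24L, widths = c(3, 4, 2))  # y-symmetric
  vol <- build_phantom(spec)
  tr <- c(-8, -3, 1.5)
  mk <- function(tt) lt_geometry(sod = 60, sdd = 200,
                                 detector_shape = c(16, 48), pixel_pitch = 2,
                                 translations = tt)
  pa <- forward_project(vol, mk(tr), spec$grid)$data
  pb <- forward_project(vol, mk(sort(-tr)), spec$grid)$data
  # projection at translation t equals the column-mirrored projection at -t
  for (i in seq_along(tr)) {
    a <- pa[, , i]
    b <- pb[, , length(tr) + 1 - i]
    expect_equal(a, b[, ncol(b):1], tolerance = 1e-9)
  }
})

test_that("projection stack TIFF round trip preserves data and geometry link", {
  g <- tiny_grid(16)
  geom <- small_ct_geometry(n_angles = 5, rows = 16, cols = 24, sod = 20,
                            sdd = 80, pitch = 2)
  pr <- forward_project(random_volume(g, 5), geom, g)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(pr$data, f)
  back <- read_stack_tiff(f)
  expect_equal(dim(back), dim(pr$data))
  expect_lt(max(abs(back - pr$data)) / max(pr$data), 1e-8)
})
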