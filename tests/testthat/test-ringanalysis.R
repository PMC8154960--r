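test_that("slice extraction indexes depth from the front face", {
  spec <- small_phantom_spec(n = 24L, widths = c(3, 4, 2))
  vol <- build_phantom(spec)
  g <- spec$grid
  s0 <- extract_slice(vol, 0, g)
  expect_equal(s0$pixels, vol[1, , ])            # front face
  expect_equal(s0$x_mm, g$origin[1])
  s1 <- extract_slice(vol, 1, g)
  expect_equal(s1$pixels, vol[24, , ])
  # translational symmetry of the untilted phantom: any two depths agree
  expect_identical(extract_slice(vol, 0.2, g)$pixels,
                   extract_slice(vol, 0.3, g)$pixels)
  expect_error(extract_slice(vol, 1.2, g), "depth_fraction")
})

test_that("sharpness ranking prefers sharp slices and respects ties", {
  g <- volume_grid(c(10, 32, 32), 1)
  # constant volume: all scores zero, input order preserved
  const <- array(1, dim = g$shape); attr(const, "grid") <- g
  rk <- rank_slices_by_sharpness(const, c(0.3, 0.1, 0.8), g)
  expect_equal(rk$fraction, c(0.3, 0.1, 0.8))
  expect_equal(rk$score, rep(0, 3))
  # a blurred copy of a sharp pattern ranks below the original
  sharp <- matrix(rep(c(0, 0, 1, 1), 8), 32, 32)
  blur <- (sharp[c(1, 1:31), ] + sharp + sharp[c(2:32, 32), ]) / 3
  vol <- array(0, dim = g$shape)
  vol[1, , ] <- sharp; vol[5, , ] <- blur
  attr(vol, "grid") <- g
  rk2 <- rank_slices_by_sharpness(vol, c(0, 4 / 9), g)
  expect_equal(rk2$fraction[1], 0)
  expect_gt(rk2$score[1], rk2$score[2])
})

test_that("profiles interpolate bilinearly along the path", {
  g <- volume_grid(c(4, 32, 32), 1)
  vol <- array(0, dim = g$shape)
  # linear ramp along y: value = y coordinate
  ys <- g$origin[2] + (seq_len(32) - 1)
  for (i in 1:4) vol[i, , ] <- matrix(ys, 32, 32)
  attr(vol, "grid") <- g
  sl <- extract_slice(vol, 0.5, g)
  # constant image -> constant profile
  slc <- sl; slc$pixels <- matrix(3.3, 32, 32)
  p0 <- profile_along_path(slc, rbind(c(-10, 0), c(10, 0)), step = 0.5)
  expect_equal(p0$values, rep(3.3, length(p0$values)))
  # ramp image -> linear profile along the ramp direction
  p1 <- profile_along_path(sl, rbind(c(-10, 2), c(10, 2)), step = 0.5)
  expect_equal(p1$values, seq(-10, 10, by = 0.5), tolerance = 1e-12)
  # agreement with a 10x oversampled nearest-neighbour oracle
  set.seed(12)
  img <- matrix(runif(32 * 32), 32, 32)
  sl$pixels <- img
  path <- rbind(c(-9.7, -6.1), c(8.9, 7.3))
  pr <- profile_along_path(sl, path, step = 0.4)
  L <- sqrt(sum((path[2, ] - path[1, ])^2))
  for (k in seq_along(pr$positions)) {
    s <- pr$positions[k]
    pt <- path[1, ] + s / L * (path[2, ] - path[1, ])
    i <- (pt[1] - sl$origin[1]) / sl$pixel_size[1]
    j <- (pt[2] - sl$origin[2]) / sl$pixel_size[2]
    nn <- img[round(i) + 1, round(j) + 1]
    expect_lt(abs(pr$values[k] - nn), 0.5)   # within NN/bilinear gap
  }
  expect_error(profile_along_path(sl, rbind(c(0, 0), c(0, 0))), "distinct")
})

test_that("boundary detection recovers periodic structure", {
  # cosine profile with period 2 mm: latewood peaks every 2 mm, and the
  # steepest falling edge sits a quarter period after each peak
  s <- seq(0, 20, by = 0.05)
  prof <- list(positions = s, values = cos(pi * s))
  b <- detect_boundaries(prof, min_separation = 1)
  expect_gt(length(b), 7)
  expect_equal(diff(b), rep(2, length(b) - 1), tolerance = 0.03)
  # constant profile: no peaks, empty result with a warning
  expect_warning(
    empty <- detect_boundaries(list(positions = s,
                                    values = rep(1, length(s)))),
    "no latewood peaks")
  expect_length(empty, 0)
})

test_that("phantom-slice round trip recovers boundaries within 1.5 pixels", {
  series <- generate_ring_series(12, 2.5, 0.2, seed = 14)
  grid <- volume_grid(c(8, 320, 320), 0.25)
  spec <- phantom_spec(series, grid = grid)
  vol <- build_phantom(spec)
  sl <- extract_slice(vol, 0.5, grid)
  prof <- profile_along_path(sl, rbind(c(0, 0), c(38, 0)))
  b <- detect_boundaries(prof, min_separation = 0.5)
  truth <- cumsum(as.numeric(series))
  expect_equal(length(b), length(truth))
  expect_lt(max(abs(b - truth)), 1.5 * 0.25)     # 1.5 pixels of 0.25 mm
  w <- measure_rings(b)
  expect_equal(as.numeric(w), diff(truth), tolerance = 0.25)
})

test_that("ring widths are consecutive distances between points", {
  expect_series_equal(measure_rings(c(0, 1, 2)), c(1, 1))
  expect_series_equal(measure_rings(rbind(c(0, 0), c(3, 4))), 5)
  # pixel coordinates convert through the pixel size
  expect_series_equal(measure_rings(c(0, 10, 30), pixel_size = 0.1),
                      c(1, 2))
  expect_error(measure_rings(c(1, 1, 2)), "duplicate")
  expect_error(measure_rings(5), "at least 2")
  # widths telescope: sum equals the distance from first to last boundary
  b <- sort(runif(10, 0, 30))
  expect_equal(total_extent(measure_rings(b)), max(b) - min(b))
})

test_that("manual coordinate points load from CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x_mm = c(0, 1.5, 4), y_mm = c(0, 0, 0)), f,
            row.names = FALSE)
  pts <- read_coordinate_points(f)
  expect_series_equal(measure_rings(pts), c(1.5, 2.5))
  write.csv(data.frame(a = 1), f, row.names = FALSE)
  expect_error(read_coordinate_points(f), "x_mm")
})
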