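test_that("phantom voxels take exactly the three analytic values", {
  spec <- small_phantom_spec()
  vol <- build_phantom(spec)
  expect_setequal(unique(as.numeric(vol)), c(0, spec$mu_early, spec$mu_late))
  expect_equal(dim(vol), spec$grid$shape)
})

test_that("untilted phantom is translation-invariant along the pith axis", {
  vol <- build_phantom(small_phantom_spec(tilt = 0))
  for (i in c(2, 17, 41))
    expect_identical(vol[i, , ], vol[1, , ])
})

test_that("tilted phantom slices are laterally shifted tilt-0 patterns", {
  # at depth x the tilt-a pattern is the tilt-0 pattern shifted by x*tan(a)
  n <- 64L
  spec0 <- small_phantom_spec(tilt = 0, n = n)
  spec8 <- small_phantom_spec(tilt = 8, n = n)
  v0 <- build_phantom(spec0); v8 <- build_phantom(spec8)
  g <- spec0$grid
  xs <- g$origin[1] + (seq_len(n) - 1) * g$voxel_size[1]
  for (i in c(10L, 48L)) {
    shift_vox <- round(xs[i] * tan(8 * pi / 180) / g$voxel_size[2])
    cols <- seq_len(n)
    keep <- cols + shift_vox >= 1 & cols + shift_vox <= n
    a <- v8[i, cols[keep] + shift_vox, ]
    b <- v0[i, cols[keep], ]
    # shifted patterns agree except within one voxel of ring boundaries
    expect_gt(mean(a == b), 0.93)
  }
})

test_that("phantom is invariant under joint 90-degree rotation of offset and grid", {
  w <- c(2, 3, 2)
  base <- phantom_spec(ring_series(w), pith_offset = c(5, 0),
                       grid = volume_grid(c(8, 24, 24), 1))
  rot <- phantom_spec(ring_series(w), pith_offset = c(0, 5),
                      grid = volume_grid(c(8, 24, 24), 1))
  vb <- build_phantom(base); vr <- build_phantom(rot)
  # rotating offset by +90 about x maps (y, z) -> (-z, y), so the rotated
  # volume at (y, z) equals the base volume at (z, -y)
  for (i in seq_len(8))
    expect_identical(vr[i, , ], t(vb[i, , 24:1]))
})

test_that("boundary circle radii equal cumulative width sums (tilt 0)", {
  w <- c(3, 4, 2, 5)
  spec <- phantom_spec(ring_series(w), grid = volume_grid(c(4, 128, 128), 0.25))
  vol <- build_phantom(spec)
  g <- spec$grid
  ys <- g$origin[2] + (seq_len(128) - 1) * 0.25
  zmid <- which.min(abs(g$origin[3] + (seq_len(128) - 1) * 0.25))
  prof <- vol[1, , zmid]                     # radial cut through the pith
  outer_r <- max(abs(ys[prof > 0]))          # outermost non-background voxel
  expect_lt(abs(outer_r - sum(w)), 0.25)     # within one voxel
  for (k in seq_along(w)) {                  # each boundary where ring k ends
    inside <- abs(ys) <= cumsum(w)[k] - 0.125
    expect_true(all(prof[inside] > 0))
  }
})

test_that("ground-truth widths: radial path recovers the generating series", {
  spec <- phantom_spec(ring_series(c(1, 2, 3)),
                       grid = volume_grid(c(16, 16, 16), 1))
  gt <- ground_truth_widths(spec, from = c(0, 0), to = c(7.5, 0),
                            depth_fraction = 0)
  expect_series_equal(gt$widths, c(1, 2, 3), tol = 1e-9)
})

test_that("ground-truth widths: secant path stretches widths by 1/cos", {
  # pith far away so the boundaries are locally straight; a path at 60 deg
  # to the radial direction crosses 1 mm rings every 2 mm
  R <- 1e5
  spec <- phantom_spec(ring_series(rep(1, round(R) + 20)),
                       pith_offset = c(-R, 0),
                       grid = volume_grid(c(16, 64, 64), 1))
  th <- 60 * pi / 180
  gt <- ground_truth_widths(spec, from = c(0, 0),
                            to = c(10 * cos(th), 10 * sin(th)),
                            depth_fraction = 0.5)
  w <- as.numeric(gt$widths)
  expect_equal(w, rep(1 / cos(th), length(w)), tolerance = 1e-3)
})

test_that("ground-truth boundaries agree with brute-force 1-micron marching", {
  spec <- small_phantom_spec(pith_offset = c(3.3, -2.1))
  from <- c(-1.7, 4.1); to <- c(14.9, 12.3); depth <- 0.37
  gt <- ground_truth_widths(spec, from, to, depth)
  # oracle: march along the path at 1 um steps and record ring-index changes
  g <- spec$grid
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$voxel_size[1]
  x0 <- xs[1] + depth * (xs[g$shape[1]] - xs[1])
  a <- c(x0, from); b <- c(x0, to)
  L <- sqrt(sum((b - a)^2)); u <- (b - a) / L
  alpha <- spec$tilt_alpha * pi / 180
  d <- c(cos(alpha), sin(alpha), 0); p0 <- c(0, spec$pith_offset)
  s <- seq(0, L, by = 1e-3)
  pts <- t(a + outer(u, s))
  rel <- sweep(pts, 2, p0)
  tproj <- rel %*% d
  r <- sqrt(rowSums((rel - tproj %*% t(d))^2))
  cum <- cumsum(as.numeric(spec$ring_series))
  ring <- findInterval(r, cum, left.open = TRUE)
  cross <- which(diff(ring) != 0)
  pos_oracle <- (s[cross] + s[cross + 1]) / 2
  pos <- gt$positions
  pos <- pos[pos > 1e-9]                     # marching cannot see s = 0
  expect_equal(length(pos), length(pos_oracle))
  expect_lt(max(abs(pos - pos_oracle)), 2e-3)
})

test_that("degenerate measurement paths are rejected", {
  spec <- small_phantom_spec()
  expect_error(ground_truth_widths(spec, c(0.1, 0), c(0.2, 0)),
               "no boundaries crossed")
  expect_error(ground_truth_widths(spec, c(1, 1), c(1, 1)), "distinct")
})

test_that("phantom TIFF export/import round-trips volume and grid", {
  spec <- small_phantom_spec(n = 24L)
  vol <- build_phantom(spec)
  f <- withr::local_tempfile(fileext = ".tif")
  export_phantom_tiff(vol, f, spec)
  back <- import_phantom_tiff(f)
  expect_equal(dim(back), dim(vol))
  expect_lt(max(abs(back - vol)), 1e-8)
  g2 <- attr(back, "grid")
  expect_equal(g2$shape, spec$grid$shape)
  expect_equal(g2$voxel_size, spec$grid$voxel_size)
})
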