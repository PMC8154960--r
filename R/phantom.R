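#' Reconstruction/phantom voxel grid
#'
#' Describes a 3D attenuation volume: voxel counts `(nx, ny, nz)` with x the
#' source-detector axis, y the translation axis and z vertical, per-axis
#' voxel sizes in mm (cuboid voxels allowed), and the world coordinate of the
#' centre of voxel `(1, 1, 1)`. By default the grid is centred on the world
#' origin.
#'
#' @param shape integer `(nx, ny, nz)`.
#' @param voxel_size `(sx, sy, sz)` in mm; a scalar is recycled.
#' @param origin world position (mm) of the first voxel centre; `NULL`
#'   centres the grid on the origin.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = 1, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive voxel counts", call. = FALSE)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("Volume grid %d x %d x %d voxels, voxel %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# world coordinates of voxel centres along one axis (1-based index)
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

#' Tree-ring phantom specification
#'
#' A two-phase (earlywood/latewood) model of a piece of wood with perfectly
#' concentric rings around a pith axis. The pith axis runs nominally along x
#' (the source-detector axis) and is rotated about the vertical z axis by the
#' tree-ring tilt `tilt_alpha`; the rotation is about the volume centre. In
#' each ring the outer `latewood_fraction` of the width takes the denser
#' latewood attenuation `mu_late`, the rest `mu_early`; voxels beyond the
#' outermost ring are background (0).
#'
#' @param ring_series a [ring_series()] giving the ring widths pith to bark.
#' @param tilt_alpha tree-ring tilt in degrees (angle between the pith axis
#'   and the source-detector axis, rotation about z), in [-90, 90].
#' @param pith_offset `(y, z)` offset in mm of the pith axis from the volume
#'   centre; the pith may lie outside the volume.
#' @param latewood_fraction fraction of each ring width occupied by latewood
#'   at its outer edge, in [0, 1).
#' @param mu_early,mu_late attenuation coefficients (1/cm) of earlywood and
#'   latewood; `mu_late > mu_early > 0`. Defaults approximate softwood
#'   contrast; only their ratio matters for ring visibility.
#' @param grid a [volume_grid()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ring_series, tilt_alpha = 0, pith_offset = c(0, 0),
                         latewood_fraction = 0.3, mu_early = 0.3,
                         mu_late = 0.6, grid = volume_grid(c(96, 96, 96))) {
  if (!inherits(ring_series, "ring_series") || length(ring_series) < 1L)
    stop("ring_series must be a non-empty ring_series", call. = FALSE)
  if (!(latewood_fraction >= 0 && latewood_fraction < 1))
    stop("latewood_fraction must be in [0, 1)", call. = FALSE)
  if (!(mu_late > mu_early && mu_early > 0))
    stop("need mu_late > mu_early > 0", call. = FALSE)
  if (abs(tilt_alpha) > 90)
    stop("tilt_alpha must lie in [-90, 90] degrees", call. = FALSE)
  structure(list(ring_series = ring_series, tilt_alpha = tilt_alpha,
                 pith_offset = rep(as.numeric(pith_offset), length.out = 2L),
                 latewood_fraction = latewood_fraction,
                 mu_early = mu_early, mu_late = mu_late, grid = grid),
            class = "phantom_spec")
}

# point on pith axis and unit direction, world mm
pith_axis <- function(spec) {
  a <- spec$tilt_alpha * pi / 180
  list(point = c(0, spec$pith_offset[1L], spec$pith_offset[2L]),
       dir = c(cos(a), sin(a), 0))
}

#' Build the attenuation volume of a tree-ring phantom
#'
#' Each voxel takes the value at its centre (no partial-volume averaging, so
#' the phantom remains an exact analytic oracle): the radial distance from
#' the voxel centre to the tilted pith axis selects a ring, and within ring k
#' the outer `latewood_fraction` of the width maps to `mu_late`, the rest to
#' `mu_early`. The voxel values are therefore exactly
#' `{0, mu_early, mu_late}`.
#'
#' @param spec a [phantom_spec()].
#' @return A 3D array of attenuation values (1/cm) with `dim = grid$shape`
#'   and the grid attached as attribute `grid`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  ax <- pith_axis(spec)
  xs <- grid_axis(g, 1L); ys <- grid_axis(g, 2L); zs <- grid_axis(g, 3L)
  w <- as.numeric(spec$ring_series)
  cum <- cumsum(w)
  late_inner <- cum - spec$latewood_fraction * w  # latewood starts here
  nx <- g$shape[1L]; ny <- g$shape[2L]; nz <- g$shape[3L]
  vol <- array(0, dim = g$shape)
  d <- ax$dir; p0 <- ax$point
  # distance to axis, computed slice-block-wise to limit peak memory
  yy <- rep(ys, times = nz) - p0[2L]
  zz <- rep(zs, each = ny) - p0[3L]
  for (i in seq_len(nx)) {
    rx <- xs[i] - p0[1L]
    # component of (r - p0) along the axis direction
    t <- rx * d[1L] + yy * d[2L]            # d[3] = 0
    r <- sqrt((rx - t * d[1L])^2 + (yy - t * d[2L])^2 + zz^2)
    ring <- findInterval(r, cum, left.open = TRUE) + 1L  # ring index
    inside <- ring <= length(w)
    v <- numeric(ny * nz)
    v[inside] <- ifelse(r[inside] >= late_inner[ring[inside]],
                        spec$mu_late, spec$mu_early)
    vol[i, , ] <- v
  }
  attr(vol, "grid") <- g
  vol
}

#' Analytic ring widths along a measurement path
#'
#' Intersects a straight measurement path, drawn in a transverse (yz) slice
#' at a given depth, with the phantom's exact ring-boundary surfaces, and
#' returns the distances between consecutive boundary crossings. The pith
#' itself (radius 0) counts as the inner boundary of the first ring, so a
#' path starting at the pith recovers the generating widths exactly. This is
#' the oracle against which image-based ring measurement is validated.
#'
#' @param spec a [phantom_spec()].
#' @param from,to path endpoints `(y, z)` in mm, world coordinates.
#' @param depth_fraction fractional depth of the slice from the front
#'   (minimal-x) face, in [0, 1].
#' @return A list with `positions` (arc-length positions of the boundary
#'   crossings along the path, mm) and `widths` (a [ring_series()] of their
#'   consecutive differences).
#' @export
ground_truth_widths <- function(spec, from, to, depth_fraction = 0.25) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  xs <- grid_axis(g, 1L)
  x0 <- xs[1L] + depth_fraction * (xs[g$shape[1L]] - xs[1L])
  a <- c(x0, from[1L], from[2L])
  b <- c(x0, to[1L], to[2L])
  L <- sqrt(sum((b - a)^2))
  if (L <= 0) stop("path endpoints must be distinct", call. = FALSE)
  u <- (b - a) / L
  ax <- pith_axis(spec); d <- ax$dir; p0 <- ax$point
  # squared distance to axis along the path: r2(s) = |w + s*q|^2 with
  # w, q the components of (a - p0), u orthogonal to the axis direction
  w0 <- (a - p0) - sum((a - p0) * d) * d
  q <- u - sum(u * d) * d
  A <- sum(q * q); B <- 2 * sum(w0 * q); C0 <- sum(w0 * w0)
  radii <- c(0, cumsum(as.numeric(spec$ring_series)))
  pos <- c()
  for (rad in radii) {
    disc <- B^2 - 4 * A * (C0 - rad^2)
    if (A <= 0 || disc < 0) next
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    pos <- c(pos, roots[roots >= -1e-9 & roots <= L + 1e-9])
  }
  pos <- sort(unique(round(pos, 9)))
  if (length(pos) < 2L)
    stop("no boundaries crossed: path lies within a single ring",
         call. = FALSE)
  widths <- diff(pos)
  widths <- widths[widths > 1e-9]
  list(positions = pos,
       widths = ring_series(widths, label = "ground_truth"))
}
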