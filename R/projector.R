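#' Projection stack
#'
#' Container for a set of 2D radiographs: a 3D array `(rows, cols,
#' n_projections)` of either raw detector counts (`kind = "raw"`) or
#' flat-/dark-corrected attenuation line integrals (`kind = "corrected"`),
#' together with the acquisition geometry and, for raw data, optional flat
#' and dark reference frames.
#'
#' @param data numeric array `(rows, cols, n_projections)`; a matrix is
#'   treated as a single projection.
#' @param geometry an [lt_geometry()]; the projection count must match.
#' @param kind `"raw"` counts or `"corrected"` line integrals.
#' @param flats,darks optional reference frames (matrices of detector shape).
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(data, geometry, kind = c("corrected", "raw"),
                             flats = NULL, darks = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("data must be a (rows, cols, n_projections) array", call. = FALSE)
  if (!is.null(geometry)) {
    if (!all(dim(data)[1:2] == geometry$detector_shape))
      stop("data frame shape does not match the detector shape", call. = FALSE)
    if (dim(data)[3L] != n_projections(geometry))
      stop("number of frames does not match the geometry's projection count",
           call. = FALSE)
  }
  structure(list(data = data, geometry = geometry, kind = kind,
                 flats = flats, darks = darks),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Projection stack (%s): %d frames of %d x %d px\n",
              x$kind, d[3], d[1], d[2]))
  invisible(x)
}

# frames for a geometry and a centred grid (centre depth = half x-extent)
frames_for_grid <- function(geom, grid) {
  geometry_frames(geom, centre_depth = grid$shape[1L] * grid$voxel_size[1L] / 2)
}

#' Cone-beam forward projection
#'
#' Computes attenuation line integrals of a volume for every source/detector
#' position of the trajectory. Rays are cast from the source through each
#' detector pixel centre and integrated through the volume by Joseph-style
#' dominant-axis stepping with bilinear in-plane interpolation, so a ray
#' crossing a uniform region of attenuation mu over a path of length L
#' contributes mu * L (with mu in 1/cm and L in cm, i.e. lengths in mm are
#' divided by 10).
#'
#' @param volume 3D attenuation array (1/cm), dim equal to `grid$shape`.
#' @param geom an [lt_geometry()].
#' @param grid the [volume_grid()] of `volume`; defaults to the grid attached
#'   to the volume by [build_phantom()].
#' @return A corrected-kind [projection_stack()] of line integrals
#'   (dimensionless).
#' @export
forward_project <- function(volume, geom, grid = attr(volume, "grid")) {
  check_vol(volume, grid)
  fr <- frames_for_grid(geom, grid)
  pr <- .cb_project(as.numeric(volume) / 10,  # mm path lengths -> cm
                    grid$shape, grid$voxel_size, grid$origin,
                    fr$src, fr$det, fr$u, fr$v,
                    geom$detector_shape, geom$pixel_pitch,
                    numeric(0), 0L)
  dim(pr) <- c(geom$detector_shape, n_projections(geom))
  projection_stack(pr, geom, kind = "corrected")
}

#' Cone-beam backprojection (adjoint of the forward projector)
#'
#' Applies the exact transpose of [forward_project()] on the same
#' discretization: every projection value is scattered back along its ray
#' with the same interpolation weights and path-length factors. This is the
#' `A'` required by SIRT; it is not by itself a reconstruction.
#'
#' @param projections a [projection_stack()] (or bare array).
#' @param geom an [lt_geometry()]; defaults to the stack's own geometry.
#' @param grid target [volume_grid()].
#' @return A 3D array with `dim = grid$shape` and the grid attached.
#' @export
back_project <- function(projections, grid,
                         geom = NULL) {
  if (inherits(projections, "projection_stack")) {
    if (is.null(geom)) geom <- projections$geometry
    pr <- projections$data
  } else pr <- projections
  if (is.null(geom)) stop("geometry required", call. = FALSE)
  if (!all(dim(pr) == c(geom$detector_shape, n_projections(geom))))
    stop("projection array does not match the geometry", call. = FALSE)
  fr <- frames_for_grid(geom, grid)
  vol <- .cb_project(numeric(0),
                     grid$shape, grid$voxel_size, grid$origin,
                     fr$src, fr$det, fr$u, fr$v,
                     geom$detector_shape, geom$pixel_pitch,
                     as.numeric(pr) / 10, 1L)
  dim(vol) <- grid$shape
  attr(vol, "grid") <- grid
  vol
}

check_vol <- function(volume, grid) {
  if (is.null(grid))
    stop("no volume_grid supplied or attached to the volume", call. = FALSE)
  if (!all(dim(volume) == grid$shape))
    stop("volume dimensions do not match the grid", call. = FALSE)
  invisible(TRUE)
}

#' Write and read image stacks as multi-page TIFF with a sidecar
#'
#' Volumes (z pages) and projection stacks (one page per projection) are
#' written as 32-bit multi-page TIFF. TIFF storage holds values in [0, 1],
#' so data are min-max normalized on write and the `scale`/`offset` pair is
#' recorded in a plain-text sidecar (`<path>.meta`) together with the array
#' shape and, for volumes, the voxel sizes; reading undoes the normalization
#' (round-trip relative error ~1e-9).
#'
#' @param x 3D array: volume `(nx, ny, nz)` (pages along z after permuting)
#'   or projection data `(rows, cols, n)`.
#' @param path TIFF file path; the sidecar is `<path>.meta`.
#' @param meta named list of extra key/value pairs for the sidecar.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns the array with sidecar entries as attribute `meta`.
#' @export
write_stack_tiff <- function(x, path, meta = list()) {
  stopifnot(length(dim(x)) == 3L)
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(x)[3L]),
                  function(k) (x[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  m <- c(list(shape = paste(dim(x), collapse = " "),
              offset = formatC(lo, format = "g", digits = 17),
              scale = formatC(scale, format = "g", digits = 17)),
         meta)
  writeLines(paste0(names(m), ": ", unlist(lapply(m, paste, collapse = " "))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- list()
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    for (ln in readLines(mp)) {
      p <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1L]]
      meta[[trimws(p[1L])]] <- trimws(p[2L])
    }
  }
  x <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  if (!is.null(meta$scale))
    x <- x * as.numeric(meta$scale) + as.numeric(meta$offset)
  attr(x, "meta") <- meta
  x
}

#' Export and import a phantom volume as TIFF plus metadata
#'
#' Pages run along z; the sidecar records the grid shape, voxel sizes and
#' the generating spec parameters so the volume can be re-imported with its
#' grid.
#'
#' @param volume a phantom/reconstruction array with attached grid.
#' @param path TIFF path.
#' @param spec optional [phantom_spec()] whose scalar parameters are recorded.
#' @return `export_phantom_tiff` returns `path`; `import_phantom_tiff`
#'   returns the volume with its [volume_grid()] attached.
#' @export
export_phantom_tiff <- function(volume, path, spec = NULL) {
  g <- attr(volume, "grid")
  check_vol(volume, g)
  meta <- list(voxel_size = paste(g$voxel_size, collapse = " "),
               origin = paste(g$origin, collapse = " "))
  if (!is.null(spec))
    meta <- c(meta, list(tilt_alpha = spec$tilt_alpha,
                         pith_offset = paste(spec$pith_offset, collapse = " "),
                         latewood_fraction = spec$latewood_fraction,
                         mu_early = spec$mu_early, mu_late = spec$mu_late,
                         ring_widths = paste(as.numeric(spec$ring_series),
                                             collapse = " ")))
  # pages along z: permute (nx, ny, nz) -> (nx, ny) pages
  write_stack_tiff(volume, path, meta = meta)
}

#' @rdname export_phantom_tiff
#' @export
import_phantom_tiff <- function(path) {
  x <- read_stack_tiff(path)
  meta <- attr(x, "meta")
  g <- volume_grid(as.integer(strsplit(meta$shape, " ")[[1L]]),
                   as.numeric(strsplit(meta$voxel_size, " ")[[1L]]),
                   as.numeric(strsplit(meta$origin, " ")[[1L]]))
  attr(x, "grid") <- g
  x
}
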