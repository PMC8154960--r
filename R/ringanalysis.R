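#' Extract a transverse slice from a reconstruction
#'
#' Returns the yz plane at a fractional depth measured from the front
#' (source-side, minimal-x) face. The front of the object has the highest
#' magnification and hence the best resolution, but the limited-angle
#' smearing means the very front face itself is not the sharpest plane;
#' planes around a quarter of the way into the object usually are, hence the
#' default `depth_fraction = 0.25`.
#'
#' @param volume reconstruction or phantom array.
#' @param depth_fraction fraction in [0, 1] of the x extent; the slice index
#'   is `round(depth_fraction * (nx - 1)) + 1`.
#' @param grid the volume's [volume_grid()] (default: attached attribute).
#' @return An object of class `slice_image`: list with `pixels` (ny x nz
#'   matrix, first index along y), `pixel_size` (mm along y and z),
#'   `depth_fraction`, and `x_mm` (world x of the slice plane).
#' @export
extract_slice <- function(volume, depth_fraction = 0.25,
                          grid = attr(volume, "grid")) {
  check_vol(volume, grid)
  if (depth_fraction < 0 || depth_fraction > 1)
    stop("depth_fraction must lie in [0, 1]", call. = FALSE)
  i <- as.integer(round(depth_fraction * (grid$shape[1L] - 1L))) + 1L
  structure(list(pixels = volume[i, , ],
                 pixel_size = grid$voxel_size[2:3],
                 depth_fraction = depth_fraction,
                 x_mm = grid_axis(grid, 1L)[i],
                 origin = grid$origin[2:3]),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("Transverse slice at depth fraction %.2f (x = %.3f mm): %d x %d px\n",
              x$depth_fraction, x$x_mm, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Rank candidate slice depths by sharpness
#'
#' Automates the choice of the measurement slice with a Tenengrad focus
#' score: the mean squared gradient magnitude of each candidate slice
#' (central differences). Sharper ring boundaries give larger gradients; a
#' blurred copy of a slice always scores lower. Ties (e.g. a constant
#' volume) preserve the input order.
#'
#' @param volume reconstruction array.
#' @param fractions candidate depth fractions.
#' @param grid the volume's [volume_grid()].
#' @return Data frame with `fraction` and `score`, sorted by descending
#'   score.
#' @export
rank_slices_by_sharpness <- function(volume, fractions = seq(0.05, 0.95, 0.05),
                                     grid = attr(volume, "grid")) {
  if (length(fractions) < 1L) stop("no candidate fractions", call. = FALSE)
  score <- vapply(fractions, function(f) {
    tenengrad(extract_slice(volume, f, grid)$pixels)
  }, numeric(1))
  ord <- order(score, decreasing = TRUE)
  data.frame(fraction = fractions[ord], score = score[ord])
}

tenengrad <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(0)
  gx <- (m[3:nr, 2:(nc - 1)] - m[1:(nr - 2), 2:(nc - 1)]) / 2
  gy <- (m[2:(nr - 1), 3:nc] - m[2:(nr - 1), 1:(nc - 2)]) / 2
  mean(gx^2 + gy^2)
}

#' Sample an intensity profile along a measurement path
#'
#' Bilinearly interpolates the slice at equidistant arc-length positions
#' along a polyline path. Ring measurement paths are drawn perpendicular to
#' the ring boundaries, typically radially away from the pith.
#'
#' @param slice a [extract_slice()] result.
#' @param path numeric matrix (k x 2) of `(y, z)` waypoints in mm (world
#'   coordinates), k >= 2, consecutive points distinct.
#' @param step sampling step along the arc in mm (default half the smaller
#'   pixel size).
#' @return List with `positions` (arc length, mm) and `values`.
#' @export
profile_along_path <- function(slice, path, step = NULL) {
  stopifnot(inherits(slice, "slice_image"))
  path <- matrix(as.numeric(path), ncol = 2L)
  if (nrow(path) < 2L || any(rowSums(abs(diff(path))) == 0))
    stop("path needs >= 2 distinct consecutive points", call. = FALSE)
  if (is.null(step)) step <- min(slice$pixel_size) / 2
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], by = step)
  # map arc length to (y, z)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= length(cum)] <- length(cum) - 1L
  f <- (s - cum[idx]) / seg[idx]
  pts <- path[idx, , drop = FALSE] + f * (path[idx + 1L, , drop = FALSE] -
                                            path[idx, , drop = FALSE])
  vals <- bilinear_sample(slice$pixels, (pts[, 1L] - slice$origin[1L]) /
                            slice$pixel_size[1L],
                          (pts[, 2L] - slice$origin[2L]) /
                            slice$pixel_size[2L])
  list(positions = s, values = vals)
}

# bilinear interpolation at fractional 0-based indices (i along rows,
# j along cols), clamped at the image border
bilinear_sample <- function(m, i, j) {
  nr <- nrow(m); nc <- ncol(m)
  i <- pmin(pmax(i, 0), nr - 1); j <- pmin(pmax(j, 0), nc - 1)
  i0 <- pmin(floor(i), nr - 2); j0 <- pmin(floor(j), nc - 2)
  fi <- i - i0; fj <- j - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L            # to 1-based
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Detect ring boundaries along an intensity profile
#'
#' A ring boundary is the latewood-to-earlywood transition: attenuation
#' peaks in the dense latewood at the end of each ring and drops sharply
#' into the next ring's earlywood. For every prominence-filtered local
#' maximum, the boundary is placed at the steepest falling gradient after
#' the peak (before the next peak). Manual boundary coordinates can be
#' passed directly to [measure_rings()] instead.
#'
#' @param profile list with `positions` (mm) and `values`, as returned by
#'   [profile_along_path()].
#' @param min_prominence minimal peak prominence; default 10% of the profile
#'   dynamic range.
#' @param min_separation minimal distance between successive peaks in mm
#'   (default 0.2, below the narrowest rings of slow-grown conifers).
#' @return Numeric vector of strictly increasing boundary positions (mm);
#'   empty, with a warning, when no peaks are found.
#' @export
detect_boundaries <- function(profile, min_prominence = NULL,
                              min_separation = 0.2) {
  v <- profile$values; s <- profile$positions
  if (length(v) < 3L) stop("profile too short", call. = FALSE)
  if (is.null(min_prominence)) min_prominence <- 0.1 * diff(range(v))
  pk <- find_peaks(v, min_prominence, min_separation, s)
  if (length(pk) == 0L) {
    warning("no latewood peaks found in profile")
    return(numeric(0))
  }
  # boundary = the falling latewood -> earlywood edge after each peak,
  # located where the profile crosses halfway between the latewood peak and
  # the following earlywood trough; linear interpolation between samples
  # gives a sub-sample position (on smooth edges this is where the fall is
  # steepest)
  bounds <- numeric(length(pk))
  lim <- c(pk[-1L], length(v))       # search up to the next peak (or end)
  for (i in seq_along(pk)) {
    span <- seq(pk[i], lim[i])
    trough <- span[which.min(v[span])]
    half <- (v[pk[i]] + v[trough]) / 2
    j <- pk[i]
    while (j < trough && v[j + 1L] > half) j <- j + 1L
    if (j >= trough) { bounds[i] <- s[trough]; next }
    f <- (v[j] - half) / (v[j] - v[j + 1L])  # fraction into the interval
    bounds[i] <- s[j] + f * (s[j + 1L] - s[j])
  }
  unique(sort(bounds))
}

# local maxima filtered by prominence (height above the higher of the two
# flanking minima down to the neighbouring larger peaks) and by minimal
# separation (keep the larger peak)
find_peaks <- function(v, min_prominence, min_separation, s) {
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- v[seq_len(i - 1L)]
    right <- v[seq(i + 1L, n)]
    hl <- which(left > v[i]); hr <- which(right > v[i])
    lmin <- min(left[seq(if (length(hl)) max(hl) else 1L, i - 1L)])
    rmin <- min(right[seq_len(if (length(hr)) min(hr) else length(right))])
    v[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  ord <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(s[i] - s[sel]) >= min_separation))
      sel <- c(sel, i)
  sort(sel)
}

#' Ring widths from boundary positions or manual coordinate points
#'
#' Consecutive distances between boundary points, mimicking the manual
#' workflow in which a dendrochronologist places coordinate points on the
#' ring boundaries and the distance between consecutive points is the ring
#' width.
#'
#' @param points either a numeric vector of positions along a measurement
#'   line (mm), or a (k x 2) matrix of `(y, z)` coordinates in mm; k >= 2.
#' @param pixel_size optional scale factor applied to `points` given in
#'   pixels instead of mm (scalar or per-axis pair).
#' @param label label of the resulting series.
#' @return A [ring_series()] of the k - 1 consecutive distances.
#' @export
measure_rings <- function(points, pixel_size = NULL, label = "measured") {
  if (is.matrix(points)) {
    if (!is.null(pixel_size))
      points <- sweep(points, 2L, rep(pixel_size, length.out = 2L), `*`)
    d <- sqrt(rowSums(diff(points)^2))
  } else {
    points <- as.numeric(points)
    if (!is.null(pixel_size)) points <- points * pixel_size[1L]
    d <- diff(points)
  }
  if (length(d) < 1L)
    stop("need at least 2 boundary points", call. = FALSE)
  if (any(d == 0))
    stop("duplicate consecutive points", call. = FALSE)
  ring_series(abs(d), label = label)
}

#' Read manual coordinate points from CSV
#'
#' Accepts the manual measurement workflow: a CSV with columns `x_mm`,
#' `y_mm` of coordinate points placed on consecutive ring boundaries.
#'
#' @param path CSV path.
#' @return A (k x 2) numeric matrix suitable for [measure_rings()].
#' @export
read_coordinate_points <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(df)))
    stop("coordinate CSV needs columns x_mm and y_mm", call. = FALSE)
  as.matrix(df[, c("x_mm", "y_mm")])
}
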