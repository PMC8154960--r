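#' Cone-beam acquisition geometry for line and circular trajectories
#'
#' World coordinates are right-handed with x pointing from the source towards
#' the detector, y the (horizontal) translation axis and z vertical; the
#' origin sits at the reconstruction volume centre. The "front" of the object
#' is its face of minimal x, i.e. the face closest to the source. For a
#' `"line"` trajectory the object translates along y between projections;
#' internally this is represented as the physically identical opposite
#' translation of the static source-detector pair. For a `"circle"`
#' trajectory the source-detector pair rotates about the vertical axis
#' through the origin.
#'
#' @param sod source-to-object-front distance (mm).
#' @param sdd source-to-detector distance (mm); must exceed `sod`.
#' @param detector_shape integer `(rows, cols)` of the flat detector.
#' @param pixel_pitch `(pitch_u, pitch_v)` detector pixel size in mm
#'   (u horizontal along y, v vertical along z); a scalar is recycled.
#' @param translations for `"line"`: strictly increasing object positions
#'   along y (mm), one per projection.
#' @param angles for `"circle"`: rotation angles in degrees, one per
#'   projection.
#' @param trajectory_kind `"line"` or `"circle"`.
#' @return An object of class `lt_geometry`.
#' @examples
#' g <- lt_geometry(sod = 500, sdd = 650, detector_shape = c(96, 192),
#'                  pixel_pitch = 1.07,
#'                  translations = translation_positions(c(-110, 110), 221))
#' cone_angle(g)
#' @export
lt_geometry <- function(sod, sdd, detector_shape, pixel_pitch,
                        translations = NULL, angles = NULL,
                        trajectory_kind = c("line", "circle")) {
  trajectory_kind <- match.arg(trajectory_kind)
  if (!(sod > 0 && sdd > sod))
    stop("need 0 < sod < sdd", call. = FALSE)
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 1L))
    stop("detector_shape must be (rows, cols), both >= 1", call. = FALSE)
  pixel_pitch <- rep(as.numeric(pixel_pitch), length.out = 2L)
  if (any(pixel_pitch <= 0)) stop("pixel_pitch must be > 0", call. = FALSE)
  if (trajectory_kind == "line") {
    if (is.null(translations) || length(translations) < 1L)
      stop("a line trajectory needs translation positions", call. = FALSE)
    translations <- as.numeric(translations)
    if (length(translations) > 1L && any(diff(translations) <= 0))
      stop("translations must be strictly increasing", call. = FALSE)
    angles <- NULL
  } else {
    if (is.null(angles) || length(angles) < 1L)
      stop("a circle trajectory needs rotation angles", call. = FALSE)
    angles <- as.numeric(angles)
    translations <- NULL
  }
  structure(list(sod = sod, sdd = sdd, detector_shape = detector_shape,
                 pixel_pitch = pixel_pitch, translations = translations,
                 angles = angles, trajectory_kind = trajectory_kind),
            class = "lt_geometry")
}

#' @export
print.lt_geometry <- function(x, ...) {
  np <- n_projections(x)
  cat(sprintf("%s-trajectory cone-beam geometry: SOD %.6g mm, SDD %.6g mm\n",
              x$trajectory_kind, x$sod, x$sdd))
  cat(sprintf("  detector %d x %d px, pitch %.6g x %.6g mm; %d projections\n",
              x$detector_shape[1], x$detector_shape[2],
              x$pixel_pitch[1], x$pixel_pitch[2], np))
  cat(sprintf("  cone angle %.3f deg, front magnification %.4f\n",
              cone_angle(x), magnification(x, 0)))
  invisible(x)
}

#' Number of projections described by a geometry
#' @param geom an [lt_geometry()].
#' @export
n_projections <- function(geom) {
  if (geom$trajectory_kind == "line") length(geom$translations)
  else length(geom$angles)
}

#' Cone (half-fan) angle of the beam
#'
#' The half-angle, in degrees, of the horizontal fan subtended by the
#' detector at the source: `atan((cols * pitch_u / 2) / sdd)`. Tree-ring tilt
#' is benign while it stays well below this angle, because some rays then
#' still run parallel to the ring surfaces.
#'
#' @param geom an [lt_geometry()].
#' @return Half-fan angle in degrees.
#' @export
cone_angle <- function(geom) {
  half <- geom$detector_shape[2L] * geom$pixel_pitch[1L] / 2
  atan(half / geom$sdd) * 180 / pi
}

#' Equally spaced translation positions
#'
#' @param range_mm `(low, high)` translation range in mm.
#' @param n_projections number of positions (>= 2); both endpoints are
#'   included.
#' @return Numeric vector of `n_projections` positions.
#' @examples
#' diff(translation_positions(c(-110, 110), 2201))[1]  # 0.1 mm
#' @export
translation_positions <- function(range_mm, n_projections) {
  if (length(range_mm) != 2L || !(range_mm[1] < range_mm[2]))
    stop("range_mm must be (low, high) with low < high", call. = FALSE)
  if (n_projections < 2L)
    stop("need at least 2 projections", call. = FALSE)
  seq(range_mm[1], range_mm[2], length.out = as.integer(n_projections))
}

#' Largest admissible translation step
#'
#' The sampling rule for a line-trajectory scan: between two consecutive
#' projections a point on the front face of the object should move by less
#' than one detector pixel on the detector. The front face is magnified by
#' `sdd / sod`, so the bound on the object step is `pitch_u * sod / sdd`.
#'
#' @param geom an [lt_geometry()].
#' @return The maximal object translation step in mm.
#' @export
max_translation_step <- function(geom) {
  geom$pixel_pitch[1L] * geom$sod / geom$sdd
}

#' @rdname max_translation_step
#' @return `satisfies_sampling_rule` returns `TRUE` when every actual step of
#'   the geometry's translation list stays strictly below the bound.
#' @export
satisfies_sampling_rule <- function(geom) {
  if (geom$trajectory_kind != "line" || length(geom$translations) < 2L)
    return(NA)
  all(diff(geom$translations) < max_translation_step(geom))
}

#' Magnification of a plane at given depth into the object
#'
#' @param geom an [lt_geometry()].
#' @param depth distance (mm) of the plane behind the object front face;
#'   `0` gives the front-face magnification `sdd / sod`.
#' @return `sdd / (sod + depth)`, strictly decreasing in depth.
#' @export
magnification <- function(geom, depth = 0) {
  if (any(depth < 0) || any(depth > geom$sdd - geom$sod))
    stop("depth must lie between the front face and the detector",
         call. = FALSE)
  geom$sdd / (geom$sod + depth)
}

# Per-projection source/detector frame in volume-fixed world coordinates.
# Line: object moves by +t  <=>  source & detector move by -t along y.
# Circle: source-detector pair rotates about z through the origin; the
# source-to-rotation-centre distance is sod + centre_depth (centre_depth =
# half the volume extent along x when projecting a centred volume).
# Returns matrices src, det (n x 3) and unit detector axes u, v (n x 3).
geometry_frames <- function(geom, centre_depth) {
  np <- n_projections(geom)
  if (geom$trajectory_kind == "line") {
    sx <- -(centre_depth + geom$sod)           # source x, volume centred at 0
    src <- cbind(sx, -geom$translations, 0)
    det <- cbind(sx + geom$sdd, -geom$translations, 0)
    u <- cbind(0, rep(1, np), 0)
    v <- cbind(0, 0, rep(1, np))
  } else {
    rs <- geom$sod + centre_depth              # source-to-centre distance
    a <- geom$angles * pi / 180
    # at angle 0 the source sits at (-rs, 0, 0) looking along +x
    dirx <- cos(a); diry <- sin(a)             # viewing direction
    src <- cbind(-rs * dirx, -rs * diry, 0)
    det <- src + (geom$sdd) * cbind(dirx, diry, 0)
    u <- cbind(-diry, dirx, 0)                 # horizontal detector axis
    v <- cbind(0, 0, rep(1, np))
  }
  list(src = src, det = det, u = u, v = v)
}

#' Write and read a geometry as a plain-text config block
#'
#' `key: value` lines, units mm and degrees; round-trips exactly.
#'
#' @param geom an [lt_geometry()].
#' @param path file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry` the
#'   reconstructed [lt_geometry()].
#' @export
write_geometry <- function(geom, path) {
  num <- function(v) paste(formatC(v, format = "g", digits = 17),
                           collapse = " ")
  lines <- c(
    paste0("trajectory_kind: ", geom$trajectory_kind),
    paste0("sod: ", num(geom$sod)),
    paste0("sdd: ", num(geom$sdd)),
    paste0("detector_shape: ", num(geom$detector_shape)),
    paste0("pixel_pitch: ", num(geom$pixel_pitch)))
  if (geom$trajectory_kind == "line")
    lines <- c(lines, paste0("translations: ", num(geom$translations)))
  else
    lines <- c(lines, paste0("angles: ", num(geom$angles)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines[nzchar(trimws(lines))]) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = ":"))
    kv[[key]] <- val
  }
  nums <- function(k) as.numeric(strsplit(kv[[k]], "\\s+")[[1L]])
  lt_geometry(sod = nums("sod"), sdd = nums("sdd"),
              detector_shape = nums("detector_shape"),
              pixel_pitch = nums("pixel_pitch"),
              translations = if (!is.null(kv$translations)) nums("translations"),
              angles = if (!is.null(kv$angles)) nums("angles"),
              trajectory_kind = kv$trajectory_kind)
}
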