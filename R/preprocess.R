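#' Flat- and dark-field correction of raw radiographs
#'
#' Converts raw detector counts to attenuation line integrals by
#' Beer-Lambert inversion:
#' \deqn{p = -\log\!\big(\max((I - D) / (F - D), \epsilon)\big)}
#' where `I` are the raw counts, `F` the flat (full beam, no object) and `D`
#' the dark (no beam) reference frame. Pixels where the transmitted fraction
#' is non-positive (dead pixels, `F == D`) are floored at `epsilon` so the
#' output stays finite.
#'
#' @param raw raw counts: matrix, 3D array, or raw-kind
#'   [projection_stack()].
#' @param flat,dark reference frames (matrices of detector shape); taken
#'   from the stack if present.
#' @param epsilon transmission floor (default 1e-6), applied before the log.
#' @return Corrected line integrals with the input's shape; for a stack
#'   input, a corrected-kind [projection_stack()].
#' @export
flatdark_correct <- function(raw, flat = NULL, dark = NULL, epsilon = 1e-6) {
  if (inherits(raw, "projection_stack")) {
    out <- flatdark_correct(raw$data, flat %||% raw$flats,
                            dark %||% raw$darks, epsilon)
    return(projection_stack(out, raw$geometry, kind = "corrected"))
  }
  if (is.null(flat) || is.null(dark))
    stop("flat and dark frames are required", call. = FALSE)
  dn <- if (is.matrix(raw)) dim(raw) else dim(raw)[1:2]
  if (!all(dim(flat) == dn) || !all(dim(dark) == dn))
    stop("raw, flat and dark frames must share the detector shape",
         call. = FALSE)
  denom <- flat - dark
  if (mean(denom) <= 0)
    stop("flat frame is not brighter than dark on average", call. = FALSE)
  denom[denom <= 0] <- NA          # dead pixels -> transmission floor below
  tr <- sweep2(raw, dark, `-`)
  tr <- sweep2(tr, denom, `/`)
  tr[is.na(tr) | tr < epsilon] <- epsilon
  -log(tr)
}

# apply a frame-wise binary op between an array/matrix and one 2D frame
sweep2 <- function(x, frame, op) {
  if (is.matrix(x)) return(op(x, frame))
  array(op(as.numeric(x), rep(as.numeric(frame), dim(x)[3L])), dim = dim(x))
}

#' Estimate magnification and per-projection translation from a nail ruler
#'
#' For scans on uncalibrated setups a "ruler" — a lath with metal nails at a
#' known regular spacing — is placed against the object front and scanned
#' along with it. The nails are the most attenuating features in a
#' designated detector row band; their projected spacing gives the front
#' magnification, and the shift of the nail profile between consecutive
#' projections (1D cross-correlation, parabolic sub-pixel refinement) gives
#' the object translation between frames.
#'
#' @param projections corrected-kind [projection_stack()] or 3D array of
#'   line integrals (nails bright/high-attenuation).
#' @param nail_spacing physical spacing of the nails in mm (default 10, i.e.
#'   one nail every centimetre).
#' @param row_band integer range of detector rows containing the ruler;
#'   default the central fifth of the detector.
#' @param pixel_pitch horizontal detector pitch in mm; taken from the
#'   stack's geometry if present.
#' @return List with `magnification`, `translations_mm` (cumulative object
#'   position per projection, first = 0), `shifts_px` (per-pair detector
#'   shift), and `nail_positions_px` (detected nail peaks, first frame).
#' @export
estimate_geometry_from_ruler <- function(projections, nail_spacing = 10,
                                         row_band = NULL, pixel_pitch = NULL) {
  if (inherits(projections, "projection_stack")) {
    if (is.null(pixel_pitch)) pixel_pitch <- projections$geometry$pixel_pitch[1L]
    projections <- projections$data
  }
  if (is.null(pixel_pitch))
    stop("pixel_pitch is required when no geometry is attached", call. = FALSE)
  stopifnot(length(dim(projections)) == 3L)
  nr <- dim(projections)[1L]
  if (is.null(row_band))
    row_band <- seq(max(1L, round(nr * 0.4)), min(nr, round(nr * 0.6)))
  # attenuation profile across columns: maximum over the ruler band
  prof <- function(k) apply(projections[row_band, , k, drop = FALSE], 2, max)
  p1 <- prof(1L)
  peaks <- nail_peaks(p1)
  if (length(peaks) < 2L)
    stop("ruler not detected: fewer than 2 nails found in the row band",
         call. = FALSE)
  magnification <- mean(diff(peaks)) * pixel_pitch / nail_spacing
  np <- dim(projections)[3L]
  shifts <- numeric(max(np - 1L, 0L))
  if (np > 1L) {
    prev <- p1
    for (k in seq(2L, np)) {
      cur <- prof(k)
      shifts[k - 1L] <- profile_shift(prev, cur)
      prev <- cur
    }
  }
  trans <- c(0, cumsum(shifts)) * pixel_pitch / magnification
  list(magnification = magnification, translations_mm = trans,
       shifts_px = shifts, nail_positions_px = peaks)
}

# nail detection: local maxima of the attenuation profile above
# median + 3 * MAD (nails attenuate most, so appear as high peaks in p)
nail_peaks <- function(p) {
  thr <- stats::median(p) + 3 * stats::mad(p)
  n <- length(p)
  idx <- which(p > thr)
  idx <- idx[idx > 1L & idx < n]
  idx[p[idx] >= p[idx - 1L] & p[idx] >= p[idx + 1L]]
}

# sub-pixel shift of profile b relative to a via cross-correlation with
# parabolic interpolation around the integer peak
profile_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- seq(-(n - 1L), n - 1L)
  cc <- vapply(lags, function(l) {
    ia <- seq(max(1L, 1L + l), min(n, n + l))
    sum(b[ia] * a[ia - l])
  }, numeric(1))
  k <- which.max(cc)
  s <- lags[k]
  if (k > 1L && k < length(cc)) {
    y1 <- cc[k - 1L]; y2 <- cc[k]; y3 <- cc[k + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) s <- s + 0.5 * (y1 - y3) / den
  }
  s
}
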