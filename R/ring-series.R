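#' Ring-width series
#'
#' Construct a `ring_series` object: an ordered sequence of annual ring widths
#' in millimetres, measured from pith towards bark. This is the fundamental
#' object of dendrochronological analysis; crossdating operates on pairs of
#' these.
#'
#' @param widths numeric vector of strictly positive ring widths in mm,
#'   ordered pith to bark.
#' @param label free-text identifier (at most 8 characters are kept when
#'   writing Tucson RWL files).
#' @param first_index integer relative year assigned to the first ring.
#' @return An object of class `ring_series`: a numeric vector with attributes
#'   `label` and `first_index`.
#' @examples
#' rs <- ring_series(c(1.2, 0.8, 1.5), label = "DEMO")
#' total_extent(rs)
#' @export
ring_series <- function(widths, label = "series", first_index = 0L) {
  widths <- as.numeric(widths)
  if (length(widths) < 1L)
    stop("a ring series needs at least one ring", call. = FALSE)
  if (anyNA(widths) || any(widths <= 0))
    stop("all ring widths must be positive and non-missing", call. = FALSE)
  structure(widths,
            label = as.character(label)[1L],
            first_index = as.integer(first_index)[1L],
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("Ring-width series '%s': %d rings, first index %d\n",
              attr(x, "label"), length(x), attr(x, "first_index")))
  cat(sprintf("  widths (mm): mean %.3f, range [%.3f, %.3f], total %.3f\n",
              mean(x), min(x), max(x), sum(x)))
  invisible(x)
}

#' Total radial extent of a ring series
#'
#' @param x a [ring_series()].
#' @return Sum of the ring widths (mm) — the radial distance from the pith to
#'   the outer boundary of the last ring.
#' @export
total_extent <- function(x) sum(as.numeric(x))

#' Generate a synthetic ring-width series
#'
#' Widths are drawn from a lognormal distribution parameterised by its
#' arithmetic mean and coefficient of variation, then floored at 0.05 mm
#' (narrower rings are not resolvable by the imaging chain and rarely occur
#' in real wood). `variability = 0` returns constant widths.
#'
#' @param n_rings number of rings (>= 1).
#' @param mean_width target arithmetic mean width in mm (> 0).
#' @param variability coefficient of variation of the width distribution
#'   (>= 0); typical measured series fall around 0.2-0.4.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param label passed to [ring_series()].
#' @return A [ring_series()] of length `n_rings`.
#' @examples
#' generate_ring_series(10, mean_width = 1.5, variability = 0.3, seed = 1)
#' @export
generate_ring_series <- function(n_rings, mean_width, variability = 0.3,
                                 seed = 1L, label = "synth") {
  if (length(n_rings) != 1L || is.na(n_rings) || n_rings < 1)
    stop("n_rings must be a positive count", call. = FALSE)
  if (length(mean_width) != 1L || is.na(mean_width) || mean_width <= 0)
    stop("mean_width must be positive", call. = FALSE)
  if (variability < 0)
    stop("variability must be >= 0", call. = FALSE)
  n_rings <- as.integer(n_rings)
  if (variability == 0) {
    w <- rep(mean_width, n_rings)
  } else {
    # lognormal with arithmetic mean m and CV v:
    # sdlog^2 = log(1 + v^2), meanlog = log(m) - sdlog^2 / 2
    s2 <- log(1 + variability^2)
    w <- with_seed(seed, rlnorm(n_rings, meanlog = log(mean_width) - s2 / 2,
                                sdlog = sqrt(s2)))
    w <- pmax(w, 0.05)
  }
  ring_series(w, label = label)
}

#' Element-wise average of aligned ring series
#'
#' Used to average repeated measurements of the same sample (e.g. the same
#' path measured on several nearby reconstruction slices). Alignment is the
#' caller's responsibility; all series must have equal length.
#'
#' @param series a list of [ring_series()] (or numeric vectors) of equal
#'   length.
#' @param label label of the returned series.
#' @return A [ring_series()] of element-wise arithmetic means.
#' @export
average_series <- function(series, label = "mean") {
  if (!is.list(series) || length(series) < 1L)
    stop("series must be a non-empty list", call. = FALSE)
  n <- lengths(series)
  if (length(unique(n)) != 1L)
    stop("all series must have the same length; align them first",
         call. = FALSE)
  m <- rowMeans(do.call(cbind, lapply(series, as.numeric)))
  ring_series(m, label = label,
              first_index = attr(series[[1L]], "first_index") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Read and write ring-width series as CSV
#'
#' Two-column CSV (`index`, `width_mm`); round-trips exactly because widths
#' are written with full precision.
#'
#' @param x a [ring_series()].
#' @param path file path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a [ring_series()].
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "ring_series"))
  df <- data.frame(index = attr(x, "first_index") + seq_along(x) - 1L,
                   width_mm = formatC(as.numeric(x), format = "g",
                                      digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param label label for the series read back.
#' @export
read_series_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, colClasses = c("integer", "character"))
  ring_series(as.numeric(df$width_mm), label = label,
              first_index = df$index[1L])
}

#' Read and write Tucson (decadal RWL) ring-width files
#'
#' The Tucson format is the standard interchange format of the ITRDB: one row
#' per decade, an 8-character series identifier, the decade start year, then
#' up to ten widths in units of 0.01 mm, with the value `999` terminating the
#' series. Width values round-trip exactly at 0.01 mm resolution.
#'
#' @param x a [ring_series()]; widths are stored to the nearest 0.01 mm.
#' @param path file path.
#' @return `write_rwl` returns `path` invisibly; `read_rwl` returns a list of
#'   [ring_series()], one per series identifier found.
#' @export
write_rwl <- function(x, path) {
  stopifnot(inherits(x, "ring_series"))
  id <- substr(gsub("[^A-Za-z0-9_-]", "", attr(x, "label")), 1L, 8L)
  if (nchar(id) == 0L) id <- "SERIES"
  vals <- as.integer(round(as.numeric(x) * 100))
  yrs <- attr(x, "first_index") + seq_along(vals) - 1L
  vals <- c(vals, 999L)              # end-of-series marker
  yrs <- c(yrs, yrs[length(yrs)] + 1L)
  lines <- character(0)
  i <- 1L
  while (i <= length(vals)) {
    yr <- yrs[i]
    dec_end <- (yr %/% 10L) * 10L + 9L   # last year of this decade row
    j <- i
    while (j < length(vals) && yrs[j + 1L] <= dec_end) j <- j + 1L
    lines <- c(lines, paste0(formatC(id, width = -8L), formatC(yr, width = 4L),
                             paste(formatC(vals[i:j], width = 6L),
                                   collapse = "")))
    i <- j + 1L
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rwl
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- trimws(substr(lines, 1L, 8L))
  out <- list()
  for (id in unique(ids)) {
    vals <- integer(0); first <- NA_integer_
    for (ln in lines[ids == id]) {
      yr <- as.integer(substr(ln, 9L, 12L))
      if (is.na(first)) first <- yr
      body <- substr(ln, 13L, nchar(ln))
      v <- as.integer(strsplit(trimws(body), "\\s+")[[1L]])
      vals <- c(vals, v)
    }
    if (length(vals) && vals[length(vals)] == 999L)
      vals <- vals[-length(vals)]
    out[[id]] <- ring_series(vals / 100, label = id, first_index = first)
  }
  out
}
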