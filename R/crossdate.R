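#' Baillie-Pilcher normalization of a ring-width series
#'
#' Each width is divided by a centred five-term running mean of the series
#' and the ratio is log-transformed. This removes the low-frequency growth
#' trend so that the year-to-year signal dominates the correlation used by
#' the [tbp()] statistic. At the series edges the window shrinks
#' symmetrically; where a symmetric window would contain fewer than three
#' values (the outermost ring at each end) the nearest three values are used.
#'
#' @param x a [ring_series()] or numeric vector of positive widths,
#'   length >= 5.
#' @return Numeric vector of the same length: `log(width / running_mean)`.
#'   A constant series maps to all zeros, and the output is invariant under
#'   global scaling of the input.
#' @examples
#' bp_normalize(c(1, 1, 1, 1, 2, 1, 1, 1, 1))[5]  # log(2 / 1.2)
#' @export
bp_normalize <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 5L)
    stop("Baillie-Pilcher normalization needs at least 5 rings", call. = FALSE)
  if (anyNA(x) || any(x <= 0))
    stop("ring widths must be positive for BP normalization", call. = FALSE)
  rm5 <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(2L, i - 1L, n - i)
    lo <- i - h; hi <- i + h
    if (hi - lo + 1L < 3L) {           # outermost indices: nearest 3 values
      if (i == 1L) { lo <- 1L; hi <- 3L } else { lo <- n - 2L; hi <- n }
    }
    rm5[i] <- mean(x[lo:hi])
  }
  log(x / rm5)
}

#' Baillie-Pilcher t-value between two aligned ring-width series
#'
#' Both series are BP-normalized ([bp_normalize()]), their Pearson
#' correlation r is computed, and the t-statistic
#' \deqn{t = r \sqrt{n - 2} / \sqrt{1 - r^2}}
#' is returned. The statistic diverges as r approaches 1, so it is capped:
#' identical series return exactly `cap` (default 100). In dendrochronological
#' practice TBP above roughly 5 at a unique offset indicates a date, and two
#' measurements of the same sample are expected to give TBP > 10.
#'
#' @param x,y equal-length series (>= 5 rings).
#' @param cap value returned when the raw t exceeds it or r = 1.
#' @return The (capped) t-value.
#' @export
tbp <- function(x, y, cap = 100) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("series must be aligned to equal length", call. = FALSE)
  n <- length(x)
  bx <- bp_normalize(x); by <- bp_normalize(y)
  if (stats::sd(bx) == 0 || stats::sd(by) == 0)
    stop("degenerate series: zero variance after BP normalization",
         call. = FALSE)
  r <- stats::cor(bx, by)
  if (r >= 1) return(cap)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  min(t, cap)
}

#' Gleichlaeufigkeit (percentage of parallel variation)
#'
#' Non-parametric synchronicity measure: the percentage of year-to-year
#' intervals in which the two series move in the same direction. Each of the
#' n - 1 first-difference pairs scores 1 when both differences share a strict
#' sign (or are both zero), 1/2 when exactly one difference is zero, and 0
#' when the signs oppose. Under the null of independent series the score mean
#' is 0.5 with variance 1/(4(n-1)), giving the normal deviate `z` and the
#' one-sided upper-tail p-value.
#'
#' @param x,y equal-length series (n >= 2).
#' @return A list with `gl` (percentage in [0, 100]), `z`, and `p`.
#' @examples
#' s <- c(1, 2, 1.5, 3, 2)
#' gleichlaufigkeit(s, s)$gl  # 100
#' @export
gleichlaufigkeit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("series must be aligned to equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L)
    stop("Gleichlaeufigkeit needs at least 2 rings", call. = FALSE)
  dx <- sign(diff(x)); dy <- sign(diff(y))
  score <- ifelse(dx == dy, 1, ifelse(dx == 0 | dy == 0, 0.5, 0))
  gl <- 100 * mean(score)
  z <- (gl / 100 - 0.5) * 2 * sqrt(n - 1)
  list(gl = gl, z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Mean inter-series correlation (rbar)
#'
#' Arithmetic mean of the pairwise Pearson correlations of the BP-normalized
#' series; reported alongside TBP and Gl when several measurements of the
#' same sample are compared.
#'
#' @param series list of >= 2 equal-length, aligned series.
#' @return Mean pairwise correlation.
#' @export
rbar <- function(series) {
  if (!is.list(series) || length(series) < 2L)
    stop("rbar needs at least two series", call. = FALSE)
  if (length(unique(lengths(series))) != 1L)
    stop("series must be aligned to equal length", call. = FALSE)
  b <- lapply(series, bp_normalize)
  k <- length(b)
  rs <- c()
  for (i in seq_len(k - 1L))
    for (j in seq((i + 1L), k))
      rs <- c(rs, stats::cor(b[[i]], b[[j]]))
  mean(rs)
}

#' Sliding-offset crossdating of a sample against a reference
#'
#' The sample series is slid along the reference; at every integer offset
#' with at least `min_overlap` overlapping rings the overlapping segments are
#' compared with [tbp()] and [gleichlaufigkeit()]. Offsets are ranked by TBP
#' (descending), with ties broken by Gl and then by longer overlap. The
#' top-ranked offset of a correct crossdate should clearly dominate the
#' table; following dendrochronological reporting convention, `###` flags
#' Gl p < 0.0001.
#'
#' @param sample,reference [ring_series()] or numeric width vectors.
#' @param min_overlap minimum number of overlapping rings per offset
#'   (default 30, and never below 5, the BP window requirement).
#' @return A data frame of class `crossdate_result` with columns `offset`
#'   (position of the sample's first ring relative to the reference's first
#'   ring), `n_overlap`, `r`, `tbp`, `gl`, `gl_z`, `gl_p`, `marker`.
#' @examples
#' ref <- generate_ring_series(80, 1.5, 0.3, seed = 2)
#' smp <- ring_series(as.numeric(ref)[21:60])
#' head(crossdate_sliding(smp, ref), 3)
#' @export
crossdate_sliding <- function(sample, reference, min_overlap = 30L) {
  s <- as.numeric(sample); r <- as.numeric(reference)
  min_overlap <- max(5L, as.integer(min_overlap))
  ns <- length(s); nr <- length(r)
  if (ns < min_overlap || nr < min_overlap)
    stop("both series must be at least min_overlap rings long", call. = FALSE)
  offs <- seq(-(ns - min_overlap), nr - min_overlap)
  rows <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    o <- offs[k]
    i1 <- max(1L, 1L - o); i2 <- min(ns, nr - o)   # sample index range
    n <- i2 - i1 + 1L
    if (n < min_overlap) next
    xs <- s[i1:i2]; ys <- r[(i1 + o):(i2 + o)]
    bx <- bp_normalize(xs); by <- bp_normalize(ys)
    if (stats::sd(bx) == 0 || stats::sd(by) == 0) next
    rc <- stats::cor(bx, by)
    t <- if (rc >= 1) 100 else min(rc * sqrt(n - 2) / sqrt(1 - rc^2), 100)
    g <- gleichlaufigkeit(xs, ys)
    rows[[k]] <- data.frame(offset = o, n_overlap = n, r = rc, tbp = t,
                            gl = g$gl, gl_z = g$z, gl_p = g$p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(offset = integer(0), n_overlap = integer(0),
                      r = numeric(0), tbp = numeric(0), gl = numeric(0),
                      gl_z = numeric(0), gl_p = numeric(0))
  }
  out <- out[order(-out$tbp, -out$gl, -out$n_overlap), , drop = FALSE]
  rownames(out) <- NULL
  out$marker <- ifelse(out$gl_p < 1e-4, "###", "")
  class(out) <- c("crossdate_result", "data.frame")
  out
}

#' @export
print.crossdate_result <- function(x, n = 10L, ...) {
  cat(sprintf("Crossdating table: %d admissible offsets (top %d shown)\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
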