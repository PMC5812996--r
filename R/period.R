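#' Extract an averaged line profile from an image
#'
#' Samples intensities by bilinear interpolation at pixel-size steps along
#' a line, averaging over `avg_width_px` parallel lines offset
#' perpendicularly at pixel-size spacing and centred on the given line
#' (3-pixel averaging by default, the usual practice when tracing ring
#' profiles).
#'
#' @param image a [sted_image()].
#' @param line numeric vector `c(x0, y0, x1, y1)` of endpoints in nm
#'   (x along columns, y along rows, measured from the top-left pixel
#'   centre).
#' @param avg_width_px number of parallel lines averaged (odd; default 3).
#' @return numeric profile; sample `i` lies `(i - 1) * pixel_size_nm` from
#'   the first endpoint. Sample count is `floor(L / pixel) + 1`.
#' @export
extract_profile <- function(image, line, avg_width_px = 3) {
  stopifnot(inherits(image, "sted_image"), length(line) == 4)
  p <- image$pixel_size_nm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  xmax <- (nc - 1) * p; ymax <- (nr - 1) * p
  if (line[1] < 0 || line[1] > xmax || line[3] < 0 || line[3] > xmax ||
      line[2] < 0 || line[2] > ymax || line[4] < 0 || line[4] > ymax)
    stop("line endpoint outside the image", call. = FALSE)
  d <- c(line[3] - line[1], line[4] - line[2])
  L <- sqrt(sum(d^2))
  if (L == 0) stop("degenerate line (zero length)", call. = FALSE)
  u <- d / L
  perp <- c(-u[2], u[1])
  s <- seq(0, floor(L / p) * p, by = p)
  offs <- (seq_len(avg_width_px) - (avg_width_px + 1) / 2) * p
  acc <- numeric(length(s))
  for (o in offs) {
    x <- line[1] + s * u[1] + o * perp[1]
    y <- line[2] + s * u[2] + o * perp[2]
    acc <- acc + bilinear_sample(image$pixels, x / p, y / p)
  }
  acc / avg_width_px
}

# Bilinear interpolation at fractional 0-based (col, row) coordinates,
# clamped to the image border.
bilinear_sample <- function(px, cf, rf) {
  nr <- nrow(px); nc <- ncol(px)
  cf <- pmin(pmax(cf, 0), nc - 1)
  rf <- pmin(pmax(rf, 0), nr - 1)
  c0 <- pmin(floor(cf), nc - 2); r0 <- pmin(floor(rf), nr - 2)
  dc <- cf - c0; dr <- rf - r0
  i00 <- (r0 + 1) + nr * c0
  px[i00] * (1 - dr) * (1 - dc) + px[i00 + 1] * dr * (1 - dc) +
    px[i00 + nr] * (1 - dr) * dc + px[i00 + nr + 1] * dr * dc
}

#' Find peaks in a 1D profile
#'
#' Local maxima filtered by prominence (relative to the profile's dynamic
#' range) and minimum mutual separation; when two candidates are closer
#' than `min_separation_nm`, the higher one survives. A plateau of equal
#' values that is strictly higher than its surroundings counts as one peak
#' at its centre (a peak landing exactly halfway between two samples
#' produces such a two-sample plateau).
#'
#' @param profile numeric vector (length >= 3).
#' @param min_prominence_frac minimum prominence as a fraction of
#'   `max(profile) - min(profile)` (default 0.10).
#' @param min_separation_nm minimum peak-to-peak distance, nm
#'   (default 100).
#' @param pixel_size_nm sampling step, nm.
#' @return integer vector of 1-based peak indices, ascending.
#' @export
find_peaks <- function(profile, min_prominence_frac = 0.10,
                       min_separation_nm = 100, pixel_size_nm = 20) {
  n <- length(profile)
  if (n < 3) return(integer(0))
  v <- as.numeric(profile)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer(0)
  if (nr >= 3) {
    j <- 2:(nr - 1)
    is_pk <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    cand <- ((starts[j] + ends[j]) %/% 2L)[is_pk]
  }
  if (!length(cand)) return(integer(0))
  rng <- diff(range(v))
  if (rng == 0) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(integer(0))
  # greedy separation filter, highest first
  min_sep_px <- min_separation_nm / pixel_size_nm
  keep <- integer(0)
  for (i in cand[order(v[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep_px))
      keep <- c(keep, i)
  }
  sort(keep)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two lowest points separating it from higher terrain (or
# the profile ends).
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i > 1) v[1:(i - 1)] else numeric(0)
  right <- if (i < n) v[(i + 1):n] else numeric(0)
  hi_l <- which(left > v[i])
  base_l <- if (length(hi_l)) min(v[(max(hi_l)):(i - 1)]) else min(c(left, v[i]))
  hi_r <- which(right > v[i])
  base_r <- if (length(hi_r)) min(v[(i + 1):(i + min(hi_r) - 1 + 1)]) else
    min(c(right, v[i]))
  v[i] - max(base_l, base_r)
}

# Sub-pixel peak positions (nm) by quadratic refinement around each
# detected local maximum. Shared by segment_period() and count_periods().
refine_peak_positions <- function(profile, pixel_size_nm,
                                  min_prominence_frac = 0.10,
                                  min_separation_nm = 100,
                                  fit_halfwidth_px = 2) {
  pk <- find_peaks(profile, min_prominence_frac, min_separation_nm,
                   pixel_size_nm)
  n <- length(profile)
  # keep the fit window inside the quadratic-like core of a peak (~2 sigma
  # of a 25 nm ring at coarse sampling): beyond that the Gaussian tails
  # bias the parabola vertex
  hw <- max(1L, min(fit_halfwidth_px, floor(50 / pixel_size_nm)))
  pos <- vapply(pk, function(i) {
    i0 <- max(1, i - hw)
    i1 <- min(n, i + hw)
    idx <- i0:i1
    if (length(idx) < 3) return(NA_real_)
    co <- stats::lm.fit(cbind(1, idx, idx^2), profile[idx])$coefficients
    a <- co[3]; b <- co[2]
    if (!is.finite(a) || a >= 0) return(NA_real_)
    vx <- -b / (2 * a)
    if (abs(vx - i) > 1) return(NA_real_)  # flat-top / fit failure guard
    (vx - 1) * pixel_size_nm
  }, numeric(1))
  sort(pos[is.finite(pos)])
}

#' Estimate the period of one profile by quadratic peak refinement
#'
#' Each local maximum is refined to sub-pixel precision by a least-squares
#' quadratic fit over `fit_halfwidth_px` points on each side; the vertex
#' positions are converted to nm and the mean consecutive difference is
#' the segment's characteristic period. A refined vertex falling more than
#' one pixel from its integer maximum is rejected as a fit failure. The
#' estimate is flagged valid when the peak count lies within
#' `[min_peaks, max_peaks]` (default 4-7, i.e. a profile crossing about
#' 4-5 consecutive rings).
#'
#' @param profile numeric intensity profile.
#' @param pixel_size_nm sampling step, nm.
#' @param fit_halfwidth_px points on each side of a maximum used in the
#'   quadratic fit (default 2: a 5-point fit). The window is additionally
#'   capped at 50 nm per side so that coarse sampling never pushes the fit
#'   into the peak tails, where a parabola is a poor model.
#' @param min_peaks,max_peaks accepted peak-count range for `valid`.
#' @param min_prominence_frac,min_separation_nm passed to [find_peaks()].
#' @return list of class `period_estimate`: `peak_positions_nm`,
#'   `n_peaks`, `mean_period_nm`, `valid`.
#' @export
segment_period <- function(profile, pixel_size_nm, fit_halfwidth_px = 2,
                           min_peaks = 4, max_peaks = 7,
                           min_prominence_frac = 0.10,
                           min_separation_nm = 100) {
  pos <- refine_peak_positions(profile, pixel_size_nm,
                               min_prominence_frac, min_separation_nm,
                               fit_halfwidth_px)
  if (length(pos) < 2)
    stop("fewer than 2 peaks found; cannot estimate a period", call. = FALSE)
  structure(
    list(peak_positions_nm = pos,
         n_peaks = length(pos),
         mean_period_nm = mean(diff(pos)),
         valid = length(pos) >= min_peaks && length(pos) <= max_peaks),
    class = "period_estimate"
  )
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("period_estimate: %d peaks, mean period %.1f nm (%s)\n",
              x$n_peaks, x$mean_period_nm,
              if (x$valid) "valid" else "outside accepted peak-count range"))
  invisible(x)
}

#' Pool per-segment periods into a condition-level estimate
#'
#' @param estimates list of valid `period_estimate` objects (or a numeric
#'   vector of mean periods).
#' @param min_n segment count considered sufficient (default 15).
#' @return list with `mean_nm`, `sd_nm`, `n`, `sufficient`.
#' @export
condition_period <- function(estimates, min_n = 15) {
  if (is.numeric(estimates)) {
    periods <- estimates
  } else {
    ok <- vapply(estimates, function(e) inherits(e, "period_estimate"),
                 logical(1))
    if (!all(ok)) stop("all inputs must be period estimates", call. = FALSE)
    if (!all(vapply(estimates, `[[`, logical(1), "valid")))
      stop("all period estimates must be valid (4-7 peaks)", call. = FALSE)
    periods <- vapply(estimates, `[[`, numeric(1), "mean_period_nm")
  }
  if (length(periods) == 0)
    stop("no period estimates supplied", call. = FALSE)
  list(mean_nm = mean(periods),
       sd_nm = if (length(periods) > 1) stats::sd(periods) else 0,
       n = length(periods),
       sufficient = length(periods) >= min_n)
}
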