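#' Configuration of the modeled MPS pattern and its search grid
#'
#' The membrane-associated periodic skeleton (MPS) is modeled as a 1D comb
#' of Gaussian peaks spaced `spacing_nm` apart along the axon axis,
#' constant transversely. Scoring maximizes the Pearson correlation of a
#' segment with this model over a grid of lattice phases and orientation
#' offsets about the detected axon angle.
#'
#' @param spacing_nm lattice period of the model (default 190 nm).
#' @param peak_sigma_nm Gaussian sigma of a model peak (default 25 nm,
#'   matching ring width at STED resolution).
#' @param segment_um scoring window edge (default 1 um).
#' @param phase_step_nm phase-search step; `NULL` (default) uses half the
#'   image pixel size (at full-pixel steps a worst-case half-step phase
#'   miss already costs a few percent of correlation, more than the
#'   fine-grid agreement we aim for).
#' @param orientation_halfrange_deg half-range of the orientation search
#'   about the segment orientation (default 15).
#' @param orientation_step_deg orientation search step (default 1.5; at
#'   coarser steps a worst-case half-step tilt misaligns the lattice by
#'   more than the fine-grid agreement we aim for across a 1 um window).
#' @return list of class `pattern_config`.
#' @export
pattern_config <- function(spacing_nm = 190, peak_sigma_nm = 25,
                           segment_um = 1, phase_step_nm = NULL,
                           orientation_halfrange_deg = 15,
                           orientation_step_deg = 1.5) {
  assert_scalar_num(spacing_nm, "spacing_nm", 0, strict_lower = TRUE)
  assert_scalar_num(peak_sigma_nm, "peak_sigma_nm", 0, strict_lower = TRUE)
  if (!is.null(phase_step_nm)) {
    assert_scalar_num(phase_step_nm, "phase_step_nm", 0, strict_lower = TRUE)
    if (phase_step_nm > spacing_nm)
      stop("`phase_step_nm` must be <= spacing_nm", call. = FALSE)
  }
  structure(list(spacing_nm = spacing_nm, peak_sigma_nm = peak_sigma_nm,
                 segment_um = segment_um, phase_step_nm = phase_step_nm,
                 orientation_halfrange_deg = orientation_halfrange_deg,
                 orientation_step_deg = orientation_step_deg),
            class = "pattern_config")
}

# Along-axis coordinate (nm) of every pixel centre of a size_px x size_px
# patch, for an axis at `orientation_deg` (x = columns, y = rows down).
patch_axis_coord <- function(size_px, pixel_size_nm, orientation_deg) {
  th <- orientation_deg * pi / 180
  x <- matrix(rep(0:(size_px - 1), each = size_px), size_px) * pixel_size_nm
  y <- matrix(rep(0:(size_px - 1), size_px), size_px) * pixel_size_nm
  x * cos(th) + y * sin(th)
}

# Periodic Gaussian-comb response at along-axis coordinate t: wrapped sum
# over the two nearest peaks on each side (peaks two or more periods away
# contribute < exp(-spacing^2 / 2 sigma^2) and are dropped).
comb_response <- function(t, phase_nm, spacing_nm, sigma_nm) {
  r <- (t - phase_nm) %% spacing_nm
  s2 <- 2 * sigma_nm^2
  exp(-r^2 / s2) + exp(-(spacing_nm - r)^2 / s2) +
    exp(-(spacing_nm + r)^2 / s2) + exp(-(2 * spacing_nm - r)^2 / s2)
}

#' Build a standardized modeled-MPS patch
#'
#' Renders the Gaussian-comb lattice model into a square patch: peaks at
#' `phase_nm + k * spacing_nm` along the axis at `orientation_deg`,
#' constant transversely, standardized to zero mean and unit variance over
#' the patch.
#'
#' @param cfg a [pattern_config()].
#' @param pixel_size_nm sampling of the target image, nm.
#' @param orientation_deg axis angle of the model, degrees.
#' @param phase_nm lattice phase offset along the axis, nm.
#' @return numeric matrix (`round(segment_um * 1000 / pixel_size_nm)`
#'   pixels on a side) with mean 0 and variance 1.
#' @export
build_mps_model <- function(cfg, pixel_size_nm, orientation_deg = 0,
                            phase_nm = 0) {
  stopifnot(inherits(cfg, "pattern_config"))
  size_px <- round(cfg$segment_um * 1000 / pixel_size_nm)
  if (cfg$segment_um * 1000 < 2 * cfg$spacing_nm)
    stop("window must hold at least two lattice periods", call. = FALSE)
  t <- patch_axis_coord(size_px, pixel_size_nm, orientation_deg)
  m <- comb_response(t, phase_nm, cfg$spacing_nm, cfg$peak_sigma_nm)
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0)
    stop("degenerate model patch (zero variance)", call. = FALSE)
  (m - mean(m)) / s
}

#' Score one segment against the modeled MPS lattice
#'
#' Computes the maximal Pearson correlation between the segment's pixel
#' patch and the modeled lattice over all phases in `[0, spacing)` (step
#' `phase_step_nm`, default the pixel size) and orientation offsets within
#' `+/- orientation_halfrange_deg` (step `orientation_step_deg`) of the
#' segment's orientation. Ties are broken toward the smallest phase, then
#' the smallest absolute offset. Zero-variance (constant) patches score 0
#' with the `degenerate` flag set.
#'
#' @param image a [sted_image()].
#' @param segment one-row data.frame (or list) with `row`, `col`,
#'   `size_px`, `orientation_deg` as produced by [tile_segments()].
#' @param cfg a [pattern_config()].
#' @return list with `correlation`, `best_phase_nm`,
#'   `best_orientation_offset_deg`, `degenerate`.
#' @export
score_segment <- function(image, segment, cfg = pattern_config()) {
  stopifnot(inherits(image, "sted_image"))
  p <- image$pixel_size_nm
  r0 <- segment$row; c0 <- segment$col; size_px <- segment$size_px
  if (r0 < 0 || c0 < 0 || r0 + size_px > nrow(image$pixels) ||
      c0 + size_px > ncol(image$pixels))
    stop("segment out of image bounds", call. = FALSE)
  patch <- image$pixels[(r0 + 1):(r0 + size_px), (c0 + 1):(c0 + size_px)]
  v <- as.vector(patch)
  if (stats::sd(v) == 0)
    return(list(correlation = 0, best_phase_nm = NA_real_,
                best_orientation_offset_deg = NA_real_, degenerate = TRUE))
  phase_step <- cfg$phase_step_nm %||% (p / 4)
  phases <- seq(0, cfg$spacing_nm - 1e-9, by = phase_step)
  offs <- seq(-cfg$orientation_halfrange_deg, cfg$orientation_halfrange_deg,
              by = cfg$orientation_step_deg)
  offs <- offs[order(abs(offs), offs)]
  # phase shifts only translate the comb, so one periodic lookup table per
  # orientation serves every phase (0.25 nm table; the comb slope bounds
  # the lookup error at ~3e-3, negligible after standardization)
  tbl_step <- 0.25
  ng <- round(cfg$spacing_nm / tbl_step)
  G <- comb_response(seq(0, by = tbl_step, length.out = ng), 0,
                     cfg$spacing_nm, cfg$peak_sigma_nm)
  G2 <- c(G, G)  # doubled table: shifted indices need no modulo
  ph_idx <- round(phases / tbl_step)
  nph <- length(phases)
  np2 <- size_px^2
  # Pearson correlation of v against every (orientation, phase) model.
  # The model value at a pixel depends only on its along-axis coordinate
  # modulo the period, so for one orientation every phase reduces to a
  # circular cross-correlation of the comb table against 1D histograms of
  # the patch binned by that coordinate: O(table x phases) per orientation
  # instead of O(pixels x phases).
  v0 <- v - mean(v)
  sv <- sqrt(sum(v0^2))
  G2sq <- G2^2
  base <- 0:(ng - 1)
  cc_mat <- matrix(NA_real_, length(offs), nph)
  for (io in seq_along(offs)) {
    t <- patch_axis_coord(size_px, p, segment$orientation_deg + offs[io])
    t_idx <- round((as.vector(t) %% cfg$spacing_nm) / tbl_step) %% ng
    cnt <- tabulate(t_idx + 1L, nbins = ng)
    h <- numeric(ng)
    ug <- sort(unique(t_idx))
    h[ug + 1L] <- rowsum(v0, t_idx, reorder = TRUE)
    for (ip in seq_len(nph)) {
      sh <- base - ph_idx[ip] + ng + 1L
      g <- G2[sh]
      cov_vg <- sum(h * g)
      mB <- sum(cnt * g) / np2
      s2 <- sum(cnt * G2sq[sh]) - np2 * mB^2
      cc_mat[io, ip] <- cov_vg / (sv * sqrt(max(s2, 0)))
    }
  }
  cc_mat[!is.finite(cc_mat)] <- 0
  cc_mat <- pmin(pmax(cc_mat, -1), 1)
  # tie-break: phase ascending (major), then |offset| ascending (offs are
  # already in |offset| order, and columns traverse offsets within phase)
  best <- which.max(cc_mat)
  io <- (best - 1) %% length(offs) + 1
  ip <- (best - 1) %/% length(offs) + 1
  list(correlation = cc_mat[best],
       best_phase_nm = phases[ip],
       best_orientation_offset_deg = offs[io],
       degenerate = FALSE)
}

#' Score every tiled segment of an image
#'
#' @param image a [sted_image()].
#' @param segments data.frame from [tile_segments()].
#' @param cfg a [pattern_config()].
#' @return the `segments` data.frame with columns `correlation`,
#'   `best_phase_nm`, `best_orientation_offset_deg`, `degenerate` appended
#'   and a `segment_id` column prepended.
#' @export
score_segments <- function(image, segments, cfg = pattern_config()) {
  n <- nrow(segments)
  res <- lapply(seq_len(n), function(i) score_segment(image, segments[i, ], cfg))
  segments$correlation <- vapply(res, `[[`, numeric(1), "correlation")
  segments$best_phase_nm <- vapply(res, `[[`, numeric(1), "best_phase_nm")
  segments$best_orientation_offset_deg <-
    vapply(res, `[[`, numeric(1), "best_orientation_offset_deg")
  segments$degenerate <- vapply(res, `[[`, logical(1), "degenerate")
  cbind(segment_id = seq_len(n), segments)
}

#' Summarise MPS abundance and organization over a field
#'
#' A segment is MPS-positive when its correlation is strictly above the
#' threshold. *MPS abundance* is the fraction of scored segments that are
#' positive; *MPS correlation* is the mean correlation of the positive
#' segments (a measure of how well-organized the lattice is where it is
#' present).
#'
#' @param scores numeric vector of segment correlations, or a data.frame
#'   from [score_segments()] with a `correlation` column.
#' @param threshold correlation threshold (default 0.17, the shipped value
#'   corresponding to visually discernible periodicity).
#' @return list of class `mps_summary`: `n_segments`, `n_positive`,
#'   `abundance` (`NA` when no segments), `mean_correlation` (`NA` when no
#'   positive segments), `threshold`.
#' @export
summarize_mps <- function(scores, threshold = 0.17) {
  cc <- if (is.data.frame(scores)) scores$correlation else as.numeric(scores)
  n <- length(cc)
  pos <- cc > threshold
  npos <- sum(pos)
  structure(
    list(n_segments = n, n_positive = npos,
         abundance = if (n > 0) npos / n else NA_real_,
         mean_correlation = if (npos > 0) mean(cc[pos]) else NA_real_,
         threshold = threshold),
    class = "mps_summary"
  )
}

#' @export
print.mps_summary <- function(x, ...) {
  cat(sprintf("MPS summary: %d/%d segments positive (threshold %g)\n",
              x$n_positive, x$n_segments, x$threshold))
  cat(sprintf("  abundance: %s   mean correlation of positives: %s\n",
              format(x$abundance, digits = 3),
              format(x$mean_correlation, digits = 3)))
  invisible(x)
}

#' Calibrate the correlation threshold from labeled segments
#'
#' Reconstructs a visible-MPS threshold from segment correlations paired
#' with binary annotations: every midpoint between adjacent sorted unique
#' scores is a candidate boundary, and the one maximizing balanced
#' accuracy (mean of sensitivity and specificity, positive call =
#' correlation strictly above the candidate) is returned; ties go to the
#' smallest threshold.
#'
#' @param scores numeric correlations.
#' @param labels logical (or 0/1) visible-MPS annotations, same length.
#' @return the calibrated threshold (numeric scalar).
#' @export
calibrate_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present to calibrate", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2)
    stop("need at least two distinct scores", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  bal <- vapply(cand, function(th) {
    pred <- scores > th
    (mean(pred[labels]) + mean(!pred[!labels])) / 2
  }, numeric(1))
  cand[which.max(bal)]  # first max = smallest candidate on ties
}

#' Count qualifying ~spacing periods along a profile (manual criterion)
#'
#' Mirrors the manual scoring rule for the MPS: peaks are localized as in
#' [segment_period()], and consecutive inter-peak gaps falling within
#' `spacing_nm +/- tolerance_nm` count as qualifying periods. A profile is
#' called positive when it holds a run of at least `min_run` consecutive
#' qualifying periods (default 4).
#'
#' @param profile numeric intensity profile.
#' @param pixel_size_nm sampling step of the profile, nm.
#' @param spacing_nm nominal period (default 190).
#' @param tolerance_nm half-width of the accepted band (default 40).
#' @param min_run qualifying periods required for a positive call
#'   (default 4).
#' @param ... passed to [find_peaks()] / [segment_period()] peak options.
#' @return list with `n_periods` (longest consecutive qualifying run) and
#'   `positive`.
#' @export
count_periods <- function(profile, pixel_size_nm, spacing_nm = 190,
                          tolerance_nm = 40, min_run = 4, ...) {
  pos <- refine_peak_positions(profile, pixel_size_nm, ...)
  if (length(pos) < 2)
    return(list(n_periods = 0L, positive = FALSE))
  gaps <- diff(pos)
  ok <- abs(gaps - spacing_nm) <= tolerance_nm
  runs <- rle(ok)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(n_periods = as.integer(longest), positive = longest >= min_run)
}
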