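#' Detect axonal material by robust background thresholding
#'
#' Lightly smooths the image (Gaussian, sigma = 1 px), thresholds at
#' `median + background_k * MAD` of the smoothed intensities, and removes
#' 8-connected foreground objects smaller than `min_object_area_um2`.
#' Robust background statistics behave well on sparse-foreground STED
#' fields where histogram-split methods such as Otsu do not.
#'
#' @param image a [sted_image()].
#' @param background_k multiplier on the MAD above the median (default 3).
#' @param min_object_area_um2 smallest surviving object, in um^2
#'   (default 0.5).
#' @return An object of class `axon_mask`: list with `mask` (logical matrix
#'   congruent with the image), `pixel_size_nm`, `threshold` (intensity
#'   cutoff used) and `min_object_area_um2`.
#' @export
detect_axon_mask <- function(image, background_k = 3,
                             min_object_area_um2 = 0.5) {
  stopifnot(inherits(image, "sted_image"))
  sm <- as.matrix(EBImage::gblur(image$pixels, sigma = 1))
  thr <- stats::median(sm) + background_k * stats::mad(sm)
  mask <- sm > thr
  min_px <- min_object_area_um2 * 1e6 / image$pixel_size_nm^2
  if (any(mask) && min_px > 1) {
    lab <- label_components8(mask)
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  structure(
    list(mask = mask, pixel_size_nm = image$pixel_size_nm,
         threshold = thr, min_object_area_um2 = min_object_area_um2),
    class = "axon_mask"
  )
}

#' Local fibre orientation from the smoothed structure tensor
#'
#' Estimates the per-pixel orientation of elongated structures as the
#' direction of least intensity variation: the image gradient outer
#' product is averaged over a Gaussian window of scale `scale_nm`, and the
#' fibre axis is perpendicular to the dominant eigenvector. The image is
#' first smoothed at `pre_smooth_nm` so that periodic staining along the
#' fibre (rings repeating at ~190 nm would otherwise dominate the
#' gradients and flip the estimate by 90 degrees) is averaged out and the
#' axon presents as a smooth ridge. Angles wrap modulo 180 degrees (a
#' fibre has no direction sign); x runs along columns and y along rows
#' (downwards), so an axon of constant y has angle 0.
#'
#' @param image a [sted_image()].
#' @param mask optional `axon_mask`; accepted for pipeline symmetry. The
#'   tensor is computed over the full field regardless (low-coherence
#'   regions are still scored downstream, where the orientation search
#'   range absorbs moderate error).
#' @param scale_nm Gaussian smoothing scale of the tensor, nm (>= pixel
#'   size; default 200).
#' @param pre_smooth_nm Gaussian pre-smoothing of the image before
#'   gradients, nm (default 95, about half the nominal lattice period).
#' @param coherence compute the coherence map (default `TRUE`; the
#'   scoring pipeline needs only the angles and skips it).
#' @return An object of class `orientation_field`: list with matrices
#'   `angle_deg` (in \[0, 180)) and `coherence` (normalized eigenvalue
#'   contrast in \[0, 1\]; `NULL` when not computed).
#' @export
local_orientation <- function(image, mask = NULL, scale_nm = 200,
                              pre_smooth_nm = 95, coherence = TRUE) {
  stopifnot(inherits(image, "sted_image"))
  p <- image$pixel_size_nm
  if (scale_nm < p)
    stop("`scale_nm` must be at least one pixel", call. = FALSE)
  tensor <- function(I) {
    nr <- nrow(I); nc <- ncol(I)
    # central differences, replicated edges; x = columns, y = rows
    gx <- (I[, c(2:nc, nc)] - I[, c(1, 1:(nc - 1))]) / 2
    gy <- (I[c(2:nr, nr), ] - I[c(1, 1:(nr - 1)), ]) / 2
    sig <- scale_nm / p
    list(xx = as.matrix(EBImage::gblur(gx * gx, sigma = sig)),
         yy = as.matrix(EBImage::gblur(gy * gy, sigma = sig)),
         xy = as.matrix(EBImage::gblur(gx * gy, sigma = sig)))
  }
  I <- image$pixels
  Ism <- if (pre_smooth_nm / p >= 0.3)
    as.matrix(EBImage::gblur(I, sigma = pre_smooth_nm / p)) else I
  # angle from the coarse (ring-free) tensor ...
  Jc <- tensor(Ism)
  ang_grad <- 0.5 * atan2(2 * Jc$xy, Jc$xx - Jc$yy) * 180 / pi
  angle <- (ang_grad + 90) %% 180  # fibre axis is normal to the gradient
  # ... coherence from the fine-scale tensor, where isotropic noise is not
  # pre-correlated by the smoothing
  coh <- NULL
  if (coherence) {
    Jf <- tensor(I)
    tr <- Jf$xx + Jf$yy
    coh <- sqrt((Jf$xx - Jf$yy)^2 + 4 * Jf$xy^2) / (tr + 1e-12)
    coh[tr <= 0] <- 0
  }
  structure(list(angle_deg = angle, coherence = coh),
            class = "orientation_field")
}

#' Tile axon-containing square segments for lattice scoring
#'
#' Lays a non-overlapping grid of `segment_um` x `segment_um` squares
#' anchored at the image origin and keeps those whose fraction of
#' axon-mask pixels reaches `min_fill`. Each kept segment carries the
#' circular median of the orientation field over its masked pixels.
#'
#' @param mask an `axon_mask` from [detect_axon_mask()].
#' @param orientation an `orientation_field` from [local_orientation()].
#' @param segment_um square edge, um (default 1).
#' @param min_fill minimum fraction of mask pixels to keep a segment
#'   (default 0.25). With full-square Pearson scoring, squares whose axon
#'   occupies well under a quarter of the area cannot reach the positive
#'   threshold even on a perfect lattice and would only dilute abundance,
#'   so a segment must contain appreciable axonal material to be scored.
#' @return data.frame with one row per kept segment: `row`, `col` (0-based
#'   top-left pixel), `size_px`, `orientation_deg`, `fill_fraction`.
#' @export
tile_segments <- function(mask, orientation, segment_um = 1,
                          min_fill = 0.25) {
  stopifnot(inherits(mask, "axon_mask"),
            inherits(orientation, "orientation_field"))
  p <- mask$pixel_size_nm
  size_px <- round(segment_um * 1000 / p)
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  if (size_px > min(nr, nc))
    stop("segment larger than the field", call. = FALSE)
  r0s <- seq(0, nr - size_px, by = size_px)
  c0s <- seq(0, nc - size_px, by = size_px)
  rows <- cols <- fill <- ang <- numeric(0)
  for (r0 in r0s) for (c0 in c0s) {
    sub <- mask$mask[(r0 + 1):(r0 + size_px), (c0 + 1):(c0 + size_px)]
    f <- mean(sub)
    if (f >= min_fill) {
      a <- orientation$angle_deg[(r0 + 1):(r0 + size_px),
                                 (c0 + 1):(c0 + size_px)]
      rows <- c(rows, r0); cols <- c(cols, c0); fill <- c(fill, f)
      ang <- c(ang, axial_median(a[sub]))
    }
  }
  data.frame(row = rows, col = cols,
             size_px = rep(size_px, length(rows)),
             orientation_deg = ang, fill_fraction = fill)
}
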