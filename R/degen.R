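#' Binarize an axon image
#'
#' Thresholds the intensity histogram with Otsu's criterion (256 bins) by
#' default, or at a fixed cutoff; foreground is strictly above the
#' threshold. A constant image cannot be split and yields an empty mask
#' with a warning.
#'
#' @param image a [sted_image()].
#' @param method `"otsu"` or `"fixed:<value>"` (e.g. `"fixed:100"`).
#' @return logical matrix with the threshold used in attribute
#'   `"threshold"`.
#' @export
binarize_axons <- function(image, method = "otsu") {
  stopifnot(inherits(image, "sted_image"))
  px <- image$pixels
  if (identical(method, "otsu")) {
    rng <- range(px)
    if (diff(rng) == 0) {
      warning("constant image: no threshold separates a single value; ",
              "returning an empty mask")
      mask <- matrix(FALSE, nrow(px), ncol(px))
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
    norm <- (px - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                           levels = 256)
    thr <- rng[1] + thr01 * diff(rng)
  } else if (grepl("^fixed:", method)) {
    thr <- as.numeric(sub("^fixed:", "", method))
    if (!is.finite(thr)) stop("bad fixed threshold: ", method, call. = FALSE)
  } else {
    stop("`method` must be \"otsu\" or \"fixed:<value>\"", call. = FALSE)
  }
  mask <- px > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Quantify axonal area and fragmentation from a binary mask
#'
#' Labels 8-connected foreground components and separates total axonal
#' area from the area of small particles (fragments and debris excluded
#' by size): components below `min_particle_area_um2` are counted as
#' excluded particles and subtracted from the unfragmented area.
#' Cross-condition normalization (e.g. percent unfragmented relative to a
#' control) is left to the caller, which has both the numerator and the
#' denominator here.
#'
#' @param mask logical/0-1 matrix.
#' @param pixel_size_nm physical pixel size, nm.
#' @param min_particle_area_um2 size cutoff below which a component counts
#'   as a particle (default 20 um^2; record it with your results, the
#'   appropriate value depends on magnification and axon calibre).
#' @return list of class `degeneration_report`: `total_area_px`,
#'   `total_area_um2`, `unfragmented_area_px`, `unfragmented_area_um2`,
#'   `n_particles_excluded`, `min_particle_area_um2`.
#' @export
quantify_fragmentation <- function(mask, pixel_size_nm,
                                   min_particle_area_um2 = 20) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.logical(mask), is.matrix(mask))
  um2_per_px <- (pixel_size_nm / 1000)^2
  lab <- label_components8(mask)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  cutoff_px <- min_particle_area_um2 / um2_per_px
  small <- areas < cutoff_px
  total <- sum(areas)
  excluded <- sum(areas[small])
  structure(
    list(total_area_px = total,
         total_area_um2 = total * um2_per_px,
         unfragmented_area_px = total - excluded,
         unfragmented_area_um2 = (total - excluded) * um2_per_px,
         n_particles_excluded = sum(small),
         min_particle_area_um2 = min_particle_area_um2),
    class = "degeneration_report"
  )
}

#' @export
print.degeneration_report <- function(x, ...) {
  cat(sprintf(
    "degeneration: total %.2f um^2, unfragmented %.2f um^2 (%d particles < %g um^2 excluded)\n",
    x$total_area_um2, x$unfragmented_area_um2, x$n_particles_excluded,
    x$min_particle_area_um2))
  invisible(x)
}
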