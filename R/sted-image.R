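#' Single-channel calibrated microscopy image
#'
#' The unit of all analysis in this package: a 2D grid of finite,
#' non-negative intensities (arbitrary units) together with the physical
#' edge length of one pixel in nanometres. Pixel indices are 0-based
#' `(row, col)`, row-major; physical positions in nm are measured from the
#' centre of the top-left pixel, with x running along columns and y along
#' rows (downwards).
#'
#' @param pixels numeric matrix (>= 2 rows and >= 2 columns) of finite,
#'   non-negative intensities.
#' @param pixel_size_nm physical edge length of one pixel, in nm (> 0).
#' @param label free-text channel/stain tag recorded in reports.
#' @return An object of class `sted_image`: a list with elements `pixels`,
#'   `pixel_size_nm` and `label`.
#' @examples
#' img <- sted_image(matrix(runif(64), 8, 8), pixel_size_nm = 20)
#' dim(img)
#' @export
sted_image <- function(pixels, pixel_size_nm, label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("`pixels` must have at least 2 rows and 2 columns", call. = FALSE)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0", call. = FALSE)
  assert_scalar_num(pixel_size_nm, "pixel_size_nm", lower = 0,
                    strict_lower = TRUE)
  structure(
    list(pixels = pixels,
         pixel_size_nm = as.numeric(pixel_size_nm),
         label = as.character(label)[1]),
    class = "sted_image"
  )
}

#' @export
dim.sted_image <- function(x) dim(x$pixels)

#' @export
print.sted_image <- function(x, ...) {
  cat(sprintf("sted_image: %d x %d px at %g nm/px (%.2f x %.2f um)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              nrow(x$pixels) * x$pixel_size_nm / 1000,
              ncol(x$pixels) * x$pixel_size_nm / 1000,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a calibrated grayscale TIFF image
#'
#' Reads a single-channel 2D TIFF and its physical pixel size from the TIFF
#' resolution tags (XResolution/YResolution with a metric ResolutionUnit).
#' Integer-sample TIFFs are converted back to their raw integer intensity
#' scale (the `tiff` package reads them normalised to \[0, 1\]); no other
#' rescaling is applied.
#'
#' @param path path to a grayscale TIFF file.
#' @param pixel_size_nm optional pixel-size override in nm. Takes precedence
#'   over file metadata; a warning is emitted when both are present and
#'   disagree.
#' @param label free-text tag stored on the returned image.
#' @return A [sted_image()].
#' @export
load_sted_image <- function(path, pixel_size_nm = NULL, label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                   error = function(e) stop("cannot read TIFF: ",
                                            conditionMessage(e), call. = FALSE))
  if (length(imgs) != 1L)
    stop("multi-image TIFF not supported (", length(imgs), " directories)",
         call. = FALSE)
  px <- imgs[[1]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1] else
      stop("multi-channel TIFF not supported (", dim(px)[3], " channels)",
           call. = FALSE)
  }
  info <- attributes(imgs[[1]])
  bits <- info$bits.per.sample %||% NA
  fmt <- info$sample.format %||% "uint"
  if (is.finite(bits) && !identical(fmt, "float"))
    px <- round(px * (2^bits - 1))
  px <- matrix(as.numeric(px), nrow(px), ncol(px))  # drop info attributes
  meta_ps <- tiff_resolution_to_nm(info)
  if (!is.null(pixel_size_nm)) {
    assert_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict_lower = TRUE)
    if (!is.null(meta_ps) && abs(meta_ps - pixel_size_nm) > 1e-6 * meta_ps)
      warning(sprintf(
        "pixel-size override %g nm differs from TIFF metadata %g nm; using override",
        pixel_size_nm, meta_ps))
    ps <- pixel_size_nm
  } else if (!is.null(meta_ps)) {
    ps <- meta_ps
  } else {
    stop("no pixel-size calibration: TIFF has no resolution tags and no ",
         "`pixel_size_nm` override was given", call. = FALSE)
  }
  sted_image(px, ps, label = label)
}

#' Write a calibrated grayscale TIFF image
#'
#' Writes the pixel grid as a single-channel TIFF and stores the physical
#' pixel size in standard TIFF resolution tags (XResolution/YResolution,
#' ResolutionUnit = cm), so the file round-trips through
#' [load_sted_image()]. Intensities are rounded to integers and must lie in
#' \[0, 2^bits - 1\].
#'
#' @param image a [sted_image()].
#' @param path output file path.
#' @param bits bits per sample: 8 or 16 (integer samples).
#' @return `path`, invisibly.
#' @export
write_sted_image <- function(image, path, bits = 16) {
  stopifnot(inherits(image, "sted_image"))
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16", call. = FALSE)
  px <- image$pixels
  top <- 2^bits - 1
  if (max(px) > top)
    stop(sprintf("intensities exceed %d; rescale before writing", top),
         call. = FALSE)
  px <- round(px) / top
  tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  tiff_set_resolution(path, image$pixel_size_nm)
  invisible(path)
}
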