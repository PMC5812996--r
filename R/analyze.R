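#' Full MPS analysis of one field
#'
#' Runs the whole pipeline on a calibrated image: axon detection by robust
#' background thresholding, local orientation from the structure tensor,
#' tiling into square axon-containing segments, maximal lattice
#' correlation per segment, and the field-level abundance/organization
#' summary.
#'
#' @param image a [sted_image()].
#' @param cfg a [pattern_config()].
#' @param threshold correlation threshold for the positive call
#'   (default 0.17).
#' @param background_k,min_object_area_um2 passed to [detect_axon_mask()].
#' @param orientation_scale_nm passed to [local_orientation()].
#' @param min_fill passed to [tile_segments()].
#' @return list of class `mps_analysis`: `summary` ([summarize_mps()]
#'   result), `segments` (scored table), `mask`, `orientation`.
#' @examples
#' lay <- make_axon_layout(30, n_axons = 2, occupancy = 1, seed = 7)
#' ren <- render_sted_image(lay, noise = list(gaussian_sd = 5,
#'                                            poisson_scale = 1), seed = 7)
#' res <- analyze_mps(ren$image)
#' res$summary
#' @export
analyze_mps <- function(image, cfg = pattern_config(), threshold = 0.17,
                        background_k = 3, min_object_area_um2 = 0.5,
                        orientation_scale_nm = 200, min_fill = 0.25) {
  mask <- detect_axon_mask(image, background_k, min_object_area_um2)
  orient <- local_orientation(image, mask, scale_nm = orientation_scale_nm,
                              coherence = FALSE)
  segs <- tile_segments(mask, orient, segment_um = cfg$segment_um,
                        min_fill = min_fill)
  scored <- score_segments(image, segs, cfg)
  structure(
    list(summary = summarize_mps(scored, threshold),
         segments = scored, mask = mask, orientation = orient),
    class = "mps_analysis"
  )
}

#' @export
print.mps_analysis <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
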