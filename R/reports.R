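#' Write per-segment and summary reports
#'
#' Writes the scored segment table as CSV (one row per segment) and the
#' field summary as JSON, creating the output directory if needed. The
#' JSON echoes the analysis configuration when one is supplied.
#'
#' @param summary an `mps_summary` from [summarize_mps()].
#' @param scores data.frame from [score_segments()] (may have zero rows).
#' @param out_dir output directory.
#' @param config optional list echoed into the JSON under `config`.
#' @param basename file stem for the two outputs (default `"mps"`).
#' @return character vector of the two file paths, invisibly.
#' @export
write_reports <- function(summary, scores, out_dir, config = NULL,
                          basename = "mps") {
  stopifnot(inherits(summary, "mps_summary"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  csv <- file.path(out_dir, paste0(basename, "_segments.csv"))
  json <- file.path(out_dir, paste0(basename, "_summary.json"))
  cols <- c("segment_id", "row", "col", "orientation_deg", "fill_fraction",
            "correlation", "best_phase_nm", "best_orientation_offset_deg",
            "degenerate")
  tab <- if (nrow(scores) > 0) scores[, intersect(cols, names(scores))] else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  tab$positive <- if (nrow(tab) > 0) tab$correlation > summary$threshold else
    logical(0)
  utils::write.csv(tab, csv, row.names = FALSE)
  payload <- list(
    n_segments = summary$n_segments,
    n_positive = summary$n_positive,
    abundance = if (is.na(summary$abundance)) NULL else summary$abundance,
    mean_correlation = if (is.na(summary$mean_correlation)) NULL else
      summary$mean_correlation,
    threshold = summary$threshold,
    config = config
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv, json = json))
}
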