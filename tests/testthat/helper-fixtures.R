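# Shared fixtures built in code.

# A hand-built straight horizontal axon layout (no RNG): one polyline at
# constant y, every 1 um stretch labelled.
straight_layout <- function(y_nm = 5000, x0 = 500, x1 = 9500,
                            positive = TRUE, spacing_nm = 190,
                            jitter_nm = 0, width_nm = 150, field_um = 10) {
  n <- floor((x1 - x0) / 1000)
  structure(
    list(polylines = list(cbind(x_nm = c(x0, x1), y_nm = c(y_nm, y_nm))),
         stretches = data.frame(axon = 1L, stretch = seq_len(n),
                                s_start_nm = (seq_len(n) - 1) * 1000,
                                s_end_nm = seq_len(n) * 1000,
                                mps_positive = positive),
         axon_width_nm = width_nm, spacing_nm = spacing_nm,
         spacing_jitter_nm = jitter_nm, occupancy = as.numeric(positive),
         field_um = field_um, curvature_sd_deg = 0, stretch_um = 1),
    class = "axon_layout")
}

# Rotate a layout's polylines about the field centre (degrees).
rotate_layout <- function(layout, angle_deg, field_um = layout$field_um) {
  th <- angle_deg * pi / 180
  c0 <- field_um * 1000 / 2
  layout$polylines <- lapply(layout$polylines, function(p) {
    x <- p[, 1] - c0; y <- p[, 2] - c0
    cbind(x_nm = c0 + x * cos(th) - y * sin(th),
          y_nm = c0 + x * sin(th) + y * cos(th))
  })
  layout
}

# Count ground-truth rings falling inside each tiled segment.
rings_per_segment <- function(segments, rings, pixel_size_nm) {
  rr <- floor(rings$y_nm / pixel_size_nm)
  cc <- floor(rings$x_nm / pixel_size_nm)
  vapply(seq_len(nrow(segments)), function(i) {
    sum(rr >= segments$row[i] & rr < segments$row[i] + segments$size_px[i] &
        cc >= segments$col[i] & cc < segments$col[i] + segments$size_px[i])
  }, numeric(1))
}
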