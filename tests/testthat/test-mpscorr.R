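# Independent reference implementation of the lattice-model patch used to
# cross-check build_mps_model and score_segment: direct double loop over
# pixel coordinates and explicit sum over peak replicates.
reference_model <- function(size_px, pixel_size_nm, spacing, sigma,
                            orientation_deg, phase) {
  th <- orientation_deg * pi / 180
  m <- matrix(0, size_px, size_px)
  for (i in seq_len(size_px)) {
    for (j in seq_len(size_px)) {
      t <- (j - 1) * pixel_size_nm * cos(th) + (i - 1) * pixel_size_nm * sin(th)
      ks <- ceiling((t - phase - 8 * sigma) / spacing):
        floor((t - phase + 8 * sigma) / spacing)
      m[i, j] <- sum(exp(-(t - phase - ks * spacing)^2 / (2 * sigma^2)))
    }
  }
  m
}

test_that("model patch is a standardized Gaussian comb with the expected peaks", {
  cfg <- pattern_config()
  m <- build_mps_model(cfg, pixel_size_nm = 20, orientation_deg = 0,
                       phase_nm = 0)
  expect_equal(dim(m), c(50, 50))
  expect_lt(abs(mean(m)), 1e-9)
  expect_lt(abs(sd(as.vector(m)) - 1), 1e-9)
  # peaks at 0, 190, ..., 950 nm along x: 6 peak centres in a 1 um window
  # (the one at x = 0 sits on the window border, so 5 interior maxima)
  row1 <- m[1, ]
  pk <- find_peaks(row1, pixel_size_nm = 20, min_separation_nm = 100)
  x_nm <- (pk - 1) * 20
  expect_equal(length(x_nm), 5)
  expect_true(all(abs(x_nm - (1:5) * 190) <= 10))
  expect_equal(which.max(row1[1:5]), 1)  # border peak at x = 0
  # transposition symmetry between 0 and 90 degrees
  m90 <- build_mps_model(cfg, 20, orientation_deg = 90, phase_nm = 0)
  expect_equal(m90, t(m))
  # agreement with the independent double-loop construction
  ref <- reference_model(50, 20, 190, 25, 37, 55)
  ref <- (ref - mean(ref)) / sd(as.vector(ref))
  expect_equal(build_mps_model(cfg, 20, 37, 55), ref, tolerance = 1e-8)
})

test_that("a segment that equals the model scores ~1 and a constant one is degenerate", {
  cfg <- pattern_config()
  m <- build_mps_model(cfg, 20, orientation_deg = 5, phase_nm = 60)
  img <- sted_image(m - min(m), 20)
  seg <- data.frame(row = 0, col = 0, size_px = 50, orientation_deg = 5)
  sc <- score_segment(img, seg, cfg)
  expect_gte(sc$correlation, 0.99)
  flat <- sted_image(matrix(7, 50, 50), 20)
  sc0 <- score_segment(flat, seg, cfg)
  expect_identical(sc0$correlation, 0)
  expect_true(sc0$degenerate)
  expect_error(score_segment(img, data.frame(row = 30, col = 0, size_px = 50,
                                             orientation_deg = 0), cfg),
               "bounds")
})

test_that("score_segment matches an exhaustive fine-grid search on noisy lattices", {
  # smaller-n version of the oracle-equivalence property (the full 50-segment
  # run lives in the acceptance suite)
  cfg <- pattern_config()
  set.seed(101)
  for (k in 1:5) {
    true_or <- runif(1, 0, 180)
    true_ph <- runif(1, 0, 190)
    patch <- reference_model(50, 20, 190, 25,
                             true_or + runif(1, -10, 10), true_ph)
    patch <- patch * 100 + matrix(rnorm(2500, 0, 20), 50, 50)
    img <- sted_image(patch - min(patch), 20)
    seg <- data.frame(row = 0, col = 0, size_px = 50,
                      orientation_deg = true_or)
    got <- score_segment(img, seg, cfg)$correlation
    best <- -1
    for (off in seq(-15, 15, by = 1)) {
      mref <- reference_model(50, 20, 190, 25, true_or + off, 0)
      # phase shifts along the axis are evaluated via cor against shifted
      # combs built independently
      for (ph in seq(0, 189, by = 4)) {
        mm <- reference_model(50, 20, 190, 25, true_or + off, ph)
        best <- max(best, cor(as.vector(patch), as.vector(mm)))
      }
    }
    expect_gt(got, 0.17)
    expect_lt(abs(got - best), 0.02)
  }
})

test_that("summarize_mps implements the abundance and organization definitions", {
  s <- summarize_mps(c(0.30, 0.10, 0.25, 0.05), threshold = 0.17)
  expect_equal(s$n_segments, 4)
  expect_equal(s$n_positive, 2)
  expect_equal(s$abundance, 0.5)
  expect_equal(s$mean_correlation, 0.275)
  # all below threshold
  s0 <- summarize_mps(c(0.1, 0.05))
  expect_equal(s0$abundance, 0)
  expect_true(is.na(s0$mean_correlation))
  # boundary value is NOT positive (strictly above)
  expect_equal(summarize_mps(c(0.17))$n_positive, 0)
  # default threshold
  expect_equal(summarize_mps(c(0.2))$threshold, 0.17)
  # empty input
  se <- summarize_mps(numeric(0))
  expect_true(is.na(se$abundance))
})

test_that("threshold calibration finds the balanced-accuracy midpoint", {
  # perfectly separable: midpoint of the separating gap
  sc <- c(0.40, 0.45, 0.50, 0.02, 0.05, 0.10)
  lb <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(calibrate_threshold(sc, lb), 0.25)
  expect_error(calibrate_threshold(c(0.1, 0.2), c(TRUE, TRUE)),
               "both classes")
  # overlapping distributions: equals an exhaustive scan
  set.seed(7)
  sco <- c(rnorm(120, 0.30, 0.10), rnorm(120, 0.08, 0.06))
  lab <- rep(c(TRUE, FALSE), each = 120)
  got <- calibrate_threshold(sco, lab)
  u <- sort(unique(sco))
  cand <- (u[-1] + u[-length(u)]) / 2
  bal <- sapply(cand, function(th) {
    (mean(sco[lab] > th) + mean(sco[!lab] <= th)) / 2
  })
  expect_equal(got, cand[which.max(bal)])
})

test_that("count_periods applies the >= 4 qualifying periods rule", {
  five <- render_profile((0:4) * 190, pixel_size_nm = 20)
  r5 <- count_periods(five, pixel_size_nm = 20)
  expect_equal(r5$n_periods, 4L)
  expect_true(r5$positive)
  four <- render_profile((0:3) * 190, pixel_size_nm = 20)
  r4 <- count_periods(four, pixel_size_nm = 20)
  expect_equal(r4$n_periods, 3L)
  expect_false(r4$positive)
  wide <- render_profile((0:5) * 350, pixel_size_nm = 20)
  rw <- count_periods(wide, pixel_size_nm = 20)
  expect_equal(rw$n_periods, 0L)
  expect_false(rw$positive)
})

test_that("correlation classification agrees with the manual period count on clean fields", {
  # noise-free straight axons, one fully positive and one fully negative
  ren_pos <- render_sted_image(straight_layout(positive = TRUE), seed = 41)
  ren_neg <- render_sted_image(straight_layout(positive = FALSE), seed = 41)
  agree <- 0; total <- 0
  for (ren in list(ren_pos, ren_neg)) {
    res <- analyze_mps(ren$image)
    segs <- res$segments
    nring <- rings_per_segment(segs, ren$ground_truth$rings, 20)
    for (i in seq_len(nrow(segs))) {
      # line profile along the segment centre in the axon direction
      cy <- (segs$row[i] + segs$size_px[i] / 2) * 20
      line <- c(segs$col[i] * 20, cy, (segs$col[i] + segs$size_px[i] - 1) * 20, cy)
      prof <- extract_profile(ren$image, line)
      manual <- count_periods(prof, pixel_size_nm = 20)$positive
      auto <- segs$correlation[i] > 0.17
      total <- total + 1
      agree <- agree + (manual == auto)
    }
  }
  expect_gte(agree / total, 0.9)
})
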