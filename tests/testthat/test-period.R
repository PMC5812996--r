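test_that("extract_profile averages parallel lines and counts samples correctly", {
  # three sampled rows hold constants 1, 2, 3 -> profile constant at 2
  px <- matrix(0, 10, 50)
  px[4, ] <- 1; px[5, ] <- 2; px[6, ] <- 3
  img <- sted_image(px, 20)
  prof <- extract_profile(img, c(100, 4 * 20, 900, 4 * 20), avg_width_px = 3)
  expect_true(all(abs(prof - 2) < 1e-12))
  # sample count: floor(L / p) + 1
  expect_equal(length(prof), floor(800 / 20) + 1)
  expect_error(extract_profile(img, c(0, 0, 2000, 0)), "outside")
})

test_that("find_peaks detects strict local maxima with prominence and separation", {
  expect_equal(find_peaks(c(0, 1, 0, 1, 0), min_separation_nm = 0,
                          pixel_size_nm = 20), c(2L, 4L))
  expect_equal(find_peaks(1:10, pixel_size_nm = 20), integer(0))
  # 5% secondary bump is dropped at 10% prominence
  x <- seq(0, 1000, by = 20)
  v <- exp(-(x - 300)^2 / (2 * 50^2)) + 0.05 * exp(-(x - 700)^2 / (2 * 50^2))
  pk <- find_peaks(v, min_prominence_frac = 0.10, pixel_size_nm = 20)
  expect_equal(length(pk), 1)
  expect_equal(x[pk], 300)
  # of two close candidates the higher survives
  v2 <- c(0, 5, 1, 4, 0, 0, 0, 0, 3, 0)
  pk2 <- find_peaks(v2, min_separation_nm = 100, pixel_size_nm = 20,
                    min_prominence_frac = 0)
  expect_true(2 %in% pk2 && !(4 %in% pk2))
})

test_that("quadratic refinement recovers sub-pixel peak positions without bias", {
  # symmetric Gaussian comb: estimate within 1 nm at several spacings and
  # pixel sizes, including spacings incommensurate with the grid
  for (sp in c(150, 190, 213, 250)) {
    for (p in c(10, 20, 30)) {
      prof <- render_profile((0:5) * sp + 7, peak_sigma_nm = 25,
                             pixel_size_nm = p)
      est <- segment_period(prof, pixel_size_nm = p)
      expect_lt(abs(est$mean_period_nm - sp), 1)
    }
  }
})

test_that("segment_period applies the accepted peak-count range", {
  est6 <- segment_period(render_profile((0:5) * 190), pixel_size_nm = 20)
  expect_equal(est6$n_peaks, 6)
  expect_true(est6$valid)
  est3 <- segment_period(render_profile((0:2) * 190), pixel_size_nm = 20)
  expect_equal(est3$n_peaks, 3)
  expect_false(est3$valid)
  est8 <- segment_period(render_profile((0:7) * 190), pixel_size_nm = 20)
  expect_false(est8$valid)
  # peaks on grid points -> refined positions are exact, mean of the
  # consecutive differences is exact arithmetic
  est <- segment_period(render_profile(c(0, 200, 400, 600, 800),
                                       pad_nm = 100),
                        pixel_size_nm = 20)
  expect_equal(est$mean_period_nm, 200, tolerance = 1e-6)
  flat <- rep(1, 100)
  expect_error(segment_period(flat, pixel_size_nm = 20), "fewer than 2")
})

test_that("period estimates are noise robust and intensity-affine invariant", {
  errs <- vapply(1:60, function(s) {
    prof <- render_profile((0:5) * 190, pixel_size_nm = 20,
                           amplitude = 100, noise_sd = 10, seed = s)
    segment_period(prof, pixel_size_nm = 20)$mean_period_nm - 190
  }, numeric(1))
  expect_lt(mean(abs(errs)), 5)
  # affine transform leaves the estimate unchanged
  prof <- render_profile((0:5) * 190, noise_sd = 8, seed = 3)
  e1 <- segment_period(prof, pixel_size_nm = 20)
  e2 <- segment_period(3.7 * prof + 55, pixel_size_nm = 20)
  expect_equal(e1$peak_positions_nm, e2$peak_positions_nm, tolerance = 1e-9)
})

test_that("condition_period pools segment periods and applies the n >= 15 rule", {
  mk <- function(v) structure(list(peak_positions_nm = cumsum(c(0, rep(v, 4))),
                                   n_peaks = 5, mean_period_nm = v,
                                   valid = TRUE), class = "period_estimate")
  r15 <- condition_period(lapply(rep(190, 15), mk))
  expect_equal(r15$mean_nm, 190)
  expect_equal(r15$sd_nm, 0)
  expect_true(r15$sufficient)
  r10 <- condition_period(lapply(rep(190, 10), mk))
  expect_false(r10$sufficient)
  expect_equal(r10$n, 10)
  r3 <- condition_period(c(180, 190, 200))
  expect_equal(r3$mean_nm, 190)
  expect_equal(r3$sd_nm, 10)
  expect_error(condition_period(numeric(0)), "no period estimates")
  bad <- mk(190); bad$valid <- FALSE
  expect_error(condition_period(list(bad)), "valid")
})
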