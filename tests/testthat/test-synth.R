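test_that("layout generation respects occupancy and determinism", {
  # degenerate probabilities
  lay1 <- make_axon_layout(50, n_axons = 2, occupancy = 1, seed = 1)
  expect_true(all(lay1$stretches$mps_positive))
  lay0 <- make_axon_layout(50, n_axons = 2, occupancy = 0, seed = 1)
  expect_false(any(lay0$stretches$mps_positive))
  # binomial proportion at n ~ 200 stays within +/- 0.1 of the target
  lay <- make_axon_layout(200, n_axons = 8, occupancy = 0.5,
                          field_um = 20, seed = 11)
  expect_gt(nrow(lay$stretches), 150)
  expect_lt(abs(mean(lay$stretches$mps_positive) - 0.5), 0.1)
  # determinism
  a <- make_axon_layout(30, n_axons = 2, occupancy = 0.5, seed = 99)
  b <- make_axon_layout(30, n_axons = 2, occupancy = 0.5, seed = 99)
  expect_identical(a, b)
  expect_error(make_axon_layout(30, occupancy = 1.5), "occupancy")
})

test_that("layout stretches cover every full 1 um of centre line exactly once", {
  lay <- make_axon_layout(40, n_axons = 3, occupancy = 0.5, seed = 5)
  for (a in 1:3) {
    st <- lay$stretches[lay$stretches$axon == a, ]
    L <- sum(sqrt(rowSums(diff(lay$polylines[[a]])^2)))
    expect_equal(nrow(st), floor(L / 1000))
    expect_equal(st$s_start_nm, (seq_len(nrow(st)) - 1) * 1000)
    expect_equal(st$s_end_nm - st$s_start_nm, rep(1000, nrow(st)))
  }
})

test_that("zero-jitter rings are spaced exactly spacing_nm apart within a run", {
  lay <- straight_layout(spacing_nm = 190, jitter_nm = 0)
  ren <- render_sted_image(lay, seed = 2)
  gaps <- diff(ren$ground_truth$rings$s_nm)
  expect_true(all(abs(gaps - 190) < 1e-9))
})

test_that("rendered straight axon has maxima spaced one period apart on the centre line", {
  lay <- straight_layout(y_nm = 5000)
  ren <- render_sted_image(lay, psf_sigma_nm = 25, seed = 1)
  prof <- ren$image$pixels[251, ]  # row through y = 5000 at 20 nm/px
  pk <- find_peaks(prof, pixel_size_nm = 20)
  gaps_nm <- diff(pk) * 20
  expect_gt(length(pk), 30)
  expect_true(all(abs(gaps_nm - 190) <= 20))  # grid resolution
})

test_that("ground-truth mask covers the centre-line corridor", {
  lay <- straight_layout(y_nm = 5000)
  ren <- render_sted_image(lay, seed = 1)
  m <- ren$ground_truth$axon_mask
  # every pixel within axon_width of the line y=5000, x in [500, 9500]
  rows <- which(abs((0:499) * 20 - 5000) <= 150)
  cols <- which((0:499) * 20 >= 500 & (0:499) * 20 <= 9500)
  expect_true(all(m[rows, cols]))
})

test_that("rendering is deterministic under a fixed seed and flags bad geometry", {
  lay <- make_axon_layout(20, n_axons = 2, occupancy = 0.5, seed = 4)
  a <- render_sted_image(lay, noise = list(gaussian_sd = 5, poisson_scale = 1),
                         seed = 21)
  b <- render_sted_image(lay, noise = list(gaussian_sd = 5, poisson_scale = 1),
                         seed = 21)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_error(render_sted_image(lay, field_um = 5), "beyond the field")
})

test_that("render_profile samples a Gaussian comb exactly", {
  pos <- c(0, 190, 380, 570, 760)
  prof <- render_profile(pos, peak_sigma_nm = 25, pixel_size_nm = 20,
                         amplitude = 100, noise_sd = 0)
  x <- attr(prof, "origin_nm") + (seq_along(prof) - 1) * 20
  # local maxima at the grid points nearest each true peak
  pk <- find_peaks(prof, pixel_size_nm = 20)
  expect_equal(length(pk), 5)
  expect_true(all(abs(x[pk] - pos) <= 10))
  # peak value reaches the amplitude within 0.1% (well-separated peaks,
  # and 0 nm falls on a grid point)
  expect_lt(abs(max(prof) - 100) / 100, 1e-3)
  expect_error(render_profile(c(190, 0)), "sorted")
  expect_identical(render_profile(pos, noise_sd = 3, seed = 8),
                   render_profile(pos, noise_sd = 3, seed = 8))
})

test_that("render_fragment_field places exactly the requested 8-connected components", {
  areas <- c(5000, 20, 20, 20)
  img <- render_fragment_field(areas, field_shape = c(256, 256), seed = 6)
  lab <- axonmps:::label_components8(img)
  got <- sort(tabulate(lab[lab > 0]))
  expect_equal(got, sort(areas))
  expect_equal(max(lab), length(areas))
  # empty case
  expect_equal(sum(render_fragment_field(integer(0))), 0)
  # oversubscribed field
  expect_error(render_fragment_field(1e5, field_shape = c(100, 100)),
               "50%")
})

test_that("fragment components are separated by background", {
  img <- render_fragment_field(rep(50, 30), field_shape = c(200, 200),
                               seed = 9)
  # dilating by one pixel must not merge any components
  lab0 <- axonmps:::label_components8(img)
  dil <- EBImage::dilate(img * 1, EBImage::makeBrush(3, "box"))
  lab1 <- axonmps:::label_components8(dil > 0)
  expect_equal(max(lab1), max(lab0))
})
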