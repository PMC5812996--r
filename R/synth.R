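#' Generate a random axon layout with known MPS ground truth
#'
#' Draws smooth (bounded-curvature) random polylines confined to a square
#' field, divides each centre line into 1 um stretches, and labels every
#' full stretch MPS-positive independently with probability `occupancy`.
#' The layout is the structural ground truth consumed by
#' [render_sted_image()]: MPS-positive stretches receive transverse rings
#' spaced `spacing_nm` apart (perturbed gap-by-gap with standard deviation
#' `spacing_jitter_nm`), MPS-negative stretches only the smooth backbone.
#'
#' @param total_length_um total centre-line length to generate, split evenly
#'   over `n_axons` polylines (>= 1 um).
#' @param n_axons number of axons (>= 1).
#' @param occupancy target fraction of MPS-positive 1 um stretches, in
#'   \[0, 1\].
#' @param spacing_nm nominal lattice period (default 190 nm).
#' @param spacing_jitter_nm per-ring standard deviation of the gap
#'   perturbation (>= 0).
#' @param axon_width_nm transverse Gaussian sigma of the axon backbone.
#' @param field_um edge length of the square field the polylines must stay
#'   inside.
#' @param curvature_sd_deg standard deviation of the random heading change
#'   per 250 nm step (default 2.5: gently curving axons, RMS heading drift
#'   ~16 degrees over 10 um).
#' @param stretch_um stretch length used for MPS labelling (default 1 um).
#' @param seed integer seed; identical seeds give identical layouts. `NULL`
#'   uses the current RNG state.
#' @return An object of class `axon_layout`: list with `polylines` (list of
#'   n x 2 matrices of x,y vertices in nm), `stretches` (data.frame with
#'   columns `axon`, `stretch`, `s_start_nm`, `s_end_nm`, `mps_positive`),
#'   and the generating parameters.
#' @examples
#' lay <- make_axon_layout(20, n_axons = 2, occupancy = 0.5, seed = 1)
#' mean(lay$stretches$mps_positive)
#' @export
make_axon_layout <- function(total_length_um, n_axons = 3, occupancy = 0.5,
                             spacing_nm = 190, spacing_jitter_nm = 0,
                             axon_width_nm = 150, field_um = 10,
                             curvature_sd_deg = 2.5,
                             stretch_um = 1, seed = NULL) {
  assert_scalar_num(total_length_um, "total_length_um", lower = 1)
  assert_scalar_num(n_axons, "n_axons", lower = 1)
  assert_scalar_num(occupancy, "occupancy", lower = 0, upper = 1)
  assert_scalar_num(spacing_nm, "spacing_nm", 0, strict_lower = TRUE)
  assert_scalar_num(spacing_jitter_nm, "spacing_jitter_nm", lower = 0)
  with_seed_or_current(seed, {
    field_nm <- field_um * 1000
    margin <- max(3 * axon_width_nm, 300)
    len_each <- total_length_um * 1000 / n_axons
    step <- 250  # vertex spacing, nm
    polylines <- lapply(seq_len(n_axons), function(a) {
      p <- c(stats::runif(1, margin, field_nm - margin),
             stats::runif(1, margin, field_nm - margin))
      heading <- stats::runif(1, 0, 2 * pi)
      nstep <- ceiling(len_each / step)
      pts <- matrix(NA_real_, nstep + 1, 2)
      pts[1, ] <- p
      for (k in seq_len(nstep)) {
        heading <- heading + stats::rnorm(1, 0, curvature_sd_deg * pi / 180)
        cand <- p + step * c(cos(heading), sin(heading))
        tries <- 0
        while ((any(cand < margin) || any(cand > field_nm - margin)) &&
               tries < 72) {
          # steer towards the field centre until the step stays inside
          to_centre <- atan2(field_nm / 2 - p[2], field_nm / 2 - p[1])
          heading <- heading + 0.3 * sin(to_centre - heading) +
            stats::rnorm(1, 0, 2 * pi / 180)
          cand <- p + step * c(cos(heading), sin(heading))
          tries <- tries + 1
        }
        p <- cand
        pts[k + 1, ] <- p
      }
      colnames(pts) <- c("x_nm", "y_nm")
      pts
    })
    stretch_nm <- stretch_um * 1000
    stretches <- do.call(rbind, lapply(seq_len(n_axons), function(a) {
      L <- polyline_length(polylines[[a]])
      nfull <- floor(L / stretch_nm)
      if (nfull == 0) return(NULL)
      data.frame(axon = a, stretch = seq_len(nfull),
                 s_start_nm = (seq_len(nfull) - 1) * stretch_nm,
                 s_end_nm = seq_len(nfull) * stretch_nm)
    }))
    stretches$mps_positive <- stats::runif(nrow(stretches)) < occupancy
    structure(
      list(polylines = polylines, stretches = stretches,
           axon_width_nm = axon_width_nm, spacing_nm = spacing_nm,
           spacing_jitter_nm = spacing_jitter_nm, occupancy = occupancy,
           field_um = field_um, curvature_sd_deg = curvature_sd_deg,
           stretch_um = stretch_um),
      class = "axon_layout"
    )
  })
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Resample a polyline at `step` nm: returns x, y, arclength s and local
# direction theta (radians) per sample.
densify_polyline <- function(pts, step = 5) {
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  cs <- c(0, cumsum(seg_len))
  total <- cs[length(cs)]
  s <- seq(0, total, by = step)
  x <- stats::approx(cs, pts[, 1], xout = s)$y
  y <- stats::approx(cs, pts[, 2], xout = s)$y
  iseg <- pmin(findInterval(s, cs, rightmost.closed = TRUE),
               nrow(seg))
  theta <- atan2(seg[iseg, 2], seg[iseg, 1])
  list(x = x, y = y, s = s, theta = theta, total = total)
}

# Arclength -> position/direction lookup on a densified polyline.
polyline_at <- function(dense, s) {
  x <- stats::approx(dense$s, dense$x, xout = s, rule = 2)$y
  y <- stats::approx(dense$s, dense$y, xout = s, rule = 2)$y
  i <- pmax(1, pmin(findInterval(s, dense$s), length(dense$theta)))
  list(x = x, y = y, theta = dense$theta[i])
}

# Realize ring centre arclengths. The lattice is continuous across runs of
# consecutive MPS-positive stretches (a random phase is drawn only at the
# start of each run), so a physical ring train never shows an artificial
# phase jump at a stretch boundary. Gap-wise jitter: each gap is
# spacing + N(0, jitter), truncated below at 0.3 * spacing so rings cannot
# collide or reorder. Zero jitter gives exact spacing within a run.
realize_rings <- function(layout) {
  st <- layout$stretches
  sp <- layout$spacing_nm
  jit <- layout$spacing_jitter_nm
  out <- list()
  for (a in unique(st$axon)) {
    sa <- st[st$axon == a, ]
    sa <- sa[order(sa$stretch), ]
    i <- 1
    while (i <= nrow(sa)) {
      if (!sa$mps_positive[i]) { i <- i + 1; next }
      j <- i
      while (j < nrow(sa) && sa$mps_positive[j + 1] &&
             sa$stretch[j + 1] == sa$stretch[j] + 1) j <- j + 1
      s <- sa$s_start_nm[i] + stats::runif(1, 0, sp)
      run_end <- sa$s_end_nm[j]
      pos <- numeric(0)
      while (s < run_end) {
        pos <- c(pos, s)
        gap <- sp + if (jit > 0) stats::rnorm(1, 0, jit) else 0
        s <- s + max(gap, 0.3 * sp)
      }
      if (length(pos)) {
        stretch_of <- sa$stretch[findInterval(pos, sa$s_start_nm)]
        out[[length(out) + 1]] <-
          data.frame(axon = a, stretch = stretch_of, s_nm = pos)
      }
      i <- j + 1
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Accumulate point masses onto the pixel grid (nearest-pixel binning).
bin_points <- function(x_nm, y_nm, w, n_px, pixel_size_nm) {
  col <- round(x_nm / pixel_size_nm)
  row <- round(y_nm / pixel_size_nm)
  keep <- row >= 0 & row < n_px & col >= 0 & col < n_px
  img <- matrix(0, n_px, n_px)
  if (!any(keep)) return(img)
  idx <- row[keep] + n_px * col[keep] + 1  # column-major linear index
  if (length(w) == 1L) w <- rep(w, length(x_nm))
  acc <- rowsum(w[keep], group = idx)
  img[as.integer(rownames(acc))] <- acc[, 1]
  img
}

gaussian_blur_nm <- function(img, sigma_nm, pixel_size_nm) {
  sigma_px <- sigma_nm / pixel_size_nm
  if (sigma_px < 0.3) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma_px))
}

#' Render a synthetic STED-like image of axons with known ground truth
#'
#' Rasterizes an [make_axon_layout()] geometry into a calibrated image:
#' a smooth Gaussian-profile backbone along every centre line, transverse
#' Gaussian rings (perpendicular to the local axon direction) in
#' MPS-positive stretches, and optional longitudinal "actin trail" fibres.
#' The structural image is convolved with a Gaussian point-spread function
#' and optionally degraded with Poisson shot noise followed by additive
#' Gaussian read noise.
#'
#' @param layout an `axon_layout`.
#' @param field_um edge of the square field in um (>= 2); must be at least
#'   the layout's field.
#' @param pixel_size_nm sampling, nm per pixel (default 20).
#' @param ring_amplitude peak intensity of one ring above the backbone
#'   (arbitrary units).
#' @param backbone_amplitude peak intensity of the smooth backbone ridge.
#' @param trail_density longitudinal trail fibres per 10 um of axon length.
#' @param trail_amplitude peak intensity of a trail fibre.
#' @param psf_sigma_nm Gaussian PSF sigma (default 25 nm, ~60 nm FWHM).
#' @param noise list with `gaussian_sd` (additive read noise, a.u.) and
#'   `poisson_scale` (counts per intensity unit for shot noise; 0 disables).
#' @param seed integer seed (`NULL`: current RNG state).
#' @return A list with `image` (a [sted_image()]) and `ground_truth` (list
#'   with the layout, a data.frame `rings` of realized ring centres
#'   `(axon, stretch, s_nm, x_nm, y_nm, theta_deg)`, and `axon_mask`, the
#'   binary grid of pixels within the axon width of a centre line).
#' @export
render_sted_image <- function(layout, field_um = NULL, pixel_size_nm = 20,
                              ring_amplitude = 100, backbone_amplitude = 30,
                              trail_density = 0, trail_amplitude = 80,
                              psf_sigma_nm = 25,
                              noise = list(gaussian_sd = 0, poisson_scale = 0),
                              seed = NULL) {
  stopifnot(inherits(layout, "axon_layout"))
  field_um <- field_um %||% layout$field_um
  assert_scalar_num(field_um, "field_um", lower = 2)
  assert_scalar_num(psf_sigma_nm, "psf_sigma_nm", lower = 0)
  field_nm <- field_um * 1000
  xy <- do.call(rbind, layout$polylines)
  if (any(xy < 0) || any(xy > field_nm))
    stop("layout extends beyond the field", call. = FALSE)
  n_px <- round(field_nm / pixel_size_nm)
  w <- layout$axon_width_nm
  ds <- 5  # centre-line sampling step, nm

  with_seed_or_current(seed, {
    dense <- lapply(layout$polylines, densify_polyline, step = ds)

    # --- backbone: centre-line mass, blurred by width (+) PSF -------------
    sig_bb <- sqrt(w^2 + psf_sigma_nm^2)
    w_bb <- backbone_amplitude * ds * sqrt(2 * pi) * sig_bb / pixel_size_nm^2
    bb <- bin_points(unlist(lapply(dense, `[[`, "x")),
                     unlist(lapply(dense, `[[`, "y")),
                     w_bb, n_px, pixel_size_nm)
    img <- gaussian_blur_nm(bb, sig_bb, pixel_size_nm)

    # --- rings: transverse Gaussian-weighted line of mass per ring --------
    rings <- realize_rings(layout)
    ring_sigma_long <- 25  # longitudinal sigma of one ring before the PSF
    sig_r <- sqrt(ring_sigma_long^2 + psf_sigma_nm^2)
    if (!is.null(rings) && nrow(rings) > 0) {
      pos <- lapply(seq_len(nrow(rings)), function(i) {
        d <- dense[[rings$axon[i]]]
        polyline_at(d, rings$s_nm[i])
      })
      rings$x_nm <- vapply(pos, `[[`, numeric(1), "x")
      rings$y_nm <- vapply(pos, `[[`, numeric(1), "y")
      theta <- vapply(pos, `[[`, numeric(1), "theta")
      rings$theta_deg <- (theta * 180 / pi) %% 180
      # transverse offsets: one Gaussian-weighted comb of point masses
      toff <- seq(-3 * w, 3 * w, by = ds)
      tw <- exp(-toff^2 / (2 * w^2))
      # per-sample mass such that the convolved ring peaks at ring_amplitude
      sig_t <- sqrt(w^2 + sig_r^2)
      amp_scale <- ring_amplitude * ds * sqrt(2 * pi) * sig_r * sig_t /
        (w * pixel_size_nm^2)
      nr <- nrow(rings)
      px <- rep(rings$x_nm, each = length(toff)) +
        rep(-sin(theta), each = length(toff)) * rep(toff, nr)
      py <- rep(rings$y_nm, each = length(toff)) +
        rep(cos(theta), each = length(toff)) * rep(toff, nr)
      pw <- rep(tw, nr) * amp_scale
      rimg <- bin_points(px, py, pw, n_px, pixel_size_nm)
      img <- img + gaussian_blur_nm(rimg, sig_r, pixel_size_nm)
    } else {
      rings <- data.frame(axon = integer(0), stretch = integer(0),
                          s_nm = numeric(0), x_nm = numeric(0),
                          y_nm = numeric(0), theta_deg = numeric(0))
    }

    # --- actin trails: longitudinal fibres inside axons -------------------
    total_len_um <- sum(vapply(dense, `[[`, numeric(1), "total")) / 1000
    n_trails <- round(trail_density * total_len_um / 10)
    if (n_trails > 0) {
      sig_tr <- sqrt(20^2 + psf_sigma_nm^2)
      w_tr <- trail_amplitude * ds * sqrt(2 * pi) * sig_tr / pixel_size_nm^2
      tx <- ty <- list()
      for (k in seq_len(n_trails)) {
        a <- sample.int(length(dense), 1)
        d <- dense[[a]]
        len <- stats::runif(1, 2000, 5000)
        s0 <- stats::runif(1, 0, max(d$total - len, 1))
        off <- stats::runif(1, -w / 2, w / 2)
        s <- seq(s0, min(s0 + len, d$total), by = ds)
        at <- polyline_at(d, s)
        tx[[k]] <- at$x - sin(at$theta) * off
        ty[[k]] <- at$y + cos(at$theta) * off
      }
      timg <- bin_points(unlist(tx), unlist(ty), w_tr, n_px, pixel_size_nm)
      img <- img + gaussian_blur_nm(timg, sig_tr, pixel_size_nm)
    }

    # --- noise ------------------------------------------------------------
    img[img < 0] <- 0
    gsd <- noise$gaussian_sd %||% 0
    psc <- noise$poisson_scale %||% 0
    if (psc > 0)
      img <- matrix(stats::rpois(length(img), img * psc) / psc,
                    n_px, n_px)
    if (gsd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, gsd), n_px, n_px)
    img[img < 0] <- 0

    # --- geometric ground-truth mask --------------------------------------
    centre <- bin_points(unlist(lapply(dense, `[[`, "x")),
                         unlist(lapply(dense, `[[`, "y")),
                         1, n_px, pixel_size_nm) > 0
    r_px <- ceiling(w / pixel_size_nm)
    mask <- EBImage::dilate(centre * 1, EBImage::makeBrush(2 * r_px + 1, "disc"))
    mask <- matrix(as.logical(mask), n_px, n_px)

    list(image = sted_image(img, pixel_size_nm, label = "synthetic"),
         ground_truth = list(layout = layout, rings = rings,
                             axon_mask = mask))
  })
}

#' Render a 1D profile of Gaussian peaks
#'
#' Samples a sum of Gaussian peaks on a regular pixel grid, optionally with
#' additive Gaussian noise — the fixture for the period-estimation module.
#'
#' @param peak_positions_nm sorted (ascending) peak centres, nm.
#' @param peak_sigma_nm Gaussian sigma of each peak (> 0).
#' @param pixel_size_nm sampling step, nm.
#' @param amplitude peak amplitude, arbitrary units.
#' @param noise_sd additive Gaussian noise sd (0 disables); noisy
#'   intensities are clamped at 0 (physical intensities are non-negative).
#' @param pad_nm flat margin added before the first and after the last
#'   peak (default 100 nm = 4 sigma at the default peak width: the minimal
#'   support carrying the full shape of the extreme peaks).
#' @param seed integer seed (`NULL`: current RNG state).
#' @return numeric vector of intensities; sample `i` (1-based) lies at
#'   position `(i - 1) * pixel_size_nm - pad_nm + peak_positions_nm[1]`.
#'   The position of sample 1 is stored in the `"origin_nm"` attribute.
#' @export
render_profile <- function(peak_positions_nm, peak_sigma_nm = 25,
                           pixel_size_nm = 20, amplitude = 100,
                           noise_sd = 0, pad_nm = 100, seed = NULL) {
  if (is.unsorted(peak_positions_nm, strictly = TRUE))
    stop("`peak_positions_nm` must be sorted ascending", call. = FALSE)
  assert_scalar_num(peak_sigma_nm, "peak_sigma_nm", 0, strict_lower = TRUE)
  with_seed_or_current(seed, {
    x0 <- min(peak_positions_nm) - pad_nm
    x1 <- max(peak_positions_nm) + pad_nm
    x <- seq(x0, x1, by = pixel_size_nm)
    v <- rowSums(vapply(peak_positions_nm, function(p) {
      amplitude * exp(-(x - p)^2 / (2 * peak_sigma_nm^2))
    }, numeric(length(x))))
    if (noise_sd > 0) {
      v <- v + stats::rnorm(length(v), 0, noise_sd)
      v[v < 0] <- 0
    }
    attr(v, "origin_nm") <- x0
    v
  })
}

#' Render a binary field of disjoint connected components
#'
#' Places one compact 8-connected component per requested pixel area on an
#' empty field, pairwise separated by at least 2 background pixels — the
#' fixture for fragmentation quantification.
#'
#' @param component_areas_px pixel areas of the components to place.
#' @param field_shape `c(rows, cols)` of the output.
#' @param seed integer seed (`NULL`: current RNG state).
#' @param max_tries placement retries per component before giving up.
#' @return logical matrix.
#' @export
render_fragment_field <- function(component_areas_px,
                                  field_shape = c(512, 512),
                                  seed = NULL, max_tries = 200) {
  nr <- field_shape[1]; nc <- field_shape[2]
  if (sum(component_areas_px) > 0.5 * nr * nc)
    stop("requested areas exceed 50% of the field", call. = FALSE)
  out <- matrix(FALSE, nr, nc)
  if (length(component_areas_px) == 0) return(out)
  with_seed_or_current(seed, {
    # occupancy grid including the 2 px clearance
    blocked <- matrix(FALSE, nr, nc)
    for (area in component_areas_px) {
      blob <- compact_blob(area)
      placed <- FALSE
      for (tr in seq_len(max_tries)) {
        r0 <- sample.int(nr - nrow(blob) + 1, 1)
        c0 <- sample.int(nc - ncol(blob) + 1, 1)
        rs <- r0:(r0 + nrow(blob) - 1); cs <- c0:(c0 + ncol(blob) - 1)
        rs2 <- max(1, r0 - 2):min(nr, r0 + nrow(blob) + 1)
        cs2 <- max(1, c0 - 2):min(nc, c0 + ncol(blob) + 1)
        if (!any(blocked[rs2, cs2])) {
          out[rs, cs] <- out[rs, cs] | blob
          blocked[rs, cs] <- blocked[rs, cs] | blob
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all components disjointly; reduce areas or ",
             "enlarge the field", call. = FALSE)
    }
    out
  })
}

# A filled, roughly circular blob of exactly `area` pixels (the `area`
# pixels nearest the disc centre; always 4- and 8-connected).
compact_blob <- function(area) {
  r <- ceiling(sqrt(area / pi)) + 1
  n <- 2 * r + 1
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  sel <- order(d2)[seq_len(area)]
  m <- matrix(FALSE, n, n)
  m[sel] <- TRUE
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}
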