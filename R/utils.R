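# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a fixed RNG seed, or under the current RNG state
#' @noRd
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%g, %g]", name, lower, upper), call. = FALSE)
  invisible(x)
}

# Circular median of axial data (angles modulo 180 degrees).  The angles are
# doubled so that 0 and 180 coincide, a circular mean fixes a reference
# direction, and the ordinary median is taken after unwrapping every angle
# into the half-turn centred on that reference.
axial_median <- function(angle_deg) {
  angle_deg <- angle_deg[is.finite(angle_deg)]
  if (length(angle_deg) == 0L) return(NA_real_)
  a2 <- angle_deg * pi / 90  # doubled angle in radians
  m <- atan2(mean(sin(a2)), mean(cos(a2))) * 90 / pi  # axis, in degrees
  d <- ((angle_deg - m + 90) %% 180) - 90
  (m + stats::median(d)) %% 180
}

# Label 8-connected foreground components of a logical/0-1 matrix.
# EBImage::bwlabel is 4-connected; components touching only diagonally are
# merged afterwards with a union-find pass over the label pairs.
label_components8 <- function(mask) {
  mask <- (mask > 0) * 1
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) > 0) {
    parent <- seq_len(nlab)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(root, sort(unique(root)))
    nz <- lab > 0
    lab[nz] <- relab[lab[nz]]
  }
  lab
}
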