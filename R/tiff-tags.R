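# Minimal TIFF tag surgery for physical pixel-size calibration.
#
# The `tiff` package reads XResolution/YResolution/ResolutionUnit but cannot
# write them, so after writing an image we rewrite its first image file
# directory (IFD) with the three resolution entries added. The pixel data
# and all existing tag payloads stay where they are; a new IFD (plus the two
# 8-byte RATIONAL payloads) is appended at the end of the file and the IFD
# pointer in the header is redirected to it.

tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
tiff_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
tiff_read_u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
tiff_read_u32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

# Append XResolution (282), YResolution (283) and ResolutionUnit (296, cm)
# tags encoding `pixel_size_nm` to the first IFD of a little-endian TIFF.
tiff_set_resolution <- function(path, pixel_size_nm) {
  f <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(f[1:2]) != "II")
    stop("only little-endian TIFF supported", call. = FALSE)
  ifd_off <- tiff_read_u32(f, 4)
  n <- tiff_read_u16(f, ifd_off)
  entries <- vector("list", n)
  tags <- integer(n)
  for (i in seq_len(n)) {
    e0 <- ifd_off + 2 + (i - 1) * 12
    entries[[i]] <- f[(e0 + 1):(e0 + 12)]
    tags[i] <- tiff_read_u16(f, e0)
  }
  next_ifd <- f[(ifd_off + 2 + n * 12 + 1):(ifd_off + 2 + n * 12 + 4)]
  keep <- !(tags %in% c(282L, 283L, 296L))
  entries <- entries[keep]
  tags <- tags[keep]

  # pixels per cm as a RATIONAL kept within signed-32-bit range
  res <- 1e7 / pixel_size_nm
  den <- max(1, floor((2^31 - 1) / res))
  den <- min(den, 1e6)
  num <- round(res * den)

  out_len <- length(f)
  if (out_len %% 2 == 1) { f <- c(f, as.raw(0)); out_len <- out_len + 1 }
  rat_off <- out_len                     # shared payload for X and Y
  f <- c(f, tiff_u32(num), tiff_u32(den))
  new_ifd_off <- rat_off + 8

  mk_entry <- function(tag, type, count, value4) {
    c(tiff_u16(tag), tiff_u16(type), tiff_u32(count), value4)
  }
  entries <- c(entries, list(
    mk_entry(282L, 5L, 1L, tiff_u32(rat_off)),     # XResolution, RATIONAL
    mk_entry(283L, 5L, 1L, tiff_u32(rat_off)),     # YResolution, RATIONAL
    mk_entry(296L, 3L, 1L, c(tiff_u16(3L), tiff_u16(0L)))  # unit = cm
  ))
  tags <- c(tags, 282L, 283L, 296L)
  ord <- order(tags)                      # IFD entries must be tag-sorted
  ifd <- c(tiff_u16(length(entries)),
           do.call(c, entries[ord]),
           next_ifd)
  f <- c(f, ifd)
  f[5:8] <- tiff_u32(new_ifd_off)
  writeBin(f, path)
  invisible(path)
}

# Physical pixel size (nm) from readTIFF() info attributes, or NULL when the
# file carries no usable calibration. Per the TIFF spec the default
# ResolutionUnit is inch.
tiff_resolution_to_nm <- function(info) {
  xres <- info$x.resolution
  if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
  unit <- info$resolution.unit %||% "inch"
  nm_per_unit <- switch(unit, cm = 1e7, inch = 2.54e7, NULL)
  if (is.null(nm_per_unit)) return(NULL)
  nm_per_unit / xres
}
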