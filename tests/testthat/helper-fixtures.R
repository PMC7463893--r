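# Fixtures built in code: small deterministic stacks, a hand-written
# minimal TIFF (for metadata-precedence checks independent of any TIFF
# writer), and brute-force oracles used across test files.

# A tiny stack whose channels are distinct constants: channel k has value
# 10 * k, so role -> plane addressing can be verified exactly.
constant_channel_stack <- function(shape = c(2, 8, 8),
                                   channels = c("dapi", "cea", "coll4",
                                                "marker"),
                                   voxel_size_um = c(1, 1, 1)) {
  vox <- array(0, c(shape, length(channels)))
  for (k in seq_along(channels)) vox[, , , k] <- 10 * k
  image_stack(vox, channels, voxel_size_um)
}

# Minimal single-page little-endian uncompressed 16-bit grayscale TIFF
# with an ImageDescription tag, written byte by byte. Used to test OME
# metadata parsing against a file this package's writer did not produce.
write_minimal_tiff_with_description <- function(path, m, description) {
  stopifnot(is.matrix(m), all(m == round(m)), max(m) <= 65535)
  h <- nrow(m); w <- ncol(m)
  desc <- c(charToRaw(description), as.raw(0))   # NUL-terminated ASCII
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0))
  data_off <- 8L
  data_len <- 2L * w * h
  desc_off <- data_off + data_len
  ifd_off <- desc_off + length(desc)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.integer(t(m)), con, size = 2, endian = "little")
  writeBin(desc, con)
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {            # SHORT: value left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(10L, con, size = 2, endian = "little")  # entry count
  entry(256, 3, 1, w)                  # ImageWidth
  entry(257, 3, 1, h)                  # ImageLength
  entry(258, 3, 1, 16)                 # BitsPerSample
  entry(259, 3, 1, 1)                  # Compression = none
  entry(262, 3, 1, 1)                  # Photometric = BlackIsZero
  entry(270, 2, length(desc), desc_off)  # ImageDescription
  entry(273, 4, 1, data_off)           # StripOffsets
  entry(277, 3, 1, 1)                  # SamplesPerPixel
  entry(278, 3, 1, h)                  # RowsPerStrip
  entry(279, 4, 1, data_len)           # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")   # next IFD
  invisible(path)
}

# Exhaustive Otsu oracle: direct recomputation of the between-class
# variance at every candidate split from the raw histogram counts.
otsu_oracle <- function(values, n_bins = 256) {
  v <- as.numeric(values)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  bin <- findInterval(v, edges, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best_k <- NA_integer_; best <- -Inf; ties <- integer()
  for (k in seq_len(n_bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    bcv <- (n0 / sum(counts)) * (n1 / sum(counts)) * (m0 - m1)^2
    if (bcv > best + 1e-12 * max(best, 1)) {
      best <- bcv; ties <- k
    } else if (abs(bcv - best) <= 1e-12 * max(abs(best), 1)) {
      ties <- c(ties, k)
    }
  }
  k <- ties[ceiling(length(ties) / 2)]
  edges[k + 1]
}

# Brute-force cube oracle: per-cube recount by explicit index arithmetic.
cube_oracle <- function(stack, mask, cube_shape = c(32, 32, 16),
                        min_fg_fraction = 0.5) {
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  d <- dim(m)
  cx <- cube_shape[1]; cy <- cube_shape[2]; cz <- cube_shape[3]
  out <- list()
  for (iz in 0:(d[1] %/% cz - 1)) for (iy in 0:(d[2] %/% cy - 1))
    for (ix in 0:(d[3] %/% cx - 1)) {
      n_fg <- 0; sums <- numeric(length(stack$channels))
      for (z in (iz * cz + 1):(iz * cz + cz))
        for (y in (iy * cy + 1):(iy * cy + cy))
          for (x in (ix * cx + 1):(ix * cx + cx))
            if (m[z, y, x]) {
              n_fg <- n_fg + 1
              for (ch in seq_along(stack$channels))
                sums[ch] <- sums[ch] + stack$voxels[z, y, x, ch]
            }
      out[[length(out) + 1]] <- list(ix = ix, iy = iy, iz = iz,
                                     n_fg = n_fg,
                                     frac = n_fg / (cx * cy * cz),
                                     included = n_fg / (cx * cy * cz) >
                                       min_fg_fraction,
                                     means = sums / n_fg)
    }
  out
}

# Direct textbook Pearson correlation (sum formula, no stats::cor).
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}
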