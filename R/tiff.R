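# Minimal baseline TIFF 6.0 I/O for 16-bit grayscale frames.
#
# Scope: uncompressed, single-sample, little-endian, one strip per page,
# multi-page. This covers exactly the frames the simulator writes and the
# analysis reads; it is not a general TIFF implementation.

u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

raw_to_u32 <- function(r, off) {
  sum(as.integer(r[off + 1:4]) * c(1, 256, 65536, 16777216))
}

raw_to_u16 <- function(r, off) {
  as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
}

u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

u16_raw <- function(v) as.raw(c(v %% 256L, v %/% 256L))

# one 12-byte IFD entry; type 3 = SHORT, 4 = LONG
ifd_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(u16_raw(value), as.raw(c(0, 0))) else u32_raw(value)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val)
}

#' Write 16-bit grayscale frames to a TIFF file
#'
#' Writes one or more count matrices as an uncompressed, little-endian,
#' 16-bit grayscale (multi-page) TIFF. Values are rounded and clipped to
#' \[0, 65535\].
#'
#' @param frames a matrix or list of matrices (rows = image rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  assert(length(frames) >= 1 && all(vapply(frames, is.matrix, logical(1))),
         "`frames` must be a matrix or list of matrices")
  sizes <- vapply(frames, length, numeric(1)) * 2
  data_off <- 8 + c(0, cumsum(sizes))[seq_along(frames)]
  ifd_size <- 2 + 9 * 12 + 4
  ifd_off <- 8 + sum(sizes) + (seq_along(frames) - 1) * ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16_raw(42L), u32_raw(ifd_off[1])), con)
  for (m in frames) {
    v <- pmin(pmax(round(as.vector(t(m))), 0), 65535)
    writeBin(u16_to_raw(v), con)
  }
  for (i in seq_along(frames)) {
    m <- frames[[i]]
    entries <- c(
      ifd_entry(256L, 3L, 1, ncol(m)),          # ImageWidth
      ifd_entry(257L, 3L, 1, nrow(m)),          # ImageLength
      ifd_entry(258L, 3L, 1, 16L),              # BitsPerSample
      ifd_entry(259L, 3L, 1, 1L),               # Compression = none
      ifd_entry(262L, 3L, 1, 1L),               # Photometric = BlackIsZero
      ifd_entry(273L, 4L, 1, data_off[i]),      # StripOffsets
      ifd_entry(277L, 3L, 1, 1L),               # SamplesPerPixel
      ifd_entry(278L, 3L, 1, nrow(m)),          # RowsPerStrip
      ifd_entry(279L, 4L, 1, sizes[i])          # StripByteCounts
    )
    nxt <- if (i < length(frames)) ifd_off[i + 1] else 0
    writeBin(c(u16_raw(9L), entries, u32_raw(nxt)), con)
  }
  invisible(path)
}

#' Read 16-bit grayscale frames from a TIFF file
#'
#' Reads uncompressed little-endian 16-bit grayscale TIFFs (single- or
#' multi-page, one strip per page) such as those written by
#' [write_tiff16()].
#'
#' @param path TIFF file path.
#' @return list of integer count matrices, one per page.
#' @export
read_tiff16 <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path),
         "toccsl_io_error")
  r <- readBin(path, "raw", n = file.info(path)$size)
  assert(length(r) > 8 && rawToChar(r[1:2]) == "II" && raw_to_u16(r, 2) == 42L,
         "not a little-endian TIFF file", "toccsl_io_error")
  ifd_off <- raw_to_u32(r, 4)
  frames <- list()
  while (ifd_off != 0) {
    n_ent <- raw_to_u16(r, ifd_off)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- raw_to_u16(r, base)
      type <- raw_to_u16(r, base + 2)
      val <- if (type == 3L) raw_to_u16(r, base + 8) else raw_to_u32(r, base + 8)
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    assert(all(need %in% names(tags)), "TIFF page missing required tags",
           "toccsl_io_error")
    assert(is.null(tags[["258"]]) || tags[["258"]] == 16L,
           "only 16-bit TIFF is supported", "toccsl_io_error")
    assert(is.null(tags[["259"]]) || tags[["259"]] == 1L,
           "only uncompressed TIFF is supported", "toccsl_io_error")
    w <- tags[["256"]]; h <- tags[["257"]]
    off <- tags[["273"]]; nb <- tags[["279"]]
    assert(nb == 2 * w * h, "unexpected strip size (multi-strip TIFF?)",
           "toccsl_io_error")
    strip <- r[off + seq_len(nb)]
    v <- readBin(strip, "integer", n = w * h, size = 2, signed = FALSE,
                 endian = "little")
    frames[[length(frames) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- raw_to_u32(r, ifd_off + 2 + n_ent * 12)
  }
  frames
}
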