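# Minimal baseline TIFF support: uncompressed grayscale 8/16-bit,
# multi-page, little- or big-endian read, little-endian write. Implemented
# here because no TIFF-capable R package ships with the target environment.

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("qicgfa_format_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(sprintf(...), class = c("qicgfa_validation_error", "error")))
}

rd_uint <- function(bytes, offset, n, size, endian) {
  if (offset + n * size - 1L > length(bytes)) {
    stop_format("TIFF appears truncated (read past end of file)")
  }
  chunk <- bytes[offset:(offset + n * size - 1L)]
  if (size == 4L) {
    v <- readBin(chunk, "integer", n = n, size = 4L, endian = endian, signed = TRUE)
    if (any(v < 0)) stop_format("TIFF offset exceeds supported range")
    v
  } else {
    readBin(chunk, "integer", n = n, size = size, endian = endian, signed = FALSE)
  }
}

# Reads one IFD; returns list(tags = named numeric vectors, next_offset)
read_ifd <- function(bytes, offset, endian) {
  n_entries <- rd_uint(bytes, offset, 1L, 2L, endian)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  for (i in seq_len(n_entries)) {
    base <- offset + 2L + (i - 1L) * 12L
    tag <- rd_uint(bytes, base, 1L, 2L, endian)
    typ <- rd_uint(bytes, base + 2L, 1L, 2L, endian)
    cnt <- rd_uint(bytes, base + 4L, 1L, 4L, endian)
    sz <- type_size[as.character(typ)]
    if (is.na(sz)) next  # rational / unknown types are not needed here
    total <- sz * cnt
    voff <- if (total <= 4L) base + 8L else rd_uint(bytes, base + 8L, 1L, 4L, endian) + 1L
    tags[[as.character(tag)]] <- rd_uint(bytes, voff, cnt, sz, endian)
  }
  nxt <- rd_uint(bytes, offset + 2L + n_entries * 12L, 1L, 4L, endian)
  list(tags = tags, next_offset = nxt)
}

tag_or <- function(tags, tag, default = NULL) {
  v <- tags[[as.character(tag)]]
  if (is.null(v)) default else v
}

# Returns list of numeric matrices (one per page), row-major pixel order
read_tiff_frames <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L) stop_format("not a TIFF: file too short")
  order_mark <- rawToChar(bytes[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop_format("not a TIFF: bad byte-order mark"))
  if (rd_uint(bytes, 3L, 1L, 2L, endian) != 42L) {
    stop_format("not a TIFF: magic number missing")
  }
  offset <- rd_uint(bytes, 5L, 1L, 4L, endian) + 1L
  frames <- list()
  while (offset > 1L) {
    ifd <- read_ifd(bytes, offset, endian)
    tg <- ifd$tags
    width <- tag_or(tg, 256); height <- tag_or(tg, 257)
    if (is.null(width) || is.null(height)) stop_format("TIFF page missing dimensions")
    bits <- tag_or(tg, 258, 1L)[1L]
    if (!bits %in% c(8L, 16L)) stop_format("unsupported TIFF bit depth: %d", bits)
    if (tag_or(tg, 259, 1L) != 1L) stop_format("compressed TIFF not supported")
    if (tag_or(tg, 277, 1L) != 1L) stop_format("only single-sample (grayscale) TIFF supported")
    strip_off <- tag_or(tg, 273); strip_cnt <- tag_or(tg, 279)
    if (is.null(strip_off) || is.null(strip_cnt)) stop_format("TIFF page missing strip layout")
    data <- raw(0)
    for (k in seq_along(strip_off)) {
      s <- strip_off[k] + 1L
      e <- strip_off[k] + strip_cnt[k]
      if (e > length(bytes)) stop_format("TIFF appears truncated (strip past end)")
      data <- c(data, bytes[s:e])
    }
    npx <- width * height
    if (length(data) < npx * (bits %/% 8L)) stop_format("TIFF strip data shorter than image")
    vals <- if (bits == 8L) {
      as.integer(data[seq_len(npx)])
    } else {
      readBin(data, "integer", n = npx, size = 2L, endian = endian, signed = FALSE)
    }
    frames[[length(frames) + 1L]] <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    offset <- ifd$next_offset + 1L
  }
  if (!length(frames)) stop_format("TIFF contains no images")
  frames
}

wr_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2L, endian = "little")
wr_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4L, endian = "little")

ifd_entry <- function(con, tag, type, count, value) {
  wr_u16(con, tag); wr_u16(con, type); wr_u32(con, count)
  if (type == 3L) { wr_u16(con, value); wr_u16(con, 0L) } else wr_u32(con, value)
}

u16_raw <- function(v) {
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

# frames: list of integer matrices; bits 8 or 16; little-endian output
write_tiff_frames <- function(frames, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop_validation("frames have mismatched dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  bpp <- bits %/% 8L
  frame_bytes <- h * w * bpp
  n <- length(frames)
  ifd_bytes <- 2L + 9L * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + n * frame_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); wr_u16(con, 42L); wr_u32(con, ifd_start)
  maxv <- 2^bits - 1
  for (f in frames) {
    v <- pmin(pmax(round(as.numeric(t(f))), 0), maxv)  # row-major order
    if (bits == 8L) writeBin(as.raw(v), con) else writeBin(u16_raw(as.integer(v)), con)
  }
  for (k in seq_len(n)) {
    wr_u16(con, 9L)
    ifd_entry(con, 256L, 4L, 1L, w)
    ifd_entry(con, 257L, 4L, 1L, h)
    ifd_entry(con, 258L, 3L, 1L, bits)
    ifd_entry(con, 259L, 3L, 1L, 1L)   # no compression
    ifd_entry(con, 262L, 3L, 1L, 1L)   # BlackIsZero
    ifd_entry(con, 273L, 4L, 1L, data_start + (k - 1L) * frame_bytes)
    ifd_entry(con, 277L, 3L, 1L, 1L)
    ifd_entry(con, 278L, 4L, 1L, h)
    ifd_entry(con, 279L, 4L, 1L, frame_bytes)
    wr_u32(con, if (k < n) ifd_start + k * ifd_bytes else 0L)
  }
  invisible(path)
}

# Mask PNG: any channel > 0.5 counts as inside
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
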