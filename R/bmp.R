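# Minimal BMP codec: writes 24-bit uncompressed BI_RGB; reads 8-bit
# palette, 24-bit and 32-bit uncompressed files. Rows are stored
# bottom-up and padded to 4-byte boundaries per the format.

bmp_u <- function(raw, off, size) {
  b <- as.integer(raw[off:(off + size - 1L)])
  sum(b * 256^(seq_along(b) - 1L))
}

read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54L || !identical(raw[1:2], charToRaw("BM")))
    stop_format(paste0("not a BMP file: ", path))
  data_off <- bmp_u(raw, 11L, 4L)
  header_size <- bmp_u(raw, 15L, 4L)
  if (header_size < 40L) stop_format(paste0("unsupported BMP header: ", path))
  w <- bmp_u(raw, 19L, 4L)
  h_raw <- bmp_u(raw, 23L, 4L)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- bmp_u(raw, 29L, 2L)
  compression <- bmp_u(raw, 31L, 4L)
  if (compression != 0) stop_format(paste0("compressed BMP unsupported: ", path))
  if (!bpp %in% c(8L, 24L, 32L))
    stop_format(paste0("unsupported BMP bit depth: ", bpp))

  if (bpp == 8L) {
    n_colors <- bmp_u(raw, 47L, 4L)
    if (n_colors == 0) n_colors <- 256
    pal_off <- 15L + header_size
    pal <- matrix(as.integer(raw[pal_off:(pal_off + 4L * n_colors - 1L)]),
                  ncol = 4L, byrow = TRUE)  # B,G,R,0
  }
  bytes_pp <- bpp %/% 8L
  stride <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  need <- data_off + stride * h
  if (length(raw) < need) stop_format(paste0("truncated BMP: ", path))

  rows <- if (top_down) seq_len(h) else rev(seq_len(h))
  if (bpp == 8L) {
    idx <- matrix(0L, h, w)
    for (i in seq_len(h)) {
      off <- data_off + (i - 1L) * stride
      idx[rows[i], ] <- as.integer(raw[(off + 1L):(off + w)])
    }
    rgb <- pal[idx + 1L, c(3L, 2L, 1L)]
    gray_pal <- all(pal[, 1] == pal[, 2] & pal[, 2] == pal[, 3])
    if (gray_pal) return(matrix(rgb[, 1], h, w))
    return(array(rgb, dim = c(h, w, 3L)))
  }
  img <- array(0, dim = c(h, w, 3L))
  for (i in seq_len(h)) {
    off <- data_off + (i - 1L) * stride
    row <- as.integer(raw[(off + 1L):(off + w * bytes_pp)])
    m <- matrix(row, ncol = bytes_pp, byrow = TRUE)  # B,G,R(,A)
    img[rows[i], , ] <- m[, c(3L, 2L, 1L)]
  }
  if (all(img[, , 1] == img[, , 2]) && all(img[, , 2] == img[, , 3]))
    return(img[, , 1])                   # grayscale stored as 24-bit
  img
}

write_bmp <- function(img, path) {
  check_image(img)
  h <- nrow(img); w <- ncol(img)
  if (is_gray_image(img)) {
    g <- img
    img <- array(0, dim = c(h, w, 3L))
    img[, , 1] <- g; img[, , 2] <- g; img[, , 3] <- g
  }
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  pad <- stride - w * 3L
  data_size <- stride * h
  u <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                  endian = "little")
  header <- c(charToRaw("BM"), u(54 + data_size, 4L), u(0L, 4L), u(54L, 4L),
              u(40L, 4L), u(w, 4L), u(h, 4L), u(1L, 2L), u(24L, 2L),
              u(0L, 4L), u(data_size, 4L), u(2835L, 4L), u(2835L, 4L),
              u(0L, 4L), u(0L, 4L))
  body <- raw(data_size)
  pos <- 0L
  imgi <- round(img)
  for (r in rev(seq_len(h))) {
    row_bgr <- as.raw(as.integer(t(imgi[r, , c(3L, 2L, 1L)])))
    body[(pos + 1L):(pos + w * 3L)] <- row_bgr
    pos <- pos + stride
  }
  writeBin(c(header, body), path)
  invisible(path)
}
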