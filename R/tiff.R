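# Minimal baseline TIFF codec: uncompressed, 8-bit, grayscale or RGB,
# chunky planar layout. Exists because calibration metadata lives in the
# TIFF X/Y-resolution tags and no pre-installed R package decodes TIFF.
# Little- and big-endian files are read; files are written little-endian
# with a single strip and resolution expressed in pixels per centimetre.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               spp = 277L, rows_per_strip = 278L, strip_bytes = 279L,
               xres = 282L, yres = 283L, planar = 284L, res_unit = 296L)

tiff_u <- function(raw, off, size, endian) {
  # unsigned integer at 1-based offset `off`
  b <- as.integer(raw[off:(off + size - 1L)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_along(b) - 1L))
}

tiff_read_values <- function(raw, entry_off, endian) {
  type  <- tiff_u(raw, entry_off + 2L, 2L, endian)
  count <- tiff_u(raw, entry_off + 4L, 4L, endian)
  size  <- switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L,
                  "4" = 4L, "5" = 8L, NA_integer_)
  if (is.na(size)) return(NULL)
  total <- size * count
  data_off <- if (total <= 4L) entry_off + 8L
              else tiff_u(raw, entry_off + 8L, 4L, endian) + 1L
  if (type == 2L) {                       # ASCII, NUL-terminated
    chars <- raw[data_off:(data_off + count - 1L)]
    return(rawToChar(chars[chars != as.raw(0)]))
  }
  if (type == 5L) {                       # RATIONAL
    vals <- vapply(seq_len(count) - 1L, function(i) {
      num <- tiff_u(raw, data_off + 8L * i, 4L, endian)
      den <- tiff_u(raw, data_off + 8L * i + 4L, 4L, endian)
      if (den == 0) NA_real_ else num / den
    }, numeric(1))
    return(vals)
  }
  vapply(seq_len(count) - 1L,
         function(i) tiff_u(raw, data_off + size * i, size, endian),
         numeric(1))
}

read_tiff_image <- function(path, metadata_only = FALSE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop_format(paste0("truncated TIFF: ", path))
  endian <- if (identical(raw[1:2], charToRaw("II"))) "little"
            else if (identical(raw[1:2], charToRaw("MM"))) "big"
            else stop_format(paste0("not a TIFF file: ", path))
  if (tiff_u(raw, 3L, 2L, endian) != 42L)
    stop_format(paste0("not a TIFF file: ", path))
  ifd <- tiff_u(raw, 5L, 4L, endian) + 1L
  if (ifd + 1L > length(raw)) stop_format(paste0("truncated TIFF: ", path))
  n_entries <- tiff_u(raw, ifd, 2L, endian)
  tags <- list()
  for (i in seq_len(n_entries) - 1L) {
    off <- ifd + 2L + 12L * i
    if (off + 11L > length(raw)) stop_format(paste0("truncated TIFF: ", path))
    tag <- tiff_u(raw, off, 2L, endian)
    name <- names(TIFF_TAGS)[match(tag, TIFF_TAGS)]
    if (!is.na(name)) tags[[name]] <- tiff_read_values(raw, off, endian)
  }
  meta <- list(xres = tags$xres[1], yres = tags$yres[1],
               res_unit = tags$res_unit[1], description = tags$description)
  if (metadata_only) return(meta)

  w <- as.integer(tags$width[1]); h <- as.integer(tags$length[1])
  if (is.null(w) || is.null(h) || is.na(w) || is.na(h))
    stop_format(paste0("TIFF missing image dimensions: ", path))
  if (!is.null(tags$compression) && tags$compression[1] != 1)
    stop_format(paste0("only uncompressed TIFF is supported: ", path))
  if (!is.null(tags$bits) && any(tags$bits != 8))
    stop_format(paste0("only 8-bit TIFF is supported: ", path))
  if (!is.null(tags$planar) && tags$planar[1] != 1)
    stop_format(paste0("only chunky-planar TIFF is supported: ", path))
  spp <- as.integer(tags$spp[1] %||% 1L)
  if (!spp %in% c(1L, 3L, 4L))
    stop_format(paste0("unsupported TIFF sample count: ", spp))

  offsets <- as.numeric(tags$strip_offsets)
  counts  <- as.numeric(tags$strip_bytes %||% (w * h * spp))
  if (length(counts) == 1L && length(offsets) > 1L)
    counts <- rep(counts / length(offsets), length(offsets))
  pix <- raw(0)
  for (i in seq_along(offsets)) {
    a <- offsets[i] + 1; b <- offsets[i] + counts[i]
    if (b > length(raw)) stop_format(paste0("truncated TIFF strip: ", path))
    pix <- c(pix, raw[a:b])
  }
  vals <- as.integer(pix)
  if (length(vals) < w * h * spp)
    stop_format(paste0("TIFF pixel data too short: ", path))
  vals <- vals[seq_len(w * h * spp)]
  img <- if (spp == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- aperm(array(vals, dim = c(spp, w, h)), c(3, 2, 1))
    arr[, , 1:3, drop = FALSE]
  }
  list(image = img, meta = meta)
}

tiff_raw_u <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

write_tiff_image <- function(img, path, mpp = NULL, description = NULL) {
  check_image(img)
  h <- nrow(img); w <- ncol(img)
  rgb <- is_rgb_image(img)
  spp <- if (rgb) 3L else 1L
  pix <- if (rgb) as.raw(as.integer(round(aperm(img, c(3, 2, 1)))))
         else as.raw(as.integer(round(t(img))))
  n_pix <- length(pix)
  if (n_pix %% 2L == 1L) pix <- c(pix, as.raw(0))  # word-align what follows

  # resolution: pixels per centimetre, stored as a rational; omitted
  # entirely when no calibration is supplied
  has_res <- !is.null(mpp)
  res_num <- if (has_res) round(10000 / mpp * 10000) else 0
  res_den <- 10000
  desc <- if (is.null(description)) NULL else {
    d <- c(charToRaw(description), as.raw(0))   # NUL-terminated ASCII
    if (length(d) %% 2L == 1L) d <- c(d, as.raw(0))
    d
  }

  aux_off <- 8L + n_pix + (n_pix %% 2L)
  bits_off <- aux_off                      # 3 shorts when RGB
  xres_off <- bits_off + if (rgb) 6L else 0L
  yres_off <- xres_off + if (has_res) 8L else 0L
  desc_off <- yres_off + if (has_res) 8L else 0L
  ifd_off  <- desc_off + if (is.null(desc)) 0L else length(desc)

  entry <- function(tag, type, count, value, offset = FALSE) {
    v <- if (offset) tiff_raw_u(value, 4L)
         else if (type == 3L) c(tiff_raw_u(value, 2L), as.raw(c(0, 0)))
         else tiff_raw_u(value, 4L)
    c(tiff_raw_u(tag, 2L), tiff_raw_u(type, 2L), tiff_raw_u(count, 4L), v)
  }
  entries <- list(
    entry(256L, 4L, 1L, w),
    entry(257L, 4L, 1L, h),
    if (rgb) entry(258L, 3L, 3L, bits_off, offset = TRUE)
    else     entry(258L, 3L, 1L, 8L),
    entry(259L, 3L, 1L, 1L),                       # no compression
    entry(262L, 3L, 1L, if (rgb) 2L else 1L),      # RGB / black-is-zero
    if (!is.null(desc)) entry(270L, 2L, length(desc), desc_off, offset = TRUE),
    entry(273L, 4L, 1L, 8L),                       # single strip at 8
    entry(277L, 3L, 1L, spp),
    entry(278L, 4L, 1L, h),
    entry(279L, 4L, 1L, n_pix),
    if (has_res) entry(282L, 5L, 1L, xres_off, offset = TRUE),
    if (has_res) entry(283L, 5L, 1L, yres_off, offset = TRUE),
    entry(284L, 3L, 1L, 1L),
    if (has_res) entry(296L, 3L, 1L, 3L)           # unit = centimetre
  )
  entries <- Filter(Negate(is.null), entries)
  # IFD entries must be sorted by tag; construction order already is.
  ifd <- c(tiff_raw_u(length(entries), 2L), do.call(c, entries),
           tiff_raw_u(0L, 4L))
  out <- c(charToRaw("II"), tiff_raw_u(42L, 2L), tiff_raw_u(ifd_off, 4L),
           pix,
           if (rgb) c(tiff_raw_u(8L, 2L), tiff_raw_u(8L, 2L), tiff_raw_u(8L, 2L)),
           if (has_res) c(tiff_raw_u(res_num, 4L), tiff_raw_u(res_den, 4L),
                          tiff_raw_u(res_num, 4L), tiff_raw_u(res_den, 4L)),
           desc,
           ifd)
  stopifnot(length(out) == ifd_off + length(ifd))
  writeBin(out, path)
  invisible(path)
}
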