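#' @name image-conventions
#' @title Image and coordinate conventions
#' @description
#' Images are plain base-R arrays of intensities in `[0, 255]`: a numeric
#' `H x W` matrix for grayscale, or an `H x W x 3` array for RGB. Binary
#' masks are logical `H x W` matrices with `TRUE` = foreground (cell
#' interior). All pixel coordinates are 0-based `(row, col)` with row 0 at
#' the top and row increasing downward, matching raster storage order.
NULL

is_rgb_image <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

is_gray_image <- function(img) is.matrix(img)

check_image <- function(img) {
  if (!is_rgb_image(img) && !is_gray_image(img))
    stop_domain("expected an H x W grayscale matrix or H x W x 3 RGB array")
  if (any(img < 0 | img > 255, na.rm = TRUE))
    stop_domain("image intensities must lie in [0, 255]")
  invisible(img)
}

image_shape <- function(img) dim(img)[1:2]

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_domain("expected a logical H x W mask matrix")
  invisible(mask)
}

#' Load a raster image
#'
#' Reads TIFF, PNG, JPEG or BMP into the package's array convention
#' (intensities 0-255; grayscale sources stay single-channel). The file
#' type is sniffed from the magic bytes, falling back to the extension.
#'
#' @param path Path to an image file.
#' @return Numeric `H x W` matrix or `H x W x 3` array with attribute
#'   `source_path`.
#' @seealso [write_image()], [read_mpp_metadata()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such image file: ", path))
  kind <- sniff_format(path)
  img <- tryCatch(
    switch(kind,
      png  = decode_png(path),
      jpeg = decode_jpeg(path),
      tiff = read_tiff_image(path)$image,
      bmp  = read_bmp(path),
      stop_format(paste0("unsupported image format: ", path))
    ),
    error = function(e) {
      if (inherits(e, "adiposize_format_error")) stop(e)
      stop_format(paste0("unreadable ", kind, " file: ", path,
                         " (", conditionMessage(e), ")"))
    })
  check_image(img)
  attr(img, "source_path") <- path
  img
}

decode_png <- function(path) {
  x <- png::readPNG(path)
  from_unit_image(x)
}

decode_jpeg <- function(path) {
  x <- jpeg::readJPEG(path)
  from_unit_image(x)
}

# png/jpeg packages use [0,1] doubles; alpha channels are dropped.
from_unit_image <- function(x) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 2L) x <- x[, , 1, drop = TRUE]       # gray + alpha
    else if (dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  }
  round(x * 255)
}

sniff_format <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L) {
    if (identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) return("png")
    if (identical(magic[1:2], as.raw(c(0xff, 0xd8)))) return("jpeg")
    if (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
        identical(magic[1:2], as.raw(c(0x4d, 0x4d)))) return("tiff")
    if (identical(magic[1:2], as.raw(c(0x42, 0x4d)))) return("bmp")
  }
  switch(tolower(tools::file_ext(path)),
         png = "png", jpg = , jpeg = "jpeg", tif = , tiff = "tiff",
         bmp = "bmp", "unknown")
}

#' Write a raster image
#'
#' Format is chosen from the file extension: `.png`, `.tif`/`.tiff`,
#' `.bmp` (all lossless) or `.jpg`/`.jpeg` (lossy, emits a warning).
#' TIFF output can embed a microns-per-pixel calibration in the standard
#' resolution tags so that [read_mpp_metadata()] recovers it.
#'
#' @param img Grayscale matrix or RGB array, intensities 0-255.
#' @param path Output path.
#' @param mpp Optional microns-per-pixel to embed (TIFF only).
#' @param description Optional free-text image description (TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, mpp = NULL, description = NULL) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(unit_image(img), path),
    tif = ,
    tiff = write_tiff_image(img, path, mpp = mpp, description = description),
    bmp = write_bmp(img, path),
    jpg = ,
    jpeg = {
      warning("JPEG is lossy; masks and label maps should use PNG/TIFF/BMP")
      jpeg::writeJPEG(unit_image(img), path, quality = 0.95)
    },
    stop_format(paste0("unsupported output extension: .", ext))
  )
  invisible(path)
}

unit_image <- function(img) {
  x <- img / 255
  attr(x, "source_path") <- NULL
  x
}

#' Read microns-per-pixel metadata from an image file
#'
#' Looks for a physical pixel size in, in order: the TIFF X/Y-resolution
#' tags (with their resolution unit), then a case-insensitive
#' `"<number> micron(s) per pixel"` / `"um/px"` phrase in the TIFF image
#' description. Other formats carry no supported calibration metadata.
#'
#' @param path Path to an image file.
#' @return A [calibration()] object, or `NULL` when no calibration
#'   metadata is present.
#' @details X and Y resolutions differing by more than 1% signal an
#'   anisotropic-pixel error, which this package does not support.
#' @export
read_mpp_metadata <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such image file: ", path))
  if (sniff_format(path) != "tiff") return(NULL)
  meta <- read_tiff_image(path, metadata_only = TRUE)
  if (!is.null(meta$xres) && !is.null(meta$yres) &&
      meta$xres > 0 && meta$yres > 0) {
    if (abs(meta$xres - meta$yres) / max(meta$xres, meta$yres) > 0.01)
      stop_domain(sprintf(
        "anisotropic pixels are unsupported (X %.6g vs Y %.6g px/unit)",
        meta$xres, meta$yres))
    unit_um <- switch(as.character(meta$res_unit %||% 2L),
                      "2" = 25400, "3" = 10000, NA_real_)  # inch / cm
    if (!is.na(unit_um)) return(calibration(unit_um / meta$xres))
  }
  if (!is.null(meta$description)) {
    m <- regmatches(meta$description, regexec(
      "([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)[[:space:]]*(microns? per pixel|µm/px|um/px|µm per pixel)",
      meta$description, ignore.case = TRUE))[[1]]
    if (length(m) >= 2L) return(calibration(as.numeric(m[2])))
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
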