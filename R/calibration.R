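#' Spatial calibration of a microscopy image
#'
#' A calibration ties pixel measurements to physical units. `mpp` is the
#' length of one pixel side in microns; `area_factor = mpp^2` converts a
#' pixel count into an area in square microns (um^2).
#'
#' @param mpp Microns per pixel, a single positive number.
#' @return An object of class `"calibration"`: a list with elements `mpp`
#'   and `area_factor`.
#' @examples
#' cal <- calibration(0.5)
#' cal$area_factor  # 0.25
#' @export
calibration <- function(mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop_domain("mpp must be a single positive finite number")
  structure(list(mpp = as.numeric(mpp), area_factor = as.numeric(mpp)^2),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4f microns/pixel (%.4f um^2/pixel)\n",
              x$mpp, x$area_factor))
  invisible(x)
}

#' Calibration factor from a measured scale bar
#'
#' The microns-per-pixel factor is the physical length of a reference line
#' (typically the slide's scale bar) divided by its length in pixels:
#' `mpp = length_microns / length_pixels`.
#'
#' @param length_pixels Length of the line in pixels (> 0).
#' @param length_microns Physical length of the same line in microns (> 0).
#' @return A [calibration()] object.
#' @examples
#' calibration_from_line(454.02, 400)  # 0.8810 microns/pixel
#' @export
calibration_from_line <- function(length_pixels, length_microns) {
  for (v in list(length_pixels, length_microns))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_domain("calibration line lengths must be single positive numbers")
  calibration(length_microns / length_pixels)
}

#' Euclidean distance between two pixel positions
#'
#' Positions are `(row, col)` pairs in the package-wide 0-based raster
#' convention (row increases downward). Used to measure a scale bar from
#' its two endpoints.
#'
#' @param p1,p2 Numeric length-2 vectors `(row, col)`.
#' @return Distance in pixels.
#' @export
pixel_distance <- function(p1, p2) {
  if (length(p1) != 2L || length(p2) != 2L)
    stop_domain("points must be (row, col) pairs")
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Convert a pixel count to physical area
#'
#' @param pixel_count Non-negative number of pixels.
#' @param cal A [calibration()] object.
#' @return Area in square microns: `pixel_count * cal$area_factor`.
#' @export
area_to_physical <- function(pixel_count, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(pixel_count < 0)) stop_domain("pixel_count must be non-negative")
  as.numeric(pixel_count) * cal$area_factor
}

# Classed conditions so callers (and the CLI) can distinguish user errors.
stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("adiposize_domain_error", "error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("adiposize_format_error", "error")))
}
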