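# Colour-range segmentation and fluorescent channel handling.

#' An inclusive RGB box
#'
#' Three independent inclusive intensity intervals, one per channel,
#' matching a three-slider colour picker. A pixel is selected iff all
#' three of its channel values fall inside their interval.
#'
#' @param r_lo,r_hi,g_lo,g_hi,b_lo,b_hi Bounds in `[0, 255]`, `lo <= hi`.
#' @return A list of class `"color_range"`.
#' @export
color_range <- function(r_lo = 0, r_hi = 255, g_lo = 0, g_hi = 255,
                        b_lo = 0, b_hi = 255) {
  v <- c(r_lo, r_hi, g_lo, g_hi, b_lo, b_hi)
  if (any(v < 0 | v > 255)) stop_domain("colour bounds must be in [0, 255]")
  if (r_lo > r_hi || g_lo > g_hi || b_lo > b_hi)
    stop_domain("each colour channel needs lo <= hi")
  structure(list(r = c(r_lo, r_hi), g = c(g_lo, g_hi), b = c(b_lo, b_hi)),
            class = "color_range")
}

#' Named default colour ranges
#'
#' Convenience presets for common stain targets (e.g. `"reddish_brown"`
#' for chromogenic DAB-like staining). These are tool defaults for a
#' starting point, not measured constants; tune the sliders per assay.
#'
#' @param name One of `names(color_presets())`.
#' @return A [color_range()]; with no argument, the named list of all
#'   presets.
#' @export
color_presets <- function(name) {
  presets <- list(
    reddish_brown = color_range(90, 200, 40, 110, 20, 90),
    purple        = color_range(80, 180, 40, 120, 120, 220),
    light_red     = color_range(180, 255, 80, 180, 80, 180)
  )
  if (missing(name)) return(presets)
  if (!name %in% names(presets))
    stop_domain(paste0("unknown colour preset: ", name))
  presets[[name]]
}

#' Select pixels inside an RGB range
#'
#' @param img `H x W x 3` RGB image.
#' @param range A [color_range()].
#' @return Logical mask, `TRUE` where all three channels are inside
#'   their inclusive bounds.
#' @export
mask_by_rgb_range <- function(img, range) {
  check_image(img)
  if (!is_rgb_image(img)) stop_domain("mask_by_rgb_range expects an RGB image")
  stopifnot(inherits(range, "color_range"))
  img[, , 1] >= range$r[1] & img[, , 1] <= range$r[2] &
  img[, , 2] >= range$g[1] & img[, , 2] <= range$g[2] &
  img[, , 3] >= range$b[1] & img[, , 3] <= range$b[2]
}

#' Area covered by a mask
#'
#' @param mask Logical mask.
#' @param cal Optional [calibration()] for physical area.
#' @return List with `percent` (100 x foreground / total pixels),
#'   `pixels`, and `area_um2` (`NA` when uncalibrated).
#' @export
area_percentage <- function(mask, cal = NULL) {
  check_mask(mask)
  n_fg <- sum(mask)
  list(percent = 100 * n_fg / length(mask),
       pixels = n_fg,
       area_um2 = if (is.null(cal)) NA_real_ else area_to_physical(n_fg, cal))
}

#' Split or combine fluorescent colour channels
#'
#' Each selected channel contributes a binary mask (`intensity >
#' display_threshold`); the rendering paints every selected channel at
#' full, uniform intensity where its mask is true and leaves everything
#' else black, matching the flat single-colour display used for
#' fluorescent review. Renderings can be written with [write_image()]
#' and re-loaded as new session images.
#'
#' @param img `H x W x 3` RGB image.
#' @param channels Character subset of `c("red", "green", "blue")`
#'   (initials accepted), non-empty.
#' @param display_threshold Membership cutoff, 0-255 (default 0: any
#'   nonzero intensity counts).
#' @return List with `rendering` (RGB image) and `masks` (named list of
#'   logical masks, one per selected channel).
#' @export
extract_channels <- function(img, channels, display_threshold = 0) {
  check_image(img)
  if (!is_rgb_image(img)) stop_domain("extract_channels expects an RGB image")
  full <- c(r = "red", g = "green", b = "blue")
  channels <- unname(full[match(substr(tolower(channels), 1, 1), names(full))])
  if (!length(channels) || anyNA(channels) || any(duplicated(channels)))
    stop_domain("channels must be a non-empty subset of red/green/blue")
  if (display_threshold < 0 || display_threshold > 255)
    stop_domain("display_threshold must be in [0, 255]")
  plane <- c(red = 1L, green = 2L, blue = 3L)
  masks <- lapply(channels, function(ch) img[, , plane[[ch]]] > display_threshold)
  names(masks) <- channels
  rendering <- array(0, dim = dim(img))
  for (ch in channels) rendering[, , plane[[ch]]][masks[[ch]]] <- 255
  list(rendering = rendering, masks = masks)
}

#' Render a mask as a black and white image
#'
#' @param mask Logical mask.
#' @return Grayscale image: foreground 255, background 0.
#' @export
convert_black_white <- function(mask) {
  check_mask(mask)
  matrix(ifelse(mask, 255, 0), nrow(mask), ncol(mask))
}
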