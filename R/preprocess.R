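#' Preprocessing parameters for cell detection
#'
#' Bundles the conditioning knobs applied before contour tracing, in the
#' order they run: haze removal, dot-noise removal, grayscale conversion,
#' thresholding, and border-line thickening.
#'
#' @param dehaze_strength Fraction in `[0, 1]`; 0 disables haze removal.
#' @param denoise_radius Median-filter radius in pixels (>= 0); window is
#'   a square of side `2 * radius + 1`. 0 disables.
#' @param threshold `"auto"` (Otsu) or an integer 0-255. Pixels strictly
#'   above the threshold become foreground.
#' @param border_thickness Border-thickening radius in pixels (>= 0),
#'   applied as erosion of the foreground.
#' @param invert Flip foreground polarity, for stains whose cell
#'   interiors are darker than the membranes.
#' @return A list of class `"preprocess_params"`.
#' @export
preprocess_params <- function(dehaze_strength = 0, denoise_radius = 0,
                              threshold = "auto", border_thickness = 0,
                              invert = FALSE) {
  if (dehaze_strength < 0 || dehaze_strength > 1)
    stop_domain("dehaze_strength must be in [0, 1]")
  if (denoise_radius < 0) stop_domain("denoise_radius must be >= 0")
  if (border_thickness < 0) stop_domain("border_thickness must be >= 0")
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 255))
    stop_domain("threshold must be \"auto\" or a number in [0, 255]")
  structure(list(dehaze_strength = dehaze_strength,
                 denoise_radius = as.integer(denoise_radius),
                 threshold = threshold,
                 border_thickness = as.integer(border_thickness),
                 invert = isTRUE(invert)),
            class = "preprocess_params")
}

#' Convert an RGB image to grayscale
#'
#' Uses the standard luma weights `0.299 R + 0.587 G + 0.114 B`, rounded
#' to integers. Grayscale input is returned unchanged.
#'
#' @param img Image array (see [image-conventions]).
#' @return `H x W` numeric matrix.
#' @export
to_grayscale <- function(img) {
  check_image(img)
  if (is_gray_image(img)) return(img)
  g <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  attr(g, "source_path") <- attr(img, "source_path")
  g
}

#' Remove uniform haze from a micrograph
#'
#' Dark-channel-prior style veil removal. The atmospheric (veiling) light
#' `A` is estimated as the mean colour of the brightest 0.1% of the
#' per-pixel channel-minimum map; the transmission is
#' `t = 1 - strength * darkA` (where `darkA` is the dark channel of the
#' image normalised by `A`), floored at 0.1; the scene radiance
#' `(I - A) / t + A` is recovered per channel and clipped to `[0, 255]`.
#' `strength = 0` returns the input unchanged, and a structureless
#' (uniform) image stays uniform at any strength.
#'
#' @param img Image array.
#' @param strength Fraction in `[0, 1]` of the veil to remove.
#' @return Image of the same shape.
#' @export
dehaze <- function(img, strength) {
  check_image(img)
  if (strength < 0 || strength > 1) stop_domain("strength must be in [0, 1]")
  if (strength == 0) return(img)
  channels <- if (is_rgb_image(img)) lapply(1:3, function(k) img[, , k])
              else list(img)
  dark <- Reduce(pmin, channels)
  n_top <- max(1L, ceiling(length(dark) * 0.001))
  top <- order(dark, decreasing = TRUE)[seq_len(n_top)]
  A <- vapply(channels, function(ch) max(mean(ch[top]), 1), numeric(1))
  darkA <- Reduce(pmin, Map(function(ch, a) ch / a, channels, A))
  t_map <- pmax(1 - strength * pmin(darkA, 1), 0.1)
  out_ch <- Map(function(ch, a) {
    pmin(pmax(round((ch - a) / t_map + a), 0), 255)
  }, channels, A)
  if (is_rgb_image(img)) {
    out <- array(0, dim = dim(img))
    for (k in 1:3) out[, , k] <- out_ch[[k]]
    out
  } else out_ch[[1]]
}

#' Remove dot noise with a median filter
#'
#' Square window of side `2 * radius + 1`, edge pixels handled by
#' replicate padding. Removes dust specks and similar isolated dots
#' while preserving membranes wider than the window's minority limit.
#' `radius = 0` is the identity.
#'
#' @param img Image array (RGB filtered per channel).
#' @param radius Window radius in pixels.
#' @return Image of the same shape.
#' @export
denoise <- function(img, radius) {
  check_image(img)
  if (radius < 0) stop_domain("radius must be >= 0")
  radius <- as.integer(radius)
  if (radius == 0L) return(img)
  if (is_rgb_image(img)) {
    out <- array(0, dim = dim(img))
    for (k in 1:3) out[, , k] <- median_filter(img[, , k], radius)
    return(out)
  }
  median_filter(img, radius)
}

median_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h + 2L * r) - r, 1L), h)
  ci <- pmin(pmax(seq_len(w + 2L * r) - r, 1L), w)
  pad <- m[ri, ci, drop = FALSE]
  k <- (2L * r + 1L)^2
  stack <- matrix(0, nrow = h * w, ncol = k)
  j <- 0L
  for (dr in 0:(2L * r)) for (dc in 0:(2L * r)) {
    j <- j + 1L
    stack[, j] <- as.vector(pad[(1L + dr):(h + dr), (1L + dc):(w + dc)])
  }
  med <- apply(stack, 1L, stats::median)
  matrix(med, h, w)
}

#' Otsu threshold of a grayscale image
#'
#' Chooses the integer threshold maximising the between-class variance of
#' the intensity histogram. When several thresholds tie (a plateau), the
#' plateau midpoint is returned, so a two-level image is split between
#' its levels.
#'
#' @param gray `H x W` matrix of intensities 0-255.
#' @return Integer threshold in `[0, 254]`; pixels `> threshold` are
#'   foreground.
#' @export
otsu_threshold <- function(gray) {
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  total <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)                # pixels <= t
  sum0 <- cumsum(counts * levels)
  mu_total <- sum0[256]
  t_idx <- 1:255                      # thresholds 0..254
  w0t <- w0[t_idx]; w1t <- total - w0t
  valid <- w0t > 0 & w1t > 0
  if (!any(valid)) return(127L)       # constant image: arbitrary midpoint
  mu0 <- sum0[t_idx] / w0t
  mu1 <- (mu_total - sum0[t_idx]) / w1t
  between <- w0t * w1t * (mu0 - mu1)^2
  between[!valid] <- -Inf
  best <- which(between == max(between))
  as.integer(round(mean(best - 1L)))
}

#' Binarize a grayscale image
#'
#' Foreground is `gray > threshold`, XOR the `invert` flag. With the
#' default polarity, bright cell interiors become foreground and dark
#' membranes become background, which is what the contour tracer expects.
#'
#' @param gray `H x W` grayscale matrix.
#' @param threshold `"auto"` for [otsu_threshold()], or a number 0-255.
#' @param invert Flip polarity.
#' @return Logical `H x W` mask.
#' @export
binarize <- function(gray, threshold = "auto", invert = FALSE) {
  if (!is_gray_image(gray)) stop_domain("binarize expects a grayscale matrix")
  t_val <- if (identical(threshold, "auto")) otsu_threshold(gray)
           else as.numeric(threshold)
  mask <- gray > t_val
  if (isTRUE(invert)) mask <- !mask
  attr(mask, "threshold") <- t_val
  mask
}

#' Thicken border lines of a binary mask
#'
#' Erodes the foreground by a disc of the given radius, which is the same
#' as dilating the background membrane lines. Thicker borders seal small
#' breaks so that neighbouring cells stop merging, at the cost of
#' reducing each cell's measured area. The image frame is not treated as
#' a border line: out-of-frame pixels are taken as copies of the edge
#' pixels, so frame-touching cells keep touching the frame.
#'
#' @param mask Logical `H x W` mask.
#' @param thickness Erosion radius in pixels (>= 0); 0 is the identity.
#' @return Logical mask of the same shape with foreground a subset of the
#'   input foreground.
#' @export
thicken_borders <- function(mask, thickness) {
  check_mask(mask)
  if (thickness < 0) stop_domain("thickness must be >= 0")
  thickness <- as.integer(thickness)
  if (thickness == 0L) return(mask)
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dr in -thickness:thickness) for (dc in -thickness:thickness) {
    if (dr == 0L && dc == 0L) next
    if (dr * dr + dc * dc > thickness * thickness) next
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    out <- out & mask[ri, ci, drop = FALSE]
  }
  out
}

#' Export a mask for manual border correction, and read it back
#'
#' `export_for_edit()` writes the mask as a lossless black/white image
#' (0 = border/background, 255 = cell interior) that can be opened in any
#' paint program to connect broken membranes by drawing black strokes.
#' `import_edited()` re-binarizes the edited file (any pixel < 128 counts
#' as border/background) and checks the shape still matches.
#'
#' @param mask Logical mask.
#' @param path File path; PNG, BMP or TIFF for a lossless round trip.
#' @param expected_shape `(H, W)` the edited image must have.
#' @return `import_edited()` returns the re-binarized logical mask.
#' @export
export_for_edit <- function(mask, path) {
  check_mask(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg"))
    warning("JPEG is lossy; the re-imported mask may differ from the export")
  write_image(convert_black_white(mask), path)
}

#' @rdname export_for_edit
#' @export
import_edited <- function(path, expected_shape) {
  img <- to_grayscale(load_image(path))
  if (!identical(as.integer(dim(img)), as.integer(expected_shape)))
    stop_domain(sprintf(
      "edited image is %d x %d but %d x %d was expected",
      nrow(img), ncol(img), expected_shape[1], expected_shape[2]))
  img >= 128
}
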