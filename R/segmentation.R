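# Contour-based object detection on binary masks.
#
# Foreground is 8-connected (background 4-connected), so a diagonal break
# in a membrane does not split a cell in two. Only external boundaries
# are traced: interior holes neither create objects nor contribute to an
# object's pixel count.

# Clockwise Moore neighbourhood in (row, col) with row increasing downward.
MOORE_DIRS <- matrix(c(0, 1,   1, 1,   1, 0,   1, -1,
                       0, -1, -1, -1, -1, 0,  -1, 1),
                     ncol = 2, byrow = TRUE)

# delta (row, col) in {-1,0,1}^2 -> direction index
MOORE_INDEX <- local({
  m <- matrix(NA_integer_, 3, 3)
  for (k in 1:8) m[MOORE_DIRS[k, 1] + 2L, MOORE_DIRS[k, 2] + 2L] <- k
  m
})

#' Label 8-connected foreground components
#'
#' Breadth-first flood fill; labels `1..N` are assigned in raster-scan
#' order (top row first, left to right) of each component's first pixel.
#'
#' @param mask Logical `H x W` mask.
#' @return Integer `H x W` matrix, 0 = background.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  r0 <- (fg - 1L) %% h
  c0 <- (fg - 1L) %/% h
  seeds <- fg[order(r0, c0)]
  lab <- 0L
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      fr <- (frontier - 1L) %% h
      fc <- (frontier - 1L) %/% h
      nxt <- integer(0)
      for (k in 1:8) {
        nr <- fr + MOORE_DIRS[k, 1]
        nc <- fc + MOORE_DIRS[k, 2]
        ok <- nr >= 0L & nr < h & nc >= 0L & nc < w
        idx <- nr[ok] + nc[ok] * h + 1L
        idx <- idx[mask[idx] & labels[idx] == 0L]
        if (length(idx)) {
          labels[idx] <- lab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- nxt
    }
  }
  labels
}

# Moore border following from the component's raster-first pixel
# (whose west and whole top arc are guaranteed background). `fgmat` is a
# logical matrix restricted to one component. Jacob's stopping criterion:
# stop on re-entering the start pixel with the starting backtrack.
# 1-based coordinates in and out.
trace_boundary <- function(fgmat, sr, sc) {
  h <- nrow(fgmat); w <- ncol(fgmat)
  fg <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && fgmat[r, c]
  has_nb <- FALSE
  for (k in 1:8)
    if (fg(sr + MOORE_DIRS[k, 1], sc + MOORE_DIRS[k, 2])) { has_nb <- TRUE; break }
  if (!has_nb) return(matrix(c(sr, sc), ncol = 2))

  advance <- function(cur, b) {
    d <- MOORE_INDEX[b[1] - cur[1] + 2L, b[2] - cur[2] + 2L]
    prev <- b
    for (i in 1:8) {
      k <- (d + i - 1L) %% 8L + 1L      # clockwise, starting after backtrack
      cand <- cur + MOORE_DIRS[k, ]
      if (fg(cand[1], cand[2])) return(list(cur = cand, b = prev))
      prev <- cand
    }
    NULL                                # isolated pixel; excluded above
  }
  start <- c(sr, sc)
  first <- advance(start, c(sr, sc - 1L))
  second <- first$cur
  boundary <- vector("list", 64L)
  boundary[[1L]] <- start
  n_pts <- 1L
  cur <- first$cur; b <- first$b
  max_iter <- 8L * h * w + 16L
  for (iter in seq_len(max_iter)) {
    if (cur[1] == start[1] && cur[2] == start[2]) {
      # Jacob's criterion: closed once the next move re-enters the
      # second chain pixel from the start
      peek <- advance(cur, b)
      if (peek$cur[1] == second[1] && peek$cur[2] == second[2]) break
    }
    n_pts <- n_pts + 1L
    if (n_pts > length(boundary))
      boundary <- c(boundary, vector("list", length(boundary)))
    boundary[[n_pts]] <- cur
    nx <- advance(cur, b)
    cur <- nx$cur; b <- nx$b
  }
  do.call(rbind, boundary[seq_len(n_pts)])
}

#' Compress a boundary chain to line endpoints
#'
#' Replaces each maximal run of identical unit steps in a closed
#' 8-connected boundary chain with the run's two endpoints, so an
#' axis-aligned rectangle keeps only its 4 corners. The compression is
#' lossless: [decompress_chain()] reproduces the original point sequence.
#'
#' @param boundary `m x 2` matrix of `(row, col)` boundary points in
#'   traversal order (closed implicitly, last connects to first).
#' @return Matrix of retained vertices, in the same order.
#' @export
compress_chain <- function(boundary) {
  if (!is.matrix(boundary) || ncol(boundary) != 2L)
    stop_domain("boundary must be an m x 2 matrix")
  m <- nrow(boundary)
  if (m <= 2L) return(boundary)
  step <- boundary[c(2:m, 1L), , drop = FALSE] - boundary
  prev <- step[c(m, 1:(m - 1L)), , drop = FALSE]
  corner <- step[, 1] != prev[, 1] | step[, 2] != prev[, 2]
  if (!any(corner)) corner[1L] <- TRUE
  boundary[corner, , drop = FALSE]
}

#' @rdname compress_chain
#' @param vertices Output of `compress_chain()`.
#' @return `decompress_chain()` returns the full cyclic point sequence,
#'   starting from the first vertex.
#' @export
decompress_chain <- function(vertices) {
  m <- nrow(vertices)
  if (m == 1L) return(vertices)
  pts <- vector("list", m)
  for (i in seq_len(m)) {
    a <- vertices[i, ]
    b <- vertices[if (i == m) 1L else i + 1L, ]
    n <- max(abs(b - a))
    stepv <- sign(b - a)
    k <- seq_len(n) - 1L               # include a, exclude b
    pts[[i]] <- cbind(a[1] + k * stepv[1], a[2] + k * stepv[2])
  }
  out <- do.call(rbind, pts)
  dimnames(out) <- NULL
  out
}

#' Trace the external contours of a binary mask
#'
#' One contour per 8-connected foreground component, outer boundary only
#' (interior holes are ignored), reported in raster-scan order of the
#' component's first pixel. Each contour carries its compressed vertex
#' chain, bounding box, component pixel count and a frame-contact flag.
#' All coordinates are 0-based `(row, col)`.
#'
#' @param mask Logical `H x W` mask.
#' @return List of `"cell_contour"` objects with fields `vertices`,
#'   `bbox` (`min_row, min_col, max_row, max_col`), `pixel_count`,
#'   `touches_frame`, `start`, `label`.
#' @export
trace_external_contours <- function(mask) {
  check_mask(mask)
  labels <- label_components(mask)
  contours_from_labels(labels, nrow(mask), ncol(mask))
}

contours_from_labels <- function(labels, h, w) {
  n <- max(labels)
  if (n == 0L) return(list())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(labels == k)
    rr <- (idx - 1L) %% h + 1L
    cc <- (idx - 1L) %/% h + 1L
    first <- order(rr, cc)[1L]
    comp <- matrix(FALSE, h, w)
    comp[idx] <- TRUE
    chain <- trace_boundary(comp, rr[first], cc[first])
    out[[k]] <- structure(list(
      vertices = compress_chain(chain) - 1L,
      bbox = c(min_rr <- min(rr) - 1L, min(cc) - 1L,
               max(rr) - 1L, max(cc) - 1L),
      pixel_count = length(idx),
      touches_frame = any(rr == 1L | rr == h | cc == 1L | cc == w),
      start = c(rr[first] - 1L, cc[first] - 1L),
      label = k
    ), class = "cell_contour")
  }
  out
}

#' Pixel area of a traced object
#'
#' Counts the foreground pixels of the contour's connected component
#' (boundary and interior; holes excluded) by flood fill from the
#' contour's start pixel.
#'
#' @param contour A `"cell_contour"`.
#' @param mask The mask the contour was traced from.
#' @return Integer pixel count; also cached on the returned contour's
#'   `pixel_count` field when reassigned by the caller.
#' @export
contour_pixel_area <- function(contour, mask) {
  check_mask(mask)
  h <- nrow(mask)
  seed <- contour$start[1] + contour$start[2] * h + 1L
  if (!mask[seed]) stop_domain("contour start pixel is background in this mask")
  seen <- matrix(FALSE, h, ncol(mask))
  seen[seed] <- TRUE
  frontier <- seed
  count <- 1L
  w <- ncol(mask)
  while (length(frontier)) {
    fr <- (frontier - 1L) %% h
    fc <- (frontier - 1L) %/% h
    nxt <- integer(0)
    for (k in 1:8) {
      nr <- fr + MOORE_DIRS[k, 1]
      nc <- fc + MOORE_DIRS[k, 2]
      ok <- nr >= 0L & nr < h & nc >= 0L & nc < w
      idx <- nr[ok] + nc[ok] * h + 1L
      idx <- idx[mask[idx] & !seen[idx]]
      if (length(idx)) {
        seen[idx] <- TRUE
        count <- count + length(idx)
        nxt <- c(nxt, idx)
      }
    }
    frontier <- nxt
  }
  count
}

#' Detect cells in a calibrated image
#'
#' Runs the full counting pipeline: grayscale conversion, haze removal,
#' median denoising, thresholding, border thickening, then external
#' contour tracing and per-object pixel counting. Every detected object
#' starts out included; use the filter functions to curate.
#'
#' @param img Image array.
#' @param cal A [calibration()].
#' @param params A [preprocess_params()].
#' @return A `"cell_population"`: list with `cells` (data frame: `id`,
#'   `area_px`, `area_um2`, `touches_frame`, `included`,
#'   `exclusion_reason`), `contours`, `calibration`, `image_shape`, and
#'   the integer label map `labels`.
#' @export
detect_cells <- function(img, cal, params = preprocess_params()) {
  check_image(img)
  stopifnot(inherits(cal, "calibration"), inherits(params, "preprocess_params"))
  g <- to_grayscale(img)
  g <- dehaze(g, params$dehaze_strength)
  g <- denoise(g, params$denoise_radius)
  mask <- binarize(g, params$threshold, params$invert)
  mask <- thicken_borders(mask, params$border_thickness)
  labels <- label_components(mask)
  contours <- contours_from_labels(labels, nrow(mask), ncol(mask))
  n <- length(contours)
  area_px <- vapply(contours, `[[`, numeric(1), "pixel_count")
  cells <- data.frame(
    id = seq_len(n),
    area_px = as.integer(area_px),
    area_um2 = area_to_physical(area_px, cal),
    touches_frame = vapply(contours, `[[`, logical(1), "touches_frame"),
    included = rep(TRUE, n),
    exclusion_reason = rep("none", n),
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, contours = contours, calibration = cal,
                 image_shape = c(nrow(mask), ncol(mask)), labels = labels,
                 mask = mask),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  inc <- x$cells$included
  cat(sprintf(
    "<cell_population> %d objects, %d included; included area %.1f um^2 (mpp %.4f)\n",
    nrow(x$cells), sum(inc), sum(x$cells$area_um2[inc]), x$calibration$mpp))
  invisible(x)
}

#' Label map of a population
#'
#' Integer image in which background is 0 and each pixel of cell *k*
#' carries value *k*, mirroring a numbered segmentation overlay. Useful
#' for visual audit; write it with [write_image()] after scaling.
#'
#' @param pop A `"cell_population"`.
#' @param included_only Zero out cells currently excluded.
#' @return Integer `H x W` matrix.
#' @export
label_map <- function(pop, included_only = FALSE) {
  stopifnot(inherits(pop, "cell_population"))
  labels <- pop$labels
  if (included_only) {
    drop <- pop$cells$id[!pop$cells$included]
    labels[labels %in% drop] <- 0L
  }
  labels
}
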