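# Synthetic adipose-tissue-like images with exact ground truth, so every
# pipeline stage is testable without real slides. All randomness flows
# from a single integer seed; the same parameters always produce
# bit-identical images.

#' Parameters for the synthetic tissue generators
#'
#' @param shape `(H, W)` image size in pixels.
#' @param n_cells Number of cells in a Voronoi mosaic.
#' @param membrane_width Membrane line width in pixels.
#' @param gap_fraction Fraction of membrane pixels deleted in random
#'   patches, simulating light or broken cell borders.
#' @param haze Fraction in `[0, 1]` of uniform white veil to blend in.
#' @param n_dust Number of dust specks to stamp.
#' @param dust_radius Speck radius in pixels (<= 2).
#' @param scratch Draw one long thin bright scratch.
#' @param scratch_row Row (0-based) of the scratch centreline; default
#'   mid-image.
#' @param interior_mean,interior_jitter Cell-interior intensity mean and
#'   half-range of its uniform jitter.
#' @param membrane_mean,membrane_jitter Membrane/background intensity
#'   mean and jitter half-range.
#' @param mpp Microns per pixel recorded in the ground truth (and in the
#'   TIFF tag when the image is written).
#' @param rng_seed Integer seed fixing all randomness.
#' @return A list of class `"fixture_params"`.
#' @export
fixture_params <- function(shape = c(192L, 192L), n_cells = 50L,
                           membrane_width = 3L, gap_fraction = 0,
                           haze = 0, n_dust = 0L, dust_radius = 1L,
                           scratch = FALSE, scratch_row = NULL,
                           interior_mean = 230, interior_jitter = 10,
                           membrane_mean = 40, membrane_jitter = 10,
                           mpp = 1, rng_seed = 1L) {
  for (f in c(gap_fraction, haze))
    if (f < 0 || f > 1) stop_domain("fractions must be in [0, 1]")
  if (dust_radius > 2L) stop_domain("dust specks are at most 2 px in radius")
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 membrane_width = as.integer(membrane_width),
                 gap_fraction = gap_fraction, haze = haze,
                 n_dust = as.integer(n_dust),
                 dust_radius = as.integer(dust_radius),
                 scratch = isTRUE(scratch), scratch_row = scratch_row,
                 interior_mean = interior_mean,
                 interior_jitter = interior_jitter,
                 membrane_mean = membrane_mean,
                 membrane_jitter = membrane_jitter,
                 mpp = mpp, rng_seed = as.integer(rng_seed)),
            class = "fixture_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

jitter_intensity <- function(n, mean, half_range) {
  pmin(pmax(round(mean + stats::runif(n, -half_range, half_range)), 0), 255)
}

ground_truth <- function(cells, label_map, mpp, artifacts = list()) {
  structure(list(n_cells = nrow(cells), cells = cells,
                 label_map = label_map, mpp = mpp, artifacts = artifacts),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells, %d interior px, artifacts: %s\n",
              x$n_cells, sum(x$cells$pixel_count),
              if (length(x$artifacts)) paste(names(x$artifacts), collapse = ", ")
              else "none"))
  invisible(x)
}

# relabel ground-truth cells 1..n in raster-scan order of each cell's
# first interior pixel, the same order detection reports objects
relabel_raster <- function(label_map) {
  h <- nrow(label_map)
  idx <- which(label_map > 0L)
  r <- (idx - 1L) %% h
  c <- (idx - 1L) %/% h
  lab_sorted <- label_map[idx][order(r, c)]
  first_rank <- tapply(seq_along(lab_sorted), lab_sorted, min)
  old_order <- as.integer(names(sort(first_rank)))
  new <- integer(max(label_map))
  new[old_order] <- seq_along(old_order)
  out <- label_map
  out[idx] <- new[label_map[idx]]
  out
}

gt_cells_from_labels <- function(label_map) {
  h <- nrow(label_map); w <- ncol(label_map)
  ids <- sort(unique(label_map[label_map > 0L]))
  cells <- lapply(ids, function(k) {
    idx <- which(label_map == k)
    r <- (idx - 1L) %% h
    c <- (idx - 1L) %/% h
    data.frame(id = k, pixel_count = length(idx),
               touches_frame = any(r == 0L | r == h - 1L |
                                   c == 0L | c == w - 1L),
               centroid_row = mean(r), centroid_col = mean(c))
  })
  do.call(rbind, cells)
}

#' Grid of disc cells with exact pixel counts
#'
#' `rows x cols` bright discs on a dark background; the simplest fixture
#' for exercising detection, since each disc's rasterized pixel count is
#' known exactly. A negative `margin` clips the outer discs at the image
#' frame, producing frame-touching cells.
#'
#' @param rows,cols Grid dimensions.
#' @param radius_px Disc radius in pixels.
#' @param params A [fixture_params()] (intensities, jitter, seed, mpp).
#' @param spacing_gap Extra dark pixels between disc bounding circles
#'   (> 0 or the discs would overlap, which is an error).
#' @param margin Dark margin around the grid (may be negative).
#' @return List with `image` (grayscale matrix) and `truth`
#'   (`"ground_truth"`).
#' @export
make_grid_cells <- function(rows, cols, radius_px, params = fixture_params(),
                            spacing_gap = 7L, margin = 4L) {
  if (spacing_gap <= 0L) stop_domain("discs must not overlap: spacing_gap > 0")
  s <- 2L * radius_px + spacing_gap
  h <- rows * s + 2L * margin
  w <- cols * s + 2L * margin
  if (h < 1L || w < 1L) stop_domain("margin too negative for grid size")
  label <- matrix(0L, h, w)
  rv <- seq_len(h) - 1L
  cv <- seq_len(w) - 1L
  k <- 0L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    k <- k + 1L
    cr <- margin + (i - 0.5) * s - 0.5
    cc <- margin + (j - 0.5) * s - 0.5
    disc <- outer((rv - cr)^2, (cv - cc)^2, `+`) <= radius_px^2
    label[disc] <- k
  }
  label <- relabel_raster(label)
  with_seed(params$rng_seed, {
    img <- matrix(jitter_intensity(h * w, params$membrane_mean,
                                   params$membrane_jitter), h, w)
    fg <- label > 0L
    img[fg] <- jitter_intensity(sum(fg), params$interior_mean,
                                params$interior_jitter)
  })
  list(image = img, truth = ground_truth(gt_cells_from_labels(label),
                                         label, params$mpp))
}

#' Voronoi mosaic emulating an H&E adipose section
#'
#' Seeds sites on a jittered grid (so no cell is degenerately small),
#' assigns every pixel to its nearest site, and draws dark membranes of
#' the requested width along region boundaries; interiors are bright
#' with intensity jitter. `gap_fraction > 0` deletes round patches of
#' membrane to simulate faint or broken borders, which makes
#' neighbouring cells merge until borders are thickened. Ground truth
#' records each cell's interior pixel count (membrane pixels belong to
#' no cell) and frame contact.
#'
#' @param params A [fixture_params()].
#' @return List with `image` and `truth`; `truth$artifacts$gaps` holds
#'   the gap-patch centres and the achieved deleted fraction.
#' @export
make_voronoi_tissue <- function(params = fixture_params()) {
  h <- params$shape[1]; w <- params$shape[2]
  n <- params$n_cells
  if (n < 1L) stop_domain("n_cells must be >= 1")
  with_seed(params$rng_seed, {
    nr <- max(1L, round(sqrt(n * h / w)))
    nc <- ceiling(n / nr)
    pitch_r <- h / nr; pitch_c <- w / nc
    grid_idx <- seq_len(n) - 1L
    site_r <- (grid_idx %/% nc + 0.5) * pitch_r +
      stats::runif(n, -0.25, 0.25) * pitch_r
    site_c <- (grid_idx %% nc + 0.5) * pitch_c +
      stats::runif(n, -0.25, 0.25) * pitch_c

    rv <- seq_len(h) - 1L
    cv <- seq_len(w) - 1L
    best_d2 <- matrix(Inf, h, w)
    label <- matrix(0L, h, w)
    for (k in seq_len(n)) {
      d2 <- outer((rv - site_r[k])^2, (cv - site_c[k])^2, `+`)
      better <- d2 < best_d2
      best_d2[better] <- d2[better]
      label[better] <- k
    }

    # one-pixel boundary line, then dilate to the requested width
    edge <- matrix(FALSE, h, w)
    edge[, -w][label[, -w] != label[, -1]] <- TRUE
    edge[-h, ][label[-h, ] != label[-1, ]] <- TRUE
    membrane <- dilate_disc(edge, params$membrane_width %/% 2L)

    gaps <- NULL
    if (params$gap_fraction > 0) {
      gap_radius <- params$membrane_width
      target <- round(params$gap_fraction * sum(membrane))
      cand <- sample(which(membrane))
      centers <- matrix(numeric(0), 0, 2)
      removed <- 0L
      for (idx in cand) {
        if (removed >= target) break
        gr <- (idx - 1L) %% h; gc <- (idx - 1L) %/% h
        if (nrow(centers) &&
            min((centers[, 1] - gr)^2 + (centers[, 2] - gc)^2) <
              (3 * gap_radius)^2) next
        disc <- outer((rv - gr)^2, (cv - gc)^2, `+`) <= gap_radius^2
        removed <- removed + sum(membrane & disc)
        membrane[disc] <- FALSE
        centers <- rbind(centers, c(gr, gc))
      }
      gaps <- list(centers = centers,
                   deleted_fraction = removed / max(1L, sum(membrane) + removed),
                   gap_radius = gap_radius)
    }

    interior <- label
    interior[membrane] <- 0L
    interior <- relabel_raster(interior)
    img <- matrix(0, h, w)
    img[membrane] <- jitter_intensity(sum(membrane), params$membrane_mean,
                                      params$membrane_jitter)
    img[!membrane] <- jitter_intensity(sum(!membrane), params$interior_mean,
                                       params$interior_jitter)
    truth <- ground_truth(gt_cells_from_labels(interior), interior,
                          params$mpp,
                          artifacts = if (is.null(gaps)) list()
                                      else list(gaps = gaps))
    list(image = img, truth = truth)
  })
}

dilate_disc <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if ((dr | dc) && dr * dr + dc * dc <= radius * radius) {
      sr <- seq_len(h) + dr; sc <- seq_len(w) + dc
      ok_r <- sr >= 1L & sr <= h; ok_c <- sc >= 1L & sc <= w
      out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[sr[ok_r], sc[ok_c]]
    }
  }
  out
}

#' Stamp haze, dust and a scratch onto a fixture image
#'
#' Haze is a convex blend with white. Dust specks are small discs whose
#' intensity contrasts with the locale they land on (dark on a bright
#' interior, bright on dark background), so specks on background create
#' spurious objects that a median denoise removes. The optional scratch
#' is one long thin bright streak across the image, recorded in the
#' registry together with a point that can be used to click it away.
#'
#' @param img Grayscale fixture image.
#' @param truth Its `"ground_truth"`.
#' @param params A [fixture_params()] (`haze`, `n_dust`, `dust_radius`,
#'   `scratch`, `scratch_row`, `rng_seed`).
#' @return List with the modified `image` and updated `truth`.
#' @export
add_artifacts <- function(img, truth, params) {
  stopifnot(is_gray_image(img), inherits(truth, "ground_truth"))
  h <- nrow(img); w <- ncol(img)
  artifacts <- truth$artifacts
  with_seed(params$rng_seed + 1L, {
    if (params$haze > 0) {
      img <- round((1 - params$haze) * img + params$haze * 255)
      artifacts$haze <- params$haze
    }
    if (params$n_dust > 0L) {
      rv <- seq_len(h) - 1L; cv <- seq_len(w) - 1L
      specks <- data.frame(row = sample.int(h, params$n_dust, TRUE) - 1L,
                           col = sample.int(w, params$n_dust, TRUE) - 1L,
                           radius = params$dust_radius,
                           intensity = NA_real_)
      for (i in seq_len(params$n_dust)) {
        disc <- outer((rv - specks$row[i])^2, (cv - specks$col[i])^2, `+`) <=
          specks$radius[i]^2
        specks$intensity[i] <- if (mean(img[disc]) > 128) 30 else 230
        img[disc] <- specks$intensity[i]
      }
      artifacts$dust <- specks
    }
    if (params$scratch) {
      r0 <- params$scratch_row %||% (h %/% 2L)
      rows <- r0:(r0 + 1L)
      rows <- rows[rows >= 0L & rows < h]
      cols <- 2L:(w - 3L)
      img[rows + 1L, cols + 1L] <- 220
      artifacts$scratch <- list(
        rows = rows, cols = range(cols),
        click_point = c(rows[1L], (w %/% 2L)))
    }
  })
  truth$artifacts <- artifacts
  list(image = img, truth = truth)
}

#' Fluorescent overlay with disjoint colour blobs
#'
#' Black field with disjoint red, green and blue discs of known pixel
#' counts, so channel masks and area percentages have exact expected
#' values.
#'
#' @param params A [fixture_params()]; `shape` and `rng_seed` are used.
#' @param n_blobs Named counts of blobs per channel.
#' @param blob_radius Range of blob radii in pixels.
#' @param intensity Channel intensity of the painted blobs.
#' @return List with `image` (RGB) and `truth`; `truth$artifacts$channels`
#'   maps channel name to exact pixel count.
#' @export
make_fluorescent_overlay <- function(params = fixture_params(shape = c(100L, 100L)),
                                     n_blobs = c(red = 3L, green = 3L, blue = 3L),
                                     blob_radius = c(4L, 8L),
                                     intensity = 200) {
  h <- params$shape[1]; w <- params$shape[2]
  img <- array(0, dim = c(h, w, 3L))
  occupied <- matrix(FALSE, h, w)
  counts <- c(red = 0L, green = 0L, blue = 0L)
  plane <- c(red = 1L, green = 2L, blue = 3L)
  rv <- seq_len(h) - 1L; cv <- seq_len(w) - 1L
  with_seed(params$rng_seed, {
    for (ch in names(n_blobs)) {
      placed <- 0L
      tries <- 0L
      while (placed < n_blobs[[ch]] && tries < 500L) {
        tries <- tries + 1L
        rad <- sample(seq(blob_radius[1], blob_radius[2]), 1L)
        cr <- stats::runif(1, rad, h - 1 - rad)
        cc <- stats::runif(1, rad, w - 1 - rad)
        disc <- outer((rv - cr)^2, (cv - cc)^2, `+`) <= rad^2
        guard <- dilate_disc(disc, 1L)    # keep channels disjoint
        if (any(occupied & guard)) next
        occupied <- occupied | guard
        img[, , plane[[ch]]][disc] <- intensity
        counts[[ch]] <- counts[[ch]] + sum(disc)
        placed <- placed + 1L
      }
      if (placed < n_blobs[[ch]])
        stop_domain("could not place all blobs; reduce counts or radii")
    }
  })
  truth <- ground_truth(
    data.frame(id = integer(0), pixel_count = integer(0),
               touches_frame = logical(0), centroid_row = numeric(0),
               centroid_col = numeric(0)),
    matrix(0L, h, w), params$mpp,
    artifacts = list(channels = as.list(counts)))
  list(image = img, truth = truth)
}
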