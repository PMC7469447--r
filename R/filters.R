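# Curation of a detected population. All three mechanisms only flip
# inclusion flags; geometry and areas are never touched, so every
# operation is reversible without re-running detection.

#' Filter specification
#'
#' @param min_area_um2,max_area_um2 Closed size interval in um^2; cells
#'   outside `[min, max]` are excluded with reason `"size"`.
#' @param exclude_border Exclude cells whose boundary touches the image
#'   frame (incompletely imaged cells).
#' @param manual_points List or `m x 2` matrix of 0-based `(row, col)`
#'   points; each point toggles the cell under it.
#' @return A list of class `"filter_spec"`.
#' @export
filter_spec <- function(min_area_um2 = 0, max_area_um2 = Inf,
                        exclude_border = FALSE, manual_points = NULL) {
  if (min_area_um2 > max_area_um2)
    stop_domain("min_area_um2 must not exceed max_area_um2")
  if (min_area_um2 < 0) stop_domain("min_area_um2 must be >= 0")
  if (is.matrix(manual_points))
    manual_points <- lapply(seq_len(nrow(manual_points)),
                            function(i) manual_points[i, ])
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 exclude_border = isTRUE(exclude_border),
                 manual_points = manual_points),
            class = "filter_spec")
}

#' Exclude cells outside a size range
#'
#' Cells with `area_um2` outside the closed interval `[min, max]` get
#' `included = FALSE` with reason `"size"`; cells inside the interval
#' have a previous size exclusion lifted. Manual and border exclusions
#' are left untouched.
#'
#' @param pop A `"cell_population"`.
#' @param min_area_um2,max_area_um2 Interval bounds in um^2.
#' @return The updated population.
#' @export
filter_by_area <- function(pop, min_area_um2 = 0, max_area_um2 = Inf) {
  stopifnot(inherits(pop, "cell_population"))
  if (min_area_um2 > max_area_um2)
    stop_domain("min_area_um2 must not exceed max_area_um2")
  a <- pop$cells$area_um2
  out_of_range <- a < min_area_um2 | a > max_area_um2
  hit <- out_of_range & pop$cells$exclusion_reason %in% c("none", "size")
  lift <- !out_of_range & pop$cells$exclusion_reason == "size"
  pop$cells$included[hit] <- FALSE
  pop$cells$exclusion_reason[hit] <- "size"
  pop$cells$included[lift] <- TRUE
  pop$cells$exclusion_reason[lift] <- "none"
  pop
}

#' Exclude (or restore) border cells
#'
#' When `on`, every cell whose contour touches the image frame is
#' excluded with reason `"border"`. When `off`, border-reason exclusions
#' are lifted; exclusions for other reasons persist.
#'
#' @param pop A `"cell_population"`.
#' @param on Logical switch.
#' @return The updated population.
#' @export
exclude_border_cells <- function(pop, on = TRUE) {
  stopifnot(inherits(pop, "cell_population"))
  if (isTRUE(on)) {
    hit <- pop$cells$touches_frame &
      pop$cells$exclusion_reason %in% c("none", "border")
    pop$cells$included[hit] <- FALSE
    pop$cells$exclusion_reason[hit] <- "border"
  } else {
    lift <- pop$cells$exclusion_reason == "border"
    pop$cells$included[lift] <- TRUE
    pop$cells$exclusion_reason[lift] <- "none"
  }
  pop
}

#' Toggle a single object by pointing at it
#'
#' Emulates click curation: if the 0-based `(row, col)` point falls on a
#' foreground pixel of some cell's component, that cell's manual state
#' flips — an included cell becomes excluded with reason `"manual"`, a
#' manually excluded cell is brought back. A point on background leaves
#' the population unchanged and records a miss in the `"toggle_miss"`
#' attribute of the result.
#'
#' @param pop A `"cell_population"`.
#' @param point Numeric `(row, col)`, 0-based, inside the image.
#' @return The updated population.
#' @export
toggle_at_point <- function(pop, point) {
  stopifnot(inherits(pop, "cell_population"))
  if (length(point) != 2L) stop_domain("point must be (row, col)")
  r <- as.integer(point[1]); c <- as.integer(point[2])
  h <- pop$image_shape[1]; w <- pop$image_shape[2]
  if (r < 0L || r >= h || c < 0L || c >= w)
    stop_domain(sprintf("point (%d, %d) is outside the %d x %d image",
                        r, c, h, w))
  lab <- pop$labels[r + 1L, c + 1L]
  if (lab == 0L) {
    attr(pop, "toggle_miss") <- rbind(attr(pop, "toggle_miss"), c(r, c))
    return(pop)
  }
  i <- which(pop$cells$id == lab)
  if (pop$cells$included[i]) {
    pop$cells$included[i] <- FALSE
    pop$cells$exclusion_reason[i] <- "manual"
  } else if (pop$cells$exclusion_reason[i] == "manual") {
    pop$cells$included[i] <- TRUE
    pop$cells$exclusion_reason[i] <- "none"
  } else {
    # excluded for another reason: a click overrides it and brings the
    # cell back, mirroring manual curation winning last
    pop$cells$included[i] <- TRUE
    pop$cells$exclusion_reason[i] <- "none"
  }
  pop
}

#' Apply a combined filter specification
#'
#' Applies the size filter, then border exclusion, then manual toggles,
#' in that order (clicks win last). Re-applying the same spec with no
#' manual points is idempotent.
#'
#' @param pop A `"cell_population"`.
#' @param spec A [filter_spec()].
#' @return The updated population.
#' @export
apply_filters <- function(pop, spec) {
  stopifnot(inherits(pop, "cell_population"), inherits(spec, "filter_spec"))
  pop <- filter_by_area(pop, spec$min_area_um2, spec$max_area_um2)
  pop <- exclude_border_cells(pop, spec$exclude_border)
  for (p in spec$manual_points) pop <- toggle_at_point(pop, p)
  pop
}

#' Reset all exclusions
#'
#' Restores the freshly detected state: every cell included.
#'
#' @param pop A `"cell_population"`.
#' @return The updated population.
#' @export
reset_filters <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  pop$cells$included <- TRUE
  pop$cells$exclusion_reason <- "none"
  attr(pop, "toggle_miss") <- NULL
  pop
}
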