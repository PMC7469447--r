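test_that("generators are bit-deterministic under a fixed seed", {
  p <- fixture_params(n_cells = 20, shape = c(96L, 96L), gap_fraction = 0.2,
                      rng_seed = 77)
  a <- make_voronoi_tissue(p); b <- make_voronoi_tissue(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$cells, b$truth$cells)
  g1 <- make_grid_cells(2, 2, 6, fixture_params(rng_seed = 5))
  g2 <- make_grid_cells(2, 2, 6, fixture_params(rng_seed = 5))
  expect_identical(g1$image, g2$image)
  f1 <- make_fluorescent_overlay(fixture_params(shape = c(80L, 80L),
                                                rng_seed = 2))
  f2 <- make_fluorescent_overlay(fixture_params(shape = c(80L, 80L),
                                                rng_seed = 2))
  expect_identical(f1$image, f2$image)
  # a different seed gives a different image
  expect_false(identical(a$image,
                         make_voronoi_tissue(fixture_params(
                           n_cells = 20, shape = c(96L, 96L),
                           gap_fraction = 0.2, rng_seed = 78))$image))
})

test_that("ground truth is self-consistent", {
  fx <- make_voronoi_tissue(fixture_params(n_cells = 40, rng_seed = 21))
  h <- nrow(fx$image); w <- ncol(fx$image)
  n_membrane <- sum(fx$truth$label_map == 0L)
  expect_identical(sum(fx$truth$cells$pixel_count) + n_membrane, h * w)
  expect_identical(fx$truth$n_cells, 40L)
  # per-cell counts agree with the label map
  expect_equal(as.vector(table(fx$truth$label_map[fx$truth$label_map > 0])),
               fx$truth$cells$pixel_count)
  expect_true(all(fx$truth$cells$centroid_row >= 0 &
                    fx$truth$cells$centroid_row < h))
})

test_that("grid fixture geometry: counts, clipping, overlap guard", {
  fx <- make_grid_cells(3, 3, 10)
  expect_identical(fx$truth$n_cells, 9L)
  expect_false(any(fx$truth$cells$touches_frame))
  # rasterized disc size, same for every unclipped disc
  expect_length(unique(fx$truth$cells$pixel_count), 1L)

  clipped <- make_grid_cells(2, 2, 10, margin = -4L)
  expect_true(all(clipped$truth$cells$touches_frame))
  expect_lt(clipped$truth$cells$pixel_count[1],
            fx$truth$cells$pixel_count[1])

  expect_error(make_grid_cells(2, 2, 10, spacing_gap = 0L),
               class = "adiposize_domain_error")
})

test_that("gap_fraction breaks borders; thickening restores the count", {
  sealed <- make_voronoi_tissue(fixture_params(n_cells = 50, rng_seed = 3))
  expect_equal(nrow(detect_cells(sealed$image, calibration(1))$cells), 50L)

  gapped <- make_voronoi_tissue(fixture_params(n_cells = 50,
                                               gap_fraction = 0.3,
                                               rng_seed = 3))
  n0 <- nrow(detect_cells(gapped$image, calibration(1))$cells)
  expect_lt(n0, 50L)                                 # merged cells undercount
  n4 <- nrow(detect_cells(gapped$image, calibration(1),
                          preprocess_params(border_thickness = 4))$cells)
  expect_identical(n4, 50L)
  expect_gt(gapped$truth$artifacts$gaps$deleted_fraction, 0.2)
})

test_that("add_artifacts without artifacts is the identity", {
  fx <- make_grid_cells(2, 2, 8, fixture_params(rng_seed = 6))
  out <- add_artifacts(fx$image, fx$truth, fixture_params(rng_seed = 6))
  expect_identical(out$image, fx$image)
  expect_identical(out$truth$cells, fx$truth$cells)
})

test_that("haze blends toward white and is removable", {
  fx <- make_voronoi_tissue(fixture_params(n_cells = 20, shape = c(96L, 96L),
                                           rng_seed = 10))
  hz <- add_artifacts(fx$image, fx$truth,
                      fixture_params(haze = 0.4, rng_seed = 10))
  expect_equal(unname(hz$image), unname(round(0.6 * fx$image + 0.4 * 255)))
  expect_equal(hz$truth$artifacts$haze, 0.4)
})

test_that("dust perturbs the object count and denoise restores it", {
  fx <- make_grid_cells(3, 3, 10, fixture_params(rng_seed = 4))
  art <- add_artifacts(fx$image, fx$truth,
                       fixture_params(n_dust = 20, rng_seed = 4))
  expect_equal(nrow(art$truth$artifacts$dust), 20L)
  n_raw <- nrow(detect_cells(art$image, calibration(1))$cells)
  expect_gt(n_raw, fx$truth$n_cells)                 # specks become objects
  n_clean <- nrow(detect_cells(art$image, calibration(1),
                               preprocess_params(denoise_radius = 2))$cells)
  expect_identical(n_clean, fx$truth$n_cells)
})

test_that("the scratch is one extra object with a recorded click point", {
  fx <- make_grid_cells(2, 3, 10, fixture_params(rng_seed = 9))
  art <- add_artifacts(fx$image, fx$truth,
                       fixture_params(scratch = TRUE, scratch_row = 4L,
                                      rng_seed = 9))
  pop <- detect_cells(art$image, calibration(1))
  expect_identical(nrow(pop$cells), fx$truth$n_cells + 1L)
  pt <- art$truth$artifacts$scratch$click_point
  expect_equal(cell_totals(toggle_at_point(pop, pt))$count, fx$truth$n_cells)
})

test_that("fluorescent overlay has exact disjoint channel geometry", {
  fx <- make_fluorescent_overlay()
  counts <- fx$truth$artifacts$channels
  res <- extract_channels(fx$image, c("r", "g", "b"))
  expect_equal(sum(res$masks$red), counts$red)
  expect_equal(sum(res$masks$green), counts$green)
  expect_equal(sum(res$masks$blue), counts$blue)
  expect_false(any(res$masks$red & res$masks$green))
  expect_false(any(res$masks$red & res$masks$blue))
  # union of channel masks equals the nonzero-pixel set at threshold 0
  nonzero <- apply(fx$image > 0, c(1, 2), any)
  expect_equal(res$masks$red | res$masks$green | res$masks$blue, nonzero)
  expect_equal(area_percentage(res$masks$green)$percent,
               100 * counts$green / prod(dim(fx$image)[1:2]))

  blue_only <- make_fluorescent_overlay(
    fixture_params(shape = c(60L, 60L), rng_seed = 3),
    n_blobs = c(blue = 2L))
  r2 <- extract_channels(blue_only$image, c("r", "g", "b"))
  expect_false(any(r2$masks$red))
  expect_false(any(r2$masks$green))
  expect_gt(sum(r2$masks$blue), 0)
})
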