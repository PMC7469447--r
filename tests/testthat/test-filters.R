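test_that("area filter keeps the closed interval [min, max]", {
  pop <- mock_population(c(100, 250, 1500, 2000, 2500))
  f <- filter_by_area(pop, 250, 2000)
  expect_equal(f$cells$area_um2[f$cells$included], c(250, 1500, 2000))
  expect_equal(f$cells$exclusion_reason[!f$cells$included],
               c("size", "size"))

  all_in <- filter_by_area(pop, 0, Inf)
  expect_true(all(all_in$cells$included))

  degenerate <- filter_by_area(pop, 1500, 1500)
  expect_equal(degenerate$cells$area_um2[degenerate$cells$included], 1500)

  expect_error(filter_by_area(pop, 10, 5), class = "adiposize_domain_error")
  # geometry untouched, only flags change
  expect_identical(f$cells$area_px, pop$cells$area_px)
  # re-filtering with wider limits lifts size exclusions
  back <- filter_by_area(f, 0, Inf)
  expect_identical(back$cells, pop$cells)
})

test_that("border exclusion flags frame cells and is reversible", {
  pop <- mock_population(rep(100, 7),
                         touches = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  on <- exclude_border_cells(pop, TRUE)
  expect_equal(sum(on$cells$included), 4L)
  expect_true(all(on$cells$exclusion_reason[!on$cells$included] == "border"))
  off <- exclude_border_cells(on, FALSE)
  expect_identical(off$cells, pop$cells)
  # non-border exclusions persist through the off switch; lifted border
  # cells come back even if a later size filter would have caught them,
  # because filters are flags, not standing rules
  sz <- filter_by_area(on, 200, Inf)
  off2 <- exclude_border_cells(sz, FALSE)
  expect_equal(off2$cells$included, pop$cells$touches_frame)
  expect_true(all(off2$cells$exclusion_reason[!off2$cells$included] == "size"))
})

test_that("one full-frame cell excludes to an empty count", {
  img <- matrix(230, 30, 30)
  pop <- detect_cells(img, calibration(1), preprocess_params(threshold = 100))
  expect_equal(nrow(pop$cells), 1L)
  expect_true(pop$cells$touches_frame[1])
  pop <- exclude_border_cells(pop, TRUE)
  expect_equal(cell_totals(pop)$count, 0L)
})

test_that("point toggling flips cells, reports misses, and double-toggles to identity", {
  fx <- make_grid_cells(2, 2, 8)
  pop <- detect_cells(fx$image, calibration(1))
  centroid <- round(c(fx$truth$cells$centroid_row[2],
                      fx$truth$cells$centroid_col[2]))
  once <- toggle_at_point(pop, centroid)
  expect_equal(sum(once$cells$included), 3L)
  expect_equal(once$cells$exclusion_reason[2], "manual")
  twice <- toggle_at_point(once, centroid)
  expect_identical(twice$cells, pop$cells)

  miss <- toggle_at_point(pop, c(0, 0))              # dark margin corner
  expect_identical(miss$cells, pop$cells)
  expect_equal(nrow(attr(miss, "toggle_miss")), 1L)

  expect_error(toggle_at_point(pop, c(-1, 4)), class = "adiposize_domain_error")
  expect_error(toggle_at_point(pop, c(4, 10000)), class = "adiposize_domain_error")
})

test_that("a scratch object can be clicked away while equal-sized cells stay", {
  fx <- make_grid_cells(2, 3, 10, fixture_params(rng_seed = 9))
  art <- add_artifacts(fx$image, fx$truth,
                       fixture_params(scratch = TRUE, scratch_row = 4L,
                                      rng_seed = 9))
  pop <- detect_cells(art$image, calibration(1))
  expect_equal(nrow(pop$cells), fx$truth$n_cells + 1L)
  cleaned <- toggle_at_point(pop, art$truth$artifacts$scratch$click_point)
  expect_equal(cell_totals(cleaned)$count, fx$truth$n_cells)
  # the real cells are untouched
  expect_equal(sum(cleaned$cells$included & !cleaned$cells$touches_frame),
               sum(fx$truth$cells$pixel_count > 0))
})

test_that("apply_filters composes size, border, manual in order", {
  pop <- mock_population(c(100, 300, 900, 2500, 600),
                         touches = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  spec <- filter_spec(min_area_um2 = 250, max_area_um2 = 2000,
                      exclude_border = TRUE)
  combined <- apply_filters(pop, spec)
  only_size <- filter_by_area(pop, 250, 2000)
  only_border <- exclude_border_cells(pop, TRUE)
  expect_equal(combined$cells$included,
               only_size$cells$included & only_border$cells$included)
  # idempotent
  again <- apply_filters(combined, spec)
  expect_identical(again$cells, combined$cells)
  # empty spec is the identity
  expect_identical(apply_filters(pop, filter_spec())$cells, pop$cells)
  expect_error(filter_spec(min_area_um2 = 10, max_area_um2 = 1),
               class = "adiposize_domain_error")
})

test_that("any filter sequence can be undone without re-detection", {
  fx <- make_grid_cells(3, 3, 9, fixture_params(rng_seed = 12))
  pop <- detect_cells(fx$image, calibration(1))
  centroids <- round(cbind(fx$truth$cells$centroid_row,
                           fx$truth$cells$centroid_col))
  mangled <- pop
  mangled <- filter_by_area(mangled, 100, 200)
  mangled <- exclude_border_cells(mangled, TRUE)
  mangled <- toggle_at_point(mangled, centroids[5, ])
  # reasons partition the excluded set
  excl <- !mangled$cells$included
  expect_true(all(mangled$cells$exclusion_reason[excl] %in%
                    c("size", "border", "manual")))
  expect_true(all(mangled$cells$exclusion_reason[!excl] == "none"))
  restored <- reset_filters(mangled)
  expect_identical(restored$cells, pop$cells)
  # included-area bookkeeping moves by exactly the flipped cells' areas
  before <- cell_totals(pop)$total_area_um2
  one_off <- toggle_at_point(pop, centroids[1, ])
  expect_equal(before - cell_totals(one_off)$total_area_um2,
               pop$cells$area_um2[1])
})
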