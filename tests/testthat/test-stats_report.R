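test_that("cell_totals sums included cells only", {
  empty <- mock_population(numeric(0))
  expect_equal(cell_totals(empty), list(count = 0L, total_area_um2 = 0))
  pop <- mock_population(c(100, 100, 100, 100))
  pop$cells$included[4] <- FALSE; pop$cells$exclusion_reason[4] <- "manual"
  expect_equal(cell_totals(pop), list(count = 3L, total_area_um2 = 300))
  fx <- make_voronoi_tissue(fixture_params(n_cells = 30, shape = c(128L, 128L),
                                           rng_seed = 14))
  det <- detect_cells(fx$image, calibration(1))
  expect_equal(cell_totals(det)$count, fx$truth$n_cells)
  expect_equal(cell_totals(det)$total_area_um2, sum(fx$truth$cells$pixel_count))
})

test_that("histogram bins are half-open with underflow bookkeeping", {
  pop <- mock_population(c(5, 10, 10.5, 250, 251, 700, 5000))
  tab <- size_histogram(pop, c(10, 251, 501, 1001))
  expect_equal(tab$count, c(3, 1, 1, 1))
  # 251 sits in the bin that starts at 251 (half-open convention)
  expect_equal(tab$area_um2, c(10 + 10.5 + 250, 251, 700, 5000))
  expect_equal(attr(tab, "underflow_count"), 1)
  expect_equal(attr(tab, "underflow_area"), 5)
  expect_error(size_histogram(pop, c(10, 10, 20)),
               class = "adiposize_domain_error")
})

test_that("histogram matches a brute-force binning loop and conserves totals", {
  set.seed(17)
  for (i in 1:10) {
    areas <- round(runif(60, 0, 8000), 1)
    edges <- sort(sample(seq(10, 6000, by = 10), 6))
    pop <- mock_population(areas)
    pop$cells$included[sample(60, 10)] <- FALSE
    tab <- size_histogram(pop, edges)
    inc <- pop$cells$area_um2[pop$cells$included]
    brute_counts <- integer(length(edges))
    brute_areas <- numeric(length(edges))
    under_n <- 0L; under_a <- 0
    for (a in inc) {
      placed <- FALSE
      for (b in rev(seq_along(edges))) {
        if (a >= edges[b]) {
          brute_counts[b] <- brute_counts[b] + 1L
          brute_areas[b] <- brute_areas[b] + a
          placed <- TRUE
          break
        }
      }
      if (!placed) { under_n <- under_n + 1L; under_a <- under_a + a }
    }
    expect_equal(tab$count, brute_counts)
    expect_equal(tab$area_um2, brute_areas)
    expect_equal(attr(tab, "underflow_count"), under_n)
    expect_equal(sum(tab$count) + attr(tab, "underflow_count"),
                 cell_totals(pop)$count)
    expect_equal(sum(tab$area_um2) + attr(tab, "underflow_area"),
                 cell_totals(pop)$total_area_um2)
  }
})

test_that("percent_difference matches the published worked examples", {
  expect_equal(round(percent_difference(475217.7, 490921.3), 1), 3.3)
  expect_equal(round(percent_difference(133, 179)), 35)
  expect_equal(percent_difference(7, 7), 0)
  expect_true(is.na(percent_difference(0, 5)))
})

test_that("compare_methods reproduces the benchmark correlations", {
  a <- bench_table("bench_clear_ref")
  b <- bench_table("bench_clear_alt")
  cmp <- compare_methods(a, b)
  expect_equal(round(cmp$r_count, 9), 0.982815341)
  expect_equal(round(cmp$r_area, 9), 0.950701594)
  expect_equal(cmp$p_count, 0.0000125, tolerance = 2e-3)
  expect_equal(cmp$p_area, 0.000288563, tolerance = 1e-5)

  a3 <- bench_table("bench_unclear_ref")
  b3 <- bench_table("bench_unclear_alt")
  cmp3 <- compare_methods(a3, b3)
  expect_equal(round(cmp3$r_count, 5), 0.97372)
  expect_equal(round(cmp3$r_area, 5), 0.52901)
  expect_equal(round(cmp3$p_area, 5), 0.17762)
  expect_equal(round(cmp3$total_area_pct_diff, 1), 3.3)
  expect_equal(round(cmp3$total_count_pct_diff), 35)
  expect_equal(round(cmp3$per_bin$area_pct_diff[8]), 66)
})

test_that("compare_methods invariants: identity, symmetry, lm cross-check", {
  a <- bench_table("bench_clear_ref")
  b <- bench_table("bench_clear_alt")
  self <- compare_methods(a, a)
  expect_equal(self$r_count, 1)
  expect_equal(self$r_area, 1)
  expect_true(all(self$per_bin$count_pct_diff == 0))
  expect_equal(self$total_area_pct_diff, 0)

  fwd <- compare_methods(a, b); rev <- compare_methods(b, a)
  expect_equal(fwd$r_count, rev$r_count)
  expect_equal(fwd$r_area, rev$r_area)
  expect_false(isTRUE(all.equal(fwd$total_area_pct_diff,
                                rev$total_area_pct_diff)))

  # |r| equals sqrt(R^2) of the least-squares fit on both benchmarks
  for (pair in list(list(a, b),
                    list(bench_table("bench_unclear_ref"),
                         bench_table("bench_unclear_alt")))) {
    fit <- stats::lm(pair[[2]]$count ~ pair[[1]]$count)
    expect_equal(abs(compare_methods(pair[[1]], pair[[2]])$r_count),
                 sqrt(summary(fit)$r.squared))
  }

  flat <- binned_table(a$label, rep(5, 8), a$area_um2)
  expect_true(is.na(compare_methods(flat, a)$r_count))
  short <- binned_table(c("a", "b"), c(1, 2), c(10, 20))
  expect_error(compare_methods(short, short),
               class = "adiposize_domain_error")
  mismatched <- binned_table(paste0("x", 1:8), a$count, a$area_um2)
  expect_error(compare_methods(a, mismatched),
               class = "adiposize_domain_error")
})

test_that("CSV export round trips numerically; xlsx mirror exists", {
  fx <- make_grid_cells(2, 3, 7, fixture_params(rng_seed = 4))
  pop <- detect_cells(fx$image, calibration(0.881))
  p <- withr::local_tempfile(fileext = ".csv")
  export_table(pop, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(pop$cells))
  expect_equal(back$area_um2, pop$cells$area_um2)

  tab <- size_histogram(pop, c(0, 100, 200))
  pt <- withr::local_tempfile(fileext = ".csv")
  export_table(tab, pt)
  tab2 <- read_binned_table(pt)
  expect_identical(tab2$count, tab$count)
  expect_identical(tab2$area_um2, tab$area_um2)
  expect_equal(attr(tab2, "total_area"), attr(tab, "total_area"))

  empty <- mock_population(numeric(0))
  pe <- withr::local_tempfile(fileext = ".csv")
  export_table(empty, pe)
  expect_equal(nrow(utils::read.csv(pe)), 0L)

  px <- withr::local_tempfile(fileext = ".xlsx")
  export_table(pop, px, format = "xlsx")
  expect_true(file.exists(px) && file.size(px) > 200)
  cmp <- compare_methods(tab, tab)
  pc <- withr::local_tempfile(fileext = ".csv")
  export_table(cmp, pc)
  got <- utils::read.csv(pc)
  expect_equal(got$count[got$label == "r"], 1)
})
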