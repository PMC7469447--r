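# Population summaries, size histograms, two-analysis comparison
# statistics, and tabular export.

#' Totals over the included cells
#'
#' @param pop A `"cell_population"`.
#' @return List with `count` and `total_area_um2`, computed over cells
#'   with `included = TRUE` only.
#' @export
cell_totals <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  inc <- pop$cells$included
  list(count = sum(inc), total_area_um2 = sum(pop$cells$area_um2[inc]))
}

#' Build a binned size table
#'
#' @param labels Character bin labels.
#' @param count Integer cell counts per bin.
#' @param area_um2 Summed areas per bin.
#' @param underflow_count,underflow_area Cells below the first bin edge,
#'   kept in a separate bookkeeping row.
#' @param total_count,total_area Optional explicit totals row; defaults
#'   to the column sums (an explicit row is kept when re-reading a table
#'   whose printed totals differ from its bins).
#' @return A data frame of class `"binned_table"`.
#' @export
binned_table <- function(labels, count, area_um2,
                         underflow_count = 0L, underflow_area = 0,
                         total_count = NULL, total_area = NULL) {
  stopifnot(length(labels) == length(count), length(count) == length(area_um2))
  df <- data.frame(label = as.character(labels), count = as.numeric(count),
                   area_um2 = as.numeric(area_um2), stringsAsFactors = FALSE)
  structure(df,
            underflow_count = as.numeric(underflow_count),
            underflow_area = as.numeric(underflow_area),
            total_count = as.numeric(total_count %||% sum(count)),
            total_area = as.numeric(total_area %||% sum(area_um2)),
            class = c("binned_table", "data.frame"))
}

#' Size histogram of a population
#'
#' Bins included cells by area. Bin *i* is the half-open interval
#' `[edge[i], edge[i+1])`; the last bin is open-ended `[edge[k], Inf)`.
#' Cells below the first edge are reported in the table's underflow
#' attributes so that counts always conserve.
#'
#' @param pop A `"cell_population"`.
#' @param bin_edges Strictly ascending numeric vector of um^2 edges.
#' @return A [binned_table()] with one row per bin.
#' @export
size_histogram <- function(pop, bin_edges) {
  stopifnot(inherits(pop, "cell_population"))
  if (length(bin_edges) < 1L || is.unsorted(bin_edges, strictly = TRUE))
    stop_domain("bin_edges must be strictly ascending")
  a <- pop$cells$area_um2[pop$cells$included]
  k <- length(bin_edges)
  idx <- findInterval(a, bin_edges)      # 0 = underflow
  count <- tabulate(idx, nbins = k)
  area <- vapply(seq_len(k), function(i) sum(a[idx == i]), numeric(1))
  labels <- c(if (k > 1L)
                sprintf("[%g,%g)", bin_edges[-k], bin_edges[-1L]),
              sprintf("[%g,Inf)", bin_edges[k]))
  binned_table(labels, count, area,
               underflow_count = sum(idx == 0L),
               underflow_area = sum(a[idx == 0L]))
}

#' @export
print.binned_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("Total: %g cells, %g um^2", attr(x, "total_count"),
              attr(x, "total_area")))
  if (attr(x, "underflow_count") > 0)
    cat(sprintf("  (underflow: %g cells, %g um^2)",
                attr(x, "underflow_count"), attr(x, "underflow_area")))
  cat("\n")
  invisible(x)
}

#' Percent difference relative to a reference value
#'
#' `100 * |b - a| / a`, with `a` the reference. Undefined for a zero
#' reference, in which case `NA` is returned.
#'
#' @param a Reference value (first method).
#' @param b Comparison value (second method).
#' @return Percent difference, or `NA` where `a == 0`.
#' @export
percent_difference <- function(a, b) {
  out <- 100 * abs(b - a) / a
  out[a == 0] <- NA_real_
  out
}

#' Compare two binned analyses of the same image
#'
#' Computes the Pearson correlation between the per-bin cell-count
#' vectors and between the per-bin area vectors of two [binned_table()]s
#' with identical bin structure, with two-sided p-values from the
#' t statistic `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (the same p a spreadsheet linear regression reports). Also
#' reports per-bin and total percent differences with the *first* table
#' as reference, so the comparison is symmetric in `r` but not in the
#' percent differences.
#'
#' @param table_a Reference [binned_table()].
#' @param table_b Comparison [binned_table()].
#' @return List of class `"comparison_stats"`: `r_count`, `p_count`,
#'   `r_area`, `p_area`, `n_bins`, `per_bin` (data frame of percent
#'   differences), `total_count_pct_diff`, `total_area_pct_diff`.
#' @export
compare_methods <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "binned_table"), inherits(table_b, "binned_table"))
  if (!identical(table_a$label, table_b$label))
    stop_domain("the two tables must have identical bin structure")
  n <- nrow(table_a)
  if (n < 3L) stop_domain("at least 3 bins are required for the p-value")
  cor_p <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(r = NA_real_, p = NA_real_))   # r undefined at zero variance
    r <- stats::cor(x, y)
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    c(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
  }
  cnt <- cor_p(table_a$count, table_b$count)
  ar <- cor_p(table_a$area_um2, table_b$area_um2)
  structure(list(
    r_count = unname(cnt["r"]), p_count = unname(cnt["p"]),
    r_area = unname(ar["r"]), p_area = unname(ar["p"]),
    n_bins = n,
    per_bin = data.frame(
      label = table_a$label,
      count_pct_diff = percent_difference(table_a$count, table_b$count),
      area_pct_diff = percent_difference(table_a$area_um2, table_b$area_um2),
      stringsAsFactors = FALSE),
    total_count_pct_diff = percent_difference(attr(table_a, "total_count"),
                                              attr(table_b, "total_count")),
    total_area_pct_diff = percent_difference(attr(table_a, "total_area"),
                                             attr(table_b, "total_area"))
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("counts: r = %.9f (p = %.3g)\n", x$r_count, x$p_count))
  cat(sprintf("areas:  r = %.5f (p = %.3g)\n", x$r_area, x$p_area))
  cat(sprintf("total percent difference: count %.1f%%, area %.1f%%\n",
              x$total_count_pct_diff, x$total_area_pct_diff))
  invisible(x)
}

#' Read a binned table from CSV
#'
#' Expects columns `label`, `count`, `area_um2`; optional rows labelled
#' `Total` and `Underflow` populate the corresponding attributes.
#'
#' @param path CSV path (as written by [export_table()]).
#' @return A [binned_table()].
#' @export
read_binned_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "count", "area_um2")
  if (!all(need %in% names(df)))
    stop_format(paste0("binned-table CSV needs columns: ",
                       paste(need, collapse = ", ")))
  is_total <- df$label == "Total"
  is_under <- df$label == "Underflow"
  bins <- df[!is_total & !is_under, , drop = FALSE]
  binned_table(bins$label, bins$count, bins$area_um2,
               underflow_count = if (any(is_under)) df$count[is_under][1] else 0,
               underflow_area = if (any(is_under)) df$area_um2[is_under][1] else 0,
               total_count = if (any(is_total)) df$count[is_total][1] else NULL,
               total_area = if (any(is_total)) df$area_um2[is_total][1] else NULL)
}

#' Export results to CSV or xlsx
#'
#' CSV (RFC 4180, dot decimal separator, UTF-8) is the canonical
#' bit-exact format; xlsx is a convenience mirror. A population exports
#' one row per cell (`id`, `area_px`, `area_um2`, `included`,
#' `exclusion_reason`); a binned table exports its bins plus `Underflow`
#' (when non-empty) and `Total` rows; comparison statistics export the
#' per-bin percent differences followed by the summary statistics.
#'
#' @param x A `"cell_population"`, `"binned_table"` or
#'   `"comparison_stats"`.
#' @param path Output path.
#' @param format `"csv"` or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(x, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  df <- as_export_df(x)
  if (format == "csv") {
    con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                    error = function(e) stop_format(
                      paste0("cannot write to ", path)))
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    write_minimal_xlsx(df, path)
  }
  invisible(path)
}

as_export_df <- function(x) UseMethod("as_export_df")

#' @export
as_export_df.cell_population <- function(x) {
  x$cells[, c("id", "area_px", "area_um2", "included", "exclusion_reason")]
}

#' @export
as_export_df.binned_table <- function(x) {
  df <- as.data.frame(x)
  if (attr(x, "underflow_count") > 0)
    df <- rbind(df, data.frame(label = "Underflow",
                               count = attr(x, "underflow_count"),
                               area_um2 = attr(x, "underflow_area")))
  rbind(df, data.frame(label = "Total", count = attr(x, "total_count"),
                       area_um2 = attr(x, "total_area")))
}

#' @export
as_export_df.comparison_stats <- function(x) {
  rbind(
    data.frame(label = x$per_bin$label, metric = "pct_diff",
               count = x$per_bin$count_pct_diff,
               area_um2 = x$per_bin$area_pct_diff,
               stringsAsFactors = FALSE),
    data.frame(label = "r", metric = "pearson",
               count = x$r_count, area_um2 = x$r_area),
    data.frame(label = "p", metric = "pearson",
               count = x$p_count, area_um2 = x$p_area),
    data.frame(label = "Total", metric = "pct_diff",
               count = x$total_count_pct_diff,
               area_um2 = x$total_area_pct_diff)
  )
}
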