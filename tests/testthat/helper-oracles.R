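# Independent oracles used across tests.

# 8-connected component labeling through igraph: build the pixel
# adjacency graph and take its connected components. Deliberately a
# different algorithm and library than the package's BFS/border tracer.
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(n = 0L, sizes = integer(0)))
  r <- (idx - 1L) %% h
  c <- (idx - 1L) %/% h
  edges <- integer(0)
  for (k in seq_along(idx)) {
    for (dd in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
      nr <- r[k] + dd[1]; nc <- c[k] + dd[2]
      if (nr >= 0L && nr < h && nc >= 0L && nc < w) {
        j <- match(nr + nc * h + 1L, idx)
        if (!is.na(j)) edges <- c(edges, k, j)
      }
    }
  }
  comp <- igraph::components(
    igraph::make_graph(edges, n = length(idx), directed = FALSE))
  list(n = as.integer(comp$no), sizes = sort(as.integer(comp$csize)))
}

# minimal synthetic population when only areas/flags matter
mock_population <- function(areas_um2, touches = rep(FALSE, length(areas_um2)),
                            mpp = 1) {
  cal <- calibration(mpp)
  n <- length(areas_um2)
  structure(list(
    cells = data.frame(id = seq_len(n),
                       area_px = as.integer(round(areas_um2 / cal$area_factor)),
                       area_um2 = as.numeric(areas_um2),
                       touches_frame = touches,
                       included = rep(TRUE, n),
                       exclusion_reason = rep("none", n),
                       stringsAsFactors = FALSE),
    contours = list(), calibration = cal, image_shape = c(1L, 1L),
    labels = matrix(0L, 1, 1), mask = matrix(FALSE, 1, 1)),
    class = "cell_population")
}

bench_table <- function(name) {
  read_binned_table(system.file("extdata", paste0(name, ".csv"),
                                package = "adiposize", mustWork = TRUE))
}
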