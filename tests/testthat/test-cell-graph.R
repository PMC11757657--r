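test_that("polygon morphometrics agree with analytic shapes", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(pannetips:::poly_area(square), 1)
  expect_equal(pannetips:::poly_perimeter(square), 4)
  expect_equal(pannetips:::poly_solidity(square), 1)

  tri <- cbind(c(0, 30, 0), c(0, 0, 40))   # 3-4-5 right triangle x10
  expect_equal(pannetips:::poly_area(tri), 600)
  expect_equal(pannetips:::poly_perimeter(tri), 120)
})

test_that("nucleus exports round-trip and compute contour features", {
  nuc <- synthesize_nuclei("PanNET", 0, 4, 12, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_nucleus_export(nuc, path, patch_size = 256)
  back <- read_nucleus_export(path)
  expect_equal(back$x, nuc$x)
  expect_equal(back$area, nuc$area)
  expect_equal(back$perimeter, nuc$perimeter)

  # contour-only export: features are derived from the polygon
  doc <- list(patch_size = 100, nuc = list(
    "1" = list(centroid = c(10, 10),
               contour = list(c(8, 8), c(12, 8), c(12, 12), c(8, 12)))
  ))
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, p2, auto_unbox = TRUE)
  one <- read_nucleus_export(p2)
  expect_equal(one$area, 16)
  expect_equal(one$perimeter, 16)
  expect_equal(one$solidity, 1)
  expect_equal(one$eccentricity, 0)
  expect_equal(one$intensity, 0.5)
})

test_that("nucleus reader drops out-of-bounds instances and names bad ones", {
  doc <- list(patch_size = 50, nuc = list(
    ok = list(centroid = c(10, 10),
              features = list(area = 100, eccentricity = 0.5, solidity = 0.9,
                              intensity = 0.4, perimeter = 40)),
    outside = list(centroid = c(300, 10),
                   features = list(area = 100, eccentricity = 0.5,
                                   solidity = 0.9, intensity = 0.4,
                                   perimeter = 40))
  ))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_warning(out <- read_nucleus_export(path), "outside")
  expect_equal(nrow(out), 1)

  doc$nuc$bad <- list(centroid = c(5, 5))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(suppressWarnings(read_nucleus_export(path)), "bad")
})

test_that("identical nuclei in range link with weight 1", {
  nuc <- toy_nuclei(1, seed = 1)
  two <- dplyr::bind_rows(nuc, nuc)
  two$x <- c(0, 10); two$y <- c(0, 0)
  g <- build_cell_graph(two, k = 3, max_edge_dist = 50)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1)
})

test_that("the spatial gate suppresses edges regardless of similarity", {
  nuc <- toy_nuclei(1, seed = 2)
  two <- dplyr::bind_rows(nuc, nuc)
  two$x <- c(0, 500); two$y <- c(0, 0)
  g <- build_cell_graph(two, k = 3, max_edge_dist = 50)
  expect_equal(nrow(g$edges), 0)
  expect_error(build_cell_graph(two, k = 0), "positive")
})

test_that("edge set equals the brute-force kNN-union oracle", {
  for (seed in c(3, 9, 27)) {
    nuc <- toy_nuclei(20, seed = seed)
    k <- 4; maxd <- 60
    g <- build_cell_graph(nuc, k = k, max_edge_dist = maxd,
                          similarity_threshold = 0)
    # oracle: exhaustive pairwise kNN-union
    D <- as.matrix(dist(cbind(nuc$x, nuc$y)))
    diag(D) <- Inf
    want <- matrix(FALSE, 20, 20)
    for (i in 1:20) {
      nb <- order(D[i, ])[1:k]
      nb <- nb[D[i, nb] <= maxd]
      want[cbind(pmin(i, nb), pmax(i, nb))] <- TRUE
    }
    got <- matrix(FALSE, 20, 20)
    got[cbind(g$edges$from, g$edges$to)] <- TRUE
    expect_identical(got, want)
    expect_true(all(g$edges$weight > 0 & g$edges$weight <= 1))
    expect_true(all(g$edges$from < g$edges$to))
  }
})

test_that("graph construction is permutation-invariant", {
  nuc <- toy_nuclei(15, seed = 5)
  g1 <- build_cell_graph(nuc, k = 4, max_edge_dist = 80)
  perm <- withr::with_seed(1, sample.int(15))
  g2 <- build_cell_graph(nuc[perm, ], k = 4, max_edge_dist = 80)
  # map g2's edges back to original indices
  back <- order(perm)
  e2 <- tibble::tibble(
    from = pmin(perm[g2$edges$from], perm[g2$edges$to]),
    to = pmax(perm[g2$edges$from], perm[g2$edges$to]),
    weight = g2$edges$weight
  )
  e2 <- dplyr::arrange(e2, from, to)
  expect_equal(as.data.frame(e2), as.data.frame(g1$edges), tolerance = 1e-12)
})

test_that("feature standardisation uses training statistics only", {
  gs <- lapply(1:4, function(i) build_cell_graph(toy_nuclei(12, seed = i)))
  stats <- compute_feature_stats(gs)
  std <- standardize_features(gs, stats)
  pooled <- do.call(rbind, lapply(std, pannetips:::node_feature_matrix))
  expect_equal(colMeans(pooled), setNames(rep(0, 5), stats$feature),
               tolerance = 1e-6)
  expect_equal(apply(pooled, 2, sd), setNames(rep(1, 5), stats$feature),
               tolerance = 1e-6)

  # a constant dimension standardises to zero without dividing by zero
  gc <- lapply(1:3, function(i) {
    n <- toy_nuclei(8, seed = i); n$solidity <- 0.9
    build_cell_graph(n)
  })
  stc <- compute_feature_stats(gc)
  stdc <- standardize_features(gc, stc)
  expect_true(all(pannetips:::node_feature_matrix(stdc[[1]])[, "solidity"] == 0))

  # shifted test split: training statistics differ from pooled statistics
  test_graphs <- lapply(5:6, function(i) {
    n <- toy_nuclei(12, seed = i); n$area <- n$area + 300
    build_cell_graph(n)
  })
  full_stats <- compute_feature_stats(c(gs, test_graphs))
  expect_gt(abs(full_stats$mean[1] - stats$mean[1]), 10)

  expect_error(standardize_features(gs), "statistics")
})

test_that("cell-graphs round-trip through the JSON schema", {
  g <- build_cell_graph(toy_nuclei(10, seed = 7),
                        meta = list(slide_id = "s", row = 2, col = 3, d = 1,
                                    label = "IPS2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_cell_graph(g, path)
  back <- read_cell_graph(path)
  expect_equal(as.data.frame(back$nodes), as.data.frame(g$nodes))
  expect_equal(as.data.frame(back$edges), as.data.frame(g$edges))
  expect_equal(back$meta, g$meta)

  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 10)
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
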