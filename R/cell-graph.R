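# Polygon morphometrics for nucleus contours (x, y vertex matrices).
poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i <- seq_len(nrow(xy)); j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

poly_perimeter <- function(xy) {
  nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - xy)^2)))
}

poly_solidity <- function(xy) {
  if (nrow(xy) < 3) return(1)
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  ha <- poly_area(hull)
  if (ha <= 0) return(1)
  min(1, poly_area(xy) / ha)
}

# Eccentricity of the ellipse matched to the vertex scatter (second moments).
poly_eccentricity <- function(xy) {
  if (nrow(xy) < 3) return(0)
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1] <= 0) return(0)
  sqrt(1 - ev[2] / ev[1])
}

#' Read a nucleus-detector JSON export
#'
#' Parses the JSON dialect exported by Hover-Net-style nucleus segmenters:
#' a top-level `nuc` object mapping instance ids to records with a
#' `centroid` `[x, y]`, an optional polygon `contour`, an optional detector
#' `type` code, and (for fixture-generated files) an optional `features`
#' record. Morphology features (area, eccentricity, solidity, mean
#' intensity, perimeter) are taken from `features` when present, otherwise
#' computed from the contour: shoelace area and perimeter, convex-hull
#' solidity and ellipse-fit eccentricity. Mean intensity defaults to 0.5
#' when the export carries no intensity information.
#'
#' Instances whose centroid lies outside the patch bounds are dropped with a
#' warning; structurally malformed instances raise an error naming the
#' offending id.
#'
#' @param path Path to the JSON export.
#' @param patch_size Patch bound in pixels; defaults to the `patch_size`
#'   field of the file, else `Inf` (no bound check).
#' @return Tibble with `x`, `y`, the five morphology features and `type`.
#' @export
read_nucleus_export <- function(path, patch_size = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$nuc)) abort("nucleus export has no `nuc` record")
  bound <- patch_size %||% doc$patch_size %||% Inf
  rows <- vector("list", length(doc$nuc))
  keep <- logical(length(doc$nuc))
  ids <- names(doc$nuc) %||% as.character(seq_along(doc$nuc))
  for (i in seq_along(doc$nuc)) {
    inst <- doc$nuc[[i]]
    cen <- unlist(inst$centroid)
    if (length(cen) != 2 || !is.numeric(cen) || anyNA(cen)) {
      abort(sprintf("malformed nucleus instance '%s': bad centroid", ids[i]))
    }
    if (any(cen < 0) || any(cen > bound)) {
      warn(sprintf("nucleus '%s' centroid outside patch bounds; dropped", ids[i]))
      next
    }
    if (!is.null(inst$features)) {
      f <- inst$features
      need <- NUCLEUS_FEATURES
      if (!all(need %in% names(f))) {
        abort(sprintf("malformed nucleus instance '%s': incomplete features",
                      ids[i]))
      }
      feats <- vapply(f[need], as.numeric, numeric(1))
    } else if (!is.null(inst$contour)) {
      xy <- do.call(rbind, lapply(inst$contour, function(p) {
        p <- unlist(p)
        if (length(p) != 2 || !is.numeric(p)) {
          abort(sprintf("malformed nucleus instance '%s': bad contour", ids[i]))
        }
        p
      }))
      feats <- c(area = poly_area(xy),
                 eccentricity = poly_eccentricity(xy),
                 solidity = poly_solidity(xy),
                 intensity = as.numeric(inst$mean_intensity %||% 0.5),
                 perimeter = poly_perimeter(xy))
    } else {
      abort(sprintf(
        "malformed nucleus instance '%s': neither features nor contour", ids[i]))
    }
    if (any(!is.finite(feats))) {
      abort(sprintf("malformed nucleus instance '%s': non-finite features",
                    ids[i]))
    }
    keep[i] <- TRUE
    tp <- unlist(inst$type)
    if (length(tp) != 1) tp <- NA_integer_
    rows[[i]] <- tibble(x = cen[1], y = cen[2],
                        area = feats[["area"]],
                        eccentricity = feats[["eccentricity"]],
                        solidity = feats[["solidity"]],
                        intensity = feats[["intensity"]],
                        perimeter = feats[["perimeter"]],
                        type = as.integer(tp))
  }
  dplyr::bind_rows(rows[keep])
}

#' Write nuclei in the detector-export JSON schema
#'
#' Writes a nucleus table (as produced by [synthesize_nuclei()] or
#' [read_nucleus_export()]) in the same JSON dialect the reader consumes,
#' so synthetic fixtures and real detector exports are interchangeable.
#'
#' @param nuclei Tibble with `x`, `y` and the five morphology features.
#' @param path Output path.
#' @param patch_size Patch bound recorded in the file.
#' @export
write_nucleus_export <- function(nuclei, path, patch_size = 256) {
  has_type <- "type" %in% names(nuclei)
  nuc <- lapply(seq_len(nrow(nuclei)), function(i) {
    rec <- list(
      centroid = c(nuclei$x[i], nuclei$y[i]),
      features = as.list(nuclei[i, NUCLEUS_FEATURES])
    )
    if (has_type) rec$type <- nuclei$type[i]
    rec
  })
  names(nuc) <- as.character(seq_len(nrow(nuclei)))
  jsonlite::write_json(list(patch_size = patch_size, nuc = nuc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

cosine_similarity_rows <- function(m, i, j) {
  num <- rowSums(m[i, , drop = FALSE] * m[j, , drop = FALSE])
  ni <- sqrt(rowSums(m[i, , drop = FALSE]^2))
  nj <- sqrt(rowSums(m[j, , drop = FALSE]^2))
  s <- num / (ni * nj)
  # degenerate zero-norm vectors: identical rows are maximally similar,
  # otherwise maximally dissimilar
  degen <- ni < 1e-12 | nj < 1e-12
  if (any(degen)) {
    same <- rowSums(abs(m[i, , drop = FALSE] - m[j, , drop = FALSE])) < 1e-12
    s[degen] <- ifelse(same[degen], 1, -1)
  }
  pmin(pmax(s, -1), 1)
}

#' Build a cell-graph from a nucleus table
#'
#' Nodes sit at nucleus centroids and carry the five morphology features.
#' Candidate edges are the union-symmetrised spatial k-nearest neighbours
#' within `max_edge_dist`; each candidate is weighted by the cosine
#' similarity of the two nuclei's feature vectors mapped to `(0, 1]` via
#' `(s + 1) / 2`, and candidates whose weight falls below
#' `similarity_threshold` are dropped. Isolated nodes are permitted. The
#' construction is permutation-invariant: reordering the input nuclei gives
#' an isomorphic graph with identical weights.
#'
#' @param nuclei Tibble with `x`, `y` and the five morphology feature
#'   columns (at least one row).
#' @param k Number of spatial nearest neighbours (>= 1).
#' @param max_edge_dist Maximum centroid distance for an edge, in pixels.
#' @param similarity_threshold Candidates with weight strictly below this
#'   are removed (default 0: keep all, weight only).
#' @param meta Named list of patch metadata (`slide_id`, `row`, `col`, `d`,
#'   `label`, `case_id`, ...).
#' @return Object of class `cell_graph`: list with `nodes` (tibble),
#'   `edges` (tibble of `from`, `to`, `weight` with `from < to`) and `meta`.
#' @export
build_cell_graph <- function(nuclei, k = 5, max_edge_dist = 50,
                             similarity_threshold = 0, meta = list()) {
  if (!is.data.frame(nuclei) || nrow(nuclei) < 1) {
    abort("`nuclei` must have at least one row")
  }
  if (k <= 0) abort("`k` must be a positive integer")
  n <- nrow(nuclei)
  fm <- as.matrix(nuclei[NUCLEUS_FEATURES])
  edges <- tibble(from = integer(), to = integer(), weight = numeric())
  if (n >= 2) {
    D <- as.matrix(stats::dist(cbind(nuclei$x, nuclei$y)))
    diag(D) <- Inf
    pair_list <- vector("list", n)
    for (i in seq_len(n)) {
      ord <- order(D[i, ])[seq_len(min(k, n - 1L))]
      ord <- ord[D[i, ord] <= max_edge_dist]
      if (length(ord)) pair_list[[i]] <- cbind(pmin(i, ord), pmax(i, ord))
    }
    pairs <- do.call(rbind, pair_list)
    if (!is.null(pairs) && nrow(pairs)) {
      pairs <- unique(pairs)
      s <- cosine_similarity_rows(fm, pairs[, 1], pairs[, 2])
      w <- pmax((s + 1) / 2, 1e-12)
      keep <- w >= similarity_threshold
      ord <- order(pairs[keep, 1], pairs[keep, 2])
      edges <- tibble(from = pairs[keep, 1][ord], to = pairs[keep, 2][ord],
                      weight = w[keep][ord])
    }
  }
  structure(list(nodes = as_tibble(nuclei), edges = edges, meta = meta,
                 features = fm),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  d <- if (!is.null(x$meta$d)) sprintf(" d=%s", x$meta$d) else ""
  cat(sprintf("<cell_graph> %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges), d))
  invisible(x)
}

#' @method tidy cell_graph
#' @export
tidy.cell_graph <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  if (what == "nodes") x$nodes else x$edges
}

# Cached at construction; fall back to the nodes tibble for graphs built
# by hand or read from JSON.
node_feature_matrix <- function(graph) {
  graph$features %||% as.matrix(graph$nodes[NUCLEUS_FEATURES])
}

# Standardise a pooled node-feature matrix with stored statistics;
# zero-variance dimensions map to 0.
standardize_matrix <- function(m, stats) {
  sds <- ifelse(stats$sd < 1e-12, Inf, stats$sd)
  sweep(sweep(m, 2, stats$mean), 2, sds, "/")
}

#' Node-feature standardisation statistics
#'
#' Computes per-dimension mean and standard deviation of the node features
#' pooled over a set of graphs. In the scoring pipeline these statistics are
#' computed on the training split only and stored with the model, so that
#' inference applies the training-time transformation.
#'
#' @param graphs List of [build_cell_graph()] objects.
#' @return Object of class `graph_feature_stats` (tibble with `feature`,
#'   `mean`, `sd`).
#' @export
compute_feature_stats <- function(graphs) {
  stopifnot(length(graphs) > 0)
  m <- do.call(rbind, lapply(graphs, node_feature_matrix))
  structure(
    tibble(feature = NUCLEUS_FEATURES,
           mean = colMeans(m),
           sd = apply(m, 2, sd)),
    class = c("graph_feature_stats", class(tibble()))
  )
}

#' Standardise node features with stored statistics
#'
#' Applies the z-transformation `(x - mean) / sd` per feature dimension.
#' Zero-variance dimensions are mapped to 0 rather than dividing by zero.
#'
#' @param graphs List of cell-graphs.
#' @param stats A [compute_feature_stats()] object. Must be supplied:
#'   standardising at inference time without the stored training statistics
#'   is an error.
#' @return The graphs with standardised node features.
#' @export
standardize_features <- function(graphs, stats) {
  if (missing(stats) || is.null(stats)) {
    abort("standardization statistics are required; compute them on the training split with `compute_feature_stats()`")
  }
  lapply(graphs, function(g) {
    m <- standardize_matrix(node_feature_matrix(g), stats)
    g$nodes[NUCLEUS_FEATURES] <- as_tibble(m)
    g$features <- m
    g
  })
}

#' Serialise a cell-graph to JSON
#'
#' A documented schema: `nodes` (centroids + features), `edges`
#' (`from`/`to` 1-based indices + `weight`) and `meta`. The round trip
#' through [read_cell_graph()] is lossless.
#'
#' @param graph A [build_cell_graph()] object.
#' @param path Output path.
#' @export
write_cell_graph <- function(graph, path) {
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges, meta = graph$meta),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_cell_graph
#' @export
read_cell_graph <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as_tibble(doc$edges)
  if (nrow(edges) == 0) {
    edges <- tibble(from = integer(), to = integer(), weight = numeric())
  }
  structure(list(nodes = as_tibble(doc$nodes), edges = edges,
                 meta = as.list(doc$meta)),
            class = "cell_graph")
}

#' Convert a cell-graph to an igraph object
#'
#' Handy for GraphML export (`igraph::write_graph(..., format = "graphml")`)
#' and for standard graph algorithms.
#'
#' @param graph A [build_cell_graph()] object.
#' @return An `igraph` undirected weighted graph with node attributes.
#' @export
as_igraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    abort("the igraph package is required for this conversion")
  }
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = cbind(name = seq_len(nrow(graph$nodes)), graph$nodes)
  )
  g
}
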