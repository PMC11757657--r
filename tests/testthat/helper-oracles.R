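# Independent oracles used to cross-check the package implementations.
# They deliberately take different algorithmic routes (igraph lattice
# graphs, table-based confusion matrices) from the code they verify.

tissue_code_of <- function(label) match(label, tissue_levels()) - 1L

# Random prediction-map grid with the four tissue classes.
random_map <- function(nr = 12, nc = 12, p = c(0.15, 0.4, 0.3, 0.15),
                       seed = 1) {
  withr::with_seed(seed, {
    matrix(sample(0:3, nr * nc, replace = TRUE, prob = p), nr, nc)
  })
}

# Brute-force interface patch selection via igraph shortest paths.
oracle_select <- function(grid, max_hops, connectivity = 4L) {
  nr <- nrow(grid); nc <- ncol(grid)
  idx <- which(grid == 1L)
  if (length(idx) == 0) return(NULL)
  cellr <- ((idx - 1L) %% nr) + 1L
  cellc <- ((idx - 1L) %/% nr) + 1L
  off <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1)[-5, ])
  }
  key <- function(r, c) paste(r, c)
  vmap <- setNames(seq_along(idx), key(cellr, cellc))
  edges <- c()
  for (v in seq_along(idx)) {
    for (o in seq_len(nrow(off))) {
      nk <- key(cellr[v] + off[o, 1], cellc[v] + off[o, 2])
      w <- vmap[nk]
      if (!is.na(w) && w > v) edges <- c(edges, v, w)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first <- vapply(best, function(b) {
      mem <- which(comp$membership == b)
      o <- order(cellr[mem], cellc[mem])
      cellr[mem[o[1]]] * (nc + 1) + cellc[mem[o[1]]]
    }, numeric(1))
    best <- best[which.min(first)]
  }
  members <- which(comp$membership == best)
  # border: adjacent to NNPP (2) or stroma (3)
  qual <- grid == 2L | grid == 3L
  is_border <- vapply(members, function(v) {
    any(vapply(seq_len(nrow(off)), function(o) {
      r <- cellr[v] + off[o, 1]; c <- cellc[v] + off[o, 2]
      r >= 1 && r <= nr && c >= 1 && c <= nc && qual[r, c]
    }, logical(1)))
  }, logical(1))
  border <- members[is_border]
  if (length(border) == 0) {
    return(data.frame(row = integer(), col = integer(), d = integer()))
  }
  sub <- igraph::induced_subgraph(g, members)
  dm <- igraph::distances(sub, v = match(border, members))
  dmin <- apply(dm, 2, min)
  keep <- is.finite(dmin) & dmin <= max_hops
  out <- data.frame(row = cellr[members][keep], col = cellc[members][keep],
                    d = as.integer(dmin[keep]))
  out[order(out$row, out$col), ]
}

# Brute-force classification metrics from an explicit confusion matrix.
oracle_report <- function(truth, pred, levels = ips_levels()) {
  tab <- table(factor(truth, levels), factor(pred, levels))
  per <- t(vapply(levels, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = 100 * p, recall = 100 * r, f1 = 100 * f1,
      support = tp + fn)
  }, numeric(4)))
  list(per = per,
       weighted_f1 = sum(per[, "support"] / length(truth) * per[, "f1"]))
}

# A nucleus table with the expected feature columns.
toy_nuclei <- function(n = 10, seed = 1, spread = 100) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = runif(n, 0, spread), y = runif(n, 0, spread),
      area = runif(n, 100, 400), eccentricity = runif(n),
      solidity = runif(n, 0.6, 1), intensity = runif(n),
      perimeter = runif(n, 30, 90)
    )
  })
}

# Small cohorts for learning experiments: strong interface signal, classes
# enriched in the two well-separated extremes.
easy_config <- function(n_cases, seed, grid = c(16, 16), n_nuclei = 35,
                        mixing_decay = 1) {
  cohort_config(
    n_cases = n_cases, ips_proportions = c(0.45, 0.10, 0.45),
    grid_shape = grid, mixing_floor = 0.05, mixing_slope = 0.2,
    mixing_decay = mixing_decay, n_nuclei = n_nuclei, feature_noise = 0.8,
    seed = seed
  )
}

graph_case_ids <- function(graphs) {
  vapply(graphs, function(g) g$meta$case_id, character(1))
}
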