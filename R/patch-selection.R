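neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    o <- expand.grid(dr = -1:1, dc = -1:1)
    as.matrix(o[!(o$dr == 0 & o$dc == 0), ])
  } else {
    abort("`connectivity` must be 4 or 8")
  }
}

# Connected-component labelling of a logical matrix by breadth-first search.
# Components are discovered in column-major scan order, so component ids are
# deterministic.
label_components <- function(mask, connectivity = 4L) {
  off <- neighbor_offsets(connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  n_comp <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    labels[start] <- n_comp
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      nb_r <- r + off[, 1L]; nb_c <- cl + off[, 2L]
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- n_comp
      queue <- c(queue, nb)
    }
  }
  list(labels = labels, n_components = n_comp)
}

#' Largest tumor region of interest
#'
#' Finds the connected component of PanNET-labelled patches with the largest
#' cell count in a prediction map. Ties are broken deterministically in
#' favour of the component whose lexicographically smallest member
#' `(row, col)` is smallest.
#'
#' @param map A [prediction_map()] (or a tissue map matrix).
#' @param connectivity Grid connectivity, 4 (default) or 8.
#' @return Object of class `tumor_region`: list with `cells` (tibble of
#'   `row`, `col`), `size`, `component_id` and the connectivity used.
#' @export
find_largest_troi <- function(map, connectivity = 4L) {
  grid <- if (inherits(map, "prediction_map")) map$grid else map
  mask <- grid == tissue_code("PanNET")
  if (!any(mask)) abort("no tumor found: map contains no PanNET patches")
  comp <- label_components(mask, connectivity)
  sizes <- tabulate(comp$labels[comp$labels > 0L], comp$n_components)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest (row, col) of each candidate's minimal member
    first_member <- vapply(best, function(b) {
      idx <- which(comp$labels == b)
      r <- ((idx - 1L) %% nrow(grid)) + 1L
      cl <- ((idx - 1L) %/% nrow(grid)) + 1L
      ord <- order(r, cl)
      r[ord[1L]] * (ncol(grid) + 1L) + cl[ord[1L]]
    }, numeric(1))
    best <- best[which.min(first_member)]
  }
  idx <- which(comp$labels == best)
  cells <- tibble(
    row = ((idx - 1L) %% nrow(grid)) + 1L,
    col = ((idx - 1L) %/% nrow(grid)) + 1L
  )
  cells <- dplyr::arrange(cells, .data$row, .data$col)
  structure(
    list(cells = cells, size = nrow(cells), component_id = best,
         connectivity = as.integer(connectivity), grid_shape = dim(grid)),
    class = "tumor_region"
  )
}

#' @export
print.tumor_region <- function(x, ...) {
  cat(sprintf("<tumor_region> %d PanNET patches (component %d, %d-connectivity)\n",
              x$size, x$component_id, x$connectivity))
  invisible(x)
}

#' Border patches of the tumor region
#'
#' Selects exactly those patches of the tumor region that are adjacent
#' (under the configured connectivity) to at least one patch labelled NNPP
#' or stroma. Adjacency to background alone does not qualify: a tumor region
#' bordered only by background yields an empty selection with a warning,
#' since no tumor-parenchyma interface is exposed.
#'
#' @param troi A [find_largest_troi()] result derived from `map`.
#' @param map The same prediction map (or tissue map matrix).
#' @param connectivity Grid connectivity, 4 or 8; defaults to the one stored
#'   in `troi`.
#' @return Tibble of `row`, `col`, `d` (all `d = 0`).
#' @export
select_border <- function(troi, map, connectivity = troi$connectivity) {
  grid <- if (inherits(map, "prediction_map")) map$grid else map
  off <- neighbor_offsets(connectivity)
  qual <- grid == tissue_code("NNPP") | grid == tissue_code("stroma")
  nr <- nrow(grid); nc <- ncol(grid)
  is_border <- vapply(seq_len(nrow(troi$cells)), function(i) {
    r <- troi$cells$row[i]; cl <- troi$cells$col[i]
    nb_r <- r + off[, 1L]; nb_c <- cl + off[, 2L]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    any(qual[cbind(nb_r[ok], nb_c[ok])])
  }, logical(1))
  out <- troi$cells[is_border, ]
  out$d <- 0L
  if (nrow(out) == 0) {
    warn("tumor region is not adjacent to NNPP or stroma; empty border selection")
  }
  out
}

#' Expand the border selection into the tumor by hop distance
#'
#' Breadth-first expansion from the border patches, restricted to the tumor
#' region: each selected patch's hop distance `d` is the length of the
#' shortest within-region path to any border patch. Patches farther than
#' `max_hops` are excluded. Increasing `max_hops` only ever adds patches and
#' never changes an existing distance.
#'
#' @param border Border selection from [select_border()].
#' @param troi The [find_largest_troi()] result.
#' @param max_hops Maximum hop distance to keep (>= 0).
#' @param connectivity Grid connectivity; defaults to the one stored in
#'   `troi`.
#' @return Tibble of `row`, `col`, `d`, ordered by `d` then `(row, col)`.
#' @export
expand_hops <- function(border, troi, max_hops = 6L,
                        connectivity = troi$connectivity) {
  check_scalar_number(max_hops, "max_hops", lower = 0)
  if (nrow(border) == 0) return(border[c("row", "col", "d")])
  off <- neighbor_offsets(connectivity)
  nr <- troi$grid_shape[1]; nc <- troi$grid_shape[2]
  in_troi <- matrix(FALSE, nr, nc)
  in_troi[cbind(troi$cells$row, troi$cells$col)] <- TRUE
  dist <- matrix(NA_integer_, nr, nc)
  frontier <- cbind(border$row, border$col)
  dist[frontier] <- 0L
  d <- 0L
  while (nrow(frontier) > 0 && d < max_hops) {
    cand <- cbind(
      rep(frontier[, 1], each = nrow(off)) + rep(off[, 1], nrow(frontier)),
      rep(frontier[, 2], each = nrow(off)) + rep(off[, 2], nrow(frontier))
    )
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[ok, , drop = FALSE]
    ok <- in_troi[cand] & is.na(dist[cand])
    cand <- unique(cand[ok, , drop = FALSE])
    d <- d + 1L
    dist[cand] <- d
    frontier <- cand
  }
  sel <- which(!is.na(dist))
  out <- tibble(
    row = ((sel - 1L) %% nr) + 1L,
    col = ((sel - 1L) %/% nr) + 1L,
    d = dist[sel]
  )
  dplyr::arrange(out, .data$d, .data$row, .data$col)
}

#' Select representative tumor-parenchyma interface patches
#'
#' Full selection step for one slide: find the largest tumor region in the
#' prediction map, take its border patches (adjacent to NNPP or stroma), and
#' expand inwards up to `max_hops` with breadth-first hop distances.
#'
#' @param map A [prediction_map()] (or tissue map matrix).
#' @param max_hops Maximum hop distance (default 6).
#' @param connectivity Grid connectivity, 4 (default) or 8.
#' @param slide_id Optional slide id recorded in the output; defaults to the
#'   map's.
#' @param max_patches Optional cap on the number of selected patches per
#'   slide (default unlimited). Patches are kept in order of increasing hop
#'   distance; if a hop ring overflows the cap, the remainder is drawn from
#'   that ring by seeded simple random sampling.
#' @param seed Seed for the cap sampling (ignored when no cap applies).
#' @return Tibble of `slide_id`, `row`, `col`, `d`.
#' @export
select_patches <- function(map, max_hops = 6L, connectivity = 4L,
                           slide_id = NULL, max_patches = Inf, seed = 1L) {
  sid <- slide_id %||%
    (if (inherits(map, "prediction_map")) map$slide_id else NA_character_)
  troi <- find_largest_troi(map, connectivity)
  border <- select_border(troi, map, connectivity)
  sel <- expand_hops(border, troi, max_hops, connectivity)
  if (is.finite(max_patches) && nrow(sel) > max_patches) {
    keep <- integer(0)
    for (dd in sort(unique(sel$d))) {
      ring <- which(sel$d == dd)
      room <- max_patches - length(keep)
      if (room <= 0) break
      if (length(ring) <= room) {
        keep <- c(keep, ring)
      } else {
        keep <- c(keep, withr::with_seed(derive_seed(seed, dd),
                                         sort(sample(ring, room))))
      }
    }
    sel <- sel[keep, ]
  }
  dplyr::bind_cols(tibble(slide_id = rep(sid, nrow(sel))), sel)
}

#' Summarise a patch selection
#'
#' @param selection Output of [select_patches()] or [expand_hops()].
#' @param troi Optional [find_largest_troi()] result for the same slide.
#' @return List with the tumor-region size (if given), border count and
#'   per-hop-distance counts; serialisable to JSON.
#' @export
selection_summary <- function(selection, troi = NULL) {
  per_d <- as.list(table(selection$d))
  list(
    troi_size = if (!is.null(troi)) troi$size else NA_integer_,
    n_selected = nrow(selection),
    n_border = sum(selection$d == 0),
    per_hop = per_d
  )
}

#' Write a patch selection to CSV
#'
#' Columns: `slide_id`, `row`, `col`, `hop_distance`.
#'
#' @param selection Output of [select_patches()].
#' @param path File path.
#' @export
write_selected_patches <- function(selection, path) {
  out <- dplyr::rename(selection, hop_distance = "d")
  readr::write_csv(out, path)
  invisible(path)
}
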