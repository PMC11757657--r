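#' Per-class precision/recall/F1 report
#'
#' One-vs-rest true/false positives and false negatives per class, with
#' precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`, all reported in
#' percent. An F1 whose precision and recall are both zero is defined as 0.
#' The weighted F1 is the support-weighted mean of the per-class F1s,
#' `sum_c (support_c / n) * F1_c`.
#'
#' @param truth,pred Equal-length label vectors over the three IPS classes.
#' @param levels Class levels (default [ips_levels()]).
#' @return Object of class `score_report`: list with `per_class` (tibble of
#'   `class`, `precision`, `recall`, `f1`, `support`), `weighted_f1` and `n`.
#' @export
classification_report <- function(truth, pred, levels = ips_levels()) {
  if (length(truth) == 0) abort("empty input: no labels to score")
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length")
  }
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  if (anyNA(truth) || anyNA(pred)) abort("labels outside the class set")
  per <- lapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    tibble(class = cl, precision = 100 * precision, recall = 100 * recall,
           f1 = 100 * f1, support = tp + fn)
  })
  per <- dplyr::bind_rows(per)
  wf1 <- sum(per$support / length(truth) * per$f1)
  structure(list(per_class = per, weighted_f1 = wf1, n = length(truth)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> n=%d  weighted F1 = %.2f%%\n", x$n,
              x$weighted_f1))
  print(as.data.frame(x$per_class), digits = 4)
  invisible(x)
}

#' @method tidy score_report
#' @export
tidy.score_report <- function(x, ...) x$per_class

#' @method glance score_report
#' @export
glance.score_report <- function(x, ...) {
  tibble(weighted_f1 = x$weighted_f1, n = x$n)
}

#' Write a score report as JSON (plus readable text)
#'
#' @param report A [classification_report()] result.
#' @param path Output JSON path.
#' @export
write_score_report <- function(report, path) {
  jsonlite::write_json(
    list(weighted_f1 = report$weighted_f1, n = report$n,
         per_class = report$per_class),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' Stratified case-level fold plan
#'
#' Assigns cases to `n_folds` folds, stratified by IPS label: within each
#' class, cases are shuffled (seeded) and dealt round-robin, so per-fold
#' class counts differ by at most one case from the achievable proportions.
#' Splitting at the case level guarantees that all three slides of a case
#' share a fold.
#'
#' @param cases Data frame with `case_id` and `ips_label`.
#' @param n_folds Number of folds (default 5).
#' @param runs_per_fold Training repetitions per fold (default 3).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: tibble of `case_id`, `ips_label`,
#'   `fold`, with `n_folds`, `runs_per_fold` and `seed` attributes.
#' @export
fold_plan <- function(cases, n_folds = 5, runs_per_fold = 3, seed = 1L) {
  stopifnot(all(c("case_id", "ips_label") %in% names(cases)))
  if (n_folds < 2 || n_folds > nrow(cases)) {
    abort("`n_folds` must be between 2 and the number of cases")
  }
  lab <- ips_factor(cases$ips_label)
  fold <- integer(nrow(cases))
  withr::with_seed(seed, {
    start <- 0L
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes to keep fold sizes balanced
      fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
      start <- start + length(idx)
    }
  })
  out <- tibble(case_id = cases$case_id, ips_label = lab, fold = fold)
  attr(out, "n_folds") <- as.integer(n_folds)
  attr(out, "runs_per_fold") <- as.integer(runs_per_fold)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("fold_plan", class(out))
  out
}

#' Materialise the cell-graphs of a synthetic cohort
#'
#' Runs the first pipeline step on every slide of a synthetic cohort: wraps
#' the slide's tissue map as a prediction map, selects representative
#' interface patches with hop distances, synthesises each selected patch's
#' nucleus population (from seeds derived from the cohort seed, so the
#' result is reproducible) and builds its cell-graph. Every graph carries
#' `meta` fields `case_id`, `slide_id`, `row`, `col`, `d` and the case's
#' IPS label (weak supervision).
#'
#' @param cohort A [generate_cohort()] result.
#' @param max_hops Maximum hop distance for patch selection.
#' @param connectivity Grid connectivity (4 or 8).
#' @param k,max_edge_dist,similarity_threshold Cell-graph construction knobs
#'   (see [build_cell_graph()]).
#' @param max_patches_per_slide Optional per-slide cap on selected patches
#'   (see [select_patches()]).
#' @return List of cell-graphs.
#' @export
build_cohort_graphs <- function(cohort, max_hops = 6L, connectivity = 4L,
                                k = 5, max_edge_dist = 50,
                                similarity_threshold = 0,
                                max_patches_per_slide = Inf) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  label_of <- setNames(as.character(cohort$cases$ips_label),
                       cohort$cases$case_id)
  graphs <- vector("list", 0)
  for (si in seq_len(nrow(cohort$slides))) {
    sl <- cohort$slides[si, ]
    pm <- prediction_map(sl$tissue_map[[1]], patch_size = cfg$patch_size,
                         slide_id = sl$slide_id)
    sel <- select_patches(pm, max_hops = max_hops,
                          connectivity = connectivity,
                          max_patches = max_patches_per_slide,
                          seed = derive_seed(cfg$seed, si))
    if (nrow(sel) == 0) next
    gs <- lapply(seq_len(nrow(sel)), function(pi) {
      d_i <- sel$d[pi]
      nuc <- synthesize_nuclei(
        patch_label = "PanNET", hop_distance = d_i,
        slide_score = sl$slide_score, n_nuclei = cfg$n_nuclei,
        seed = derive_seed(cfg$seed, si, sel$row[pi], sel$col[pi]),
        mixing_floor = cfg$mixing_floor, mixing_slope = cfg$mixing_slope,
        mixing_decay = cfg$mixing_decay, patch_size = cfg$patch_size,
        feature_noise = cfg$feature_noise
      )
      build_cell_graph(
        nuc[c("x", "y", NUCLEUS_FEATURES)], k = k,
        max_edge_dist = max_edge_dist,
        similarity_threshold = similarity_threshold,
        meta = list(case_id = sl$case_id, slide_id = sl$slide_id,
                    row = sel$row[pi], col = sel$col[pi], d = d_i,
                    label = label_of[[sl$case_id]])
      )
    })
    graphs <- c(graphs, gs)
  }
  graphs
}

#' Case-level stratified cross-validation of the scoring step
#'
#' Splits cases into stratified folds (all slides of a case share a fold),
#' trains the GNN on the training folds' patches — feature standardisation
#' included, so no test-fold statistics leak into training — and votes
#' patch predictions into case-level scores on the held-out fold. Each fold
#' is repeated `runs_per_fold` times with different training seeds. Reports
#' per-run case-level metrics and their mean and standard deviation over all
#' runs jointly, with per-fold aggregates as diagnostics.
#'
#' @param graphs List of cell-graphs with `meta$case_id` and `meta$label`
#'   (e.g. from [build_cohort_graphs()]).
#' @param cases Data frame with `case_id` and `ips_label`.
#' @param config A [gnn_config()] used for every training run (the run seed
#'   is derived from it per fold and repetition).
#' @param plan Optional [fold_plan()]; built from `cases`, `n_folds`,
#'   `runs_per_fold` and `config$seed` when absent.
#' @param n_folds,runs_per_fold Used when `plan` is absent.
#' @param weight_by_d Passed to [predict_case()].
#' @return Object of class `cv_result`: list with `runs` (per-run tibble of
#'   weighted F1 and per-class F1), `case_predictions`, `summary` (mean and
#'   sd of weighted F1 over runs) and the `plan`.
#' @export
run_cross_validation <- function(graphs, cases, config = gnn_config(),
                                 plan = NULL, n_folds = 5, runs_per_fold = 3,
                                 weight_by_d = FALSE) {
  plan <- plan %||% fold_plan(cases, n_folds, runs_per_fold,
                              seed = config$seed)
  n_folds <- attr(plan, "n_folds")
  runs_per_fold <- attr(plan, "runs_per_fold")
  graph_case <- vapply(graphs, function(g) g$meta$case_id, character(1))
  missing_cases <- setdiff(plan$case_id, graph_case)
  if (length(missing_cases)) {
    abort(paste0("no graphs for case(s): ",
                 paste(head(missing_cases, 5), collapse = ", ")))
  }
  truth <- setNames(as.character(plan$ips_label), plan$case_id)

  run_rows <- list(); pred_rows <- list()
  for (fold in seq_len(n_folds)) {
    test_cases <- plan$case_id[plan$fold == fold]
    train_cases <- plan$case_id[plan$fold != fold]
    train_labels <- ips_factor(truth[train_cases])
    if (length(unique(train_labels)) < 3) {
      miss <- setdiff(ips_levels(), unique(as.character(train_labels)))
      abort(sprintf(
        "fold %d: class %s absent from the training folds (fold sizes: %s)",
        fold, paste(miss, collapse = ","),
        paste(table(plan$fold), collapse = "/")))
    }
    train_graphs <- graphs[graph_case %in% train_cases]
    for (run in seq_len(runs_per_fold)) {
      cfg_run <- config
      cfg_run$seed <- derive_seed(config$seed, fold, run)
      model <- train_gnn(train_graphs, config = cfg_run)
      preds <- dplyr::bind_rows(lapply(test_cases, function(cid) {
        bag <- graphs[graph_case == cid]
        predict_case(model, bag, case_id = cid, weight_by_d = weight_by_d)
      }))
      preds$fold <- fold; preds$run <- run
      preds$truth <- ips_factor(truth[preds$case_id])
      rep_run <- classification_report(preds$truth, preds$.pred)
      f1s <- setNames(rep_run$per_class$f1, rep_run$per_class$class)
      run_rows[[length(run_rows) + 1L]] <- tibble(
        fold = fold, run = run, n_cases = nrow(preds),
        weighted_f1 = rep_run$weighted_f1,
        f1_IPS1 = f1s[["IPS1"]], f1_IPS2 = f1s[["IPS2"]],
        f1_IPS3 = f1s[["IPS3"]]
      )
      pred_rows[[length(pred_rows) + 1L]] <- preds
    }
  }
  runs <- dplyr::bind_rows(run_rows)
  structure(
    list(
      runs = runs,
      case_predictions = dplyr::bind_rows(pred_rows),
      summary = tibble(
        n_runs = nrow(runs),
        mean_weighted_f1 = mean(runs$weighted_f1),
        sd_weighted_f1 = sd(runs$weighted_f1)
      ),
      plan = plan
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d runs (%d folds x %d): weighted F1 %.2f +/- %.2f %%\n",
    x$summary$n_runs, attr(x$plan, "n_folds"), attr(x$plan, "runs_per_fold"),
    x$summary$mean_weighted_f1,
    ifelse(is.na(x$summary$sd_weighted_f1), 0, x$summary$sd_weighted_f1)))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$runs

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary
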