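#' Configuration of the graph neural network classifier
#'
#' @param n_layers Number of message-passing layers (>= 1, default 3).
#' @param hidden Hidden width of the node update MLPs.
#' @param readout Graph readout: `"mean"` (default), `"sum"` or `"max"`.
#' @param dropout Dropout probability on node activations during training.
#' @param lr Adam learning rate.
#' @param epochs Training epochs (full-batch updates).
#' @param batch_size Graphs per mini-batch; `NULL` (default) trains
#'   full-batch, which makes single-threaded runs bitwise reproducible.
#' @param lambda Decay rate of the infiltration loss (>= 0, default 0.5).
#'   0 recovers the ordinary mean cross-entropy.
#' @param seed Integer seed for initialisation (and batching/dropout).
#' @return Object of class `gnn_config`.
#' @export
gnn_config <- function(n_layers = 3, hidden = 16,
                       readout = c("mean", "sum", "max"),
                       dropout = 0, lr = 0.01, epochs = 100,
                       batch_size = NULL, lambda = 0.5, seed = 1L) {
  readout <- match.arg(readout)
  check_scalar_number(n_layers, "n_layers", lower = 1)
  check_scalar_number(hidden, "hidden", lower = 1)
  check_scalar_number(dropout, "dropout", lower = 0, upper = 0.95)
  check_scalar_number(lr, "lr", lower = 1e-8)
  check_scalar_number(epochs, "epochs", lower = 1)
  check_scalar_number(lambda, "lambda", lower = 0)
  structure(
    list(n_layers = as.integer(n_layers), hidden = as.integer(hidden),
         readout = readout, dropout = dropout, lr = lr,
         epochs = as.integer(epochs),
         batch_size = if (!is.null(batch_size)) as.integer(batch_size),
         lambda = lambda, seed = as.integer(seed)),
    class = "gnn_config"
  )
}

#' Hop-distance weights of the infiltration loss
#'
#' Softmax of `-lambda * d` over the batch: weights are positive, sum to 1,
#' and are strictly decreasing in `d` for `lambda > 0`. With `lambda = 0`
#' every patch receives weight `1/n`.
#'
#' @param d Non-negative hop distances, one per patch in the batch.
#' @param lambda Decay rate (>= 0).
#' @return Numeric weights summing to 1.
#' @export
infiltration_weights <- function(d, lambda) {
  if (any(d < 0)) abort("hop distances must be non-negative")
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0) {
    abort("`lambda` must be a single non-negative number")
  }
  z <- -lambda * d
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Distance-weighted classification loss
#'
#' The infiltration loss is a cross-entropy whose per-patch weights decay
#' exponentially with the patch's hop distance from the tumor-parenchyma
#' interface: `L = sum_i w(d_i) * CE_i` with
#' `w(d) = exp(-lambda d) / sum_j exp(-lambda d_j)` (normalised within the
#' batch). Border patches (`d = 0`) therefore dominate the training signal,
#' and `lambda = 0` reduces the loss to the unweighted mean cross-entropy.
#'
#' @param ce Per-patch cross-entropies (non-negative).
#' @param d Per-patch hop distances (same length).
#' @param lambda Decay rate (>= 0).
#' @return Scalar loss.
#' @examples
#' infiltration_loss(c(1, 1), c(0, 1), lambda = log(2)) # weights 2/3, 1/3
#' @export
infiltration_loss <- function(ce, d, lambda) {
  if (length(ce) != length(d)) abort("`ce` and `d` must have equal length")
  sum(infiltration_weights(d, lambda) * ce)
}

# ---- internal: batched forward / backward ---------------------------------

# Collate a list of cell-graphs into one block-diagonal batch.
batch_graphs <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) nrow(g$nodes), integer(1))
  offsets <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  N <- sum(n_nodes)
  X <- do.call(rbind, lapply(graphs, node_feature_matrix))
  ei <- ej <- ew <- vector("list", length(graphs))
  for (g in seq_along(graphs)) {
    e <- graphs[[g]]$edges
    ei[[g]] <- e$from + offsets[g]
    ej[[g]] <- e$to + offsets[g]
    ew[[g]] <- e$weight
  }
  ei <- unlist(ei); ej <- unlist(ej); ew <- unlist(ew)
  A <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(ew, ew),
                            dims = c(N, N))
  gidx <- rep(seq_along(graphs), n_nodes)
  R_mean <- Matrix::sparseMatrix(i = gidx, j = seq_len(N),
                                 x = 1 / n_nodes[gidx],
                                 dims = c(length(graphs), N))
  list(X = X, A = A, gidx = gidx, n_nodes = n_nodes, R_mean = R_mean)
}

init_params <- function(n_features, n_classes, cfg) {
  withr::with_seed(cfg$seed, {
    layers <- vector("list", cfg$n_layers)
    f_in <- n_features
    for (l in seq_len(cfg$n_layers)) {
      h <- cfg$hidden
      layers[[l]] <- list(
        W1 = matrix(rnorm(f_in * h, 0, sqrt(2 / f_in)), f_in, h),
        b1 = rep(0, h),
        W2 = matrix(rnorm(h * h, 0, sqrt(2 / h)), h, h),
        b2 = rep(0, h)
      )
      f_in <- h
    }
    list(layers = layers,
         Wo = matrix(rnorm(cfg$hidden * n_classes, 0, sqrt(2 / cfg$hidden)),
                     cfg$hidden, n_classes),
         bo = rep(0, n_classes))
  })
}

add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

gnn_forward <- function(params, batch, readout, dropmasks = NULL) {
  H <- batch$X
  cache <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    M <- H + as.matrix(batch$A %*% H)
    Z1 <- add_bias(M %*% p$W1, p$b1)
    U <- pmax(Z1, 0)
    Z2 <- add_bias(U %*% p$W2, p$b2)
    Hn <- pmax(Z2, 0)
    if (!is.null(dropmasks)) Hn <- Hn * dropmasks[[l]]
    cache[[l]] <- list(M = M, Z1 = Z1, U = U, Z2 = Z2)
    H <- Hn
  }
  G <- max(batch$gidx)
  if (readout == "mean") {
    Zg <- as.matrix(batch$R_mean %*% H)
    ro <- NULL
  } else if (readout == "sum") {
    Zg <- as.matrix(batch$R_mean %*% (H * batch$n_nodes[batch$gidx]))
    ro <- NULL
  } else {  # max readout: track argmax nodes per graph/channel
    Zg <- matrix(-Inf, G, ncol(H))
    arg <- matrix(0L, G, ncol(H))
    for (g in seq_len(G)) {
      rows <- which(batch$gidx == g)
      sub <- H[rows, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      Zg[g, ] <- sub[cbind(am, seq_len(ncol(H)))]
      arg[g, ] <- rows[am]
    }
    ro <- arg
  }
  logits <- add_bias(Zg %*% params$Wo, params$bo)
  logits_s <- logits - apply(logits, 1, max)
  P <- exp(logits_s) / rowSums(exp(logits_s))
  list(H = H, cache = cache, Zg = Zg, logits = logits, P = P, ro = ro)
}

gnn_backward <- function(params, batch, fwd, Y, w, readout, dropmasks = NULL) {
  G <- nrow(Y)
  dlogits <- (fwd$P - Y) * w
  gWo <- crossprod(fwd$Zg, dlogits)
  gbo <- colSums(dlogits)
  dZg <- dlogits %*% t(params$Wo)
  if (readout == "mean") {
    dH <- as.matrix(Matrix::crossprod(batch$R_mean, dZg))
  } else if (readout == "sum") {
    dH <- as.matrix(Matrix::crossprod(batch$R_mean, dZg)) *
      batch$n_nodes[batch$gidx]
  } else {
    dH <- matrix(0, nrow(fwd$H), ncol(fwd$H))
    for (g in seq_len(G)) {
      dH[cbind(fwd$ro[g, ], seq_len(ncol(dH)))] <-
        dH[cbind(fwd$ro[g, ], seq_len(ncol(dH)))] + dZg[g, ]
    }
  }
  glayers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    cc <- fwd$cache[[l]]
    if (!is.null(dropmasks)) dH <- dH * dropmasks[[l]]
    dZ2 <- dH * (cc$Z2 > 0)
    gW2 <- crossprod(cc$U, dZ2)
    gb2 <- colSums(dZ2)
    dU <- dZ2 %*% t(p$W2)
    dZ1 <- dU * (cc$Z1 > 0)
    gW1 <- crossprod(cc$M, dZ1)
    gb1 <- colSums(dZ1)
    dM <- dZ1 %*% t(p$W1)
    dH <- dM + as.matrix(batch$A %*% dM)  # A is symmetric
    glayers[[l]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  list(layers = glayers, Wo = gWo, bo = gbo)
}

flatten_params <- function(p) {
  unlist(c(lapply(p$layers, function(l) list(l$W1, l$b1, l$W2, l$b2)),
           list(p$Wo, p$bo)))
}

relist_like <- function(flat, p) {
  pos <- 0L
  take <- function(template) {
    n <- length(template)
    out <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(template)) matrix(out, nrow(template), ncol(template)) else out
  }
  layers <- lapply(p$layers, function(l) {
    list(W1 = take(l$W1), b1 = take(l$b1), W2 = take(l$W2), b2 = take(l$b2))
  })
  list(layers = layers, Wo = take(p$Wo), bo = take(p$bo))
}

# ---- training --------------------------------------------------------------

graph_meta_field <- function(graphs, field, default = NULL) {
  vals <- lapply(graphs, function(g) g$meta[[field]])
  if (all(vapply(vals, is.null, logical(1)))) {
    if (is.null(default)) return(NULL)
    return(rep(default, length(graphs)))
  }
  unlist(lapply(vals, function(v) v %||% default))
}

#' Train the graph neural network patch classifier
#'
#' Trains an isomorphism-style message-passing network (sum-aggregation over
#' weighted neighbours, two-layer node updates, configurable readout) to
#' classify cell-graphs into IPS1/IPS2/IPS3, minimising the
#' [infiltration_loss()]: a cross-entropy whose per-patch weight decays
#' exponentially with the patch's hop distance from the tumor-parenchyma
#' interface. Labels follow the weak-supervision scheme of the pipeline: the
#' case-level score is used as the label of every patch selected for that
#' case.
#'
#' Node features are standardised with statistics computed from the training
#' graphs; the statistics are stored in the model and re-applied at
#' inference. Optimisation is full-batch Adam by default, which makes
#' single-threaded runs reproducible from the seed.
#'
#' @param graphs List of cell-graphs. Labels and hop distances are read from
#'   each graph's `meta$label` and `meta$d` unless supplied explicitly.
#' @param labels Optional vector of patch labels (IPS classes).
#' @param d Optional vector of hop distances (defaults to `meta$d`, else 0).
#' @param config A [gnn_config()].
#' @return Object of class `gnn_model`: parameters, config, feature
#'   standardisation statistics, class levels and a per-epoch training `log`.
#' @export
train_gnn <- function(graphs, labels = NULL, d = NULL, config = gnn_config()) {
  if (length(graphs) == 0) abort("empty training set")
  labels <- labels %||% graph_meta_field(graphs, "label")
  if (is.null(labels)) abort("no labels: supply `labels` or set meta$label")
  labels <- ips_factor(labels)
  if (anyNA(labels)) abort("labels must be IPS1/IPS2/IPS3")
  if (length(unique(labels)) < 2) {
    abort("training data must contain at least 2 classes")
  }
  d <- d %||% graph_meta_field(graphs, "d", default = 0)
  if (any(d < 0)) abort("hop distances must be non-negative")

  batch_all <- batch_graphs(graphs)
  stats <- structure(
    tibble(feature = NUCLEUS_FEATURES,
           mean = colMeans(batch_all$X),
           sd = apply(batch_all$X, 2, sd)),
    class = c("graph_feature_stats", class(tibble()))
  )
  batch_all$X <- standardize_matrix(batch_all$X, stats)
  nG <- length(graphs)
  Y <- matrix(0, nG, 3)
  Y[cbind(seq_len(nG), as.integer(labels))] <- 1

  params <- init_params(ncol(batch_all$X), 3, config)
  m_flat <- v_flat <- numeric(length(flatten_params(params)))
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  t_step <- 0L
  log_rows <- vector("list", config$epochs)

  batches <- if (is.null(config$batch_size) || config$batch_size >= nG) {
    list(seq_len(nG))
  } else NULL

  rng_seed <- derive_seed(config$seed, 1L)
  withr::with_seed(rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      idx_order <- if (is.null(batches)) NULL else sample.int(nG)
      epoch_batches <- batches %||%
        split(idx_order, ceiling(seq_along(idx_order) / config$batch_size))
      epoch_loss <- 0
      for (bi in epoch_batches) {
        if (is.null(batches)) {
          bb <- batch_all
          Yb <- Y; db <- d
        } else {
          bb <- batch_graphs(graphs[bi])
          bb$X <- standardize_matrix(bb$X, stats)
          Yb <- Y[bi, , drop = FALSE]; db <- d[bi]
        }
        dropmasks <- NULL
        if (config$dropout > 0) {
          dropmasks <- lapply(seq_len(config$n_layers), function(l) {
            matrix(stats::rbinom(nrow(bb$X) * config$hidden, 1,
                                 1 - config$dropout) / (1 - config$dropout),
                   nrow(bb$X), config$hidden)
          })
        }
        fwd <- gnn_forward(params, bb, config$readout, dropmasks)
        ce <- -log(fwd$P[cbind(seq_len(nrow(Yb)), max.col(Yb))] + 1e-12)
        w <- infiltration_weights(db, config$lambda)
        loss <- sum(w * ce)
        grads <- gnn_backward(params, bb, fwd, Yb, w, config$readout,
                              dropmasks)
        g_flat <- flatten_params(grads)
        p_flat <- flatten_params(params)
        t_step <- t_step + 1L
        m_flat <- beta1 * m_flat + (1 - beta1) * g_flat
        v_flat <- beta2 * v_flat + (1 - beta2) * g_flat^2
        mhat <- m_flat / (1 - beta1^t_step)
        vhat <- v_flat / (1 - beta2^t_step)
        p_flat <- p_flat - config$lr * mhat / (sqrt(vhat) + eps_adam)
        params <- relist_like(p_flat, params)
        epoch_loss <- epoch_loss + loss * length(bi)
      }
      log_rows[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss / nG)
    }
  })

  structure(
    list(params = params, config = config, feature_stats = stats,
         classes = ips_levels(), log = dplyr::bind_rows(log_rows)),
    class = "gnn_model"
  )
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf(
    "<gnn_model> %d message-passing layers, width %d, %s readout; lambda=%g\n",
    x$config$n_layers, x$config$hidden, x$config$readout, x$config$lambda))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              nrow(x$log), x$log$loss[nrow(x$log)]))
  invisible(x)
}

#' @method tidy gnn_model
#' @export
tidy.gnn_model <- function(x, ...) x$log

#' @method glance gnn_model
#' @export
glance.gnn_model <- function(x, ...) {
  tibble(epochs = nrow(x$log), final_loss = x$log$loss[nrow(x$log)],
         lambda = x$config$lambda, n_layers = x$config$n_layers,
         hidden = x$config$hidden)
}

#' Predict patch-level infiltration scores
#'
#' Applies the stored feature standardisation and runs the trained network.
#'
#' @param object A [train_gnn()] model.
#' @param graphs List of cell-graphs (raw, unstandardised).
#' @param ... Unused.
#' @return Tibble with one row per graph: patch metadata (`slide_id`,
#'   `row`, `col`, `d`, `case_id` where present), class probabilities
#'   `p_IPS1..p_IPS3` (summing to 1) and the hard `.pred` factor.
#' @export
predict.gnn_model <- function(object, graphs, ...) {
  if (is.null(object$feature_stats)) {
    abort("model carries no standardization statistics; cannot predict")
  }
  if (length(graphs) == 0) abort("no graphs to predict")
  bb <- batch_graphs(graphs)
  bb$X <- standardize_matrix(bb$X, object$feature_stats)
  fwd <- gnn_forward(object$params, bb, object$config$readout)
  P <- fwd$P
  meta_cols <- lapply(c("case_id", "slide_id", "row", "col", "d"),
                      function(f) graph_meta_field(graphs, f))
  names(meta_cols) <- c("case_id", "slide_id", "row", "col", "d")
  out <- as_tibble(meta_cols[!vapply(meta_cols, is.null, logical(1))])
  if (nrow(out) == 0) out <- tibble(.rows = length(graphs))
  out$p_IPS1 <- P[, 1]; out$p_IPS2 <- P[, 2]; out$p_IPS3 <- P[, 3]
  out$.pred <- ips_factor(ips_levels()[max.col(P, ties.method = "first")])
  out
}

#' Case-level score by voting over the bag of patch predictions
#'
#' All representative patches selected from a case's three slides form one
#' bag. The case score is the plurality vote over the patches' hard class
#' predictions; a tie is broken in favour of the tied class with the highest
#' summed class probability across the bag (and, should that also tie, the
#' lowest class index). The result is invariant to the order of the bag.
#' Hop distances influence training only; an optional distance-weighted vote
#' (`weight_by_d = TRUE`, weights `exp(-lambda d)`) is provided for
#' sensitivity analyses.
#'
#' @param model A trained [train_gnn()] model.
#' @param graphs Non-empty list of the case's cell-graphs.
#' @param case_id Optional case identifier (defaults to the graphs' meta).
#' @param weight_by_d Use distance-decayed vote weights instead of the
#'   unweighted vote.
#' @return Object of class `case_prediction`: one-row tibble with `case_id`,
#'   `.pred`, per-class vote tallies `n_IPS1..n_IPS3` and `n_patches`.
#' @export
predict_case <- function(model, graphs, case_id = NULL, weight_by_d = FALSE) {
  if (length(graphs) == 0) {
    abort("no representative patches: the case bag is empty")
  }
  case_id <- case_id %||% graph_meta_field(graphs, "case_id")[1] %||%
    NA_character_
  pred <- predict(model, graphs)
  votes <- as.integer(pred$.pred)
  vote_w <- rep(1, length(votes))
  if (weight_by_d) {
    dd <- pred$d %||% rep(0, length(votes))
    vote_w <- exp(-model$config$lambda * dd)
  }
  winner <- vote_bag(votes, as.matrix(pred[c("p_IPS1", "p_IPS2", "p_IPS3")]),
                     vote_w)
  out <- tibble(
    case_id = case_id,
    .pred = ips_factor(ips_levels()[winner]),
    n_IPS1 = sum(votes == 1), n_IPS2 = sum(votes == 2),
    n_IPS3 = sum(votes == 3),
    n_patches = length(votes)
  )
  class(out) <- c("case_prediction", class(out))
  out
}

# Plurality vote over hard patch classes; ties broken by the summed class
# probability over the bag, then by the lowest class index.
vote_bag <- function(votes, probs, weights = rep(1, length(votes))) {
  tally <- vapply(1:3, function(k) sum(weights[votes == k]), numeric(1))
  winners <- which(tally == max(tally))
  if (length(winners) > 1) {
    psum <- colSums(probs)
    winners <- winners[order(-psum[winners], winners)]
  }
  winners[1]
}

#' Save and load a trained model checkpoint
#'
#' The checkpoint is a versioned JSON document holding the network weights,
#' the [gnn_config()] and the feature-standardisation statistics, so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model A [train_gnn()] model.
#' @param path Checkpoint path (JSON).
#' @return `read_gnn_model()` returns the restored `gnn_model`.
#' @export
write_gnn_model <- function(model, path) {
  stopifnot(inherits(model, "gnn_model"))
  doc <- list(
    format = "pannetips-gnn",
    version = 1L,
    config = unclass(model$config),
    feature_stats = as.data.frame(model$feature_stats),
    classes = model$classes,
    layers = lapply(model$params$layers, function(l) {
      list(W1 = l$W1, b1 = l$b1, W2 = l$W2, b2 = l$b2)
    }),
    Wo = model$params$Wo, bo = model$params$bo,
    log = as.data.frame(model$log)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_gnn_model
#' @export
read_gnn_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "pannetips-gnn")) {
    abort("not a gnn model checkpoint")
  }
  cfg <- doc$config
  config <- gnn_config(
    n_layers = cfg$n_layers, hidden = cfg$hidden, readout = cfg$readout,
    dropout = cfg$dropout, lr = cfg$lr, epochs = cfg$epochs,
    batch_size = cfg$batch_size, lambda = cfg$lambda, seed = cfg$seed
  )
  as_mat <- function(x) if (is.matrix(x)) x else as.matrix(x)
  params <- list(
    layers = lapply(doc$layers, function(l) {
      list(W1 = as_mat(l$W1), b1 = as.numeric(l$b1),
           W2 = as_mat(l$W2), b2 = as.numeric(l$b2))
    }),
    Wo = as_mat(doc$Wo), bo = as.numeric(doc$bo)
  )
  stats <- structure(as_tibble(doc$feature_stats),
                     class = c("graph_feature_stats", class(tibble())))
  structure(
    list(params = params, config = config, feature_stats = stats,
         classes = doc$classes, log = as_tibble(doc$log)),
    class = "gnn_model"
  )
}

#' Node attention map (graph Grad-CAM)
#'
#' Explains a prediction by the gradient of the target class score with
#' respect to the last message-passing layer's node activations: the
#' gradient is channel-averaged into channel weights, the weighted node
#' activations are rectified at zero, and the scores are normalised so the
#' maximum is 1 (when any score is positive). Nodes with identical features
#' and neighbourhoods receive identical scores.
#'
#' @param model A trained [train_gnn()] model.
#' @param graph A single cell-graph.
#' @param target_class Class to explain (`"IPS1"`, `"IPS2"` or `"IPS3"`).
#' @return Numeric vector of per-node attention scores in `[0, 1]`.
#' @export
node_attention_map <- function(model, graph, target_class) {
  if (!inherits(model, "gnn_model") || is.null(model$params)) {
    abort("`model` must be a trained gnn_model")
  }
  k <- match(target_class, ips_levels())
  if (is.na(k)) abort("`target_class` must be one of IPS1, IPS2, IPS3")
  gstd <- standardize_features(list(graph), model$feature_stats)
  bb <- batch_graphs(gstd)
  fwd <- gnn_forward(model$params, bb, model$config$readout)
  # d(logit_k)/dH differs across nodes only by the readout weight, which the
  # final max-normalisation cancels; the channel weights are Wo[, k].
  alpha <- model$params$Wo[, k]
  score <- pmax(as.numeric(fwd$H %*% alpha), 0)
  if (max(score) > 0) score <- score / max(score)
  score
}
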