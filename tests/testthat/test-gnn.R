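test_that("infiltration loss reduces to mean cross-entropy at lambda 0", {
  withr::with_seed(1, {
    ce <- runif(20, 0, 3)
    d <- sample(0:6, 20, TRUE)
  })
  expect_lt(abs(infiltration_loss(ce, d, 0) - mean(ce)), 1e-12)
  # equal distances neutralise lambda
  expect_equal(infiltration_loss(ce, rep(3, 20), 5), mean(ce),
               tolerance = 1e-12)
})

test_that("infiltration loss matches the closed-form two-patch example", {
  expect_equal(infiltration_weights(c(0, 1), log(2)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(infiltration_loss(c(1, 1), c(0, 1), log(2)), 1,
               tolerance = 1e-12)
})

test_that("infiltration weights normalise, decay strictly, and validate", {
  d <- 0:6
  for (lam in c(0.25, 0.5, 2)) {
    w <- infiltration_weights(d, lam)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w) < 0))
  }
  expect_error(infiltration_weights(c(0, -1), 0.5), "non-negative")
  expect_error(infiltration_loss(c(1, 1), c(0, 1), -0.1), "non-negative")
  expect_error(infiltration_loss(c(1, 1, 1), c(0, 1), 0.5), "equal length")
})

small_graphs <- function(n, seed, d_vals = 0, n_nuclei = 12) {
  lapply(seq_len(n), function(i) {
    lab <- c("IPS1", "IPS2", "IPS3")[(i %% 3) + 1]
    score <- c(IPS1 = 1, IPS2 = 3, IPS3 = 5)[lab]
    nuc <- synthesize_nuclei("PanNET", 0, score, n_nuclei,
                             seed = seed * 1000 + i, feature_noise = 0.8,
                             mixing_floor = 0.05, mixing_slope = 0.2)
    build_cell_graph(nuc[c("x", "y", "area", "eccentricity", "solidity",
                           "intensity", "perimeter")],
                     meta = list(case_id = sprintf("c%d", i), d = d_vals,
                                 label = lab))
  })
}

test_that("analytic gradients match finite differences", {
  graphs <- small_graphs(6, seed = 2)
  cfg <- gnn_config(n_layers = 2, hidden = 5, epochs = 1, seed = 3,
                    lambda = 0.7)
  bb <- pannetips:::batch_graphs(graphs)
  stats <- compute_feature_stats(graphs)
  bb$X <- pannetips:::standardize_matrix(bb$X, stats)
  params <- pannetips:::init_params(5, 3, cfg)
  y <- c(1, 2, 3, 1, 2, 3)
  d <- c(0, 1, 2, 0, 1, 2)
  Y <- matrix(0, 6, 3); Y[cbind(1:6, y)] <- 1
  w <- infiltration_weights(d, cfg$lambda)

  loss_at <- function(flat) {
    p <- pannetips:::relist_like(flat, params)
    fwd <- pannetips:::gnn_forward(p, bb, "mean")
    ce <- -log(fwd$P[cbind(1:6, y)] + 1e-12)
    sum(w * ce)
  }
  fwd <- pannetips:::gnn_forward(params, bb, "mean")
  grads <- pannetips:::gnn_backward(params, bb, fwd, Y, w, "mean")
  g_flat <- pannetips:::flatten_params(grads)
  p_flat <- pannetips:::flatten_params(params)

  idx <- withr::with_seed(5, sample(length(p_flat), 25))
  eps <- 1e-5
  for (i in idx) {
    up <- p_flat; up[i] <- up[i] + eps
    dn <- p_flat; dn[i] <- dn[i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(g_flat[i], num, tolerance = 1e-4)
  }
})

test_that("training is reproducible and learns an easy patch task", {
  # interface graphs whose class determines the nucleus mixture directly
  # (slide phenotypes 1/3/5), i.e. fully informative patch labels
  graphs <- small_graphs(240, seed = 51, n_nuclei = 30)
  test_graphs <- small_graphs(90, seed = 52, n_nuclei = 30)
  truth <- vapply(test_graphs, function(g) g$meta$label, character(1))

  cfg <- gnn_config(n_layers = 2, hidden = 10, epochs = 50, lr = 0.02,
                    seed = 4)
  m1 <- train_gnn(graphs, config = cfg)
  m2 <- train_gnn(graphs, config = cfg)
  expect_identical(tidy(m1)$loss, tidy(m2)$loss)
  expect_lt(tidy(m1)$loss[50], tidy(m1)$loss[1])

  pred <- predict(m1, test_graphs)
  rep <- classification_report(truth, pred$.pred)
  expect_gte(rep$weighted_f1, 80)

  # label permutation null: within 10 points of the class-prior baseline
  shuffled <- withr::with_seed(9, sample(vapply(graphs, function(g)
    g$meta$label, character(1))))
  m_null <- train_gnn(graphs, labels = shuffled, config = cfg)
  pred_null <- predict(m_null, test_graphs)
  prior <- max(table(truth)) / length(truth)
  acc_null <- mean(as.character(pred_null$.pred) == truth)
  expect_lt(acc_null, prior + 0.10)
})

test_that("training input is validated", {
  graphs <- small_graphs(4, seed = 8)
  expect_error(train_gnn(list()), "empty")
  expect_error(train_gnn(graphs, labels = rep("IPS1", 4)), "2 classes")
  expect_error(train_gnn(graphs, d = c(-1, 0, 0, 0)), "non-negative")
})

test_that("case voting is plurality with deterministic tie-breaks", {
  graphs <- small_graphs(6, seed = 12)
  model <- train_gnn(graphs,
                     config = gnn_config(n_layers = 1, hidden = 6,
                                         epochs = 10, seed = 1))
  # permutation invariance of the bag
  bag <- graphs
  p1 <- predict_case(model, bag, case_id = "k")
  p2 <- predict_case(model, rev(bag), case_id = "k")
  expect_equal(p1$.pred, p2$.pred)
  expect_equal(p1$n_patches, 6)
  expect_equal(p1$n_IPS1 + p1$n_IPS2 + p1$n_IPS3, p1$n_patches)
  expect_error(predict_case(model, list()), "no representative patches")
})

test_that("vote tallies follow hard patch predictions, ties by probability", {
  vote <- pannetips:::vote_bag
  # unanimous bag
  un <- matrix(rep(c(0.1, 0.8, 0.1), 5), ncol = 3, byrow = TRUE)
  expect_equal(vote(rep(2L, 5), un), 2L)
  # plurality 5-3-2
  pl <- matrix(0.05, 10, 3)
  pl[1:5, 1] <- 0.9; pl[6:8, 2] <- 0.9; pl[9:10, 3] <- 0.9
  expect_equal(vote(rep(1:3, c(5, 3, 2)), pl), 1L)
  # 4-4-2 tie resolved by summed probability in favour of the second class
  tie <- rbind(
    matrix(rep(c(0.60, 0.35, 0.05), 4), ncol = 3, byrow = TRUE),
    matrix(rep(c(0.05, 0.90, 0.05), 4), ncol = 3, byrow = TRUE),
    matrix(rep(c(0.10, 0.10, 0.80), 2), ncol = 3, byrow = TRUE)
  )
  expect_equal(vote(rep(1:3, c(4, 4, 2)), tie), 2L)
  # exact double tie falls back to the lowest class index
  flat <- matrix(1 / 3, 4, 3)
  expect_equal(vote(c(1L, 1L, 3L, 3L), flat), 1L)
})

test_that("model checkpoints restore predictions exactly", {
  graphs <- small_graphs(9, seed = 33)
  model <- train_gnn(graphs, config = gnn_config(n_layers = 2, hidden = 6,
                                                 epochs = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_gnn_model(model, path)
  back <- read_gnn_model(path)
  p1 <- predict(model, graphs)
  p2 <- predict(back, graphs)
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_equal(back$config$lambda, model$config$lambda)
  expect_error(read_gnn_model(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "checkpoint")
})

test_that("node attention is normalised and symmetric for identical nodes", {
  graphs <- small_graphs(6, seed = 14)
  model <- train_gnn(graphs,
                     config = gnn_config(n_layers = 2, hidden = 6,
                                         epochs = 15, seed = 2))
  att <- node_attention_map(model, graphs[[1]], "IPS3")
  expect_true(all(att >= 0 & att <= 1))
  if (any(att > 0)) expect_equal(max(att), 1)

  # all-identical isolated nodes share one attention score
  one <- toy_nuclei(1, seed = 3)
  same <- dplyr::bind_rows(one, one, one)
  same$x <- c(0, 100, 200); same$y <- 0
  g_same <- build_cell_graph(same, max_edge_dist = 10)
  att_same <- node_attention_map(model, g_same, "IPS1")
  expect_equal(length(unique(round(att_same, 12))), 1)

  expect_error(node_attention_map(structure(list(), class = "list"),
                                  graphs[[1]], "IPS1"), "trained")
  expect_error(node_attention_map(model, graphs[[1]], "IPS9"), "target_class")
})

test_that("interface graphs draw more attention to parenchyma-like nodes", {
  coh <- generate_cohort(easy_config(18, seed = 31))
  graphs <- build_cohort_graphs(coh, max_hops = 0,
                                max_patches_per_slide = 8)
  model <- train_gnn(graphs, config = gnn_config(n_layers = 2, hidden = 10,
                                                 epochs = 40, lr = 0.02,
                                                 seed = 6))
  # regenerate the nuclei of IPS3 interface patches to recover components
  labs <- vapply(graphs, function(g) g$meta$label, character(1))
  att_par <- c(); att_tum <- c()
  for (g in graphs[labs == "IPS3"][1:20]) {
    att <- node_attention_map(model, g, "IPS3")
    comp <- g$nodes$intensity > 0.475  # parenchyma-like are brighter
    if (any(comp) && any(!comp)) {
      att_par <- c(att_par, mean(att[comp]))
      att_tum <- c(att_tum, mean(att[!comp]))
    }
  }
  expect_gt(mean(att_par), mean(att_tum))
})
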