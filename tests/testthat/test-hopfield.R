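two_clique_fixture <- function() {
  # two disconnected triangles plus one unknown node hanging off each
  edges <- tibble::tibble(
    from = c("a1", "a1", "a2", "a1", "b1", "b1", "b2", "b1"),
    to = c("a2", "a3", "a3", "aU", "b2", "b3", "b3", "bU"),
    weight = 1
  )
  net <- toy_network(edges)
  ann <- tibble::tibble(
    protein = c("a1", "a2", "a3", "b1", "b2", "b3"),
    term = c("T", "T", "T", "other", "other", "other"),
    evidence = "EXP"
  )
  list(network = net, annotations = ann)
}

test_that("provisional initialization matches the labeled class balance", {
  labels <- tibble::tibble(
    protein = sprintf("p%03d", 1:150),
    label = c(rep("positive", 5), rep("negative", 45), rep("unknown", 100))
  )
  init <- hopfield_init(labels, seed = 4)
  expect_length(init, 100)
  expect_equal(sum(init), 10)  # 10% of 100
  expect_identical(init, hopfield_init(labels, seed = 4))
  expect_false(identical(init, hopfield_init(labels, seed = 5)))
  none <- hopfield_init(labels[1:50, ], seed = 1)
  expect_length(none, 0)
})

test_that("parameter learning separates separable labeled points", {
  fx <- two_clique_fixture()
  labels <- hopfield_labels(fx$network, fx$annotations, "T")
  params <- hopfield_learn(fx$network, labels)
  expect_equal(params$training_f1, 1)
  expect_gt(sin(params$alpha), 0)
  expect_gt(cos(params$alpha), 0)

  # one positive and one negative with distinct points: any separator works
  edges <- tibble::tibble(from = c("p", "n"), to = c("x", "y"), weight = c(1, 1))
  net <- toy_network(edges)
  ann <- tibble::tibble(protein = c("p", "n", "x", "y"),
                        term = c("T", "o", "T", "o"), evidence = "EXP")
  lab <- hopfield_labels(net, ann, "T")
  expect_equal(hopfield_learn(net, lab)$training_f1, 1)

  expect_error(
    hopfield_learn(fx$network, dplyr::mutate(labels, label = "positive")),
    "at least one"
  )
})

test_that("learning on label-free structure degrades to the class-rate baseline", {
  # labels independent of the graph: training F cannot beat the positive-rate
  # baseline 2p/(1+p) by much
  f1s <- vapply(1:10, function(s) {
    inst <- random_hopfield_instance(80, seed = 100 + s, pos_frac = 0.2)
    inst$labels$label[inst$labels$label == "unknown"] <- "negative"
    inst$labels$label <- sample(inst$labels$label)
    hopfield_learn(inst$network, inst$labels)$training_f1
  }, numeric(1))
  p <- 0.2 * 0.6 / 0.8
  baseline <- 2 * p / (1 + p)
  expect_lt(mean(f1s), baseline + 0.25)
})

test_that("dynamics settle into clique-consistent equilibria", {
  fx <- two_clique_fixture()
  labels <- hopfield_labels(fx$network, fx$annotations, "T")
  params <- hopfield_learn(fx$network, labels)
  dyn <- hopfield_dynamics(fx$network, labels, params, cost = 0, seed = 1)
  expect_true(dyn$converged)
  states <- setNames(dyn$states, labels$protein)
  expect_gt(states[["aU"]], 0)
  expect_lt(states[["bU"]], 0)

  # unbounded cost drives every unknown negative
  dyn_inf <- hopfield_dynamics(fx$network, labels, params, cost = 1e9, seed = 1)
  expect_true(all(dyn_inf$states[labels$label == "unknown"] < 0))

  # zero-weight graph: activation is -gamma - cost <= 0, all negative
  zero <- fx$network
  igraph::E(zero)$weight <- 0
  dynz <- hopfield_dynamics(zero, labels, list(alpha = pi / 4, gamma = 0.1),
                            cost = 0.1, seed = 1)
  expect_true(all(dynz$states[labels$label == "unknown"] < 0))
})

test_that("energy never increases along asynchronous updates", {
  for (s in 1:20) {
    inst <- random_hopfield_instance(sample(20:100, 1), seed = 300 + s)
    params <- hopfield_learn(inst$network, inst$labels)
    dyn <- hopfield_dynamics(inst$network, inst$labels, params,
                             cost = 10^runif(1, -6, 0), seed = s,
                             record_energy = TRUE)
    expect_true(all(diff(dyn$energy_trace) <= 1e-9))
    expect_true(dyn$converged)
  }
})

test_that("raising the cost never increases the positive count", {
  fx <- two_clique_fixture()
  grid <- 10^seq(1, -10)
  counts <- vapply(grid, function(lambda) {
    col <- hopfield_predict_term(fx$network, fx$annotations, "T",
                                 cost = lambda, seed = 7)
    sum(col$state == 1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  inst <- random_hopfield_instance(120, seed = 55)
  ann <- tibble::tibble(
    protein = inst$labels$protein[inst$labels$label != "unknown"],
    term = ifelse(inst$labels$label[inst$labels$label != "unknown"] == "positive",
                  "T", "other"),
    evidence = "EXP"
  )
  counts2 <- vapply(grid, function(lambda) {
    col <- hopfield_predict_term(inst$network, ann, "T", cost = lambda, seed = 3)
    sum(col$state == 1, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts2) >= 0))
})

test_that("per-term prediction abstains without labeled support and is deterministic", {
  fx <- two_clique_fixture()
  nopos <- hopfield_predict_term(fx$network, fx$annotations, "absent-term")
  expect_true(all(is.na(nopos$state)))
  expect_setequal(nopos$protein, c("aU", "bU"))

  col1 <- hopfield_predict_term(fx$network, fx$annotations, "T", seed = 11)
  col2 <- hopfield_predict_term(fx$network, fx$annotations, "T", seed = 11)
  expect_identical(col1, col2)
  expect_equal(col1$state[col1$protein == "aU"], 1)
  expect_equal(col1$state[col1$protein == "bU"], 0)
})

test_that("noiseless planted labels are recovered for the masked nodes", {
  cfg <- simulation_config(n_proteins = 120, n_complexes = 12,
                           complex_size_range = c(4, 6), n_baits = 50,
                           fn_rate = 0, fp_rate = 0, allow_overlap = FALSE,
                           n_proteoform_genes = 0, master_fraction = 0,
                           complex_annotation_prob = 1, annotation_rate = 0,
                           upe1_fraction = 0.1, seed = 23)
  sim <- simulate_apms_study(cfg)
  net <- build_network(score_pairs(count_cooccurrence(sim$purifications)), 0.5)
  preds <- predict_functions(net, sim$annotations,
                             unknowns = sim$truth$upe1_mask, cost = 1e-5,
                             seed = 2)
  truth <- sim$truth$true_annotations
  masked_in_net <- intersect(sim$truth$upe1_mask, igraph::V(net)$name)
  for (p in masked_in_net) {
    true_terms <- truth$term[truth$protein == p]
    called <- preds$term[preds$protein == p & !is.na(preds$state) & preds$state == 1]
    evaluable <- intersect(called, unique(sim$annotations$term))
    expect_true(all(evaluable %in% true_terms))
  }
})

test_that("the prediction matrix has the full shape with abstentions flagged", {
  fx <- two_clique_fixture()
  preds <- predict_functions(fx$network, fx$annotations, dag = NULL,
                             terms = c("T", "other", "ghost"))
  expect_equal(nrow(preds), 2 * 3)
  expect_true(all(is.na(preds$state[preds$term == "ghost"])))
  empty <- predict_functions(fx$network, fx$annotations, terms = character())
  expect_equal(nrow(empty), 0)
  g <- glance(preds)
  expect_equal(g$n_terms, 3)
})

test_that("cost search honours the grid and the smallest-cost tie-break", {
  fx <- two_clique_fixture()
  # labeled sets are too small to evaluate: every cost ties at NA -> smallest
  single <- hopfield_cost_search(fx$network, fx$annotations, grid = 0.5)
  expect_equal(single$best_cost, 0.5)

  cfg <- simulation_config(n_proteins = 150, n_complexes = 15, n_baits = 40,
                           fn_rate = 0.05, fp_rate = 0.2,
                           n_proteoform_genes = 0, master_fraction = 0,
                           seed = 31)
  sim <- simulate_apms_study(cfg)
  net <- build_network(score_pairs(count_cooccurrence(sim$purifications)), 0.2)
  terms <- unique(sim$annotations$term)[1:4]
  search <- hopfield_cost_search(net, sim$annotations, terms = terms,
                                 grid = c(10, 1e-5), seed = 5)
  expect_true(search$best_cost %in% c(10, 1e-5))
  expect_equal(nrow(search$results), 2)
  # informative network: the best cost is at least as good as the largest
  f_largest <- search$results$mean_f1[search$results$cost == 10]
  f_best <- max(search$results$mean_f1, na.rm = TRUE)
  expect_gte(f_best, f_largest)
})
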