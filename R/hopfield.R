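# internal adjacency representation: neighbor index + weight lists per node
graph_adjacency <- function(network) {
  nodes <- igraph::V(network)$name
  df <- igraph::as_data_frame(network, what = "edges")
  w <- df$weight %||% rep(1, nrow(df))
  i <- match(df$from, nodes)
  j <- match(df$to, nodes)
  f <- factor(c(i, j), levels = seq_along(nodes))
  nbr <- split(c(j, i), f)
  wts <- split(c(w, w), f)
  list(nodes = nodes, nbr = nbr, w = wts)
}

#' Per-term node labels on a PPI network
#'
#' A node is `positive` for a term when it is annotated with that term,
#' `negative` when it carries at least one annotation but not this term, and
#' `unknown` when it has no visible annotation (or is listed explicitly in
#' `unknowns`, e.g. the uPE1 set).
#'
#' @param network A [build_network()] graph.
#' @param annotations Visible annotation tibble (`protein`, `term`).
#' @param term Term id.
#' @param unknowns Optional character vector of proteins to force into the
#'   unknown class even if annotated.
#' @return Tibble `protein`, `label` in node order.
#' @export
hopfield_labels <- function(network, annotations, term, unknowns = NULL) {
  nodes <- igraph::V(network)$name
  ann <- filter(as_tibble(annotations), .data$protein %in% nodes)
  if (!is.null(unknowns)) ann <- filter(ann, !.data$protein %in% unknowns)
  annotated <- unique(ann$protein)
  positives <- unique(ann$protein[ann$term == term])
  tibble(
    protein = nodes,
    label = dplyr::case_when(
      nodes %in% positives ~ "positive",
      nodes %in% annotated ~ "negative",
      TRUE ~ "unknown"
    )
  )
}

#' Provisional bipolar initialization of unknown nodes
#'
#' Unknown nodes are randomly assigned provisional positive/negative classes
#' in the same proportion as the labeled nodes (proportional rounding), so
#' the dynamics start from a configuration with realistic class balance.
#'
#' @param labels A [hopfield_labels()] tibble.
#' @param seed Integer seed (fixed seed gives an identical assignment).
#' @return Logical vector over the unknown nodes (in label order):
#'   `TRUE` = provisional positive.
#' @export
hopfield_init <- function(labels, seed = 1L) {
  n_pos <- sum(labels$label == "positive")
  n_neg <- sum(labels$label == "negative")
  if (n_pos + n_neg == 0) abort("no labeled nodes for this term")
  unknown_idx <- which(labels$label == "unknown")
  n_unknown <- length(unknown_idx)
  k <- round(n_pos / (n_pos + n_neg) * n_unknown)
  with_seed(seed, {
    prov <- rep(FALSE, n_unknown)
    if (k > 0) prov[sample.int(n_unknown, k)] <- TRUE
    prov
  })
}

#' Learn Hopfield neuron parameters on the labeled subnetwork
#'
#' Each labeled node is summarised by the point `(P_i, N_i)`: its total edge
#' weight to labeled positives and to labeled negatives. A finite sweep over
#' neuron angles `alpha` and activation thresholds `gamma` selects the
#' linear rule `sin(alpha) * P - cos(alpha) * N - gamma > 0` maximising the
#' F-score on the labeled nodes (the cost-sensitive step that copes with
#' heavily unbalanced term labelings). Ties break toward the larger margin,
#' then the smaller angle.
#'
#' @param network A [build_network()] graph.
#' @param labels A [hopfield_labels()] tibble (needs at least one positive
#'   and one negative).
#' @param n_alpha Number of candidate angles in `(0, pi/2)`.
#' @param max_gamma Cap on the number of candidate thresholds.
#' @return List `alpha`, `gamma`, `training_f1`, `n_pos`, `n_neg`.
#' @export
hopfield_learn <- function(network, labels, n_alpha = 64, max_gamma = 128) {
  adj <- if (is.list(network) && !igraph::is_igraph(network)) network else graph_adjacency(network)
  lab <- labels$label
  lab_idx <- which(lab != "unknown")
  pos_set <- which(lab == "positive")
  neg_set <- which(lab == "negative")
  if (length(pos_set) == 0 || length(neg_set) == 0) {
    abort("learning requires at least one labeled positive and one labeled negative")
  }
  pn <- vapply(lab_idx, function(i) {
    nb <- adj$nbr[[i]]
    w <- adj$w[[i]]
    c(sum(w[nb %in% pos_set]), sum(w[nb %in% neg_set]))
  }, numeric(2))
  p_i <- pn[1, ]
  n_i <- pn[2, ]
  is_pos <- lab[lab_idx] == "positive"
  alphas <- pi / 2 * seq_len(n_alpha) / (n_alpha + 1)
  if (length(unique(p_i)) == 1 && length(unique(n_i)) == 1) {
    z <- sin(pi / 4) * p_i - cos(pi / 4) * n_i
    return(list(
      alpha = pi / 4, gamma = median(z), training_f1 = 0,
      n_pos = length(pos_set), n_neg = length(neg_set)
    ))
  }
  best <- list(f1 = -1, margin = -Inf, alpha = Inf, gamma = Inf)
  for (a in alphas) {
    z <- sin(a) * p_i - cos(a) * n_i
    uz <- sort(unique(z))
    if (length(uz) > max_gamma) {
      uz <- unique(unname(quantile(uz, seq(0, 1, length.out = max_gamma),
                                   type = 1)))
    }
    # candidate thresholds at midpoints between consecutive projections:
    # same training decisions as data-value cuts, but with maximal margin
    mid <- if (length(uz) > 1) (uz[-1] + uz[-length(uz)]) / 2 else numeric()
    cand <- c(min(z) - 1, mid, max(z) + 1)
    pred <- outer(z, cand, ">")
    tp <- colSums(pred & is_pos)
    fp <- colSums(pred & !is_pos)
    fn <- sum(is_pos) - tp
    denom <- 2 * tp + fp + fn
    f1 <- ifelse(denom > 0, 2 * tp / denom, 0)
    k <- which.max(f1)
    margin <- min(abs(z - cand[k]))
    better <- f1[k] > best$f1 ||
      (f1[k] == best$f1 && (margin > best$margin ||
        (margin == best$margin && (a < best$alpha ||
          (a == best$alpha && cand[k] < best$gamma)))))
    if (better) {
      best <- list(f1 = f1[k], margin = margin, alpha = a, gamma = cand[k])
    }
  }
  list(
    alpha = best$alpha, gamma = best$gamma, training_f1 = best$f1,
    n_pos = length(pos_set), n_neg = length(neg_set)
  )
}

#' Hopfield energy of a state configuration
#'
#' `E(x) = -1/2 * sum_ij w_ij x_i x_j + sum_i theta_i x_i`, the Lyapunov
#' function of the asynchronous dynamics: it never increases along single
#' node updates, which guarantees convergence to a fixed point.
#'
#' @param network A [build_network()] graph (or internal adjacency list).
#' @param states Numeric state vector over the nodes.
#' @param theta Activation threshold(s): the learned `gamma` plus
#'   regularization cost (plus any per-node centring offset); scalar or one
#'   value per node.
#' @return Scalar energy.
#' @export
hopfield_energy <- function(network, states, theta) {
  adj <- if (is.list(network) && !igraph::is_igraph(network)) network else graph_adjacency(network)
  quad <- sum(vapply(seq_along(adj$nodes), function(i) {
    sum(adj$w[[i]] * states[adj$nbr[[i]]]) * states[i]
  }, numeric(1)))
  -quad / 2 + sum(theta * states)
}

#' Run the regularized asynchronous Hopfield dynamics
#'
#' Labeled nodes are clamped at `sin(alpha)` (positive) or `-cos(alpha)`
#' (negative) and act as a fixed external field; unknown nodes are updated
#' asynchronously in a fixed seeded permutation, each taking the positive
#' value iff its weighted input exceeds its threshold. The additive cost
#' regularizes the dynamics toward the negative (majority) class. Sweeps
#' repeat until no state changes (an equilibrium, guaranteed to exist by the
#' energy argument) or `max_sweeps` is hit.
#'
#' Unknown nodes start either at the decisions of the learned linear rule
#' applied to the labeled field (`init = "field"`, the default: relaxation
#' then starts from the best labeled-only solution) or at random provisional
#' classes drawn in the labeled class proportion (`init = "proportional"`,
#' via [hopfield_init()]); a logical provisional-positive vector is also
#' accepted. With `center = TRUE` (default) each node's threshold carries a
#' constant offset equal to its unknown-neighbor weight sum times the mean
#' initial unknown state, so the dynamics respond to deviations from the
#' starting configuration rather than to its bulk: the learned `gamma` is
#' calibrated on labeled-only fields, and without centring the extra input
#' from unknown neighbors systematically inflates activations. Thresholds
#' stay constant during the run, so the energy argument is untouched.
#'
#' @param network A [build_network()] graph.
#' @param labels A [hopfield_labels()] tibble.
#' @param params A [hopfield_learn()] parameter list.
#' @param cost Regularization cost `lambda >= 0`.
#' @param init `"field"`, `"proportional"`, or a logical
#'   provisional-positive vector over the unknown nodes.
#' @param center Centre the unknown-neighbor field at the initial-state
#'   mean?
#' @param seed Seed for the proportional initialization and the update
#'   order.
#' @param max_sweeps Sweep cap.
#' @param record_energy Record the Lyapunov energy after every single node
#'   update (adds an `energy_trace` element; intended for diagnostics, it
#'   slows the dynamics down).
#' @return List `states` (numeric, node order), `activations`
#'   (`sum w x - theta_i`, NA for labeled nodes), `converged`, `sweeps`,
#'   `params`, `theta` (per-node thresholds).
#' @export
hopfield_dynamics <- function(network, labels, params, cost = 0,
                              init = c("field", "proportional"),
                              center = TRUE, seed = 1L, max_sweeps = 100,
                              record_energy = FALSE) {
  if (cost < 0) abort("`cost` must be non-negative")
  adj <- if (is.list(network) && !igraph::is_igraph(network)) network else graph_adjacency(network)
  pos_val <- sin(params$alpha)
  neg_val <- -cos(params$alpha)
  lab <- labels$label
  n <- length(lab)
  unknown_idx <- which(lab == "unknown")
  pos_set <- which(lab == "positive")
  neg_set <- which(lab == "negative")
  x <- numeric(n)
  x[pos_set] <- pos_val
  x[neg_set] <- neg_val
  if (is.character(init)) {
    init <- match.arg(init)
    if (init == "proportional") {
      prov <- hopfield_init(labels, seed)
    } else {
      # labeled-field rule: provisional positive iff the learned line fires
      prov <- vapply(unknown_idx, function(i) {
        nb <- adj$nbr[[i]]
        w <- adj$w[[i]]
        z <- sin(params$alpha) * sum(w[nb %in% pos_set]) -
          cos(params$alpha) * sum(w[nb %in% neg_set])
        z > params$gamma
      }, logical(1))
    }
  } else {
    prov <- init
  }
  x[unknown_idx] <- ifelse(prov, pos_val, neg_val)
  theta <- rep(params$gamma + cost, n)
  if (center && length(unknown_idx) > 0) {
    xbar <- mean(x[unknown_idx])
    is_unknown <- logical(n)
    is_unknown[unknown_idx] <- TRUE
    offsets <- vapply(seq_len(n), function(i) {
      sum(adj$w[[i]][is_unknown[adj$nbr[[i]]]])
    }, numeric(1))
    theta <- theta + offsets * xbar
  }
  order_idx <- with_seed(seed + 1L, {
    if (length(unknown_idx) > 0) unknown_idx[sample.int(length(unknown_idx))] else integer()
  })
  sweeps <- 0
  converged <- length(order_idx) == 0
  energy_trace <- if (record_energy) hopfield_energy(adj, x, theta) else NULL
  while (!converged && sweeps < max_sweeps) {
    sweeps <- sweeps + 1
    changed <- FALSE
    for (i in order_idx) {
      h <- sum(adj$w[[i]] * x[adj$nbr[[i]]])
      new <- if (h - theta[i] > 0) pos_val else neg_val
      if (new != x[i]) {
        x[i] <- new
        changed <- TRUE
      }
      if (record_energy) {
        energy_trace <- c(energy_trace, hopfield_energy(adj, x, theta))
      }
    }
    if (!changed) converged <- TRUE
  }
  act <- rep(NA_real_, n)
  for (i in unknown_idx) {
    act[i] <- sum(adj$w[[i]] * x[adj$nbr[[i]]]) - theta[i]
  }
  out <- list(
    states = x, activations = act, converged = converged,
    sweeps = sweeps, params = params, theta = theta
  )
  if (record_energy) out$energy_trace <- energy_trace
  out
}

term_seed <- function(seed, term) {
  as.integer((as.double(seed) * 7919 + sum(utf8ToInt(term))) %% 2147483647)
}

#' Predict one GO term for the unknown nodes of a network
#'
#' Composes labeling, provisional initialization, parameter learning and the
#' regularized dynamics for a single term. The classifier abstains for the
#' whole column when fewer than `min_positives` labeled positives (or no
#' labeled negative) exist, and abstains on individual nodes whose final
#' activation sits within `epsilon` of the decision threshold (data too thin
#' for a reliable call).
#'
#' @inheritParams hopfield_dynamics
#' @param annotations Visible annotation tibble.
#' @param term Term id.
#' @param unknowns Optional forced-unknown proteins (e.g. the uPE1 list).
#' @param min_positives Minimum labeled positives required to attempt the
#'   term (default 2).
#' @param epsilon_frac Abstention band around the threshold, as a fraction
#'   of the largest nodewise weight sum (default `1e-8`).
#' @return Tibble `protein`, `term`, `state` (1 positive, 0 negative, NA
#'   abstained) over the unknown nodes, with the learned parameters in the
#'   `"params"` attribute.
#' @export
hopfield_predict_term <- function(network, annotations, term, unknowns = NULL,
                                  cost = 1e-5, seed = 1L, min_positives = 2,
                                  epsilon_frac = 1e-8, max_sweeps = 100,
                                  init = c("field", "proportional"),
                                  center = TRUE) {
  adj <- graph_adjacency(network)
  labels <- hopfield_labels(network, annotations, term, unknowns)
  unknown <- labels$protein[labels$label == "unknown"]
  abstain_all <- function(reason) {
    out <- tibble(protein = unknown, term = term, state = NA_real_)
    attr(out, "params") <- NULL
    attr(out, "abstained") <- reason
    out
  }
  n_pos <- sum(labels$label == "positive")
  n_neg <- sum(labels$label == "negative")
  if (n_pos < min_positives || n_neg < 1) {
    return(abstain_all("insufficient labeled nodes"))
  }
  params <- hopfield_learn(adj, labels)
  ts <- term_seed(seed, term)
  dyn <- hopfield_dynamics(adj, labels, params, cost = cost, seed = ts,
                           max_sweeps = max_sweeps, init = init,
                           center = center)
  max_wsum <- max(vapply(adj$w, function(w) sum(abs(w)), numeric(1)), 0)
  eps <- epsilon_frac * max_wsum
  idx <- match(unknown, labels$protein)
  state <- ifelse(dyn$states[idx] > 0, 1, 0)
  state[abs(dyn$activations[idx]) < eps] <- NA_real_
  out <- tibble(protein = unknown, term = term, state = state)
  attr(out, "params") <- params
  attr(out, "converged") <- dyn$converged
  out
}

#' Weighted majority-vote baseline for one term
#'
#' Predicts an unknown node positive when the summed edge weight to labeled
#' positives exceeds that to labeled negatives. A deliberately simple
#' neighborhood-vote reference against which the Hopfield classifier is
#' compared.
#'
#' @inheritParams hopfield_predict_term
#' @return Tibble `protein`, `term`, `state` over unknown nodes.
#' @export
baseline_majority_vote <- function(network, annotations, term, unknowns = NULL) {
  adj <- graph_adjacency(network)
  labels <- hopfield_labels(network, annotations, term, unknowns)
  pos_set <- which(labels$label == "positive")
  neg_set <- which(labels$label == "negative")
  unknown_idx <- which(labels$label == "unknown")
  state <- vapply(unknown_idx, function(i) {
    nb <- adj$nbr[[i]]
    w <- adj$w[[i]]
    as.numeric(sum(w[nb %in% pos_set]) > sum(w[nb %in% neg_set]))
  }, numeric(1))
  tibble(protein = labels$protein[unknown_idx], term = term, state = state)
}

#' Predict all terms for the unknown proteins
#'
#' Runs [hopfield_predict_term()] once per term and assembles the long
#' binary prediction table. Each (protein, term) cell is exactly one of
#' predicted-positive (1), predicted-negative (0) or abstained (NA).
#'
#' @inheritParams hopfield_predict_term
#' @param terms Terms to predict (default: all terms in `annotations`).
#' @param dag Optional [go_dag()]; adds a `namespace` column.
#' @param exclude_terms Terms dropped from [glance()] summaries (but kept in
#'   the matrix), e.g. a ubiquitous protein-binding term.
#' @return A `function_predictions` tibble `protein`, `term`, (`namespace`,)
#'   `state`, with provenance (cost, seed, per-term training F1) in
#'   attributes.
#' @export
predict_functions <- function(network, annotations, unknowns = NULL,
                              terms = NULL, dag = NULL, cost = 1e-5,
                              seed = 1L, min_positives = 2,
                              exclude_terms = character(), ...) {
  terms <- terms %||% sort(unique(as_tibble(annotations)$term))
  cols <- purrr::map(terms, function(t) {
    col <- hopfield_predict_term(
      network, annotations, t, unknowns = unknowns,
      cost = cost, seed = seed, min_positives = min_positives, ...
    )
    prm <- attr(col, "params")
    attr(col, "provenance") <- tibble(
      term = t,
      training_f1 = if (is.null(prm)) NA_real_ else prm$training_f1,
      alpha = if (is.null(prm)) NA_real_ else prm$alpha,
      gamma = if (is.null(prm)) NA_real_ else prm$gamma,
      n_pos = if (is.null(prm)) 0L else prm$n_pos
    )
    col
  })
  out <- bind_rows(cols)
  if (nrow(out) == 0) {
    out <- tibble(protein = character(), term = character(), state = numeric())
  }
  if (!is.null(dag)) {
    out <- left_join(out, select(dag$terms, term = "id", "namespace"), by = "term")
    out <- select(out, "protein", "term", "namespace", "state")
  }
  attr(out, "provenance") <- bind_rows(purrr::map(cols, attr, "provenance"))
  attr(out, "cost") <- cost
  attr(out, "seed") <- seed
  attr(out, "exclude_terms") <- exclude_terms
  class(out) <- c("function_predictions", class(out))
  out
}

#' @exportS3Method generics::glance
glance.function_predictions <- function(x, ...) {
  excl <- attr(x, "exclude_terms") %||% character()
  kept <- filter(as_tibble(x), !.data$term %in% excl)
  tibble(
    n_proteins = length(unique(x$protein)),
    n_terms = length(unique(x$term)),
    n_predicted_positive = sum(kept$state == 1, na.rm = TRUE),
    n_predicted_negative = sum(kept$state == 0, na.rm = TRUE),
    n_abstained = sum(is.na(kept$state)),
    n_proteins_with_prediction = length(unique(kept$protein[!is.na(kept$state) & kept$state == 1])),
    cost = attr(x, "cost") %||% NA_real_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.function_predictions <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(outcome = dplyr::case_when(
      is.na(.data$state) ~ "abstained",
      .data$state == 1 ~ "positive",
      TRUE ~ "negative"
    )) |>
    count(.data$term, .data$outcome)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$n, fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "unknown proteins", fill = NULL,
                  title = "Per-term prediction outcomes") +
    ggplot2::theme_minimal()
}

#' Held-out evaluation of a per-term predictor
#'
#' Hides a random `1 - split` fraction of each term's labeled nodes, asks
#' the predictor to classify them, and scores F1 against the hidden truth.
#' Terms left with fewer than two labeled nodes in either class after the
#' split are excluded.
#'
#' @inheritParams predict_functions
#' @param split Training fraction of labeled nodes (default 0.8).
#' @param predictor `"hopfield"` or `"majority"` (the vote baseline).
#' @return Tibble `term`, `f1`, `n_test` (one row per evaluable term).
#' @export
evaluate_holdout <- function(network, annotations, terms = NULL, split = 0.8,
                             cost = 1e-5, seed = 1L,
                             predictor = c("hopfield", "majority")) {
  predictor <- match.arg(predictor)
  if (split <= 0 || split >= 1) abort("`split` must be in (0, 1)")
  annotations <- as_tibble(annotations)
  terms <- terms %||% sort(unique(annotations$term))
  nodes <- igraph::V(network)$name
  rows <- purrr::map(terms, function(t) {
    labels <- hopfield_labels(network, annotations, t)
    labeled <- labels$protein[labels$label != "unknown"]
    if (length(labeled) < 4) return(NULL)
    hidden <- with_seed(term_seed(seed, t), {
      sample(labeled, max(1, round((1 - split) * length(labeled))))
    })
    train_lab <- labels$label[match(setdiff(labeled, hidden), labels$protein)]
    if (sum(train_lab == "positive") < 2 || sum(train_lab == "negative") < 2) {
      return(NULL)
    }
    train_ann <- filter(annotations, !.data$protein %in% hidden)
    pred <- if (predictor == "hopfield") {
      hopfield_predict_term(network, train_ann, t, unknowns = hidden,
                            cost = cost, seed = seed)
    } else {
      baseline_majority_vote(network, train_ann, t, unknowns = hidden)
    }
    pred <- filter(pred, .data$protein %in% hidden)
    truth_pos <- labels$protein[labels$label == "positive"]
    tp <- sum(pred$state == 1 & pred$protein %in% truth_pos, na.rm = TRUE)
    fp <- sum(pred$state == 1 & !pred$protein %in% truth_pos, na.rm = TRUE)
    fn <- sum(hidden %in% truth_pos) - tp
    denom <- 2 * tp + fp + fn
    tibble(term = t, f1 = if (denom > 0) 2 * tp / denom else 0,
           n_test = length(hidden))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(term = character(), f1 = numeric(), n_test = integer()) else out
}

#' Grid search over the regularization cost
#'
#' For each candidate cost, runs a fresh held-out evaluation (the 80/20
#' split is re-drawn per cost) and averages the per-term F1. Returns the
#' cost with the highest mean F1; exact ties break toward the smallest cost.
#'
#' @inheritParams evaluate_holdout
#' @param grid Candidate costs; default the 12 decade values from `10^1`
#'   down to `10^-10`.
#' @return A `cost_search` list: `best_cost`, `results` (tibble `cost`,
#'   `mean_f1`, `n_terms`).
#' @export
hopfield_cost_search <- function(network, annotations, terms = NULL,
                                 grid = 10^seq(1, -10), split = 0.8,
                                 seed = 1L) {
  if (length(grid) == 0) abort("`grid` must be non-empty")
  results <- purrr::imap(grid, function(cost, k) {
    ev <- evaluate_holdout(
      network, annotations, terms = terms, split = split,
      cost = cost, seed = derive_seed(seed, 100L + k),
      predictor = "hopfield"
    )
    tibble(cost = cost, mean_f1 = if (nrow(ev) > 0) mean(ev$f1) else NA_real_,
           n_terms = nrow(ev))
  }) |>
    bind_rows()
  ok <- which(!is.na(results$mean_f1))
  best <- if (length(ok) == 0) {
    min(grid)
  } else {
    cand <- results$cost[ok][results$mean_f1[ok] == max(results$mean_f1[ok])]
    min(cand)
  }
  structure(list(best_cost = best, results = results), class = "cost_search")
}

#' @export
print.cost_search <- function(x, ...) {
  cat("<cost_search> best cost = ", format(x$best_cost, digits = 3), "\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cost_search <- function(x, ...) x$results
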