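# Independent brute-force oracles and tiny fixture builders shared across
# the suite. These deliberately avoid the package's own counting/scoring
# code paths.

# long purification tibble from a list of character vectors (first element
# of each record is the bait)
purif_table <- function(records) {
  if (length(records) == 0) {
    return(tibble::tibble(purification_id = character(), bait = character(),
                          protein = character()))
  }
  dplyr::bind_rows(lapply(seq_along(records), function(k) {
    r <- unique(records[[k]])
    tibble::tibble(
      purification_id = sprintf("AP%03d", k),
      bait = r[1],
      protein = r
    )
  }))
}

# exhaustive pairwise scan: q, n_i, n_j and Dice for every protein pair
brute_force_pair_scan <- function(records) {
  records <- lapply(records, unique)
  prots <- sort(unique(unlist(records)))
  empty <- tibble::tibble(
    protein_a = character(), protein_b = character(), q = integer(),
    n_a = integer(), n_b = integer(), dice = numeric()
  )
  if (length(prots) < 2) return(empty)
  out <- list()
  for (a_i in seq_along(prots)) {
    for (b_i in seq_len(a_i - 1)) {
      a <- prots[b_i]
      b <- prots[a_i]
      q <- sum(vapply(records, function(r) a %in% r && b %in% r, logical(1)))
      na <- sum(vapply(records, function(r) a %in% r, logical(1)))
      nb <- sum(vapply(records, function(r) b %in% r, logical(1)))
      denom <- 2 * q + (na - q) + (nb - q)
      out[[length(out) + 1]] <- tibble::tibble(
        protein_a = a, protein_b = b, q = q, n_a = na, n_b = nb,
        dice = if (denom > 0) 2 * q / denom else NA_real_
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), protein_a, protein_b)
}

# exhaustive hypergeometric upper tail: place protein i in purifications
# 1..n_i, enumerate every subset of size n_j for protein j
brute_force_hyper <- function(q, n_i, n_j, n_total) {
  if (n_j == 0) return(as.numeric(q <= 0))
  subsets <- utils::combn(n_total, n_j)
  overlaps <- colSums(subsets <= n_i)
  mean(overlaps >= q)
}

# set-algebra confusion oracle on pair tibbles
brute_force_confusion <- function(predicted, gold) {
  key <- function(df) {
    unique(paste(pmin(df$protein_a, df$protein_b),
                 pmax(df$protein_a, df$protein_b)))
  }
  pk <- key(predicted)
  gk <- key(gold)
  tp <- sum(pk %in% gk)
  fp <- sum(!pk %in% gk)
  fn <- sum(!gk %in% pk)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}

# small hand-checkable DAG: one namespace rooted at `root`
toy_dag <- function() {
  terms <- tibble::tibble(
    id = c("root", "A", "B", "C", "T", "child"),
    name = paste("term", c("root", "A", "B", "C", "T", "child")),
    namespace = "biological_process"
  )
  edges <- tibble::tibble(
    id = c("A", "B", "C", "T", "T", "child"),
    parent = c("root", "root", "B", "A", "C", "root"),
    relation = "is_a"
  )
  go_dag(terms, edges)
}

# weighted undirected test network from an edge tibble (from, to, weight)
toy_network <- function(edges, isolated = character()) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = unique(c(edges$from, edges$to, isolated)))
  class(g) <- c("ppi_network", class(g))
  g
}

# random Hopfield instance: Erdos-Renyi weighted graph + unbalanced labels
random_hopfield_instance <- function(n, seed, p = NULL, pos_frac = 0.15) {
  set.seed(seed)
  p <- p %||% min(1, 4 / n)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n))
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.05, 1)
  class(g) <- c("ppi_network", class(g))
  lab <- sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                prob = c(pos_frac * 0.6, (1 - pos_frac) * 0.6, 0.4))
  if (sum(lab == "positive") < 2) lab[seq_len(2)] <- "positive"
  if (sum(lab == "negative") < 1) lab[3] <- "negative"
  list(network = g, labels = tibble::tibble(protein = igraph::V(g)$name, label = lab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
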