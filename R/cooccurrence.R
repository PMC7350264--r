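#' Normalize proteoform accessions in a purification table
#'
#' Applies the master-form rule: identifications reported as an unresolved
#' "master" accession are replaced by the gene's canonical accession (the
#' specific proteoform cannot be determined, so the canonical form stands in
#' for it). Splice accessions are kept distinct, and duplicates created by
#' the substitution are collapsed within each purification.
#'
#' @param purifications Tibble `purification_id`, `bait`, `protein` (long
#'   format, one identified protein per row; the bait appears among its own
#'   record's proteins).
#' @param proteoform_map Tibble `gene`, `accession`, `form` with `form` in
#'   `canonical`/`splice`/`master`.
#' @return The normalized purification table.
#' @export
normalize_forms <- function(purifications, proteoform_map) {
  purifications <- as_tibble(purifications)
  proteoform_map <- as_tibble(proteoform_map)
  canon <- proteoform_map |>
    filter(.data$form == "canonical") |>
    select("gene", canonical = "accession")
  masters <- proteoform_map |>
    filter(.data$form == "master") |>
    left_join(canon, by = "gene")
  orphans <- masters$accession[is.na(masters$canonical)]
  if (length(orphans) > 0) {
    abort(paste0(
      "master accessions with no canonical mapping: ",
      paste(orphans, collapse = ", ")
    ))
  }
  lut <- setNames(masters$canonical, masters$accession)
  hit_m <- purifications$protein %in% names(lut)
  purifications$protein[hit_m] <- lut[purifications$protein[hit_m]]
  hit_b <- purifications$bait %in% names(lut)
  purifications$bait[hit_b] <- lut[purifications$bait[hit_b]]
  distinct(purifications, .data$purification_id, .data$bait, .data$protein)
}

#' Count pairwise co-occurrence across purifications
#'
#' Under the matrix model every pair of proteins identified in the same
#' purification — bait-prey and prey-prey alike — is a candidate
#' interaction. Counts `q(i,j)` (purifications containing both) and `n(i)`
#' (purifications containing `i`); only pairs with `q > 0` are materialized.
#'
#' @param purifications Long purification tibble (`purification_id`, `bait`,
#'   `protein`).
#' @return A `cooccurrence_counts` object: list with `pairs` (tibble
#'   `protein_a`, `protein_b`, `q`, ordered `protein_a < protein_b`), `n`
#'   (named occurrence counts), and `n_purifications`.
#' @export
count_cooccurrence <- function(purifications) {
  purifications <- as_tibble(purifications)
  if (nrow(purifications) == 0) {
    return(structure(
      list(
        pairs = tibble(protein_a = character(), protein_b = character(), q = integer()),
        n = setNames(integer(), character()),
        n_purifications = 0L
      ),
      class = "cooccurrence_counts"
    ))
  }
  purifications <- distinct(
    purifications, .data$purification_id, .data$protein
  )
  ids <- unique(purifications$purification_id)
  prots <- sort(unique(purifications$protein))
  m <- Matrix::sparseMatrix(
    i = match(purifications$purification_id, ids),
    j = match(purifications$protein, prots),
    x = 1,
    dims = c(length(ids), length(prots))
  )
  q <- Matrix::crossprod(m)
  n <- setNames(as.integer(Matrix::diag(q)), prots)
  qt <- Matrix::triu(q, k = 1)
  idx <- Matrix::summary(qt)
  pairs <- tibble(
    protein_a = prots[idx$i],
    protein_b = prots[idx$j],
    q = as.integer(idx$x)
  ) |>
    arrange(.data$protein_a, .data$protein_b)
  structure(
    list(pairs = pairs, n = n, n_purifications = length(ids)),
    class = "cooccurrence_counts"
  )
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat("<cooccurrence_counts> ", length(x$n), " proteins, ",
      nrow(x$pairs), " co-occurring pairs over ",
      x$n_purifications, " purifications\n", sep = "")
  invisible(x)
}

#' Dice coefficient from co-occurrence counts
#'
#' `D = 2q / (2q + r + s)` where `q` counts purifications containing both
#' proteins, `r` those containing only the first and `s` only the second.
#' Vectorized.
#'
#' @param q,r,s Non-negative co-occurrence counts.
#' @return Dice score(s) in `[0, 1]`.
#' @export
dice_score <- function(q, r, s) {
  if (any(q < 0 | r < 0 | s < 0)) abort("counts must be non-negative")
  denom <- 2 * q + r + s
  if (any(denom == 0)) {
    abort("Dice score undefined for q = r = s = 0")
  }
  2 * q / denom
}

#' Hart hypergeometric co-occurrence score
#'
#' Upper-tail probability that two proteins observed in `n_i` and `n_j` of
#' `N` purifications co-occur at least `q` times by chance, under the
#' hypergeometric model (population `N`, `n_i` successes, `n_j` draws).
#' Smaller values indicate stronger evidence of interaction. Vectorized.
#'
#' @param q Observed co-occurrence count.
#' @param n_i,n_j Per-protein occurrence counts.
#' @param n_purifications Total number of purifications `N`.
#' @return p-value(s) in `(0, 1]`.
#' @export
hart_score <- function(q, n_i, n_j, n_purifications) {
  if (any(n_i > n_purifications | n_j > n_purifications)) {
    abort("occurrence counts cannot exceed the number of purifications")
  }
  if (any(q > pmin(n_i, n_j))) {
    abort("q cannot exceed min(n_i, n_j)")
  }
  phyper(q - 1, n_i, n_purifications - n_i, n_j, lower.tail = FALSE)
}

#' Score all co-occurring pairs
#'
#' Computes, for every materialized pair, the counts `q`, `r`, `s`, the Dice
#' coefficient and the Hart hypergeometric p-value.
#'
#' @param counts A [count_cooccurrence()] result, or a long purification
#'   tibble (counted on the fly).
#' @return A `scored_pairs` tibble: `protein_a`, `protein_b`, `q`, `n_a`,
#'   `n_b`, `r`, `s`, `dice`, `hart_p`, with attributes `n_purifications`
#'   and `universe`.
#' @export
score_pairs <- function(counts) {
  if (!inherits(counts, "cooccurrence_counts")) {
    counts <- count_cooccurrence(counts)
  }
  pairs <- counts$pairs |>
    mutate(
      n_a = unname(counts$n[.data$protein_a]),
      n_b = unname(counts$n[.data$protein_b]),
      r = .data$n_a - .data$q,
      s = .data$n_b - .data$q,
      dice = dice_score(.data$q, .data$r, .data$s),
      hart_p = hart_score(.data$q, .data$n_a, .data$n_b, counts$n_purifications)
    )
  attr(pairs, "n_purifications") <- counts$n_purifications
  attr(pairs, "universe") <- names(counts$n)
  class(pairs) <- c("scored_pairs", class(pairs))
  pairs
}

#' Build the thresholded PPI network
#'
#' Two proteins interact when their score is strictly beyond the threshold:
#' Dice strictly greater than `threshold`, or Hart p-value strictly below it
#' when `metric = "hart"`. Edge weights always carry the Dice score. The
#' network is undirected with no self-loops or duplicate edges; only
#' proteins incident to a retained edge appear as vertices.
#'
#' @param scores A [score_pairs()] tibble.
#' @param threshold Numeric threshold in `[0, 1]`.
#' @param metric `"dice"` (default) or `"hart"`.
#' @return A `ppi_network`: an igraph graph with `weight` edge attribute and
#'   graph attributes `threshold` and `metric`.
#' @export
build_network <- function(scores, threshold, metric = c("dice", "hart")) {
  metric <- match.arg(metric)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single value in [0, 1]")
  }
  keep <- if (metric == "dice") {
    scores$dice > threshold
  } else {
    scores$hart_p < threshold
  }
  edges <- as_tibble(scores)[keep, c("protein_a", "protein_b", "dice")]
  g <- igraph::graph_from_data_frame(
    rename(edges, weight = "dice"),
    directed = FALSE
  )
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "metric", metric)
  class(g) <- c("ppi_network", class(g))
  g
}

#' Summary statistics of a PPI network
#'
#' @param network A [build_network()] graph (any igraph works).
#' @param hub_threshold Degree above which a node counts as a hub (strict
#'   `>`, default 150).
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `giant_component_size`, `median_degree`, `n_hubs`; the hub accessions
#'   are attached as the `"hubs"` attribute.
#' @export
network_stats <- function(network, hub_threshold = 150) {
  if (igraph::vcount(network) == 0) {
    out <- tibble(
      n_nodes = 0L, n_edges = 0L, n_components = 0L,
      giant_component_size = 0L, median_degree = 0, n_hubs = 0L
    )
    attr(out, "hubs") <- character()
    return(out)
  }
  comps <- igraph::components(network)
  deg <- igraph::degree(network)
  hubs <- names(sort(deg[deg > hub_threshold], decreasing = TRUE))
  out <- tibble(
    n_nodes = igraph::vcount(network),
    n_edges = igraph::ecount(network),
    n_components = comps$no,
    giant_component_size = max(comps$csize),
    median_degree = median(deg),
    n_hubs = length(hubs)
  )
  attr(out, "hubs") <- hubs
  out
}

#' @exportS3Method generics::glance
glance.ppi_network <- function(x, ...) network_stats(x, ...)

#' @exportS3Method generics::tidy
tidy.ppi_network <- function(x, ...) {
  df <- igraph::as_data_frame(x, what = "edges")
  tibble(protein_a = df$from, protein_b = df$to, weight = df$weight)
}
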