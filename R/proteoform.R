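#' Interactome profiles of network nodes
#'
#' The interactome profile of a protein is its set of network partners. All
#' nodes get a profile; `passes_filter` marks the analysis view of proteins
#' with strictly more than `min_partners` partners.
#'
#' @param network A [build_network()] graph.
#' @param min_partners Strict lower bound on degree for the filtered view
#'   (default 10).
#' @return Tibble `protein`, `partners` (list-column), `degree`,
#'   `passes_filter`.
#' @export
extract_profiles <- function(network, min_partners = 10) {
  nodes <- igraph::V(network)$name
  if (length(nodes) == 0) {
    return(tibble(protein = character(), partners = list(),
                  degree = integer(), passes_filter = logical()))
  }
  adj <- igraph::as_adj_list(network)
  partners <- purrr::map(adj, function(v) sort(unique(names(v))))
  tibble(
    protein = nodes,
    partners = unname(partners),
    degree = lengths(partners),
    passes_filter = lengths(partners) > min_partners
  ) |>
    mutate(partners = purrr::map2(.data$partners, .data$protein, setdiff))
}

#' Difference between two interactome profiles
#'
#' Jaccard distance `1 - |A and B| / |A or B|` between two partner sets
#' (default), or `1 -` overlap coefficient (`|A and B| / min(|A|, |B|)`)
#' with `method = "overlap"`. The two profiled proteins themselves are
#' removed from both partner sets before comparison, so a canonical/splice
#' pair is not penalised for interacting with each other.
#'
#' @param partners_a,partners_b Character vectors of partners.
#' @param proteins Optional length-2 character vector of the profiled
#'   proteins, removed from both sets.
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return Difference fraction in `[0, 1]`.
#' @export
profile_difference <- function(partners_a, partners_b, proteins = NULL,
                               method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  if (!is.null(proteins)) {
    partners_a <- setdiff(partners_a, proteins)
    partners_b <- setdiff(partners_b, proteins)
  }
  partners_a <- unique(partners_a)
  partners_b <- unique(partners_b)
  if (length(partners_a) == 0 && length(partners_b) == 0) {
    abort("profile difference undefined for two empty partner sets")
  }
  common <- length(intersect(partners_a, partners_b))
  shared_frac <- switch(method,
    jaccard = common / length(union(partners_a, partners_b)),
    overlap = common / min(length(partners_a), length(partners_b))
  )
  1 - shared_frac
}

#' Divergence of canonical vs splice interactome profiles
#'
#' Pairs every canonical accession with each splice accession of the same
#' gene (both present in the network with non-empty profiles), computes the
#' profile difference and assigns the exclusive divergence bin
#' (`[0, 0.5)`, `[0.5, 0.75)`, `[0.75, 0.9)`, `[0.9, 1]`).
#'
#' @param network A [build_network()] graph (or an [extract_profiles()]
#'   tibble).
#' @param proteoform_map Tibble `gene`, `accession`, `form`.
#' @param min_partners Only compare forms whose profiles pass the strict
#'   degree filter (default 10; set to 0 to compare every pair).
#' @param method Passed to [profile_difference()].
#' @return Tibble `gene`, `canonical`, `splice`, `degree_canonical`,
#'   `degree_splice`, `difference`, `bin`.
#' @export
profile_divergence <- function(network, proteoform_map, min_partners = 10,
                               method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  profiles <- if (is.data.frame(network)) network else extract_profiles(network, min_partners)
  pmap <- as_tibble(proteoform_map)
  canon <- filter(pmap, .data$form == "canonical")
  splice <- filter(pmap, .data$form == "splice")
  pairs <- inner_join(
    select(canon, "gene", canonical = "accession"),
    select(splice, "gene", splice = "accession"),
    by = "gene",
    relationship = "many-to-many"
  )
  prof <- setNames(profiles$partners, profiles$protein)
  deg <- setNames(profiles$degree, profiles$protein)
  ok <- setNames(profiles$degree > min_partners, profiles$protein)
  rows <- purrr::pmap(pairs, function(gene, canonical, splice) {
    if (!canonical %in% names(prof) || !splice %in% names(prof)) return(NULL)
    if (!isTRUE(ok[[canonical]]) || !isTRUE(ok[[splice]])) return(NULL)
    d <- profile_difference(
      prof[[canonical]], prof[[splice]],
      proteins = c(canonical, splice), method = method
    )
    tibble(
      gene = gene, canonical = canonical, splice = splice,
      degree_canonical = deg[[canonical]], degree_splice = deg[[splice]],
      difference = d
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      gene = character(), canonical = character(), splice = character(),
      degree_canonical = integer(), degree_splice = integer(),
      difference = numeric()
    )
  }
  mutate(out, bin = divergence_bin(.data$difference))
}

divergence_bin <- function(difference) {
  cut(
    difference,
    breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
    labels = c("<50%", ">=50%", ">=75%", ">=90%"),
    right = FALSE
  )
}

#' Bin divergence records into the summary table
#'
#' Counts proteoform pairs per exclusive divergence bin. The bins partition
#' `[0, 1]` (`[0, 0.5)`, `[0.5, 0.75)`, `[0.75, 0.9)`, `[0.9, 1]`) so the
#' row always sums to the pair total.
#'
#' @param records A [profile_divergence()] tibble (needs a `difference`
#'   column).
#' @return One-row tibble `n_pairs`, `<50%`, `>=50%`, `>=75%`, `>=90%`.
#' @export
classify_divergence <- function(records) {
  bins <- divergence_bin(records$difference)
  counts <- table(bins)
  tibble(
    n_pairs = nrow(records),
    `<50%` = as.integer(counts[["<50%"]]),
    `>=50%` = as.integer(counts[[">=50%"]]),
    `>=75%` = as.integer(counts[[">=75%"]]),
    `>=90%` = as.integer(counts[[">=90%"]])
  )
}

#' Group proteins sharing interaction partners into functional components
#'
#' Builds a similarity graph over the filtered profiles with an edge
#' whenever two proteins share strictly more than `share_threshold` of
#' their partners (Jaccard by default), and takes connected components
#' (single linkage). Components are labelled with size classes:
#' `two-protein` (2), `micro` (3-7), then `mini`/`mid`/`macro` by the
#' configurable ascending `size_breaks`. Profiles with no qualifying partner
#' are reported as singletons.
#'
#' @param profiles An [extract_profiles()] tibble (only rows with
#'   `passes_filter` are grouped).
#' @param share_threshold Strict lower bound on the common-partner fraction
#'   (default 0.5).
#' @param method `"jaccard"` or `"overlap"` partner-sharing normalisation.
#' @param size_breaks Named upper bounds for `micro`, `mini`, `mid`
#'   (anything larger is `macro`).
#' @return Tibble `protein`, `component`, `component_size`, `size_class`.
#' @export
build_components <- function(profiles, share_threshold = 0.5,
                             method = c("jaccard", "overlap"),
                             size_breaks = c(micro = 7, mini = 50, mid = 500)) {
  method <- match.arg(method)
  prof <- filter(profiles, .data$passes_filter)
  if (nrow(prof) == 0) {
    return(tibble(protein = character(), component = integer(),
                  component_size = integer(), size_class = character()))
  }
  n <- nrow(prof)
  edges_i <- integer()
  edges_j <- integer()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- 1 - profile_difference(
        prof$partners[[i]], prof$partners[[j]],
        proteins = c(prof$protein[i], prof$protein[j]),
        method = method
      )
      if (shared > share_threshold) {
        edges_i <- c(edges_i, i)
        edges_j <- c(edges_j, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges_i) > 0) {
    g <- igraph::add_edges(g, rbind(edges_i, edges_j))
  }
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  size_class <- dplyr::case_when(
    sizes == 1 ~ "singleton",
    sizes == 2 ~ "two-protein",
    sizes <= size_breaks[["micro"]] ~ "micro",
    sizes <= size_breaks[["mini"]] ~ "mini",
    sizes <= size_breaks[["mid"]] ~ "mid",
    TRUE ~ "macro"
  )
  tibble(
    protein = prof$protein,
    component = as.integer(comp$membership),
    component_size = as.integer(sizes),
    size_class = size_class
  ) |>
    arrange(.data$component, .data$protein)
}

#' Enrich functional components with GO terms
#'
#' Runs the hypergeometric enrichment of each multi-protein component
#' against the reference protein set at the stringent raw cutoff.
#'
#' @param components A [build_components()] tibble.
#' @param annotations Annotation tibble.
#' @param reference Background protein universe.
#' @param alpha Significance cutoff (default `1e-7`).
#' @return Tibble of per-component enriched terms (`component`,
#'   `component_size`, enrichment columns), empty when nothing passes.
#' @export
annotate_components <- function(components, annotations, reference,
                                alpha = 1e-7) {
  comps <- components |>
    filter(.data$component_size >= 2) |>
    group_by(.data$component) |>
    summarise(
      proteins = list(.data$protein),
      component_size = .data$component_size[1],
      .groups = "drop"
    )
  rows <- purrr::pmap(comps, function(component, proteins, component_size) {
    target <- intersect(proteins, reference)
    if (length(target) == 0) return(NULL)
    enr <- go_enrichment(target, reference, annotations, alpha = alpha)
    if (nrow(enr) == 0) return(NULL)
    mutate(enr, component = component, component_size = component_size,
           .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(component = integer(), component_size = integer(),
           term = character(), overlap = integer(), term_size = integer(),
           target_size = integer(), reference_size = integer(),
           p_value = numeric())
  } else {
    out
  }
}

#' Hub proteins of a network
#'
#' @param network A [build_network()] graph.
#' @param min_degree Strict degree threshold (default 150 partners).
#' @return Tibble `protein`, `degree`, sorted by decreasing degree.
#' @export
find_hubs <- function(network, min_degree = 150) {
  if (igraph::vcount(network) == 0) {
    return(tibble(protein = character(), degree = integer()))
  }
  deg <- igraph::degree(network)
  hubs <- deg[deg > min_degree]
  tibble(protein = names(hubs), degree = as.integer(hubs)) |>
    arrange(dplyr::desc(.data$degree), .data$protein)
}

#' Compare predicted functions of canonical and splice forms
#'
#' For every gene whose canonical and splice accessions both received at
#' least one non-abstained prediction, reports the symmetric difference of
#' their predicted-positive term sets per namespace. Abstained cells are
#' excluded from the comparison; genes with one form fully abstained are
#' counted separately in the `"excluded_genes"` attribute.
#'
#' @param predictions A [predict_functions()] tibble (with `namespace` if a
#'   DAG was supplied).
#' @param proteoform_map Tibble `gene`, `accession`, `form`.
#' @return Tibble `gene`, `canonical`, `splice`, `namespace`,
#'   `canonical_only`, `splice_only` (list-columns), `n_disagreements`; only
#'   genes with at least one disagreement are returned.
#' @export
compare_form_predictions <- function(predictions, proteoform_map) {
  pred <- as_tibble(predictions)
  if (!"namespace" %in% names(pred)) pred$namespace <- "all"
  pmap <- as_tibble(proteoform_map)
  pairs <- inner_join(
    select(filter(pmap, .data$form == "canonical"), "gene", canonical = "accession"),
    select(filter(pmap, .data$form == "splice"), "gene", splice = "accession"),
    by = "gene",
    relationship = "many-to-many"
  )
  decided <- filter(pred, !is.na(.data$state))
  pos <- filter(decided, .data$state == 1)
  excluded <- character()
  rows <- purrr::pmap(pairs, function(gene, canonical, splice) {
    has_c <- canonical %in% decided$protein
    has_s <- splice %in% decided$protein
    if (!has_c || !has_s) {
      if (xor(has_c, has_s)) excluded <<- c(excluded, gene)
      return(NULL)
    }
    purrr::map(sort(unique(decided$namespace)), function(ns) {
      tc <- pos$term[pos$protein == canonical & pos$namespace == ns]
      ts <- pos$term[pos$protein == splice & pos$namespace == ns]
      c_only <- setdiff(tc, ts)
      s_only <- setdiff(ts, tc)
      if (length(c_only) == 0 && length(s_only) == 0) return(NULL)
      tibble(
        gene = gene, canonical = canonical, splice = splice, namespace = ns,
        canonical_only = list(c_only), splice_only = list(s_only),
        n_disagreements = length(c_only) + length(s_only)
      )
    }) |>
      bind_rows()
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      gene = character(), canonical = character(), splice = character(),
      namespace = character(), canonical_only = list(), splice_only = list(),
      n_disagreements = integer()
    )
  }
  attr(out, "excluded_genes") <- unique(excluded)
  out
}
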