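#' Construct a GO DAG object
#'
#' Builds the directed acyclic graph backing a Gene Ontology subset: terms
#' belong to one of the three namespaces (`biological_process`,
#' `molecular_function`, `cellular_component`) and child terms point at
#' parents through `is_a` or `part_of` edges. Each namespace must have
#' exactly one root (a term with no parents) reachable from every term in
#' that namespace.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `id` (child), `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @return A `go_dag` object: a list with tibbles `terms` and `edges` plus a
#'   named `roots` vector (one root id per namespace).
#' @export
go_dag <- function(terms, edges) {
  terms <- as_tibble(terms)[, c("id", "name", "namespace")]
  edges <- as_tibble(edges)[, c("id", "parent", "relation")]
  ns_ok <- c("biological_process", "molecular_function", "cellular_component")
  if (!all(terms$namespace %in% ns_ok)) {
    abort("term namespaces must be one of biological_process, molecular_function, cellular_component")
  }
  if (anyDuplicated(terms$id)) abort("duplicated term ids in DAG")
  if (!all(edges$relation %in% c("is_a", "part_of"))) {
    abort("edge relations must be is_a or part_of")
  }
  unknown <- setdiff(c(edges$id, edges$parent), terms$id)
  if (length(unknown) > 0) {
    abort(paste0("edges reference unknown terms: ", paste(head(unknown, 5), collapse = ", ")))
  }
  roots <- terms |>
    filter(!.data$id %in% edges$id) |>
    group_by(.data$namespace) |>
    summarise(root = .data$id[1], n = dplyr::n(), .groups = "drop")
  if (any(roots$n != 1)) {
    abort("each namespace must have exactly one root term")
  }
  dag <- structure(
    list(
      terms = terms,
      edges = edges,
      roots = setNames(roots$root, roots$namespace)
    ),
    class = "go_dag"
  )
  lv <- term_levels(dag)
  if (anyNA(lv$level)) {
    abort("DAG is not rooted: some terms cannot reach their namespace root")
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", nrow(x$terms), " terms, ", nrow(x$edges), " edges\n", sep = "")
  ns <- table(x$terms$namespace)
  for (n in names(ns)) cat("  ", n, ": ", ns[[n]], " terms\n", sep = "")
  invisible(x)
}

# named list child -> tibble(parent, relation)
parent_map <- function(dag) {
  split(dag$edges[c("parent", "relation")], dag$edges$id)
}

#' Term levels (shortest-path depth to the namespace root)
#'
#' The level of a term is the length of the shortest directed path from the
#' term to its namespace root following `is_a` and `part_of` edges; roots are
#' level 0. This is the min-depth convention common in GO tooling. A
#' max-depth convention (longest path) is available via `convention`.
#'
#' @param dag A [go_dag()].
#' @param convention `"min"` (default, shortest path) or `"max"` (longest
#'   path).
#' @return Tibble with columns `id`, `namespace`, `level`.
#' @export
term_levels <- function(dag, convention = c("min", "max")) {
  convention <- match.arg(convention)
  agg <- if (convention == "min") min else max
  level <- setNames(rep(NA_real_, nrow(dag$terms)), dag$terms$id)
  level[dag$roots] <- 0
  # relax child levels from parent levels; DAG depth bounds the iterations
  children <- split(dag$edges$id, dag$edges$parent)
  by_child <- split(dag$edges$parent, dag$edges$id)
  repeat {
    changed <- FALSE
    for (child in names(by_child)) {
      pl <- level[by_child[[child]]]
      if (all(is.na(pl))) next
      cand <- agg(pl, na.rm = TRUE) + 1
      if (is.na(level[child]) || cand != level[child]) {
        if (is.na(level[child]) ||
            (convention == "min" && cand < level[child]) ||
            (convention == "max" && cand > level[child])) {
          level[child] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  tibble(
    id = dag$terms$id,
    namespace = dag$terms$namespace,
    level = as.numeric(level[dag$terms$id])
  )
}

#' Level of a single term
#'
#' @inheritParams term_levels
#' @param term Term id.
#' @return Integer level (root = 0).
#' @export
term_level <- function(dag, term, convention = c("min", "max")) {
  lv <- term_levels(dag, convention)
  hit <- lv$level[lv$id == term]
  if (length(hit) == 0) abort(paste0("unknown term: ", term))
  hit
}

#' All ancestors of a term
#'
#' @param dag A [go_dag()].
#' @param term Term id.
#' @param include_self Include the term itself?
#' @return Character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term, include_self = FALSE) {
  if (!term %in% dag$terms$id) abort(paste0("unknown term: ", term))
  by_child <- split(dag$edges$parent, dag$edges$id)
  seen <- character()
  frontier <- term
  while (length(frontier) > 0) {
    parents <- unique(unlist(by_child[frontier], use.names = FALSE))
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  if (include_self) unique(c(term, seen)) else unique(seen)
}

# ancestor closure for many terms at once: named list term -> ancestors incl self
ancestor_closure <- function(dag, terms = dag$terms$id) {
  by_child <- split(dag$edges$parent, dag$edges$id)
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    parents <- by_child[[t]]
    anc <- t
    for (p in parents) anc <- c(anc, get_anc(p))
    anc <- unique(anc)
    memo[[t]] <- anc
    anc
  }
  setNames(lapply(terms, get_anc), terms)
}

# Wang S-values: semantic contribution of every ancestor of `term`,
# decaying multiplicatively by edge-type weight along the best path
wang_svalues <- function(dag, term, weights = c(is_a = 0.8, part_of = 0.6)) {
  by_child <- split(dag$edges[c("parent", "relation")], dag$edges$id)
  sval <- setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character()
    for (t in frontier) {
      pe <- by_child[[t]]
      if (is.null(pe)) next
      for (k in seq_len(nrow(pe))) {
        p <- pe$parent[k]
        cand <- sval[[t]] * weights[[pe$relation[k]]]
        if (!(p %in% names(sval)) || cand > sval[[p]]) {
          sval[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sval
}

#' Wang semantic similarity between two GO terms
#'
#' Implements the graph-based similarity of Wang et al. (2007): each term's
#' ancestors receive S-values decaying multiplicatively along edges (weight
#' 0.8 for `is_a`, 0.6 for `part_of` by default, taking the best path), and
#' the similarity is the summed S-values of shared ancestors normalised by
#' the two semantic totals. Identical terms score 1; terms from different
#' namespaces score 0 by definition.
#'
#' @param dag A [go_dag()].
#' @param term_a,term_b Term ids.
#' @param weights Named numeric edge-type weights for `is_a` and `part_of`.
#' @return Similarity in `[0, 1]`.
#' @export
wang_similarity <- function(dag, term_a, term_b,
                            weights = c(is_a = 0.8, part_of = 0.6)) {
  ns <- setNames(dag$terms$namespace, dag$terms$id)
  for (t in c(term_a, term_b)) {
    if (!t %in% dag$terms$id) abort(paste0("unknown term: ", t))
  }
  if (ns[[term_a]] != ns[[term_b]]) return(0)
  sa <- wang_svalues(dag, term_a, weights)
  sb <- wang_svalues(dag, term_b, weights)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' Best-match-average Wang similarity between two GO term sets
#'
#' For every term in one set its best Wang similarity in the other set is
#' taken; the two directional means are averaged, yielding a symmetric score
#' in `[0, 1]` (the best-match average combining rule).
#'
#' @param dag A [go_dag()].
#' @param set_a,set_b Non-empty character vectors of term ids.
#' @param weights Passed to [wang_similarity()].
#' @return Similarity in `[0, 1]`.
#' @export
wang_set_similarity <- function(dag, set_a, set_b,
                                weights = c(is_a = 0.8, part_of = 0.6)) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) {
    abort("wang_set_similarity() requires non-empty term sets")
  }
  sim <- matrix(0, length(set_a), length(set_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      sim[i, j] <- wang_similarity(dag, set_a[i], set_b[j], weights)
    }
  }
  (mean(apply(sim, 1, max)) + mean(apply(sim, 2, max))) / 2
}
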