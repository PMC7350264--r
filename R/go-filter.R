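#' Propagate annotations to ancestor terms (true-path rule)
#'
#' Every (protein, term) assignment implies the protein is also annotated
#' with all ancestors of the term; propagated rows carry the evidence code
#' of the originating leaf assignment. Duplicate (protein, term) pairs keep
#' the first evidence code after sorting, so output is deterministic.
#'
#' @param annotations Tibble with columns `protein`, `term`, `evidence`.
#' @param dag A [go_dag()].
#' @return Ancestor-closed annotation tibble.
#' @export
propagate_annotations <- function(annotations, dag) {
  annotations <- as_tibble(annotations)
  if (nrow(annotations) == 0) {
    return(tibble(protein = character(), term = character(), evidence = character()))
  }
  closure <- ancestor_closure(dag, unique(annotations$term))
  out <- annotations |>
    mutate(term = unname(closure[.data$term])) |>
    tidyr::unnest_longer("term")
  out |>
    arrange(.data$protein, .data$term, .data$evidence) |>
    distinct(.data$protein, .data$term, .keep_all = TRUE)
}

#' Per-term protein support
#'
#' @param annotations Annotation tibble (`protein`, `term`, ...).
#' @return Tibble `term`, `support` (distinct proteins per term).
#' @export
term_support <- function(annotations) {
  as_tibble(annotations) |>
    distinct(.data$protein, .data$term) |>
    count(.data$term, name = "support") |>
    rename(term = "term")
}

#' Filter annotations by evidence code
#'
#' Keeps only assignments whose evidence code is in `allowed_codes`; the
#' default set is the six experimental codes (EXP, IDA, IPI, IMP, IGI, IEP),
#' dropping computational annotations such as IEA.
#'
#' @param annotations Annotation tibble with an `evidence` column.
#' @param allowed_codes Character vector of evidence codes to retain.
#' @return Filtered annotation tibble.
#' @export
filter_evidence <- function(annotations,
                            allowed_codes = c("EXP", "IDA", "IPI", "IMP",
                                              "IGI", "IEP")) {
  filter(as_tibble(annotations), .data$evidence %in% allowed_codes)
}

#' Filter out weakly supported GO terms
#'
#' Removes every term supported by fewer than `min_proteins` distinct
#' proteins, together with all its assignments ("supported by less than 10
#' proteins" is removed; support of exactly `min_proteins` is retained).
#'
#' @param annotations Annotation tibble.
#' @param min_proteins Minimum distinct-protein support (default 10).
#' @return Filtered annotation tibble.
#' @export
filter_support <- function(annotations, min_proteins = 10) {
  assert_count(min_proteins, "min_proteins", min = 1)
  keep <- term_support(annotations) |>
    filter(.data$support >= min_proteins)
  semi_join(as_tibble(annotations), keep, by = "term")
}

#' Filter out deep (too specific) GO terms
#'
#' Drops terms whose level — shortest-path distance to the namespace root —
#' is strictly greater than the namespace cutoff. Defaults mirror the usual
#' generality cutoffs: level 10 for BP and CC, level 6 for MF.
#'
#' @param annotations Annotation tibble.
#' @param dag A [go_dag()].
#' @param max_level Named numeric vector of cutoffs with names
#'   `biological_process`, `cellular_component`, `molecular_function` (short
#'   names BP/CC/MF also accepted).
#' @param convention Level convention passed to [term_levels()].
#' @return Filtered annotation tibble.
#' @export
filter_level <- function(annotations, dag,
                         max_level = c(biological_process = 10,
                                       cellular_component = 10,
                                       molecular_function = 6),
                         convention = c("min", "max")) {
  convention <- match.arg(convention)
  short <- c(BP = "biological_process", CC = "cellular_component",
             MF = "molecular_function")
  hits <- names(max_level) %in% names(short)
  names(max_level)[hits] <- short[names(max_level)[hits]]
  if (!all(short %in% names(max_level))) {
    abort("`max_level` must name all three namespaces")
  }
  lv <- term_levels(dag, convention) |>
    mutate(cutoff = unname(max_level[.data$namespace])) |>
    filter(.data$level <= .data$cutoff)
  semi_join(as_tibble(annotations), lv, by = c(term = "id"))
}

#' Hypergeometric GO-term enrichment of a target set
#'
#' For every term annotated to at least one target protein, computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of term-annotated proteins when sampling `|target|` proteins from
#' the reference set. Terms with `p < alpha` are returned sorted by
#' p-value. This is a raw-p cutoff by default (as in single-list GO
#' enrichment at a stringent threshold); Benjamini-Hochberg adjustment is
#' available via `p_adjust`.
#'
#' @param target Character vector of proteins (must be a subset of
#'   `reference`).
#' @param reference Character vector: the background protein universe.
#' @param annotations Annotation tibble (`protein`, `term`).
#' @param alpha Significance cutoff (default `1e-7`).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble `term`, `overlap`, `term_size`, `target_size`,
#'   `reference_size`, `p_value` (and `p_adjusted` if requested), ascending
#'   in p.
#' @export
go_enrichment <- function(target, reference, annotations, alpha = 1e-7,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  target <- unique(target)
  reference <- unique(reference)
  if (length(target) == 0) abort("`target` must be non-empty")
  if (!all(target %in% reference)) {
    abort("`target` must be a subset of `reference`")
  }
  ann <- as_tibble(annotations) |>
    distinct(.data$protein, .data$term) |>
    filter(.data$protein %in% reference)
  sizes <- count(ann, .data$term, name = "term_size")
  hits <- ann |>
    filter(.data$protein %in% target) |>
    count(.data$term, name = "overlap")
  res <- inner_join(hits, sizes, by = "term") |>
    mutate(
      target_size = length(target),
      reference_size = length(reference),
      p_value = phyper(
        .data$overlap - 1, .data$term_size,
        .data$reference_size - .data$term_size,
        .data$target_size,
        lower.tail = FALSE
      )
    )
  if (p_adjust == "BH") {
    res <- mutate(res, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
    res <- filter(res, .data$p_adjusted < alpha)
  } else {
    res <- filter(res, .data$p_value < alpha)
  }
  arrange(res, .data$p_value, .data$term)
}

#' Apply the three-step GO filtering cascade
#'
#' Convenience wrapper running [filter_evidence()], [filter_support()] and
#' [filter_level()] in order on an ancestor-propagated annotation set.
#'
#' @inheritParams filter_level
#' @inheritParams filter_support
#' @inheritParams filter_evidence
#' @return Filtered annotation tibble, with a per-step term-count summary in
#'   the `"filter_summary"` attribute.
#' @export
filter_go_cascade <- function(annotations, dag,
                              allowed_codes = c("EXP", "IDA", "IPI", "IMP",
                                                "IGI", "IEP"),
                              min_proteins = 10,
                              max_level = c(biological_process = 10,
                                            cellular_component = 10,
                                            molecular_function = 6)) {
  n_terms <- function(a) length(unique(a$term))
  a0 <- as_tibble(annotations)
  a1 <- filter_evidence(a0, allowed_codes)
  a2 <- filter_support(a1, min_proteins)
  a3 <- filter_level(a2, dag, max_level)
  attr(a3, "filter_summary") <- tibble(
    step = c("input", "evidence", "support", "level"),
    n_terms = c(n_terms(a0), n_terms(a1), n_terms(a2), n_terms(a3))
  )
  a3
}
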