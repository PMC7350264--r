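make_annotations <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein = vapply(rows, `[[`, "", 1),
    term = vapply(rows, `[[`, "", 2),
    evidence = vapply(rows, `[[`, "", 3)
  )
}

test_that("evidence filtering keeps only experimental codes", {
  ann <- make_annotations(
    c("p1", "T", "EXP"), c("p2", "T", "EXP"), c("p3", "T", "EXP"),
    c("p4", "T", "IEA"), c("p5", "T", "IEA")
  )
  out <- filter_evidence(ann)
  expect_equal(nrow(out), 3)
  expect_true(all(out$evidence == "EXP"))
  expect_equal(nrow(filter_evidence(make_annotations(c("p", "T", "IEA")))), 0)
  all_exp <- make_annotations(c("p", "T", "EXP"))
  expect_identical(filter_evidence(all_exp), all_exp)
})

test_that("support filtering removes terms below the protein threshold", {
  nine <- do.call(make_annotations, lapply(1:9, function(i) c(paste0("p", i), "T9", "EXP")))
  ten <- do.call(make_annotations, lapply(1:10, function(i) c(paste0("p", i), "T10", "EXP")))
  both <- dplyr::bind_rows(nine, ten)
  out <- filter_support(both, 10)
  expect_setequal(unique(out$term), "T10")
  expect_equal(nrow(filter_support(nine[0, ], 10)), 0)
})

test_that("term levels use the shortest path to the namespace root", {
  dag <- toy_dag()
  expect_equal(term_level(dag, "root"), 0)
  expect_equal(term_level(dag, "A"), 1)
  # diamond: T -> A -> root and T -> C -> B -> root; min-depth wins
  expect_equal(term_level(dag, "T"), 2)
  expect_equal(term_level(dag, "T", convention = "max"), 3)
  expect_error(term_level(dag, "nope"), "unknown term")
})

test_that("level filtering drops terms deeper than the namespace cutoff", {
  dag <- toy_dag()
  ann <- make_annotations(
    c("p1", "T", "EXP"), c("p2", "C", "EXP"), c("p3", "root", "EXP")
  )
  out <- filter_level(ann, dag, max_level = c(BP = 1, CC = 10, MF = 6))
  expect_setequal(unique(out$term), "root")
  # boundary: level exactly at the cutoff is retained
  out2 <- filter_level(ann, dag, max_level = c(BP = 2, CC = 10, MF = 6))
  expect_setequal(unique(out2$term), c("T", "C", "root"))
  # permissive cutoff: identity
  out3 <- filter_level(ann, dag, max_level = c(BP = 10, CC = 10, MF = 6))
  expect_identical(out3, ann)
})

test_that("the filter cascade is idempotent, commutative and monotone", {
  cfg <- simulation_config(n_proteins = 150, n_complexes = 15, seed = 17)
  truth <- generate_complexes(cfg)
  go <- generate_go(truth, cfg)
  ann <- go$annotations
  dag <- go$dag
  n_terms <- function(a) length(unique(a$term))

  f_e <- function(a) filter_evidence(a)
  f_s <- function(a) filter_support(a, 5)
  f_l <- function(a) filter_level(a, dag, c(BP = 2, CC = 2, MF = 2))

  for (f in list(f_e, f_s, f_l)) {
    once <- f(ann)
    expect_identical(f(once), once)
    expect_lte(n_terms(once), n_terms(ann))
  }
  # pairwise commutation on the propagated set
  combos <- list(list(f_e, f_s), list(f_e, f_l), list(f_s, f_l))
  for (cmb in combos) {
    ab <- cmb[[2]](cmb[[1]](ann))
    ba <- cmb[[1]](cmb[[2]](ann))
    expect_identical(dplyr::arrange(ab, protein, term),
                     dplyr::arrange(ba, protein, term))
  }
  casc <- filter_go_cascade(ann, dag, min_proteins = 5,
                            max_level = c(BP = 2, CC = 2, MF = 2))
  steps <- attr(casc, "filter_summary")$n_terms
  expect_true(all(diff(steps) <= 0))
})

test_that("annotation propagation closes over ancestors deterministically", {
  dag <- toy_dag()
  ann <- make_annotations(c("p1", "T", "IDA"))
  out <- propagate_annotations(ann, dag)
  expect_setequal(out$term, c("T", "A", "C", "B", "root"))
  expect_true(all(out$evidence == "IDA"))
  expect_identical(propagate_annotations(ann, dag), out)
  expect_equal(nrow(propagate_annotations(ann[0, ], dag)), 0)
})

test_that("Wang similarity matches hand-computed S-values", {
  # chain: child -is_a-> root gives (0.8 + 1) / (1.8 + 1)
  dag <- toy_dag()
  expect_equal(wang_similarity(dag, "child", "root"), 1.8 / 2.8,
               tolerance = 1e-12)
  expect_equal(wang_similarity(dag, "T", "T"), 1)
  expect_equal(wang_similarity(dag, "A", "B"),
               (0.8 + 0.8) / (1.8 + 1.8), tolerance = 1e-12)
  # symmetry and bounds on all pairs
  ids <- dag$terms$id
  for (a in ids) {
    for (b in ids) {
      s1 <- wang_similarity(dag, a, b)
      expect_equal(s1, wang_similarity(dag, b, a), tolerance = 1e-12)
      expect_gte(s1, 0)
      expect_lte(s1, 1)
      if (a != b) expect_lt(s1, 1)
    }
  }
})

test_that("cross-namespace terms have zero similarity", {
  terms <- tibble::tibble(
    id = c("bp_root", "mf_root", "bp1", "mf1"),
    name = c("bp_root", "mf_root", "bp1", "mf1"),
    namespace = c("biological_process", "molecular_function",
                  "biological_process", "molecular_function")
  )
  edges <- tibble::tibble(id = c("bp1", "mf1"),
                          parent = c("bp_root", "mf_root"),
                          relation = "is_a")
  dag <- go_dag(terms, edges)
  expect_equal(wang_similarity(dag, "bp1", "mf1"), 0)
})

test_that("set similarity is the symmetric best-match average", {
  dag <- toy_dag()
  expect_equal(wang_set_similarity(dag, c("T", "A"), c("T", "A")), 1)
  expect_equal(wang_set_similarity(dag, "T", "T"), 1)
  expect_equal(wang_set_similarity(dag, "root", "child"),
               wang_similarity(dag, "root", "child"))
  # two-vs-one: directional means averaged
  s_ta <- wang_similarity(dag, "T", "A")
  expect_equal(wang_set_similarity(dag, c("T", "A"), "A"),
               ((s_ta + 1) / 2 + 1) / 2, tolerance = 1e-12)
  expect_error(wang_set_similarity(dag, character(), "A"), "non-empty")
})

test_that("hypergeometric enrichment reproduces exhaustive probabilities", {
  ann <- do.call(make_annotations, lapply(1:5, function(i) c(paste0("p", i), "T", "EXP")))
  reference <- paste0("p", 1:10)
  res <- go_enrichment(paste0("p", 1:3), reference, ann, alpha = 1)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3), tolerance = 1e-12)

  # a term absent from the target is never reported
  ann2 <- dplyr::bind_rows(ann, make_annotations(c("p9", "U", "EXP")))
  res2 <- go_enrichment(paste0("p", 1:3), reference, ann2, alpha = 1)
  expect_false("U" %in% res2$term)

  # target = reference: p = 1 everywhere, nothing passes
  res3 <- go_enrichment(reference, reference, ann, alpha = 1)
  expect_equal(nrow(res3), 0)

  expect_error(go_enrichment(character(), reference, ann), "non-empty")
  expect_error(go_enrichment("zz", reference, ann), "subset")
})
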