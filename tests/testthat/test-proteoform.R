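star_network <- function(center, n_leaves, prefix = "L") {
  edges <- tibble::tibble(
    from = center,
    to = sprintf("%s%03d", prefix, seq_len(n_leaves)),
    weight = 1
  )
  toy_network(edges)
}

test_that("profiles apply the strict partner filter", {
  net <- star_network("hub", 11)
  prof <- extract_profiles(net, min_partners = 10)
  hub_row <- prof[prof$protein == "hub", ]
  expect_equal(hub_row$degree, 11)
  expect_true(hub_row$passes_filter)
  leaf_row <- prof[prof$protein == "L001", ]
  expect_false(leaf_row$passes_filter)

  # boundary: exactly min_partners partners is excluded
  net10 <- star_network("hub", 10)
  prof10 <- extract_profiles(net10, min_partners = 10)
  expect_false(prof10$passes_filter[prof10$protein == "hub"])
})

test_that("profile differences follow Jaccard set arithmetic", {
  expect_equal(profile_difference(c("1", "2", "3", "4"), c("3", "4", "5", "6")),
               1 - 2 / 6)
  expect_equal(profile_difference(c("a", "b"), c("a", "b")), 0)
  expect_equal(profile_difference(c("a"), c("b")), 1)
  expect_equal(
    profile_difference(c("1", "2", "3"), c("2", "3", "4"), method = "overlap"),
    1 - 2 / 3
  )
  # the paired proteins themselves are ignored
  expect_equal(
    profile_difference(c("spl", "x"), c("can", "x"), proteins = c("can", "spl")),
    0
  )
  expect_error(profile_difference("a", "b", proteins = c("a", "b")),
               "undefined")

  # symmetry and identity-of-indiscernibles on random set pairs
  set.seed(61)
  for (k in 1:50) {
    a <- sample(letters, sample(1:10, 1))
    b <- sample(letters, sample(1:10, 1))
    d_ab <- profile_difference(a, b)
    expect_equal(d_ab, profile_difference(b, a))
    expect_gte(d_ab, 0)
    expect_lte(d_ab, 1)
    expect_equal(d_ab == 0, setequal(a, b))
  }
})

test_that("divergence binning is exclusive, exhaustive and sums to the total", {
  recs <- tibble::tibble(difference = c(0.4, 0.6, 0.8, 0.95))
  tab <- classify_divergence(recs)
  expect_equal(unlist(tab[c("<50%", ">=50%", ">=75%", ">=90%")]),
               c("<50%" = 1L, ">=50%" = 1L, ">=75%" = 1L, ">=90%" = 1L))
  expect_equal(tab$n_pairs, 4)

  empty <- classify_divergence(tibble::tibble(difference = numeric()))
  expect_equal(empty$n_pairs, 0)
  expect_equal(sum(unlist(empty[-1])), 0)

  zeros <- classify_divergence(tibble::tibble(difference = rep(0, 5)))
  expect_equal(zeros$`<50%`, 5L)

  # boundary values land in the right-closed upper bins
  edges <- classify_divergence(tibble::tibble(difference = c(0.5, 0.75, 0.9, 1)))
  expect_equal(unlist(edges[c("<50%", ">=50%", ">=75%", ">=90%")]),
               c("<50%" = 0L, ">=50%" = 1L, ">=75%" = 1L, ">=90%" = 2L))
})

test_that("mean measured divergence tracks the planted divergence dose", {
  meas <- vapply(c(0, 0.5, 1), function(d) {
    cfg <- simulation_config(n_proteins = 200, n_complexes = 20,
                             complex_size_range = c(4, 6), n_baits = 70,
                             fn_rate = 0.05, fp_rate = 0.2,
                             n_proteoform_genes = 10,
                             proteoform_divergence = d,
                             master_fraction = 0, seed = 71)
    sim <- simulate_apms_study(cfg)
    net <- build_network(score_pairs(count_cooccurrence(sim$purifications)), 0.2)
    div <- profile_divergence(net, sim$proteoform_map, min_partners = 1)
    mean(div$difference)
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})

test_that("shared-partner components use strict single-linkage grouping", {
  # two proteins sharing exactly half their partners are not grouped
  edges <- tibble::tibble(
    from = rep(c("x", "y"), each = 12),
    to = c(sprintf("s%02d", 1:8), sprintf("xo%02d", 1:4),
           sprintf("s%02d", 1:8), sprintf("yo%02d", 1:4)),
    weight = 1
  )
  net <- toy_network(edges)
  prof <- extract_profiles(net, min_partners = 10)
  expect_setequal(prof$protein[prof$passes_filter], c("x", "y"))
  # Jaccard share = 8/16 = 0.5, not > 0.5
  comps <- build_components(prof, share_threshold = 0.5)
  expect_equal(nrow(dplyr::filter(comps, component_size > 1)), 0)
  expect_setequal(comps$size_class, "singleton")

  # three profiles pairwise sharing > 50%: one micro component via closure
  edges2 <- tibble::tibble(
    from = rep(c("a", "b", "c"), each = 12),
    to = c(sprintf("s%02d", 1:11), "ao1",
           sprintf("s%02d", 1:11), "bo1",
           sprintf("s%02d", 1:11), "co1"),
    weight = 1
  )
  prof2 <- extract_profiles(toy_network(edges2), min_partners = 10)
  comps2 <- build_components(prof2, share_threshold = 0.5)
  grouped <- dplyr::filter(comps2, protein %in% c("a", "b", "c"))
  expect_equal(unique(grouped$component_size), 3L)
  expect_equal(unique(grouped$size_class), "micro")
  expect_equal(length(unique(grouped$component)), 1)

  # components partition the filtered profiles
  expect_setequal(comps2$protein, prof2$protein[prof2$passes_filter])
  expect_equal(anyDuplicated(comps2$protein), 0)
})

test_that("component enrichment flags the shared rare term", {
  comps <- tibble::tibble(
    protein = c("a", "b", "c"), component = 1L,
    component_size = 3L, size_class = "micro"
  )
  reference <- c("a", "b", "c", sprintf("r%02d", 1:27))
  ann <- tibble::tibble(
    protein = c("a", "b", "c", "r01"),
    term = "RARE",
    evidence = "EXP"
  )
  enr <- annotate_components(comps, ann, reference, alpha = 0.01)
  expect_equal(enr$term, "RARE")
  expect_equal(enr$p_value,
               (choose(4, 3) * choose(26, 0)) / choose(30, 3),
               tolerance = 1e-12)

  # no annotations: nothing reported
  expect_equal(nrow(annotate_components(comps, ann[0, ], reference)), 0)
})

test_that("hub detection is strict at the degree threshold", {
  expect_equal(nrow(find_hubs(star_network("h", 150), 150)), 0)
  hubs <- find_hubs(star_network("h", 200), 150)
  expect_equal(hubs$protein, "h")
  expect_equal(hubs$degree, 200L)
  empty <- build_network(
    score_pairs(count_cooccurrence(purif_table(list(c("A", "B"))))), 1
  )
  expect_equal(nrow(find_hubs(empty)), 0)
})

test_that("canonical/splice prediction disagreements are reported per namespace", {
  pmap <- tibble::tibble(
    gene = c("G1", "G1", "G2", "G2"),
    accession = c("P1", "P1-2", "P2", "P2-2"),
    form = c("canonical", "splice", "canonical", "splice")
  )
  preds <- tibble::tibble(
    protein = c("P1", "P1", "P1-2", "P1-2", "P1-2",
                "P2", "P2-2"),
    term = c("t1", "t2", "t1", "t2", "t3", "t1", "t1"),
    namespace = "biological_process",
    state = c(1, 1, 1, 1, 1, 1, NA)
  )
  out <- compare_form_predictions(preds, pmap)
  expect_equal(out$gene, "G1")
  expect_equal(out$splice_only[[1]], "t3")
  expect_length(out$canonical_only[[1]], 0)
  # P2-2 fully abstained: gene excluded and counted separately
  expect_equal(attr(out, "excluded_genes"), "G2")

  # identical columns: no disagreement
  same <- dplyr::mutate(preds[1:4, ], state = 1)
  expect_equal(nrow(compare_form_predictions(same, pmap)), 0)
})
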