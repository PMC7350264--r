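test_that("planted complexes respect sizes, capacity and the background pool", {
  cfg <- simulation_config(n_proteins = 200, n_complexes = 50,
                           complex_size_range = c(3, 6), seed = 7)
  truth <- generate_complexes(cfg)
  expect_length(truth$complexes, 50)
  sizes <- lengths(truth$complexes)
  expect_true(all(sizes >= 3 & sizes <= 6))
  members <- unlist(truth$complexes)
  expect_true(all(members %in% truth$proteins))
  # background proteins belong to no complex
  expect_length(intersect(members, truth$background), 0)
  # overlap cap: nobody sits in more than two complexes
  expect_lte(max(table(members)), 2)

  empty <- generate_complexes(simulation_config(n_complexes = 0))
  expect_length(empty$complexes, 0)

  expect_error(
    simulation_config(n_proteins = 4, complex_size_range = c(2, 10)),
    "exceeds the protein universe"
  )
})

test_that("the generator chain is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_proteins = 120, n_complexes = 12, n_baits = 30,
                           seed = 42)
  s1 <- simulate_apms_study(cfg)
  s2 <- simulate_apms_study(cfg)
  expect_identical(s1$purifications, s2$purifications)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth$complexes, s2$truth$complexes)
  expect_identical(s1$truth$upe1_mask, s2$truth$upe1_mask)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("purifications follow the dropout and contamination model", {
  # noiseless limit: each purification is exactly the bait's complex
  cfg0 <- simulation_config(n_proteins = 100, n_complexes = 10,
                            n_baits = 20, fn_rate = 0, fp_rate = 0,
                            allow_overlap = FALSE, n_proteoform_genes = 0,
                            master_fraction = 0, seed = 3)
  truth0 <- generate_complexes(cfg0)
  pur0 <- simulate_purifications(truth0, cfg0)
  for (id in unique(pur0$purification_id)) {
    rec <- pur0[pur0$purification_id == id, ]
    bait <- rec$bait[1]
    cpx <- truth0$complexes[[which(vapply(truth0$complexes,
                                          function(m) bait %in% m, logical(1)))]]
    expect_setequal(rec$protein, cpx)
  }

  # total dropout: purification collapses to the bait alone
  cfg1 <- simulation_config(n_proteins = 100, n_complexes = 10, n_baits = 20,
                            fn_rate = 1, fp_rate = 0, master_fraction = 0,
                            n_proteoform_genes = 0, seed = 3)
  pur1 <- simulate_purifications(generate_complexes(cfg1), cfg1)
  expect_true(all(pur1$protein == pur1$bait))

  # contaminant count is Poisson(fp_rate): mean within 3 SE
  cfg2 <- simulation_config(n_proteins = 3000, n_complexes = 250,
                            complex_size_range = c(3, 4), n_baits = 450,
                            fn_rate = 1, fp_rate = 2, background_fraction = 0.5,
                            master_fraction = 0, n_proteoform_genes = 0, seed = 9)
  truth2 <- generate_complexes(cfg2)
  pur2 <- simulate_purifications(truth2, cfg2)
  n_cont <- pur2 |>
    dplyr::filter(protein != bait) |>
    dplyr::count(purification_id) |>
    dplyr::pull(n)
  n_cont <- c(n_cont, rep(0, 450 - length(n_cont)))
  se <- sqrt(2 / 450)
  expect_lt(abs(mean(n_cont) - 2), 3 * se)
})

test_that("planted GO annotations obey the true-path rule and enrich complexes", {
  cfg <- simulation_config(n_proteins = 200, n_complexes = 20, seed = 5)
  truth <- plant_proteoforms(generate_complexes(cfg), cfg)
  go <- generate_go(truth, cfg)
  ann <- go$annotations
  # ancestor closure: every annotated term's parents are annotated too
  by_child <- split(go$dag$edges$parent, go$dag$edges$id)
  for (k in sample(nrow(ann), 200)) {
    parents <- by_child[[ann$term[k]]]
    for (p in parents) {
      expect_true(any(ann$protein == ann$protein[k] & ann$term == p))
    }
  }
  # no annotations at all when both annotation channels are off
  cfg0 <- simulation_config(annotation_rate = 0, complex_annotation_prob = 0)
  go0 <- generate_go(generate_complexes(cfg0), cfg0)
  expect_equal(nrow(go0$annotations), 0)

  # within-complex pairs share more terms than cross-complex pairs
  term_sets <- split(ann$term, ann$protein)
  overlap <- function(a, b) {
    ta <- term_sets[[a]]; tb <- term_sets[[b]]
    if (is.null(ta) || is.null(tb)) return(0)
    length(intersect(ta, tb))
  }
  cpx <- truth$complexes
  set.seed(1)
  within <- unlist(lapply(cpx[1:10], function(m) {
    if (length(m) < 2) return(NULL)
    p <- sample(m, 2)
    overlap(p[1], p[2])
  }))
  cross <- replicate(30, {
    ks <- sample(length(cpx), 2)
    overlap(sample(cpx[[ks[1]]], 1), sample(cpx[[ks[2]]], 1))
  })
  expect_gt(mean(within), mean(cross))
})

test_that("proteoform planting resamples the stated fraction of memberships", {
  cfg <- simulation_config(n_proteins = 300, n_complexes = 30,
                           n_proteoform_genes = 12,
                           proteoform_divergence = 0.5, seed = 11)
  truth <- plant_proteoforms(generate_complexes(cfg), cfg)
  splice_rows <- truth$proteoform_map[truth$proteoform_map$form == "splice", ]
  expect_equal(nrow(splice_rows), 12)
  memberships <- function(acc) {
    names(truth$complexes)[vapply(truth$complexes, function(m) acc %in% m,
                                  logical(1))]
  }
  for (k in seq_len(nrow(splice_rows))) {
    can <- sub("^G", "P", splice_rows$gene[k])
    spl <- splice_rows$accession[k]
    mc <- memberships(can)
    ms <- memberships(spl)
    n_res <- round(0.5 * length(mc))
    expect_length(ms, length(mc))
    expect_length(intersect(mc, ms), length(mc) - n_res)
  }

  # divergence 0: splice memberships equal canonical's
  cfg0 <- simulation_config(n_proteoform_genes = 5, proteoform_divergence = 0,
                            seed = 2)
  t0 <- plant_proteoforms(generate_complexes(cfg0), cfg0)
  spl0 <- t0$proteoform_map[t0$proteoform_map$form == "splice", ]
  for (k in seq_len(nrow(spl0))) {
    can <- sub("^G", "P", spl0$gene[k])
    in_same <- vapply(t0$complexes, function(m) {
      (can %in% m) == (spl0$accession[k] %in% m)
    }, logical(1))
    expect_true(all(in_same))
  }

  # divergence 1: no shared complex
  cfg1 <- simulation_config(n_proteoform_genes = 5, proteoform_divergence = 1,
                            seed = 2)
  t1 <- plant_proteoforms(generate_complexes(cfg1), cfg1)
  spl1 <- t1$proteoform_map[t1$proteoform_map$form == "splice", ]
  for (k in seq_len(nrow(spl1))) {
    can <- sub("^G", "P", spl1$gene[k])
    both <- vapply(t1$complexes, function(m) {
      can %in% m && spl1$accession[k] %in% m
    }, logical(1))
    expect_false(any(both))
  }
})

test_that("uPE1 masking hides the exact sampled fraction and never leaks", {
  cfg <- simulation_config(n_proteins = 400, upe1_fraction = 0.1, seed = 13)
  truth <- plant_proteoforms(generate_complexes(cfg), cfg)
  go <- generate_go(truth, cfg)
  annotated <- unique(go$annotations$protein)
  masked <- mask_upe1(go$annotations, cfg)
  expect_length(masked$mask, round(0.1 * length(annotated)))
  expect_length(intersect(masked$visible$protein, masked$mask), 0)

  none <- mask_upe1(go$annotations, simulation_config(upe1_fraction = 0))
  expect_identical(none$visible, go$annotations)
  all_mask <- mask_upe1(go$annotations, simulation_config(upe1_fraction = 1))
  expect_equal(nrow(all_mask$visible), 0)
  expect_setequal(all_mask$mask, annotated)
})
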