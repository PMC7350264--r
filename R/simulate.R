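#' Configuration for a synthetic AP-MS study
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' generator plants protein complexes, samples bait purifications with
#' false-negative dropout and Poisson contaminants, builds a three-namespace
#' GO DAG with true-path-propagated annotations, adds canonical/splice
#' proteoform pairs with controlled interactome divergence, and masks a
#' fraction of annotated proteins as "uPE1" (function hidden, ground truth
#' recorded).
#'
#' @param n_proteins Number of canonical proteins in the universe.
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Integer vector `c(min, max)` of complex sizes
#'   (`min >= 2`).
#' @param n_baits Number of purifications (one bait each), sampled from
#'   complex members.
#' @param fn_rate Probability a true complex co-member is missed in a
#'   purification.
#' @param fp_rate Expected number of contaminant (background) proteins per
#'   purification (Poisson mean).
#' @param n_go_terms_per_namespace Number of non-root terms per namespace.
#' @param dag_depth Number of levels below each namespace root (>= 1).
#' @param annotation_rate Background probability that a protein is annotated
#'   with any given leaf term.
#' @param complex_terms_per_namespace Leaf terms assigned to each complex in
#'   each namespace; complex members receive these terms with probability
#'   `complex_annotation_prob`, making network proximity correlate with
#'   function.
#' @param complex_annotation_prob See `complex_terms_per_namespace`.
#' @param evidence_experimental_frac Fraction of leaf annotations carrying an
#'   experimental evidence code (uniform over EXP/IDA/IPI/IMP/IGI/IEP); the
#'   remainder are IEA.
#' @param n_proteoform_genes Number of genes given an alternative splice
#'   form.
#' @param proteoform_divergence Fraction of a splice form's complex
#'   memberships resampled away from the canonical form's complexes.
#' @param upe1_fraction Fraction of annotated proteins whose annotations are
#'   masked (the planted uPE1 set).
#' @param background_fraction Fraction of proteins kept out of all complexes
#'   and used as the contaminant pool.
#' @param allow_overlap Allow a protein to sit in up to two complexes?
#' @param master_fraction Fraction of complex-member proteins that also emit
#'   an unresolved "master form" accession in purifications.
#' @param master_emit_prob Probability that a prey occurrence of a
#'   master-flagged protein is reported as the master accession.
#' @param seed Integer RNG seed; fixed seed gives byte-identical artifacts.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 400,
                              n_complexes = 40,
                              complex_size_range = c(3, 6),
                              n_baits = 120,
                              fn_rate = 0.1,
                              fp_rate = 0.5,
                              n_go_terms_per_namespace = 18,
                              dag_depth = 3,
                              annotation_rate = 0.02,
                              complex_terms_per_namespace = 2,
                              complex_annotation_prob = 0.9,
                              evidence_experimental_frac = 0.7,
                              n_proteoform_genes = 15,
                              proteoform_divergence = 0.5,
                              upe1_fraction = 0.1,
                              background_fraction = 0.15,
                              allow_overlap = TRUE,
                              master_fraction = 0.1,
                              master_emit_prob = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, n_complexes = n_complexes,
    complex_size_range = as.integer(complex_size_range), n_baits = n_baits,
    fn_rate = fn_rate, fp_rate = fp_rate,
    n_go_terms_per_namespace = n_go_terms_per_namespace,
    dag_depth = dag_depth, annotation_rate = annotation_rate,
    complex_terms_per_namespace = complex_terms_per_namespace,
    complex_annotation_prob = complex_annotation_prob,
    evidence_experimental_frac = evidence_experimental_frac,
    n_proteoform_genes = n_proteoform_genes,
    proteoform_divergence = proteoform_divergence,
    upe1_fraction = upe1_fraction,
    background_fraction = background_fraction,
    allow_overlap = isTRUE(allow_overlap),
    master_fraction = master_fraction,
    master_emit_prob = master_emit_prob,
    seed = as.integer(seed)
  )
  assert_count(cfg$n_proteins, "n_proteins", min = 1)
  assert_count(cfg$n_complexes, "n_complexes")
  assert_count(cfg$n_baits, "n_baits")
  assert_count(cfg$dag_depth, "dag_depth", min = 1)
  assert_count(cfg$n_go_terms_per_namespace, "n_go_terms_per_namespace", min = 1)
  assert_count(cfg$n_proteoform_genes, "n_proteoform_genes")
  for (p in c("fn_rate", "annotation_rate", "complex_annotation_prob",
              "evidence_experimental_frac", "proteoform_divergence",
              "upe1_fraction", "background_fraction", "master_fraction",
              "master_emit_prob")) {
    assert_probability(cfg[[p]], p)
  }
  if (!is.numeric(cfg$fp_rate) || cfg$fp_rate < 0) {
    abort("`fp_rate` must be a non-negative Poisson mean")
  }
  if (length(cfg$complex_size_range) != 2 ||
      cfg$complex_size_range[1] < 2 ||
      cfg$complex_size_range[1] > cfg$complex_size_range[2]) {
    abort("`complex_size_range` must be c(min, max) with min >= 2")
  }
  if (cfg$complex_size_range[2] > cfg$n_proteins) {
    abort("`complex_size_range` max exceeds the protein universe")
  }
  structure(cfg, class = "simulation_config")
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))
gene_of <- function(accession) sub("^P", "G", sub("-.*$", "", accession))

#' Plant protein complexes
#'
#' Samples `n_complexes` complexes with sizes uniform in
#' `complex_size_range` from the non-background protein pool. A protein may
#' belong to at most two complexes when `allow_overlap` is set (mirroring
#' overlapping curated complexes), otherwise at most one. A
#' `background_fraction` of the universe belongs to no complex and serves as
#' the contaminant pool.
#'
#' @param config A [simulation_config()].
#' @return A `planted_truth` list with elements `proteins`, `complexes`
#'   (named list of accession sets), `background`, and a canonical-only
#'   `proteoform_map` tibble (`gene`, `accession`, `form`).
#' @export
generate_complexes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 11L), {
    proteins <- protein_ids(config$n_proteins)
    n_bg <- floor(config$background_fraction * config$n_proteins)
    background <- if (n_bg > 0) sample(proteins, n_bg) else character()
    eligible <- setdiff(proteins, background)
    cap <- setNames(
      rep(if (config$allow_overlap) 2L else 1L, length(eligible)),
      eligible
    )
    complexes <- list()
    if (config$n_complexes > 0) {
      size_choices <- seq(config$complex_size_range[1], config$complex_size_range[2])
      sizes <- if (length(size_choices) == 1) {
        rep(size_choices, config$n_complexes)
      } else {
        sample(size_choices, config$n_complexes, replace = TRUE)
      }
      for (k in seq_len(config$n_complexes)) {
        open <- names(cap)[cap > 0]
        if (length(open) < sizes[k]) {
          abort("not enough protein capacity to plant the requested complexes")
        }
        members <- sample(open, sizes[k])
        cap[members] <- cap[members] - 1L
        complexes[[sprintf("CPX%03d", k)]] <- sort(members)
      }
    }
    structure(
      list(
        proteins = proteins,
        complexes = complexes,
        background = sort(background),
        proteoform_map = tibble(
          gene = gene_of(proteins),
          accession = proteins,
          form = "canonical"
        )
      ),
      class = "planted_truth"
    )
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth> ", length(x$proteins), " proteins, ",
      length(x$complexes), " complexes, ",
      sum(x$proteoform_map$form == "splice"), " splice forms\n", sep = "")
  invisible(x)
}

#' Plant canonical/splice proteoform pairs
#'
#' Picks `n_proteoform_genes` genes among complex members and gives each a
#' splice-form accession (`-2` suffix). The splice form inherits the
#' canonical form's complex memberships, except that a
#' `proteoform_divergence` fraction (rounded) is resampled to complexes the
#' canonical form does not belong to; at divergence 1 the two forms share no
#' complex. A `master_fraction` of complex-member genes is additionally
#' flagged as emitting a master-form accession (`-M` suffix) in
#' purifications.
#'
#' @param truth A `planted_truth` from [generate_complexes()].
#' @param config A [simulation_config()].
#' @return The updated `planted_truth` (complex membership now includes
#'   splice accessions; `proteoform_map` gains `splice` and `master` rows).
#' @export
plant_proteoforms <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"))
  if (config$proteoform_divergence < 0 || config$proteoform_divergence > 1) {
    abort("`proteoform_divergence` must be in [0, 1]")
  }
  with_seed(derive_seed(config$seed, 12L), {
    members <- unique(unlist(truth$complexes, use.names = FALSE))
    members <- members[!grepl("-", members)]
    if (config$n_proteoform_genes > length(members)) {
      abort("n_proteoform_genes exceeds the number of complex-member genes")
    }
    chosen <- if (config$n_proteoform_genes > 0) {
      sort(sample(members, config$n_proteoform_genes))
    } else {
      character()
    }
    map <- truth$proteoform_map
    for (acc in chosen) {
      splice <- paste0(acc, "-2")
      in_cpx <- names(truth$complexes)[
        vapply(truth$complexes, function(m) acc %in% m, logical(1))
      ]
      n_res <- round(config$proteoform_divergence * length(in_cpx))
      keep <- in_cpx
      resampled <- character()
      if (n_res > 0) {
        keep <- sample(in_cpx, length(in_cpx) - n_res)
        pool <- setdiff(names(truth$complexes), in_cpx)
        resampled <- sample(pool, min(n_res, length(pool)))
      }
      for (cpx in c(keep, resampled)) {
        truth$complexes[[cpx]] <- sort(unique(c(truth$complexes[[cpx]], splice)))
      }
      map <- bind_rows(map, tibble(
        gene = gene_of(acc), accession = splice, form = "splice"
      ))
    }
    n_master <- round(config$master_fraction * length(members))
    masters <- if (n_master > 0) sort(sample(members, n_master)) else character()
    for (acc in masters) {
      map <- bind_rows(map, tibble(
        gene = gene_of(acc), accession = paste0(acc, "-M"), form = "master"
      ))
    }
    truth$proteoform_map <- arrange(map, .data$gene, .data$accession)
    truth
  })
}

#' Simulate bait purifications from planted complexes
#'
#' Samples `n_baits` baits (without replacement) from complex-member
#' accessions. Each purification contains the bait, each co-member of the
#' bait's complexes retained with probability `1 - fn_rate`, and a
#' Poisson(`fp_rate`) number of contaminants drawn from the background pool.
#' Prey occurrences of master-flagged proteins are reported as the master
#' accession with probability `master_emit_prob` (the bait identity is
#' always reported as-is).
#'
#' @param truth A `planted_truth` (after [plant_proteoforms()] if proteoform
#'   pairs are wanted).
#' @param config A [simulation_config()].
#' @return A purification table: tibble with columns `purification_id`,
#'   `bait`, `protein` (one row per identified protein, bait included).
#' @export
simulate_purifications <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"))
  with_seed(derive_seed(config$seed, 14L), {
    pool <- sort(unique(unlist(truth$complexes, use.names = FALSE)))
    if (config$n_baits > length(pool)) {
      abort("n_baits exceeds the number of complex-member accessions")
    }
    baits <- sample(pool, config$n_baits)
    masters <- truth$proteoform_map$gene[truth$proteoform_map$form == "master"]
    master_acc <- setNames(
      truth$proteoform_map$accession[truth$proteoform_map$form == "master"],
      sub("^G", "P", masters)
    )
    recs <- purrr::map(seq_along(baits), function(k) {
      bait <- baits[k]
      co <- setdiff(
        unique(unlist(
          truth$complexes[vapply(truth$complexes, function(m) bait %in% m, logical(1))],
          use.names = FALSE
        )),
        bait
      )
      kept <- co[runif(length(co)) >= config$fn_rate]
      n_cont <- rpois(1, config$fp_rate)
      cont <- if (n_cont > 0 && length(truth$background) > 0) {
        unique(sample(truth$background, min(n_cont, length(truth$background))))
      } else {
        character()
      }
      preys <- unique(c(kept, cont))
      if (length(preys) > 0 && length(master_acc) > 0) {
        hit <- preys %in% names(master_acc) & runif(length(preys)) < config$master_emit_prob
        preys[hit] <- master_acc[preys[hit]]
      }
      tibble(
        purification_id = sprintf("AP%04d", k),
        bait = bait,
        protein = unique(c(bait, preys))
      )
    })
    bind_rows(recs)
  })
}

#' Generate a GO DAG and planted annotations
#'
#' Builds one rooted DAG per namespace (BP, MF, CC) with `dag_depth` levels
#' below the root; every term has an `is_a` parent on the previous level and
#' occasionally a second (`is_a` or `part_of`) parent. Deepest-level terms
#' are the annotatable leaves. Each complex draws
#' `complex_terms_per_namespace` leaf terms per namespace which its members
#' receive with probability `complex_annotation_prob`; every protein also
#' picks up each leaf term at the background `annotation_rate`. Leaf
#' annotations get an evidence code (experimental with probability
#' `evidence_experimental_frac`, else IEA) and are propagated to all
#' ancestors under the true-path rule.
#'
#' @param truth A `planted_truth`.
#' @param config A [simulation_config()].
#' @return List with `dag` (a [go_dag()]) and `annotations` (tibble
#'   `protein`, `term`, `evidence`, ancestor-closed).
#' @export
generate_go <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"))
  with_seed(derive_seed(config$seed, 13L), {
    namespaces <- c(
      BP = "biological_process",
      MF = "molecular_function",
      CC = "cellular_component"
    )
    terms <- list()
    edges <- list()
    leaves <- list()
    counter <- 0
    for (ns_key in names(namespaces)) {
      ns <- namespaces[[ns_key]]
      counter <- counter + 1
      root <- sprintf("GO:%07d", counter)
      terms[[length(terms) + 1]] <- tibble(
        id = root, name = paste0(ns, " root"), namespace = ns
      )
      n_per_level <- rep(config$n_go_terms_per_namespace %/% config$dag_depth,
                         config$dag_depth)
      rem <- config$n_go_terms_per_namespace %% config$dag_depth
      if (rem > 0) {
        n_per_level[config$dag_depth] <- n_per_level[config$dag_depth] + rem
      }
      prev_level <- root
      for (d in seq_len(config$dag_depth)) {
        ids <- sprintf("GO:%07d", counter + seq_len(n_per_level[d]))
        counter <- counter + n_per_level[d]
        terms[[length(terms) + 1]] <- tibble(
          id = ids,
          name = paste0(ns_key, " level-", d, " term ", seq_along(ids)),
          namespace = ns
        )
        p1 <- if (length(prev_level) == 1) {
          rep(prev_level, length(ids))
        } else {
          sample(prev_level, length(ids), replace = TRUE)
        }
        edges[[length(edges) + 1]] <- tibble(id = ids, parent = p1, relation = "is_a")
        if (length(prev_level) > 1) {
          extra <- runif(length(ids)) < 0.3
          for (i in which(extra)) {
            alt <- setdiff(prev_level, p1[i])
            if (length(alt) == 0) next
            p2 <- if (length(alt) == 1) alt else sample(alt, 1)
            rel <- if (runif(1) < 0.5) "part_of" else "is_a"
            edges[[length(edges) + 1]] <- tibble(id = ids[i], parent = p2, relation = rel)
          }
        }
        if (d == config$dag_depth) leaves[[ns_key]] <- ids
        prev_level <- ids
      }
    }
    dag <- go_dag(bind_rows(terms), bind_rows(edges))

    all_proteins <- sort(unique(c(
      truth$proteins,
      unlist(truth$complexes, use.names = FALSE)
    )))
    all_proteins <- all_proteins[!grepl("-M$", all_proteins)]
    assign_leaf <- list()
    # functional signal: complex members share their complex's leaf terms
    for (cpx in names(truth$complexes)) {
      mem <- truth$complexes[[cpx]]
      for (ns_key in names(leaves)) {
        k <- min(config$complex_terms_per_namespace, length(leaves[[ns_key]]))
        if (k == 0) next
        cpx_terms <- sample(leaves[[ns_key]], k)
        for (t in cpx_terms) {
          got <- mem[runif(length(mem)) < config$complex_annotation_prob]
          if (length(got) > 0) {
            assign_leaf[[length(assign_leaf) + 1]] <- tibble(protein = got, term = t)
          }
        }
      }
    }
    all_leaves <- unlist(leaves, use.names = FALSE)
    if (config$annotation_rate > 0 && length(all_leaves) > 0) {
      hits <- which(
        runif(length(all_proteins) * length(all_leaves)) < config$annotation_rate
      )
      if (length(hits) > 0) {
        assign_leaf[[length(assign_leaf) + 1]] <- tibble(
          protein = all_proteins[((hits - 1) %% length(all_proteins)) + 1],
          term = all_leaves[((hits - 1) %/% length(all_proteins)) + 1]
        )
      }
    }
    leaf_ann <- if (length(assign_leaf) > 0) {
      distinct(bind_rows(assign_leaf), .data$protein, .data$term)
    } else {
      tibble(protein = character(), term = character())
    }
    exp_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
    if (nrow(leaf_ann) > 0) {
      is_exp <- runif(nrow(leaf_ann)) < config$evidence_experimental_frac
      leaf_ann$evidence <- ifelse(
        is_exp, sample(exp_codes, nrow(leaf_ann), replace = TRUE), "IEA"
      )
      leaf_ann <- arrange(leaf_ann, .data$protein, .data$term)
    } else {
      leaf_ann$evidence <- character()
    }
    annotations <- propagate_annotations(leaf_ann, dag)
    list(dag = dag, annotations = annotations)
  })
}

#' Mask a uPE1 subset
#'
#' Samples `round(upe1_fraction * n)` of the annotated proteins without
#' replacement and removes every annotation of the sampled proteins from the
#' visible set, recording the mask so downstream recovery can be scored
#' against the hidden truth.
#'
#' @param annotations Tibble `protein`, `term`, `evidence` (the full planted
#'   annotations).
#' @param config A [simulation_config()].
#' @return List with `visible` (annotations minus masked proteins) and
#'   `mask` (character vector of masked proteins).
#' @export
mask_upe1 <- function(annotations, config) {
  with_seed(derive_seed(config$seed, 15L), {
    annotated <- sort(unique(annotations$protein))
    n_mask <- round(config$upe1_fraction * length(annotated))
    mask <- if (n_mask > 0) sort(sample(annotated, n_mask)) else character()
    list(
      visible = filter(annotations, !.data$protein %in% mask),
      mask = mask
    )
  })
}

#' Simulate a complete synthetic AP-MS study
#'
#' Runs the full generator chain — complexes, proteoform pairs, GO DAG and
#' annotations, purifications, uPE1 masking — under deterministic
#' stage-derived seeds. The result bundles everything the analysis pipeline
#' consumes plus the planted ground truth used only for scoring.
#'
#' @param config A [simulation_config()].
#' @return An `apms_simulation` list: `config`, `truth` (with
#'   `true_annotations` and `upe1_mask`), `purifications`, `dag`,
#'   `annotations` (visible only), `proteoform_map`.
#' @export
simulate_apms_study <- function(config = simulation_config()) {
  truth <- generate_complexes(config)
  truth <- plant_proteoforms(truth, config)
  go <- generate_go(truth, config)
  purifications <- simulate_purifications(truth, config)
  masked <- mask_upe1(go$annotations, config)
  truth$true_annotations <- go$annotations
  truth$upe1_mask <- masked$mask
  structure(
    list(
      config = config,
      truth = truth,
      purifications = purifications,
      dag = go$dag,
      annotations = masked$visible,
      proteoform_map = truth$proteoform_map
    ),
    class = "apms_simulation"
  )
}

#' @export
print.apms_simulation <- function(x, ...) {
  cat("<apms_simulation>\n")
  cat("  purifications: ", length(unique(x$purifications$purification_id)), "\n", sep = "")
  cat("  proteins seen: ", length(unique(x$purifications$protein)), "\n", sep = "")
  cat("  complexes:     ", length(x$truth$complexes), "\n", sep = "")
  cat("  GO terms:      ", nrow(x$dag$terms), "\n", sep = "")
  cat("  visible annotations: ", nrow(x$annotations), "\n", sep = "")
  cat("  masked (uPE1): ", length(x$truth$upe1_mask), "\n", sep = "")
  invisible(x)
}
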