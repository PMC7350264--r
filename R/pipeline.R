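#' Pipeline configuration
#'
#' Validates and bundles every parameter of the end-to-end analysis:
#' simulation settings (or a directory of existing input artifacts), the
#' scoring metric and threshold calibration grid, the GO filtering cutoffs,
#' the Hopfield cost, and the proteoform-comparison thresholds. Unknown
#' arguments are rejected.
#'
#' @param simulation A [simulation_config()] used when no `input_dir` is
#'   given.
#' @param input_dir Optional directory holding `purifications.tsv`,
#'   `go.obo`, `annotations.tsv`, `complexes.gmt`, `proteoforms.tsv`,
#'   `upe1.tsv` (skips the simulation stage).
#' @param metric Interaction score used for thresholding: `"dice"` or
#'   `"hart"`.
#' @param threshold Fixed score threshold; `NULL` (default) calibrates it by
#'   the Fmax scan against the gold-standard complexes.
#' @param scan_grid,scan_type Grid and mode for [scan_thresholds()].
#' @param allowed_codes,min_support,max_level GO filtering cascade
#'   parameters (see [filter_go_cascade()]).
#' @param cost Hopfield regularization cost; `"auto"` runs
#'   [hopfield_cost_search()] over `cost_grid`.
#' @param cost_grid Candidate costs for `cost = "auto"`.
#' @param min_positives,exclude_terms Passed to [predict_functions()].
#' @param min_partners,share_threshold,hub_threshold,divergence_method
#'   Proteoform analysis parameters.
#' @param enrichment_alpha Component-enrichment significance cutoff.
#' @param seed Global seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            metric = c("dice", "hart"),
                            threshold = NULL,
                            scan_grid = seq(0.01, 0.99, by = 0.01),
                            scan_type = c("quantile", "value"),
                            allowed_codes = c("EXP", "IDA", "IPI", "IMP",
                                              "IGI", "IEP"),
                            min_support = 10,
                            max_level = c(biological_process = 10,
                                          cellular_component = 10,
                                          molecular_function = 6),
                            cost = 1e-5,
                            cost_grid = 10^seq(1, -10),
                            min_positives = 2,
                            exclude_terms = character(),
                            min_partners = 10,
                            share_threshold = 0.5,
                            hub_threshold = 150,
                            divergence_method = c("jaccard", "overlap"),
                            enrichment_alpha = 1e-7,
                            seed = 1L) {
  cfg <- list(
    simulation = simulation, input_dir = input_dir,
    metric = match.arg(metric), threshold = threshold,
    scan_grid = scan_grid, scan_type = match.arg(scan_type),
    allowed_codes = allowed_codes, min_support = min_support,
    max_level = max_level, cost = cost, cost_grid = cost_grid,
    min_positives = min_positives, exclude_terms = exclude_terms,
    min_partners = min_partners, share_threshold = share_threshold,
    hub_threshold = hub_threshold,
    divergence_method = match.arg(divergence_method),
    enrichment_alpha = enrichment_alpha, seed = as.integer(seed)
  )
  if (!is.null(cfg$threshold)) {
    if (!is.numeric(cfg$threshold) || cfg$threshold < 0 || cfg$threshold > 1) {
      abort("`threshold` must be in [0, 1] or NULL")
    }
  }
  if (!identical(cfg$cost, "auto") &&
      (!is.numeric(cfg$cost) || cfg$cost < 0)) {
    abort("`cost` must be \"auto\" or a non-negative number")
  }
  if (is.null(cfg$input_dir) && !inherits(cfg$simulation, "simulation_config")) {
    abort("either `input_dir` or a valid `simulation` config is required")
  }
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys must match [pipeline_config()] arguments (a `simulation`
#' block maps to [simulation_config()] arguments); unknown keys raise an
#' error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config keys: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$simulation)) {
    sim_known <- names(formals(simulation_config))
    sim_unknown <- setdiff(names(raw$simulation), sim_known)
    if (length(sim_unknown) > 0) {
      abort(paste0("unknown simulation config keys: ",
                   paste(sim_unknown, collapse = ", ")))
    }
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  if (!is.null(raw$max_level)) raw$max_level <- unlist(raw$max_level)
  do.call(pipeline_config, raw)
}

read_input_artifacts <- function(dir) {
  list(
    purifications = validate_io(file.path(dir, "purifications.tsv"), "purifications"),
    dag = validate_io(file.path(dir, "go.obo"), "obo"),
    annotations = validate_io(file.path(dir, "annotations.tsv"), "annotations"),
    complexes = validate_io(file.path(dir, "complexes.gmt"), "gmt"),
    proteoform_map = validate_io(file.path(dir, "proteoforms.tsv"), "proteoforms"),
    upe1 = {
      p <- file.path(dir, "upe1.tsv")
      if (file.exists(p)) readLines(p) else character()
    }
  )
}

stage_log <- function(quiet, ...) {
  if (!quiet) message("[apmsfun] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> proteoform normalization -> co-occurrence
#' scoring -> threshold calibration against the gold-standard complexes ->
#' network construction -> GO filtering -> Hopfield function prediction for
#' the unknown (uPE1) proteins -> proteoform divergence analysis, persisting
#' every intermediate artifact under `out_dir` so stages can be inspected
#' and re-run individually. A failure in any stage halts with a
#' stage-tagged error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for all artifacts and the run report.
#' @param quiet Suppress per-stage log messages?
#' @return A `pipeline_report` list (also written as `report.json` and
#'   `report.md`); the returned object additionally carries wall-clock
#'   timings, which are not persisted so that equal-seed runs produce
#'   byte-identical files.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  run_stage <- function(name, expr) {
    stage_log(quiet, "stage: ", name)
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$input_dir)) {
      read_input_artifacts(config$input_dir)
    } else {
      sim <- simulate_apms_study(config$simulation)
      write_simulation(sim, out_dir)
      list(
        purifications = sim$purifications,
        dag = sim$dag,
        annotations = sim$annotations,
        complexes = tibble(
          complex = rep(names(sim$truth$complexes),
                        lengths(sim$truth$complexes)),
          protein = unlist(sim$truth$complexes, use.names = FALSE)
        ),
        proteoform_map = sim$proteoform_map,
        upe1 = sim$truth$upe1_mask
      )
    }
  })
  report$inputs <- list(
    n_purifications = length(unique(inputs$purifications$purification_id)),
    n_proteins_seen = length(unique(inputs$purifications$protein)),
    n_complexes = length(unique(inputs$complexes$complex)),
    n_upe1 = length(inputs$upe1)
  )

  scores <- run_stage("score", {
    norm <- normalize_forms(inputs$purifications, inputs$proteoform_map)
    s <- score_pairs(count_cooccurrence(norm))
    write_scored_pairs(s, file.path(out_dir, "scored_pairs.tsv"))
    s
  })
  report$score <- list(
    n_pairs = nrow(scores),
    n_purifications = attr(scores, "n_purifications")
  )

  calibration <- run_stage("calibrate", {
    cal <- scan_thresholds(
      scores, inputs$complexes,
      grid = config$scan_grid, metric = config$metric, type = config$scan_type
    )
    readr::write_tsv(cal$curve, file.path(out_dir, "f1_curve.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(f_max = cal$f_max, best_threshold = cal$best_threshold,
           best_grid_point = cal$best_grid_point, metric = cal$metric,
           type = cal$type, n_shared = cal$n_shared),
      file.path(out_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA
    )
    cal
  })
  threshold <- config$threshold %||% calibration$best_threshold
  report$calibration <- list(
    f_max = calibration$f_max,
    best_threshold = calibration$best_threshold,
    threshold_used = threshold,
    metric = config$metric,
    n_shared = calibration$n_shared
  )

  network <- run_stage("network", {
    net <- build_network(scores, threshold, metric = config$metric)
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    net
  })
  net_stats <- network_stats(network, hub_threshold = config$hub_threshold)
  report$network <- c(
    as.list(net_stats),
    list(threshold = threshold)
  )

  filtered <- run_stage("filter_go", {
    f <- filter_go_cascade(
      inputs$annotations, inputs$dag,
      allowed_codes = config$allowed_codes,
      min_proteins = config$min_support,
      max_level = config$max_level
    )
    write_annotations(f, file.path(out_dir, "filtered_annotations.tsv"))
    f
  })
  fs <- attr(filtered, "filter_summary")
  report$go_filter <- as.list(setNames(fs$n_terms, paste0("n_terms_", fs$step)))

  predictions <- run_stage("predict", {
    cost <- config$cost
    if (identical(cost, "auto")) {
      search <- hopfield_cost_search(
        network, filtered, grid = config$cost_grid,
        seed = derive_seed(config$seed, "predict")
      )
      cost <- search$best_cost
      readr::write_tsv(search$results, file.path(out_dir, "cost_search.tsv"),
                       progress = FALSE)
    }
    preds <- predict_functions(
      network, filtered,
      unknowns = inputs$upe1, dag = inputs$dag, cost = cost,
      seed = derive_seed(config$seed, "predict"),
      min_positives = config$min_positives,
      exclude_terms = config$exclude_terms
    )
    readr::write_tsv(as_tibble(preds), file.path(out_dir, "predictions.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(cost = cost, seed = derive_seed(config$seed, "predict"),
           provenance = attr(preds, "provenance")),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    preds
  })
  pred_summary <- glance(predictions)
  ns_overlap <- namespace_overlap(predictions)
  report$predictions <- c(as.list(pred_summary), list(namespace_overlap = ns_overlap))
  run_stage("report_upset", {
    readr::write_tsv(term_set_summary(predictions),
                     file.path(out_dir, "term_sets.tsv"), progress = FALSE)
  })

  proteoforms <- run_stage("proteoforms", {
    div <- profile_divergence(
      network, inputs$proteoform_map,
      min_partners = config$min_partners, method = config$divergence_method
    )
    readr::write_tsv(div, file.path(out_dir, "divergence.tsv"), progress = FALSE)
    readr::write_tsv(classify_divergence(div),
                     file.path(out_dir, "divergence_table.tsv"), progress = FALSE)
    profiles <- extract_profiles(network, config$min_partners)
    comps <- build_components(profiles, config$share_threshold,
                              method = config$divergence_method)
    readr::write_tsv(comps, file.path(out_dir, "components.tsv"), progress = FALSE)
    enr <- annotate_components(
      comps, inputs$annotations,
      reference = igraph::V(network)$name,
      alpha = config$enrichment_alpha
    )
    readr::write_tsv(enr, file.path(out_dir, "component_enrichment.tsv"),
                     progress = FALSE)
    hubs <- find_hubs(network, config$hub_threshold)
    readr::write_tsv(hubs, file.path(out_dir, "hubs.tsv"), progress = FALSE)
    disagreements <- compare_form_predictions(predictions, inputs$proteoform_map)
    readr::write_tsv(
      mutate(disagreements,
             canonical_only = purrr::map_chr(.data$canonical_only, paste, collapse = ","),
             splice_only = purrr::map_chr(.data$splice_only, paste, collapse = ",")),
      file.path(out_dir, "form_disagreements.tsv"), progress = FALSE
    )
    list(divergence = div, components = comps, hubs = hubs,
         disagreements = disagreements)
  })
  report$proteoforms <- list(
    n_form_pairs = nrow(proteoforms$divergence),
    divergence_bins = as.list(classify_divergence(proteoforms$divergence)),
    n_components = length(unique(proteoforms$components$component)),
    n_hubs = nrow(proteoforms$hubs),
    n_disagreement_genes = length(unique(proteoforms$disagreements$gene))
  )

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stage_log(quiet, sprintf("done in %.1f s", elapsed))
  out <- c(report, list(elapsed_seconds = elapsed, out_dir = out_dir))
  class(out) <- "pipeline_report"
  out
}

# Venn-style counts of proteins with >=1 positive prediction per namespace
namespace_overlap <- function(predictions) {
  pred <- as_tibble(predictions)
  if (!"namespace" %in% names(pred) || nrow(pred) == 0) return(list())
  pos <- filter(pred, !is.na(.data$state) & .data$state == 1)
  sets <- split(pos$protein, pos$namespace)
  ns <- names(sets)
  out <- list()
  for (k in seq_along(ns)) {
    combos <- utils::combn(ns, k, simplify = FALSE)
    for (cmb in combos) {
      inter <- Reduce(intersect, sets[cmb])
      out[[paste(cmb, collapse = "&")]] <- length(unique(inter))
    }
  }
  out
}

# Upset-style tabular summary: identical predicted term sets and their counts
term_set_summary <- function(predictions) {
  pos <- filter(as_tibble(predictions), !is.na(.data$state) & .data$state == 1)
  if (nrow(pos) == 0) {
    return(tibble(term_set = character(), n_proteins = integer()))
  }
  pos |>
    group_by(.data$protein) |>
    summarise(term_set = paste(sort(unique(.data$term)), collapse = ","),
              .groups = "drop") |>
    count(.data$term_set, name = "n_proteins") |>
    arrange(dplyr::desc(.data$n_proteins), .data$term_set)
}

format_report_md <- function(report) {
  fmt <- function(x) {
    if (is.numeric(x)) format(x, digits = 6) else as.character(x)
  }
  lines <- c("# Pipeline run report", "")
  for (section in setdiff(names(report), "seed")) {
    lines <- c(lines, paste0("## ", section), "")
    vals <- report[[section]]
    for (key in names(vals)) {
      v <- vals[[key]]
      if (is.list(v)) {
        lines <- c(lines, paste0("- ", key, ":"))
        for (k2 in names(v)) {
          lines <- c(lines, paste0("  - ", k2, ": ", fmt(v[[k2]])))
        }
      } else {
        lines <- c(lines, paste0("- ", key, ": ", fmt(v)))
      }
    }
    lines <- c(lines, "")
  }
  c(lines, paste0("seed: ", report$seed))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$seed, "\n", sep = "")
  cat("  network: ", x$network$n_nodes, " nodes / ", x$network$n_edges,
      " edges (threshold ", format(x$network$threshold, digits = 3), ")\n", sep = "")
  cat("  Fmax: ", format(x$calibration$f_max, digits = 4), "\n", sep = "")
  cat("  predictions: ", x$predictions$n_predicted_positive, " positives, ",
      x$predictions$n_abstained, " abstentions\n", sep = "")
  cat("  artifacts: ", x$out_dir, "\n", sep = "")
  invisible(x)
}
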