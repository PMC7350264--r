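io_error <- function(path, line, msg) {
  abort(paste0(path, if (!is.null(line)) paste0(":", line), ": ", msg))
}

#' Read and write purification tables
#'
#' Purification files are ragged TSVs: one purification per line with the
#' purification id, the bait accession, then the prey accessions. On
#' reading, the bait is always included among the record's proteins and
#' duplicates within a record are collapsed.
#'
#' @param path File path.
#' @return `read_purifications()`: long tibble `purification_id`, `bait`,
#'   `protein`.
#' @export
read_purifications <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- purrr::imap(lines, function(l, k) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      io_error(path, k, "purification line needs at least an id and a bait")
    }
    if (any(!nzchar(fields))) {
      io_error(path, k, "empty field in purification record")
    }
    tibble(
      purification_id = fields[1],
      bait = fields[2],
      protein = unique(c(fields[2], fields[-(1:2)]))
    )
  })
  out <- bind_rows(recs)
  if (anyDuplicated(unique(out[c("purification_id", "bait")])$purification_id)) {
    io_error(path, NULL, "duplicated purification ids")
  }
  out
}

#' @rdname read_purifications
#' @param purifications Long purification tibble.
#' @export
write_purifications <- function(purifications, path) {
  recs <- purifications |>
    group_by(.data$purification_id, .data$bait) |>
    summarise(
      line = paste(
        c(.data$purification_id[1], .data$bait[1],
          setdiff(.data$protein, .data$bait[1])),
        collapse = "\t"
      ),
      .groups = "drop"
    )
  writeLines(recs$line, path)
  invisible(path)
}

#' Read and write GMT complex files
#'
#' GMT lines are `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' An optional `filter` function receives the description string and can
#' drop complexes (e.g. a disease-comment filter); it must return TRUE to
#' keep.
#'
#' @param path File path.
#' @param filter Optional predicate on the description column.
#' @return `read_gmt()`: long tibble `complex`, `description`, `protein`.
#' @export
read_gmt <- function(path, filter = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- purrr::imap(lines, function(l, k) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      io_error(path, k, "GMT line needs a name, description and at least one member")
    }
    if (!is.null(filter) && !isTRUE(filter(fields[2]))) return(NULL)
    tibble(
      complex = fields[1],
      description = fields[2],
      protein = unique(fields[-(1:2)])
    )
  })
  bind_rows(recs)
}

#' @rdname read_gmt
#' @param complexes Named list of member vectors, or a long
#'   `complex`/`protein` tibble.
#' @export
write_gmt <- function(complexes, path) {
  if (is.data.frame(complexes)) {
    complexes <- split(complexes$protein, complexes$complex)
  }
  lines <- purrr::imap_chr(complexes, function(members, name) {
    paste(c(name, "synthetic complex", members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a minimal OBO ontology file
#'
#' Supports the OBO 1.2 subset used for GO DAG exchange: `[Term]` stanzas
#' with `id`, `name`, `namespace`, `is_a` and `relationship: part_of`
#' lines.
#'
#' @param path File path.
#' @return `read_obo()`: a [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return()
    if (is.null(cur$id) || is.null(cur$namespace)) {
      io_error(path, cur$line, "[Term] stanza missing id or namespace")
    }
    terms[[length(terms) + 1]] <<- tibble(
      id = cur$id, name = cur$name %||% cur$id, namespace = cur$namespace
    )
    for (p in cur$is_a) {
      edges[[length(edges) + 1]] <<- tibble(id = cur$id, parent = p, relation = "is_a")
    }
    for (p in cur$part_of) {
      edges[[length(edges) + 1]] <<- tibble(id = cur$id, parent = p, relation = "part_of")
    }
  }
  in_term <- FALSE
  for (k in seq_along(lines)) {
    l <- trimws(lines[k])
    if (l == "[Term]") {
      flush(cur)
      cur <- list(line = k)
      in_term <- TRUE
    } else if (grepl("^\\[", l)) {
      flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(l)) {
      if (grepl("^id:", l)) {
        cur$id <- trimws(sub("^id:", "", l))
      } else if (grepl("^name:", l)) {
        cur$name <- trimws(sub("^name:", "", l))
      } else if (grepl("^namespace:", l)) {
        cur$namespace <- trimws(sub("^namespace:", "", l))
      } else if (grepl("^is_a:", l)) {
        cur$is_a <- c(cur$is_a, trimws(sub("!.*$", "", sub("^is_a:", "", l))))
      } else if (grepl("^relationship: *part_of", l)) {
        cur$part_of <- c(
          cur$part_of,
          trimws(sub("!.*$", "", sub("^relationship: *part_of", "", l)))
        )
      }
    }
  }
  flush(cur)
  if (length(terms) == 0) io_error(path, NULL, "no [Term] stanzas found")
  go_dag(bind_rows(terms), if (length(edges) > 0) bind_rows(edges) else
    tibble(id = character(), parent = character(), relation = character()))
}

#' @rdname read_obo
#' @param dag A [go_dag()].
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges, dag$edges$id)
  for (k in seq_len(nrow(dag$terms))) {
    t <- dag$terms[k, ]
    stanza <- c(
      "[Term]",
      paste0("id: ", t$id),
      paste0("name: ", t$name),
      paste0("namespace: ", t$namespace)
    )
    e <- by_child[[t$id]]
    if (!is.null(e)) {
      for (j in seq_len(nrow(e))) {
        stanza <- c(stanza, if (e$relation[j] == "is_a") {
          paste0("is_a: ", e$parent[j])
        } else {
          paste0("relationship: part_of ", e$parent[j])
        })
      }
    }
    writeLines(c(stanza, ""), con)
  }
  invisible(path)
}

#' Read and write annotation tables
#'
#' Plain TSVs with columns `protein`, `term`, `evidence`.
#'
#' @param path File path.
#' @return `read_annotations()`: annotation tibble.
#' @export
read_annotations <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("protein", "term", "evidence")
  if (!all(need %in% names(out))) {
    io_error(path, 1, paste0("annotation file must have columns ",
                             paste(need, collapse = ", ")))
  }
  out[need]
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read and write proteoform maps
#'
#' TSVs with columns `gene`, `accession`, `form`
#' (canonical/splice/master).
#'
#' @param path File path.
#' @return `read_proteoforms()`: proteoform-map tibble.
#' @export
read_proteoforms <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("gene", "accession", "form")
  if (!all(need %in% names(out))) {
    io_error(path, 1, "proteoform file must have columns gene, accession, form")
  }
  bad <- which(!out$form %in% c("canonical", "splice", "master"))
  if (length(bad) > 0) {
    io_error(path, bad[1] + 1, paste0("invalid form: ", out$form[bad[1]]))
  }
  out[need]
}

#' @rdname read_proteoforms
#' @param proteoform_map Proteoform-map tibble.
#' @export
write_proteoforms <- function(proteoform_map, path) {
  readr::write_tsv(proteoform_map, path, progress = FALSE)
  invisible(path)
}

#' Read and write scored pair tables
#'
#' @param path File path.
#' @param scores A [score_pairs()] tibble.
#' @return `read_scored_pairs()`: a `scored_pairs` tibble (the
#'   `n_purifications` attribute is stored in a header comment).
#' @export
write_scored_pairs <- function(scores, path) {
  n <- attr(scores, "n_purifications")
  header <- paste0("# n_purifications=", n %||% NA)
  writeLines(header, path)
  readr::write_tsv(as_tibble(scores), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_scored_pairs
#' @export
read_scored_pairs <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub("^# n_purifications=", "", first))
  out <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols())
  attr(out, "n_purifications") <- n
  attr(out, "universe") <- sort(unique(c(out$protein_a, out$protein_b)))
  class(out) <- c("scored_pairs", class(out))
  out
}

#' Read and write PPI networks as GraphML
#'
#' @param network A [build_network()] graph.
#' @param path File path.
#' @return `read_network_graphml()`: a `ppi_network` igraph (directed
#'   GraphML is rejected — the interaction network is undirected).
#' @export
write_network_graphml <- function(network, path) {
  g <- network
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) {
    io_error(path, NULL, "GraphML network must be undirected")
  }
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  class(g) <- c("ppi_network", class(g))
  g
}

#' Validate an artifact file against its schema
#'
#' Strictly parses one of the pipeline's exchange formats, raising
#' line-tagged errors for malformed records, and returns the parsed
#' artifact.
#'
#' @param path File path.
#' @param schema One of `"purifications"`, `"obo"`, `"gmt"`,
#'   `"annotations"`, `"proteoforms"`, `"graphml"`, `"scored_pairs"`.
#' @return The parsed artifact.
#' @export
validate_io <- function(path, schema = c("purifications", "obo", "gmt",
                                         "annotations", "proteoforms",
                                         "graphml", "scored_pairs")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(schema,
    purifications = read_purifications(path),
    obo = read_obo(path),
    gmt = read_gmt(path),
    annotations = read_annotations(path),
    proteoforms = read_proteoforms(path),
    graphml = read_network_graphml(path),
    scored_pairs = read_scored_pairs(path)
  )
}

#' Write every artifact of a synthetic study to a directory
#'
#' Persists `purifications.tsv`, `go.obo`, `annotations.tsv` (visible
#' annotations only — masked proteins never leak), `complexes.gmt`,
#' `proteoforms.tsv`, `upe1.tsv` and `truth.json` (planted ground truth,
#' for scoring only).
#'
#' @param sim An [simulate_apms_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_purifications(sim$purifications, file.path(dir, "purifications.tsv"))
  write_obo(sim$dag, file.path(dir, "go.obo"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_gmt(sim$truth$complexes, file.path(dir, "complexes.gmt"))
  write_proteoforms(sim$proteoform_map, file.path(dir, "proteoforms.tsv"))
  writeLines(sim$truth$upe1_mask, file.path(dir, "upe1.tsv"))
  truth <- list(
    complexes = sim$truth$complexes,
    upe1_mask = sim$truth$upe1_mask,
    background = sim$truth$background,
    true_annotations = sim$truth$true_annotations
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
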