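#' Co-complex reference pairs of a gold-standard complex set
#'
#' Expands a complex catalogue into the set of unordered within-complex
#' protein pairs (the matrix-model reading of "interactions" in a complex
#' gold standard), deduplicated across overlapping complexes.
#'
#' @param complexes Either a named list of protein character vectors or a
#'   long tibble with columns `complex`, `protein`.
#' @return Tibble `protein_a`, `protein_b` with `protein_a < protein_b`.
#' @export
gold_standard_pairs <- function(complexes) {
  if (is.data.frame(complexes)) {
    complexes <- split(complexes$protein, complexes$complex)
  }
  pairs <- purrr::map(complexes, function(members) {
    members <- unique(members)
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(sort(members), 2)
    tibble(protein_a = cmb[1, ], protein_b = cmb[2, ])
  })
  out <- bind_rows(pairs)
  if (nrow(out) == 0) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  distinct(arrange(out, .data$protein_a, .data$protein_b))
}

#' Restrict scores and gold standard to their shared proteins
#'
#' Threshold calibration only makes sense over proteins observed on both
#' sides; this drops scored pairs and gold pairs involving proteins absent
#' from the other set.
#'
#' @param scores A [score_pairs()] tibble.
#' @param gold_pairs A [gold_standard_pairs()] tibble.
#' @return List with `scores`, `gold_pairs` (both restricted) and `shared`
#'   (the protein intersection).
#' @export
restrict_to_shared <- function(scores, gold_pairs) {
  score_proteins <- unique(c(scores$protein_a, scores$protein_b))
  gold_proteins <- unique(c(gold_pairs$protein_a, gold_pairs$protein_b))
  shared <- intersect(score_proteins, gold_proteins)
  if (length(shared) == 0) {
    abort("no proteins shared between scored pairs and the gold standard; cannot calibrate")
  }
  list(
    scores = filter(
      as_tibble(scores),
      .data$protein_a %in% shared & .data$protein_b %in% shared
    ),
    gold_pairs = filter(
      gold_pairs,
      .data$protein_a %in% shared & .data$protein_b %in% shared
    ),
    shared = sort(shared)
  )
}

#' Confusion counts and F1 between predicted and gold pair sets
#'
#' TP are pairs in both sets, FP pairs only predicted, FN pairs only in the
#' gold standard; precision, recall and `F1 = 2TP / (2TP + FP + FN)` follow.
#' F1 is defined as 0 when TP is 0.
#'
#' @param predicted_pairs,gold_pairs Tibbles with `protein_a`, `protein_b`
#'   (unordered pairs; orientation is normalized internally).
#' @return One-row tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
pair_confusion <- function(predicted_pairs, gold_pairs) {
  pk <- unique(pair_key(predicted_pairs$protein_a, predicted_pairs$protein_b))
  gk <- unique(pair_key(gold_pairs$protein_a, gold_pairs$protein_b))
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  )
}

#' Scan score thresholds against a gold standard (Fmax calibration)
#'
#' For every grid point a candidate network is thresholded out of the scored
#' pairs and compared with the gold-standard co-complex pairs; the maximum
#' F1 over the grid (Fmax) selects the operating threshold. With
#' `type = "quantile"` the grid points are quantiles of the observed score
#' distribution (the threshold reported is the raw score value at each
#' quantile); with `type = "value"` the grid points are raw score thresholds
#' themselves. Dice keeps pairs strictly above the threshold (high = good);
#' Hart keeps pairs strictly below (low p = good).
#'
#' @param scores A [score_pairs()] tibble.
#' @param gold Gold-standard complexes (list or `complex`/`protein` tibble)
#'   or a precomputed pair tibble from [gold_standard_pairs()].
#' @param grid Sorted numeric grid in `(0, 1)`: quantiles or raw thresholds
#'   depending on `type`. Default: 99 evenly spaced quantiles.
#' @param metric `"dice"` or `"hart"`.
#' @param type `"quantile"` (default) or `"value"`.
#' @return An `fmax_calibration` object: list with `curve` (tibble
#'   `grid_point`, `threshold`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`), `f_max`, `best_threshold`, `best_grid_point`, `metric`, `type`,
#'   `n_shared`.
#' @export
scan_thresholds <- function(scores, gold, grid = seq(0.01, 0.99, by = 0.01),
                            metric = c("dice", "hart"),
                            type = c("quantile", "value")) {
  metric <- match.arg(metric)
  type <- match.arg(type)
  if (length(grid) == 0) abort("`grid` must be non-empty")
  if (any(grid <= 0 | grid >= 1)) abort("`grid` points must lie in (0, 1)")
  grid <- sort(unique(grid))
  if (is.data.frame(gold) && all(c("protein_a", "protein_b") %in% names(gold))) {
    gp <- gold
  } else {
    gp <- gold_standard_pairs(gold)
  }
  shared <- restrict_to_shared(scores, gp)
  score_col <- if (metric == "dice") shared$scores$dice else shared$scores$hart_p
  thresholds <- if (type == "quantile") {
    unname(quantile(score_col, grid, names = FALSE))
  } else {
    grid
  }
  rows <- purrr::map2(grid, thresholds, function(g, thr) {
    keep <- if (metric == "dice") score_col > thr else score_col < thr
    conf <- pair_confusion(shared$scores[keep, ], shared$gold_pairs)
    mutate(conf, grid_point = g, threshold = thr, .before = 1)
  })
  curve <- bind_rows(rows)
  best <- which.max(curve$f1)
  structure(
    list(
      curve = curve,
      f_max = curve$f1[best],
      best_threshold = curve$threshold[best],
      best_grid_point = curve$grid_point[best],
      metric = metric,
      type = type,
      n_shared = length(shared$shared)
    ),
    class = "fmax_calibration"
  )
}

#' @export
print.fmax_calibration <- function(x, ...) {
  cat("<fmax_calibration> metric = ", x$metric, " (", x$type, " grid)\n", sep = "")
  cat("  Fmax = ", format(x$f_max, digits = 4),
      " at threshold ", format(x$best_threshold, digits = 4),
      " (grid point ", format(x$best_grid_point, digits = 4), ")\n", sep = "")
  cat("  shared proteins: ", x$n_shared, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fmax_calibration <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.fmax_calibration <- function(x, ...) {
  tibble(
    f_max = x$f_max,
    best_threshold = x$best_threshold,
    best_grid_point = x$best_grid_point,
    metric = x$metric,
    type = x$type,
    n_shared = x$n_shared
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fmax_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$grid_point, y = .data$f1)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(
      data = object$curve[which.max(object$curve$f1), ],
      color = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = if (object$type == "quantile") "score quantile" else "score threshold",
      y = "F1 against gold standard",
      title = sprintf(
        "Fmax = %.3f at %s threshold %.3f",
        object$f_max, object$metric, object$best_threshold
      )
    ) +
    ggplot2::theme_minimal()
}
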