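#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage index to a new
#' 32-bit seed, so pipeline stages can be re-run in isolation while the full
#' run stays reproducible.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (>= 0) or a known stage name.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(
      simulate = 1L, network = 2L, calibrate = 3L, go = 4L,
      predict = 5L, proteoforms = 6L
    )
    if (!stage %in% names(stages)) {
      abort(paste0("unknown pipeline stage: ", stage))
    }
    stage <- stages[[stage]]
  }
  seed <- as.double(seed)
  stage <- as.double(stage)
  # affine hash mod the Mersenne prime 2^31 - 1; keeps every derived seed a
  # valid 32-bit integer and distinct across stages for any base seed
  as.integer((seed * 2654435.0 + stage * 40503.0 + 97.0) %% 2147483647)
}

# canonical unordered pair representation: a < b lexicographically
canonical_pairs <- function(a, b) {
  swap <- a > b
  tibble(
    protein_a = ifelse(swap, b, a),
    protein_b = ifelse(swap, a, b)
  )
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- rlang::`%||%`

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min))
  }
  invisible(x)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
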