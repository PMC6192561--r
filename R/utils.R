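#' Canonical unordered pair keys
#'
#' Protein pairs are unordered throughout the package. All pair tables are
#' keyed on the lexicographically sorted pair, so queries are insensitive to
#' the order of the two identifiers.
#'
#' @param a,b Character vectors of protein identifiers (recycled).
#' @return Character vector of keys of the form `"A|B"` with `A <= B`.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split pair keys back into sorted identifier columns
#' @param keys Character vector produced by [pair_key()].
#' @return data.frame with columns `id_a`, `id_b` (`id_a <= id_b`).
#' @export
split_pair_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    id_a = vapply(parts, `[`, character(1), 1L),
    id_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Functions with a `seed` argument use this so
# that seeded calls are reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives the whole workflow; each stage (world generation,
#' elution simulation, each genomic feature, fold assignment, ...) gets its
#' own deterministic sub-seed so stages stay independent when one is re-run.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 104729L
  as.integer((as.numeric(master) * 48271 + h * 7919 + 12345) %% (2^31 - 1))
}

all_pair_keys <- function(ids) {
  ids <- sort(ids)
  n <- length(ids)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  paste(ids[idx[1L, ]], ids[idx[2L, ]], sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
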