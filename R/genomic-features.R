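# Construction of the nine external genomic features at the protein-pair
# level: mRNA coexpression, phylogenetic profile correlation, domain-domain
# interaction indicator, literature co-citation, gene fusion, gene
# neighborhood (the last three consumed as precomputed score tables), and
# three interolog indicators (small-scale literature-curated, yeast
# two-hybrid, co-immunoprecipitation) derived from a cross-species
# interaction catalog.

sort_pair_columns <- function(df) {
  swap <- df$id_a > df$id_b
  tmp <- df$id_a[swap]
  df$id_a[swap] <- df$id_b[swap]
  df$id_b[swap] <- tmp
  df
}

#' Coexpression scores from an expression matrix
#'
#' Pairwise Pearson correlation of expression vectors across samples.
#' Constant genes have no defined correlation and are dropped.
#'
#' @param expression Numeric gene x sample matrix with gene rownames.
#' @return data.frame `(id_a, id_b, score)` keyed on sorted pairs.
#' @export
coexpression_scores <- function(expression) {
  if (ncol(expression) < 3L) stop("need at least 3 samples")
  pairwise_correlation_table(expression)
}

#' Phylogenetic profile scores from presence/absence calls
#'
#' Pairwise Pearson correlation between binary presence/absence vectors
#' across species (the phi coefficient). Profiles that are all present or
#' all absent are dropped (no defined correlation).
#'
#' @param presence 0/1 protein x species matrix with protein rownames.
#' @return data.frame `(id_a, id_b, score)`.
#' @export
phylogenetic_profile_scores <- function(presence) {
  if (ncol(presence) < 2L) stop("need at least 2 species")
  if (!all(presence %in% c(0, 1))) stop("presence matrix must be 0/1")
  pairwise_correlation_table(presence)
}

pairwise_correlation_table <- function(mat) {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  variable <- apply(mat, 1L, stats::sd) > 0
  mat <- mat[variable, , drop = FALSE]
  n <- nrow(mat)
  if (n < 2L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  r <- stats::cor(t(mat))
  idx <- utils::combn(n, 2L)
  data.frame(id_a = rownames(mat)[idx[1L, ]],
             id_b = rownames(mat)[idx[2L, ]],
             score = r[t(idx)], stringsAsFactors = FALSE)
}

#' Domain-domain interaction indicator
#'
#' A pair scores 1 iff some domain of one protein is known to interact with
#' some domain of the other (unordered; a domain may interact with itself).
#'
#' @param domains Named list: protein -> character vector of domain ids.
#' @param ddi data.frame `(domain_a, domain_b)` of interacting domain pairs.
#' @return data.frame `(id_a, id_b, score)` over all protein pairs in
#'   `domains`.
#' @export
domain_interaction_indicator <- function(domains, ddi) {
  ddi_keys <- if (nrow(ddi) > 0L) {
    unique(pair_key(as.character(ddi[[1]]), as.character(ddi[[2]])))
  } else {
    character(0)
  }
  ids <- sort(names(domains))
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  score <- vapply(seq_len(ncol(idx)), function(c) {
    da <- domains[[ids[idx[1L, c]]]]
    db <- domains[[ids[idx[2L, c]]]]
    if (length(da) == 0L || length(db) == 0L) return(0)
    combos <- expand.grid(da, db, stringsAsFactors = FALSE)
    as.numeric(any(pair_key(combos[[1]], combos[[2]]) %in% ddi_keys))
  }, numeric(1))
  data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]], score = score,
             stringsAsFactors = FALSE)
}

#' Interolog indicator from a cross-species interaction catalog
#'
#' A focal pair scores 1 iff some orthologous pair has a catalog record of
#' the requested evidence class in a species other than `exclude_species`
#' (excluding the species of interest avoids circular training evidence).
#' Classes: `Y2H` records whose method string contains "two hybrid"; `IP`
#' records containing "coimmunoprecipitation" (both case-insensitive); `LC`
#' records whose supporting publication reports at most
#' `small_scale_max_ppis` distinct interactions within this catalog.
#'
#' @param catalog Catalog data.frame
#'   `(id_a, id_b, method, pmid, year, species)`.
#' @param method_class `"LC"`, `"Y2H"` or `"IP"`.
#' @param orthologs data.frame `(foreign_id, focal_id)` mapping catalog
#'   identifiers to the species of interest. Pairs with an unmapped
#'   endpoint are absent from the result (feature missing).
#' @param exclude_species Taxon label of the species of interest.
#' @param small_scale_max_ppis Small-scale threshold for the `LC` class.
#' @return data.frame `(id_a, id_b, score)` with `score = 1` rows for
#'   supported focal pairs.
#' @export
interolog_indicator <- function(catalog, method_class = c("LC", "Y2H", "IP"),
                                orthologs, exclude_species,
                                small_scale_max_ppis = 25L) {
  method_class <- match.arg(method_class)
  cat_ok <- catalog[catalog$species != exclude_species, , drop = FALSE]
  if (nrow(cat_ok) > 0L) {
    sel <- switch(method_class,
      Y2H = grepl("two hybrid", cat_ok$method, ignore.case = TRUE),
      IP = grepl("coimmunoprecipitation", cat_ok$method, ignore.case = TRUE),
      LC = {
        per_pub <- tapply(pair_key(catalog$id_a, catalog$id_b), catalog$pmid,
                          function(k) length(unique(k)))
        cat_ok$pmid %in% names(per_pub)[per_pub <= small_scale_max_ppis]
      })
    cat_ok <- cat_ok[sel, , drop = FALSE]
  }
  map <- stats::setNames(as.character(orthologs$focal_id),
                         as.character(orthologs$foreign_id))
  fa <- map[cat_ok$id_a]
  fb <- map[cat_ok$id_b]
  ok <- !is.na(fa) & !is.na(fb) & fa != fb
  keys <- unique(pair_key(fa[ok], fb[ok]))
  if (length(keys) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  ends <- split_pair_key(sort(keys))
  data.frame(id_a = ends$id_a, id_b = ends$id_b, score = 1,
             stringsAsFactors = FALSE)
}

#' Load a precomputed pair score table (co-citation, fusion, neighborhood)
#'
#' Expects a TSV with columns `(id_a, id_b, score)`, scores in `[0, 1]`.
#' Pairs are order-normalized; duplicate pairs keep the maximum score
#' (evidence-union semantics).
#'
#' @param path TSV path.
#' @param kind `"cocitation"`, `"fusion"` or `"neighborhood"` (recorded as
#'   an attribute).
#' @return data.frame `(id_a, id_b, score)`.
#' @export
load_pair_score_table <- function(path, kind = c("cocitation", "fusion",
                                                 "neighborhood")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (nrow(df) > 0L) {
    bad <- which(is.na(df[[1]]) | is.na(df[[2]]) | is.na(df[[3]]) |
                   df[[1]] == "" | df[[2]] == "")
    if (length(bad) > 0L) {
      stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
    }
    if (any(df[[3]] < 0 | df[[3]] > 1)) {
      stop(sprintf("scores outside [0, 1] at line %d of %s",
                   which(df[[3]] < 0 | df[[3]] > 1)[1] + 1L, path))
    }
  }
  names(df) <- c("id_a", "id_b", "score")
  if (nrow(df) == 0L) {
    attr(df, "kind") <- kind
    return(df)
  }
  df <- sort_pair_columns(df)
  key <- pair_key(df$id_a, df$id_b)
  score <- tapply(df$score, key, max)
  ends <- split_pair_key(names(score))
  out <- data.frame(id_a = ends$id_a, id_b = ends$id_b,
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  out
}

#' Attach external genomic features to a pair feature table
#'
#' Adds one column per feature in the combination; pairs absent from a
#' feature's table get `NA` (carried as an explicit missing value — the
#' classifier treats missing evidence as neutral). Dataset-derived columns
#' are untouched.
#'
#' @param table A pair feature table (`id_a`, `id_b`, feature columns).
#' @param combination Character vector of feature names (0 to 9 of
#'   [genomic_feature_kinds]), no duplicates.
#' @param feature_tables Named list of `(id_a, id_b, score)` tables, one
#'   per feature named in `combination`.
#' @return The table with the extra columns appended.
#' @export
attach_external_features <- function(table, combination, feature_tables) {
  if (length(combination) == 0L) return(table)
  if (anyDuplicated(combination)) stop("duplicate feature names")
  unknown <- setdiff(combination, genomic_feature_kinds)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown feature name '%s'", unknown[1]))
  }
  key <- pair_key(table$id_a, table$id_b)
  for (f in combination) {
    ft <- feature_tables[[f]]
    if (is.null(ft)) stop(sprintf("no feature table supplied for '%s'", f))
    fkey <- pair_key(ft$id_a, ft$id_b)
    table[[f]] <- ft$score[match(key, fkey)]
  }
  table
}
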