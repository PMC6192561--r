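# The evaluation battery for a predicted network: neighbor-voting
# functional connectivity, novelty fraction, time-split validation rate,
# degree-publication study bias, global clustering coefficient, and
# robustness (Jaccard) under feature withholding. Undefined metrics
# propagate as NA, never as zeros.

edge_keys <- function(network) {
  pair_key(network$edges$id_a, network$edges$id_b)
}

#' Filter a functional annotation table for neighbor voting
#'
#' Drops (protein, term) annotations supported only by the excluded
#' evidence codes, restricts to the network's proteins, and keeps terms
#' annotating between `min_frac` and `max_frac` (inclusive) of the
#' network's proteins — excluding very broad and very specific terms.
#'
#' @param ann data.frame `(protein, term, evidence)`; multiple rows per
#'   (protein, term) carry multiple codes.
#' @param network A `predicted_network`.
#' @param min_frac,max_frac Term-frequency band as fractions of network
#'   proteins (boundaries inclusive).
#' @param drop_codes Evidence codes that cannot by themselves support an
#'   annotation.
#' @return Filtered data.frame `(protein, term)` (deduplicated); warns when
#'   no term survives.
#' @export
filter_annotations <- function(ann, network, min_frac = 0.005,
                               max_frac = 0.05,
                               drop_codes = c("ND", "IPI", "IEA", "NAS")) {
  prots <- network_proteins(network)
  key <- paste(ann$protein, ann$term, sep = "\r")
  has_support <- tapply(!ann$evidence %in% drop_codes, key, any)
  ann <- ann[has_support[key], , drop = FALSE]
  ann <- unique(ann[ann$protein %in% prots, c("protein", "term")])
  n <- length(prots)
  term_n <- table(ann$term)
  frac <- as.numeric(term_n) / n
  keep_terms <- names(term_n)[frac >= min_frac & frac <= max_frac]
  out <- ann[ann$term %in% keep_terms, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no terms survive annotation filtering")
  out
}

#' Neighbor-voting functional connectivity of a network
#'
#' For each term, annotations are split into `n_folds`; in each fold every
#' network protein is scored by the fraction of its interaction partners
#' annotated with the term in the training split (guilt by association),
#' and the AUROC of recovering the fold's hidden annotations against
#' never-annotated proteins is computed by the rank statistic with
#' mid-ranks. Per-term AUROC is the mean over folds; the network summary is
#' the median over terms.
#'
#' @param network A `predicted_network`.
#' @param ann Filtered annotation data.frame `(protein, term)`.
#' @param n_folds Number of annotation folds.
#' @param seed Fold-assignment seed.
#' @return List with `per_term` (named numeric AUROCs) and `median`.
#' @export
neighbor_voting_auroc <- function(network, ann, n_folds = 3L, seed = 1L) {
  prots <- network_proteins(network)
  if (nrow(ann) == 0L || length(prots) == 0L) {
    return(list(per_term = stats::setNames(numeric(0), character(0)),
                median = NA_real_))
  }
  n <- length(prots)
  adj <- matrix(0, n, n, dimnames = list(prots, prots))
  adj[cbind(network$edges$id_a, network$edges$id_b)] <- 1
  adj[cbind(network$edges$id_b, network$edges$id_a)] <- 1
  degree <- rowSums(adj)
  terms <- unique(ann$term)
  per_term <- with_seed(seed, {
    vapply(terms, function(tm) {
      annotated <- intersect(ann$protein[ann$term == tm], prots)
      fold <- sample(rep(seq_len(n_folds), length.out = length(annotated)))
      aucs <- vapply(seq_len(n_folds), function(f) {
        hidden <- annotated[fold == f]
        train <- annotated[fold != f]
        if (length(hidden) == 0L) return(NA_real_)
        votes <- as.numeric(adj[, train, drop = FALSE] %*%
                              rep(1, length(train)))
        score <- ifelse(degree > 0, votes / degree, 0)
        names(score) <- prots
        candidates <- setdiff(prots, train)
        negatives <- setdiff(candidates, hidden)
        if (length(negatives) == 0L) return(NA_real_)
        rank_auroc(score[hidden], score[negatives])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
  })
  per_term <- per_term[!is.nan(per_term)]
  list(per_term = per_term,
       median = if (length(per_term) > 0) stats::median(per_term) else NA_real_)
}

# AUROC via the Mann-Whitney rank statistic with mid-ranks for ties.
rank_auroc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Fraction of a network's edges absent from the interaction catalog
#'
#' `known` edges are those present in the catalog, optionally restricted to
#' records dated strictly before `cutoff_year`; the novelty fraction is
#' `1 - known / total`.
#'
#' @param network A `predicted_network`.
#' @param catalog Catalog data.frame with `id_a`, `id_b`, `year`.
#' @param cutoff_year Optional year; only records with `year < cutoff_year`
#'   count as known.
#' @return Fraction in `[0, 1]`, or `NA` for an empty network.
#' @export
novelty_fraction <- function(network, catalog, cutoff_year = NULL) {
  if (nrow(network$edges) == 0L) return(NA_real_)
  if (!is.null(cutoff_year)) {
    catalog <- catalog[catalog$year < cutoff_year, , drop = FALSE]
  }
  known <- unique(pair_key(catalog$id_a, catalog$id_b))
  1 - mean(edge_keys(network) %in% known)
}

#' Time-split validation rate of putatively novel edges
#'
#' Records supported only by the excluded publication ids are removed (to
#' eliminate circularity with the analyzed experiments). Edges with no
#' record before `cutoff_year` are `novel`; the validation rate is the
#' fraction of novel edges with at least one record in `cutoff_year` or
#' later. A record's discovery date is its earliest year.
#'
#' @param network A `predicted_network`.
#' @param catalog Catalog data.frame with `id_a`, `id_b`, `year`, `pmid`.
#' @param cutoff_year Split year (e.g. 2017: pre-cutoff = known).
#' @param exclude_pmids Publication ids whose records are discarded.
#' @return Fraction in `[0, 1]`, or `NA` when there are no novel edges.
#' @export
timesplit_validation_rate <- function(network, catalog, cutoff_year,
                                      exclude_pmids = NULL) {
  if (!is.null(exclude_pmids)) {
    catalog <- catalog[!catalog$pmid %in% exclude_pmids, , drop = FALSE]
  }
  keys <- edge_keys(network)
  ckey <- pair_key(catalog$id_a, catalog$id_b)
  known <- unique(ckey[catalog$year < cutoff_year])
  after <- unique(ckey[catalog$year >= cutoff_year])
  novel <- keys[!keys %in% known]
  if (length(novel) == 0L) return(NA_real_)
  mean(novel %in% after)
}

#' Study bias of a network: degree vs publication count
#'
#' Spearman rank correlation (mid-ranks) between each network protein's
#' degree and its publication count. Proteins without a count get 0 with a
#' warning.
#'
#' @param network A `predicted_network`.
#' @param pubs data.frame `(protein, publications)`.
#' @return Spearman rho, or `NA` for fewer than 3 proteins or zero variance.
#' @export
degree_publication_bias <- function(network, pubs) {
  prots <- network_proteins(network)
  if (length(prots) < 3L) return(NA_real_)
  degree <- table(factor(c(network$edges$id_a, network$edges$id_b),
                         levels = prots))
  counts <- pubs$publications[match(prots, pubs$protein)]
  if (anyNA(counts)) {
    warning("proteins without publication counts treated as 0")
    counts[is.na(counts)] <- 0
  }
  if (stats::sd(counts) == 0 || stats::sd(degree) == 0) return(NA_real_)
  stats::cor(rank(as.numeric(degree)), rank(counts))
}

#' Global clustering coefficient (transitivity) of a network
#'
#' `3 * triangles / connected triples`: the probability that two proteins
#' connected to a common third protein are themselves connected. Returns 0
#' when the network has no connected triples.
#'
#' @param network A `predicted_network`.
#' @return Value in `[0, 1]`.
#' @export
global_clustering_coefficient <- function(network) {
  if (nrow(network$edges) == 0L) return(0)
  g <- igraph::graph_from_data_frame(network$edges[, c("id_a", "id_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  ct <- igraph::transitivity(g, type = "global")
  if (is.nan(ct)) 0 else ct
}

#' Jaccard index between two networks' edge sets
#' @param net_a,net_b `predicted_network` objects.
#' @return `|intersection| / |union|`, or `NA` when both are empty.
#' @export
jaccard_index <- function(net_a, net_b) {
  a <- unique(edge_keys(net_a))
  b <- unique(edge_keys(net_b))
  u <- union(a, b)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

#' Robustness of a pipeline to incomplete genomic data
#'
#' Randomly withholds a fraction of a feature table's entries, rebuilds the
#' network with the pipeline closure, repeats, and returns the Jaccard
#' indices between all pairs of resulting networks (plus their median). A
#' fragile feature yields low Jaccard indices under 20% withholding.
#'
#' @param build_fn Closure mapping a (perturbed) feature table to a
#'   `predicted_network`; must be deterministic given its own internal
#'   seeds.
#' @param feature_table data.frame of the feature's underlying entries
#'   (rows are the withholding unit).
#' @param withhold Fraction of rows withheld per repeat.
#' @param repeats Number of perturbed rebuilds.
#' @param seed Withholding seed.
#' @return List with `jaccards` (length `choose(repeats, 2)`) and `median`.
#' @export
robustness_jaccard <- function(build_fn, feature_table, withhold = 0.2,
                               repeats = 5L, seed = 1L) {
  nets <- with_seed(seed, {
    lapply(seq_len(repeats), function(i) {
      keep <- sample(nrow(feature_table),
                     nrow(feature_table) - floor(withhold * nrow(feature_table)))
      build_fn(feature_table[sort(keep), , drop = FALSE])
    })
  })
  idx <- utils::combn(repeats, 2L)
  js <- vapply(seq_len(ncol(idx)),
               function(c) jaccard_index(nets[[idx[1L, c]]], nets[[idx[2L, c]]]),
               numeric(1))
  list(jaccards = js, median = stats::median(js))
}
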