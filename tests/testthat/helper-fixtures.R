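# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_proteins = 60L, n_complexes = 8L, complex_size_range = c(3L, 4L),
    n_fractions = 20L, n_terms = 8L, seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(world_config, args)
}

# A deterministic scored-pair table for network assembly tests.
toy_scores <- function(n = 6L) {
  ids <- sprintf("P%02d", seq_len(n))
  idx <- utils::combn(n, 2L)
  data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
             score = seq_len(ncol(idx)) / (ncol(idx) + 1),
             stringsAsFactors = FALSE)
}

# Build a predicted_network directly from an edge list.
edges_network <- function(pairs) {
  edges <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                      score = rev(seq_len(nrow(pairs))) / (nrow(pairs) + 1),
                      rank = seq_len(nrow(pairs)), stringsAsFactors = FALSE)
  coelnet:::new_predicted_network(edges, assembly = list(mode = "manual"))
}

# Independent all-pairs AUROC oracle: fraction of (positive, negative)
# score pairs won, counting ties as half.
auroc_oracle <- function(pos, neg) {
  wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(wins)
}

# Independent neighbor-voting oracle for small networks: recompute the
# vote fractions and AUROCs by explicit loops, mirroring the documented
# definition rather than the package's matrix algebra.
neighbor_voting_oracle <- function(network, ann, n_folds, seed) {
  prots <- network_proteins(network)
  key <- pair_key(network$edges$id_a, network$edges$id_b)
  neighbors <- function(p) {
    unique(c(network$edges$id_b[network$edges$id_a == p],
             network$edges$id_a[network$edges$id_b == p]))
  }
  terms <- unique(ann$term)
  per_term <- withr::with_seed(seed, vapply(terms, function(tm) {
    annotated <- intersect(ann$protein[ann$term == tm], prots)
    fold <- sample(rep(seq_len(n_folds), length.out = length(annotated)))
    aucs <- vapply(seq_len(n_folds), function(f) {
      hidden <- annotated[fold == f]
      train <- annotated[fold != f]
      if (length(hidden) == 0L) return(NA_real_)
      score <- vapply(prots, function(p) {
        nb <- neighbors(p)
        if (length(nb) == 0L) return(0)
        sum(nb %in% train) / length(nb)
      }, numeric(1))
      candidates <- setdiff(prots, train)
      negs <- setdiff(candidates, hidden)
      if (length(negs) == 0L) return(NA_real_)
      auroc_oracle(score[hidden], score[negs])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1)))
  per_term <- per_term[!is.nan(per_term)]
  list(per_term = per_term, median = stats::median(per_term))
}
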