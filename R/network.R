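# Assembly of predicted interaction networks from ranked pair scores:
# fixed-size (top-N) networks, which control for interactome size when
# comparing feature combinations, and precision-controlled networks cut at
# the score threshold where labeled-pair precision reaches a target.

rejected_network <- function(reason) {
  structure(list(reason = reason), class = "rejected_network")
}

#' Was a precision-controlled assembly rejected?
#' @param x Result of [assemble_network_precision()].
#' @return `TRUE` for a `rejected_network`.
#' @export
is_rejected_network <- function(x) inherits(x, "rejected_network")

#' @export
print.rejected_network <- function(x, ...) {
  cat("rejected network:", x$reason, "\n")
  invisible(x)
}

new_predicted_network <- function(edges, assembly, provenance = list()) {
  rownames(edges) <- NULL
  structure(list(edges = edges, assembly = assembly, provenance = provenance),
            class = "predicted_network")
}

#' @export
print.predicted_network <- function(x, ...) {
  cat(sprintf("predicted_network: %d edges, %d proteins (%s)\n",
              nrow(x$edges),
              length(unique(c(x$edges$id_a, x$edges$id_b))),
              paste(names(x$assembly), unlist(x$assembly), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Proteins incident to a network's edges
#' @param network A `predicted_network`.
#' @return Sorted character vector.
#' @export
network_proteins <- function(network) {
  sort(unique(c(network$edges$id_a, network$edges$id_b)))
}

# Rank by log-odds when available (posteriors saturate at 1 in double
# precision); the two orderings are otherwise identical.
ranking_values <- function(scores) {
  scores$logit %||% scores$score
}

order_scored_pairs <- function(scores) {
  order(-ranking_values(scores), scores$id_a, scores$id_b)
}

#' Assemble a fixed-size network from scored pairs
#'
#' Takes the `n` highest-scoring pairs; score ties at the boundary are
#' broken by lexicographic pair order so assembly is deterministic and
#' invariant to input order. If fewer than `n` pairs are available, all are
#' taken and the shortfall flagged in the assembly metadata.
#'
#' @param scores data.frame `(id_a, id_b, score)`.
#' @param n Network size (number of edges).
#' @param provenance Optional provenance list (dataset, combination, seed).
#' @return A `predicted_network` with ranked edges.
#' @export
assemble_network_topN <- function(scores, n = 10000L, provenance = list()) {
  ord <- order_scored_pairs(scores)
  take <- seq_len(min(n, nrow(scores)))
  edges <- scores[ord[take], c("id_a", "id_b", "score")]
  edges$rank <- seq_len(nrow(edges))
  new_predicted_network(
    edges,
    assembly = list(mode = "top_n", n = n, shortfall = nrow(scores) < n),
    provenance = provenance)
}

#' Precision along the score ranking of labeled pairs
#'
#' For every distinct score threshold `t` (taken over labeled pairs,
#' descending), the precision `TP / (TP + FP)` among labeled pairs with
#' score >= `t`.
#'
#' @param scores data.frame `(id_a, id_b, score)`.
#' @param labels Factor from [label_pairs()] aligned with `scores`.
#' @return data.frame `(threshold, precision, n_labeled)`.
#' @export
precision_curve <- function(scores, labels) {
  v <- ranking_values(scores)
  lab <- which(labels != "unlabeled")
  s <- v[lab]
  pos <- labels[lab] == "positive"
  ord <- order(-s)
  s <- s[ord]; pos <- pos[ord]
  cum_tp <- cumsum(pos)
  prec <- cum_tp / seq_along(pos)
  last <- !duplicated(s, fromLast = TRUE)  # per distinct threshold: all >= t
  data.frame(threshold = s[last], precision = prec[last],
             n_labeled = seq_along(pos)[last])
}

#' Assemble a precision-controlled network
#'
#' Cuts the full ranking (labeled and unlabeled pairs) at the smallest
#' score threshold whose labeled-pair precision is at least `precision`.
#' Networks with fewer than `min_edges` edges are rejected, as are
#' unreachable precision targets.
#'
#' @param scores data.frame `(id_a, id_b, score)`.
#' @param labels Factor from [label_pairs()].
#' @param precision Target precision in `(0, 1]`.
#' @param min_edges Minimum acceptable network size.
#' @param provenance Optional provenance list.
#' @return A `predicted_network`, or a `rejected_network` object whose
#'   `reason` element explains the rejection.
#' @export
assemble_network_precision <- function(scores, labels, precision = 0.5,
                                       min_edges = 2000L,
                                       provenance = list()) {
  curve <- precision_curve(scores, labels)
  ok <- which(curve$precision >= precision)
  if (length(ok) == 0L) {
    return(rejected_network(sprintf("precision %.2f unreachable", precision)))
  }
  thr <- min(curve$threshold[ok])
  keep <- ranking_values(scores) >= thr
  if (sum(keep) < min_edges) {
    return(rejected_network(sprintf("only %d edges at precision %.2f (< %d)",
                                    sum(keep), precision, min_edges)))
  }
  ord <- order_scored_pairs(scores[keep, , drop = FALSE])
  edges <- scores[keep, c("id_a", "id_b", "score")][ord, ]
  edges$rank <- seq_len(nrow(edges))
  new_predicted_network(
    edges,
    assembly = list(mode = "precision", precision = precision,
                    threshold = thr, min_edges = min_edges),
    provenance = provenance)
}
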