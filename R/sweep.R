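# The combination sweep: enumerate external-feature combinations, run the
# full prediction + evaluation pipeline for every (dataset, combination),
# and compute trend statistics over the resulting points.

#' Enumerate external-feature combinations for a sweep
#'
#' For every combination size `m` from 0 to `length(features)`: all
#' combinations when there are at most `max_per_size` of them, otherwise
#' `max_per_size` distinct combinations sampled without replacement.
#'
#' @param features Character vector of feature names (unique).
#' @param max_per_size Cap on combinations per size.
#' @param seed Sampling seed.
#' @return A `combination_plan`: list of character vectors (the empty
#'   vector is the size-0 baseline), ordered by size.
#' @export
enumerate_combinations <- function(features = genomic_feature_kinds,
                                   max_per_size = 10L, seed = 1L) {
  if (anyDuplicated(features)) stop("feature names must be unique")
  plan <- with_seed(seed, {
    out <- list(character(0))
    for (m in seq_along(features)) {
      combos <- utils::combn(features, m, simplify = FALSE)
      if (length(combos) > max_per_size) {
        combos <- combos[sort(sample(length(combos), max_per_size))]
      }
      out <- c(out, combos)
    }
    out
  })
  structure(plan, class = "combination_plan",
            max_per_size = max_per_size, seed = seed)
}

#' Generate a complete synthetic co-elution dataset
#'
#' Runs the whole synthetic-data module for one study: ground-truth world,
#' elution matrix (filtered), the six dataset-derived pair features, all
#' nine external genomic feature tables (attached as columns), reference
#' labels, the time-stamped interaction catalog, functional annotations and
#' publication counts. The catalog's pre-cutoff years use the configured
#' discovery bias; post-cutoff years use `post_cutoff_bias_strength`
#' (default: the same bias; set 0 to make prospective validation-period
#' discoveries independent of study intensity and hence of feature
#' coverage).
#'
#' @param config A [world_config()].
#' @param id Dataset identifier.
#' @param cutoff_year Time-split year separating known from withheld
#'   discoveries.
#' @param post_cutoff_bias_strength Discovery bias exponent for years at or
#'   after `cutoff_year`.
#' @param post_cutoff_detection_rate Per-pair, per-year discovery
#'   probability in the validation window. The default is much higher than
#'   the historical accrual rate: the recent withheld window of a real
#'   catalog holds a large share of all records, and the validation-rate
#'   metric needs non-degenerate counts at desk scale.
#' @return A `coelution_dataset` list.
#' @export
prepare_synthetic_dataset <- function(config, id = "ds1", cutoff_year = 2017L,
                                      post_cutoff_bias_strength = NULL,
                                      post_cutoff_detection_rate = 0.4) {
  world <- generate_world(config)
  mat <- filter_proteins(simulate_elution(world, config))
  pt <- build_pair_features(mat, seed = derive_seed(config$seed, "clean"))
  feats <- stats::setNames(
    lapply(genomic_feature_kinds, simulate_genomic_feature,
           world = world, config = config),
    genomic_feature_kinds)
  pt <- attach_external_features(pt, genomic_feature_kinds, feats)
  labels <- label_pairs(pt, world$complexes)
  years <- seq(config$catalog_years[1], config$catalog_years[2])
  pre_years <- years[years < cutoff_year]
  post_years <- years[years >= cutoff_year]
  catalog <- simulate_interaction_catalog(world, config, years = pre_years)
  if (length(post_years) > 0L) {
    catalog <- rbind(catalog, simulate_interaction_catalog(
      world, config, years = post_years,
      detection_rate = post_cutoff_detection_rate,
      bias_strength = post_cutoff_bias_strength %||% config$bias_strength))
  }
  structure(list(
    id = id, config = config, world = world, elution = mat,
    pair_table = pt, labels = labels, feature_tables = feats,
    catalog = catalog, cutoff_year = cutoff_year,
    annotations = simulate_annotations(
      world, config$n_terms, config$term_size_range,
      config$annotation_coherence, seed = derive_seed(config$seed, "ann")),
    publications = simulate_publication_counts(
      world, config$mean_publications, seed = derive_seed(config$seed, "pubs"))
  ), class = "coelution_dataset")
}

#' Evaluate one predicted network against a dataset's references
#'
#' @param network A `predicted_network`.
#' @param dataset A `coelution_dataset` (or any list with `annotations`,
#'   `catalog`, `publications`, `cutoff_year`).
#' @param seed Neighbor-voting fold seed.
#' @return Named list of the evaluation metrics: `functional_connectivity`
#'   (median neighbor-voting AUROC), `novelty_fraction`, `validation_rate`,
#'   `bias_rho`, `clustering_coefficient`, `n_edges`, `n_proteins`.
#' @export
evaluate_network <- function(network, dataset, seed = 1L) {
  fa <- suppressWarnings(filter_annotations(dataset$annotations, network))
  nv <- neighbor_voting_auroc(network, fa, n_folds = 3L, seed = seed)
  list(
    functional_connectivity = nv$median,
    novelty_fraction = novelty_fraction(network, dataset$catalog,
                                        dataset$cutoff_year),
    validation_rate = timesplit_validation_rate(network, dataset$catalog,
                                                dataset$cutoff_year),
    bias_rho = degree_publication_bias(network, dataset$publications),
    clustering_coefficient = global_clustering_coefficient(network),
    n_edges = nrow(network$edges),
    n_proteins = length(network_proteins(network))
  )
}

#' Metric columns produced by [evaluate_network()]
#' @export
sweep_metrics <- c("functional_connectivity", "novelty_fraction",
                   "validation_rate", "bias_rho", "clustering_coefficient")

#' Run a combination sweep over datasets
#'
#' For each (dataset, combination): score all pairs with the naive Bayes
#' classifier in k-fold cross-validation using the six dataset-derived
#' features plus the combination's external columns, assemble a top-N
#' network and evaluate all metrics. Per-feature fold likelihood ratios are
#' precomputed once per dataset, so combinations reuse the same fitted
#' densities. Per-row failures are recorded (column `error`) and the sweep
#' continues; rows already present in `cache` are reused.
#'
#' @param datasets List of `coelution_dataset` objects.
#' @param plan A `combination_plan`.
#' @param top_n Network size.
#' @param k Cross-validation folds.
#' @param seed Master seed for fold assignment and evaluation folds.
#' @param cache Optional environment used to memoize rows across calls.
#' @return data.frame: one row per (dataset, combination) with the metric
#'   columns of [sweep_metrics].
#' @export
run_sweep <- function(datasets, plan, top_n = 1000L, k = 10L, seed = 1L,
                      cache = NULL) {
  rows <- list()
  for (ds in datasets) {
    pre <- cv_feature_llr(ds$pair_table, ds$labels, k = k,
                          seed = derive_seed(seed, paste0("folds_", ds$id)))
    for (combo in plan) {
      combo_id <- paste(combo, collapse = ";")
      key <- paste(ds$id, combo_id, top_n, k, seed, sep = "|")
      if (!is.null(cache) && !is.null(cache[[key]])) {
        rows[[length(rows) + 1L]] <- cache[[key]]
        next
      }
      row <- tryCatch({
        s <- scores_from_llr(pre, c(elution_feature_names, combo))
        scores <- data.frame(
          id_a = ds$pair_table$id_a, id_b = ds$pair_table$id_b,
          score = s$score, logit = s$logit, stringsAsFactors = FALSE)
        net <- assemble_network_topN(
          scores, n = top_n,
          provenance = list(dataset = ds$id, combination = combo, seed = seed))
        metrics <- evaluate_network(net, ds,
                                    seed = derive_seed(seed, "neighbor_voting"))
        c(list(dataset = ds$id, combination = combo_id,
               n_features = length(combo)), metrics, list(error = NA_character_))
      }, error = function(e) {
        list(dataset = ds$id, combination = combo_id,
             n_features = length(combo),
             functional_connectivity = NA_real_, novelty_fraction = NA_real_,
             validation_rate = NA_real_, bias_rho = NA_real_,
             clustering_coefficient = NA_real_, n_edges = NA_integer_,
             n_proteins = NA_integer_, error = conditionMessage(e))
      })
      if (!is.null(cache)) cache[[key]] <- row
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Spearman trend of a metric against the number of external features
#'
#' @param result A sweep result data.frame.
#' @param metric One of [sweep_metrics].
#' @return List `(rho, p, n)` from [spearman_test()].
#' @export
spearman_trend <- function(result, metric) {
  if (!metric %in% names(result)) stop(sprintf("unknown metric '%s'", metric))
  spearman_test(result$n_features, result[[metric]])
}

#' Single-feature effects relative to the baseline networks
#'
#' For each external feature and metric, compares the metric values of the
#' single-feature (`m = 1`) networks against the baseline (`m = 0`)
#' networks across datasets with a two-sided Brunner-Munzel test, with
#' Bonferroni adjustment within each metric.
#'
#' @param result A sweep result data.frame.
#' @param metrics Metric columns to test.
#' @return data.frame `(feature, metric, estimate, p, p_adjusted)`.
#' @export
single_feature_effects <- function(result, metrics = sweep_metrics) {
  base <- result[result$n_features == 0L, , drop = FALSE]
  singles <- result[result$n_features == 1L, , drop = FALSE]
  rows <- list()
  for (metric in metrics) {
    for (f in unique(singles$combination)) {
      a <- base[[metric]][!is.na(base[[metric]])]
      b <- singles[[metric]][singles$combination == f &
                               !is.na(singles[[metric]])]
      res <- if (length(a) >= 2L && length(b) >= 2L) {
        tryCatch(brunner_munzel(a, b),
                 error = function(e) list(estimate = NA_real_, p = NA_real_))
      } else {
        list(estimate = NA_real_, p = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, metric = metric, estimate = res$estimate, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::ave(out$p, out$metric,
                               FUN = function(p) bonferroni_adjust(p))
  out
}

#' Write the machine-readable summary of a sweep
#'
#' Writes the full scatter table (one row per network), the per-metric
#' Spearman trend statistics, and the single-feature-vs-baseline
#' comparison table.
#'
#' @param result A sweep result data.frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `trends` and `single_features`.
#' @export
summarize_sweep <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(result) == 0L) {
    warning("empty sweep result")
    utils::write.table(result, file.path(dir, "sweep_scatter.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(list(trends = NULL, single_features = NULL)))
  }
  utils::write.table(result, file.path(dir, "sweep_scatter.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  trends <- do.call(rbind, lapply(sweep_metrics, function(m) {
    tr <- spearman_trend(result, m)
    data.frame(metric = m, rho = tr$rho, p = tr$p, n = tr$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(trends, file.path(dir, "trend_statistics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sf <- single_feature_effects(result)
  utils::write.table(sf, file.path(dir, "single_feature_effects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(trends = trends, single_features = sf))
}
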