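#!/usr/bin/env Rscript

# Step 2 — predict interaction networks from the simulated study written by
# 01_simulate.R: label pairs from the reference complexes, train the naive
# Bayes co-complex classifier in 10-fold cross-validation on the six
# co-elution features alone (baseline) and supplemented with all nine
# external genomic features, and assemble fixed-size and
# precision-controlled networks.

library(coelnet)

data_dir <- "results/data"
out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pair_table <- read_pair_table_tsv(file.path(data_dir, "pair_features.tsv"))
complexes <- read_complexes_tsv(file.path(data_dir, "complexes.tsv"))
labels <- label_pairs(pair_table, complexes)
message(sprintf("Labeled pairs: %d positive, %d negative, %d unlabeled.",
                sum(labels == "positive"), sum(labels == "negative"),
                sum(labels == "unlabeled")))

for (combo in list(baseline = character(0), integrated = genomic_feature_kinds)) {
  name <- if (length(combo) == 0) "baseline" else "integrated"
  cols <- c(elution_feature_names, combo)
  scores <- cross_validated_scores(pair_table, labels, k = 10L, seed = 7L,
                                   feature_cols = cols)
  net <- assemble_network_topN(scores, n = 800L,
                               provenance = list(dataset = "demo",
                                                 combination = combo,
                                                 seed = 7L))
  write_network_tsv(net, file.path(out, paste0(name, "_top800.tsv")))
  prec <- assemble_network_precision(scores, labels, precision = 0.5,
                                     min_edges = 100L,
                                     provenance = list(dataset = "demo",
                                                       combination = combo,
                                                       seed = 7L))
  if (is_rejected_network(prec)) {
    message(name, ": 50%-precision network rejected (", prec$reason, ")")
  } else {
    write_network_tsv(prec, file.path(out, paste0(name, "_precision50.tsv")))
    message(sprintf("%s: top-800 written; 50%%-precision network has %d edges.",
                    name, nrow(prec$edges)))
  }
}
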