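#!/usr/bin/env Rscript

# Step 3 — evaluate the networks written by 02_predict.R with the full
# metric battery: neighbor-voting functional connectivity, novelty
# fraction, time-split validation rate (2017 cutoff), degree-publication
# study bias, and the global clustering coefficient.

library(coelnet)

data_dir <- "results/data"
out <- "results"
catalog <- read_catalog_tsv(file.path(data_dir, "catalog.tsv"))
annotations <- read_annotations_tsv(file.path(data_dir, "annotations.tsv"))
pubs <- read_publication_counts_tsv(file.path(data_dir,
                                              "publication_counts.tsv"))
dataset <- list(catalog = catalog, annotations = annotations,
                publications = pubs, cutoff_year = 2017L)

rows <- list()
for (f in list.files("results/networks", pattern = "\\.tsv$",
                     full.names = TRUE)) {
  net <- read_network_tsv(f)
  m <- evaluate_network(net, dataset, seed = 11L)
  rows[[length(rows) + 1L]] <- data.frame(
    network = sub("\\.tsv$", "", basename(f)),
    as.data.frame(m), stringsAsFactors = FALSE)
}
report <- do.call(rbind, rows)
utils::write.table(report, file.path(out, "network_evaluation.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
print(report, digits = 3)
message("Wrote results/network_evaluation.tsv")
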