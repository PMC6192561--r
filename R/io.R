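# Readers and writers for the plain-text dialects used throughout:
# chromatogram CSV (rows = proteins, columns = fraction_1..F, empty cell =
# missing), complex TSV (complex_id, semicolon-separated members), catalog
# TSV, GAF-like annotation TSV, publication-count TSV, pair-feature TSV and
# network TSV with a '#' header block. All round-trip losslessly.

#' @rdname elution_io
#' @param matrix Proteins x fractions numeric matrix with `NA` missing.
#' @param path File path.
#' @export
write_elution_csv <- function(matrix, path) {
  df <- data.frame(protein = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read/write chromatogram matrices
#'
#' @name elution_io
#' @return `read_elution_csv` returns a proteins x fractions matrix.
#' @export
read_elution_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname complex_io
#' @param complexes Named list: complex id -> character vector of members.
#' @param path File path.
#' @export
write_complexes_tsv <- function(complexes, path) {
  df <- data.frame(complex_id = names(complexes),
                   members = vapply(complexes, paste, character(1),
                                    collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write reference complex files (CORUM-like dialect)
#'
#' One row per complex: `complex_id`, then the member accessions joined by
#' semicolons.
#'
#' @name complex_io
#' @return `read_complexes_tsv` returns a named list of member vectors.
#' @export
read_complexes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(df$members, ";", fixed = TRUE), df$complex_id)
}

#' @rdname catalog_io
#' @param catalog Catalog data.frame.
#' @param path File path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read/write time-stamped interaction catalogs
#' @name catalog_io
#' @return `read_catalog_tsv` returns a data.frame
#'   `(id_a, id_b, method, pmid, year, species)`.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(year = "integer", pmid = "character"))
  df
}

#' @rdname annotation_io
#' @param ann Annotation data.frame `(protein, term, evidence)`.
#' @param path File path.
#' @export
write_annotations_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write GAF-like annotation tables
#' @name annotation_io
#' @export
read_annotations_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pub_io
#' @param pubs data.frame `(protein, publications)`.
#' @param path File path.
#' @export
write_publication_counts_tsv <- function(pubs, path) {
  utils::write.table(pubs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write per-protein publication counts
#' @name pub_io
#' @export
read_publication_counts_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pair_table_io
#' @param table Pair table data.frame whose first two columns are
#'   `id_a`, `id_b`.
#' @param path File path.
#' @export
write_pair_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read/write generic pair tables (id_a, id_b, value columns)
#' @name pair_table_io
#' @export
read_pair_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a predicted network with its provenance header
#'
#' The header block (`# key: value` lines) records the dataset id, the
#' external-feature combination, the assembly mode and the seed, followed by
#' a TSV body `(id_a, id_b, score, rank)`.
#'
#' @param network A `predicted_network`.
#' @param path File path.
#' @export
write_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(dataset = network$provenance$dataset %||% "NA",
           combination = paste(network$provenance$combination %||% character(0),
                               collapse = ";"),
           assembly = paste(names(network$assembly), unlist(network$assembly),
                            sep = "=", collapse = ";"),
           seed = as.character(network$provenance$seed %||% "NA"))
  writeLines(sprintf("# %s: %s", names(hdr), hdr), con)
  utils::write.table(network$edges, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a predicted network written by [write_network_tsv()]
#' @param path File path.
#' @return A `predicted_network`.
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- sub("^# ", "", lines[hdr])
  kv <- strsplit(meta, ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = ": "),
                                 character(1)),
                          vapply(kv, `[`, character(1), 1))
  edges <- utils::read.delim(text = paste(lines[-hdr], collapse = "\n"),
                             stringsAsFactors = FALSE)
  combo <- strsplit(meta[["combination"]], ";", fixed = TRUE)[[1]]
  new_predicted_network(edges,
                        assembly = list(mode = meta[["assembly"]]),
                        provenance = list(dataset = meta[["dataset"]],
                                          combination = combo,
                                          seed = meta[["seed"]]))
}
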