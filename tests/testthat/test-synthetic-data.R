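# Generator contracts: determinism, exact enumerability of the ground
# truth, and the conditional distributions of every observable.

test_that("world generation is deterministic and exactly enumerable", {
  cfg <- tiny_config(seed = 4L)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)

  empty <- generate_world(tiny_config(n_complexes = 0L, n_terms = 0L))
  expect_length(empty$true_interactions, 0L)

  cfg10 <- world_config(n_proteins = 100L, n_complexes = 10L,
                        complex_size_range = c(4L, 4L), n_fractions = 20L,
                        n_terms = 10L, seed = 2L)
  w <- generate_world(cfg10)
  expect_length(w$true_interactions, 10 * choose(4, 2))
  expect_true(all(lengths(w$complexes) == 4L))
  # every true interaction is intra-complex
  intra <- unlist(lapply(w$complexes, function(m) coelnet:::all_pair_keys(m)))
  expect_setequal(w$true_interactions, intra)
  expect_true(all(w$study_intensity > 0))

  expect_error(
    generate_world(world_config(n_proteins = 10L, n_complexes = 3L,
                                complex_size_range = c(2L, 4L),
                                n_fractions = 10L, n_terms = 0L)),
    "infeasible")
})

test_that("elution profiles follow the co-complex peak model", {
  cfg0 <- tiny_config(noise_sd = 0, missing_rate = 0, peak_jitter_sd = 0)
  w <- generate_world(cfg0)
  mat <- simulate_elution(w, cfg0)
  cpx <- w$complexes[[1]]
  r <- cor(mat[cpx[1], ], mat[cpx[2], ])
  expect_equal(r, 1, tolerance = 1e-9)

  cfg_miss <- tiny_config(missing_rate = 1)
  expect_true(all(is.na(simulate_elution(generate_world(cfg_miss), cfg_miss))))

  # Monte-Carlo contract: within-complex correlation beats between-complex
  within <- between <- numeric(0)
  for (s in 1:5) {
    cfg <- tiny_config(seed = s)
    w <- generate_world(cfg)
    mat <- simulate_elution(w, cfg)
    mat[is.na(mat)] <- 0
    cors <- suppressWarnings(cor(t(mat)))
    keys <- outer(rownames(mat), rownames(mat), pair_key)
    truth <- matrix(keys %in% w$true_interactions, nrow(mat))
    ut <- upper.tri(cors)
    within <- c(within, cors[ut & truth])
    between <- c(between, cors[ut & !truth])
  }
  expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE))
})

test_that("feature informativeness and coverage bias behave as declared", {
  # informativeness 0 => score distribution independent of co-complex status
  n_sig <- 0L
  for (s in 1:20) {
    cfg <- tiny_config(seed = s, feature_informativeness = 0,
                       study_coupling = 0, coverage_bias = 0)
    w <- generate_world(cfg)
    ft <- simulate_genomic_feature(w, "coexpression", cfg)
    co <- pair_key(ft$id_a, ft$id_b) %in% w$true_interactions
    if (sum(co) >= 5) {
      p <- suppressWarnings(ks.test(ft$score[co], ft$score[!co]))$p.value
      if (p < 0.05) n_sig <- n_sig + 1L
    }
  }
  expect_lte(n_sig, 4L)  # ~binomial(20, 0.05) under the null

  # coverage_bias 0 => observation rate uncorrelated with study intensity
  rhos <- vapply(1:20, function(s) {
    cfg <- world_config(n_proteins = 500L, n_complexes = 20L,
                        n_fractions = 10L, coverage_bias = 0,
                        study_coupling = 0, n_terms = 0L, seed = s)
    w <- generate_world(cfg)
    ft <- simulate_genomic_feature(w, "cocitation", cfg)
    obs <- table(factor(c(ft$id_a, ft$id_b), levels = w$proteins))
    cor(rank(as.numeric(obs)), rank(w$study_intensity))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)

  # limit case: perfect, fully covered interolog equals co-complex truth
  cfg1 <- tiny_config(feature_informativeness = 1, feature_coverage = 1,
                      coverage_bias = 0, study_coupling = 0,
                      feature_fp_rate = 0)
  w1 <- generate_world(cfg1)
  ft1 <- simulate_genomic_feature(w1, "interolog_Y2H", cfg1)
  expect_setequal(pair_key(ft1$id_a, ft1$id_b)[ft1$score == 1],
                  w1$true_interactions)
  expect_true(all(ft1$score %in% c(0, 1)))

  expect_error(simulate_genomic_feature(w1, "telepathy", cfg1), "unknown")
})

test_that("interaction catalog accrual follows detection and bias settings", {
  cfg <- tiny_config()
  w <- generate_world(cfg)
  expect_identical(nrow(simulate_interaction_catalog(w, cfg, detection_rate = 0)),
                   0L)

  all_at_once <- simulate_interaction_catalog(
    w, cfg, years = 2010L, detection_rate = 1, bias_strength = 0, fp_rate = 0)
  expect_setequal(pair_key(all_at_once$id_a, all_at_once$id_b),
                  w$true_interactions)

  # study bias: discovered pairs are better-studied than undiscovered ones
  diffs <- vapply(1:20, function(s) {
    cfg_s <- tiny_config(seed = s)
    w_s <- generate_world(cfg_s)
    cat_s <- simulate_interaction_catalog(w_s, cfg_s, years = 2005L,
                                          detection_rate = 0.3,
                                          bias_strength = 2, fp_rate = 0)
    disc <- unique(pair_key(cat_s$id_a, cat_s$id_b))
    gm <- function(keys) {
      e <- split_pair_key(keys)
      mean(sqrt(w_s$study_intensity[e$id_a] * w_s$study_intensity[e$id_b]))
    }
    und <- setdiff(w_s$true_interactions, disc)
    if (length(disc) == 0 || length(und) == 0) return(NA_real_)
    gm(disc) - gm(und)
  }, numeric(1))
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("annotations and publication counts track the ground truth", {
  cfg <- tiny_config()
  w <- generate_world(cfg)
  coherent <- simulate_annotations(w, n_terms = length(w$complexes),
                                   coherence = 1, seed = 3L)
  for (i in seq_along(w$complexes)) {
    members <- coherent$protein[coherent$term == sprintf("T%04d", i)]
    expect_setequal(members, w$complexes[[i]])
  }
  expect_identical(nrow(simulate_annotations(w, n_terms = 0L)), 0L)
  expect_error(simulate_annotations(w, 3L, size_range = c(0L, 5L)),
               "size_range")

  rhos <- vapply(1:20, function(s) {
    cfg_s <- world_config(n_proteins = 500L, n_complexes = 20L,
                          n_fractions = 10L, n_terms = 0L, seed = s)
    w_s <- generate_world(cfg_s)
    pubs <- simulate_publication_counts(w_s, seed = s)
    cor(rank(pubs$publications), rank(w_s$study_intensity))
  }, numeric(1))
  expect_gt(mean(rhos), 0.5)
})

test_that("all emitted tables round-trip losslessly through their writers", {
  cfg <- tiny_config(seed = 9L)
  w <- generate_world(cfg)
  mat <- simulate_elution(w, cfg)
  ann <- simulate_annotations(w, 5L, seed = 2L)
  cat_df <- simulate_interaction_catalog(w, cfg)
  pubs <- simulate_publication_counts(w, seed = 2L)

  d <- withr::local_tempdir()
  p <- file.path(d, "elution.csv")
  write_elution_csv(mat, p)
  expect_equal(read_elution_csv(p), mat)

  p <- file.path(d, "complexes.tsv")
  write_complexes_tsv(w$complexes, p)
  expect_identical(read_complexes_tsv(p), w$complexes)

  p <- file.path(d, "catalog.tsv")
  write_catalog_tsv(cat_df, p)
  expect_equal(read_catalog_tsv(p), cat_df, ignore_attr = TRUE)

  p <- file.path(d, "ann.tsv")
  write_annotations_tsv(ann, p)
  expect_equal(read_annotations_tsv(p), ann, ignore_attr = TRUE)

  p <- file.path(d, "pubs.tsv")
  write_publication_counts_tsv(pubs, p)
  expect_equal(read_publication_counts_tsv(p), pubs, ignore_attr = TRUE)

  net <- assemble_network_topN(toy_scores(), n = 5L,
                               provenance = list(dataset = "toy",
                                                 combination = c("a", "b"),
                                                 seed = 7L))
  p <- file.path(d, "net.tsv")
  write_network_tsv(net, p)
  back <- read_network_tsv(p)
  expect_equal(back$edges, net$edges, ignore_attr = TRUE)
  expect_identical(back$provenance$combination, c("a", "b"))
})
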