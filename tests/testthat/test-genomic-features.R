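# The nine external genomic features: correlation-based scores against
# closed forms, indicator features against brute-force enumeration, score
# table loading, and feature attachment.

test_that("coexpression scores are pairwise Pearson correlations", {
  set.seed(21)
  expr <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("G", 1:5), NULL))
  expr[2, ] <- expr[1, ]            # duplicated gene
  expr[3, ] <- -expr[1, ]           # negated gene
  sc <- coexpression_scores(expr)
  key <- pair_key(sc$id_a, sc$id_b)
  expect_equal(sc$score[key == "G1|G2"], 1, tolerance = 1e-12)
  expect_equal(sc$score[key == "G1|G3"], -1, tolerance = 1e-12)
  for (r in sample(nrow(sc), 5)) {
    expect_equal(sc$score[r], cor(expr[sc$id_a[r], ], expr[sc$id_b[r], ]),
                 tolerance = 1e-12)
  }
  expr[4, ] <- 7                    # constant gene: no defined correlation
  expect_false("G4" %in% unlist(coexpression_scores(expr)[, 1:2]))
  expect_error(coexpression_scores(expr[, 1:2]), "3 samples")
})

test_that("phylogenetic profile scores equal the phi coefficient", {
  set.seed(22)
  pres <- matrix(rbinom(80, 1, 0.5), 4, 20,
                 dimnames = list(paste0("P", 1:4), NULL))
  pres[2, ] <- pres[1, ]
  sc <- phylogenetic_profile_scores(pres)
  key <- pair_key(sc$id_a, sc$id_b)
  expect_equal(sc$score[key == "P1|P2"], 1, tolerance = 1e-12)
  phi <- function(x, y) {
    n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y)
    n00 <- sum(!x & !y)
    (n11 * n00 - n10 * n01) /
      sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  }
  r34 <- sc$score[key == "P3|P4"]
  expect_equal(r34, phi(pres[3, ] == 1, pres[4, ] == 1), tolerance = 1e-12)
  # complementary profiles anti-correlate perfectly
  pres[3, ] <- 1 - pres[1, ]
  sc2 <- phylogenetic_profile_scores(pres)
  expect_equal(sc2$score[pair_key(sc2$id_a, sc2$id_b) == "P1|P3"], -1,
               tolerance = 1e-12)
  pres[4, ] <- 1                    # all-present: dropped
  expect_false("P4" %in% unlist(phylogenetic_profile_scores(pres)[, 1:2]))
  expect_error(phylogenetic_profile_scores(pres[, 1, drop = FALSE]),
               "2 species")
  expect_error(phylogenetic_profile_scores(pres * 2), "0/1")
})

test_that("domain interaction indicator equals the brute-force double loop", {
  empty <- domain_interaction_indicator(
    list(A = "D1", B = "D2"),
    data.frame(domain_a = character(0), domain_b = character(0)))
  expect_true(all(empty$score == 0))

  simple <- domain_interaction_indicator(
    list(A = "D1", B = "D2"),
    data.frame(domain_a = "D1", domain_b = "D2"))
  expect_identical(simple$score, 1)

  set.seed(23)
  doms <- paste0("D", 1:6)
  prots <- stats::setNames(
    lapply(1:10, function(i) sample(doms, sample(0:3, 1))),
    paste0("P", sprintf("%02d", 1:10)))
  ddi <- unique(data.frame(domain_a = sample(doms, 5, TRUE),
                           domain_b = sample(doms, 5, TRUE)))
  got <- domain_interaction_indicator(prots, ddi)
  ddi_keys <- pair_key(ddi$domain_a, ddi$domain_b)
  for (r in seq_len(nrow(got))) {
    hit <- FALSE
    for (da in prots[[got$id_a[r]]]) for (db in prots[[got$id_b[r]]]) {
      if (pair_key(da, db) %in% ddi_keys) hit <- TRUE
    }
    expect_identical(got$score[r], as.numeric(hit))
  }
})

test_that("interolog classes respect species exclusion and the 25-PPI rule", {
  orth <- data.frame(foreign_id = paste0("y", 1:6),
                     focal_id = paste0("H", 1:6))
  catalog <- data.frame(
    id_a = c("y1", "y1", "y3", "y5", "h1"),
    id_b = c("y2", "y4", "y4", "y6", "h2"),
    method = c("two hybrid", "anti bait coimmunoprecipitation",
               "Two Hybrid", "x-ray diffraction", "two hybrid"),
    pmid = c("pm1", "pm2", "pm1", "pm3", "pm4"),
    year = rep(2010L, 5), species = c(rep("yeast", 4), "human"),
    stringsAsFactors = FALSE)

  y2h <- interolog_indicator(catalog, "Y2H", orth, exclude_species = "human")
  expect_setequal(pair_key(y2h$id_a, y2h$id_b), c("H1|H2", "H3|H4"))

  ip <- interolog_indicator(catalog, "IP", orth, exclude_species = "human")
  expect_setequal(pair_key(ip$id_a, ip$id_b), "H1|H4")

  # the human-only record never crosses the species exclusion
  none <- interolog_indicator(catalog, "Y2H", orth, exclude_species = "yeast")
  expect_false("H1|H2" %in% pair_key(none$id_a, none$id_b))

  # LC boundary: a publication with 26 interactions is not small-scale
  big <- data.frame(id_a = sprintf("y%03d", 1:26), id_b = sprintf("z%03d", 1:26),
                    method = "affinity", pmid = "bigpub", year = 2010L,
                    species = "yeast", stringsAsFactors = FALSE)
  small <- data.frame(id_a = "y1", id_b = "y2", method = "affinity",
                      pmid = "smallpub", year = 2010L, species = "yeast",
                      stringsAsFactors = FALSE)
  orth2 <- data.frame(
    foreign_id = c(big$id_a, big$id_b, "y1", "y2"),
    focal_id = c(sprintf("A%03d", 1:26), sprintf("B%03d", 1:26), "HA", "HB"))
  lc26 <- interolog_indicator(rbind(big, small), "LC", orth2,
                              exclude_species = "human")
  expect_setequal(pair_key(lc26$id_a, lc26$id_b), "HA|HB")
  lc25 <- interolog_indicator(rbind(big[1:25, ], small), "LC", orth2,
                              exclude_species = "human")
  expect_identical(nrow(lc25), 26L)
})

test_that("pair score tables load with max-dedup and strict validation", {
  d <- withr::local_tempdir()
  p <- file.path(d, "scores.tsv")
  writeLines(c("id_a\tid_b\tscore", "a\tb\t0.2", "b\ta\t0.5", "c\td\t0.1"), p)
  tab <- load_pair_score_table(p, "cocitation")
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$score[tab$id_a == "a"], 0.5)

  writeLines("id_a\tid_b\tscore", p)
  expect_identical(nrow(load_pair_score_table(p, "fusion")), 0L)

  writeLines(c("id_a\tid_b\tscore", "a\tb\t0.2", "\tb\t0.3"), p)
  expect_error(load_pair_score_table(p, "fusion"), "line 3")
  writeLines(c("id_a\tid_b\tscore", "a\tb\t1.7"), p)
  expect_error(load_pair_score_table(p, "fusion"), "\\[0, 1\\]")

  set.seed(24)
  ids <- paste0("P", 1:30)
  raw <- data.frame(id_a = sample(ids, 100, TRUE),
                    id_b = sample(ids, 100, TRUE),
                    score = round(runif(100), 3))
  raw <- raw[raw$id_a != raw$id_b, ]
  utils::write.table(raw, p, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- load_pair_score_table(p, "neighborhood")
  expect_identical(nrow(tab), length(unique(pair_key(raw$id_a, raw$id_b))))
})

test_that("external features attach by sorted pair with explicit missingness", {
  cfg <- tiny_config(seed = 31L)
  w <- generate_world(cfg)
  mat <- simulate_elution(w, cfg)
  base <- build_pair_features(filter_proteins(mat))

  expect_identical(attach_external_features(base, character(0), list()), base)

  feats <- stats::setNames(
    lapply(genomic_feature_kinds, simulate_genomic_feature, world = w,
           config = cfg),
    genomic_feature_kinds)
  one <- attach_external_features(base, "domain", feats)
  expect_true(all(one$domain %in% c(0, 1, NA)))

  all9 <- attach_external_features(base, genomic_feature_kinds, feats)
  expect_identical(ncol(all9), 2L + 6L + 9L)
  # symmetric lookup: swapped ids find the same value
  swapped <- base
  tmp <- swapped$id_a; swapped$id_a <- swapped$id_b; swapped$id_b <- tmp
  all9s <- attach_external_features(swapped, genomic_feature_kinds, feats)
  expect_identical(all9s$cocitation, all9$cocitation)

  expect_error(attach_external_features(base, "nonsense", feats), "unknown")
  expect_error(attach_external_features(base, c("domain", "domain"), feats),
               "duplicate")
})
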