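# The evaluation battery: annotation filtering, neighbor voting against an
# all-pairs oracle, novelty and time-split accounting, study bias, network
# topology, and robustness.

test_that("annotation filtering enforces evidence codes and term frequency", {
  # a 200-protein path network
  prots <- sprintf("N%03d", 1:200)
  net <- edges_network(cbind(prots[-200], prots[-1]))

  ann <- rbind(
    data.frame(protein = prots[1:120], term = "broad", evidence = "EXP"),
    data.frame(protein = prots[1], term = "boundary_low", evidence = "IDA"),
    data.frame(protein = prots[1:10], term = "boundary_high", evidence = "EXP"),
    data.frame(protein = prots[1:11], term = "too_big", evidence = "EXP"),
    data.frame(protein = prots[5:8], term = "iea_only", evidence = "IEA"),
    data.frame(protein = c(prots[5:8], prots[5]), term = "iea_exp",
               evidence = c(rep("IEA", 4), "EXP")))
  kept <- filter_annotations(ann, net)
  expect_false("broad" %in% kept$term)          # 60% of proteins
  expect_true("boundary_low" %in% kept$term)    # 1/200 = 0.5%, inclusive
  expect_true("boundary_high" %in% kept$term)   # 10/200 = 5%, inclusive
  expect_false("too_big" %in% kept$term)        # 5.5%
  expect_false("iea_only" %in% kept$term)       # only excluded codes
  # a protein with IEA + EXP support survives, IEA-only co-annotations drop
  expect_identical(kept$protein[kept$term == "iea_exp"], prots[5])

  expect_warning(filter_annotations(ann[1:120, ], net), "no terms")
})

test_that("neighbor voting is perfect on clique-aligned terms and null otherwise", {
  # disjoint 4-cliques; one term annotates exactly one clique
  cliques <- lapply(0:3, function(b) sprintf("C%02d", b * 4 + 1:4))
  edges <- do.call(rbind, lapply(cliques, function(m) t(utils::combn(m, 2))))
  net <- edges_network(edges)
  ann <- data.frame(protein = cliques[[1]], term = "T1")
  nv <- neighbor_voting_auroc(net, ann, n_folds = 2L, seed = 3L)
  expect_equal(unname(nv$per_term["T1"]), 1)
  expect_equal(nv$median, 1)

  # labels independent of topology give AUROC near 0.5 on average
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      prots <- sprintf("R%02d", 1:24)
      e <- unique(t(replicate(60, sort(sample(prots, 2)))))
      rnet <- edges_network(e)
      rann <- data.frame(protein = sample(network_proteins(rnet), 8),
                         term = "T")
      neighbor_voting_auroc(rnet, rann, n_folds = 2L, seed = s)$median
    })
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
})

test_that("neighbor voting matches the brute-force oracle on small networks", {
  for (s in 1:5) {
    set.seed(s)
    prots <- sprintf("X%02d", 1:12)
    e <- unique(t(replicate(20, sort(sample(prots, 2)))))
    net <- edges_network(e)
    ann <- rbind(
      data.frame(protein = sample(prots, 6), term = "A"),
      data.frame(protein = sample(prots, 5), term = "B"))
    got <- neighbor_voting_auroc(net, ann, n_folds = 3L, seed = s + 10L)
    want <- neighbor_voting_oracle(net, ann, n_folds = 3L, seed = s + 10L)
    expect_equal(got$per_term, want$per_term, tolerance = 1e-12)
    expect_equal(got$median, want$median, tolerance = 1e-12)
  }
})

test_that("novelty fraction counts catalog membership exactly", {
  pairs <- cbind(paste0("n", 1:10), paste0("m", 1:10))
  net <- edges_network(pairs)
  cat_all <- data.frame(id_a = pairs[, 2], id_b = pairs[, 1], year = 2010L)
  expect_equal(novelty_fraction(net, cat_all), 0)
  cat_none <- data.frame(id_a = "q1", id_b = "q2", year = 2010L)
  expect_equal(novelty_fraction(net, cat_none), 1)
  cat4 <- cat_all[1:4, ]
  expect_equal(novelty_fraction(net, cat4), 0.6)
  # known + novel partition the edges exactly
  expect_equal((1 - novelty_fraction(net, cat4)) * 10 +
                 novelty_fraction(net, cat4) * 10, 10)
  # cutoff: records at or after the cutoff do not count as known
  expect_equal(novelty_fraction(net, cat_all, cutoff_year = 2010L), 1)
  empty <- edges_network(cbind(character(0), character(0)))
  expect_true(is.na(novelty_fraction(empty, cat_all)))
})

test_that("time-split validation excludes circular records and splits by year", {
  pairs <- cbind(paste0("n", 1:6), paste0("m", 1:6))
  net <- edges_network(pairs)
  catalog <- data.frame(
    id_a = c("n1", "n2", "n3", "n4", "n4"),
    id_b = c("m1", "m2", "m3", "m4", "m4"),
    pmid = c("old1", "new1", "circ1", "old2", "new2"),
    year = c(2010L, 2017L, 2017L, 2012L, 2018L))
  # novel = edges without pre-2017 records: n2, n3, n5, n6 (n1, n4 known)
  # validated among them: n2 (2017) and n3 (2017) -> 2/4; excluding the
  # circular pmid removes n3's only support -> 1/4
  expect_equal(timesplit_validation_rate(net, catalog, 2017L), 2 / 4)
  expect_equal(timesplit_validation_rate(net, catalog, 2017L,
                                         exclude_pmids = "circ1"), 1 / 4)
  # duplicating pre-cutoff evidence changes nothing (idempotent evidence)
  dup <- rbind(catalog, catalog[catalog$year < 2017L, ])
  expect_equal(timesplit_validation_rate(net, dup, 2017L),
               timesplit_validation_rate(net, catalog, 2017L))
  # no rediscovery after the cutoff
  pre_only <- catalog[catalog$year < 2017L, ]
  expect_equal(timesplit_validation_rate(net, pre_only, 2017L), 0)
  # nothing novel -> undefined
  allknown <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                         pmid = "p", year = 2000L)
  expect_true(is.na(timesplit_validation_rate(net, allknown, 2017L)))
})

test_that("study bias is the Spearman correlation of degree and publications", {
  star <- cbind(rep("hub", 4), paste0("leaf", 1:4))
  net <- edges_network(star)
  pubs <- data.frame(protein = c("hub", paste0("leaf", 1:4)),
                     publications = c(40L, rep(10L, 4)))
  # publications proportional to degree (4,1,1,1,1), ties and all
  expect_equal(degree_publication_bias(net, pubs), 1, tolerance = 1e-12)
  flat <- pubs; flat$publications <- 5L
  expect_true(is.na(suppressWarnings(degree_publication_bias(net, flat))))

  set.seed(61)
  prots <- sprintf("Y%02d", 1:10)
  e <- unique(t(replicate(18, sort(sample(prots, 2)))))
  rnet <- edges_network(e)
  rpubs <- data.frame(protein = network_proteins(rnet),
                      publications = rpois(length(network_proteins(rnet)), 9))
  deg <- table(factor(c(rnet$edges$id_a, rnet$edges$id_b),
                      levels = network_proteins(rnet)))
  oracle <- cor(rank(as.numeric(deg)), rank(rpubs$publications))
  expect_equal(degree_publication_bias(rnet, rpubs), oracle,
               tolerance = 1e-12)
  expect_warning(degree_publication_bias(rnet, rpubs[-1, ]), "treated as 0")
})

test_that("global clustering coefficient equals triangle/triple enumeration", {
  tri <- edges_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(global_clustering_coefficient(tri), 1)
  path <- edges_network(cbind(c("a", "b"), c("b", "c")))
  expect_equal(global_clustering_coefficient(path), 0)

  for (s in 1:5) {
    set.seed(s + 70)
    prots <- letters[1:8]
    e <- unique(t(replicate(12, sort(sample(prots, 2)))))
    net <- edges_network(e)
    keys <- pair_key(e[, 1], e[, 2])
    ids <- sort(unique(c(e[, 1], e[, 2])))
    triangles <- 0L; triples <- 0L
    for (trip in utils::combn(ids, 3, simplify = FALSE)) {
      k <- pair_key(trip[c(1, 1, 2)], trip[c(2, 3, 3)])
      m <- sum(k %in% keys)
      if (m == 3L) triangles <- triangles + 1L
      triples <- triples + choose(m, 2)  # paths centered at shared nodes
    }
    oracle <- if (triples > 0) 3 * triangles / triples else 0
    expect_equal(global_clustering_coefficient(net), oracle,
                 tolerance = 1e-12)
  }
})

test_that("Jaccard robustness is exact under identity and disjointness", {
  a <- edges_network(cbind(c("a", "b"), c("b", "c")))
  b <- edges_network(cbind(c("x", "y"), c("y", "z")))
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, b), 0)
  empty <- edges_network(cbind(character(0), character(0)))
  expect_true(is.na(jaccard_index(empty, empty)))

  # withholding nothing must reproduce the same network every repeat
  ft <- data.frame(id_a = paste0("p", 1:50), id_b = paste0("q", 1:50),
                   score = runif(50))
  build <- function(tab) {
    assemble_network_topN(tab, n = 20L)
  }
  rob <- robustness_jaccard(build, ft, withhold = 0, repeats = 5L, seed = 2L)
  expect_length(rob$jaccards, choose(5, 2))
  expect_true(all(rob$jaccards == 1))
  expect_equal(rob$median, 1)

  # withholding 20% perturbs the network measurably but stays in [0, 1]
  rob2 <- robustness_jaccard(build, ft, withhold = 0.2, repeats = 4L,
                             seed = 2L)
  expect_true(all(rob2$jaccards >= 0 & rob2$jaccards <= 1))
})

test_that("evaluation metrics respect their declared ranges on random inputs", {
  for (s in 1:5) {
    set.seed(s + 80)
    prots <- sprintf("Z%02d", 1:15)
    e <- unique(t(replicate(25, sort(sample(prots, 2)))))
    net <- edges_network(e)
    ann <- data.frame(protein = sample(prots, 7), term = "T", evidence = "EXP")
    cat_df <- data.frame(id_a = sample(prots, 8), id_b = sample(prots, 8),
                         pmid = paste0("p", 1:8),
                         year = sample(2000:2018, 8, TRUE))
    cat_df <- cat_df[cat_df$id_a != cat_df$id_b, ]
    pubs <- data.frame(protein = prots, publications = rpois(15, 5))
    nv <- neighbor_voting_auroc(net, ann[, 1:2], seed = s)
    if (!is.na(nv$median)) expect_true(nv$median >= 0 && nv$median <= 1)
    novf <- novelty_fraction(net, cat_df)
    expect_true(is.na(novf) || (novf >= 0 && novf <= 1))
    tsr <- timesplit_validation_rate(net, cat_df, 2017L)
    expect_true(is.na(tsr) || (tsr >= 0 && tsr <= 1))
    rho <- suppressWarnings(degree_publication_bias(net, pubs))
    expect_true(is.na(rho) || abs(rho) <= 1)
    cc <- global_clustering_coefficient(net)
    expect_true(cc >= 0 && cc <= 1)
  }
})
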