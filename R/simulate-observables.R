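#' Simulate one external genomic feature at the protein-pair level
#'
#' Co-complex pairs receive an elevated score with probability
#' `feature_informativeness[kind]`; other pairs draw from a background
#' distribution (binary kinds flip to 1 at `feature_fp_rate`). A pair's
#' value is observed at all with probability
#' `coverage * ((1 - bias) + bias * u_a * u_b)` where `u` is the protein's
#' study-intensity quantile — so when `coverage_bias > 0` the feature
#' covers well-studied proteins preferentially, as curated genomic
#' resources do. For kinds with positive `study_coupling`, the *values*
#' carry study bias too: the elevation probability of a co-complex pair and
#' the background false-positive signal are both weighted by
#' `(1 - c) + c * 16 * (u_a * u_b)^3` (mean-preserving, sharply
#' concentrated on the most-studied pairs), emulating curated evidence that
#' recapitulates the existing literature. Unobserved pairs
#' are simply absent from the table.
#'
#' @param world A `synthetic_world`.
#' @param kind One of [genomic_feature_kinds].
#' @param config The study's [world_config()].
#' @param seed Optional override of the derived stage seed.
#' @return data.frame `(id_a, id_b, score)`, keyed on the sorted pair.
#' @export
simulate_genomic_feature <- function(world, kind, config, seed = NULL) {
  if (!kind %in% genomic_feature_kinds) {
    stop(sprintf("unknown feature kind '%s'", kind))
  }
  seed <- seed %||% derive_seed(config$seed, paste0("feature_", kind))
  informativeness <- config$feature_informativeness[[kind]]
  coverage <- config$feature_coverage[[kind]]
  bias <- config$coverage_bias[[kind]]
  coupling <- config$study_coupling[[kind]]
  fp_rate <- config$feature_fp_rate[[kind]]
  binary <- kind %in% c("domain", "interolog_LC", "interolog_Y2H", "interolog_IP")
  signed <- kind %in% c("coexpression", "phylogenetic")
  with_seed(seed, {
    keys <- all_pair_keys(world$proteins)
    m <- length(keys)
    cocomplex <- keys %in% world$true_interactions
    u <- stats::setNames(
      (rank(world$study_intensity, ties.method = "first") - 0.5) /
        length(world$study_intensity),
      names(world$study_intensity))
    ends <- split_pair_key(keys)
    uu <- u[ends$id_a] * u[ends$id_b]          # mean 1/4 over random pairs
    study_w <- (1 - coupling) + coupling * 16 * uu^3
    elevated <- cocomplex & stats::runif(m) < pmin(1, informativeness * study_w)
    if (binary) {
      score <- as.numeric(stats::runif(m) <
                            pmin(1, fp_rate * study_w))
      score[elevated] <- 1
    } else if (signed) {
      score <- 2 * stats::rbeta(m, 6, 6) - 1   # tight null centered on 0
      score[elevated] <- stats::runif(sum(elevated), 0.7, 0.98)
    } else {
      # database-score null: low, with a high-score background tail for
      # well-studied pairs when the kind is study-coupled (famous protein
      # pairs get co-cited whether or not they interact)
      score <- stats::rbeta(m, 1, 9)
      bg_hit <- !elevated & stats::runif(m) <
        pmin(1, fp_rate * study_w)
      score[bg_hit] <- stats::rbeta(sum(bg_hit), 8, 1.5)
      score[elevated] <- stats::rbeta(sum(elevated), 8, 1.5)
    }
    p_obs <- coverage * ((1 - bias) + bias * u[ends$id_a] * u[ends$id_b])
    keep <- stats::runif(m) < p_obs
    data.frame(id_a = ends$id_a[keep], id_b = ends$id_b[keep],
               score = score[keep], stringsAsFactors = FALSE)
  })
}

#' Simulate a time-stamped interaction catalog
#'
#' Each true interaction is independently "discovered" in each calendar year
#' with probability `detection_rate * g^bias_strength` (capped at 1), where
#' `g` is the geometric mean of the pair's study intensities normalized to
#' geometric mean 1 across pairs — so `bias_strength > 0` makes well-studied
#' pairs enter the literature earlier and more often. Each discovery is one
#' record carrying a synthetic publication id, an evidence-method string and
#' a species tag; a configurable fraction of spurious records (non-true
#' pairs) is appended.
#'
#' @param world A `synthetic_world`.
#' @param config The study's [world_config()].
#' @param years Optional integer vector of years (default the config range).
#' @param detection_rate,bias_strength,fp_rate Optional overrides.
#' @param seed Optional override of the derived stage seed.
#' @return data.frame `(id_a, id_b, method, pmid, year, species)`; one row
#'   per discovery record.
#' @export
simulate_interaction_catalog <- function(world, config, years = NULL,
                                         detection_rate = NULL,
                                         bias_strength = NULL,
                                         fp_rate = NULL, seed = NULL) {
  years <- years %||% seq(config$catalog_years[1], config$catalog_years[2])
  detection_rate <- detection_rate %||% config$detection_rate
  bias_strength <- bias_strength %||% config$bias_strength
  fp_rate <- fp_rate %||% config$catalog_fp_rate
  seed <- seed %||% derive_seed(config$seed, paste0("catalog_", min(years)))
  methods <- c("affinity chromatography technology", "two hybrid",
               "anti bait coimmunoprecipitation", "x-ray crystallography")
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      method = character(0), pmid = character(0),
                      year = integer(0), species = character(0),
                      stringsAsFactors = FALSE)
  if (length(years) == 0L || length(world$true_interactions) == 0L) {
    return(empty)
  }
  with_seed(seed, {
    keys <- world$true_interactions
    ends <- split_pair_key(keys)
    g <- sqrt(world$study_intensity[ends$id_a] * world$study_intensity[ends$id_b])
    g <- g / exp(mean(log(g)))
    p <- pmin(1, detection_rate * g^bias_strength)
    hits <- outer(p, rep(1, length(years))) >=
      matrix(stats::runif(length(keys) * length(years)), nrow = length(keys))
    idx <- which(hits, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(empty)
    rec <- data.frame(
      id_a = ends$id_a[idx[, 1]],
      id_b = ends$id_b[idx[, 1]],
      method = sample(methods, nrow(idx), replace = TRUE,
                      prob = c(0.45, 0.25, 0.2, 0.1)),
      pmid = sprintf("PM%07d", seq_len(nrow(idx))),
      year = years[idx[, 2]],
      species = config$species,
      stringsAsFactors = FALSE
    )
    n_fp <- round(fp_rate * nrow(rec))
    if (n_fp > 0L) {
      non_true <- setdiff(all_pair_keys(world$proteins), keys)
      n_fp <- min(n_fp, length(non_true))
      fp_keys <- sample(non_true, n_fp)
      fe <- split_pair_key(fp_keys)
      rec <- rbind(rec, data.frame(
        id_a = fe$id_a, id_b = fe$id_b,
        method = sample(methods, n_fp, replace = TRUE),
        pmid = sprintf("PMFP%05d", seq_len(n_fp)),
        year = sample(years, n_fp, replace = TRUE),
        species = config$species, stringsAsFactors = FALSE))
    }
    rownames(rec) <- NULL
    rec[order(rec$year, rec$id_a, rec$id_b), , drop = FALSE]
  })
}

#' Simulate a functional annotation table
#'
#' With probability `coherence` a term annotates exactly one complex's
#' membership (so network assortativity with terms is non-trivial);
#' otherwise it annotates a random protein set. Each (protein, term) row
#' carries an evidence code, mostly experimental.
#'
#' @param world A `synthetic_world`.
#' @param n_terms Number of terms.
#' @param size_range `(min, max)` size of incoherent terms' annotation sets.
#' @param coherence Probability a term copies one complex's membership.
#' @param seed RNG seed.
#' @return data.frame `(protein, term, evidence)`.
#' @export
simulate_annotations <- function(world, n_terms, size_range = c(3L, 6L),
                                 coherence = 0.9, seed = 1L) {
  if (size_range[1] < 1L || size_range[2] > length(world$proteins)) {
    stop("size_range must lie within [1, n_proteins]")
  }
  codes <- c("EXP", "IDA", "IMP", "HDA", "IEA", "NAS")
  wts <- c(0.3, 0.25, 0.15, 0.1, 0.15, 0.05)
  if (n_terms == 0L) {
    return(data.frame(protein = character(0), term = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(i) {
      use_complex <- length(world$complexes) > 0L && stats::runif(1) < coherence
      members <- if (use_complex) {
        world$complexes[[(i - 1L) %% length(world$complexes) + 1L]]
      } else {
        sample(world$proteins, sample(seq(size_range[1], size_range[2]), 1))
      }
      data.frame(protein = members, term = sprintf("T%04d", i),
                 evidence = sample(codes, length(members), replace = TRUE,
                                   prob = wts),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-protein publication counts
#'
#' Poisson counts with mean proportional to the latent study intensity, so
#' the synthetic literature is biased toward "well-studied" proteins.
#'
#' @param world A `synthetic_world`.
#' @param mean_publications Mean count across proteins.
#' @param seed RNG seed.
#' @return data.frame `(protein, publications)`.
#' @export
simulate_publication_counts <- function(world, mean_publications = 20,
                                        seed = 1L) {
  with_seed(seed, {
    lam <- mean_publications * world$study_intensity /
      mean(world$study_intensity)
    data.frame(protein = world$proteins,
               publications = stats::rpois(length(lam), lam),
               stringsAsFactors = FALSE)
  })
}
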