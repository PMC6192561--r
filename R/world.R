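#' The nine external genomic feature kinds
#'
#' Continuous kinds score protein pairs in `[-1, 1]` (correlation-like) or
#' `[0, 1]` (database scores); `domain` and the three interolog kinds are
#' binary indicators.
#' @export
genomic_feature_kinds <- c(
  "coexpression", "phylogenetic", "domain", "cocitation", "fusion",
  "neighborhood", "interolog_LC", "interolog_Y2H", "interolog_IP"
)

#' Configuration for a synthetic co-elution study
#'
#' Bundles every knob of the synthetic world: how many proteins assemble into
#' how many complexes, the chromatographic geometry (fractions, peak widths,
#' noise, missingness), how informative and how coverage-biased each external
#' genomic feature is, and how the time-stamped interaction catalog accrues
#' discoveries as a function of how intensely each protein is studied.
#'
#' @param n_proteins Number of proteins in the world.
#' @param n_complexes Number of protein complexes.
#' @param complex_size_range Integer `(min, max)` complex sizes; min >= 2.
#' @param n_fractions Number of chromatographic fractions (>= 5).
#' @param peak_width_range `(min, max)` Gaussian peak sd, in fractions.
#' @param peak_jitter_sd Sd of the per-protein offset from its complex's
#'   elution peak, in fractions; small relative to peak width.
#' @param noise_sd Sd of additive measurement noise (profiles peak at 1).
#' @param missing_rate Probability that any single measurement is missing.
#' @param monomer_rate Probability that a complexed protein carries an extra
#'   monomeric peak (off by default so single-peak deconvolution is exact).
#' @param overlap Logical; allow complexes to share members (default
#'   disjoint, which keeps true-interaction counts exactly enumerable).
#' @param intensity_sdlog Sd (log scale) of the log-normal per-protein study
#'   intensity; heavy-tailed like real publication counts.
#' @param feature_informativeness Per-kind probability in `[0, 1]` that a
#'   co-complex pair receives an elevated feature score (scalar recycled).
#'   Defaults mirror each evidence type's sensitivity in practice: broad for
#'   coexpression and co-citation, sparse for binary indicators (domain,
#'   interologs) and rare genomic events (fusion, neighborhood) — sparse
#'   binary evidence matters because the likelihood ratio of an *absent*
#'   indicator is only as mild as the evidence is rare among true pairs.
#' @param feature_coverage Per-kind base probability that a pair's feature
#'   value is observed at all.
#' @param coverage_bias Per-kind strength in `[0, 1]` coupling observation to
#'   the two proteins' study intensities (0 = coverage independent of bias).
#'   Defaults are high for literature- and curation-derived kinds (domain,
#'   co-citation, interologs) and mild for genome-derived kinds.
#' @param study_coupling Per-kind strength in `[0, 1]` coupling the feature's
#'   *values* to study intensity: for coupled kinds, co-complex pairs of
#'   well-studied proteins are more likely to carry the elevated signal, and
#'   background false positives concentrate on well-studied pairs — the way
#'   curated evidence recapitulates the existing literature. Genome-derived
#'   kinds (coexpression, phylogenetic profiles, fusion, neighborhood)
#'   default to 0.
#' @param feature_fp_rate Per-kind background rate at which non-co-complex
#'   pairs carry an elevated signal anyway. Defaults reflect each evidence
#'   type's promiscuity: high for literature co-citation (famous proteins
#'   are co-cited regardless of interaction) and domain-domain templates
#'   (common domains match promiscuously), low for rare genomic events.
#' @param catalog_years `(first, last)` calendar years of catalog accrual.
#' @param detection_rate Per-true-pair, per-year baseline discovery
#'   probability.
#' @param bias_strength Exponent coupling discovery probability to the
#'   geometric mean of the pair's study intensities (0 = unbiased).
#' @param catalog_fp_rate Fraction of catalog records that are spurious
#'   (non-true pairs); real interaction databases are noisy.
#' @param species Taxon label stamped on synthetic catalog records.
#' @param n_terms Number of synthetic functional annotation terms.
#' @param term_size_range `(min, max)` annotated-set size for incoherent
#'   terms.
#' @param annotation_coherence Probability that a term annotates exactly one
#'   complex's membership rather than a random protein set.
#' @param mean_publications Mean publication count across proteins.
#' @param seed Master seed; every downstream stage derives its own sub-seed.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_proteins = 300L,
                         n_complexes = 40L,
                         complex_size_range = c(3L, 6L),
                         n_fractions = 50L,
                         peak_width_range = c(2, 4),
                         peak_jitter_sd = 0.5,
                         noise_sd = 0.28,
                         missing_rate = 0.4,
                         monomer_rate = 0,
                         overlap = FALSE,
                         intensity_sdlog = 1,
                         feature_informativeness = c(
                           coexpression = 0.04, phylogenetic = 0.03,
                           domain = 0.2, cocitation = 0.25, fusion = 0.02,
                           neighborhood = 0.03, interolog_LC = 0.15,
                           interolog_Y2H = 0.15, interolog_IP = 0.15),
                         feature_coverage = 0.6,
                         coverage_bias = c(
                           coexpression = 0.6, phylogenetic = 0.6,
                           domain = 0.4, cocitation = 0.4, fusion = 0.4,
                           neighborhood = 0.4, interolog_LC = 0.4,
                           interolog_Y2H = 0.4, interolog_IP = 0.4),
                         study_coupling = c(
                           coexpression = 0, phylogenetic = 0,
                           domain = 1, cocitation = 1, fusion = 0,
                           neighborhood = 0, interolog_LC = 1,
                           interolog_Y2H = 1, interolog_IP = 1),
                         feature_fp_rate = c(
                           coexpression = 0.02, phylogenetic = 0.02,
                           domain = 0.04, cocitation = 0.15, fusion = 0.003,
                           neighborhood = 0.008, interolog_LC = 0.02,
                           interolog_Y2H = 0.02, interolog_IP = 0.02),
                         catalog_years = c(2000L, 2018L),
                         detection_rate = 0.08,
                         bias_strength = 2,
                         catalog_fp_rate = 0.05,
                         species = "synthetic_sapiens",
                         n_terms = n_complexes,
                         term_size_range = complex_size_range,
                         annotation_coherence = 0.9,
                         mean_publications = 20,
                         seed = 1L) {
  per_kind <- function(x, name) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(genomic_feature_kinds)),
                                              genomic_feature_kinds)
    if (is.null(names(x)) && length(x) == length(genomic_feature_kinds)) {
      names(x) <- genomic_feature_kinds
    }
    if (!all(genomic_feature_kinds %in% names(x))) {
      stop(sprintf("'%s' must name all feature kinds", name))
    }
    x[genomic_feature_kinds]
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    n_fractions = as.integer(n_fractions),
    peak_width_range = as.numeric(peak_width_range),
    peak_jitter_sd = peak_jitter_sd,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    monomer_rate = monomer_rate,
    overlap = isTRUE(overlap),
    intensity_sdlog = intensity_sdlog,
    feature_informativeness = per_kind(feature_informativeness,
                                       "feature_informativeness"),
    feature_coverage = per_kind(feature_coverage, "feature_coverage"),
    coverage_bias = per_kind(coverage_bias, "coverage_bias"),
    study_coupling = per_kind(study_coupling, "study_coupling"),
    feature_fp_rate = per_kind(feature_fp_rate, "feature_fp_rate"),
    catalog_years = as.integer(catalog_years),
    detection_rate = detection_rate,
    bias_strength = bias_strength,
    catalog_fp_rate = catalog_fp_rate,
    species = species,
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    annotation_coherence = annotation_coherence,
    mean_publications = mean_publications,
    seed = as.integer(seed)
  )
  probs <- c(cfg$missing_rate, cfg$monomer_rate, cfg$feature_informativeness,
             cfg$feature_coverage, cfg$coverage_bias, cfg$study_coupling,
             cfg$feature_fp_rate, cfg$catalog_fp_rate, cfg$annotation_coherence)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$complex_size_range[1] < 2L) stop("complex sizes must be >= 2")
  if (cfg$n_fractions < 5L) stop("n_fractions must be >= 5")
  if (cfg$n_complexes > 0L && diff(cfg$complex_size_range) < 0) {
    stop("complex_size_range must be non-decreasing")
  }
  class(cfg) <- "world_config"
  cfg
}

#' Generate the ground-truth world of a synthetic study
#'
#' Draws complex memberships (disjoint by default), the latent per-protein
#' study intensity (log-normal, heavy-tailed), and one elution peak position
#' per complex. The true interaction set is exactly the set of intra-complex
#' pairs.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list with elements `proteins`, `complexes`
#'   (named list of member vectors), `true_interactions` (character pair
#'   keys), `study_intensity` (named numeric) and `peak_positions`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (!config$overlap &&
      config$n_complexes * config$complex_size_range[2] > config$n_proteins) {
    stop("infeasible config: disjoint complexes cannot fit in n_proteins")
  }
  with_seed(derive_seed(config$seed, "world"), {
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))
    size_choices <- seq(config$complex_size_range[1],
                        config$complex_size_range[2])
    sizes <- if (config$n_complexes > 0L) {
      # sample() treats a length-1 vector as 1:n, so guard degenerate ranges
      if (length(size_choices) == 1L) {
        rep(size_choices, config$n_complexes)
      } else {
        sample(size_choices, config$n_complexes, replace = TRUE)
      }
    } else {
      integer(0)
    }
    complexes <- list()
    pool <- proteins
    for (i in seq_along(sizes)) {
      members <- if (config$overlap) {
        sample(proteins, sizes[i])
      } else {
        picked <- sample(pool, sizes[i])
        pool <- setdiff(pool, picked)
        picked
      }
      complexes[[sprintf("CPX%03d", i)]] <- sort(members)
    }
    true_int <- unique(unlist(lapply(complexes, all_pair_keys), use.names = FALSE))
    world <- list(
      proteins = proteins,
      complexes = complexes,
      true_interactions = sort(true_int %||% character(0)),
      study_intensity = stats::setNames(
        stats::rlnorm(config$n_proteins, 0, config$intensity_sdlog), proteins),
      peak_positions = stats::setNames(
        stats::runif(length(complexes), 5, config$n_fractions - 4),
        names(complexes))
    )
    class(world) <- "synthetic_world"
    world
  })
}

#' Which complex (if any) does each protein belong to?
#' @param world A `synthetic_world`.
#' @return Named character vector, `NA` for monomeric proteins. Under
#'   overlapping complexes the first containing complex is reported.
#' @export
protein_complex_map <- function(world) {
  m <- stats::setNames(rep(NA_character_, length(world$proteins)), world$proteins)
  for (cid in rev(names(world$complexes))) m[world$complexes[[cid]]] <- cid
  m
}

#' Simulate a co-elution chromatogram matrix
#'
#' Each complexed protein elutes as a Gaussian peak of unit amplitude
#' centered near its complex's peak position (per-protein jitter much
#' smaller than the peak width); monomeric proteins elute at their own
#' random positions. Additive Gaussian measurement noise and independent
#' missingness complete the observable.
#'
#' @param world A `synthetic_world`.
#' @param config The [world_config()] the world was generated from.
#' @param seed Optional override of the derived stage seed.
#' @return Numeric matrix proteins x fractions with `NA` for missing values;
#'   columns named `fraction_1..F`.
#' @export
simulate_elution <- function(world, config, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  seed <- seed %||% derive_seed(config$seed, "elution")
  with_seed(seed, {
    ff <- seq_len(config$n_fractions)
    cmap <- protein_complex_map(world)
    widths <- stats::setNames(
      stats::runif(length(world$complexes), config$peak_width_range[1],
                   config$peak_width_range[2]),
      names(world$complexes))
    n <- length(world$proteins)
    mat <- matrix(0, n, config$n_fractions,
                  dimnames = list(world$proteins, paste0("fraction_", ff)))
    for (i in seq_len(n)) {
      cid <- cmap[[i]]
      if (!is.na(cid)) {
        center <- world$peak_positions[[cid]] +
          stats::rnorm(1, 0, config$peak_jitter_sd)
        width <- widths[[cid]]
      } else {
        center <- stats::runif(1, 1, config$n_fractions)
        width <- stats::runif(1, config$peak_width_range[1],
                              config$peak_width_range[2])
      }
      y <- exp(-(ff - center)^2 / (2 * width^2))
      if (!is.na(cid) && config$monomer_rate > 0 &&
          stats::runif(1) < config$monomer_rate) {
        mcent <- stats::runif(1, 1, config$n_fractions)
        y <- y + 0.5 * exp(-(ff - mcent)^2 / (2 * width^2))
      }
      mat[i, ] <- y
    }
    if (config$noise_sd > 0) {
      mat <- mat + matrix(stats::rnorm(length(mat), 0, config$noise_sd),
                          nrow = n)
    }
    if (config$missing_rate > 0) {
      mat[matrix(stats::runif(length(mat)) < config$missing_rate, nrow = n)] <- NA
    }
    mat
  })
}
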