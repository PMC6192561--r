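---
title: "Methods: co-elution interactome prediction and the cost of genomic data integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-elution interactome prediction and the cost of genomic data integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coelnet)
```

## The question

Protein correlation profiling (co-elution / co-fractionation) infers
co-complex membership from correlated protein abundance across
chromatographic fractions: subunits of a complex co-migrate, so their
chromatograms share a peak. Machine-learning pipelines turn these
chromatograms into ranked protein-pair predictions, and it is common to
supplement the chromatogram-derived features with external genomic
evidence — mRNA coexpression, phylogenetic profiles, domain–domain
interaction templates, literature co-citation, gene fusion and gene
neighborhood scores, and interologs (interactions transferred from other
species). Integration reliably raises conventional accuracy measures. The
question this package operationalizes is what that gain costs: whether
integrated networks are less novel, more biased toward well-studied
proteins, less complex-like in topology, and less robust to incompleteness
of the external resources.

`coelnet` implements the full pipeline (feature extraction, naive Bayes
co-complex classification, network assembly) together with a five-part
evaluation battery, and a synthetic-data generator that emulates the
statistical structure of such studies so that every claim is testable
end-to-end on a laptop, without downloading any proteomic or genomic
resource.

## Dataset-derived features

For every pair of proteins co-quantified in at least 3 fractions,
`build_pair_features()` computes six features:

* **Euclidean distance** between cleaned profiles.
* **Pearson correlation** of the raw profiles over jointly observed
  fractions, and its **two-sided P-value** from the t transform
  `t = r sqrt((n-2)/(1-r^2))`.
* **Pearson correlation of cleaned profiles.** Cleaning imputes isolated
  single missing values with the mean of the two flanking fractions and
  replaces remaining missing values with near-zero Gaussian noise. The
  noise sd is 5% of the profile's maximum observed value — a scale-free
  choice that keeps the imputed values near zero relative to signal. Raw
  and cleaned correlations are computed on different supports (co-observed
  fractions vs the full cleaned vectors); this is the only reading under
  which the two correlation features differ meaningfully.
* **Co-apex distance**: distance in fractions between the two profiles'
  maxima, ties broken by the earliest maximal fraction (deterministic and
  order-independent).
* **Gaussian component distance**: each cleaned profile is deconvolved
  into a mixture of 1–5 Gaussians, and the feature is the minimum
  Euclidean distance between any component of one profile and any
  component of the other, with components vectorized as `(mu, sigma, A)`
  triples. Peak centers dominate this distance in practice; the
  vectorization is a declared choice, since "distance between Gaussians"
  admits several readings.

Deconvolution is bounded Levenberg–Marquardt least squares
(`minpack.lm`), with deterministic initialization: the first component at
the global apex, each further component at the largest absolute residual
of the previous fit. Bounds are `mu` in `[-1, F+2]`, `sigma` in
`[0.5, F]`, `A` in `[0, 2 max]`. Mixture size is selected by corrected
AIC; because the mixtures are nested, the search stops after two
consecutive AICc increases. On noiseless planted profiles the fitter
recovers single-component `(mu, sigma)` within 0.05 fraction units and
two-component centers within 0.2 (tested).

## External genomic features

Nine pair-level features are supported. Coexpression and phylogenetic
profile similarity are Pearson correlations computed from their raw
matrices (expression across samples; binarized presence/absence across
species). The domain feature is an indicator of a known domain–domain
interaction between any domain pair of the two proteins. Co-citation,
fusion and neighborhood are consumed as prepared `[0, 1]` score tables
(duplicate pairs resolved by maximum — evidence-union semantics).
Interologs are derived from a cross-species catalog: `Y2H` and `IP`
records are matched by case-insensitive substrings of the evidence-method
string ("two hybrid", "coimmunoprecipitation"), `LC` (literature-curated
small-scale) records are those whose supporting publication reports at
most 25 interactions *within the assembled catalog itself* — the counting
universe is deliberately self-contained so the rule is reproducible.
Records from the species of interest are always excluded to avoid
circularity with the training labels.

Missing external values are carried as an explicit mask, never imputed:
absence from a curated resource is lack of evidence, not evidence of
absence. The classifier gives missing values a unit likelihood ratio.

## Classifier and networks

Pairs are labeled from a reference complex set: intra-complex pairs are
positives, pairs of complex-member proteins never seen together are
negatives, everything else is unlabeled. The classifier is naive Bayes
with kernel-density class-conditional likelihoods (Silverman bandwidth)
for continuous features and Laplace-smoothed Bernoulli likelihoods for
binary ones; class priors come from training frequencies. Scoring runs in
stratified 10-fold cross-validation. Unlabeled pairs receive the median of
their ten fold scores; labeled pairs receive the score of the one model
whose training set excluded them. Scoring labeled pairs by the median over
all folds would let nine of the ten models see the pair's own label, so
the out-of-fold score is the default (a `labeled_in_fold` flag implements
the literal median-of-folds reading).

Scores are combined and ranked on the log-odds scale: the logistic map is
monotone, so the median commutes with it, and posteriors saturate at 1.0
in double precision for thousands of confident pairs, which would reduce
top-N selection to an arbitrary tie-break. The reported `score` column is
still the posterior probability.

Networks are assembled two ways: the top-N pairs by score (N fixed across
combinations, controlling for interactome size; boundary ties break
lexicographically), or all pairs above the smallest score threshold at
which labeled-pair precision reaches a target (defaults: 50% precision,
rejecting networks under 2,000 edges; the synthetic study uses smaller
floors commensurate with its scale).

## Evaluation battery

* **Functional connectivity** — neighbor voting: annotations are split
  into three folds; each protein is scored for a term by the fraction of
  its network neighbors annotated with that term in the training split,
  and the AUROC of recovering hidden annotations (vs never-annotated
  proteins, mid-rank ties) is averaged over folds; the network summary is
  the median over terms. Terms are pre-filtered to those annotating
  0.5%–5% of the network's proteins (bounds inclusive), and annotations
  supported only by the ND/IPI/IEA/NAS evidence codes are dropped. The
  plain fraction-of-neighbors vote is used, without a node-degree null
  correction; that is the default here because it matches the metric's
  plain description, and the brute-force oracle tests pin exactly this
  definition.
* **Novelty fraction** — the proportion of network edges absent from the
  interaction catalog (records before the cutoff year).
* **Time-split validation rate** — among edges with no catalog record
  before the cutoff year, the fraction rediscovered at or after it; a
  record's discovery date is its earliest year, and records supported only
  by excluded publication ids are removed first to eliminate circularity.
* **Study bias** — Spearman correlation between each network protein's
  degree and its publication count.
* **Clustering coefficient** — global transitivity, `3 x triangles /
  connected triples` (via igraph, verified against brute-force
  enumeration).
* **Robustness** — withhold a random 20% of one feature's underlying
  entries, rebuild the network, repeat five times, and report all pairwise
  Jaccard indices between the rebuilt networks. The withholding unit is a
  row of the feature's pair table; for matrix-derived features the
  protein-level inputs could be withheld instead, but row-level
  withholding applies uniformly to all nine kinds.

Undefined metrics (empty networks, no novel edges, zero-variance
publication counts) propagate as missing values, never as zeros.

The trend statistics over a combination sweep are Spearman's rho with the
t-approximation P-value, the two-sided Brunner–Munzel test (rank-based,
Satterthwaite-style degrees of freedom) for single-feature-vs-baseline
comparisons, Fisher's method for aggregating P-values, the two-proportion
z test without continuity correction (the variant is a declared choice),
and Bonferroni adjustment.

## The synthetic world

The generator is the package's testbed, not a model of any particular
experiment. A world is `n_proteins` (default 300) partitioned partly into
`n_complexes` (40) disjoint complexes of 3–6 members; disjointness keeps
the true-interaction count exactly enumerable for tests. Each protein
carries a latent log-normal (sd(log) = 1) *study intensity* — how much the
literature cares about it — which is the single hidden variable coupling
every biased observable.

* **Chromatograms**: each complex elutes as a Gaussian peak (width 2–4
  fractions) over 50 fractions; members share the peak up to small jitter
  (sd 0.3 fractions); monomeric proteins elute at random positions.
  Measurement noise (sd 0.28 relative to unit peaks) and 40% missingness
  make profile evidence realistically equivocal: the baseline classifier
  recovers only a minority of true pairs, as real pipelines do.
* **External features**: a co-complex pair receives an elevated score with
  a per-kind probability (informativeness); other pairs draw from a
  background. Observation (coverage) is biased toward well-studied pairs.
  For the literature- and curation-derived kinds (domain, co-citation,
  interologs) the *values* are study-coupled too: elevation and background
  false positives are weighted by a mean-preserving, sharply concentrated
  function of the pair's study-intensity quantiles (`16 (u_a u_b)^3`), so
  famous pairs carry most of the signal — and most of the spurious signal.
  Per-kind defaults encode each evidence type's character: co-citation is
  broad and promiscuous (famous proteins are co-cited whether or not they
  interact); binary indicators are sparse, which matters because the
  likelihood ratio of an *absent* indicator is only as mild as the
  evidence is rare among true pairs; fusion and neighborhood are very rare
  genomic events; coexpression and phylogenetic profiles are unbiased in
  value but only mildly informative at the pair level.
* **Catalog**: each true interaction is discovered per year with
  probability `detection_rate x g^2` (g = normalized geometric mean of the
  pair's study intensities), so the known interactome is strongly biased
  toward famous pairs; 5% of records are spurious. The validation window
  (2017–2018) is generated with the bias exponent set to 0 in the study
  driver: prospective discovery is independent of study intensity, so a
  rising validation rate cannot be manufactured by coverage alone. The
  window's detection rate is high (0.3–0.4/year) because the withheld
  recent window of a real catalog holds a large share of all records, and
  the metric needs non-degenerate counts at this scale.
* **Annotations** copy one complex's membership per term with probability
  0.9 (otherwise a random set), so neighbor voting is non-trivial;
  publication counts are Poisson with mean proportional to study
  intensity.

What the generator does *not* emulate: instrument-level artifacts (ratio
compression, carryover), overlapping complexes (available behind a flag,
off by default), correlated missingness, or any particular real dataset.
Passing the synthetic study therefore shows that the pipeline and metrics
behave as designed under the stated statistical structure — not that any
particular real interactome shows effects of a given size.

## The synthetic study and its scale

The headline experiment (`run_synthetic_study()`) uses 5 master seeds,
each generating 5 datasets of 300 proteins x 50 fractions, a combination
plan capped at 4 random combinations per size (0–9 features), top-800
networks (of ~45,000 candidate pairs; the boundary then sits in the
uncertain-evidence region where external features can move membership),
and 10-fold cross-validation. These sizes keep a full replicate around a
minute on one core. Under these conditions functional connectivity rises
with the number of integrated features, the novelty fraction falls, bias
toward well-studied proteins rises, the clustering coefficient falls, and
the time-split validation rate — computed against the unbiased validation
window — shows no significant positive trend: integration recovers more of
what is already known, not more of what is about to be discovered.

## Numerical choices and degenerate inputs

Seeds: one master seed derives per-stage seeds through a documented
string-hash (`derive_seed()`), so stages are independently reproducible;
profile-cleaning noise is seeded per protein identifier, making pair
tables invariant to row order. KDE likelihoods are floored at 1e-12 before
taking logs. Degenerate features (constant in training) are dropped with a
warning; a fold whose feature degenerates simply contributes a unit
likelihood ratio. Empty annotation sets, empty networks and zero-variance
metrics yield `NA`. All pair tables are keyed on the lexicographically
sorted pair, so every operation is symmetric in the pair's order.

## Known limitations

The naive Bayes independence assumption is clearly violated by the six
co-elution features (all derived from the same profiles); this mirrors the
pipeline being modeled rather than a statistical recommendation. The
neighbor-voting score omits degree-null correction, so very high-degree
proteins can inflate per-term AUROCs in dense networks. The robustness
procedure withholds table rows, which for matrix-derived features is an
approximation to withholding underlying annotations. And all quantitative
effect sizes in the synthetic study are properties of the generator's
declared parameters, not estimates of any real study's effect sizes.
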