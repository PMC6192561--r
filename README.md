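# coelnet

Protein interaction networks from co-elution data, and what external
genomic evidence does to them.

Protein correlation profiling (co-elution / co-fractionation) separates a
cell lysate across chromatographic fractions and quantifies thousands of
proteins in each; subunits of a complex co-migrate, so correlated
chromatograms are evidence of co-complex membership. `coelnet` implements
the standard machine-learning pipeline over such data — six
chromatogram-derived features per protein pair (Euclidean distance,
raw-profile Pearson r and its P-value, cleaned-profile Pearson r, co-apex
distance, and the minimum distance between fitted Gaussian mixture
components), a naive Bayes co-complex classifier trained on reference
complexes in 10-fold cross-validation, and top-N or precision-controlled
network assembly — together with nine external genomic features
(coexpression, phylogenetic profiles, domain–domain interactions,
co-citation, gene fusion, gene neighborhood, and three interolog classes)
that can be attached in any combination.

The package's point is evaluative. Genomic data integration reliably
raises conventional accuracy measures, and `coelnet` quantifies what that
costs, with five outcomes computed for any predicted network:

* **functional connectivity** — median neighbor-voting AUROC over
  annotation terms (guilt by association, 3-fold cross-validation);
* **novelty fraction** — proportion of edges absent from a time-stamped
  interaction catalog;
* **time-split validation rate** — proportion of putatively novel edges
  rediscovered at or after a cutoff year;
* **study bias** — Spearman correlation between protein degree and
  publication count;
* **clustering coefficient** — global transitivity (complex-likeness),
  plus **robustness** — Jaccard similarity of networks rebuilt after
  randomly withholding 20% of a feature's entries.

A synthetic-data generator produces complete studies — ground-truth
complexes, chromatograms, all nine feature tables, a year-stamped
interaction catalog with configurable discovery bias toward well-studied
proteins, annotations and publication counts — so the entire pipeline and
its conclusions are testable offline. See the methods vignette
(`vignettes/methods.Rmd`) for the models, parameter choices, and
limitations.

## Worked example

The numbered scripts under `analysis/` run a complete study. Step 1
simulates a 300-protein world (40 complexes, 50 fractions) and writes
every observable as CSV/TSV; steps 2–3 predict and evaluate a baseline
network (co-elution features only) and an integrated network (all nine
external features):

```
$ Rscript analysis/01_simulate.R
World: 300 proteins, 40 complexes, 322 true interactions.
Elution matrix: 300 proteins retained after filtering; 44850 co-quantified pairs.
Catalog: 1275 records (272 pre-2017 pairs known); 171 annotation rows.

$ Rscript analysis/02_predict.R
Labeled pairs: 322 positive, 15078 negative, 29450 unlabeled.

$ Rscript analysis/03_evaluate.R
            network functional_connectivity novelty_fraction validation_rate
1   baseline_top800                   0.496            0.951          0.0158
2 integrated_top800                   0.796            0.922          0.0217
  bias_rho clustering_coefficient n_edges n_proteins
1   0.0183                  0.441     800        266
2   0.1648                  0.369     800        267
```

Read: integrating all nine external features raises the network's
biological coherence (median neighbor-voting AUROC 0.50 → 0.80) but makes
it less novel (novelty 0.95 → 0.92: more of its edges were already in the
catalog), more biased toward well-studied proteins (degree–publication
Spearman ρ 0.02 → 0.16), and less clique-like (clustering coefficient
0.44 → 0.37). Step 4 runs the full combination sweep (5 datasets ×
combinations of 0–9 features) and writes per-metric Spearman trends under
`results/sweep/`; step 5 measures per-feature robustness to 20%
withholding.

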