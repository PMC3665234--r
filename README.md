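# ctnpharm

Network-pharmacology inference of compound–target associations for
multi-constituent herbal prescriptions.

Multi-herb preparations act through many constituents — and through their
in-vivo metabolites — hitting many protein targets at once. `ctnpharm`
implements the full desk-side inference chain for such a preparation,
using the Yuanhu Zhitong prescription (*Rhizoma corydalis* alkaloids plus
*Radix angelicae dahuricae* coumarins; 15 absorbed prototype constituents
and 6 metabolites) as its packaged worked example:

1. **Metabolite prediction at the formula level.** Biotransformation
   rules are signed element deltas (demethylation −CH₂, the composite
   −CH₂+H₂, methylene-to-ketone +O−H₂) applied to parent molecular
   formulas. Candidates are matched to observed LC-MS features by
   protonated-ion m/z, where *m/z*([M+H]⁺) = monoisotopic mass + 1.0072765
   Da (the proton, not the hydrogen atom), within a ppm tolerance
   (default 10 ppm).
2. **Similarity-based target inference.** Constituents are screened
   against an ATC- and target-annotated drug library by Tanimoto
   similarity *T* = |A∩B| / |A∪B| on binary fingerprints; the targets of
   high-similarity drugs become candidate targets, with provenance.
3. **ATC semantic similarity.** Lin-style information-content similarity
   of ATC codes, S(a,b) = 2·ln p(prefix(a,b)) / (ln p(a) + ln p(b)) with
   prefix frequencies estimated from the library, and target therapeutic
   similarity (TST) between targets' ATC code sets (Jaccard, or maximum
   pairwise code similarity).
4. **Compound–target network.** A strictly bipartite graph with degree
   summaries, average-linkage fingerprint clustering of compounds, and
   Cytoscape-compatible SIF/GraphML export.
5. **Enrichment.** Two-sided hypergeometric enrichment/depletion tests of
   the candidate target set against GMT annotation sets, with BH
   correction.
6. **Docking triage.** Threshold filtering (score ≤ −5.0) and
   per-compound summaries of a docking-score table.

A seeded synthetic-data generator (`synth_config()`, `gen_library()`,
`gen_queries()`, …) produces every input with known ground truth, so
recovery of planted neighbors, targets, clusters and enrichment signals
is benchmarked in the test suite.

## Worked example

```r
library(ctnpharm)

cons    <- yzp_constituents()                    # 21 constituents
parents <- cons[cons$kind == "prototype", c("id", "formula")]
cand    <- enumerate_candidates(parents, default_rules())
asg     <- match_features(cand, yzp_features(), tol_ppm = 10)
asg[asg$feature_id == "M6", c("formula", "theoretical_mh", "mz", "ppm_error")]
#>     formula theoretical_mh       mz  ppm_error
#> 1 C19H19NO4       326.1387 326.1386 -0.2572525
```

The demethylation product of tetrahydroberberine (C₁₉H₁₉NO₄) has a
theoretical [M+H]⁺ of 326.1387 Th; the measured feature M6 at 326.1386
agrees within 0.26 ppm, so the formula-level assignment stands. All six
observed features are matched this way (the two demethylation isomer
pairs collapse onto one formula each — positional isomers are
indistinguishable at the formula level).

```r
summ <- summarize_docking(filter_docking(yzp_docking(), -5.0))
head(summ, 3)
#>              compound n_targets               targets best_score
#> 1          corydaline         4 CHRM2;CHRM3;DRD3;ESR1      -6.99
#> 2        protopine_M1         4 ABCC8;BCHE;KCNJ8;RNASE3    -5.74
#> 3 tetrahydropalmatine         3     ADRA1A;HRH1;OPRK1      -5.97
```

All 17 packaged docking pairs survive the −5.0 cutoff; corydaline binds 4
distinct targets and the strongest predicted interaction is
corydaline–ESR1 at −6.99.

An end-to-end run on synthetic inputs:

```r
paths <- write_synthetic_inputs(synth_config(seed = 1), "inputs")
cfg <- run_config(library = paths$library, queries = paths$queries,
                  docking = paths$docking, annotations = paths$annotations,
                  truth = paths$truth, out_dir = "out", threshold = 0.6)
report <- run_all(cfg)   # report$target_precision, $n_edges, ...
```

A thin CLI with the same stages (`simulate`, `metabolites`, `screen`,
`atcsim`, `network`, `enrich`, `dockfilter`, `run-all`) is installed at
`system.file("scripts", "ctnpharm", package = "ctnpharm")`.

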