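---
title: "Methods: compound-target inference for multi-constituent prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound-target inference for multi-constituent prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnpharm)
```

## The problem

A herbal prescription is a mixture: many constituents are absorbed, some
are biotransformed in vivo, and the pharmacology emerges from the joint
action of all of them on many protein targets. `ctnpharm` implements a
desk-side inference chain for this setting: predict metabolite formulas
and confirm them against LC-MS features, infer candidate targets by
structural similarity to annotated drugs, organize targets by therapeutic
class, assemble and summarize the bipartite compound-target network, test
the target set for annotation enrichment, and triage docking scores. The
packaged worked example is the Yuanhu Zhitong prescription: 15 absorbed
prototypes (7 *Rhizoma corydalis* alkaloids, 8 *Radix angelicae
dahuricae* coumarins) and 6 in-vivo metabolites.

## Metabolite prediction at the formula level

Biotransformations are represented as signed element deltas on molecular
formulas: demethylation is $-\mathrm{CH_2}$, i.e. $\{C{:}-1, H{:}-2\}$;
the observed composite demethylation-plus-hydrogenation is the net
$\{C{:}-1\}$; methylene-to-ketone oxidation is $\{O{:}+1, H{:}-2\}$.
This deliberately stops short of regiochemistry: atom-level
site-of-metabolism scoring requires a trained model of CYP chemistry and
cannot be reproduced from formulas, so candidates are enumerated and
matched at the formula/mass level only. A consequence the package
surfaces explicitly is that positional isomers (the two demethylation
products of tetrahydropalmatine, for instance) collapse onto a single
formula-level candidate: both observed features map to it, and no
position is invented.

Matching uses the protonated ion: $m/z([\mathrm{M+H}]^+) = M_{mono} +
1.0072765\ \mathrm{Da}$. The proton mass is used rather than the
hydrogen-atom mass because the adduct carries no electron; at $m/z
\approx 330$ the electron mass alone is a 1.7 ppm effect, larger than the
instrument error of good Q-TOF data, and only the proton convention
reproduces the packaged measured values to better than 1 ppm. Isotope
masses are packaged constants (`isotope_masses()`), most-abundant-isotope
values for CHNOPS and halogens.

**Tolerance.** The default matching window is 10 ppm. The packaged
features sit within 3 ppm of theory, and 10 ppm is a conventional
wide-open window for Q-TOF instruments; the knob (`tol_ppm`) exists
because tighter windows are appropriate for better-calibrated data.
Rule-composition depth defaults to 1 — the catalogue already contains the
one observed composite change, and free composition grows candidates
combinatorially while real metabolite series are shallow.

## Similarity-based target inference

Constituents are screened against a drug library in which every entry
carries a fingerprint, ATC codes and target gene symbols. Similarity is
the Tanimoto coefficient on binary fingerprints. Because the similarity
engine used in the original analysis is proprietary and unspecified, the
fingerprint backend is pluggable: everything downstream consumes plain
bit vectors. The structure-backed path (`fingerprint_of()`) computes a
deterministic 1024-bit atom-pair fingerprint from SMILES via
ChemmineR/ChemmineOB; the synthetic generator and most tests inject raw
bit vectors and bypass chemistry parsing entirely. No claim is made that
any particular backend reproduces the original engine's rankings.

**Threshold.** What counted as "highly similar" in the original analysis
was never published — neither a score cutoff nor a rank cutoff. The
package defaults to Tanimoto $\ge 0.85$, the conventional
same-activity heuristic for 2D fingerprints, exposes the cutoff as a
parameter, and offers `top_k` rank selection as an alternative mode.
Neither mode claims to reproduce the original 122-target set, which also
depended on a specific 2011 library snapshot.

Compounds whose screen returns nothing are retained with empty target
sets rather than dropped: a zero-degree compound is a result (the
packaged example has one), and the network stage reports it.

## ATC similarity and target therapeutic similarity

The ATC hierarchy has five nested levels (prefix lengths 1, 3, 4, 5, 7).
Code similarity is the Lin form driven by occurrence frequencies in the
library,

$$S(a,b) = \frac{2\,\ln p(\mathrm{prefix}(a,b))}{\ln p(a) + \ln p(b)},$$

where $\mathrm{prefix}(a,b)$ is the deepest shared official-level prefix
and $p(x)$ = (occurrences of prefix $x$) / (total code occurrences). The
method description this implements writes the formula as a log of an
"information content"; read literally with IC as $-\ln p$ the expression
leaves $[0,1]$, so the package adopts the standard Lin reading (IC
entering as the prefix probability), which is the only interpretation
bounded in $[0,1]$ and consistent with the cited similarity literature.
Frequencies count code *occurrences* (a drug with $k$ codes contributes
$k$), matching "prior probabilities (frequency)" of codes. Two
conventions close the degenerate corners: identical codes score 1 even
when their probability is 1, and an empty matched prefix — or one with
$p = 1$, whose log is 0 — scores 0.

Target therapeutic similarity (TST) compares the ATC code sets of the
drugs annotated to two targets. The method's description contains two
different definitions — a printed Jaccard overlap and a sentence defining
TST as the *maximum* pairwise code similarity. They are different scales,
so both are implemented (`tst_jaccard()`, `tst_max_similarity()`); the
pipeline default is the printed Jaccard form, with the max form
selectable (`tst_mode`). Whether target profiles should draw on all
library drugs or only the screened hits is likewise unstated; the
functions accept any profile source.

## Network construction and clustering

The compound-target network is strictly bipartite by construction: edges
only connect compound nodes to target nodes, an id appearing in both
classes is an error, and every operation preserves the degree-sum
identity $\sum_c \deg(c) = \sum_t \deg(t) = |E|$. Exports are SIF
(`compound binds target`, with bare lines for zero-degree nodes so the
node set round-trips) and GraphML with a node-type attribute, both
re-importable by the package's own readers.

Compound clustering uses average-linkage hierarchical clustering on
Tanimoto distance $1 - T$, cut at 0.4 by default. The original
three-way classing of the constituents came from a proprietary tool, so
the package ships the expected labels as a qualitative fixture
(`yzp_categories()`) for side-by-side comparison, not as an asserted
truth. Determinism: compounds are sorted by id before clustering, so the
partition is invariant to input order; merge ties are resolved by the
fixed ordering.

## Enrichment

Annotation enrichment is the two-sided hypergeometric test: for overlap
$k$ between an $n$-gene query and a $K$-gene term in an $N$-gene
background, $p_{enrich} = P(X \ge k)$ and $p_{deplete} = P(X \le k)$,
both tails including $k$ (so $p_{enrich} + p_{deplete} = 1 + P(X = k)$,
a property the tests assert exactly). The two-sided p doubles the
smaller tail and caps at 1 — the simplest defensible convention for a
discrete two-sided test. BH correction across terms is the default; the
original analysis does not state one. Tails are computed with
`stats::phyper` and cross-checked in the tests against exhaustive
binomial-coefficient enumeration of the pmf for all configurations with
$N \le 30$. Term grouping by kappa statistics and term-network layout
(features of the interactive tool the original analysis used) are out of
scope; only the stated statistic is implemented.

## Docking triage

The docking stage consumes any score table in the stated schema and
applies the published cutoff: score $\le -5.0$ nominates a pair. The
boundary is inclusive: the method text says "lower than −5.0" in one
place and "greater than 5" in magnitude in another, and on the packaged
table (weakest retained score −5.21) both readings agree, so the
inclusive convention is documented rather than consequential. Docking
itself (engine, structure preparation, 3D generation) is explicitly not
reimplemented — the stage is a filter and summarizer, enabling
substitution of open docking engines upstream.

## The synthetic generator: what it emulates, and what it does not

`gen_library()` emulates a drug library of the kind the screening stage
needs: fingerprints as Bernoulli bit vectors, ATC codes sampled
root-to-leaf down a synthetic 5-level tree with Zipf-weighted branches
(uniform branches would flatten the information-content model to a
constant — Zipf weighting keeps prefix frequencies, and hence Lin
similarities, non-degenerate), and drug-target links. For each query
compound a hidden archetype fingerprint is drawn and `n_neighbors`
library drugs are planted as independent per-bit flips of it; the
planted drugs share a per-query target pool, so both the neighbor set
and the target set are recoverable ground truth.

Key defaults and their reasoning:

* **Fingerprint density 0.1 at 2048 bits** (~205 set bits). With
  symmetric per-bit flips at rate $f$, the expected query-neighbor
  Tanimoto is $S(1-f) / (S + (n-S)f)$; at $f = 0.05$ this is $\approx
  0.65$, comfortably above a 0.6 screening threshold while far from the
  identity, and two independent background fingerprints score only
  $\approx 0.05$. Sparser fingerprints (density 0.05) would push planted
  similarity below 0.5 and make 5% flips indistinguishable from
  background at practical thresholds.
* **5 planted neighbors per query at 5% flips, 200-drug libraries** —
  the recovery benchmark conditions; screening at 0.6 then recovers
  planted drugs and targets with precision and recall above 0.9 on
  average, which the acceptance tests measure over 100 seeds.
* **3 ppm m/z noise** against a 10 ppm matching window, the regime of
  the packaged measured features.
* **Docking mixture** Normal(−6.0, 0.5) for binders vs Normal(−3.5,
  0.8) for non-binders with binder fraction 0.3: modes on either side of
  the −5.0 cutoff at roughly two standard deviations, giving the
  sensitivity/specificity ≥ 0.9 the tests verify.

Everything is a pure function of (config, seed); regeneration is
bit-identical, and generated artifacts are written in exactly the
formats the real-input readers consume (one parser path, no special
cases).

What the generator does **not** emulate: real molecular property
distributions, correlated fingerprint bits from actual substructures,
pharmacophore structure in the target assignments, or the composition of
any particular drug database. Passing recovery tests therefore
demonstrates the correctness and calibration of the inference machinery
under the stated noise model — not that the pipeline reproduces any
specific database-scale result. The original DrugBank-scale counts (143
nodes, 1049 edges, 122 candidate targets, per-compound degrees 73/42/34/
19/0) depend on a 2011 snapshot and unpublished thresholds; the run
report prints them as non-reproducible context next to the current run's
numbers.

## Numerical and design notes

* Formula parsing accepts Hill-order-like strings, strips the
  underscore subscript markers that appear in extracted tables, sums
  repeated element tokens, rejects unknown element symbols with the
  offending position, and round-trips exactly through
  `format_formula()`.
* Tanimoto of two all-zero fingerprints is defined as 0 (an empty
  fingerprint carries no evidence of similarity; avoids 0/0).
* Screening ties at equal score are broken by drug id, and `top_k`
  applies after the threshold, so results are order-independent.
* Matching problem sizes in the tests are chosen to keep the default
  suite in the low minutes: recovery benchmarks use 200-drug libraries
  over 100 seeds, pmf enumeration stops at backgrounds of 30 genes, and
  the null-calibration simulation uses 2,000 draws.
* Degenerate inputs are first-class: empty rule lists, empty feature
  tables, compounds with no hits, empty networks and single-compound
  clusterings all return well-formed empty or singleton results rather
  than errors; genuinely inconsistent inputs (dangling drug ids,
  query genes outside the background, malformed ATC codes, non-numeric
  docking scores) fail fast with the offending item named.
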