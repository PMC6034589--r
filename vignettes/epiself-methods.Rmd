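---
title: "Methods: contrasting HLA-DQ and HLA-DR epitope presentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting HLA-DQ and HLA-DR epitope presentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiself)
```

## The scientific question

HLA class II molecules present peptides to CD4+ T cells, and the outcome of
presentation — immune activation or tolerance — depends on which molecule
does the presenting. DQ heterodimers (encoded jointly by DQA1 and DQB1) are
enriched in the thymic cortex, where self-peptide presentation drives the
negative selection of autoreactive T cells, suggesting a tolerogenic role
that contrasts with the classically immunogenic DR molecules (variable chain
DRB1). `epiself` implements a pipeline for probing three consequences of
that hypothesis:

1. pathogen epitopes bound by DQ should look more *human-like* (their short
   peptide words should be more frequent in the human proteome) than
   epitopes bound by DR;
2. DQ and DR alleles should prefer different pathogen species;
3. among alleles associated with autoimmune diseases, stronger auto-epitope
   binding by a DQ allele should accompany *lower* disease risk (binding in
   the thymus deletes the corresponding autoreactive clones).

Because the primary data sources (epitope databases, reference proteomes,
allele catalogs, disease-association catalogs) are large external resources
and MHC-II binding prediction requires an external tool, every input is
emulated by a seeded synthetic generator with plantable effect sizes, and
the binding predictor sits behind a small interface (`predict_rank()`).
Every stage can therefore be tested for recovery of known ground truth,
offline and deterministically.

## Redundancy filtering

Public epitope sets are heavily redundant: overlapping 15-mers tiled across
the same antigen would otherwise be counted as independent observations.
`filter_redundant()` computes an alignment-free k-tuple distance between all
pairs,

\[ d(a,b) \;=\; 1 - \frac{|\text{k-tuples}(a) \cap \text{k-tuples}(b)|}
  {\min(|a|,|b|) - k + 1}, \]

with the intersection taken as a multiset, and iteratively removes peptides:
in each iteration, for every pair attaining the smallest distance, the
member with the *smaller* mean distance to all other retained peptides is
excluded (it sits deeper inside the retained set), ties broken against the
later input sequence; iterations repeat until every remaining pairwise
distance exceeds the threshold (default 0.5). The loop is deterministic and
its output is idempotent.

**Word length.** The package default is `k = 2` (dipeptides). At `k = 1`
this distance is a bag-of-residues overlap, and two *unrelated* uniform
15-mers over the 20-letter alphabet already share about 40% of their residue
multiset (median distance 0.6; roughly a quarter of random pairs fall at or
below 0.5). Consequently no set of more than ~15–18 mutually ">0.5-distant"
15-mers exists at `k = 1`, and any sizeable epitope set would be filtered to
a rump — in particular, no species could retain the 25 specific epitopes the
species analysis requires. At `k = 2` identical and frame-shifted
overlapping peptides still share most of their dipeptides (distance well
below 0.5 — they are removed), while unrelated peptides sit near 1. The
threshold of 0.5 is kept as the "about half the sequence differs" working
definition of redundancy; both `k` and the threshold are configuration
values (`run_config()`).

## 5-mer human-likeness and the permutation test

Each epitope is decomposed into overlapping 5-mers (a 15-mer yields 11, with
multiplicity retained), and each 5-mer is counted in the reference proteome
(overlapping matches, never spanning two proteins; 5-mers containing the
unknown residue `X` are excluded from both sides, since they cannot be
matched meaningfully). The *rarity profile* of an epitope set is the
fraction of its 5-mers found 0, 1, 2, … times in the proteome; a set is
more human-like when it contains fewer *rare* 5-mers (occurrence ≤ 0, ≤ 2,
≤ 5; configurable) and more *common* ones (occurrence ≥ 30).

Significance is assessed by label permutation: the two epitope sets are
pooled and randomly reassigned to the DQ/DR labels (set sizes preserved)
`n_iter` times (default 10,000), and the p-value is the proportion of
permutations whose difference in rare (or common) fraction is at least as
large as the observed one. The reported p is the plain proportion, without a
+1 correction; a zero is printed as "< 1/n_iter".

**Sidedness.** The default comparison is on the *magnitude*: a permutation
counts when its absolute difference reaches the observed absolute
difference. A one-sided comparison *in the observed direction* — pick the
direction after seeing the data, then count only that tail — doubles the
type-I error (each tail contributes α), so it cannot satisfy the calibration
this package tests for (rejection rate within [0.03, 0.07] at α = 0.05
under an exchangeable null); the magnitude comparison is calibrated, gives
p = 1 for identical input multisets, and is invariant to swapping the two
sets. Fixed-direction (`"greater"`) and observed-direction (`"observed"`)
alternatives remain available via the `alternative` argument for directional
hypotheses fixed a priori.

## Paired assay contingency

The in-vitro comparison counts positive and negative assay results, per
assay (an epitope assayed three times contributes three counts; an
epitope-level any-positive collapse is available behind `per_epitope =
TRUE`), restricted to epitopes tested against at least one DQ allele or pair
*and* at least one DRB1 allele (`paired_epitope_subset()`; MHC-binding
assays by default, T-cell assays poolable by argument). `fisher_or()`
reports the cross-product odds ratio (Haldane–Anscombe +0.5 correction,
flagged, when a cell is zero; undefined with p = 1 on a degenerate margin)
and the standard two-sided Fisher exact p-value.

## Species preference

Epitopes are grouped by source species, redundancy-filtered, and kept only
if *species specific* (their sequence occurs as a substring in exactly one
of the supplied reference proteomes); species retaining fewer than 25
specific epitopes are dropped, and obligate intracellular pathogens are
excluded via a metadata flag (their peptides are predominantly presented on
MHC-I). The recognition matrix holds, for every DRB1 allele and every
non-forbidden DQA1/DQB1 pair, the fraction of each species' epitopes
predicted to bind (rank percentile ≤ 10, inclusive). Columns (species) are
centered and scaled, rows are clustered with Ward's criterion in the
squared-distance (`ward.D2`) formulation on Euclidean distances, and the
two-cluster cut is compared against the DQ/DR row groups. The per-species
DQ/DR ratio of mean recognition summarises which group prefers the species.

The scoring-matrix confirmation emulates the check against in-vitro data:
position-specific scoring matrices (15 positions × 20 residues, entries are
relative frequencies so each position row sums to 1 and scores are
comparable across training sets; no pseudocounts — scores are sums, not log
products, so zeros do not annihilate them) are trained on DQ- and
DR-associated epitope sets with the examined species excluded
(leave-one-species-out). Every overlapping 15-mer of the species' epitopes
is scored under both matrices, the two score samples are compared with an
unpaired Wilcoxon rank-sum test (a paired signed-rank variant is exposed via
`paired = TRUE`), and p-values are Benjamini–Hochberg adjusted across
species with significance at adjusted p < 0.1. In `run_full()`, where no
external DQ/DR-associated training sets exist, the training sets are built
from the species the *prediction* stage classified as DQ- vs DR-preferred
(recognition ratio above/below 1), so the score stage acts as an internal
confirmation of the prediction-based split; both classifications are
reported separately and no automatic override is applied.

## Auto-epitope binding and autoimmune risk

Disease associations arrive as (allele, disease) or (chain, position,
residue, disease) records with odds ratios and p-values; associations with
p < 10⁻⁵ are significant, risk when OR > 1, protective when OR < 1. Disease
epitopes supported by fewer than two references are discarded. Because the
catalog reports single DQA1/DQB1 alleles while binding is a property of the
heterodimer, the binding level of an allele is the *median*, over all
common pairs containing it, of the fraction of disease epitopes bound
(DRB1 alleles are evaluated directly); amino-acid-level targets take the
median over pairs whose chain-side allele carries the residue at the
position (1-based within the supplied allele protein sequences — catalog
numbering schemes are out of scope, and the synthetic data defines its own
consistent numbering).

Three analyses relate binding to risk:

* Spearman correlation between bound fraction and OR (rank-based, so
  indifferent to the log scale of the plotted axis), per target kind;
* an OLS model `log(OR) ~ fraction + disease + chain` on the natural log
  (slope sign and variance shares are base-invariant), with per-term
  variance explained from sequential (type-I) sums of squares in that fixed
  order, an overall F-test, and a Breusch–Pagan heteroscedasticity check
  (studentized, via `lmtest::bptest`). Factor covariates with a single
  observed level are dropped rather than erroring (a single-disease,
  single-chain design is a legitimate reduced model); genuinely aliased
  designs error, naming the terms. One row per association enters the model
  (an allele associated with two diseases contributes two rows);
* a Kruskal–Wallis comparison of bound fractions across protective, neutral
  and risk alleles, with the three pairwise rank-sum tests BH-adjusted.
  Neutral alleles are the catalog alleles with no significant association,
  and their fraction is computed against the pooled all-disease epitope
  set. DRB1 associations are analysed separately from the DQ-focused
  correlation, mirroring the expectation that the effect is DQ-specific.

## The synthetic-data generators

The generators emulate the *statistical structure* of the real inputs — set
sizes, binder rates, effect sizes, occurrence-count profiles — not
immunological realism (residues are i.i.d. draws from a composition, not
motif-anchored peptides). What passing tests show is therefore that the
pipeline recovers planted statistical structure at realistic sizes; they
cannot show anything about binding motif biology, which lives entirely
behind the predictor interface.

* **Residue composition.** Proteomes and random epitopes draw residues from
  a fixed natural frequency table (`AA_COMPOSITION`, UniProtKB-scale). This
  matters: with a uniform composition at desk scale, a random 5-mer is
  essentially never found in the proteome, every epitope 5-mer is "rare",
  and the permutation null collapses onto a handful of atoms (the exact test
  then becomes visibly conservative purely through discreteness). With the
  natural composition and the default ~540k-residue proteome (1200 proteins
  of mean length 450), occurrence counts are dispersed and heavy-tailed —
  about 70% of random 5-mers absent, the rest spread over 1 to >30 — which
  is the qualitative shape of real proteome profiles and what the rare/
  common cutoffs (0/2/5 and 30) were designed against.
* **Human-likeness bias.** DQ epitopes are proteome substrings with
  probability δ (default 0.15) and random 15-mers otherwise; DR epitopes are
  all random. δ = 0 is the exchangeable null used for calibration; δ = 1
  forces every DQ 5-mer to occur.
* **Assay tables** plant an odds ratio via the DQ/DR positive rates (DR rate
  0.3 by default), with every epitope tested once per group.
* **Species bundles** plant the DQ/DR preference twice over: the mock
  predictor binds a preferred species' epitopes at `base + effect` (defaults
  0.1 + 0.4, several column standard deviations at 40 epitopes/species), and
  each group's species draw residues from a group-specific composition so
  the scoring-matrix confirmation has ground truth too. Epitopes are
  substrings of their own proteome only, hence species-specific by
  construction, and ≥ 25 per species so none is dropped.
* **Association bundles** give every catalog allele a binding propensity
  (protective/risk alleles sit `group_effect` above/below the neutral centre
  0.5), set every pair's binder rate to the mean of its two propensities,
  and draw `log(OR) = slope·(fraction − 0.5) + disease offset + N(0, σ)`
  from the *realised* fraction computed by the package's own pipeline — so
  a noise-free single-disease bundle is recovered exactly, and no
  attenuation bias enters the planted slope. Default sizes mirror the
  emulated study (6 diseases, 22 allele-level and 61 amino-acid-level
  associations). The default effect/noise scale (0.3/0.15) keeps planted
  effects decisively larger than noise, as for real catalog associations
  passing a 10⁻⁵ threshold, so the OR-derived class labels cohere with the
  planted groups; the slope-recovery tests use larger noise (σ = 0.3)
  explicitly.
* **Mock predictor.** A deterministic keyed hash of (seed, allele, sequence)
  — a fixed-width Lehmer-style fold in double precision, so values are
  identical across platforms and independent of call batching — is warped so
  that P(rank ≤ 10) equals the planted binder rate for the (allele, tag)
  combination. Predictions are pure functions of their inputs: bundles on
  disk fully determine later runs, and regeneration from a seed is
  byte-identical.

## Numerical choices and problem sizes

* Distances, fractions and scores are plain doubles; minimal-distance pairs
  are matched with a 1e-12 tolerance, and permutation-tail comparisons use
  the same tolerance so ties count toward the p-value (conservative side).
* The binder cutoff (rank ≤ 10) is inclusive; the redundancy threshold
  (distance > 0.5) is strict, matching "only larger values remain".
* `run_config()` houses every constant (rank cutoff 10, threshold 0.5,
  k = 2, 5-mers, rare cutoffs 0/2/5, common 30, 10,000 permutations,
  corrected significance 0.1, association significance 10⁻⁵) and one root
  seed from which stages derive fixed offsets; reruns are byte-identical.
* Test and demonstration problem sizes were chosen to exercise each
  statistic at realistic power on a single CPU within minutes: 200+200
  epitopes against a 540k-residue proteome for the permutation analyses
  (500 null datasets at 1000 permutations for calibration), 2000 assays,
  6 species × 40 epitopes × 6 DRB1 alleles + 11 DQ pairs for clustering,
  and 100 replicate bundles for slope-recovery coverage.

## Known limitations

* The k-tuple distance is a design stand-in for the word-match heuristic of
  alignment tools; exact reproduction of published filtered-set sizes is not
  attempted (it would require the original database snapshots).
* The species analysis reports prediction-based and score-based
  classifications separately and does not automate reconciling them.
* Linkage disequilibrium between alleles and HLA imputation are not
  modelled; one association is one observation.
* The neutral-allele group's fractions are computed against the pooled
  epitope set, so they are not strictly exchangeable with the per-disease
  fractions of the associated groups; the rank-based tests tolerate, but do
  not remove, that design asymmetry.
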