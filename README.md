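# epiself

Analysis pipeline contrasting peptide presentation by **HLA-DQ** and
**HLA-DR** molecules. HLA class II molecules present peptides to CD4+ T
cells; DQ heterodimers (encoded by DQA1 + DQB1) are enriched in the thymic
cortex where self-peptide presentation induces tolerance, suggesting a
tolerogenic role that contrasts with the classically immunogenic DR
(variable chain DRB1). `epiself` is aimed at immunoinformaticians who want
to test the consequences of that hypothesis on epitope-scale data:

* **Are DQ-bound pathogen epitopes more human-like?** Epitopes are
  redundancy-filtered by an iterative k-tuple-distance exclusion
  (`filter_redundant()`: remove peptides until every pairwise distance
  `1 − |shared k-tuples| / (min length − k + 1)` exceeds 0.5), decomposed
  into overlapping 5-mers, and profiled by how often each 5-mer occurs in
  the human proteome. The DQ/DR difference in the fraction of *rare* 5-mers
  (proteome occurrence ≤ 0/2/5) or *common* ones (≥ 30) is tested by label
  permutation: `P = #{permutations with |Δ| ≥ |Δ_obs|} / n_iter` over 10,000
  reassignments of epitopes to the two sets.
* **Do DQ and DR bind more human epitopes in vitro?** Paired assay counting
  (epitopes tested against both DQ and DR) in a 2×2 group-by-outcome table,
  with the cross-product odds ratio and the two-sided Fisher exact test
  (`fisher_or()`).
* **Do DQ and DR prefer different pathogen species?** A recognition matrix
  (fraction of each species' specific epitopes bound by each DRB1 allele and
  each non-forbidden DQA1/DQB1 pair at rank percentile ≤ 10), column-scaled
  and Ward-clustered (`ward.D2`), plus a position-specific scoring-matrix
  confirmation: 15×20 prevalence matrices trained leave-one-species-out,
  per-15-mer DQ vs DR scores compared by Wilcoxon rank-sum with
  Benjamini–Hochberg correction across species (significant at adjusted
  p < 0.1).
* **Does auto-epitope binding by DQ protect from autoimmune disease?** The
  binding level of a disease-associated allele is the median bound fraction
  over all common DQ pairs containing it; binding is related to the
  association odds ratio by Spearman correlation, by the model
  `log(OR) ~ fraction + disease + chain` (sequential variance decomposition,
  F-test, Breusch–Pagan check), and by a Kruskal–Wallis comparison of
  protective vs neutral vs risk alleles.

All external inputs — epitope/assay tables, reference proteomes, allele
catalogs, forbidden DQA1–DQB1 pair lists, allele protein sequences,
disease-association catalogs, and the MHC-II binding predictor — are
emulated by seeded synthetic generators with plantable effect sizes
(`make_full_bundle()` and friends), and the predictor sits behind a small
interface (`predict_rank()`), so the full pipeline runs, and is testable,
offline and deterministically.

## Worked example

Plant a modest human-likeness bias (15% of DQ epitopes are proteome
substrings) and an assay odds ratio of 1.8, then recover both:

```r
library(epiself)

prot <- make_proteome(1200, 450, seed = 42)                 # ~540k residues
sets <- make_epitope_sets(prot, n_dq = 200, n_dr = 200,
                          humanlike_bias = 0.15, seed = 43)
idx  <- kmer_occurrence_index(prot, proteome_id = "synthetic-human")
permutation_test(sets$dq, sets$dr, idx, cutoff = 0, mode = "rare",
                 n_iter = 10000, seed = 44)
#> permutation test (rare 5-mers, cutoff 0, 10000 iterations)
#>   fraction DQ: 0.5818  fraction DR: 0.6932  diff: +0.1114
#>   p < 0.0001 (no permutation reached the observed difference)

at <- make_assay_table(target_or = 1.8, n_assays = 2000, seed = 45)
fisher_or(build_contingency(at$table, paired_epitope_subset(at$table)))
#>    positive negative
#> DQ      431      569
#> DR      302      698
#> OR: 1.751, Fisher exact P: 2.662e-09
```

58% of DQ 5-mers are absent from the proteome versus 69% of DR 5-mers — the
planted bias (0.15 × the ~74% baseline) — and no random relabelling of the
400 epitopes reproduces a gap that large. The assay table recovers the
planted odds ratio within sampling error.

The end-to-end driver chains every stage over a bundle directory and writes
per-stage TSV reports plus a summary:

```r
make_full_bundle("bundle", seed = 1)
run_full("bundle", run_config(seed = 1), "reports")
```

A thin command-line wrapper over the same functions is installed with the
package (`system.file("cli", "epiself.R", package = "epiself")`) with
subcommands `synth`, `filter`, `kmer-test`, `assay-or` and `run-full`.

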