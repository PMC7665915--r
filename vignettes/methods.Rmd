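---
title: "Methods: co-prescription networks and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-prescription networks and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic data does and
does not emulate, and the design decisions taken where the analysis left
genuine freedom.

## 1. The analysis

The package implements a prescription-pattern analysis for Chinese
herbal medicine (CHM) in a claims-style database, for a single
indication (the shipped study conditions model allergic rhinitis):

1. **Cohort description.** Users vs nonusers of CHM are compared on
   demographics, comorbidity flags and conventional-medication burden
   with grouped counts, percentages, and Pearson chi-square tests.
2. **Association-rule mining (ARM).** Prescriptions are transactions of
   herb codes (set semantics; duplicates collapse). For an ordered pair
   A→B: support = percentage of prescriptions containing both herbs,
   confidence = 100·P(B|A), lift = P(A,B)/(P(A)P(B)). All pairs are
   counted exactly; no sampling and no apriori approximation is needed
   at the pair level. The denominator is always the number of
   prescriptions, not patients.
3. **Network.** The top 100 unordered pairs by support (ties:
   confidence, then pair name) become edges of an undirected network;
   each pair is represented by its higher-confidence direction. Node
   prevalence is the single-herb support; where no external prevalence
   table is supplied it is recovered from the rule identities
   (support(A) = 100·support(A,B)/confidence(A→B)).
4. **Clustering.** Weighted modularity Q = Σ_c(e_c − a_c²) with pair
   support as edge weight, maximised by agglomerative greedy merging.
5. **Core herbs.** Per cluster: maximum degree (raw edge count), ties
   broken by prevalence, then by name — an explicit operationalisation
   of the informal "high prevalence and high degree centrality"
   criterion.
6. **Ingredient screening.** Ingredients are retained when oral
   bioavailability OB > 0.30 *and* drug-likeness DL > 0.18 (strict, per
   "higher than") and the ingredient is organic. Only these three
   criteria are applied.
7. **Overrepresentation analysis (ORA).** Cluster target sets (unions of
   retained ingredients' protein targets) are tested per pathway with
   the hypergeometric upper tail P(X ≥ k); only pathways with k ≥ 1 are
   tested; Benjamini–Hochberg q-values are computed over the tested
   pathways; a pathway is *covered* at q ≤ α. Coverage patterns of the
   herb network and a comparator drug set are compared per category.

## 2. Parameters, defaults, and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_support` | 1.0 | % of prescriptions | permissive floor; every network-worthy pair in the reference setting sits above 1% |
| `min_confidence` | 15 | % | drops directions that add no information about co-use |
| `min_lift` | 1.0 | — | keeps only positively associated pairs; negative association cannot form a co-prescription community |
| `top_n` | 100 | pairs | the conventional size for a readable co-prescription network |
| `ob_min`, `dl_min` | 0.30, 0.18 | fraction | the standard systems-pharmacology screening cutoffs, strict inequalities |
| `ob_units` | `"fraction"` | — | some databases publish OB as percent (30%); `"percent"` divides by 100 before filtering |
| `alpha` | 0.05 | — | coverage criterion q ≤ α with BH-FDR; a raw-p mode exists for sensitivity analysis |

The mining thresholds are deliberately loose: their job is to bound the
candidate set before the top-N cut, not to select the network.

## 3. What the synthetic data emulates

The generator plays the role of the claims extract the analysis was
designed for, with known ground truth:

- **Cohort** (`ar_cohort_spec`): per-group category probabilities are
  the observed proportions of a published baseline table shipped in
  `inst/extdata/ar_cohort_counts.csv`; variables are drawn
  independently. One quirk of that table is preserved deliberately: the
  nonuser medication-type counts sum to one more than the group size, so
  percentages are always recomputed against the group size
  (`summary_from_counts`), and the row-level expansion
  (`cohort_from_counts`) is restricted to internally consistent
  variables.
- **Transactions** (`ar_network_spec`): 31 herbs in six planted
  communities — two formula-centred clusters of eight, clusters of six
  and five around common single herbs, and two isolated dyads — over a
  60-herb background pool. Each transaction draws its size from a
  right-skewed distribution (mode 5 at 17% of mass, mean 5.63, 6.3% of
  mass at ≥ 10, tail split geometrically with ratio ½; only the mode,
  the mean and the tail mass are externally constrained, the remaining
  bin masses are a modeling choice), picks one cluster with weight equal
  to the intended core prevalence (0.255, 0.229, 0.162, 0.155, 0.100,
  0.099), always includes the core, and fills the remaining slots from
  cluster members vs background with odds `co_draw : background_mass`
  (0.8 : 0.05). Background herbs are association-free by construction:
  they appear only as fillers, so their pairwise lift stays below 1 and
  the default thresholds exclude them from the network. An alternative
  reading — background-only noise transactions — was rejected because it
  makes the background pool itself a positively associated community.
  A `cluster_mixing` parameter (default 0) lets fillers leak across
  clusters for robustness experiments.
- **Pharmacology** (`ar_pharm_fixture`): a protein universe partitioned
  into an herb-biased pool (400), a drug pool (150), a shared set of 18
  inflammation proteins present in both, and an unrelated background
  pool; 31 herbs × ~70–87 ingredients each (≈ 2,430 in total) with
  Beta-distributed OB/DL scores; 39 comparator drugs in four classes;
  and a 300-pathway collection planting 140 herb-side pathways (19 of
  them immune), 55 drug-side pathways (8 immune) and 105 background
  pathways overlapping neither target set, so the ORA's coverage counts
  are known by construction.

What it does **not** emulate: patient-level longitudinal structure
(visits, refills), dose–response, herb–herb substitution, correlated
cohort covariates, identifier vocabularies of real protein databases,
or the real pathway hierarchy beyond a two-level category path. Passing
tests therefore show that the pipeline recovers structure it was told to
plant — not that any particular real-world claim holds.

## 4. Numerical choices

- **Rounding**: percentages round half-up to one decimal
  (`round_half_up`), which reproduces conventionally formatted tables;
  base R's round-half-to-even does not.
- **Chi-square** without continuity correction by default (exposed as an
  option); degenerate tables (any zero expected cell, or fewer than two
  nonzero rows/columns) are errors, not NA.
- **Exact identities**: lift·support(consequent) = confidence holds by
  construction and is asserted to 1e-12; the miner is checked against a
  brute-force ordered-pair scan (identical rule sets and supports,
  ratios to 1e-12 — the two routes differ only in floating-point
  association order).
- **Hypergeometric tail** via the exact log-space implementation in
  `stats::phyper`; validated against direct summation of
  binomial-coefficient terms for every admissible (N ≤ 60, K, n, k) at
  1e-10.
- **Clustering determinism**: the greedy agglomeration is hand-written
  so that ties in ΔQ break toward the lexicographically smallest cluster
  pair (clusters named by their smallest member). Components are merged
  independently; the best-Q partition along the merge path is returned,
  which keeps isolated dyads as their own clusters and makes the result
  invariant to node and edge order without any seed. `igraph`'s CNM and
  Louvain implementations serve as cross-checks, not as the
  implementation, because neither exposes this tie-break.
- **Seeds**: a single global integer seed drives every generator through
  `derive_seed(seed, tag)`, so each stage can be regenerated
  independently; all derived seeds stay below 2³¹. Generators restore
  the caller's RNG state.
- **Determinism of artifacts**: writers embed only version and seed as
  comment metadata (never timestamps), so a rerun with the same
  configuration is byte-identical.

## 5. Evaluation of recovery

`planted_recovery` scores the pipeline against the generator's ground
truth: the adjusted Rand index (ARI) between detected and planted
partitions, computed over the planted herbs present in the network —
background herbs have no meaningful community label, so they are
excluded from the comparison — and the fraction of planted cluster cores
that are also the identified core of the detected cluster containing
them. The reference benchmark uses 20 generator seeds at 20,000
transactions each; the demo pipeline and the analysis drivers use the
same problem size, chosen as the smallest scale at which pair-support
estimates are stable to well under a support point.

## 6. Known limitations

- Pair-level rules only feed the network; the optional k-itemset miner
  (`frequent_itemsets`, apriori-pruned up to k = 4) is exploratory.
- Greedy modularity has a resolution limit; very small true communities
  attached to large ones may be absorbed. The planted dyads avoid this
  by being disconnected, which mirrors the structure the method is meant
  to surface.
- The ORA universe defaults to the pathway collection's annotated
  universe; changing the universe changes p-values, and the package
  makes that choice explicit rather than hiding it.
- The cohort generator draws variables independently, so it cannot be
  used to study confounding between covariates — only marginal summaries
  and their tests.
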