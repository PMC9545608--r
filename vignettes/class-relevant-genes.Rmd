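---
title: "Calling conserved and region-specific class-relevant genes in neocortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling conserved and region-specific class-relevant genes in neocortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticlass)
```

## The problem and the model

Major neuronal classes of the mouse neocortex — the glutamatergic
projection classes L2/3 IT, L5 IT, L5 PT and L6 CT, and the GABAergic
interneuron classes VIP, SST and PV — recur in functionally distinct
cortical regions. `corticlass` asks, for genes involved in synaptic
connectivity ("circuit-related" genes), whether the expression differences
that distinguish these classes are the same in two regions at opposite ends
of the rostro-caudal axis (the anterior lateral motor cortex, ALM, and the
primary visual cortex, VISp), specific to one region, or reversed between
them.

The pipeline is a chain of deliberately simple, auditable steps:

1. **Normalization.** Raw counts are library-size normalized and
   log-transformed: `ln(count / total * 10^4 + 1)`. The pseudocount of one
   inside the log keeps zeros at zero and preserves sparsity.
2. **Ordered pairwise differential expression.** Within each region, every
   class pair within a neurotransmitter group is tested; across regions,
   each class is tested ALM vs VISp. Classes are always compared in a fixed
   canonical order (L2/3 IT, L5 IT, L5 PT, L6 CT; VIP, SST, PV; ALM before
   VISp), so the sign of the average log fold change is directly comparable
   between analogous tests: positive always means "higher in the first
   group". A full dataset yields 25 comparisons (6 + 3 pairs per region,
   plus 7 cross-region tests; see `build_comparison_plan()`).
   Per gene the engine computes the average log fold change of
   back-transformed group means,
   `avg_logFC = ln(mean(expm1(x_A)) + 1) - ln(mean(expm1(x_B)) + 1)`,
   pre-filters at `|avg_logFC| >= 0.25` (natural-log units, two-sided) and
   at a 10% detection fraction, applies a two-sided Wilcoxon rank-sum test
   to the survivors, and Bonferroni-corrects by the full gene universe,
   keeping adjusted p < 0.05.
3. **Region-specificity collapse.** Each (gene, class pair) significant in
   at least one region is categorized: significant in both regions with
   one sign is *conserved* (the two values are averaged), with opposite
   signs *divergent* (both values kept), in one region only *ALM-specific*
   or *VISp-specific*. The four categories partition all possible
   significance/sign patterns.
4. **Class relevance.** A gene is *class-relevant* to a class only if its
   results cover that class's fixed *class set* of comparisons (see
   `class_set_table()`) and the class sits on the same side — consistently
   higher (up) or lower (down) — in all of them. The composite class `IT`
   captures genes shared by L2/3 IT and L5 IT; its set deliberately omits
   the comparison between those two classes. The search runs three times:
   on the conserved results alone, and on everything significant in each
   region. Region records already explained by the conserved run are
   removed; genes whose region-specific call differs in (class, direction)
   from their conserved call are flagged with an asterisk on both records.
5. **Region bias.** Cross-region results are queried for genes uniformly
   biased to one region across every class of a group, and for interneuron
   genes biased in a single embryonic-origin compartment (VIP-only, or
   PV & SST only).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `scale_factor` | 10,000 | counts | library-size normalization target |
| `logfc_threshold` | 0.25 | natural-log | two-sided pre-filter before testing |
| `alpha` | 0.05 | probability | level on the Bonferroni-adjusted p |
| `min_detect_fraction` | 0.10 | fraction | minimum detection in one group |
| `adjust_n` | all genes | count | Bonferroni multiplier |

The pre-filter is applied to the absolute fold change because both
enriched and depleted genes are reported per comparison. The Bonferroni
multiplier is the full gene universe of the dataset, not the tested
subset, matching the convention of the marker-detection tooling
contemporaneous with this analysis style; both choices are configurable in
`de_test_config()`.

## Numerical choices

* **Rank-sum p-values** use the normal approximation with midrank tie
  handling, tie-corrected variance, *and the continuity correction*
  (`stats::wilcox.test(exact = FALSE, correct = TRUE)`), with p = 1 when
  the pooled sample is constant. The continuity correction keeps the
  approximation within 0.05 of the exact permutation p for fully separated
  3-vs-3 groups (0.081 vs 0.100) and within about 0.1 of the exact value
  across small tied samples in the decision-relevant regime (exact
  p ≤ 0.2); without it, the approximation overshoots significance in small
  samples. Near the Bonferroni threshold the approximation can still flip
  individual decisions; the test suite therefore compares significant sets
  against an exact-permutation oracle allowing disagreement only for genes
  whose exact p lies within a factor of 6 of the per-gene threshold.
* **Averaging** happens only for conserved records; divergent records keep
  both regional values because their interpretation differs per region.
* **Report rounding**: DE percentages are rounded half-up to one decimal
  at report time only; full precision is kept internally.
* **Degenerate inputs**: cells with zero total counts abort normalization
  by name; genes undetected in both groups are removed by the detection
  filter; a significant row with a fold change of exactly zero is treated
  as a contract violation (the pre-filter makes it impossible) and errors.
* **Missing matrix cells** in exports are empty fields, never zero — a
  significant result always has `|avg_logFC| >= 0.25`.

## Open design points and how they were resolved

* **Cross-region reconciliation inputs.** The region-specific
  class-relevance runs operate on *everything significant in that region*
  — the union of the conserved and region-specific collapse categories,
  using the region's own fold-change values. This joint interpretation is
  what makes the canonical asterisk example work: a gene significant in
  all three interneuron tests in ALM but only two in VISp yields an ALM
  VIP-up record (from the joint ALM run) and a conserved PV-down record,
  and the two are cross-flagged.
* **IT supersedes its constituents** only when L2/3 IT, L5 IT and IT
  records would all be emitted for the same gene; an IT record can coexist
  with records for other classes (distinct class sets).
* **Dual (diamond) genes** — one class up and another down — are stored as
  two linked rows (`dual_partner`) for flat CSV output. Note that a gene
  significant in *all* comparisons of a group with internally consistent
  signs necessarily emits such a pair (e.g. VIP up implies PV or SST
  down); the worked seven-gene example therefore carries PV-down partners
  alongside its four VIP-up calls.
* **SST-vs-PV direction in the seven-gene fixture.** The source pattern
  states significance for all three interneuron tests of the four retained
  genes but not the direction of SST vs PV; the fixture encodes SST > PV.
  The categorization depends only on significance and sign structure, and
  the retained/discarded gene sets are unaffected by this choice.

## The synthetic data generator

`generate_counts()` draws negative-binomial counts (variance
`mu + phi * mu^2`, default `phi = 0.5`) with log-normal per-cell size
factors (CV 0.2) around a baseline mean of 2 counts per gene, for all 14
(region, class) groups. Planted genes multiply the mean by `effect_fold`
(default 4, reciprocal for "down" effects) in the cells that encode their
category: a conserved VIP-up gene in VIP cells of both regions, an
ALM-specific one only in ALM VIP cells, a divergent gene in class A of ALM
and class B of VISp, a region-biased gene in every class of one group in
one region, an origin-specific gene in the VIP (or PV and SST) cells of
one region. These defaults were chosen once as a realistic middle ground
for SMART-seq-style data — moderate overdispersion, detectable baseline
expression, and an effect size comfortably above the 0.25 pre-filter — and
give near-complete power at 200 cells per group, which mirrors the scale
of the smaller real class/region groups.

*Inconsistent decoys* are genes that reach significance in several
comparisons without satisfying any class set. In the GABAergic group the
three class sets tile every two-subset of the three comparisons, and any
robust single-gene mean profile over three classes with all gaps
significant has a consistent extreme — so a count-level GABAergic decoy
would need knife-edge half-effects. Decoys are therefore planted in the
glutamatergic group with mean profile (f, 1, f, 1) over (L2/3 IT, L5 IT,
L5 PT, L6 CT): four comparisons are significant, yet no class set is a
subset. The GABAergic decoy pattern (significant in one comparison only)
is exercised at the DE-table level through `generate_de_table()` and the
seven-gene fixture.

What the generator does *not* emulate: zero-inflation beyond the NB model,
platform-specific read-depth profiles, correlated genes, subtype structure
within classes, and ambient contamination. Passing the recovery tests
shows the set logic and the test chain behave as specified under the
stated model, not that the thresholds are optimal for any particular real
dataset.

## Validation problem sizes

The test suite enumerates all 8 significance/sign patterns per comparison
pair for the collapse, all 27 interneuron and all 729 projection-neuron
sign patterns for the class-set logic against independent brute-force
oracles; checks the DE engine against exact-permutation p-values on
8-vs-8-cell groups with 20 genes; and measures planted-effect recovery at
200 cells per group with 300 genes (36 planted class-relevant genes, 4
decoys) plus null calibration on two all-null runs of 400 genes at 60
cells per group. These sizes give exhaustive coverage of the discrete
logic and high power for the stochastic checks while keeping a full run in
well under a minute.

## A small worked run

```{r example}
sim <- generate_counts(synth_config(n_cells_per_group = 60, n_genes = 80,
                                    seed = 42))
res <- run_pipeline(sim$dataset)
head(res$collapsed[, c("gene", "pair", "category", "avg_logFC")])
res$relevance$conserved[, c("gene", "class", "direction", "asterisk")]
res$bias
```

## Known limitations

* The categorization is pure significance/sign algebra; no interaction
  test backs the conserved/specific/divergent labels, so a gene just
  under threshold in one region flips category.
* Gene symbols are matched case-insensitively with no ortholog or alias
  resolution; supplied GMT and risk lists must use the same symbol space
  as the count matrix.
* Class-set consistency is all-or-nothing: a single non-significant
  comparison inside a class set removes the gene, which is deliberate but
  conservative.
* The worked examples encode published significance patterns; reproducing
  the source's full gene lists would require the external atlas dataset
  and version-specific ontology/risk lists, which are out of scope.
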