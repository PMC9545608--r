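# corticlass

Assigning circuit-related genes to major neocortical neuronal classes, and
deciding whether each gene–class relationship is conserved between two
cortical regions, specific to one, or divergent.

## What it is for

Single-cell RNA-seq of mouse neocortex shows the same major neuronal
classes — glutamatergic L2/3 IT, L5 IT, L5 PT and L6 CT projection
neurons, and GABAergic VIP, SST and PV interneurons — in functionally
distinct regions such as the anterior lateral motor cortex (ALM) and the
primary visual cortex (VISp). For genes involved in synaptic connectivity,
`corticlass` answers: *which class does a gene mark, in which region(s),
and in which direction?* It is aimed at people mining class-labeled count
matrices (e.g. atlas data) for cell-type-specific circuit candidates.

## The method

Starting from a gene × cell raw count matrix with per-cell (region, class)
labels:

1. **Log-normalization** — `ln(count / total · 10⁴ + 1)` per cell.
2. **Ordered pairwise DE** — within each region, every class pair inside a
   neurotransmitter group; across regions, each class ALM vs VISp
   (25 comparisons in all). Per gene:
   `avg_logFC = ln(mean(expm1 x_A)+1) − ln(mean(expm1 x_B)+1)`, a
   two-sided pre-filter at |avg_logFC| ≥ 0.25, a 10% detection filter, a
   Wilcoxon rank-sum test, Bonferroni correction over all genes, and
   adjusted p < 0.05. Because analogous ALM/VISp tests share class order,
   fold-change signs are directly comparable.
3. **Collapse** — each (gene, class pair) becomes *conserved* (significant
   both regions, one sign; values averaged), *divergent* (both regions,
   opposite signs; values kept), *ALM-specific* or *VISp-specific*.
4. **Class relevance** — a gene is relevant to a class when its results
   cover the class's fixed *class set* of comparisons with a consistent
   side (up or down) throughout; a composite `IT` class captures genes
   shared by L2/3 IT and L5 IT. The search runs on the conserved subset
   and on each region's full subset; duplicates are reconciled and genes
   with different conserved vs region-specific calls are asterisked.
5. **Region bias** — genes uniformly biased to one region across a whole
   group, or within interneuron embryonic-origin compartments (VIP-only,
   PV & SST-only).

Circuit-related filtering (GMT gene sets: cell–cell adhesion, regulation
of cell–cell adhesion, regulation of trans-synaptic signaling) and
risk-gene flagging (CSV: gene, category) slot in between steps 2 and 3.
A negative-binomial synthetic generator with planted effect categories
makes the whole chain testable end to end.

## Worked example

The seven-gene interneuron example: seven circuit-related genes with
significant results among the VIP/SST/PV comparisons, of which only four
are consistent across every test of a class set.

```r
library(corticlass)
rel <- class_relevance(collapse_de(seven_gene_fixture()))
rbind(rel$conserved, rel$alm, rel$visp)[, c("gene", "class", "direction",
                                            "regionality", "asterisk")]
#>     gene class direction regionality asterisk
#> 1  nrxn1   VIP        up   conserved    FALSE
#> 2 snap25   VIP        up   conserved    FALSE
#> 3  nrxn1    PV      down   conserved    FALSE
#> 4 snap25    PV      down   conserved    FALSE
#> 5  socs5   VIP        up         ALM    FALSE
#> 6  socs5    PV      down         ALM    FALSE
#> 7   pten   VIP        up        VISp    FALSE
#> 8   pten    PV      down        VISp    FALSE
```

`nrxn1` and `snap25` are VIP-relevant in both regions, `socs5` only in
ALM, `pten` only in VISp — each read as "higher in VIP than every other
interneuron class" (and, dually, lower in PV). `cyfip1`, `dlg2` and
`kctd13`, significant in VIP vs PV but not in the rest of their class
set, are discarded. On a full dataset the same call is one line:

```r
res <- run_pipeline(dataset, out_dir = "out",
                    gene_sets = load_gene_sets("circuit.gmt"),
                    risk = load_risk_genes("risk.csv"))
```

which writes per-comparison DE tables, the collapsed categorization,
class-relevance tables per regionality, region-bias queries, chord-diagram
matrices of DE percentages, stacked-bar category counts, heatmap-ready
fold-change matrices, and a run manifest.

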