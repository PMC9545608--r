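# Summary matrices: normalized DE proportions per comparison (chord-diagram
# input) and per-category gene counts per class pair (stacked-bar input).

round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Number of genes expressed within a comparison's pair of cell groups
#'
#' A gene counts as expressed when it has a nonzero raw count in at least
#' one cell of the union of the two groups (equivalently, average expression
#' within the pair greater than zero).
#'
#' @param dataset an [expression_dataset()].
#' @param spec one row of [build_comparison_plan()].
#' @return integer count.
#' @export
expressed_gene_count <- function(dataset, spec) {
  idx <- comparison_groups(dataset, as.list(spec))
  cells <- c(idx$a, idx$b)
  sum(Matrix::rowSums(dataset$counts[, cells, drop = FALSE]) > 0)
}

#' Normalized percentage of differentially expressed genes
#'
#' `100 * n_de / n_expressed`, reported to one decimal (half-up), the
#' normalization used for the chord-diagram band thicknesses.
#'
#' @param n_de number of significant genes in the comparison.
#' @param n_expressed number of genes expressed within the pair (> 0).
#' @return percentage on the 0-100 scale, one decimal.
#' @export
de_percentage <- function(n_de, n_expressed) {
  if (n_expressed <= 0) stop("n_expressed must be positive")
  if (n_de < 0 || n_de > n_expressed)
    stop("n_de must lie in [0, n_expressed]")
  round_half_up(100 * n_de / n_expressed, 1L)
}

#' Per-comparison DE summaries
#'
#' One row per plan comparison with the significant-gene count, the
#' expressed-gene count within the pair, and the normalized percentage.
#' With `genes` supplied (e.g. one circuit-related gene-set), both numerator
#' and denominator are restricted to that gene universe.
#'
#' @param dataset an [expression_dataset()].
#' @param de significant results from [run_de_plan()].
#' @param plan comparison plan (built from the dataset when `NULL`).
#' @param genes optional character vector restricting the gene universe.
#' @return data.frame with `comparison_id`, `kind`, `node_a`, `node_b`,
#'   `n_de`, `n_expressed`, `pct_de`.
#' @export
pair_summaries <- function(dataset, de, plan = NULL, genes = NULL) {
  if (is.null(plan)) plan <- attr(de, "plan")
  if (is.null(plan)) plan <- build_comparison_plan(dataset)
  universe <- rownames(dataset$counts)
  if (!is.null(genes))
    universe <- universe[normalize_symbol(universe) %in%
                           normalize_symbol(genes)]
  out <- lapply(seq_len(nrow(plan)), function(i) {
    spec <- plan[i, ]
    idx <- comparison_groups(dataset, as.list(spec))
    cells <- c(idx$a, idx$b)
    expressed <- Matrix::rowSums(
      dataset$counts[universe, cells, drop = FALSE]) > 0
    n_expressed <- sum(expressed)
    hits <- de$comparison_id == spec$comparison_id &
      de$gene %in% universe
    n_de <- length(unique(de$gene[hits]))
    if (spec$kind == "within_region") {
      node_a <- paste(spec$region, spec$class_a)
      node_b <- paste(spec$region, spec$class_b)
    } else {
      node_a <- paste("ALM", spec$class_a)
      node_b <- paste("VISp", spec$class_a)
    }
    data.frame(comparison_id = spec$comparison_id, kind = spec$kind,
               node_a = node_a, node_b = node_b, n_de = n_de,
               n_expressed = n_expressed,
               pct_de = if (n_expressed > 0) de_percentage(n_de, n_expressed)
                        else NA_real_,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Chord-diagram matrix of DE percentages
#'
#' Symmetric matrix over the 14 (region, class) nodes; tested pairs carry
#' their normalized DE percentage, untested pairs are NA.
#'
#' @param summaries output of [pair_summaries()].
#' @return labeled square numeric matrix.
#' @export
build_chord_matrix <- function(summaries) {
  nodes <- as.vector(outer(cortical_regions(), names(cortical_classes()),
                           paste))
  m <- matrix(NA_real_, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (anyDuplicated(paste(summaries$node_a, summaries$node_b)))
    stop("duplicate comparison pair in summaries")
  ia <- match(summaries$node_a, nodes)
  ib <- match(summaries$node_b, nodes)
  if (anyNA(ia) || anyNA(ib))
    stop("summary references an unknown (region, class) node")
  m[cbind(ia, ib)] <- summaries$pct_de
  m[cbind(ib, ia)] <- summaries$pct_de
  m
}

#' Per-category gene counts per class pair
#'
#' Counts of genes in each region-specificity category for every within-group
#' class pair (the stacked-bar summary). Each (gene, pair) collapsed record
#' counts once, including conserved and divergent records.
#'
#' @param collapsed output of [collapse_de()] (filter to circuit-related
#'   genes first if desired).
#' @return data.frame with `group`, `pair` and one column per category
#'   (`ALM-specific`, `VISp-specific`, `conserved`, `divergent`).
#' @export
category_counts_by_pair <- function(collapsed) {
  categories <- c("ALM-specific", "VISp-specific", "conserved", "divergent")
  pairs <- rbind(class_pairs("glutamatergic"), class_pairs("GABAergic"))
  counts <- matrix(0L, nrow(pairs), length(categories),
                   dimnames = list(NULL, categories))
  if (nrow(collapsed)) {
    tab <- table(factor(collapsed$pair, levels = pairs$pair),
                 factor(collapsed$category, levels = categories))
    counts[] <- as.integer(tab)
  }
  cbind(pairs[, c("group", "pair")], as.data.frame(counts, optional = TRUE))
}

#' Write a chord matrix as TSV
#'
#' @param m matrix from [build_chord_matrix()].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_chord_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, na = "",
                     col.names = NA)
  invisible(path)
}
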