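# Pairwise differential expression: log normalization, ordered comparison
# plan, average log fold change, Wilcoxon rank-sum, significance filters.

#' Configuration for the differential expression tests
#'
#' Defaults reproduce the conventions of 2019-era single-cell marker
#' detection: a pre-filter on the absolute natural-log average fold change,
#' a minimum detection fraction in at least one group, and Bonferroni
#' correction over the full gene universe of the dataset.
#'
#' @param logfc_threshold nonnegative; genes with `|avg_logFC|` below it are
#'   never tested (natural-log units; default 0.25).
#' @param alpha significance level applied to the adjusted p-value
#'   (default 0.05).
#' @param min_detect_fraction a gene must be detected (count > 0) in at
#'   least this fraction of cells in one of the two groups (default 0.10;
#'   set to 0 to disable).
#' @param adjust_n Bonferroni multiplier; `NULL` (default) means the total
#'   number of genes in the dataset.
#' @param log_base base of the fold-change logarithm (default natural log).
#' @return list of class `de_test_config`.
#' @export
de_test_config <- function(logfc_threshold = 0.25, alpha = 0.05,
                           min_detect_fraction = 0.10, adjust_n = NULL,
                           log_base = exp(1)) {
  stopifnot(logfc_threshold >= 0, alpha > 0, alpha < 1,
            min_detect_fraction >= 0, min_detect_fraction <= 1,
            is.null(adjust_n) || adjust_n >= 1, log_base > 1)
  structure(list(logfc_threshold = logfc_threshold, alpha = alpha,
                 min_detect_fraction = min_detect_fraction,
                 adjust_n = adjust_n, log_base = log_base),
            class = "de_test_config")
}

#' Log-normalize raw counts
#'
#' Each entry is divided by its cell's total count, multiplied by
#' `scale_factor`, and natural-log transformed with a pseudocount of one:
#' `ln(count / total * scale_factor + 1)`. A zero count therefore maps to 0
#' and sparsity is preserved.
#'
#' @param counts gene x cell count matrix (dense or sparse).
#' @param scale_factor positive scalar, default 10,000.
#' @return gene x cell `dgCMatrix` of normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  counts <- as_dgc(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cell(s) with zero total count: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

#' Average log fold change between two groups of normalized profiles
#'
#' Per gene: the normalized values are back-transformed (`expm1`), averaged
#' within each group, and the log of (mean + 1) is differenced, first group
#' minus second. Positive values mean higher expression in the first group.
#'
#' @param norm_a,norm_b gene x cell matrices (or per-gene numeric vectors
#'   for a single gene) of log-normalized values for the two groups.
#' @param log_base base of the returned log fold change (default natural).
#' @return numeric vector, one value per gene.
#' @export
average_log_fold_change <- function(norm_a, norm_b, log_base = exp(1)) {
  if (is.null(dim(norm_a))) norm_a <- matrix(norm_a, nrow = 1L)
  if (is.null(dim(norm_b))) norm_b <- matrix(norm_b, nrow = 1L)
  if (ncol(norm_a) == 0L || ncol(norm_b) == 0L)
    stop("both groups must contain at least one cell")
  mean_a <- Matrix::rowMeans(expm1(norm_a))
  mean_b <- Matrix::rowMeans(expm1(norm_b))
  (log(mean_a + 1) - log(mean_b + 1)) / log(log_base)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with midrank tie handling, tie-corrected variance
#' and continuity correction. Two identical constant groups give p = 1.
#'
#' @param values_a,values_b numeric vectors for the two groups (non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(values_a, values_b,
                       exact = FALSE, correct = TRUE)$p.value)
  if (is.na(p)) 1 else min(p, 1)
}

#' Build the ordered pairwise comparison plan
#'
#' Within each region, every unordered class pair within each
#' neurotransmitter group, in canonical class order (identical in ALM and
#' VISp so fold-change signs are directly comparable); plus one
#' cross-region comparison per class with ALM always first. A full
#' seven-class, two-region dataset yields 25 comparisons:
#' (6 glutamatergic + 3 GABAergic) x 2 regions + 7 cross-region.
#'
#' @param dataset an [expression_dataset()].
#' @return data.frame of comparison specs with columns `comparison_id`,
#'   `kind` (`within_region` / `cross_region`), `group`, `region` (NA for
#'   cross-region), `class_a`, `class_b`, `pair`. For cross-region rows
#'   `class_a == class_b` is the class and `pair` is `"ALM vs VISp"`.
#' @export
build_comparison_plan <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  present <- unique(dataset$cells[, c("region", "class")])
  groups <- intersect(c("glutamatergic", "GABAergic"),
                      unique(dataset$cells$group))
  plan <- list()
  for (grp in groups) {
    cls <- intersect(classes_of_group(grp), unique(dataset$cells$class))
    # every class of the group must exist in both regions
    for (k in cls) for (r in cortical_regions())
      if (!any(present$region == r & present$class == k))
        stop("class ", k, " missing from region ", r)
    pairs <- class_pairs(grp)
    pairs <- pairs[pairs$class_a %in% cls & pairs$class_b %in% cls, ,
                   drop = FALSE]
    for (r in cortical_regions()) {
      if (nrow(pairs))
        plan[[length(plan) + 1L]] <- data.frame(
          comparison_id = within_comparison_id(grp, r, pairs$pair),
          kind = "within_region", group = grp, region = r,
          class_a = pairs$class_a, class_b = pairs$class_b,
          pair = pairs$pair, row.names = NULL)
    }
    plan[[length(plan) + 1L]] <- data.frame(
      comparison_id = cross_comparison_id(grp, cls),
      kind = "cross_region", group = grp, region = NA_character_,
      class_a = cls, class_b = cls, pair = "ALM vs VISp",
      row.names = NULL)
  }
  out <- do.call(rbind, plan)
  rownames(out) <- NULL
  out
}

# Resolve the two cell index sets of one comparison spec (one plan row).
comparison_groups <- function(dataset, spec) {
  cells <- dataset$cells
  if (spec$kind == "within_region") {
    a <- which(cells$region == spec$region & cells$class == spec$class_a)
    b <- which(cells$region == spec$region & cells$class == spec$class_b)
  } else {
    a <- which(cells$region == "ALM"  & cells$class == spec$class_a)
    b <- which(cells$region == "VISp" & cells$class == spec$class_a)
  }
  list(a = a, b = b)
}

de_table_columns <- c("comparison_id", "kind", "group", "region",
                      "class_a", "class_b", "pair", "gene", "avg_logFC",
                      "p_raw", "p_adj", "pct_a", "pct_b")

empty_de_table <- function() {
  out <- data.frame(comparison_id = character(), kind = character(),
                    group = character(), region = character(),
                    class_a = character(), class_b = character(),
                    pair = character(), gene = character(),
                    avg_logFC = numeric(), p_raw = numeric(),
                    p_adj = numeric(), pct_a = numeric(), pct_b = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Run one ordered pairwise differential expression test
#'
#' Per gene: detection fractions in each group are computed from raw counts;
#' genes detected in fewer than `min_detect_fraction` of cells in both
#' groups are dropped, then genes with `|avg_logFC|` below
#' `logfc_threshold`; survivors get a Wilcoxon rank-sum p-value on the
#' log-normalized values, Bonferroni-adjusted by the full gene universe.
#' Only rows with adjusted p below `alpha` are returned, ordered as in the
#' spec (positive fold change = higher in the first class/region).
#'
#' @param dataset an [expression_dataset()].
#' @param spec one row of [build_comparison_plan()].
#' @param de_config a [de_test_config()].
#' @param norm optional pre-computed [log_normalize()] matrix for the whole
#'   dataset (computed on the fly if `NULL`).
#' @param scale_factor normalization scale factor when `norm` is `NULL`.
#' @return data.frame of significant results (one row per gene), with
#'   columns `comparison_id`, `kind`, `group`, `region`, `class_a`,
#'   `class_b`, `pair`, `gene`, `avg_logFC`, `p_raw`, `p_adj`, `pct_a`,
#'   `pct_b`.
#' @export
run_de_test <- function(dataset, spec, de_config = de_test_config(),
                        norm = NULL, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  spec <- as.list(spec)
  idx <- comparison_groups(dataset, spec)
  if (length(idx$a) < 2L || length(idx$b) < 2L)
    stop("comparison ", spec$comparison_id,
         ": both groups need at least 2 cells")
  if (is.null(norm)) norm <- log_normalize(dataset$counts, scale_factor)

  counts <- dataset$counts
  pct_a <- Matrix::rowSums(counts[, idx$a, drop = FALSE] > 0) / length(idx$a)
  pct_b <- Matrix::rowSums(counts[, idx$b, drop = FALSE] > 0) / length(idx$b)
  keep <- pmax(pct_a, pct_b) >= de_config$min_detect_fraction
  if (!any(keep)) return(empty_de_table())

  lfc <- average_log_fold_change(norm[keep, idx$a, drop = FALSE],
                                 norm[keep, idx$b, drop = FALSE],
                                 de_config$log_base)
  keep2 <- abs(lfc) >= de_config$logfc_threshold
  if (!any(keep2)) return(empty_de_table())
  genes <- rownames(counts)[keep][keep2]
  lfc <- lfc[keep2]

  a_mat <- as.matrix(norm[genes, idx$a, drop = FALSE])
  b_mat <- as.matrix(norm[genes, idx$b, drop = FALSE])
  p_raw <- vapply(seq_along(genes), function(i)
    wilcoxon_rank_sum(a_mat[i, ], b_mat[i, ]), numeric(1L))

  adjust_n <- if (is.null(de_config$adjust_n)) nrow(counts)
              else de_config$adjust_n
  p_adj <- pmin(1, p_raw * adjust_n)
  sig <- p_adj < de_config$alpha
  if (!any(sig)) return(empty_de_table())

  data.frame(comparison_id = spec$comparison_id, kind = spec$kind,
             group = spec$group, region = spec$region,
             class_a = spec$class_a, class_b = spec$class_b,
             pair = spec$pair, gene = genes[sig],
             avg_logFC = unname(lfc[sig]), p_raw = unname(p_raw[sig]),
             p_adj = unname(p_adj[sig]),
             pct_a = unname(pct_a[keep][keep2][sig]),
             pct_b = unname(pct_b[keep][keep2][sig]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the whole comparison plan
#'
#' @inheritParams run_de_test
#' @param plan data.frame from [build_comparison_plan()]; built from the
#'   dataset when `NULL`.
#' @return concatenated significant-results table (see [run_de_test()]),
#'   with the executed plan attached as attribute `"plan"`.
#' @export
run_de_plan <- function(dataset, plan = NULL, de_config = de_test_config(),
                        scale_factor = 1e4) {
  if (is.null(plan)) plan <- build_comparison_plan(dataset)
  norm <- log_normalize(dataset$counts, scale_factor)
  tabs <- lapply(seq_len(nrow(plan)), function(i)
    run_de_test(dataset, plan[i, ], de_config, norm = norm))
  out <- do.call(rbind, c(tabs, list(empty_de_table())))
  rownames(out) <- NULL
  attr(out, "plan") <- plan
  out
}

#' Read or write a differential-expression table as CSV
#'
#' The on-disk header is fixed: comparison_id, region_scope, class_a,
#' class_b, gene, avg_logFC, p_raw, p_adj, pct_a, pct_b (plus go_terms and
#' risk_flag when present). `region_scope` is the region for within-region
#' tests and `"ALM vs VISp"` for cross-region tests.
#'
#' @param de data.frame from [run_de_test()]/[run_de_plan()].
#' @param path CSV file path.
#' @return `write_de_csv` returns `path` invisibly; `read_de_csv` the table
#'   in internal column layout.
#' @export
write_de_csv <- function(de, path) {
  out <- data.frame(comparison_id = de$comparison_id,
                    region_scope = ifelse(de$kind == "cross_region",
                                          "ALM vs VISp", de$region),
                    class_a = de$class_a, class_b = de$class_b,
                    gene = de$gene, avg_logFC = de$avg_logFC,
                    p_raw = de$p_raw, p_adj = de$p_adj,
                    pct_a = de$pct_a, pct_b = de$pct_b)
  if (!is.null(de$go_terms)) out$go_terms <- de$go_terms
  if (!is.null(de$risk_flag)) out$risk_flag <- de$risk_flag
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_de_csv
#' @export
read_de_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$kind <- ifelse(x$region_scope == "ALM vs VISp",
                   "cross_region", "within_region")
  x$region <- ifelse(x$kind == "within_region", x$region_scope,
                     NA_character_)
  x$group <- group_of_class(x$class_a)
  x$pair <- ifelse(x$kind == "within_region",
                   pair_label(x$class_a, x$class_b), "ALM vs VISp")
  x$region_scope <- NULL
  x
}
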