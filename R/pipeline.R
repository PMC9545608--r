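# End-to-end orchestration and heatmap-ready matrix export.

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(obj, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline and write all stage outputs
#'
#' Sequences the stages in analysis order: comparison plan, pairwise
#' differential expression, circuit-related filtering and risk flagging,
#' region-specificity collapse, class-relevance calls for the conserved,
#' ALM and VISp subsets with cross-region reconciliation, region-bias
#' queries, and the chord / stacked-bar summary matrices. All outputs are
#' plain text and byte-identical across reruns of the same inputs.
#'
#' @param dataset an [expression_dataset()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @param gene_sets optional [load_gene_sets()] collection; when supplied,
#'   collapse and class-relevance run on circuit-related genes only.
#' @param risk optional [load_risk_genes()] table.
#' @param de_config a [de_test_config()].
#' @param scale_factor normalization scale factor.
#' @return (invisibly) list with elements `plan`, `de`, `circuit`,
#'   `collapsed`, `relevance` (list conserved/alm/visp), `bias`,
#'   `summaries`, `chord`, `chord_go` (per-set matrices), `category_counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, out_dir = NULL, gene_sets = NULL,
                         risk = NULL, de_config = de_test_config(),
                         scale_factor = 1e4) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  plan <- build_comparison_plan(dataset)
  de <- run_de_plan(dataset, plan, de_config, scale_factor)

  circuit <- if (!is.null(gene_sets)) filter_circuit_related(de, gene_sets)
             else de
  if (!is.null(risk)) circuit <- flag_risk_genes(circuit, risk)

  collapsed <- collapse_de(circuit)
  relevance <- class_relevance(collapsed)

  cross <- circuit[circuit$kind == "cross_region", , drop = FALSE]
  bias <- rbind(region_biased_genes(cross, "glutamatergic", plan),
                region_biased_genes(cross, "GABAergic", plan),
                origin_specific_genes(cross, plan))

  summaries <- pair_summaries(dataset, de, plan)
  chord <- build_chord_matrix(summaries)
  chord_go <- list()
  if (!is.null(gene_sets))
    for (nm in names(gene_sets))
      chord_go[[nm]] <- build_chord_matrix(
        pair_summaries(dataset, de, plan, genes = gene_sets[[nm]]))
  category_counts <- category_counts_by_pair(collapsed)

  manifest <- c(
    config_hash = config_hash(list(de_config, scale_factor,
                                   names(gene_sets))),
    n_genes = nrow(dataset$counts), n_cells = ncol(dataset$counts),
    n_comparisons = nrow(plan), n_de_rows = nrow(de),
    n_circuit_rows = nrow(circuit), n_collapsed = nrow(collapsed),
    n_relevance_conserved = nrow(relevance$conserved),
    n_relevance_alm = nrow(relevance$alm),
    n_relevance_visp = nrow(relevance$visp),
    n_region_bias = nrow(bias))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in plan$comparison_id)
      write_de_csv(de[de$comparison_id == id, , drop = FALSE],
                   file.path(out_dir,
                             paste0("de_", sanitize_filename(id), ".csv")))
    write_de_csv(de, file.path(out_dir, "de_all.csv"))
    if (!is.null(gene_sets))
      write_de_csv(circuit, file.path(out_dir, "de_circuit_related.csv"))
    write_collapsed_csv(collapsed, file.path(out_dir, "collapsed.csv"))
    for (nm in names(relevance))
      utils::write.csv(relevance[[nm]],
                       file.path(out_dir,
                                 paste0("class_relevance_", nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(bias, file.path(out_dir, "region_bias.csv"),
                     row.names = FALSE)
    write_chord_matrix(chord, file.path(out_dir, "chord_all_genes.tsv"))
    for (nm in names(chord_go))
      write_chord_matrix(chord_go[[nm]],
                         file.path(out_dir,
                                   paste0("chord_",
                                          sanitize_filename(nm), ".tsv")))
    utils::write.csv(category_counts,
                     file.path(out_dir, "category_counts.csv"),
                     row.names = FALSE)
    writeLines(paste(names(manifest), manifest, sep = ": "),
               file.path(out_dir, "manifest.txt"))
  }

  invisible(list(plan = plan, de = de, circuit = circuit,
                 collapsed = collapsed, relevance = relevance, bias = bias,
                 summaries = summaries, chord = chord, chord_go = chord_go,
                 category_counts = category_counts, manifest = manifest))
}

#' Export a heatmap-ready fold-change matrix for class-relevant genes
#'
#' Rows are the within-group comparisons, columns are the class-relevant
#' genes ordered by (class, direction); each cell is the gene's collapsed or
#' regional average log fold change where the comparison was significant and
#' NA (empty on disk) where it was not. A companion annotation table carries
#' each gene's class, direction, asterisk and risk flag.
#'
#' @param records class-relevance records for one regionality (one element
#'   of [class_relevance()] output).
#' @param collapsed the [collapse_de()] table the records were derived from.
#' @param regionality `"conserved"`, `"ALM"` or `"VISp"` — selects which
#'   fold-change value fills the cells.
#' @return list with `matrix` (comparisons x genes) and `annotation`
#'   (data.frame: gene, class, direction, asterisk, risk_flag).
#' @export
export_heatmap_matrix <- function(records, collapsed,
                                  regionality = c("conserved", "ALM",
                                                  "VISp")) {
  regionality <- match.arg(regionality)
  sub <- regional_subset(collapsed, regionality)
  missing <- setdiff(records$gene, sub$gene)
  if (length(missing))
    stop("record(s) reference gene(s) absent from the collapsed data: ",
         paste(missing, collapse = ", "))
  ord <- order(match(records$class, canonical_class_order),
               records$direction, records$gene)
  records <- records[ord, , drop = FALSE]
  genes <- unique(records$gene)
  groups <- unique(group_of_class(
    setdiff(unlist(strsplit(sub$pair[sub$gene %in% genes], " vs ")), "IT")))
  pairs <- do.call(rbind, lapply(groups, class_pairs))$pair
  if (is.null(pairs)) pairs <- character()
  m <- matrix(NA_real_, length(pairs), length(genes),
              dimnames = list(pairs, genes))
  hit <- sub$gene %in% genes & sub$pair %in% pairs
  m[cbind(match(sub$pair[hit], pairs), match(sub$gene[hit], genes))] <-
    sub$avg_logFC[hit]
  anno <- records[!duplicated(records$gene),
                  c("gene", "class", "direction", "asterisk", "risk_flag"),
                  drop = FALSE]
  rownames(anno) <- NULL
  list(matrix = m, annotation = anno)
}

#' Write a heatmap export as TSV
#'
#' Annotation rows (class, direction, asterisk, risk flag) precede the
#' numeric fold-change block; missing values are empty fields, not zeros.
#'
#' @param heatmap output of [export_heatmap_matrix()].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(heatmap, path) {
  m <- heatmap$matrix
  anno <- heatmap$annotation[match(colnames(m), heatmap$annotation$gene), ]
  header <- rbind(class = anno$class, direction = anno$direction,
                  asterisk = as.character(anno$asterisk),
                  risk_flag = as.character(anno$risk_flag))
  colnames(header) <- colnames(m)
  block <- rbind(header, matrix(ifelse(is.na(m), "",
                                       format(m, trim = TRUE)),
                                nrow(m), ncol(m), dimnames = dimnames(m)))
  utils::write.table(block, path, sep = "\t", quote = FALSE, na = "",
                     col.names = NA)
  invisible(path)
}
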