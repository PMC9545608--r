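# Class-relevance logic: class-set consistency calls per gene, cross-region
# reconciliation (asterisk genes), and region-bias queries.

canonical_class_order <- c("L2/3 IT", "L5 IT", "IT", "L5 PT", "L6 CT",
                           "VIP", "SST", "PV")

#' Extract one regionality subset of a collapsed table for class calling
#'
#' The class-relevance search runs three times: on the conserved results
#' alone, and on everything significant in each region (the union of the
#' conserved and region-specific categories, using that region's fold-change
#' values). Divergent results never participate.
#'
#' @param collapsed output of [collapse_de()].
#' @param regionality `"conserved"`, `"ALM"` or `"VISp"`.
#' @return data.frame with columns `gene`, `pair`, `group`, `avg_logFC`
#'   (plus annotation columns when present) — one row per (gene, pair).
#' @export
regional_subset <- function(collapsed,
                            regionality = c("conserved", "ALM", "VISp")) {
  regionality <- match.arg(regionality)
  keep_cols <- intersect(c("gene", "pair", "group", "go_terms", "risk_flag",
                           "risk_category"), names(collapsed))
  if (regionality == "conserved") {
    sub <- collapsed[collapsed$category == "conserved", , drop = FALSE]
    sub$.lfc <- sub$avg_logFC
  } else {
    cat_keep <- c("conserved", paste0(regionality, "-specific"))
    sub <- collapsed[collapsed$category %in% cat_keep, , drop = FALSE]
    sub$.lfc <- if (regionality == "ALM") sub$avg_logFC_alm
                else sub$avg_logFC_visp
  }
  out <- sub[, keep_cols, drop = FALSE]
  out$avg_logFC <- sub$.lfc
  rownames(out) <- NULL
  out
}

empty_relevance_records <- function() {
  data.frame(gene = character(), class = character(),
             direction = character(), regionality = character(),
             asterisk = logical(), dual_partner = character(),
             go_terms = character(), risk_flag = logical(),
             risk_category = character(), stringsAsFactors = FALSE)
}

#' Identify class-relevant genes from one regionality subset
#'
#' For each gene, the comparison set is the set of class pairs in which it
#' is significant. The candidate classes are all classes appearing in that
#' set, plus the composite "IT" when both L2/3 IT and L5 IT appear. A
#' candidate class emits a record iff (1) its fixed class set (see
#' [class_set_table()]) is a subset of the gene's comparison set, and
#' (2) restricted to those comparisons the class sits on the same side in
#' every one — consistently higher ("up") or consistently lower ("down").
#' When L2/3 IT, L5 IT and IT would all emit, the IT record supersedes the
#' two constituent records. A gene may emit records for several classes; a
#' gene with both an up and a down record is a dual (diamond) gene and the
#' records are cross-linked via `dual_partner`.
#'
#' @param records one regionality subset from [regional_subset()] (or any
#'   data.frame with `gene`, `pair`, `group`, `avg_logFC`); the comparisons
#'   must belong to the within-group pair vocabulary.
#' @param regionality label stamped on the emitted records.
#' @return data.frame of class-relevance records: `gene`, `class`,
#'   `direction` (up/down), `regionality`, `asterisk` (FALSE here; set by
#'   [reconcile_regional()]), `dual_partner`, and annotation columns.
#'   Ordered by (regionality, class, direction, gene).
#' @export
identify_class_relevant <- function(records, regionality = "conserved") {
  if (!nrow(records)) return(empty_relevance_records())
  sets <- class_set_table()
  for (grp in unique(records$group)) {
    vocab <- class_pairs(grp)$pair
    bad <- setdiff(records$pair[records$group == grp], vocab)
    if (length(bad))
      stop("comparison(s) not in the ", grp, " vocabulary: ",
           paste(bad, collapse = ", "))
  }
  out <- lapply(split(records, records$gene), function(sub) {
    pairs <- sub$pair
    if (anyDuplicated(pairs))
      stop("duplicate comparison for gene ", sub$gene[1L])
    signs <- sign(sub$avg_logFC)
    classes <- unique(unlist(split_pair(pairs)))
    if (all(c("L2/3 IT", "L5 IT") %in% classes))
      classes <- c(classes, "IT")
    recs <- list()
    for (cls in intersect(names(sets), classes)) {
      cs <- sets[[cls]]
      if (!all(cs %in% pairs)) next
      side <- class_side(cls, cs)
      sgn <- signs[match(cs, pairs)]
      higher <- (sgn > 0 & side == "first") | (sgn < 0 & side == "second")
      if (all(higher)) dir <- "up"
      else if (all(!higher)) dir <- "down"
      else next
      recs[[length(recs) + 1L]] <- c(class = cls, direction = dir)
    }
    if (!length(recs)) return(NULL)
    recs <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
    if (all(c("IT", "L2/3 IT", "L5 IT") %in% recs$class))
      recs <- recs[!recs$class %in% c("L2/3 IT", "L5 IT"), , drop = FALSE]
    dual <- vapply(seq_len(nrow(recs)), function(i) {
      other <- recs$class[recs$direction != recs$direction[i]]
      if (length(other)) paste(other, collapse = ";") else NA_character_
    }, character(1L))
    anno <- function(col, default) {
      if (is.null(sub[[col]])) return(default)
      if (col == "go_terms")
        return(paste(sort(unique(unlist(
          strsplit(sub[[col]], ";", fixed = TRUE)))), collapse = ";"))
      if (col == "risk_flag") return(any(sub[[col]]))
      v <- unique(stats::na.omit(sub[[col]]))
      if (length(v)) v[1L] else default
    }
    data.frame(gene = sub$gene[1L], class = recs$class,
               direction = recs$direction, regionality = regionality,
               asterisk = FALSE, dual_partner = dual,
               go_terms = anno("go_terms", NA_character_),
               risk_flag = anno("risk_flag", NA),
               risk_category = anno("risk_category", NA_character_),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(empty_relevance_records())))
  out <- out[order(match(out$class, canonical_class_order),
                   out$direction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile conserved and region-specific class-relevance records
#'
#' The region runs (`alm_full`, `visp_full`) are made on everything
#' significant in that region, so any (gene, class, direction) that the
#' conserved run already explains is removed from the region output. A gene
#' that survives region-specifically while a *different* (class, direction)
#' of the same gene is conserved is an asterisk gene: the flag is set on
#' both its region record(s) and its conserved record(s). Applying the
#' reconciliation twice equals applying it once.
#'
#' @param conserved_records [identify_class_relevant()] output on the
#'   conserved subset alone.
#' @param alm_full_records,visp_full_records [identify_class_relevant()]
#'   output on the full ALM / VISp subsets (conserved + region-specific).
#' @return list with elements `conserved`, `alm`, `visp` — asterisk-annotated
#'   conserved records and pruned, genuinely region-specific records.
#' @export
reconcile_regional <- function(conserved_records, alm_full_records,
                               visp_full_records) {
  key <- function(x) paste(x$gene, x$class, x$direction, sep = "\r")
  ckeys <- key(conserved_records)
  relink_duals <- function(x) {
    x$dual_partner <- vapply(seq_len(nrow(x)), function(i) {
      other <- x$class[x$gene == x$gene[i] &
                         x$direction != x$direction[i]]
      if (length(other)) paste(other, collapse = ";") else NA_character_
    }, character(1L))
    x
  }
  prune <- function(region_records) {
    kept <- region_records[!key(region_records) %in% ckeys, , drop = FALSE]
    rownames(kept) <- NULL
    relink_duals(kept)
  }
  alm <- prune(alm_full_records)
  visp <- prune(visp_full_records)
  star_genes <- intersect(conserved_records$gene,
                          c(alm$gene, visp$gene))
  conserved_records$asterisk <- conserved_records$gene %in% star_genes
  alm$asterisk <- alm$gene %in% star_genes
  visp$asterisk <- visp$gene %in% star_genes
  list(conserved = conserved_records, alm = alm, visp = visp)
}

#' Run the full class-relevance analysis on a collapsed table
#'
#' Convenience wrapper: builds the conserved, full-ALM and full-VISp
#' subsets, runs [identify_class_relevant()] on each, and reconciles them.
#'
#' @param collapsed output of [collapse_de()].
#' @return list `conserved` / `alm` / `visp` as in [reconcile_regional()].
#' @export
class_relevance <- function(collapsed) {
  reconcile_regional(
    identify_class_relevant(regional_subset(collapsed, "conserved"),
                            "conserved"),
    identify_class_relevant(regional_subset(collapsed, "ALM"), "ALM"),
    identify_class_relevant(regional_subset(collapsed, "VISp"), "VISp"))
}

# Region-bias queries --------------------------------------------------------

empty_bias_records <- function() {
  data.frame(gene = character(), group = character(),
             biased_to = character(), scope = character(),
             stringsAsFactors = FALSE)
}

cross_sign_matrix <- function(cross_de, classes) {
  cross_de <- cross_de[cross_de$kind == "cross_region" &
                         cross_de$class_a %in% classes, , drop = FALSE]
  genes <- unique(cross_de$gene)
  m <- matrix(0, nrow = length(genes), ncol = length(classes),
              dimnames = list(genes, classes))
  if (nrow(cross_de))
    m[cbind(match(cross_de$gene, genes),
            match(cross_de$class_a, classes))] <- sign(cross_de$avg_logFC)
  m
}

#' Genes with uniform expression bias to one region across a whole group
#'
#' A gene qualifies when it is significant in the cross-region (ALM vs VISp)
#' test of every class in the group, with the same fold-change sign
#' throughout: all positive means biased to ALM (ALM is always the first
#' region), all negative to VISp.
#'
#' @param cross_de significant cross-region results from [run_de_plan()]
#'   (within-region rows are ignored).
#' @param group `"glutamatergic"` or `"GABAergic"`.
#' @param plan optional comparison plan used to verify that every class's
#'   cross-region test was actually run (absence of rows alone cannot
#'   distinguish "not significant" from "not tested").
#' @return data.frame: `gene`, `group`, `biased_to`, `scope = "all-classes"`.
#' @export
region_biased_genes <- function(cross_de, group, plan = NULL) {
  classes <- classes_of_group(group)
  if (!is.null(plan)) {
    ran <- plan$class_a[plan$kind == "cross_region" & plan$group == group]
    miss <- setdiff(classes, ran)
    if (length(miss))
      stop("cross-region test missing for class(es): ",
           paste(miss, collapse = ", "))
  }
  m <- cross_sign_matrix(cross_de, classes)
  all_pos <- rowSums(m > 0) == length(classes)
  all_neg <- rowSums(m < 0) == length(classes)
  hit <- all_pos | all_neg
  if (!any(hit)) return(empty_bias_records())
  out <- data.frame(gene = rownames(m)[hit], group = group,
                    biased_to = ifelse(all_pos[hit], "ALM", "VISp"),
                    scope = "all-classes", row.names = NULL)
  out[order(out$gene), , drop = FALSE]
}

#' Interneuron region-bias split by embryonic origin
#'
#' PV and SST interneurons share a medial ganglionic eminence origin while
#' VIP interneurons derive from the caudal ganglionic eminence, so the
#' cross-region results are also queried per origin: "VIP-only" genes are
#' significant in the VIP cross-region test but in neither the PV nor the
#' SST test; "PV&SST-only" genes are significant with a uniform sign in both
#' the PV and SST tests but not in VIP.
#'
#' @inheritParams region_biased_genes
#' @return data.frame: `gene`, `group = "GABAergic"`, `biased_to`, `scope`.
#' @export
origin_specific_genes <- function(cross_de, plan = NULL) {
  classes <- classes_of_group("GABAergic")
  if (!is.null(plan)) {
    ran <- plan$class_a[plan$kind == "cross_region" &
                          plan$group == "GABAergic"]
    miss <- setdiff(classes, ran)
    if (length(miss))
      stop("cross-region test missing for class(es): ",
           paste(miss, collapse = ", "))
  }
  m <- cross_sign_matrix(cross_de, classes)
  if (!nrow(m)) return(empty_bias_records())
  vip_only <- m[, "VIP"] != 0 & m[, "PV"] == 0 & m[, "SST"] == 0
  mge_only <- m[, "VIP"] == 0 & m[, "PV"] != 0 & m[, "SST"] != 0 &
    m[, "PV"] == m[, "SST"]
  rows <- list(empty_bias_records())
  if (any(vip_only))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(m)[vip_only], group = "GABAergic",
      biased_to = ifelse(m[vip_only, "VIP"] > 0, "ALM", "VISp"),
      scope = "VIP-only", row.names = NULL)
  if (any(mge_only))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = rownames(m)[mge_only], group = "GABAergic",
      biased_to = ifelse(m[mge_only, "PV"] > 0, "ALM", "VISp"),
      scope = "PV&SST-only", row.names = NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$scope, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
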