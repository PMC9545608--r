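# Region-specificity collapse: pair analogous within-region comparisons
# across ALM and VISp and categorize each gene's result as ALM-specific,
# VISp-specific, conserved, or divergent.

#' Match analogous within-region comparisons across regions
#'
#' Two within-region comparison specs are analogous when they test the same
#' ordered class pair of the same neurotransmitter group in the two regions
#' (e.g. GABAergic ALM "SST vs PV" and GABAergic VISp "SST vs PV").
#'
#' @param specs data.frame of within-region rows from
#'   [build_comparison_plan()].
#' @return data.frame with one row per pair: `group`, `pair`, `class_a`,
#'   `class_b`, `alm_id`, `visp_id`.
#' @export
match_analogous <- function(specs) {
  if (any(specs$kind != "within_region"))
    stop("match_analogous expects within-region comparison specs only")
  key <- paste(specs$group, specs$pair)
  out <- lapply(unique(key), function(k) {
    rows <- specs[key == k, , drop = FALSE]
    alm <- rows[rows$region == "ALM", , drop = FALSE]
    visp <- rows[rows$region == "VISp", , drop = FALSE]
    if (nrow(alm) != 1L || nrow(visp) != 1L)
      stop("comparison '", k, "' lacks an analogue in one region")
    data.frame(group = alm$group, pair = alm$pair, class_a = alm$class_a,
               class_b = alm$class_b, alm_id = alm$comparison_id,
               visp_id = visp$comparison_id, row.names = NULL)
  })
  do.call(rbind, out)
}

collapsed_columns <- function() {
  data.frame(gene = character(), class_a = character(),
             class_b = character(), pair = character(), group = character(),
             category = character(), avg_logFC_alm = numeric(),
             avg_logFC_visp = numeric(), avg_logFC = numeric(),
             stringsAsFactors = FALSE)
}

#' Collapse analogous cross-region differential expression results
#'
#' For every (gene, class pair) with at least one significant within-region
#' result: significant in both regions with the same fold-change sign is
#' "conserved" (the two values are averaged into one); significant in both
#' with opposite signs is "divergent" (both regional values kept, no
#' average); significant in ALM or VISp only gives "ALM-specific" /
#' "VISp-specific" carrying that region's value. Categories are therefore
#' mutually exclusive and exhaustive over the possible significance/sign
#' patterns.
#'
#' @param de significant within-region results, either one combined table
#'   from [run_de_plan()] (cross-region rows are ignored) or the ALM table
#'   if `de_visp` is supplied.
#' @param de_visp optional VISp table when ALM and VISp results are held
#'   separately.
#' @return data.frame with one row per (gene, class pair): `gene`,
#'   `class_a`, `class_b`, `pair`, `group`, `category`, `avg_logFC_alm`,
#'   `avg_logFC_visp`, `avg_logFC` (the collapsed value; NA for divergent),
#'   plus `go_terms` / `risk_flag` / `risk_category` unions when the inputs
#'   carry them. Ordered by group, pair, gene.
#' @export
collapse_de <- function(de, de_visp = NULL) {
  if (!is.null(de_visp)) de <- rbind(de, de_visp)
  de <- de[de$kind == "within_region", , drop = FALSE]
  has_anno <- !is.null(de$go_terms)
  has_risk <- !is.null(de$risk_flag)
  if (nrow(de) && any(de$avg_logFC == 0))
    stop("significant row with avg_logFC exactly 0 violates the ",
         "fold-change pre-filter")
  if (!nrow(de)) {
    out <- collapsed_columns()
    if (has_anno) out$go_terms <- character()
    if (has_risk) { out$risk_flag <- logical(); out$risk_category <- character() }
    return(out)
  }
  key <- paste(de$group, de$pair, de$gene, sep = "\r")
  rows <- lapply(split(seq_len(nrow(de)), key), function(i) {
    sub <- de[i, , drop = FALSE]
    alm <- sub[sub$region == "ALM", , drop = FALSE]
    visp <- sub[sub$region == "VISp", , drop = FALSE]
    if (nrow(alm) > 1L || nrow(visp) > 1L)
      stop("duplicate result for gene ", sub$gene[1L], " in ", sub$pair[1L])
    lfc_alm <- if (nrow(alm)) alm$avg_logFC else NA_real_
    lfc_visp <- if (nrow(visp)) visp$avg_logFC else NA_real_
    if (nrow(alm) && nrow(visp)) {
      if (sign(lfc_alm) == sign(lfc_visp)) {
        category <- "conserved"; lfc <- (lfc_alm + lfc_visp) / 2
      } else {
        category <- "divergent"; lfc <- NA_real_
      }
    } else if (nrow(alm)) {
      category <- "ALM-specific"; lfc <- lfc_alm
    } else {
      category <- "VISp-specific"; lfc <- lfc_visp
    }
    out <- data.frame(gene = sub$gene[1L], class_a = sub$class_a[1L],
                      class_b = sub$class_b[1L], pair = sub$pair[1L],
                      group = sub$group[1L], category = category,
                      avg_logFC_alm = lfc_alm, avg_logFC_visp = lfc_visp,
                      avg_logFC = lfc, row.names = NULL)
    if (has_anno)
      out$go_terms <- paste(sort(unique(unlist(
        strsplit(sub$go_terms, ";", fixed = TRUE)))), collapse = ";")
    if (has_risk) {
      out$risk_flag <- any(sub$risk_flag)
      rc <- unique(stats::na.omit(sub$risk_category))
      out$risk_category <- if (length(rc)) rc[1L] else NA_character_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$pair, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a collapsed table as CSV
#'
#' @param collapsed output of [collapse_de()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_collapsed_csv <- function(collapsed, path) {
  utils::write.csv(collapsed, path, row.names = FALSE)
  invisible(path)
}
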