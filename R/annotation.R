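# Circuit-related gene filtering (gene sets supplied as GMT files) and
# risk-gene flagging (SFARI-style CSV).

normalize_symbol <- function(x) toupper(trimws(x))

#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member symbols. Symbols are uppercased for case-insensitive matching
#' (the source data mixes Nrxn1 / nrxn1 style symbols); duplicates within a
#' line are removed.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `GeneSetCollection`),
#'   e.g. the three circuit-related categories CCA (cell-cell adhesion),
#'   RCCA (regulation of cell-cell adhesion) and RTSS (regulation of
#'   trans-synaptic signaling).
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " (need >= 3 tab-separated fields)")
    sets[[fields[1L]]] <- unique(normalize_symbol(fields[-(1:2)]))
  }
  structure(sets, class = "GeneSetCollection")
}

#' Restrict a differential-expression table to circuit-related genes
#'
#' Keeps rows whose gene belongs to the union of the supplied sets and
#' annotates each retained row with every set label it matches (in
#' `go_terms`, ";"-joined). Matching is exact after whitespace stripping,
#' then case-insensitive; row order is preserved and filtering is
#' idempotent.
#'
#' @param de differential-expression table (any table with a `gene` column).
#' @param sets a [load_gene_sets()] collection (or plain named list of
#'   symbol vectors).
#' @return subset of `de` with a `go_terms` column.
#' @export
filter_circuit_related <- function(de, sets) {
  syms <- normalize_symbol(de$gene)
  labels <- vapply(syms, function(s) {
    hit <- names(sets)[vapply(sets, function(set) s %in% set, logical(1L))]
    paste(hit, collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  keep <- nzchar(labels)
  out <- de[keep, , drop = FALSE]
  out$go_terms <- labels[keep]
  rownames(out) <- NULL
  out
}

#' Load a risk-gene list from CSV
#'
#' Expects columns `gene` and `category` (e.g. Suggestive Evidence, Strong
#' Candidate, High Confidence, Syndromic). All categories are retained.
#'
#' @param path CSV file.
#' @return data.frame with normalized `gene` symbols and `category`.
#' @export
load_risk_genes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "category"), names(x))
  if (length(miss))
    stop("risk-gene CSV lacks column(s): ", paste(miss, collapse = ", "))
  x$gene <- normalize_symbol(x$gene)
  x[!duplicated(x$gene), c("gene", "category"), drop = FALSE]
}

#' Flag risk genes in a results table
#'
#' Sets `risk_flag` to TRUE for rows whose gene appears in the risk list and
#' carries the list's category through in `risk_category`.
#'
#' @param records any table with a `gene` column.
#' @param risk a [load_risk_genes()] table (or data.frame with `gene`,
#'   `category`); an empty table flags nothing.
#' @return `records` with `risk_flag` and `risk_category` columns.
#' @export
flag_risk_genes <- function(records, risk) {
  syms <- normalize_symbol(records$gene)
  idx <- match(syms, risk$gene)
  records$risk_flag <- !is.na(idx)
  records$risk_category <- ifelse(is.na(idx), NA_character_,
                                  risk$category[idx])
  records
}
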