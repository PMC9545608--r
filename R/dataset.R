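# ExpressionDataset: the root container — raw counts plus per-cell labels.

as_dgc <- function(m) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' Build a class-labeled expression dataset
#'
#' Bundles a gene x cell raw count matrix with per-cell metadata (region,
#' class, neurotransmitter group). The class-to-group mapping is fixed and
#' validated; the group column is derived from the class labels and must not
#' contradict them if supplied.
#'
#' @param counts gene x cell matrix of nonnegative integer counts (dense or
#'   `Matrix` sparse); rownames are gene symbols, colnames are cell ids.
#' @param cells data.frame with one row per column of `counts`, columns
#'   `cell_id`, `region` (ALM or VISp) and `class` (one of the seven
#'   analyzed classes). A `group` column is added (or checked) from the
#'   fixed class-to-group map.
#' @return object of class `ExpressionDataset`: list with elements `counts`
#'   (a `dgCMatrix`) and `cells`.
#' @export
expression_dataset <- function(counts, cells) {
  counts <- as_dgc(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must carry unique gene symbols as rownames")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be nonnegative integers")
  cells <- as.data.frame(cells)
  need <- c("cell_id", "region", "class")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) != ncol(counts))
    stop("cell metadata rows (", nrow(cells), ") do not match count matrix ",
         "columns (", ncol(counts), ")")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id values")
  bad_region <- setdiff(unique(cells$region), cortical_regions())
  if (length(bad_region))
    stop("unknown region(s): ", paste(bad_region, collapse = ", "))
  grp <- group_of_class(cells$class)
  if (!is.null(cells$group) && !identical(as.character(cells$group), grp))
    stop("supplied group column contradicts the fixed class-to-group map")
  cells$group <- grp
  if (is.null(colnames(counts))) colnames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells\n")
  print(table(x$cells$region, x$cells$class))
  invisible(x)
}

#' Subset an expression dataset by cell
#'
#' @param dataset an [expression_dataset()].
#' @param region,class,group optional filters; `NULL` keeps all.
#' @return an `ExpressionDataset` restricted to the matching cells.
#' @export
subset_cells <- function(dataset, region = NULL, class = NULL, group = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep <- rep(TRUE, nrow(dataset$cells))
  if (!is.null(region)) keep <- keep & dataset$cells$region %in% region
  if (!is.null(class))  keep <- keep & dataset$cells$class %in% class
  if (!is.null(group))  keep <- keep & dataset$cells$group %in% group
  expression_dataset(dataset$counts[, keep, drop = FALSE],
                     dataset$cells[keep, , drop = FALSE])
}

#' Read and write expression datasets as MTX plus TSV sidecars
#'
#' On disk a dataset is three plain-text files in `dir`: `counts.mtx`
#' (MatrixMarket, genes x cells), `genes.tsv` (one symbol per line) and
#' `cells.tsv` (tab-separated: cell_id, region, class, group).
#'
#' @param dataset an [expression_dataset()].
#' @param dir directory to write to / read from (created if absent).
#' @return `write_expression_dataset` returns `dir` invisibly;
#'   `read_expression_dataset` returns an `ExpressionDataset`.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(dataset$counts), file.path(dir, "genes.tsv"))
  utils::write.table(
    dataset$cells[, c("cell_id", "region", "class", "group")],
    file.path(dir, "cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- cells$cell_id
  expression_dataset(counts, cells)
}
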