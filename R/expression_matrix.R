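#' Construct an ExpressionMatrix
#'
#' The pipeline's universal input: a cells x genes matrix of non-negative
#' expression values with per-cell annotations. Values may be raw counts or
#' normalized units; the `normalized` flag records which. All gene-wise
#' statistics in the package are computed over the cell axis, so the matrix is
#' always stored cells x genes regardless of on-disk orientation.
#'
#' @param values numeric matrix or sparse \code{Matrix}, cells x genes,
#'   non-negative and finite.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param condition per-cell binary label: 0 = control/air, 1 = exposed/smoke.
#' @param cell_type per-cell categorical label.
#' @param sample_id per-cell categorical label (mouse/donor of origin).
#' @param dataset_tag single string tagging the dataset of origin.
#' @param normalized logical flag; \code{FALSE} for raw counts.
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, condition,
                              cell_type = rep("cell", length(cell_ids)),
                              sample_id = rep("s1", length(cell_ids)),
                              dataset_tag = "dataset",
                              normalized = FALSE) {
  if (!is(values, "Matrix")) values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids))
    stop("values must be cells x genes (", length(cell_ids), " x ", length(gene_ids), ")")
  v <- values@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop("expression values must be finite and non-negative")
  for (nm in c("condition", "cell_type", "sample_id")) {
    a <- get(nm)
    if (length(a) != length(cell_ids))
      stop(nm, " must have exactly one entry per cell")
  }
  condition <- as.integer(condition)
  if (!all(condition %in% c(0L, 1L))) stop("condition must be binary 0/1")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values,
                 gene_ids = gene_ids,
                 cell_ids = cell_ids,
                 condition = condition,
                 cell_type = as.character(cell_type),
                 sample_id = as.character(sample_id),
                 dataset_tag = as.character(dataset_tag)[1],
                 normalized = isTRUE(normalized)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s, %s]\n",
              n_cells(x), n_genes(x), x$dataset_tag,
              if (x$normalized) "normalized" else "raw counts"))
  cat(sprintf("  condition: %d control / %d exposed; cell types: %s\n",
              sum(x$condition == 0), sum(x$condition == 1),
              paste(unique(x$cell_type), collapse = ", ")))
  invisible(x)
}

#' Number of cells / genes in an ExpressionMatrix
#' @param x an \code{ExpressionMatrix}.
#' @return integer count.
#' @export
n_cells <- function(x) length(x$cell_ids)

#' @rdname n_cells
#' @export
n_genes <- function(x) length(x$gene_ids)

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param x an \code{ExpressionMatrix}.
#' @param cells logical/integer/character index over cells, or NULL to keep all.
#' @param genes logical/integer/character index over genes, or NULL to keep all.
#' @return the subset \code{ExpressionMatrix}.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else cells
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else genes
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  if (is.character(gi)) gi <- match(gi, x$gene_ids)
  expression_matrix(x$values[ci, gi, drop = FALSE],
                    gene_ids = x$gene_ids[gi], cell_ids = x$cell_ids[ci],
                    condition = x$condition[ci], cell_type = x$cell_type[ci],
                    sample_id = x$sample_id[ci], dataset_tag = x$dataset_tag,
                    normalized = x$normalized)
}
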