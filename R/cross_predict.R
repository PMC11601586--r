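# Gene-set transfer: score a target dataset's cells with a factor gene set
# learned on a source cell type/dataset, and test whether the score separates
# the exposure groups.

#' Build a transferable factor gene set from a fitted model
#'
#' @param model a `LoveModel`.
#' @param factor integer factor index.
#' @param source_tag,source_cell_type provenance strings.
#' @return a `FactorGeneSet`: list with `factor`, `genes`, `weights`,
#'   `source_tag`, `source_cell_type`.
#' @export
factor_gene_set <- function(model, factor, source_tag = "",
                            source_cell_type = "") {
  asg <- definitive_assignment(model$allocation)
  genes <- names(asg)[!is.na(asg) & asg == factor]
  if (!length(genes)) stop("factor ", factor, " has no assigned genes")
  structure(list(factor = factor, genes = genes,
                 weights = setNames(model$allocation[genes, factor], genes),
                 source_tag = source_tag, source_cell_type = source_cell_type),
            class = "FactorGeneSet")
}

#' Score target cells with a transferred factor gene set
#'
#' `score(cell) = sum_g w_g * z_g(cell)` over the genes of the set measured in
#' the target, where `z_g` is the gene's column-standardized expression.
#' Gene symbols match case-insensitively (no ortholog mapping). With
#' `mode = "mean"` the unweighted mean of z-scores is used instead.
#'
#' @param gene_set a `FactorGeneSet` (or list with `genes` and `weights`).
#' @param X_target normalized [expression_matrix()].
#' @param mode `"weighted"` (default) or `"mean"`.
#' @return numeric per-cell score with attribute `coverage` (fraction of the
#'   set measured in the target).
#' @export
project_score <- function(gene_set, X_target, mode = c("weighted", "mean")) {
  mode <- match.arg(mode)
  idx <- match(tolower(gene_set$genes), tolower(X_target$gene_ids))
  hit <- !is.na(idx)
  if (!any(hit))
    stop("no gene of the set is measured in the target; missing: ",
         paste(head(gene_set$genes, 10), collapse = ", "))
  V <- as_dense(X_target$values[, idx[hit], drop = FALSE])
  sds <- apply(V, 2, sd)
  Zg <- scale(V)
  Zg[, sds == 0] <- 0
  w <- if (mode == "weighted") gene_set$weights[hit] else rep(1 / sum(hit), sum(hit))
  score <- as.numeric(Zg %*% w)
  attr(score, "coverage") <- mean(hit)
  score
}

#' Test whether a per-cell score predicts the exposure group
#'
#' AUC by the rank (Mann-Whitney U) statistic plus a two-sided Mann-Whitney
#' p-value (exact for group sizes up to 8, tie-corrected normal approximation
#' otherwise).
#'
#' @param score per-cell numeric score.
#' @param condition per-cell binary labels.
#' @return list with `auc`, `mann_whitney_p`, `n0`, `n1`.
#' @export
predict_group <- function(score, condition) {
  g0 <- score[condition == 0]; g1 <- score[condition == 1]
  if (!length(g0) || !length(g1)) stop("both groups must be non-empty")
  mw <- mann_whitney(g0, g1)
  list(auc = mw$auc, mann_whitney_p = mw$p,
       n0 = length(g0), n1 = length(g1))
}

#' Pearson correlation network among factor member genes
#'
#' Nodes are the given genes; an edge joins two genes iff the absolute Pearson
#' correlation of their expression is at least `cutoff` (absolute so strong
#' negative correlations are retained; set `signed = TRUE` to threshold the
#' signed value instead). Edge weight is the signed correlation. Constant
#' genes keep their node but get no edges, with a warning.
#'
#' @param X normalized [expression_matrix()].
#' @param genes member gene ids (at least 2).
#' @param cutoff correlation magnitude threshold, inclusive (default 0.1).
#' @param signed threshold `r >= cutoff` instead of `|r| >= cutoff`.
#' @return an \pkg{igraph} gene network with node `intensity` attributes.
#' @export
correlation_network <- function(X, genes, cutoff = 0.1, signed = FALSE) {
  stopifnot(length(genes) >= 2)
  idx <- match(genes, X$gene_ids)
  if (anyNA(idx)) stop("genes missing from matrix: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  V <- as_dense(X$values[, idx, drop = FALSE])
  sds <- apply(V, 2, sd)
  if (any(sds == 0))
    warning("constant gene(s) retained without edges: ",
            paste(genes[sds == 0], collapse = ", "))
  R <- suppressWarnings(cor(V))
  R[!is.finite(R)] <- 0
  keep <- if (signed) R >= cutoff else abs(R) >= cutoff
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[ij[, 1]], to = genes[ij[, 2]],
               weight = R[ij], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = genes))
  g <- igraph::set_vertex_attr(g, "role", value = rep("marker", length(genes)))
  igraph::set_vertex_attr(g, "intensity", value = colMeans(V))
}
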