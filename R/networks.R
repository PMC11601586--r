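# Nested factorization and network assembly: exclusive gene-to-factor
# assignment, split into principal gene groups, nested re-factorization,
# top-feature extraction, median-nonzero quantile noise filtering, and
# "OR"-logic protein-interaction subnetwork construction.

#' Exclusive gene-to-factor assignment by maximal absolute weight
#'
#' @param A genes x factors allocation matrix (rownames = gene ids).
#' @return named integer vector mapping each gene to its factor (NA for
#'   all-zero rows, reported as unassigned). Ties go to the lowest factor
#'   index.
#' @export
definitive_assignment <- function(A) {
  stopifnot(ncol(A) >= 1)
  out <- apply(abs(A), 1, function(r) if (all(r == 0)) NA_integer_ else which.max(r))
  setNames(as.integer(out), rownames(A))
}

#' Split genes into the two principal factors
#'
#' Returns the gene groups of the two largest factors after definitive
#' assignment. The two-group structure (housekeeping vs. functional genes) is
#' an empirical observation, not a guarantee: if more than two factors remain,
#' a warning reports all group sizes and the two largest are returned.
#'
#' @param model a `LoveModel` (or bare allocation matrix).
#' @return list of two character vectors of gene ids (largest first).
#' @export
principal_split <- function(model) {
  A <- if (is.list(model)) model$allocation else model
  asg <- definitive_assignment(A)
  tab <- sort(table(asg), decreasing = TRUE)
  if (length(tab) < 2) stop("no split possible: a single factor after assignment")
  if (length(tab) > 2)
    warning("more than 2 factors after assignment (sizes: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
            "); taking the two largest")
  top2 <- as.integer(names(tab)[1:2])
  lapply(top2, function(f) names(asg)[!is.na(asg) & asg == f])
}

#' Re-run the factor model independently within gene groups
#'
#' @param X normalized [expression_matrix()].
#' @param groups list of gene-id vectors (e.g. from [principal_split()]).
#' @param delta_grid,lambda_grid,seed,... passed to [fit_love()].
#' @param min_genes groups smaller than this are skipped with a warning
#'   (default 10).
#' @return named list of `LoveModel`s, one per retained group (names
#'   `group1`, `group2`, ...), factor ids namespaced by group.
#' @export
nested_love <- function(X, groups,
                        delta_grid = c(0.02, 0.05, 0.08, 0.12, 0.16, 0.20),
                        lambda_grid = c(0, 0.01, 0.05, 0.1),
                        seed = 1L, min_genes = 10, ...) {
  out <- list()
  for (i in seq_along(groups)) {
    g <- intersect(groups[[i]], X$gene_ids)
    if (length(g) < min_genes) {
      warning("group ", i, " has ", length(g), " genes (< ", min_genes, "); skipped")
      next
    }
    Xi <- subset_cells(X, genes = g)
    m <- tryCatch(
      fit_love(Xi, delta_grid, lambda_grid, seed = derive_seed(seed, i), ...),
      error = function(e) {
        warning("group ", i, " factorization failed (", conditionMessage(e),
                "); skipped")
        NULL
      })
    if (is.null(m)) next
    colnames(m$allocation) <- paste0("G", i, ".", colnames(m$allocation))
    out[[paste0("group", i)]] <- m
  }
  if (!length(out)) stop("no group large enough for nested factorization")
  out
}

#' Top-weighted genes of each factor
#'
#' Per factor, the `k` definitively assigned genes of largest absolute
#' allocation weight (fewer if the factor is smaller; ties broken by gene
#' order).
#'
#' @param model a `LoveModel` (or allocation matrix).
#' @param k list length per factor (default 50).
#' @return named list (one entry per factor) of gene-id vectors, ranked.
#' @export
top_features <- function(model, k = 50) {
  A <- if (is.list(model)) model$allocation else model
  asg <- definitive_assignment(A)
  lapply(setNames(seq_len(ncol(A)), colnames(A)), function(f) {
    members <- names(asg)[!is.na(asg) & asg == f]
    if (!length(members)) return(character(0))
    w <- abs(A[members, f])
    members[order(-w, seq_along(w))][seq_len(min(k, length(members)))]
  })
}

# Median of the non-zero values of a vector; -Inf when all zero (lowest rank).
median_nonzero <- function(v) {
  nz <- v[v != 0]
  if (!length(nz)) -Inf else median(nz)
}

#' Filter candidate genes by median non-zero expression in both conditions
#'
#' Per condition, each candidate's median over its non-zero values is ranked
#' among the candidates; a gene is excluded iff its median falls in the lowest
#' `q`-quantile in BOTH conditions (lower boundary inclusive). Genes with no
#' non-zero values in a condition take the lowest rank there.
#'
#' @param X_cond0,X_cond1 [expression_matrix()] objects for the two conditions.
#' @param candidates gene ids present in both matrices.
#' @param q quantile defining "lowest" (default 0.25 — the lowest quartile).
#' @return character vector of kept gene ids (original order).
#' @export
median_nonzero_filter <- function(X_cond0, X_cond1, candidates, q = 0.25) {
  in_lowest <- function(X) {
    idx <- match(candidates, X$gene_ids)
    if (anyNA(idx)) stop("candidates missing from matrix: ",
                         paste(candidates[is.na(idx)], collapse = ", "))
    med <- apply(as_dense(X$values[, idx, drop = FALSE]), 2, median_nonzero)
    med <= quantile(med, q)
  }
  low <- in_lowest(X_cond0) & in_lowest(X_cond1)
  candidates[!low]
}

#' Build a protein-interaction subnetwork around marker genes
#'
#' OR logic (default) keeps every interactome edge with at least one endpoint
#' in the marker set, pulling in first-neighbor interactors; AND logic keeps
#' only edges with both endpoints among markers. Gene-symbol matching is
#' case-insensitive; node ids keep the interactome's case. Nodes get a `role`
#' attribute (`marker`/`interactor`) and, where measured, an `intensity`
#' attribute (mean normalized expression over the group's cells).
#'
#' @param markers character vector of marker gene symbols (non-empty).
#' @param interactome undirected \pkg{igraph} graph from [read_interactome()].
#' @param logic `"OR"` (default) or `"AND"`.
#' @param X_group optional [expression_matrix()] of the condition/cell-type
#'   group, used for node intensities.
#' @return an \pkg{igraph} gene network (possibly empty, with a warning).
#' @export
build_subnetwork <- function(markers, interactome, logic = c("OR", "AND"),
                             X_group = NULL) {
  logic <- match.arg(logic)
  stopifnot(length(markers) > 0)
  nodes <- igraph::V(interactome)$name
  is_marker <- tolower(nodes) %in% tolower(markers)
  unmatched <- markers[!(tolower(markers) %in% tolower(nodes))]
  if (length(unmatched))
    rk_log("subnetwork: %d marker(s) not in interactome: %s",
           length(unmatched), paste(head(unmatched, 10), collapse = ", "))
  if (!any(is_marker)) {
    warning("no marker matches any interactome node; returning empty network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  el <- igraph::as_edgelist(interactome)
  m1 <- tolower(el[, 1]) %in% tolower(markers)
  m2 <- tolower(el[, 2]) %in% tolower(markers)
  keep <- if (logic == "OR") m1 | m2 else m1 & m2
  sub_nodes <- unique(c(el[keep, 1], el[keep, 2], nodes[is_marker]))
  g <- igraph::graph_from_data_frame(
    as.data.frame(el[keep, , drop = FALSE]), directed = FALSE,
    vertices = data.frame(name = sub_nodes))
  role <- ifelse(tolower(igraph::V(g)$name) %in% tolower(markers),
                 "marker", "interactor")
  g <- igraph::set_vertex_attr(g, "role", value = role)
  if (!is.null(X_group)) {
    idx <- match(tolower(igraph::V(g)$name), tolower(X_group$gene_ids))
    intensity <- rep(NA_real_, length(idx))
    meas <- !is.na(idx)
    if (any(meas))
      intensity[meas] <- Matrix::colMeans(X_group$values[, idx[meas], drop = FALSE])
    g <- igraph::set_vertex_attr(g, "intensity", value = intensity)
  }
  g
}
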