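# Readers and writers for the pipeline's on-disk formats: Matrix Market
# triplets + TSV annotations, delimited dense tables, TSV edge lists,
# GraphML/SIF network export, and GMT gene-set collections.

#' Read an expression matrix with per-cell annotations
#'
#' @param path path to the matrix: a Matrix Market `.mtx` triplet file or a
#'   delimited table with cell ids as row names and gene ids as column names.
#' @param format `"matrix-market-triplet"` or `"delimited-table"`.
#' @param annotations path to a TSV with one row per cell and columns
#'   `cell_id`, `condition`, `cell_type`, `sample_id` (and optionally
#'   `dataset_tag`). Row order must match the matrix rows after orientation.
#' @param genes for the Matrix Market format, path to a one-column file of gene
#'   ids (one per matrix column after orientation). Ignored for tables.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`,
#'   declaring the on-disk orientation; the returned object is always
#'   cells x genes.
#' @param normalized logical; whether values are already normalized.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            format = c("matrix-market-triplet", "delimited-table"),
                            annotations,
                            genes = NULL,
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            normalized = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  ann <- read.table(annotations, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("cell_id", "condition", "cell_type", "sample_id")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation file lacks columns: ", paste(miss, collapse = ", "))

  if (format == "matrix-market-triplet") {
    m <- Matrix::readMM(path)
    if (orientation == "genes_by_cells") m <- Matrix::t(m)
    if (is.null(genes)) stop("Matrix Market input needs a `genes` id file")
    gid <- readLines(genes)
    gid <- gid[nzchar(gid)]
    if (length(gid) != ncol(m))
      stop("gene id count (", length(gid), ") != matrix gene axis (", ncol(m), ")")
    cid <- ann$cell_id
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
    if (orientation == "genes_by_cells") m <- Matrix::t(m)
    gid <- colnames(m)
    cid <- rownames(m)
    if (!is.null(cid) && !identical(cid, as.character(ann$cell_id)))
      ann <- ann[match(cid, ann$cell_id), , drop = FALSE]
  }
  if (nrow(ann) != nrow(m))
    stop("annotation rows (", nrow(ann), ") != cells in matrix (", nrow(m), ")")
  if (anyNA(ann$cell_id)) stop("annotation cell_id has missing entries")
  tag <- if ("dataset_tag" %in% names(ann)) ann$dataset_tag[1] else "dataset"
  expression_matrix(m, gene_ids = gid, cell_ids = as.character(ann$cell_id),
                    condition = ann$condition, cell_type = ann$cell_type,
                    sample_id = ann$sample_id, dataset_tag = tag,
                    normalized = normalized)
}

#' Write an expression matrix as Matrix Market triplets plus annotations
#'
#' Emits `<basename>.mtx`, `<basename>.genes.txt` and
#' `<basename>.annotations.tsv` so that [read_expression()] round-trips the
#' object exactly.
#'
#' @param X an [expression_matrix()].
#' @param basename path prefix for the three output files.
#' @return invisibly, the three file paths.
#' @export
write_expression <- function(X, basename) {
  mtx <- paste0(basename, ".mtx")
  gfile <- paste0(basename, ".genes.txt")
  afile <- paste0(basename, ".annotations.tsv")
  Matrix::writeMM(as(X$values, "generalMatrix"), mtx)
  writeLines(X$gene_ids, gfile)
  write.table(data.frame(cell_id = X$cell_ids, condition = X$condition,
                         cell_type = X$cell_type, sample_id = X$sample_id,
                         dataset_tag = X$dataset_tag,
                         stringsAsFactors = FALSE),
              afile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mtx, genes = gfile, annotations = afile))
}

#' Read an undirected protein-protein interactome from a two-column edge list
#'
#' Self-loops and duplicate edges (in either orientation) are dropped, with a
#' message reporting the counts.
#'
#' @param path delimited file (whitespace or tab) of gene-symbol pairs.
#' @return an undirected simple \pkg{igraph} graph.
#' @export
read_interactome <- function(path) {
  ed <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("empty or unreadable interactome file: ", path))
  if (nrow(ed) == 0) stop("empty interactome file: ", path)
  ed <- ed[, 1:2]
  n_loop <- sum(ed[[1]] == ed[[2]])
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  g0 <- g
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- igraph::ecount(g0) - igraph::ecount(g)
  rk_log("interactome: dropped %d self-loop/duplicate edges (%d self-loops in input)",
         dropped, n_loop)
  g
}

#' Export a gene network as GraphML and SIF
#'
#' Nodes carry a `role` attribute (`marker` or `interactor`) and, where the
#' gene was measured, a mean-expression `intensity` attribute. The SIF file
#' uses the interaction type `pp`; node attributes go to a companion
#' `.attrs.tsv` file so Cytoscape-style tooling can ingest them.
#'
#' @param net a gene network (\pkg{igraph} graph with `role`/`intensity`
#'   vertex attributes), e.g. from [build_subnetwork()] or
#'   [correlation_network()].
#' @param basename path prefix; writes `<basename>.graphml`, `<basename>.sif`
#'   and `<basename>.attrs.tsv`.
#' @return invisibly, the file paths.
#' @export
write_network <- function(net, basename) {
  gml <- paste0(basename, ".graphml")
  sif <- paste0(basename, ".sif")
  att <- paste0(basename, ".attrs.tsv")
  if (igraph::vcount(net) == 0) {
    warning("writing an empty network")
    # igraph refuses some empty exports; emit valid empty files by hand
    writeLines(character(0), sif)
    igraph::write_graph(net, gml, format = "graphml")
    write.table(data.frame(gene = character(0), role = character(0),
                           intensity = numeric(0)),
                att, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(c(graphml = gml, sif = sif, attrs = att)))
  }
  igraph::write_graph(net, gml, format = "graphml")
  el <- igraph::as_edgelist(net)
  lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
  solo <- setdiff(igraph::V(net)$name, unique(c(el)))
  writeLines(c(lines, solo), sif)
  role <- igraph::vertex_attr(net, "role")
  if (is.null(role)) role <- rep(NA_character_, igraph::vcount(net))
  intensity <- igraph::vertex_attr(net, "intensity")
  if (is.null(intensity)) intensity <- rep(NA_real_, igraph::vcount(net))
  write.table(data.frame(gene = igraph::V(net)$name, role = role,
                         intensity = intensity, stringsAsFactors = FALSE),
              att, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gml, sif = sif, attrs = att))
}

#' Read back a GraphML network written by [write_network()]
#' @param path the `.graphml` file.
#' @return an \pkg{igraph} graph.
#' @export
read_network <- function(path) igraph::read_graph(path, format = "graphml")

#' Read a GMT gene-set collection
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields fall back to the documented stage defaults; the resolved
#' configuration (defaults merged in) is what every run logs for provenance.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return a named list of stage parameters.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    qc = list(min_genes = 200, max_genes = 3000, max_mito_frac = 0.25,
              mito_prefix = "mt-"),
    normalize = list(scale = 1e4),
    sparsity = list(gene_zero_max = 0.995, cell_zero_max = 0.90),
    de = list(p_max = 0.05, lnfc_min = 0.1),
    enrichment = list(fdr_max = 0.10),
    love = list(delta_grid = c(0.02, 0.05, 0.08, 0.12, 0.16, 0.20),
                lambda_grid = c(0, 0.01, 0.05, 0.1),
                allow_singletons = FALSE, cv_repeats = 5),
    networks = list(top_k = 50, quantile_q = 0.25, logic = "OR"),
    slide = list(iterations = 300, spec = 0.2, fdr_level = 0.1,
                 folds = 10, replicates = 20, n_perm = 100,
                 w_statistic = "lasso"),
    crosspred = list(correlation_cutoff = 0.1, score_mode = "weighted"),
    seed = 1L)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  modifyList(defaults, user)
}

#' Write the resolved configuration and seed provenance for a run
#' @param config resolved configuration list.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
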