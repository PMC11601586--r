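# Quality filtering, normalization, differential expression and enrichment —
# the stages feeding both the unsupervised and supervised factorization paths.
#
# All quoted thresholds are strict inequalities: a cell must have MORE than
# `min_genes` detected genes, FEWER than `max_genes`, LESS than `max_mito_frac`
# mitochondrial fraction, and sparsity drops genes with OVER `gene_zero_max`
# zeros / cells with MORE than `cell_zero_max` zeros. Boundary values are kept
# or removed accordingly; the boundary tests pin this down.

#' Quality-filter cells of a raw-count matrix
#'
#' Keeps cells with detected-gene count strictly greater than `min_genes` and
#' strictly less than `max_genes`, and with a mitochondrial-count fraction
#' strictly below `max_mito_frac`. Mitochondrial genes are identified by a
#' case-insensitive id prefix.
#'
#' @param X raw-count [expression_matrix()].
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 3000).
#' @param max_mito_frac maximum mitochondrial count fraction (default 0.25).
#' @param mito_prefix gene-id prefix marking mitochondrial genes
#'   (default `"mt-"`, case-insensitive).
#' @return the filtered \code{ExpressionMatrix}.
#' @export
qc_filter_cells <- function(X, min_genes = 200, max_genes = 3000,
                            max_mito_frac = 0.25, mito_prefix = "mt-") {
  if (X$normalized) stop("qc_filter_cells expects raw counts")
  detected <- Matrix::rowSums(X$values > 0)
  is_mito <- startsWith(tolower(X$gene_ids), tolower(mito_prefix))
  tot <- Matrix::rowSums(X$values)
  mito <- if (any(is_mito)) Matrix::rowSums(X$values[, is_mito, drop = FALSE]) else rep(0, n_cells(X))
  mito_frac <- ifelse(tot > 0, mito / tot, 1)
  keep_lo <- detected > min_genes
  keep_hi <- detected < max_genes
  keep_mt <- mito_frac < max_mito_frac
  keep <- keep_lo & keep_hi & keep_mt
  rk_log("qc: removed %d low-gene, %d high-gene, %d high-mito cells (kept %d/%d)",
         sum(!keep_lo), sum(!keep_hi), sum(!keep_mt), sum(keep), length(keep))
  if (!any(keep)) stop("qc_filter_cells removed all cells")
  subset_cells(X, cells = which(keep))
}

#' Log-normalize a raw-count matrix
#'
#' Per cell, each value becomes `ln(1 + scale * value / cell_total)` — the
#' standard library-size normalization for single-cell counts.
#'
#' @param X raw-count [expression_matrix()].
#' @param scale library-size scale factor (default 1e4).
#' @return the normalized \code{ExpressionMatrix} (flagged `normalized`).
#' @export
normalize_log <- function(X, scale = 1e4) {
  if (X$normalized) stop("matrix is already normalized")
  tot <- Matrix::rowSums(X$values)
  if (any(tot == 0))
    stop("zero-total cell(s): ", paste(head(X$cell_ids[tot == 0]), collapse = ", "),
         " (should have been removed by QC)")
  v <- as(X$values, "CsparseMatrix")
  # column-oriented storage: recover each entry's row (cell) to scale by total
  rows <- v@i + 1L
  v@x <- log1p(scale * v@x / tot[rows])
  out <- X
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Drop high-sparsity genes, then high-sparsity cells
#'
#' Genes whose zero fraction strictly exceeds `gene_zero_max` are dropped
#' first; zero fractions are then recomputed and cells strictly exceeding
#' `cell_zero_max` are dropped. The gene-first order is fixed for determinism.
#'
#' @param X an [expression_matrix()] (any units).
#' @param gene_zero_max maximum gene zero fraction (default 0.995).
#' @param cell_zero_max maximum cell zero fraction (default 0.90).
#' @return the filtered \code{ExpressionMatrix}.
#' @export
sparsity_filter <- function(X, gene_zero_max = 0.995, cell_zero_max = 0.90) {
  gz <- 1 - Matrix::colSums(X$values > 0) / n_cells(X)
  keep_g <- gz <= gene_zero_max
  if (!any(keep_g)) stop("sparsity_filter removed all genes")
  X2 <- subset_cells(X, genes = which(keep_g))
  cz <- 1 - Matrix::rowSums(X2$values > 0) / n_genes(X2)
  keep_c <- cz <= cell_zero_max
  rk_log("sparsity: dropped %d genes, %d cells", sum(!keep_g), sum(!keep_c))
  if (!any(keep_c)) stop("sparsity_filter removed all cells")
  subset_cells(X2, cells = which(keep_c))
}

# Mann-Whitney U and two-sided p for two samples. Exact enumeration over all
# C(n, n1) group assignments when both groups have <= `exact_max` values
# (handles ties, unlike the textbook exact distribution); otherwise the
# tie-corrected normal approximation without continuity correction.
mann_whitney <- function(x0, x1, exact_max = 8) {
  n0 <- length(x0); n1 <- length(x1)
  if (n0 == 0 || n1 == 0) stop("both groups must be non-empty")
  v <- c(x0, x1)
  r <- rank(v)
  U <- sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  mu <- n0 * n1 / 2
  if (n0 <= exact_max && n1 <= exact_max) {
    idx <- combn(n0 + n1, n1)
    d_obs <- abs(U - mu)
    dists <- apply(idx, 2, function(g1) {
      abs(sum(r[g1]) - n1 * (n1 + 1) / 2 - mu)
    })
    p <- mean(dists >= d_obs - 1e-12)
  } else {
    n <- n0 + n1
    ties <- table(v)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n0 * n1 / 12 * ((n + 1) - tie_corr)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = U, p = p, auc = U / (n0 * n1))
}

#' Wilcoxon rank-sum differential expression between conditions
#'
#' Per gene: a two-sided rank-sum p-value (exact enumeration when both groups
#' have at most 8 cells, tie-corrected normal approximation otherwise), the
#' natural-log fold change
#' `lnFC = ln[(mean(expm1(exposed)) + 1) / (mean(expm1(control)) + 1)]`
#' computed on de-logged normalized values with pseudocount 1, and
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param X normalized [expression_matrix()].
#' @param condition optional binary vector overriding `X$condition`.
#' @return a data.frame with columns `gene`, `lnFC`, `p_value`, `p_adjusted`,
#'   `mean_control`, `mean_exposed` (group means of de-logged expression).
#' @export
wilcoxon_de <- function(X, condition = X$condition) {
  if (!X$normalized) stop("wilcoxon_de expects normalized values")
  g0 <- which(condition == 0); g1 <- which(condition == 1)
  if (!length(g0) || !length(g1)) stop("both condition groups must be non-empty")
  V <- as_dense(X$values)
  res <- vapply(seq_len(ncol(V)), function(j) {
    x0 <- V[g0, j]; x1 <- V[g1, j]
    mw <- mann_whitney(x0, x1)
    m0 <- mean(expm1(x0)); m1 <- mean(expm1(x1))
    c(lnFC = log((m1 + 1) / (m0 + 1)), p = mw$p, m0 = m0, m1 = m1)
  }, numeric(4))
  data.frame(gene = X$gene_ids,
             lnFC = res["lnFC", ],
             p_value = res["p", ],
             p_adjusted = p.adjust(res["p", ], method = "BH"),
             mean_control = res["m0", ],
             mean_exposed = res["m1", ],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select significant differentially expressed genes
#'
#' Strict thresholds on the raw p-value and absolute lnFC:
#' `p_value < p_max` AND `|lnFC| > lnfc_min`.
#'
#' @param de result of [wilcoxon_de()].
#' @param p_max raw p-value cutoff (default 0.05, exclusive).
#' @param lnfc_min absolute lnFC cutoff (default 0.1, exclusive).
#' @return list with `up`, `down` and `all` gene-id vectors.
#' @export
de_significant <- function(de, p_max = 0.05, lnfc_min = 0.1) {
  sig <- de$p_value < p_max & abs(de$lnFC) > lnfc_min
  list(up = de$gene[sig & de$lnFC > 0],
       down = de$gene[sig & de$lnFC < 0],
       all = de$gene[sig])
}

#' Condition AUC of a single gene (or any per-cell score)
#'
#' `AUC = P(value in exposed > value in control) + 0.5 P(equal)`, computed by
#' ranks; equals the Mann-Whitney U statistic divided by `n0 * n1`. A constant
#' vector yields 0.5.
#'
#' @param values per-cell numeric values.
#' @param condition per-cell binary labels (0 control, 1 exposed).
#' @return the AUC in `[0, 1]`.
#' @export
gene_condition_auc <- function(values, condition) {
  g0 <- values[condition == 0]; g1 <- values[condition == 1]
  if (!length(g0) || !length(g1)) stop("both groups must be non-empty")
  r <- rank(c(g0, g1))
  U <- sum(r[(length(g0) + 1):length(r)]) - length(g1) * (length(g1) + 1) / 2
  U / (length(g0) * length(g1))
}

#' Fisher-exact (hypergeometric) over-representation analysis
#'
#' One-sided hypergeometric tail p per pathway for the overlap between a hit
#' list and each gene set, restricted to the universe; Benjamini-Hochberg
#' q-values; rows with `q < fdr_max` flagged significant.
#'
#' @param hits character vector of hit genes (must be within `universe`).
#' @param universe character vector of all tested genes.
#' @param pathways named list of gene sets (e.g. from [read_gmt()]).
#' @param fdr_max FDR flag threshold (default 0.10, exclusive).
#' @return data.frame with `pathway`, `size`, `overlap`, `p`, `q`,
#'   `significant`, sorted by p.
#' @export
fisher_enrichment <- function(hits, universe, pathways, fdr_max = 0.10) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- intersect(unique(hits), universe)
  N <- length(universe); k <- length(hits)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    m <- length(pw)
    ov <- length(intersect(pw, hits))
    p <- phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(pathway = nm, size = m, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_max
  out[order(out$p), , drop = FALSE]
}
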