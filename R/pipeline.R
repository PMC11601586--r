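# End-to-end orchestration. The unsupervised path runs per condition
# (separate air and smoke networks); the supervised path pools conditions per
# cell type and uses the labels only in factor selection, then transfers each
# selected factor's gene set across cell types and datasets.

new_manifest <- function(seed) {
  list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       master_seed = seed, stages = list())
}

add_stage <- function(manifest, name, params = list(), seed = NULL,
                      outputs = character(0), warnings = character(0)) {
  checksums <- if (length(outputs)) vapply(outputs, file_checksum, "") else character(0)
  manifest$stages[[length(manifest$stages) + 1]] <-
    list(stage = name, params = params, seed = seed,
         outputs = as.list(outputs), checksums = as.list(checksums),
         warnings = as.list(warnings))
  manifest
}

#' Summarize retained cells of a two-group cohort
#'
#' Totals the per-group retained cell counts and computes the per-mouse
#' average (total divided by the number of mice, rounded to the nearest cell).
#'
#' @param per_group_counts named or unnamed integer vector of retained cells
#'   per exposure group.
#' @param n_mice total number of mice across groups.
#' @return list with `total_cells`, `per_mouse_average`, `per_group`.
#' @export
cohort_cell_summary <- function(per_group_counts, n_mice) {
  total <- sum(per_group_counts)
  list(total_cells = total,
       per_mouse_average = round(total / n_mice),
       per_group = per_group_counts)
}

# Shared preprocessing chain: QC (raw counts only) -> normalize -> sparsity.
preprocess_chain <- function(X, config) {
  if (!X$normalized) {
    X <- qc_filter_cells(X, config$qc$min_genes, config$qc$max_genes,
                         config$qc$max_mito_frac, config$qc$mito_prefix)
    X <- normalize_log(X, config$normalize$scale)
  }
  sparsity_filter(X, config$sparsity$gene_zero_max, config$sparsity$cell_zero_max)
}

#' Run the unsupervised rewiring analysis per condition
#'
#' For each condition separately: QC, normalization, sparsity filtering,
#' latent-factor fitting, definitive assignment and principal split, nested
#' factorization of the two principal gene groups, top-feature extraction,
#' median-nonzero noise filtering (joint over both conditions), and OR-logic
#' protein-interaction subnetwork assembly.
#'
#' @param X raw-count [expression_matrix()] holding both conditions.
#' @param interactome \pkg{igraph} graph from [read_interactome()].
#' @param config configuration list from [read_config()].
#' @param seed master seed.
#' @param out_dir optional output directory; when given, networks, marker
#'   tables and the manifest are written there.
#' @return list with per-condition entries (`condition0`, `condition1`): the
#'   fitted models, factor counts, marker sets, network; plus `manifest`.
#' @export
run_unsupervised <- function(X, interactome, config = read_config(),
                             seed = config$seed, out_dir = NULL) {
  manifest <- new_manifest(seed)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prepped <- list()
  for (g in c(0L, 1L)) {
    if (!any(X$condition == g)) stop("condition ", g, " has zero cells")
    Xg <- subset_cells(X, cells = which(X$condition == g))
    prepped[[g + 1L]] <- preprocess_chain(Xg, config)
  }
  out <- list()
  for (g in c(0L, 1L)) {
    Xg <- prepped[[g + 1L]]
    model <- fit_love(Xg, config$love$delta_grid, config$love$lambda_grid,
                      seed = derive_seed(seed, 10L + g),
                      cv_repeats = config$love$cv_repeats,
                      allow_singletons = config$love$allow_singletons)
    split_groups <- withCallingHandlers(
      principal_split(model), warning = function(w) invokeRestart("muffleWarning"))
    nested <- nested_love(Xg, split_groups, config$love$delta_grid,
                          config$love$lambda_grid,
                          seed = derive_seed(seed, 20L + g),
                          cv_repeats = config$love$cv_repeats)
    tops <- unlist(lapply(nested, top_features, k = config$networks$top_k),
                   use.names = FALSE)
    other <- prepped[[2L - g]]
    candidates <- intersect(unique(tops), other$gene_ids)
    markers <- median_nonzero_filter(prepped[[1L]], prepped[[2L]],
                                     intersect(candidates, prepped[[1L]]$gene_ids),
                                     q = config$networks$quantile_q)
    net <- build_subnetwork(markers, interactome, logic = config$networks$logic,
                            X_group = Xg)
    entry <- list(model = model, K_top = model$K,
                  K_nested = vapply(nested, function(m) m$K, 1L),
                  nested = nested, markers = markers, network = net)
    outputs <- character(0)
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, paste0("condition", g))
      outputs <- write_network(net, base)
      mk <- paste0(base, ".markers.tsv")
      write.table(data.frame(gene = markers), mk, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      outputs <- c(outputs, markers = mk)
    }
    manifest <- add_stage(manifest, paste0("unsupervised_condition", g),
                          params = list(K_top = model$K, delta = model$delta,
                                        lambda = model$lambda),
                          seed = derive_seed(seed, 10L + g), outputs = outputs)
    out[[paste0("condition", g)]] <- entry
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out$manifest <- manifest
  out
}

#' Run the supervised selection and cross-prediction analysis
#'
#' Per cell type of the source dataset: pools both conditions, fits the latent
#' factor model, estimates per-cell scores, selects significant standalone
#' factors by multistage knockoffs, searches interactions, and assesses model
#' significance by replicated CV with permutation testing. Each selected
#' factor's gene set is then transferred to every other cell type of the
#' source dataset and to the target dataset (if given), reporting transfer
#' AUC and Mann-Whitney p per (gene set, target) pair.
#'
#' @param X_source raw-count [expression_matrix()] (dataset A).
#' @param X_target optional second dataset for cross-dataset transfer.
#' @param config configuration list from [read_config()].
#' @param seed master seed.
#' @param cell_types cell types to model (default: all in `X_source` with at
#'   least 50 cells per condition).
#' @param out_dir optional output directory for result tables + manifest.
#' @return list with one entry per modeled cell type (`model`, `scores`,
#'   `selection`, `interactions`, `significance`, `member_tables`,
#'   `gene_sets`, `transfers`) plus `manifest`.
#' @export
run_supervised <- function(X_source, X_target = NULL, config = read_config(),
                           seed = config$seed, cell_types = NULL,
                           out_dir = NULL) {
  manifest <- new_manifest(seed)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cell_types)) {
    tab <- table(X_source$cell_type, X_source$condition)
    cell_types <- rownames(tab)[apply(tab, 1, min) >= 50]
  }
  if (!length(cell_types)) stop("no cell type with enough cells per condition")
  prep_target <- if (!is.null(X_target)) preprocess_chain(X_target, config) else NULL
  out <- list()
  for (ct in cell_types) {
    Xc <- subset_cells(X_source, cells = which(X_source$cell_type == ct))
    Xp <- preprocess_chain(Xc, config)
    model <- fit_love(Xp, config$love$delta_grid, config$love$lambda_grid,
                      seed = derive_seed(seed, 100L),
                      cv_repeats = config$love$cv_repeats)
    Z <- estimate_latent_scores(Xp, model)
    y <- Xp$condition
    sel <- multistage_select(Z, y, iterations = config$slide$iterations,
                             spec = config$slide$spec,
                             fdr_level = config$slide$fdr_level,
                             seed = derive_seed(seed, 200L),
                             w_statistic = config$slide$w_statistic)
    inter <- interaction_search(Z, y, sel$selected,
                                iterations = config$slide$iterations,
                                spec = config$slide$spec,
                                fdr_level = config$slide$fdr_level,
                                seed = derive_seed(seed, 300L),
                                w_statistic = config$slide$w_statistic)
    sig <- NULL
    if (length(sel$selected)) {
      Zsel <- Z[, sel$selected, drop = FALSE]
      if (nrow(inter$pairs)) {
        Zs <- scale(Z)
        for (r in seq_len(nrow(inter$pairs)))
          Zsel <- cbind(Zsel, Zs[, inter$pairs[r, 1]] * Zs[, inter$pairs[r, 2]])
      }
      sig <- cv_significance(Zsel, y, folds = config$slide$folds,
                             replicates = config$slide$replicates,
                             n_perm = config$slide$n_perm,
                             seed = derive_seed(seed, 400L))
    }
    members <- factor_member_table(model, Xp, y, sel$selected)
    gene_sets <- lapply(sel$selected, function(f)
      factor_gene_set(model, f, source_tag = X_source$dataset_tag,
                      source_cell_type = ct))
    entry <- list(cell_type = ct, model = model, scores = Z, selection = sel,
                  interactions = inter, significance = sig,
                  member_tables = members, gene_sets = gene_sets,
                  transfers = NULL)
    out[[ct]] <- entry
    manifest <- add_stage(manifest, paste0("supervised_", ct),
                          params = list(K = model$K,
                                        n_selected = length(sel$selected),
                                        n_interactions = nrow(inter$pairs)),
                          seed = derive_seed(seed, 100L))
  }
  # cross-prediction grid: every selected gene set against every other
  # cell type (same dataset) and the target dataset (all its cell types)
  for (ct in names(out)) {
    gsets <- out[[ct]]$gene_sets
    if (!length(gsets)) {
      out[[ct]]$transfers <- data.frame()
      manifest <- add_stage(manifest, paste0("crosspred_", ct),
                            params = list(skipped = "empty selection"))
      next
    }
    rows <- list()
    targets <- list()
    for (ct2 in setdiff(unique(X_source$cell_type), ct)) {
      Xo <- subset_cells(X_source, cells = which(X_source$cell_type == ct2))
      targets[[paste0(X_source$dataset_tag, ":", ct2)]] <-
        tryCatch(preprocess_chain(Xo, config), error = function(e) NULL)
    }
    if (!is.null(prep_target)) {
      for (ct2 in unique(prep_target$cell_type)) {
        targets[[paste0(prep_target$dataset_tag, ":", ct2)]] <-
          subset_cells(prep_target, cells = which(prep_target$cell_type == ct2))
      }
    }
    for (gs in gsets) {
      for (tn in names(targets)) {
        Xt <- targets[[tn]]
        if (is.null(Xt)) next
        res <- tryCatch({
          sc <- project_score(gs, Xt, mode = config$crosspred$score_mode)
          pg <- predict_group(sc, Xt$condition)
          data.frame(gene_set = paste0(gs$source_tag, ":", gs$source_cell_type,
                                       ":F", gs$factor),
                     target = tn, auc = pg$auc, p = pg$mann_whitney_p,
                     coverage = attr(sc, "coverage"),
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (!is.null(res)) rows[[length(rows) + 1]] <- res
      }
    }
    out[[ct]]$transfers <- if (length(rows)) do.call(rbind, rows) else data.frame()
    manifest <- add_stage(manifest, paste0("crosspred_", ct),
                          params = list(n_transfers = length(rows)))
    if (!is.null(out_dir) && length(rows)) {
      tf <- file.path(out_dir, paste0("crosspred_", ct, ".tsv"))
      write.table(out[[ct]]$transfers, tf, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  out
}
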