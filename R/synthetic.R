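# Synthetic single-cell generator with known ground truth. Counts arise from a
# Poisson-log-normal-style mechanism: latent factors Z ~ N(0, C) drive a
# Gaussian signal Y = Z A' + E, and counts are Poisson(exp(a + b Y)), with the
# intercept a calibrated so the realized zero fraction matches the dropout
# target. Dropout therefore acts through the mean function, never by post-hoc
# zeroing, so rank statistics stay well defined. Condition labels either shift
# the signal factors' means (label_mode "shift") or are drawn from a logistic
# model on the factors and their planted interactions (label_mode "model").

#' Construct a ground-truth overlapping factor model
#'
#' The allocation has `pure_per_factor` signed unit rows per factor (anchor
#' positive), `n_mixed` mixed rows with 2-3 non-zeros drawn from
#' +/-Uniform(0.3, 1) and l1-normalized, and pure-noise rows (all-zero) for
#' the remaining genes. The latent covariance is equicorrelated.
#'
#' @param p number of genes (default 300).
#' @param K number of factors (default 6).
#' @param pure_per_factor pure genes per factor, >= 2 (default 5).
#' @param n_mixed number of mixed genes (default 60).
#' @param overlap_frac probability a mixed gene loads on 3 (vs 2) factors
#'   (default 0.5).
#' @param signal_factors factors carrying the condition effect (default 1:2).
#' @param interaction_pairs two-column matrix of interacting factor pairs
#'   (default the pair (1, 2)).
#' @param beta_marginal effect size of each signal factor on the condition
#'   (mean shift in "shift" mode, logit coefficient in "model" mode;
#'   default 2.5).
#' @param beta_interaction logit coefficient per interaction pair
#'   (default 1.5; used in "model" mode).
#' @param noise_sd sd of the Gaussian gene-level noise E (default 0.3).
#' @param dropout_rate target zero fraction of the count matrix (default 0.9).
#' @param gain slope b of the log-mean on the Gaussian signal (default 1.5).
#' @param rho latent equicorrelation (default 0.2).
#' @param batch_shift_sd sd of the per-gene log-mean offset applied to the
#'   second dataset (default 0.3).
#' @param n_background random background interactome edges (default `p`).
#' @param seed integer seed; the truth is deterministic given it.
#' @return a `TruthModel` list: `A_true`, `C_true`, `pure_sets`, `signs`,
#'   `beta_marginal`, `beta_interaction`, `interaction_pairs`,
#'   `signal_factors`, `noise_sd`, `dropout_rate`, `gain`, `batch_shift`,
#'   `module_interactome` (edge data.frame), `genes`, `seed`.
#' @export
make_truth <- function(p = 300, K = 6, pure_per_factor = 5, n_mixed = 60,
                       overlap_frac = 0.5, signal_factors = c(1L, 2L),
                       interaction_pairs = matrix(c(1L, 2L), ncol = 2),
                       beta_marginal = 2.5, beta_interaction = 1.5,
                       noise_sd = 0.3, dropout_rate = 0.9, gain = 1.5,
                       rho = 0.2, batch_shift_sd = 0.3,
                       n_background = p, seed = 1L) {
  if (pure_per_factor < 2) stop("need at least 2 pure genes per factor")
  if (p < K * pure_per_factor + n_mixed)
    stop("infeasible sizes: p < K * pure_per_factor + n_mixed")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  set.seed(derive_seed(seed, 0L))
  genes <- sprintf("gene%04d", seq_len(p))
  A <- matrix(0, p, K, dimnames = list(genes, paste0("F", seq_len(K))))
  pure_sets <- vector("list", K)
  signs <- vector("list", K)
  idx <- 1L
  for (k in seq_len(K)) {
    g <- idx:(idx + pure_per_factor - 1L)
    s <- c(1, sample(c(1, -1), pure_per_factor - 1, replace = TRUE,
                     prob = c(0.9, 0.1)))
    A[cbind(g, k)] <- s
    pure_sets[[k]] <- g
    signs[[k]] <- s
    idx <- idx + pure_per_factor
  }
  for (j in idx:(idx + n_mixed - 1L)) {
    m <- 2L + rbinom(1, 1, overlap_frac)
    ks <- sample(K, m)
    w <- sample(c(-1, 1), m, replace = TRUE) * runif(m, 0.3, 1)
    A[j, ks] <- w / sum(abs(w))
  }
  C <- matrix(rho, K, K); diag(C) <- 1
  bm <- numeric(K); bm[signal_factors] <- beta_marginal
  interaction_pairs <- matrix(as.integer(interaction_pairs), ncol = 2)
  bi <- rep(beta_interaction, nrow(interaction_pairs))
  shift <- rnorm(p, 0, batch_shift_sd)
  # planted interactome: pure-gene cliques per factor, mixed genes tethered to
  # two pure genes of their strongest factor, plus random background edges
  edges <- list()
  for (k in seq_len(K)) {
    pr <- combn(genes[pure_sets[[k]]], 2)
    edges[[k]] <- data.frame(from = pr[1, ], to = pr[2, ], stringsAsFactors = FALSE)
  }
  mixed_idx <- idx:(idx + n_mixed - 1L)
  mix_edges <- do.call(rbind, lapply(mixed_idx, function(j) {
    k <- which.max(abs(A[j, ]))
    anchors <- sample(genes[pure_sets[[k]]], 2)
    data.frame(from = genes[j], to = anchors, stringsAsFactors = FALSE)
  }))
  bg <- data.frame(from = genes[sample(p, n_background, replace = TRUE)],
                   to = genes[sample(p, n_background, replace = TRUE)],
                   stringsAsFactors = FALSE)
  interactome <- rbind(do.call(rbind, edges), mix_edges, bg)
  interactome <- interactome[interactome$from != interactome$to, ]
  key <- paste(pmin(interactome$from, interactome$to),
               pmax(interactome$from, interactome$to))
  interactome <- interactome[!duplicated(key), ]
  structure(list(A_true = A, C_true = C, pure_sets = pure_sets, signs = signs,
                 beta_marginal = bm, beta_interaction = bi,
                 interaction_pairs = interaction_pairs,
                 signal_factors = as.integer(signal_factors),
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 gain = gain, batch_shift = setNames(shift, genes),
                 module_interactome = interactome, genes = genes, seed = seed),
            class = "TruthModel")
}

# Calibrate the log-mean intercept so the expected zero fraction of
# Poisson(exp(a + bY)) over the realized Y matches the target.
calibrate_intercept <- function(Y, gain, target, lower = -25, upper = 10) {
  f <- function(a) mean(exp(-exp(a + gain * Y))) - target
  if (f(lower) < 0 || f(upper) > 0)
    stop("dropout calibration failed: target ", target,
         " unreachable for intercept in [", lower, ", ", upper, "]",
         "; f(lower) = ", round(f(lower) + target, 3),
         ", f(upper) = ", round(f(upper) + target, 3))
  uniroot(f, c(lower, upper), tol = 1e-6)$root
}

#' Simulate single-cell counts from a ground-truth model
#'
#' Per cell: `Z ~ N(0, C_true)`; in `label_mode = "shift"` the condition is
#' assigned by fixed proportions and exposed cells receive a mean shift of
#' `beta_marginal` on the signal factors; in `label_mode = "model"` the
#' condition is drawn from
#' `logit P(y = 1) = sum beta_m Z_m + sum beta_int Z_j Z_k`.
#' The Gaussian signal is `Y = Z A' + N(0, noise_sd^2)` and counts are
#' `Poisson(exp(a + gain * Y))` with `a` calibrated to the dropout target
#' (dataset B additionally adds the per-gene batch shift to `a`). Mice
#' (sample ids) are assigned in equal blocks within each condition; cell types
#' are assigned at random.
#'
#' @param truth a [make_truth()] model.
#' @param n_cells number of cells (default 2000).
#' @param group_prop exposed-group proportion in "shift" mode (default 0.5).
#' @param samples_per_group mice per condition group (default 4).
#' @param cell_types cell-type labels to assign (default AT1/AT2/ciliated).
#' @param dataset_tag dataset label (default "A").
#' @param batch apply the truth's per-gene batch shift (the "dataset B"
#'   condition; default FALSE).
#' @param label_mode `"shift"` (default) or `"model"`.
#' @param seed integer seed.
#' @return list with `X` (raw-count [expression_matrix()]), `Z` (cells x K
#'   latent scores), `condition`, and `intercept` (the calibrated `a`).
#' @export
simulate_cells <- function(truth, n_cells = 2000, group_prop = 0.5,
                           samples_per_group = 4,
                           cell_types = c("AT1", "AT2", "ciliated"),
                           dataset_tag = "A", batch = FALSE,
                           label_mode = c("shift", "model"), seed = 1L) {
  label_mode <- match.arg(label_mode)
  set.seed(derive_seed(seed, 1L))
  K <- ncol(truth$A_true); p <- nrow(truth$A_true)
  ch <- chol(truth$C_true)
  Z <- matrix(rnorm(n_cells * K), n_cells, K) %*% ch
  colnames(Z) <- colnames(truth$A_true)
  if (label_mode == "shift") {
    n1 <- round(n_cells * group_prop)
    cond <- sample(rep(c(1L, 0L), c(n1, n_cells - n1)))
    Z[cond == 1, truth$signal_factors] <-
      Z[cond == 1, truth$signal_factors, drop = FALSE] +
      rep(truth$beta_marginal[truth$signal_factors], each = sum(cond == 1))
  } else {
    eta <- as.numeric(Z %*% truth$beta_marginal)
    if (nrow(truth$interaction_pairs))
      for (r in seq_len(nrow(truth$interaction_pairs))) {
        jk <- truth$interaction_pairs[r, ]
        eta <- eta + truth$beta_interaction[r] * Z[, jk[1]] * Z[, jk[2]]
      }
    cond <- rbinom(n_cells, 1, stats::plogis(eta))
    if (length(unique(cond)) < 2)
      stop("degenerate condition draw: a single class; check effect sizes")
  }
  Y <- Z %*% t(truth$A_true) +
    matrix(rnorm(n_cells * p, 0, truth$noise_sd), n_cells, p)
  a <- calibrate_intercept(Y, truth$gain, truth$dropout_rate)
  log_mu <- a + truth$gain * Y
  if (batch) log_mu <- sweep(log_mu, 2, truth$batch_shift, "+")
  counts <- matrix(rpois(n_cells * p, exp(log_mu)), n_cells, p)
  zero_frac <- mean(counts == 0)
  if (abs(zero_frac - truth$dropout_rate) > 0.05 && !batch)
    warning(sprintf("realized zero fraction %.3f misses target %.2f",
                    zero_frac, truth$dropout_rate))
  cells <- sprintf("cell%s%05d", dataset_tag, seq_len(n_cells))
  sample_id <- character(n_cells)
  for (g in c(0L, 1L)) {
    idx <- which(cond == g)
    blocks <- sort(rep(seq_len(samples_per_group), length.out = length(idx)))
    sample_id[idx] <- sprintf("%s_m%d_%s", dataset_tag, blocks,
                              c("air", "smoke")[g + 1])
  }
  ct <- sample(cell_types, n_cells, replace = TRUE)
  X <- expression_matrix(counts, gene_ids = truth$genes, cell_ids = cells,
                         condition = cond, cell_type = ct,
                         sample_id = sample_id, dataset_tag = dataset_tag,
                         normalized = FALSE)
  list(X = X, Z = Z, condition = cond, intercept = a, zero_fraction = zero_frac)
}

#' Write ground-truth files for use as test oracles
#'
#' Emits TSVs for the allocation, latent covariance, pure sets, effect sizes,
#' the planted interactome, and (optionally) per-cell latent scores and
#' labels.
#'
#' @param truth a [make_truth()] model.
#' @param out_dir output directory (created if needed).
#' @param sim optional result of [simulate_cells()] whose `Z`/labels are also
#'   written.
#' @return invisibly, the named vector of file paths.
#' @export
emit_truth_files <- function(truth, out_dir, sim = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write.table(data.frame(gene = truth$genes, truth$A_true, check.names = FALSE),
              fp("A_true.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$C_true, fp("C_true.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ps <- do.call(rbind, lapply(seq_along(truth$pure_sets), function(k)
    data.frame(factor = k, gene = truth$genes[truth$pure_sets[[k]]],
               sign = truth$signs[[k]])))
  write.table(ps, fp("pure_sets.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(factor = seq_along(truth$beta_marginal),
                         beta = truth$beta_marginal),
              fp("beta_marginal.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(truth$interaction_pairs, beta = truth$beta_interaction),
              fp("beta_interaction.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$module_interactome, fp("interactome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  files <- c(A_true = fp("A_true.tsv"), C_true = fp("C_true.tsv"),
             pure_sets = fp("pure_sets.tsv"),
             beta_marginal = fp("beta_marginal.tsv"),
             beta_interaction = fp("beta_interaction.tsv"),
             interactome = fp("interactome.tsv"))
  if (!is.null(sim)) {
    write.table(data.frame(cell_id = sim$X$cell_ids, condition = sim$condition,
                           sim$Z, check.names = FALSE),
                fp("latent_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, latent_scores = fp("latent_scores.tsv"))
  }
  invisible(files)
}

#' Construct a noise-free planted covariance instance for the factor model
#'
#' Builds an allocation with `pure_per_factor` pure genes per factor and mixed
#' genes covering every two-factor support in both sign patterns (same-support
#' mixed genes with the same signs would be legitimately indistinguishable
#' from a pure pair of a finer factor, so sign diversity is what keeps the
#' planted representation identifiable). Returns the implied correlation-scale
#' covariance `Sigma = D A C A' D` alongside the scaled truth, for algebraic
#' recovery checks and noisy-simulation oracles.
#'
#' @param K number of factors (default 4).
#' @param pure_per_factor pure genes per factor (default 12).
#' @param rho latent equicorrelation (default 0.2).
#' @param seed integer seed for the mixed weights.
#' @return list with `Sigma` (correlation scale), `A` (correlation-scale
#'   truth), `A_raw`, `C`, `pure_sets`, `genes`.
#' @export
planted_love_instance <- function(K = 4, pure_per_factor = 12, rho = 0.2,
                                  seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  n_mixed <- choose(K, 2) * 2
  p <- K * pure_per_factor + n_mixed
  A <- matrix(0, p, K)
  for (k in seq_len(K))
    A[cbind((k - 1) * pure_per_factor + seq_len(pure_per_factor), k)] <- 1
  j <- K * pure_per_factor
  for (s in combn(K, 2, simplify = FALSE)) for (sgn in list(c(1, 1), c(1, -1))) {
    j <- j + 1
    w <- sgn * runif(2, 0.3, 1)
    A[j, s] <- w / sum(abs(w))
  }
  C <- matrix(rho, K, K); diag(C) <- 1
  S <- A %*% C %*% t(A)
  D <- diag(1 / sqrt(diag(S)))
  Sc <- D %*% S %*% D
  genes <- sprintf("g%02d", seq_len(p))
  rownames(Sc) <- colnames(Sc) <- genes
  A_cor <- D %*% A
  dimnames(A_cor) <- list(genes, paste0("F", seq_len(K)))
  list(Sigma = Sc, A = A_cor, A_raw = A, C = C,
       pure_sets = lapply(seq_len(K), function(k)
         (k - 1) * pure_per_factor + seq_len(pure_per_factor)),
       genes = genes)
}

#' Simulate Gaussian cells from a planted instance
#'
#' `X = Z A' + E` with `Z ~ N(0, C)` and i.i.d. Gaussian noise — the
#' continuous (count-free) regime used for factor-recovery oracles.
#'
#' @param instance a [planted_love_instance()].
#' @param n number of cells.
#' @param noise_sd noise standard deviation (default 0.3).
#' @param seed integer seed.
#' @return list with `X` (cells x genes matrix) and `Z`.
#' @export
planted_love_cells <- function(instance, n, noise_sd = 0.3, seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  K <- ncol(instance$A_raw); p <- nrow(instance$A_raw)
  Z <- matrix(rnorm(n * K), n, K) %*% chol(instance$C)
  X <- Z %*% t(instance$A_raw) + matrix(rnorm(n * p, 0, noise_sd), n, p)
  colnames(X) <- instance$genes
  list(X = X, Z = Z)
}
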