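# Supervised latent-factor selection. Cells are scored on the fitted factors
# by least squares; significant standalone factors are found by iterating a
# model-X knockoff+ filter many times and keeping factors whose selection
# frequency clears the stability threshold ("spec"); interactions are searched
# among products anchored on the selected marginals; model significance is
# assessed by replicated stratified cross-validation with permutation testing.

#' Estimate per-cell latent factor scores
#'
#' Least-squares scores on the allocation matrix:
#' `Z_hat = X_c A (A'A)^-1` with `X_c` the column-standardized expression.
#' A rank-deficient `A'A` falls back to a ridge-regularized solve.
#'
#' @param X normalized [expression_matrix()] whose genes match the model, or
#'   a bare cells x genes matrix (columns matched to model genes by name when
#'   both are named, else by position).
#' @param model a `LoveModel` (or bare allocation matrix with rownames).
#' @param ridge regularizer used only if `A'A` is rank-deficient.
#' @return cells x K numeric matrix of factor scores.
#' @export
estimate_latent_scores <- function(X, model, ridge = 1e-8) {
  A <- if (is.list(model)) model$allocation else model
  if (is(X, "ExpressionMatrix")) {
    idx <- match(rownames(A), X$gene_ids)
    if (anyNA(idx)) stop("model genes missing from X: ",
                         paste(head(rownames(A)[is.na(idx)]), collapse = ", "))
    V <- as_dense(X$values[, idx, drop = FALSE])
  } else {
    V <- as.matrix(X)
    if (!is.null(colnames(V)) && !is.null(rownames(A)))
      V <- V[, match(rownames(A), colnames(V)), drop = FALSE]
  }
  sds <- apply(V, 2, sd)
  Xc <- scale(V)
  Xc[, sds == 0] <- 0
  G <- crossprod(A)
  if (rcond(G) < 1e-12) {
    rk_log("rank-deficient allocation Gram; ridge %g", ridge)
    G <- G + diag(ridge, ncol(A))
  }
  Z <- Xc %*% A %*% solve(G)
  colnames(Z) <- colnames(A)
  Z
}

# Shrink a covariance toward the identity until comfortably PD.
shrink_pd <- function(S, min_eig = 1e-4, max_steps = 20) {
  g <- 0
  for (i in seq_len(max_steps)) {
    ev <- min(eigen(S * (1 - g) + diag(g, ncol(S)), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev > min_eig) return(S * (1 - g) + diag(g, ncol(S)))
    g <- if (g == 0) 0.01 else g * 2
  }
  stop("factor covariance not positive definite after shrinkage")
}

#' Sample second-order Gaussian knockoffs of the factor scores
#'
#' Equicorrelated construction on the standardized scores: with
#' `s = min(2 lambda_min(Sigma_Z), 1)`,
#' `Z_tilde = Z (I - Sigma_Z^-1 s) + N(0, 2 s I - s^2 Sigma_Z^-1)`, so the
#' joint Gram of originals and knockoffs matches
#' `[[Sigma, Sigma - sI], [Sigma - sI, Sigma]]` in population.
#'
#' @param Z_hat cells x K score matrix.
#' @param seed integer seed (same seed, same knockoffs).
#' @return cells x K knockoff matrix (standardized-score scale).
#' @export
sample_knockoffs <- function(Z_hat, seed = 1L) {
  n <- nrow(Z_hat); K <- ncol(Z_hat)
  if (n < K + 2) stop("need at least K + 2 cells for knockoffs")
  Z <- scale(Z_hat)
  S <- crossprod(Z) / (n - 1)
  S <- shrink_pd(S)
  lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  s <- min(2 * lmin, 1)
  Sinv <- solve(S)
  Vc <- 2 * s * diag(K) - s^2 * Sinv
  Vc <- (Vc + t(Vc)) / 2
  ch <- chol(Vc + diag(1e-10, K))
  set.seed(seed)
  E <- matrix(rnorm(n * K), n, K) %*% ch
  Zt <- Z %*% (diag(K) - Sinv * s) + E
  colnames(Zt) <- colnames(Z_hat)
  Zt
}

# W statistics: signed importance difference between each factor and its
# knockoff, from an l1-regularized linear-probability fit (5-fold CV lambda)
# or the fast marginal-inner-product fallback.
knockoff_W <- function(Z, Zt, y, w_statistic = c("lasso", "correlation"),
                       cv_seed = NULL) {
  w_statistic <- match.arg(w_statistic)
  K <- ncol(Z)
  X <- cbind(Z, Zt)
  if (w_statistic == "lasso") {
    if (!is.null(cv_seed)) set.seed(cv_seed)
    # lambda.1se rather than lambda.min: the one-standard-error rule keeps
    # dataset-level spurious correlations (~1/sqrt(n)) out of the fit, which
    # is what makes the selection frequencies stable across knockoff redraws
    fit <- glmnet::cv.glmnet(X, y, family = "gaussian", nfolds = 5,
                             standardize = TRUE)
    b <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1]
  } else {
    ys <- as.numeric(scale(y))
    b <- as.numeric(crossprod(scale(X), ys)) / (length(y) - 1)
  }
  abs(b[1:K]) - abs(b[(K + 1):(2 * K)])
}

#' Knockoff+ selection of significant factors
#'
#' Computes per-factor statistics `W_j = |beta_j| - |beta_{j+K}|` from an
#' l1-regularized linear-probability fit of the outcome on scores and
#' knockoffs, then applies the knockoff+ threshold
#' `tau = min{t > 0 : (1 + #\{W <= -t\}) / max(1, #\{W >= t\}) <= fdr_level}`.
#'
#' @param Z_hat cells x K score matrix.
#' @param Z_tilde knockoffs from [sample_knockoffs()].
#' @param y outcome: binary condition (both classes present) or a numeric
#'   residual vector.
#' @param fdr_level target FDR per knockoff run (default 0.1).
#' @param w_statistic `"lasso"` (default) or `"correlation"`.
#' @param cv_seed optional seed for the lasso CV folds.
#' @param offset 1 for the knockoff+ threshold shown above (default), 0 for
#'   the unshifted knockoff threshold. Note the +1 offset makes fewer than
#'   `ceiling(1 / fdr_level)` discoveries impossible, so the iterated filter
#'   inside [multistage_select()] uses offset 0 and relies on the selection
#'   frequency threshold for stability.
#' @return list with `selected` (integer factor indices) and `W`.
#' @export
knockoff_filter <- function(Z_hat, Z_tilde, y, fdr_level = 0.1,
                            w_statistic = "lasso", cv_seed = NULL,
                            offset = 1) {
  uy <- unique(y)
  if (length(uy) <= 2 && all(uy %in% c(0, 1)) && length(uy) < 2)
    stop("both outcome classes must be present")
  stopifnot(offset %in% c(0, 1))
  W <- knockoff_W(Z_hat, Z_tilde, y, w_statistic, cv_seed)
  ts <- sort(unique(abs(W[W != 0])))
  tau <- Inf
  for (t in ts) {
    ratio <- (offset + sum(W <= -t)) / max(1, sum(W >= t))
    if (ratio <= fdr_level) { tau <- t; break }
  }
  list(selected = if (is.finite(tau)) which(W >= tau) else integer(0), W = W)
}

#' Iterative multistage knockoff selection with frequency stability
#'
#' Repeats knockoff sampling + knockoff+ filtering `iterations` times with
#' deterministically derived seeds; a factor is significant if its selection
#' frequency is at least `spec`.
#'
#' @param Z_hat cells x K score matrix.
#' @param y outcome (binary condition or numeric residuals).
#' @param iterations number of knockoff iterations (default 300).
#' @param spec minimum selection frequency, inclusive (default 0.2).
#' @param fdr_level per-iteration knockoff FDR target (default 0.1).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param w_statistic W statistic passed to [knockoff_filter()].
#' @param offset knockoff threshold offset per iteration (default 0: the
#'   frequency threshold `spec` supplies the stability control; the +1
#'   knockoff+ offset would forbid selections smaller than
#'   `ceiling(1 / fdr_level)` factors outright).
#' @return list with `selected` (indices with frequency >= spec),
#'   `frequencies` (all K), `iterations`, `spec`.
#' @export
multistage_select <- function(Z_hat, y, iterations = 300, spec = 0.2,
                              fdr_level = 0.1, seed = 1L,
                              w_statistic = "lasso", offset = 0) {
  K <- ncol(Z_hat)
  counts <- numeric(K)
  for (i in seq_len(iterations)) {
    Zt <- sample_knockoffs(Z_hat, seed = derive_seed(seed, i))
    kf <- knockoff_filter(Z_hat, Zt, y, fdr_level, w_statistic,
                          cv_seed = derive_seed(seed, iterations + i),
                          offset = offset)
    counts[kf$selected] <- counts[kf$selected] + 1
  }
  f <- counts / iterations
  names(f) <- colnames(Z_hat)
  list(selected = which(f >= spec), frequencies = f,
       iterations = iterations, spec = spec)
}

#' Search for significant interacting factor pairs
#'
#' Candidate terms are products of standardized scores `Z_j * Z_k` for each
#' selected marginal `j` and every other factor `k`. The outcome is first
#' residualized on the marginal scores (linear fit), and the multistage
#' knockoff selection is run on the candidate-term matrix against the
#' residuals.
#'
#' @param Z_hat cells x K score matrix.
#' @param y binary condition.
#' @param marginals integer indices of selected standalone factors.
#' @param iterations,spec,fdr_level,seed,w_statistic as in
#'   [multistage_select()].
#' @return list with `pairs` (two-column matrix of selected (anchor, partner)
#'   indices), `frequencies` (named by "j:k"), or empty when no marginals.
#' @export
interaction_search <- function(Z_hat, y, marginals, iterations = 300,
                               spec = 0.2, fdr_level = 0.1, seed = 1L,
                               w_statistic = "lasso") {
  if (!length(marginals))
    return(list(pairs = matrix(integer(0), 0, 2), frequencies = numeric(0)))
  K <- ncol(Z_hat)
  Zs <- scale(Z_hat)
  pairs <- unique(t(apply(
    expand.grid(j = marginals, k = seq_len(K)), 1, function(r) sort(unname(r)))))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs))
    return(list(pairs = matrix(integer(0), 0, 2), frequencies = numeric(0)))
  Cand <- sapply(seq_len(nrow(pairs)), function(i) Zs[, pairs[i, 1]] * Zs[, pairs[i, 2]])
  Cand <- scale(Cand)
  colnames(Cand) <- paste0(pairs[, 1], ":", pairs[, 2])
  r <- residuals(lm.fit(cbind(1, Z_hat[, marginals, drop = FALSE]), y))
  ms <- multistage_select(Cand, r, iterations, spec, fdr_level,
                          seed = derive_seed(seed, 7L), w_statistic)
  list(pairs = pairs[ms$selected, , drop = FALSE], frequencies = ms$frequencies)
}

# Stratified fold assignment; reduces folds if a class is too small.
stratified_folds <- function(y, folds) {
  n_min <- min(table(y))
  if (n_min < folds) {
    warning("reducing folds from ", folds, " to ", n_min,
            " (smallest class size)")
    folds <- max(2, n_min)
  }
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

# Mean out-of-fold AUC of a linear-probability model over one CV pass.
cv_auc_once <- function(Xd, y, folds) {
  fold <- stratified_folds(y, folds)
  aucs <- vapply(seq_len(max(fold)), function(f) {
    tr <- fold != f; te <- !tr
    b <- lm.fit(cbind(1, Xd[tr, , drop = FALSE]), y[tr])$coefficients
    b[is.na(b)] <- 0
    pred <- cbind(1, Xd[te, , drop = FALSE]) %*% b
    gene_condition_auc(as.numeric(pred), y[te])
  }, numeric(1))
  aucs
}

#' Cross-validated significance of the selected-factor model
#'
#' Replicated stratified k-fold CV of a linear-probability model on the
#' selected factor scores (plus any selected interaction terms); the test
#' statistic is the mean out-of-fold AUC. The permutation null rebuilds the
#' same statistic with the condition labels permuted.
#'
#' @param Z_sel cells x m matrix of selected factor scores (and interaction
#'   columns, if any); must be non-empty.
#' @param y binary condition.
#' @param folds CV folds (default 10).
#' @param replicates CV replicates (default 20).
#' @param n_perm permutation count (default 100).
#' @param seed integer seed.
#' @return list with `cv_auc` (replicates x folds matrix), `mean_auc`, and
#'   `permutation_p` = `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#' @export
cv_significance <- function(Z_sel, y, folds = 10, replicates = 20,
                            n_perm = 100, seed = 1L) {
  if (is.null(dim(Z_sel)) || ncol(Z_sel) == 0) stop("no selected factors")
  set.seed(derive_seed(seed, 0L))
  cv_tab <- t(vapply(seq_len(replicates), function(r) cv_auc_once(Z_sel, y, folds),
                     numeric(min(folds, max(2, min(table(y)))))))
  obs <- mean(cv_tab)
  null_stats <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    mean(vapply(seq_len(replicates), function(r) mean(cv_auc_once(Z_sel, yp, folds)),
                numeric(1)))
  }, numeric(1))
  p <- (1 + sum(null_stats >= obs)) / (n_perm + 1)
  list(cv_auc = cv_tab, mean_auc = obs, permutation_p = p,
       null_stats = null_stats)
}

#' Top-member tables for the selected factors
#'
#' Per selected factor: the union of the top 10 genes by absolute allocation
#' weight within the factor and the factor's top 10 genes by condition AUC
#' distance from 0.5. Each member carries its AUC and a condition tag:
#' `exposed` (AUC > 0.5), `control` (AUC < 0.5), `neutral` (exactly 0.5).
#'
#' @param model a `LoveModel`.
#' @param X normalized [expression_matrix()].
#' @param y binary condition.
#' @param selected integer indices of the selected factors.
#' @param n_top genes per criterion (default 10).
#' @return named list of data.frames (`gene`, `weight`, `auc`, `tag`).
#' @export
factor_member_table <- function(model, X, y, selected, n_top = 10) {
  A <- model$allocation
  asg <- definitive_assignment(A)
  out <- list()
  for (f in selected) {
    members <- names(asg)[!is.na(asg) & asg == f]
    if (!length(members)) {
      out[[colnames(A)[f]]] <- data.frame(gene = character(0), weight = numeric(0),
                                          auc = numeric(0), tag = character(0))
      next
    }
    w <- A[members, f]
    auc <- vapply(members, function(g) {
      gene_condition_auc(as.numeric(X$values[, match(g, X$gene_ids)]), y)
    }, numeric(1))
    top_w <- members[order(-abs(w))][seq_len(min(n_top, length(members)))]
    top_a <- members[order(-abs(auc - 0.5))][seq_len(min(n_top, length(members)))]
    sel <- union(top_w, top_a)
    tag <- ifelse(auc[sel] > 0.5, "exposed", ifelse(auc[sel] < 0.5, "control", "neutral"))
    out[[colnames(A)[f]]] <- data.frame(gene = sel, weight = unname(w[sel]),
                                        auc = unname(auc[sel]), tag = unname(tag),
                                        stringsAsFactors = FALSE)
  }
  out
}
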