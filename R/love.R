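# Identifiable overlapping latent-factor estimation from the gene-gene
# correlation matrix. Three steps: (1) pure-variable detection and grouping,
# which fixes the number of factors K and anchors identifiability; (2) latent
# covariance estimation from the pure-variable blocks; (3) weight allocation
# for the mixed variables by l1-minimization under an l-infinity data-fit
# constraint. Hyperparameters (delta for pure detection, lambda for the mixed
# rows) are selected by held-out covariance reconstruction.

#' Estimate the gene-gene correlation matrix
#'
#' Pearson correlation of genes across cells. Constant genes carry no
#' correlation signal and are dropped with a warning. Working on the
#' correlation (rather than raw covariance) scale makes the pure-variable
#' tolerance delta scale-free and stops highly expressed genes from dominating.
#'
#' @param X normalized [expression_matrix()] (post sparsity filter), or a bare
#'   cells x genes numeric matrix.
#' @param use_correlation if FALSE, return the raw covariance instead.
#' @return list with `Sigma` (genes x genes), `n_cells`, and `genes` (ids kept).
#' @export
estimate_covariance <- function(X, use_correlation = TRUE) {
  V <- if (is(X, "ExpressionMatrix")) as_dense(X$values) else as.matrix(X)
  if (nrow(V) < 3) stop("need at least 3 cells to estimate covariance")
  sds <- apply(V, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from covariance")
    V <- V[, sds > 0, drop = FALSE]
  }
  S <- if (use_correlation) cor(V) else cov(V)
  list(Sigma = S, n_cells = nrow(V), genes = colnames(V))
}

#' Detect pure variables and the factor count from a correlation matrix
#'
#' A gene loading on exactly one latent factor (a pure variable) has its
#' largest absolute off-diagonal correlation achieved against other genes of
#' its own factor. Concretely, with `M_i = max_{j != i} |Sigma_ij|` and
#' `S_i = {j != i : |Sigma_ij| >= M_i - 2 delta}`, gene `i` is pure iff every
#' `j` in `S_i` satisfies `|M_j - |Sigma_ij|| <= 2 delta`. Pure genes are then
#' partitioned by the relation "j in S_i" (connected components), with signs
#' assigned relative to the lowest-index gene of each group. The number of
#' groups is the factor count K.
#'
#' @param Sigma result of [estimate_covariance()] (or a bare matrix).
#' @param delta pure-variable tolerance, > 0.
#' @param allow_singletons keep size-1 groups? If FALSE (default) they are
#'   dropped with a warning.
#' @return list with `K`, `pure_sets` (list of integer index vectors),
#'   `signs` (list of +/-1 vectors, anchor positive), `genes`.
#' @export
find_pure_variables <- function(Sigma, delta, allow_singletons = FALSE) {
  S <- if (is.list(Sigma)) Sigma$Sigma else Sigma
  genes <- if (is.list(Sigma)) Sigma$genes else colnames(S)
  if (is.null(genes)) genes <- as.character(seq_len(ncol(S)))
  stopifnot(delta > 0)
  p <- ncol(S)
  A <- abs(S); diag(A) <- -Inf
  M <- apply(A, 1, max)
  if (all(!is.finite(M)) || max(M) <= 0)
    stop("no latent structure at this delta: correlation matrix is diagonal")
  Slist <- lapply(seq_len(p), function(i) which(A[i, ] >= M[i] - 2 * delta))
  pure <- vapply(seq_len(p), function(i) {
    js <- Slist[[i]]
    length(js) > 0 && all(abs(M[js] - A[i, js]) <= 2 * delta)
  }, logical(1))
  pure_idx <- which(pure)
  if (!length(pure_idx)) stop("no latent structure at this delta: no pure variable found")
  # group pure genes: i ~ j iff j in S_i (restricted to pure genes), take
  # connected components for transitive closure; anchor = lowest index
  comp <- setNames(seq_along(pure_idx), pure_idx)
  pos <- match(seq_len(p), pure_idx)
  for (a in seq_along(pure_idx)) {
    i <- pure_idx[a]
    nb <- intersect(Slist[[i]], pure_idx)
    for (j in nb) {
      b <- pos[j]
      ra <- comp[a]; rb <- comp[b]
      if (ra != rb) comp[comp == rb] <- ra
    }
  }
  groups <- split(pure_idx, comp)
  groups <- groups[order(vapply(groups, min, 1L))]
  sizes <- lengths(groups)
  if (any(sizes == 1) && !allow_singletons) {
    warning(sum(sizes == 1), " singleton pure group(s) dropped")
    groups <- groups[sizes > 1]
  }
  if (!length(groups)) stop("no latent structure at this delta: only singleton groups")
  signs <- lapply(groups, function(g) {
    anchor <- min(g)
    s <- sign(S[anchor, g])
    s[g == anchor] <- 1
    s[s == 0] <- 1
    s
  })
  list(K = length(groups), pure_sets = unname(groups), signs = unname(signs),
       genes = genes)
}

#' Estimate the latent factor covariance from the pure-variable blocks
#'
#' Diagonal entries average the sign-corrected correlations over distinct pure
#' pairs within a group; off-diagonals average sign-corrected correlations
#' across groups. Under the model, both are unbiased for the latent covariance.
#'
#' @param Sigma correlation estimate (list or matrix, as in
#'   [find_pure_variables()]).
#' @param pure_sets,signs from [find_pure_variables()].
#' @param allow_singletons permit size-1 groups (their diagonal uses the
#'   maximal sign-corrected entry against other groups' pure genes).
#' @return K x K symmetric matrix C.
#' @export
estimate_latent_covariance <- function(Sigma, pure_sets, signs,
                                       allow_singletons = FALSE) {
  S <- if (is.list(Sigma)) Sigma$Sigma else Sigma
  K <- length(pure_sets)
  C <- matrix(0, K, K)
  for (a in seq_len(K)) {
    g <- pure_sets[[a]]; sa <- signs[[a]]
    if (length(g) == 1) {
      if (!allow_singletons) stop("pure group of size 1 without allow_singletons")
      others <- setdiff(unlist(pure_sets), g)
      C[a, a] <- if (length(others)) max(abs(S[g, others])) else 1
    } else {
      pr <- combn(length(g), 2)
      C[a, a] <- mean(sa[pr[1, ]] * sa[pr[2, ]] * S[cbind(g[pr[1, ]], g[pr[2, ]])])
    }
    if (a < K) for (b in (a + 1):K) {
      h <- pure_sets[[b]]; sb <- signs[[b]]
      blk <- outer(sa, sb) * S[g, h, drop = FALSE]
      C[a, b] <- C[b, a] <- mean(blk)
    }
  }
  C
}

# h_j: K-vector of average sign-corrected correlations of gene j against each
# group's pure variables.
pure_targets <- function(S, j, pure_sets, signs) {
  vapply(seq_along(pure_sets), function(a) {
    g <- pure_sets[[a]]
    mean(signs[[a]] * S[g, j])
  }, numeric(1))
}

# min ||a||_1  s.t.  ||C a - h||_inf <= lambda, via LP on the split
# a = a+ - a-; falls back to soft-thresholded least squares when the LP is
# degenerate. lambda = 0 short-circuits to the exact solve.
solve_mixed_row <- function(C, h, lambda) {
  K <- length(h)
  if (max(abs(h)) <= lambda) return(numeric(K))
  if (lambda == 0) return(as.numeric(solve(C, h)))
  a_lp <- tryCatch({
    cc <- rep(1, 2 * K)
    Amat <- rbind(cbind(C, -C), cbind(-C, C))
    b <- c(lambda + h, lambda - h)
    res <- pracma::linprog(cc, A = Amat, b = b, maximize = FALSE)
    if (is.null(res$x) || anyNA(res$x)) NULL else res$x[1:K] - res$x[(K + 1):(2 * K)]
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(a_lp) && max(abs(C %*% a_lp - h)) <= lambda + 1e-6) return(a_lp)
  a <- as.numeric(solve(C, h))
  sign(a) * pmax(abs(a) - lambda, 0)
}

#' Allocate weights to mixed variables
#'
#' Pure rows become signed unit vectors in their own factor's column. Each
#' remaining gene's row minimizes the l1 norm subject to fitting its average
#' correlations against the pure groups within tolerance `lambda`
#' (an l-infinity constraint). All-zero rows mean "unassigned".
#'
#' @param Sigma correlation estimate.
#' @param pure_sets,signs from [find_pure_variables()].
#' @param C latent covariance from [estimate_latent_covariance()].
#' @param lambda regularization for the mixed rows, >= 0.
#' @param ridge added to C's diagonal if it is singular (with a message).
#' @return genes x K allocation matrix A.
#' @export
estimate_mixed_rows <- function(Sigma, pure_sets, signs, C, lambda = 0,
                                ridge = 1e-8) {
  S <- if (is.list(Sigma)) Sigma$Sigma else Sigma
  genes <- if (is.list(Sigma)) Sigma$genes else colnames(S)
  p <- ncol(S); K <- length(pure_sets)
  if (rcond(C) < 1e-12) {
    if (is.null(ridge)) stop("singular latent covariance; set ridge")
    rk_log("latent covariance near-singular; adding ridge %g", ridge)
    C <- C + diag(ridge, K)
  }
  A <- matrix(0, p, K, dimnames = list(genes, paste0("F", seq_len(K))))
  pure_all <- unlist(pure_sets)
  for (a in seq_len(K)) A[cbind(pure_sets[[a]], a)] <- signs[[a]]
  mixed <- setdiff(seq_len(p), pure_all)
  for (j in mixed) {
    h <- pure_targets(S, j, pure_sets, signs)
    A[j, ] <- solve_mixed_row(C, h, lambda)
  }
  A
}

# One full three-step fit at fixed (delta, lambda) on a precomputed Sigma.
love_fit_once <- function(Sigma, delta, lambda, allow_singletons = FALSE) {
  pv <- find_pure_variables(Sigma, delta, allow_singletons = allow_singletons)
  C <- estimate_latent_covariance(Sigma, pv$pure_sets, pv$signs,
                                  allow_singletons = allow_singletons)
  A <- estimate_mixed_rows(Sigma, pv$pure_sets, pv$signs, C, lambda)
  list(K = pv$K, pure_sets = pv$pure_sets, signs = pv$signs,
       allocation = A, latent_cov = C, delta = delta, lambda = lambda,
       genes = pv$genes)
}

offdiag_frob <- function(M) {
  diag(M) <- 0
  sqrt(sum(M^2))
}

#' Fit the overlapping latent-factor model with hyperparameter selection
#'
#' Runs the three steps for every (delta, lambda) pair on the grids and picks
#' the pair minimizing held-out covariance reconstruction error
#' `||Sigma_heldout - A C A'||_F` (off-diagonal only) under a 2-fold cell
#' split repeated `cv_repeats` times, then refits on all cells.
#'
#' @param X normalized, sparsity-filtered [expression_matrix()], or a bare
#'   cells x genes numeric matrix.
#' @param delta_grid candidate pure-variable tolerances.
#' @param lambda_grid candidate mixed-row regularizers.
#' @param seed integer seed for the fold splits.
#' @param cv_repeats number of repeated 2-fold splits (default 5).
#' @param allow_singletons permit size-1 pure groups.
#' @return a `LoveModel`: list with `K`, `pure_sets`, `signs`, `allocation`,
#'   `latent_cov`, `delta`, `lambda`, `genes`, `cv_errors`.
#' @export
fit_love <- function(X, delta_grid = c(0.02, 0.05, 0.08, 0.12, 0.16, 0.20),
                     lambda_grid = c(0, 0.01, 0.05, 0.1),
                     seed = 1L, cv_repeats = 5, allow_singletons = FALSE) {
  is_em <- is(X, "ExpressionMatrix")
  n <- if (is_em) n_cells(X) else nrow(X)
  take_cells <- function(obj, idx)
    if (is_em) subset_cells(obj, cells = idx) else obj[idx, , drop = FALSE]
  grid <- expand.grid(delta = delta_grid, lambda = lambda_grid)
  err <- matrix(0, nrow(grid), 2 * cv_repeats)
  diagnostics <- character(nrow(grid))
  set.seed(derive_seed(seed, 0L))
  for (r in seq_len(cv_repeats)) {
    fold <- sample(rep(1:2, length.out = n))
    for (f in 1:2) {
      Xtr <- take_cells(X, which(fold == f))
      Xte <- take_cells(X, which(fold != f))
      Str <- tryCatch(estimate_covariance(Xtr), error = function(e) NULL)
      Ste <- tryCatch(estimate_covariance(Xte), error = function(e) NULL)
      if (is.null(Str) || is.null(Ste)) next
      common <- intersect(Str$genes, Ste$genes)
      for (gidx in seq_len(nrow(grid))) {
        fit <- tryCatch(
          suppressWarnings(love_fit_once(Str, grid$delta[gidx], grid$lambda[gidx],
                                         allow_singletons)),
          error = function(e) e)
        if (inherits(fit, "error")) {
          err[gidx, 2 * (r - 1) + f] <- Inf
          diagnostics[gidx] <- conditionMessage(fit)
          next
        }
        rec <- fit$allocation %*% fit$latent_cov %*% t(fit$allocation)
        ii <- match(common, Str$genes); jj <- match(common, Ste$genes)
        err[gidx, 2 * (r - 1) + f] <-
          offdiag_frob(Ste$Sigma[jj, jj, drop = FALSE] - rec[ii, ii, drop = FALSE])
      }
    }
  }
  tot <- rowSums(err)
  if (all(!is.finite(tot)))
    stop("fit_love: every (delta, lambda) failed; grid diagnostics: ",
         paste(unique(diagnostics[nzchar(diagnostics)]), collapse = " | "))
  best <- which.min(tot)
  Sfull <- estimate_covariance(X)
  model <- love_fit_once(Sfull, grid$delta[best], grid$lambda[best],
                         allow_singletons)
  model$cv_errors <- cbind(grid, error = tot)
  model$seed <- seed
  class(model) <- "LoveModel"
  model
}

#' @export
print.LoveModel <- function(x, ...) {
  cat(sprintf("LoveModel: K = %d factors over %d genes (delta = %g, lambda = %g)\n",
              x$K, length(x$genes), x$delta, x$lambda))
  cat("  pure set sizes:", paste(lengths(x$pure_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Write a fitted latent-factor model to TSV/JSON files
#'
#' @param model a `LoveModel`.
#' @param basename path prefix; writes `<basename>.allocation.tsv`,
#'   `<basename>.pure_sets.tsv`, `<basename>.latent_cov.tsv`,
#'   `<basename>.model.json`.
#' @return invisibly, the file paths.
#' @export
write_love_model <- function(model, basename) {
  af <- paste0(basename, ".allocation.tsv")
  pf <- paste0(basename, ".pure_sets.tsv")
  cf <- paste0(basename, ".latent_cov.tsv")
  jf <- paste0(basename, ".model.json")
  write.table(data.frame(gene = model$genes, model$allocation,
                         check.names = FALSE),
              af, sep = "\t", quote = FALSE, row.names = FALSE)
  ps <- do.call(rbind, lapply(seq_along(model$pure_sets), function(a)
    data.frame(factor = a, gene = model$genes[model$pure_sets[[a]]],
               sign = model$signs[[a]])))
  write.table(ps, pf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model$latent_cov, cf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(K = model$K, delta = model$delta,
                            lambda = model$lambda, seed = model$seed),
                       jf, auto_unbox = TRUE)
  invisible(c(allocation = af, pure_sets = pf, latent_cov = cf, model = jf))
}
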