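# Fixtures built in code: tiny expression matrices and planted factor models.

# Minimal raw-count matrix with given values (cells x genes).
make_em <- function(values, condition = NULL, normalized = FALSE, ...) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(condition)) condition <- rep(c(0L, 1L), length.out = n)
  expression_matrix(values,
                    gene_ids = sprintf("g%03d", seq_len(p)),
                    cell_ids = sprintf("c%03d", seq_len(n)),
                    condition = condition, normalized = normalized, ...)
}

# Planted allocation with `ppf` pure genes per factor and mixed rows on
# distinct 2-factor supports; returns the correlation-scale truth too.
planted_sigma <- function(K = 4, ppf = 3, mixed_supports = NULL, rho = 0.2,
                          seed = 1) {
  set.seed(seed)
  if (is.null(mixed_supports)) mixed_supports <- combn(K, 2, simplify = FALSE)
  n_mixed <- length(mixed_supports)
  p <- K * ppf + n_mixed
  A <- matrix(0, p, K)
  for (k in seq_len(K)) A[cbind((k - 1) * ppf + seq_len(ppf), k)] <- 1
  for (j in seq_len(n_mixed)) {
    ks <- mixed_supports[[j]]
    w <- runif(length(ks), 0.3, 1)
    A[K * ppf + j, ks] <- w / sum(w)
  }
  C <- matrix(rho, K, K); diag(C) <- 1
  S <- A %*% C %*% t(A)
  D <- diag(1 / sqrt(diag(S)))
  Scor <- D %*% S %*% D
  rownames(Scor) <- colnames(Scor) <- sprintf("g%02d", seq_len(p))
  A_cor <- D %*% A
  dimnames(A_cor) <- list(rownames(Scor), paste0("F", seq_len(K)))
  pure_sets <- lapply(seq_len(K), function(k) (k - 1) * ppf + seq_len(ppf))
  list(Sigma = Scor, A = A_cor, A_raw = A, C = C, pure_sets = pure_sets,
       K = K, p = p)
}

# Gaussian cells from a planted model: X = Z A' + noise (bare matrix).
planted_cells <- function(pl, n = 1500, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  K <- pl$K
  Z <- matrix(rnorm(n * K), n, K) %*% chol(pl$C)
  X <- Z %*% t(pl$A_raw) + matrix(rnorm(n * nrow(pl$A_raw), 0, noise_sd),
                                  n, nrow(pl$A_raw))
  colnames(X) <- rownames(pl$Sigma)
  list(X = X, Z = Z)
}

# Set equality of pure partitions up to factor order.
same_partition <- function(a, b) {
  norm <- function(s) sort(vapply(s, function(g) paste(sort(g), collapse = ","), ""))
  identical(norm(a), norm(b))
}
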