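test_that("correlation estimation is symmetric with unit diagonal", {
  set.seed(1)
  X <- make_em(matrix(rpois(30 * 5, 3), 30, 5), normalized = TRUE)
  S <- estimate_covariance(X)
  expect_equal(S$Sigma, t(S$Sigma))
  expect_equal(unname(diag(S$Sigma)), rep(1, 5))

  # duplicated gene columns correlate exactly 1
  V <- matrix(rnorm(50 * 2), 50, 2); V <- abs(cbind(V, V[, 1]))
  S2 <- estimate_covariance(make_em(V, normalized = TRUE))
  expect_equal(S2$Sigma[1, 3], 1)
})

test_that("independent genes have near-zero off-diagonal correlation", {
  set.seed(2)
  V <- matrix(rnorm(10000 * 6), 10000, 6)
  S <- estimate_covariance(V)
  off <- S$Sigma[upper.tri(S$Sigma)]
  expect_lt(max(abs(off)), 0.05)  # ~3/sqrt(n) sampling bound
})

test_that("pure-variable detection recovers exact block structure", {
  # two blocks of within-correlation 0.9, zero across
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 0.9; S[4:6, 4:6] <- 0.9; diag(S) <- 1
  colnames(S) <- rownames(S) <- paste0("g", 1:6)
  pv <- find_pure_variables(S, delta = 0.05)
  expect_equal(pv$K, 2)
  expect_true(same_partition(pv$pure_sets, list(1:3, 4:6)))

  # identity matrix: no latent structure at any delta < 0.5
  expect_error(find_pure_variables(diag(6), delta = 0.1), "no latent structure")
})

test_that("pure criterion on a planted 8-gene instance matches brute force", {
  # 2 factors x 2 pure genes + 4 mixed genes with sign-diverse weights
  # (mixed genes sharing one support must differ in sign pattern, or they are
  # legitimately indistinguishable from a pure pair of a finer factor)
  A_raw <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                 c(.5, .5), c(.5, -.5), c(.7, -.3), c(-.3, .7))
  C0 <- matrix(c(1, .2, .2, 1), 2)
  S0 <- A_raw %*% C0 %*% t(A_raw)
  D <- diag(1 / sqrt(diag(S0)))
  S <- D %*% S0 %*% D
  rownames(S) <- colnames(S) <- paste0("g", 1:8)
  pl <- list(Sigma = S, A = D %*% A_raw, C = C0, pure_sets = list(1:2, 3:4))
  delta <- 0.02
  # independent oracle: evaluate the criterion by exhaustive double loop
  p <- ncol(S); Aabs <- abs(S); diag(Aabs) <- NA
  M <- apply(Aabs, 1, max, na.rm = TRUE)
  pure_oracle <- logical(p)
  for (i in seq_len(p)) {
    Si <- setdiff(which(Aabs[i, ] >= M[i] - 2 * delta), i)
    pure_oracle[i] <- length(Si) > 0 &&
      all(vapply(Si, function(j) abs(M[j] - Aabs[i, j]) <= 2 * delta, TRUE))
  }
  # raw criterion (singletons permitted) matches the brute-force flags
  pv_all <- find_pure_variables(S, delta, allow_singletons = TRUE)
  expect_setequal(unlist(pv_all$pure_sets), which(pure_oracle))
  # default path drops singleton groups and reproduces the planted partition
  pv <- suppressWarnings(find_pure_variables(S, delta))
  expect_true(same_partition(pv$pure_sets, pl$pure_sets))
})

test_that("latent covariance estimation averages pure blocks", {
  S <- matrix(0.3, 6, 6)
  S[1:3, 1:3] <- 0.8; S[4:6, 4:6] <- 0.8; diag(S) <- 1
  pure_sets <- list(1:3, 4:6); signs <- list(rep(1, 3), rep(1, 3))
  C <- estimate_latent_covariance(S, pure_sets, signs)
  expect_equal(C, matrix(c(0.8, 0.3, 0.3, 0.8), 2))
  expect_equal(C, t(C))
})

test_that("noise-free planted model is recovered algebraically", {
  pl <- planted_sigma(K = 4, ppf = 3, seed = 42)
  pv <- find_pure_variables(pl$Sigma, delta = 0.02)
  expect_equal(pv$K, 4)
  expect_true(same_partition(pv$pure_sets, pl$pure_sets))
  C <- estimate_latent_covariance(pl$Sigma, pv$pure_sets, pv$signs)
  # C recovered after aligning factor order to the planted one
  ord <- order(vapply(pv$pure_sets, min, 1L))
  expect_equal(C[ord, ord], pl$C, tolerance = 1e-10, ignore_attr = TRUE)
  A <- estimate_mixed_rows(pl$Sigma, pv$pure_sets, pv$signs, C, lambda = 0)
  expect_lt(max(abs(A[, ord] - pl$A)), 1e-8)
})

test_that("mixed-row solver handles identity and full-threshold cases", {
  # a mixed gene identical to a pure gene of factor 1 gets row e1
  S <- matrix(0.2, 5, 5)
  S[1:2, 1:2] <- 1; S[3:4, 3:4] <- 1; diag(S) <- 1
  S[5, ] <- S[1, ]; S[, 5] <- S[, 1]; S[5, 5] <- 1; S[5, 1] <- S[1, 5] <- 1
  pure_sets <- list(1:2, 3:4); signs <- list(c(1, 1), c(1, 1))
  C <- estimate_latent_covariance(S, pure_sets, signs)
  A <- estimate_mixed_rows(S, pure_sets, signs, C, lambda = 0)
  expect_equal(unname(A[5, ]), c(1, 0), tolerance = 1e-10)

  # lambda above max |h_j| fully thresholds the row to zero
  h <- rewirekit:::pure_targets(S, 5, pure_sets, signs)
  A2 <- estimate_mixed_rows(S, pure_sets, signs, C, lambda = max(abs(h)) + 0.1)
  expect_equal(unname(A2[5, ]), c(0, 0))
})

test_that("the fitted model is equivariant under gene permutation", {
  pl <- planted_sigma(K = 3, ppf = 2,
                      mixed_supports = list(c(1, 2), c(2, 3)), seed = 7)
  pv1 <- find_pure_variables(pl$Sigma, 0.02)
  C1 <- estimate_latent_covariance(pl$Sigma, pv1$pure_sets, pv1$signs)
  A1 <- estimate_mixed_rows(pl$Sigma, pv1$pure_sets, pv1$signs, C1, 0)
  set.seed(8); perm <- sample(ncol(pl$Sigma))
  Sp <- pl$Sigma[perm, perm]
  pv2 <- find_pure_variables(Sp, 0.02)
  C2 <- estimate_latent_covariance(Sp, pv2$pure_sets, pv2$signs)
  A2 <- estimate_mixed_rows(Sp, pv2$pure_sets, pv2$signs, C2, 0)
  # permuted input's pure partition maps back to the original
  back <- lapply(pv2$pure_sets, function(g) sort(perm[g]))
  expect_true(same_partition(back, pv1$pure_sets))
  # allocation rows follow genes (up to factor relabeling by smallest member)
  ord1 <- order(vapply(pv1$pure_sets, min, 1L))
  ord2 <- order(vapply(lapply(pv2$pure_sets, function(g) perm[g]), min, 1L))
  expect_equal(abs(A2[order(perm), ord2]), abs(A1[, ord1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("hyperparameter selection by held-out reconstruction recovers truth", {
  pl <- planted_sigma(K = 3, ppf = 3,
                      mixed_supports = list(c(1, 2), c(1, 3), c(2, 3)),
                      seed = 10)
  cells <- planted_cells(pl, n = 800, noise_sd = 0.2, seed = 10)
  m <- fit_love(cells$X, delta_grid = c(0.02, 0.05, 0.1, 0.2),
                lambda_grid = c(0, 0.05), seed = 10, cv_repeats = 2)
  expect_equal(m$K, 3)
  expect_true(same_partition(m$pure_sets, pl$pure_sets))
  # scaling all cells by a constant leaves the model unchanged
  m2 <- fit_love(cells$X * 3.7, delta_grid = c(0.02, 0.05, 0.1, 0.2),
                 lambda_grid = c(0, 0.05), seed = 10, cv_repeats = 2)
  expect_equal(m2$allocation, m$allocation, tolerance = 1e-10)
})

test_that("duplicating a gene column keeps K and co-assigns the duplicates", {
  pl <- planted_sigma(K = 2, ppf = 3, mixed_supports = list(c(1, 2)), seed = 12)
  cells <- planted_cells(pl, n = 600, noise_sd = 0.1, seed = 12)
  X2 <- cbind(cells$X, dup = cells$X[, 1])
  colnames(X2) <- c(colnames(cells$X), "dup")
  m <- fit_love(X2, delta_grid = c(0.05, 0.1), lambda_grid = 0, seed = 12,
                cv_repeats = 2)
  expect_equal(m$K, 2)
  asg <- definitive_assignment(m$allocation)
  expect_equal(unname(asg["dup"]), unname(asg[colnames(cells$X)[1]]))
})
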