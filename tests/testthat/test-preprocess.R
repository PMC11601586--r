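# The QC / sparsity thresholds are quoted as strict inequalities; the boundary
# cases here pin the exclusive semantics exactly.

test_that("cell QC applies strict detected-gene and mito-fraction bounds", {
  p <- 3500
  build_cell <- function(n_detected) {
    v <- numeric(p); v[seq_len(n_detected)] <- 1; v
  }
  V <- rbind(build_cell(200), build_cell(201), build_cell(2999),
             build_cell(3000), build_cell(500))
  gene_ids <- c(sprintf("mt-%d", 1:10), sprintf("g%04d", seq_len(p - 10)))
  # last cell: mito fraction exactly 0.25 (100 mito counts over a 400 total)
  V[5, ] <- 0; V[5, 11:310] <- 1; V[5, 1:10] <- 10
  X <- expression_matrix(V, gene_ids = gene_ids,
                         cell_ids = paste0("c", 1:5),
                         condition = c(0, 0, 1, 1, 1))
  kept <- qc_filter_cells(X)
  # exactly 200 genes -> removed (strict >); 201 kept; 2999 kept; 3000 removed
  # (strict <); mito fraction exactly 0.25 -> removed (strict <)
  expect_setequal(kept$cell_ids, c("c2", "c3"))
})

test_that("log-normalization matches the formula and inverts to proportions", {
  X <- make_em(rbind(c(0, 10), c(3, 3)))
  Xn <- normalize_log(X, scale = 10)
  expect_equal(as.numeric(Xn$values[1, ]), c(0, log(11)))
  # all-equal counts in a cell give all-equal normalized values
  expect_equal(Xn$values[2, 1], Xn$values[2, 2])
  expect_true(Xn$normalized)

  set.seed(4)
  V <- matrix(rpois(20 * 30, 2) + 1, 20, 30)
  Xn2 <- normalize_log(make_em(V), scale = 1e4)
  back <- expm1(as.matrix(Xn2$values))
  prop <- back / rowSums(back)
  expect_equal(prop, V / rowSums(V), tolerance = 1e-9, ignore_attr = TRUE)

  X0 <- make_em(rbind(c(0, 0), c(1, 1)))
  expect_error(normalize_log(X0), "zero-total")
})

test_that("sparsity filter drops genes strictly over the zero-fraction bound", {
  n <- 1000
  V <- matrix(1, n, 3)
  V[1:996, 1] <- 0    # zero fraction 0.996 > 0.995 -> dropped
  V[1:995, 2] <- 0    # exactly 0.995 -> kept
  X <- make_em(V)
  kept <- sparsity_filter(X)
  expect_setequal(kept$gene_ids, c("g002", "g003"))

  V2 <- cbind(V[, 2:3], 0)  # all-zero gene always dropped
  kept2 <- sparsity_filter(make_em(V2))
  expect_equal(n_genes(kept2), 2)
})

test_that("sparsity and QC filters are idempotent", {
  set.seed(9)
  V <- matrix(rbinom(200 * 50, 10, 0.05), 200, 50)
  X <- make_em(V)
  f1 <- sparsity_filter(X, 0.9, 0.95)
  f2 <- sparsity_filter(f1, 0.9, 0.95)
  expect_identical(f2$gene_ids, f1$gene_ids)
  expect_identical(f2$cell_ids, f1$cell_ids)
})

test_that("Wilcoxon DE: null case, exact small-sample p, and label symmetry", {
  # identical values in both groups -> lnFC 0, p 1
  X <- make_em(matrix(rep(c(1, 2), 4), 4, 2), condition = c(0, 0, 1, 1),
               normalized = TRUE)
  de <- wilcoxon_de(X)
  expect_equal(de$lnFC, c(0, 0))
  expect_equal(de$p_value, c(1, 1))

  # groups {1,2} vs {3,4}: exact two-sided p = 2/6 over C(4,2) assignments
  X2 <- make_em(matrix(c(1, 2, 3, 4)), condition = c(0, 0, 1, 1),
                normalized = TRUE)
  expect_equal(wilcoxon_de(X2)$p_value, 1 / 3)

  # swapping labels negates lnFC, keeps p
  de_a <- wilcoxon_de(X2)
  de_b <- wilcoxon_de(X2, condition = 1 - c(0, 0, 1, 1))
  expect_equal(de_b$lnFC, -de_a$lnFC)
  expect_equal(de_b$p_value, de_a$p_value)
})

test_that("small-sample Wilcoxon p equals exhaustive permutation enumeration", {
  # independent oracle: enumerate all assignments and compare the U statistic's
  # distance from its mean; replicated over random draws with ties
  set.seed(21)
  for (rep in 1:10) {
    n0 <- sample(2:6, 1); n1 <- sample(2:6, 1)
    v <- sample(1:4, n0 + n1, replace = TRUE)  # heavy ties
    x0 <- v[seq_len(n0)]; x1 <- v[n0 + seq_len(n1)]
    got <- rewirekit:::mann_whitney(x0, x1)
    r <- rank(v); mu <- n0 * n1 / 2
    U_of <- function(idx1) sum(r[idx1]) - n1 * (n1 + 1) / 2
    d_all <- apply(combn(n0 + n1, n1), 2, function(ix) abs(U_of(ix) - mu))
    d_obs <- abs(U_of(n0 + seq_len(n1)) - mu)
    expect_equal(got$p, mean(d_all >= d_obs - 1e-12))
  }
})

test_that("large-sample Wilcoxon p matches the tie-corrected normal statistic", {
  set.seed(8)
  x0 <- rnorm(30); x1 <- rnorm(25, 0.5)
  got <- rewirekit:::mann_whitney(x0, x1)
  ref <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("rank statistics are invariant to strictly monotone transforms", {
  set.seed(13)
  v <- rnorm(40); cond <- rep(c(0, 1), 20)
  f <- function(x) exp(2 * x) + 1  # strictly increasing
  expect_equal(gene_condition_auc(v, cond), gene_condition_auc(f(v), cond))
  a <- rewirekit:::mann_whitney(v[cond == 0], v[cond == 1])
  b <- rewirekit:::mann_whitney(f(v)[cond == 0], f(v)[cond == 1])
  expect_equal(a$p, b$p)
})

test_that("DE significance uses strict raw-p and lnFC cutoffs", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   lnFC = c(0.5, 0.1, -0.3, 0.2),
                   p_value = c(0.05, 0.01, 0.01, 0.002))
  sig <- de_significant(de)
  expect_equal(sig$all, c("c", "d"))  # a: p not < .05; b: |lnFC| not > .1
  expect_equal(sig$down, "c")
  expect_equal(sig$up, "d")

  # brute-force oracle on random tables
  set.seed(2)
  de2 <- data.frame(gene = sprintf("g%02d", 1:50),
                    lnFC = round(rnorm(50, 0, 0.2), 2),
                    p_value = round(runif(50), 2))
  expect_equal(de_significant(de2)$all,
               de2$gene[de2$p_value < 0.05 & abs(de2$lnFC) > 0.1])
})

test_that("gene condition AUC matches pairwise enumeration", {
  expect_equal(gene_condition_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # values [1,4,2,3]: wins {2>1, 3>1}, losses {2<4, 3<4} -> 2/4
  expect_equal(gene_condition_auc(c(1, 4, 2, 3), c(0, 0, 1, 1)), 0.5)
  expect_equal(gene_condition_auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)

  set.seed(5)
  for (rep in 1:10) {
    v <- sample(1:6, 14, replace = TRUE)
    cond <- sample(rep(c(0, 1), 7))
    pairs <- expand.grid(i = which(cond == 0), j = which(cond == 1))
    oracle <- mean(ifelse(v[pairs$j] > v[pairs$i], 1,
                          ifelse(v[pairs$j] == v[pairs$i], 0.5, 0)))
    expect_equal(gene_condition_auc(v, cond), oracle)
    expect_equal(gene_condition_auc(-v, cond), 1 - gene_condition_auc(v, cond))
  }
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- sprintf("u%02d", 1:20)
  pw <- list(hit5 = universe[1:5], none = universe[6:10])
  res <- fisher_enrichment(universe[1:5], universe, pw)
  # all 5 hits inside a 5-gene pathway: p = 1 / C(20,5)
  expect_equal(res$p[res$pathway == "hit5"], 1 / choose(20, 5))
  # zero overlap is never flagged
  none_row <- res[res$pathway == "none", ]
  expect_equal(none_row$overlap, 0)
  expect_false(none_row$significant)

  # BH q-values are monotone in the p-value ranking
  set.seed(6)
  pws <- lapply(1:8, function(i) sample(universe, sample(3:8, 1)))
  names(pws) <- paste0("p", 1:8)
  res2 <- fisher_enrichment(sample(universe, 7), universe, pws)
  expect_true(all(diff(res2$q[order(res2$p)]) >= -1e-12))
  expect_error(fisher_enrichment("a", character(0), pws), "empty universe")
})
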