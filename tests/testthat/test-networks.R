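test_that("definitive assignment takes the max-magnitude factor with tie rule", {
  A <- rbind(g1 = c(0.9, 0.1), g2 = c(0.2, -0.8))
  expect_equal(definitive_assignment(A), c(g1 = 1L, g2 = 2L))
  # exact tie goes to the lowest factor index
  expect_equal(unname(definitive_assignment(rbind(x = c(0.5, 0.5)))), 1L)
  # all-zero row is unassigned
  expect_true(is.na(definitive_assignment(rbind(z = c(0, 0)))[1]))

  set.seed(30)
  A2 <- matrix(rnorm(100 * 6), 100, 6,
               dimnames = list(sprintf("g%03d", 1:100), NULL))
  oracle <- apply(A2, 1, function(r) which.max(abs(r)))
  expect_equal(unname(definitive_assignment(A2)), unname(oracle))
})

test_that("assigned genes form a partition across factors", {
  set.seed(31)
  A <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(sprintf("g%02d", 1:50), NULL))
  A[1:5, ] <- 0
  asg <- definitive_assignment(A)
  groups <- split(names(asg)[!is.na(asg)], asg[!is.na(asg)])
  expect_equal(sum(lengths(groups)), 45)
  expect_equal(anyDuplicated(unlist(groups)), 0L)
})

test_that("principal split returns the two largest factors", {
  A <- matrix(0, 9, 2, dimnames = list(paste0("g", 1:9), NULL))
  A[1:5, 1] <- 1; A[6:9, 2] <- 1
  sp <- principal_split(A)
  expect_setequal(sp[[1]], paste0("g", 1:5))
  expect_setequal(sp[[2]], paste0("g", 6:9))

  A3 <- matrix(0, 93, 3, dimnames = list(sprintf("g%02d", 1:93), NULL))
  A3[1:50, 1] <- 1; A3[51:90, 2] <- 1; A3[91:93, 3] <- 1
  expect_warning(sp3 <- principal_split(A3), "two largest")
  expect_equal(lengths(sp3), c(50L, 40L))

  A1 <- matrix(1, 5, 1, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(principal_split(A1), "no split")
})

test_that("nested factorization equals a fresh fit on the gene subset", {
  pl <- planted_sigma(K = 4, ppf = 3, seed = 33)
  cells <- planted_cells(pl, n = 500, noise_sd = 0.1, seed = 33)
  X <- make_em(cells$X - min(cells$X), normalized = TRUE)
  groups <- list(X$gene_ids[1:9], X$gene_ids[10:18])
  nl <- suppressWarnings(
    nested_love(X, groups, delta_grid = c(0.05, 0.1), lambda_grid = 0,
                seed = 5, cv_repeats = 2, min_genes = 8))
  direct <- suppressWarnings(
    fit_love(subset_cells(X, genes = groups[[1]]),
             delta_grid = c(0.05, 0.1), lambda_grid = 0,
             seed = derive_seed(5, 1), cv_repeats = 2))
  expect_equal(unname(nl$group1$allocation), unname(direct$allocation))
  # undersized group is skipped with a warning
  expect_warning(
    nl2 <- nested_love(X, list(groups[[1]], X$gene_ids[1:3]),
                       delta_grid = c(0.05, 0.1), lambda_grid = 0,
                       seed = 5, cv_repeats = 2, min_genes = 8),
    "skipped")
  expect_named(nl2, "group1")
})

test_that("top features ranks by absolute weight within assigned genes", {
  A <- rbind(a = c(0.9, 0), b = c(0.5, 0.1), c = c(0.1, 0.05), d = c(0, 0.7))
  tf <- top_features(A, k = 2)
  expect_equal(tf[[1]], c("a", "b"))
  expect_equal(tf[[2]], "d")
  # small factor returns all members
  expect_equal(top_features(A, k = 50)[[1]], c("a", "b", "c"))

  set.seed(34)
  A2 <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(sprintf("g%02d", 1:60), NULL))
  tf2 <- top_features(A2, k = 5)
  asg <- definitive_assignment(A2)
  for (f in 1:3) {
    members <- names(asg)[asg == f]
    oracle <- members[order(-abs(A2[members, f]))][1:min(5, length(members))]
    expect_equal(tf2[[f]], oracle)
  }
})

test_that("median non-zero filter requires lowest quantile in both conditions", {
  expect_equal(rewirekit:::median_nonzero(c(0, 0, 1, 3)), 2)
  expect_equal(rewirekit:::median_nonzero(c(0, 0)), -Inf)

  # planted medians: gene low in condition 0 only is kept (AND semantics)
  V0 <- rbind(c(1, 10, 10, 10), c(1, 10, 10, 10))    # gene 1 low in cond 0
  V1 <- rbind(c(10, 1, 10, 10), c(10, 1, 10, 10))    # gene 2 low in cond 1
  X0 <- make_em(V0, condition = c(0, 0), normalized = TRUE)
  X1 <- make_em(V1, condition = c(1, 1), normalized = TRUE)
  kept <- median_nonzero_filter(X0, X1, sprintf("g%03d", 1:4), q = 0.25)
  expect_setequal(kept, sprintf("g%03d", 1:4))
  # gene low in both conditions is excluded
  V1b <- V0
  X1b <- make_em(V1b, condition = c(1, 1), normalized = TRUE)
  kept2 <- median_nonzero_filter(X0, X1b, sprintf("g%03d", 1:4), q = 0.25)
  expect_false("g001" %in% kept2)

  # brute-force double-ranking oracle on planted medians
  set.seed(35)
  M <- matrix(sample(1:40, 40), 2, 20)   # distinct medians, 20 candidates
  Xa <- make_em(rbind(M[1, ], M[1, ]), condition = c(0, 0), normalized = TRUE)
  Xb <- make_em(rbind(M[2, ], M[2, ]), condition = c(1, 1), normalized = TRUE)
  cand <- sprintf("g%03d", 1:20)
  got <- median_nonzero_filter(Xa, Xb, cand, q = 0.25)
  low_a <- M[1, ] <= quantile(M[1, ], 0.25)
  low_b <- M[2, ] <= quantile(M[2, ], 0.25)
  expect_equal(got, cand[!(low_a & low_b)])
})

test_that("OR keeps edges with one marker endpoint, AND needs both", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ppi.tsv")
  writeLines(c("a\tb", "b\tc", "c\td"), f)
  ppi <- read_interactome(f)

  net1 <- build_subnetwork("a", ppi)
  el <- igraph::as_edgelist(net1)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("a", "b"))
  roles <- setNames(igraph::V(net1)$role, igraph::V(net1)$name)
  expect_equal(roles[["a"]], "marker")
  expect_equal(roles[["b"]], "interactor")

  net2 <- build_subnetwork(c("a", "c"), ppi)
  expect_equal(igraph::ecount(net2), 3)

  net3 <- build_subnetwork(c("a", "c"), ppi, logic = "AND")
  expect_equal(igraph::ecount(net3), 0)

  expect_warning(empty <- build_subnetwork("zzz", ppi), "no marker")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("OR networks are monotone in the marker set", {
  dir <- withr::local_tempdir()
  set.seed(36)
  nodes <- sprintf("n%02d", 1:30)
  f <- file.path(dir, "ppi.tsv")
  writeLines(paste(sample(nodes, 60, TRUE), sample(nodes, 60, TRUE), sep = "\t"), f)
  ppi <- read_interactome(f)
  m1 <- sample(nodes, 5); m2 <- sample(nodes, 5)
  eset <- function(net) {
    el <- igraph::as_edgelist(net)
    if (!nrow(el)) character(0) else
      apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  }
  e_union <- eset(build_subnetwork(union(m1, m2), ppi))
  expect_true(all(eset(build_subnetwork(m1, ppi)) %in% e_union))
  expect_true(all(eset(build_subnetwork(m2, ppi)) %in% e_union))
})

test_that("marker matching is case-insensitive with case preserved", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ppi.tsv")
  writeLines(c("Gsn\tActb", "Actb\tKrt8"), f)
  ppi <- read_interactome(f)
  net <- build_subnetwork("GSN", ppi)
  expect_true("Gsn" %in% igraph::V(net)$name)
  expect_equal(igraph::ecount(net), 1)
})
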