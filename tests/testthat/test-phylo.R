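mk_gm <- function(alleles) {
  snpanel:::new_genotype_matrix(
    sites = data.frame(replicon = "chr1", pos = seq_len(nrow(alleles)),
                       ref = rep("A", nrow(alleles)), stringsAsFactors = FALSE),
    alleles = alleles, partition = "nuclear")
}

test_that("pairwise differences are exact Hamming counts", {
  A <- cbind(i = c("A", "C", "G", "T"), j = c("A", "C", "C", "C"))
  d <- pairwise_differences(mk_gm(A))
  expect_equal(d["i", "j"], 2)
  expect_equal(d["i", "i"], 0)
  expect_equal(d, t(d))
  # random matrix vs double loop
  set.seed(8)
  B <- matrix(sample(BASES4, 60 * 5, replace = TRUE), 60, 5,
              dimnames = list(NULL, paste0("a", 1:5)))
  d <- pairwise_differences(mk_gm(B))
  for (i in 1:5) for (j in 1:5)
    expect_equal(d[i, j], sum(B[, i] != B[, j]))
  # metric properties
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, k], d[i, j] + d[j, k])
  expect_equal(unname(diag(d)), rep(0, 5))
  # per-site normalization
  expect_equal(pairwise_differences(mk_gm(B), per_site = TRUE), d / 60)
})

test_that("neighbor joining reproduces the 4-taxon worked example", {
  d <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 9,
                9, 10, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  splits <- tree_bipartitions(tr)
  expect_equal(length(splits), 1L)
  expect_equal(splits[[1]], c("C", "D"))
  tip_len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                           tr$edge[, 2])], tr$tip.label)
  expect_equal(tip_len[["A"]], 1)
  expect_equal(tip_len[["B"]], 2)
  expect_equal(tip_len[["C"]], 4)
  expect_equal(tip_len[["D"]], 5)
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(sort(internal)[length(internal)], 3)
})

test_that("three taxa solve the three-point equations exactly", {
  d <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  tip_len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                           tr$edge[, 2])], tr$tip.label)
  expect_equal(tip_len[["a"]], (5 + 7 - 8) / 2)
  expect_equal(tip_len[["b"]], (5 + 8 - 7) / 2)
  expect_equal(tip_len[["c"]], (7 + 8 - 5) / 2)
})

test_that("NJ recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  for (trial in 1:100) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    true$tip.label <- paste0("t", seq_len(n))
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d)
    expect_equal(setdiff(names(tree_bipartitions(est)),
                         names(tree_bipartitions(ape::unroot(true)))),
                 character(0))
    expect_equal(phangorn::RF.dist(est, ape::unroot(true)), 0)
  }
})

test_that("distance validation and tie-breaking are enforced", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
  d3[1, 2] <- NA; d3[2, 1] <- NA
  expect_error(nj_tree(d3), "non-finite")
})

test_that("bootstrap support is exact for a perfectly structured matrix", {
  # every column splits {a1,a2} from {b1,b2,b3} identically
  A <- rbind(matrix(rep(c("T", "T", "C", "C", "C"), 30), 30, 5, byrow = TRUE))
  colnames(A) <- c("a1", "a2", "b1", "b2", "b3")
  tr <- bootstrap_support(mk_gm(A), n_replicates = 50, seed = 1)
  sup <- attr(tr, "support")
  # the split separating {a1,a2} from the b's is supported by every replicate
  # (ties among the identical b's may add an arbitrary zero-length split)
  key <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_equal(sup$support[sup$split == key], 100)
  # reproducibility and range
  tr2 <- bootstrap_support(mk_gm(A), n_replicates = 50, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_true(all(sup$support >= 0 & sup$support <= 100))
  expect_error(bootstrap_support(mk_gm(A), n_replicates = 0), "n_replicates")
})

test_that("bootstrap support is invariant to accession input order", {
  set.seed(3)
  A <- matrix(sample(c("A", "G"), 200 * 6, replace = TRUE, prob = c(0.7, 0.3)),
              200, 6, dimnames = list(NULL, paste0("x", 1:6)))
  t1 <- bootstrap_support(mk_gm(A), 30, seed = 9)
  t2 <- bootstrap_support(mk_gm(A[, sample(6)]), 30, seed = 9)
  s1 <- attr(t1, "support"); s2 <- attr(t2, "support")
  expect_equal(s1[order(s1$split), c("split", "support")],
               s2[order(s2$split), c("split", "support")],
               ignore_attr = TRUE)
})

test_that("outgroup rooting places the root and validates monophyly", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,OUT:3):1);")
  rooted <- root_at_outgroup(tr, "OUT")
  expect_true(ape::is.rooted(rooted))
  # ingroup forms ((A,B),C) under the root
  expect_true(is_monophyletic_group(rooted, c("A", "B", "C")))
  expect_true(is_monophyletic_group(rooted, c("A", "B")))
  expect_error(root_at_outgroup(tr, "missing_leaf"), "absent")
  bad <- ape::read.tree(text = "((A:1,OG1:1):1,(B:1,OG2:1):1);")
  expect_error(root_at_outgroup(bad, c("OG1", "OG2")), "not monophyletic")
})

test_that("tree comparison counts conflicting bipartitions correctly", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(compare_trees(t1, t1)$rf, 0)
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  cmp <- compare_trees(t1, t2)
  expect_equal(cmp$rf, 2)
  expect_equal(length(cmp$only_tree1), 1L)
  expect_equal(length(cmp$only_tree2), 1L)
  expect_error(compare_trees(t1, ape::read.tree(text = "(X:1,Y:1,Z:1);")),
               "fewer than 4")
})

test_that("RF distance agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(6)
  for (trial in 1:25) {
    n <- sample(5:12, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n)
    t1$tip.label <- paste0("t", 1:n); t2$tip.label <- paste0("t", sample(n))
    expect_equal(compare_trees(t1, t2)$rf,
                 phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
  }
})

test_that("pairwise summaries flag well separated diversity clusters", {
  s <- summarize_pairwise(c(10, 12, 300, 310))
  expect_equal(s$median, 156)
  expect_true(s$gap_flag)
  expect_false(summarize_pairwise(c(10, 12, 14, 16))$gap_flag)
  expect_false(summarize_pairwise(c(0, 0, 0))$gap_flag)
})

test_that("diversity summary reports per species and skips singletons", {
  panel <- species_panel(c("a1", "a2", "a3", "b1", "og"),
                         c("A", "A", "A", "B", "OG"), outgroup = "og")
  set.seed(2)
  A <- matrix(sample(BASES4, 100 * 5, replace = TRUE), 100, 5,
              dimnames = list(NULL, panel$accession))
  d <- pairwise_differences(mk_gm(A))
  expect_warning(s <- diversity_summary(d, panel), "fewer than two")
  expect_equal(s$species, "A")
  expect_equal(s$n_pairs, 3L)
  vals <- attr(s, "values")$A
  expect_equal(sort(vals), sort(c(d["a1", "a2"], d["a1", "a3"], d["a2", "a3"])))
  expect_equal(s$median, median(vals))
})
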