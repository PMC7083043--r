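# Minimal hand-built call/status structures
mk_result <- function(calls, status) list(calls = calls, status = status)

calls_df <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  if (!nrow(d)) d <- data.frame(replicon = character(), pos = integer(),
                                ref = character(), alt = character(),
                                variant_class = character())
  d
}

status_df <- function(...) data.frame(..., stringsAsFactors = FALSE)

test_that("a site unusable in any accession is excluded from the matrix", {
  panel <- species_panel(c("x1", "y1"), c("X", "Y"))
  res <- list(
    x1 = mk_result(
      calls_df(replicon = "chr1", pos = 10L, ref = "C", alt = "T",
               variant_class = "SNP"),
      status_df(replicon = "chr1", pos = 10L, ref = "C",
                status = "ALT_CALLED", allele = "T")),
    y1 = mk_result(
      calls_df(),
      status_df(replicon = "chr1", pos = 10L, ref = "C",
                status = "LOW_DEPTH", allele = NA_character_)))
  gm <- build_matrix(res, panel)
  expect_equal(nrow(gm$sites), 0L)
  # absent status rows (no coverage at all) also exclude
  res$y1$status <- status_df(replicon = "chr1", pos = 99L, ref = "A",
                             status = "REF_CONFIRMED", allele = NA_character_)
  expect_equal(nrow(build_matrix(res, panel)$sites), 0L)
  # both usable -> retained with alt and ref cells
  res$y1$status <- status_df(replicon = "chr1", pos = 10L, ref = "C",
                             status = "REF_CONFIRMED", allele = NA_character_)
  gm <- build_matrix(res, panel)
  expect_equal(gm$sites$pos, 10L)
  expect_equal(unname(gm$alleles[1, ]), c("T", "C"))
  expect_error(build_matrix(res["x1"], panel), "no call/status")
})

test_that("indel-bearing sites never enter the matrix", {
  panel <- species_panel(c("x1", "y1"), c("X", "Y"))
  res <- list(
    x1 = mk_result(
      calls_df(replicon = "chr1", pos = 5L, ref = "G", alt = "A",
               variant_class = "SNP"),
      status_df(replicon = "chr1", pos = 5L, ref = "G",
                status = "ALT_CALLED", allele = "A")),
    y1 = mk_result(
      calls_df(replicon = "chr1", pos = 5L, ref = "G", alt = "DEL",
               variant_class = "indel"),
      status_df(replicon = "chr1", pos = 5L, ref = "G",
                status = "ALT_CALLED", allele = "DEL")))
  expect_equal(nrow(build_matrix(res, panel)$sites), 0L)
})

test_that("noiseless full-coverage matrix equals the truth set", {
  cfg <- simulation_config(
    seed = 31,
    species_tree = "((A:0.03,B:0.03):0.01,(C:0.02,(D:0.02,E:0.02):0.01):0.01,F:0.05);",
    accessions_per_species = c(A = 3L, B = 3L, C = 3L, D = 3L, E = 3L, F = 3L),
    within_species_diversity = c(A = 0.001, B = 0.001, C = 0.001,
                                 D = 0.001, E = 0.001, F = 0.001),
    replicons = data.frame(name = "chr1", length = 10000L,
                           is_organelle = FALSE),
    mean_depth = 50, dropout_rate = 0, error_rate = 0)
  sim <- simulate_panel(cfg)
  gm <- build_matrix(run_calls(sim), sim$panel)
  truthm <- sim$truth$seqs$chr1
  refv <- sim$truth$reference$chr1
  variable <- which(rowSums(truthm != refv) > 0)
  expect_equal(gm$sites$pos, variable)
  expect_false(any(is.na(gm$alleles)))
  expect_equal(unname(gm$alleles),
               unname(matrix(BASES4[truthm[variable, sim$panel$accession]],
                             nrow = length(variable))))
})

test_that("retained sites match brute-force recomputation from pileups", {
  cfg <- tiny_panel_config(seed = 32, L = 1500L)
  sim <- simulate_panel(cfg)
  gm <- build_matrix(run_calls(sim), sim$panel)
  accs <- sim$panel$accession
  # oracle: per accession, classify every emitted site with the scalar rule
  oracle <- lapply(accs, function(a) {
    p <- sim$pileups[[a]]
    st <- vapply(seq_len(nrow(p)), function(i)
      brute_status(p$nA[i], p$nC[i], p$nG[i], p$nT[i], p$nN[i], p$nDel[i],
                   p$nIns[i], p$ref[i])$status, "")
    al <- vapply(seq_len(nrow(p)), function(i)
      brute_status(p$nA[i], p$nC[i], p$nG[i], p$nT[i], p$nN[i], p$nDel[i],
                   p$nIns[i], p$ref[i])$allele, "")
    list(pos = p$pos, status = st, allele = al, ref = p$ref)
  })
  names(oracle) <- accs
  cand <- sort(unique(unlist(lapply(oracle, function(o)
    o$pos[o$status == "ALT_CALLED" & o$allele %in% BASES4]))))
  keep <- vapply(cand, function(pos) {
    all(vapply(accs, function(a) {
      o <- oracle[[a]]
      i <- match(pos, o$pos)
      if (is.na(i)) return(FALSE)
      o$status[i] == "REF_CONFIRMED" ||
        (o$status[i] == "ALT_CALLED" && o$allele[i] %in% BASES4)
    }, logical(1)))
  }, logical(1))
  expect_equal(gm$sites$pos, cand[keep])
  # cell values re-derivable from the oracle statuses
  for (a in accs) {
    o <- oracle[[a]]
    i <- match(cand[keep], o$pos)
    expected <- ifelse(o$status[i] == "ALT_CALLED", o$allele[i], o$ref[i])
    expect_equal(unname(gm$alleles[, a]), expected)
  }
})

random_matrix <- function(n_sites, panel, seed, n_alleles = 2) {
  set.seed(seed)
  alleles <- matrix(
    sample(BASES4[seq_len(n_alleles)], n_sites * nrow(panel), replace = TRUE),
    n_sites, nrow(panel), dimnames = list(NULL, panel$accession))
  snpanel:::new_genotype_matrix(
    sites = data.frame(replicon = "chr1", pos = seq_len(n_sites),
                       ref = rep("A", n_sites), stringsAsFactors = FALSE),
    alleles = alleles, partition = "nuclear")
}

test_that("classification agrees with triple-loop oracles on random matrices", {
  panel <- species_panel(
    accession = sprintf("s%02d", 1:12),
    species = rep(c("X", "Y", "Z", "W"), each = 3),
    outgroup = c("s10", "s11", "s12"))
  gm <- random_matrix(800, panel, seed = 77, n_alleles = 3)
  A <- gm$alleles
  sp_of <- setNames(panel$species, panel$accession)

  for (s in c("X", "Y")) {
    accs <- panel$accession[panel$species == s]
    oracle_poly <- which(vapply(seq_len(nrow(A)), function(i)
      length(unique(A[i, accs])) >= 2, logical(1)))
    expect_equal(polymorphic_sites(gm, panel, s)$row, oracle_poly)
  }
  oracle_fixed <- which(vapply(seq_len(nrow(A)), function(i) {
    ax <- unique(A[i, panel$accession[panel$species == "X"]])
    ay <- unique(A[i, panel$accession[panel$species == "Y"]])
    length(ax) == 1 && length(ay) == 1 && ax != ay
  }, logical(1)))
  fx <- fixed_snps(gm, panel, "X", "Y")
  expect_equal(fx$row, oracle_fixed)
  # symmetry
  fy <- fixed_snps(gm, panel, "Y", "X")
  expect_equal(fx$row, fy$row)
  expect_equal(fx$allele_a, fy$allele_b)

  ingroup <- c("X", "Y", "Z")
  for (s in ingroup) {
    accs <- panel$accession[panel$species == s]
    others <- panel$accession[panel$species %in% setdiff(ingroup, s)]
    oracle_uni <- which(vapply(seq_len(nrow(A)), function(i) {
      g <- unique(A[i, accs])
      length(g) == 1 && !g %in% A[i, others]
    }, logical(1)))
    expect_equal(unique_substitutions(gm, panel, s)$row, oracle_uni)
  }
})

test_that("biallelic sites admit at most one unique-substitution owner", {
  panel <- species_panel(sprintf("s%d", 1:9), rep(c("X", "Y", "Z"), each = 3))
  gm <- random_matrix(2000, panel, seed = 5, n_alleles = 2)
  ux <- unique_substitutions(gm, panel, "X")$row
  uy <- unique_substitutions(gm, panel, "Y")$row
  uz <- unique_substitutions(gm, panel, "Z")$row
  expect_equal(length(intersect(ux, uy)), 0L)
  expect_equal(length(intersect(ux, uz)), 0L)
  expect_equal(length(intersect(uy, uz)), 0L)
  # fixed SNPs of a pair are polymorphic in neither species
  fx <- fixed_snps(gm, panel, "X", "Y")$row
  expect_equal(length(intersect(fx, polymorphic_sites(gm, panel, "X")$row)), 0L)
  expect_equal(length(intersect(fx, polymorphic_sites(gm, panel, "Y")$row)), 0L)
})

test_that("degenerate classification inputs are rejected or warned", {
  panel <- species_panel(c("a1", "b1", "b2"), c("A", "B", "B"))
  gm <- random_matrix(50, panel, seed = 1)
  expect_warning(out <- polymorphic_sites(gm, panel, "A"), "single accession")
  expect_equal(nrow(out), 0L)
  expect_error(fixed_snps(gm, panel, "A", "A"), "distinct species")
  expect_error(unique_substitutions(gm, panel, c("A", "B")), "whole")
})
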