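#' Pairwise nucleotide differences between accessions
#'
#' Hamming distance over the matrix sites: `d(i, j)` is the number of
#' sites at which accessions `i` and `j` carry different alleles (any
#' mismatch counts once, also at multi-allelic sites).  This matches the
#' semantics of raw pairwise-difference diversity plots; set
#' `per_site = TRUE` for the rate, or `jc = TRUE` for the Jukes-Cantor
#' corrected per-site distance.
#'
#' @param gm A [genotype_matrix] (nonempty).
#' @param per_site Normalize by the number of matrix sites.
#' @param jc Apply the Jukes-Cantor correction
#'   `-3/4 * log(1 - 4p/3)` to the per-site mismatch fraction.
#' @return Symmetric numeric matrix with accession dimnames.
#' @export
pairwise_differences <- function(gm, per_site = FALSE, jc = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$sites) == 0) stop("genotype matrix is empty")
  A <- gm$alleles
  L <- nrow(A)
  S <- matrix(0, ncol(A), ncol(A))
  for (b in BASES) S <- S + crossprod(A == b)
  D <- L - S
  dimnames(D) <- list(colnames(A), colnames(A))
  if (jc) {
    p <- pmin(D / L, 0.7499)
    D <- -0.75 * log(1 - 4 * p / 3)
    diag(D) <- 0
  } else if (per_site) D <- D / L
  D
}

#' Summarize a set of pairwise difference values
#'
#' Median, range and a multimodality (gap) flag for a vector of pairwise
#' differences.  The gap flag is raised when the values split into well
#' separated clusters: with at least four values, the largest gap between
#' consecutive sorted values exceeds the sum of all other gaps (i.e. more
#' than half the total spread sits in one gap), evidence of discrete
#' sublineages.
#'
#' @param values Numeric vector of pairwise differences.
#' @return One-row data frame: n_pairs, median, min, max, gap_flag.
#' @export
summarize_pairwise <- function(values) {
  stopifnot(length(values) >= 1)
  s <- sort(values)
  gaps <- diff(s)
  flag <- length(s) >= 4 && max(gaps) > sum(gaps) - max(gaps) && max(gaps) > 0
  data.frame(n_pairs = length(s), median = stats::median(s),
             min = s[1], max = s[length(s)], gap_flag = flag)
}

#' Within-species diversity summary
#'
#' For each non-outgroup species with at least two accessions: all
#' within-species pairwise difference values with median, min, max, and
#' the sublineage gap flag of [summarize_pairwise].  Singleton species are
#' skipped with a warning.
#'
#' @param d Distance matrix from [pairwise_differences].
#' @param panel A [species_panel].
#' @return Data frame (one row per species); the raw per-species value
#'   vectors ride along as attribute `"values"`.
#' @export
diversity_summary <- function(d, panel) {
  sp <- unique(panel$species[!panel$is_outgroup])
  vals <- list()
  rows <- list()
  for (s in sp) {
    accs <- intersect(panel_accessions(panel, s), rownames(d))
    if (length(accs) < 2) {
      warning("species ", s, " has fewer than two accessions; skipped")
      next
    }
    v <- d[accs, accs][upper.tri(diag(length(accs)))]
    vals[[s]] <- v
    rows[[s]] <- cbind(data.frame(species = s, n_accessions = length(accs)),
                       summarize_pairwise(v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "values") <- vals
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (successively joining the pair
#' minimizing the Q criterion), exact on additive matrices.  Labels are
#' sorted lexicographically before construction so the result is invariant
#' to input order; negative branch lengths are clamped to zero and the
#' clamped total recorded in attribute `"clamped_total"`.
#'
#' @param d Symmetric numeric distance matrix with >= 3 labelled rows.
#' @return An unrooted [ape::phylo].
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(!is.finite(d))) stop("distance matrix contains non-finite values")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  ord <- order(rownames(d))
  tr <- ape::nj(stats::as.dist(d[ord, ord]))
  neg <- tr$edge.length < 0
  attr(tr, "clamped_total") <- sum(-tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Canonical bipartitions of an unrooted tree
#'
#' Every internal edge defines a split of the leaf set.  Splits are
#' canonicalized as the side not containing the alphabetically first leaf
#' and keyed by the sorted, `|`-joined member labels; trivial splits
#' (single leaf or its complement) are dropped.
#'
#' @param tree An [ape::phylo].
#' @return Named list of character vectors (split members), names = keys.
#' @export
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  first <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (first %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    out[[paste(sort(side), collapse = "|")]] <- sort(side)
  }
  out
}

canonical_split_key <- function(members, labs) {
  side <- members
  if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
  paste(sort(side), collapse = "|")
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples matrix columns (sites) with replacement, rebuilds the NJ tree
#' per replicate, and annotates each internal edge of the point-estimate
#' tree with the percentage of replicates containing the same bipartition.
#' Supports are written into `node.label` (the Newick convention) and the
#' full table is attached as attribute `"support"`.
#'
#' @param gm A [genotype_matrix].
#' @param n_replicates Number of bootstrap replicates (>= 1), default 1000.
#' @param seed Integer seed for the resampling.
#' @return The point-estimate [ape::phylo] with support in `node.label`.
#' @export
bootstrap_support <- function(gm, n_replicates = 1000, seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  point <- nj_tree(pairwise_differences(gm))
  splits <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(splits)), names(splits))
  A <- gm$alleles
  L <- nrow(A)
  ind <- lapply(BASES, function(b) A == b)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    S <- matrix(0, ncol(A), ncol(A))
    for (I in ind) S <- S + crossprod(I[cols, , drop = FALSE])
    D <- L - S
    dimnames(D) <- list(colnames(A), colnames(A))
    rep_splits <- names(tree_bipartitions(nj_tree(D)))
    hit <- names(counts) %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  # map supports onto internal node labels of the point tree
  ntip <- length(point$tip.label)
  pp <- ape::prop.part(point)
  labs <- point$tip.label
  node.label <- character(point$Nnode)
  for (i in seq_along(pp)) {
    key <- canonical_split_key(labs[pp[[i]]], labs)
    node.label[i] <- if (key %in% names(support))
      formatC(support[[key]], format = "f", digits = 1) else ""
  }
  point$node.label <- node.label
  attr(point, "support") <- data.frame(
    split = names(support), support = unname(support),
    members = vapply(splits, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  point
}

#' Root a tree at its outgroup
#'
#' Places the root on the edge separating the outgroup accessions from the
#' ingroup.  Errors (with the offending bipartitions listed) when the
#' outgroup is not monophyletic on the unrooted tree.
#'
#' @param tree An [ape::phylo].
#' @param panel A [species_panel] with flagged outgroup accessions, or a
#'   character vector of outgroup tip labels.
#' @return A rooted [ape::phylo].
#' @export
root_at_outgroup <- function(tree, panel) {
  og <- if (inherits(panel, "species_panel"))
    panel$accession[panel$is_outgroup] else panel
  if (!length(og)) stop("no outgroup accessions defined")
  missing <- setdiff(og, tree$tip.label)
  if (length(missing))
    stop("outgroup leaf absent from tree: ", paste(missing, collapse = ", "))
  n <- length(tree$tip.label)
  if (length(og) > 1 && length(og) < n - 1) {
    key <- canonical_split_key(og, tree$tip.label)
    if (!key %in% names(tree_bipartitions(tree))) {
      conflicts <- Filter(function(s) length(intersect(s, og)) > 0 &&
                            length(setdiff(s, og)) > 0,
                          tree_bipartitions(tree))
      stop("outgroup is not monophyletic; straddling bipartitions: ",
           paste(names(conflicts), collapse = " ; "))
    }
  }
  ape::root(tree, outgroup = og, resolve.root = TRUE)
}

induced_species_splits <- function(tree, panel) {
  sp_of <- stats::setNames(panel$species, panel$accession)
  species <- sort(unique(sp_of[tree$tip.label]))
  if (length(species) < 4) return(list())
  splits <- tree_bipartitions(tree)
  out <- list()
  for (s in splits) {
    inside <- unique(sp_of[s])
    outside <- unique(sp_of[setdiff(tree$tip.label, s)])
    if (length(intersect(inside, outside))) next  # a species straddles
    side <- sort(inside)
    if (sort(species)[1] %in% side) side <- setdiff(species, side)
    if (length(side) < 2 || length(side) > length(species) - 2) next
    out[[paste(sort(side), collapse = "|")]] <- sort(side)
  }
  out
}

#' Compare two trees (congruence report)
#'
#' Robinson-Foulds distance (count of bipartitions present in exactly one
#' tree), the conflicting bipartitions themselves, and — when a panel is
#' supplied — per-species monophyly verdicts in each tree plus the
#' comparison repeated on species-level induced splits (accession splits
#' on which every species falls wholly on one side), which is robust to
#' arbitrary resolution of within-species polytomies.  Comparison is
#' restricted to shared leaves.
#'
#' @param tree1,tree2 [ape::phylo] objects with overlapping leaf sets.
#' @param panel Optional [species_panel].
#' @return A `tree_comparison` list: `rf`, `only_tree1`, `only_tree2`,
#'   `shared_leaves`, and with a panel also `monophyly` (data frame) and
#'   `species_level` (rf + conflicting species splits).
#' @export
compare_trees <- function(tree1, tree2, panel = NULL) {
  shared <- intersect(tree1$tip.label, tree2$tip.label)
  if (length(shared) < 4)
    stop("trees share fewer than 4 leaves; comparison undefined")
  t1 <- ape::keep.tip(tree1, shared)
  t2 <- ape::keep.tip(tree2, shared)
  s1 <- tree_bipartitions(t1)
  s2 <- tree_bipartitions(t2)
  only1 <- s1[setdiff(names(s1), names(s2))]
  only2 <- s2[setdiff(names(s2), names(s1))]
  out <- list(rf = length(only1) + length(only2),
              only_tree1 = only1, only_tree2 = only2,
              shared_leaves = shared)
  if (!is.null(panel)) {
    panel <- panel[panel$accession %in% shared, ]
    sp <- unique(panel$species)
    mono <- data.frame(species = sp, tree1 = NA, tree2 = NA)
    for (i in seq_along(sp)) {
      accs <- panel$accession[panel$species == sp[i]]
      mono$tree1[i] <- is_clade(t1, accs)
      mono$tree2[i] <- is_clade(t2, accs)
    }
    i1 <- induced_species_splits(t1, panel)
    i2 <- induced_species_splits(t2, panel)
    out$monophyly <- mono
    out$species_level <- list(
      rf = length(setdiff(names(i1), names(i2))) +
           length(setdiff(names(i2), names(i1))),
      only_tree1 = i1[setdiff(names(i1), names(i2))],
      only_tree2 = i2[setdiff(names(i2), names(i1))])
  }
  class(out) <- "tree_comparison"
  out
}

#' Is a set of leaves monophyletic on an unrooted tree?
#'
#' TRUE iff the set forms one side of some edge (trivial sets of size 0, 1,
#' n-1 or n are monophyletic by convention).
#'
#' @param tree An [ape::phylo].
#' @param tips Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_monophyletic_group <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  is_clade(tree, tips)
}

# Is `tips` one side of some edge of the unrooted tree?
is_clade <- function(tree, tips) {
  n <- length(tree$tip.label)
  k <- length(tips)
  if (k <= 1 || k >= n - 1) return(TRUE)
  canonical_split_key(tips, tree$tip.label) %in% names(tree_bipartitions(tree))
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("tree comparison over", length(x$shared_leaves), "shared leaves\n")
  cat("Robinson-Foulds distance:", x$rf, "\n")
  if (length(x$only_tree1))
    cat("splits only in tree 1:\n ",
        paste(names(x$only_tree1), collapse = "\n  "), "\n")
  if (length(x$only_tree2))
    cat("splits only in tree 2:\n ",
        paste(names(x$only_tree2), collapse = "\n  "), "\n")
  if (!is.null(x$monophyly)) {
    bad <- x$monophyly[!(x$monophyly$tree1 & x$monophyly$tree2), ]
    if (nrow(bad))
      cat("non-monophyletic species:",
          paste0(bad$species, " (tree1=", bad$tree1, ", tree2=", bad$tree2, ")",
                 collapse = "; "), "\n")
    cat("species-level RF:", x$species_level$rf, "\n")
  }
  invisible(x)
}
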