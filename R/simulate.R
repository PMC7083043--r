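#' Configure a panel simulation
#'
#' Defines the generative model for a multi-species accession panel:
#' species diverge along `species_tree` under Jukes-Cantor substitution
#' (per-branch substitution probability `3/4 * (1 - exp(-4t/3))` for branch
#' length `t` in expected substitutions/site); accessions of a species hang
#' off its terminal node in a star, each on a branch of length
#' `within_species_diversity[species]`, optionally grouped into discrete
#' sublineages separated by an extra shared internal branch.  All genotypes
#' are homozygous (selfing species).  Read evidence is then emitted per
#' site with Poisson (or negative-binomial) depth, dropouts, and per-read
#' miscalls.
#'
#' @param seed Integer seed; the simulator is bit-reproducible under it.
#' @param species_tree Newick string; branch lengths in expected
#'   substitutions/site; leaf labels are species ids.
#' @param accessions_per_species Named integer vector, species -> number of
#'   accessions; names must match the tree's leaves exactly.
#' @param within_species_diversity Named numeric vector, species ->
#'   terminal per-accession branch length; species absent default to 0.
#' @param sublineage_spec Optional named list, species -> `c(k, b)`: split
#'   the species' accessions into `k` sublineages whose ancestors sit on
#'   branches of length `b` below the species node.
#' @param replicons Data frame with columns `name`, `length`,
#'   `is_organelle` describing the replicons to simulate.
#' @param organelle_tree Optional Newick over the same species; organelle
#'   replicons evolve along it instead of `species_tree`, allowing planted
#'   cytonuclear discordance.
#' @param mean_depth Mean read depth per site x accession (> 0).
#' @param depth_dispersion Depth overdispersion; 0 gives Poisson depth,
#'   otherwise negative binomial with variance `mu + d * mu^2`.
#' @param dropout_rate Probability a site x accession has no coverage.
#' @param error_rate Per-read miscall probability (uniform over the three
#'   other bases).
#' @param deletion_rate Per-site per-accession probability of a deletion,
#'   observed in pileups as deletion-supporting reads.
#' @param outgroup_species Optional species id flagged as outgroup.
#' @param outgroup_alignable_fraction Probability that a site is scorable
#'   at all in outgroup accessions (emulates a distant taxon's reduced
#'   alignable fraction).
#' @param genome_labels Optional named character vector species -> genome
#'   label for the panel manifest; defaults to the species id.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed,
                              species_tree,
                              accessions_per_species,
                              within_species_diversity = numeric(),
                              sublineage_spec = NULL,
                              replicons = data.frame(name = "chr1", length = 10000L,
                                                     is_organelle = FALSE),
                              organelle_tree = NULL,
                              mean_depth = 30,
                              depth_dispersion = 0,
                              dropout_rate = 0,
                              error_rate = 0,
                              deletion_rate = 0,
                              outgroup_species = NULL,
                              outgroup_alignable_fraction = 1,
                              genome_labels = NULL) {
  tr <- tryCatch(ape::read.tree(text = species_tree),
                 error = function(e) NULL)
  if (is.null(tr)) stop("species_tree: unparseable newick")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("species_tree must have nonnegative branch lengths")
  if (!setequal(names(accessions_per_species), tr$tip.label))
    stop("accessions_per_species names must exactly match species_tree leaves")
  if (any(accessions_per_species < 1)) stop("accession counts must be >= 1")
  if (!is.null(organelle_tree)) {
    otr <- tryCatch(ape::read.tree(text = organelle_tree), error = function(e) NULL)
    if (is.null(otr)) stop("organelle_tree: unparseable newick")
    if (!setequal(otr$tip.label, tr$tip.label))
      stop("organelle_tree leaves must match species_tree leaves")
  }
  probs <- c(dropout_rate = dropout_rate, error_rate = error_rate,
             deletion_rate = deletion_rate,
             outgroup_alignable_fraction = outgroup_alignable_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  replicons <- as.data.frame(replicons)
  if (!all(c("name", "length", "is_organelle") %in% names(replicons)))
    stop("replicons needs columns name, length, is_organelle")
  if (any(replicons$length < 1)) stop("replicon lengths must be >= 1")
  if (anyDuplicated(replicons$name)) stop("replicon names must be unique")
  if (any(within_species_diversity < 0))
    stop("within_species_diversity must be >= 0")
  if (!is.null(outgroup_species) && !outgroup_species %in% tr$tip.label)
    stop("outgroup_species not a species_tree leaf")
  if (!is.null(sublineage_spec)) {
    for (sp in names(sublineage_spec)) {
      v <- sublineage_spec[[sp]]
      if (length(v) != 2 || v[1] < 2 || v[2] < 0)
        stop("sublineage_spec[[", sp, "]] must be c(k >= 2, branch >= 0)")
      if (accessions_per_species[[sp]] < v[1])
        stop("species ", sp, " has fewer accessions than sublineages")
    }
  }
  structure(list(
    seed = as.integer(seed), species_tree = species_tree,
    accessions_per_species = accessions_per_species,
    within_species_diversity = within_species_diversity,
    sublineage_spec = sublineage_spec, replicons = replicons,
    organelle_tree = organelle_tree, mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, dropout_rate = dropout_rate,
    error_rate = error_rate, deletion_rate = deletion_rate,
    outgroup_species = outgroup_species,
    outgroup_alignable_fraction = outgroup_alignable_fraction,
    genome_labels = genome_labels
  ), class = "sim_config")
}

#' Default 12-species diploid panel configuration
#'
#' The default study conditions: eleven ingroup diploid species in three
#' deep clades (an einkorn-like pair, one deep-branching lineage, and a
#' clade holding the C/U, M/N and D/S-group species), plus a single distant
#' outgroup accession with reduced alignable fraction.  Three focal species
#' carry five accessions each (the newly genotyped panel); reused species
#' carry two or three.  One focal species has two divergent sublineages.
#' The organelle replicon evolves along a discordant tree in which the C
#' species is moved by one nearest-neighbor interchange, planting exactly
#' one conflicting species-level bipartition.  Branch lengths, depth and
#' error rates are stated and motivated in the package vignette.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
default_panel_config <- function(seed = 1) {
  nuc <- paste0(
    "(outgroupH:0.15,((speciesA:0.02,speciesAm:0.02):0.06,",
    "(speciesS:0.07,(((speciesC:0.03,speciesU:0.03):0.015,",
    "(speciesM:0.025,speciesN:0.025):0.02):0.01,",
    "(speciesD:0.03,(speciesSl:0.012,(speciesSb:0.012,speciesSs:0.012):0.006):0.015):0.01)",
    ":0.01):0.01):0.05);")
  # organelle: one NNI — speciesC swapped out of the (C,U) cherry so that
  # (U,(M,N)) forms; everything else identical, lengths scaled down 2x
  org <- paste0(
    "(outgroupH:0.075,((speciesA:0.01,speciesAm:0.01):0.03,",
    "(speciesS:0.035,((speciesC:0.0225,(speciesU:0.015,",
    "(speciesM:0.0125,speciesN:0.0125):0.01):0.0075):0.005,",
    "(speciesD:0.015,(speciesSl:0.006,(speciesSb:0.006,speciesSs:0.006):0.003):0.0075):0.005)",
    ":0.005):0.005):0.025);")
  acc <- c(speciesC = 5L, speciesM = 5L, speciesN = 5L, speciesD = 3L,
           speciesU = 2L, speciesA = 2L, speciesAm = 2L, speciesS = 2L,
           speciesSl = 2L, speciesSb = 2L, speciesSs = 2L, outgroupH = 1L)
  div <- c(speciesC = 0.0015, speciesM = 0.0008, speciesN = 0.002,
           speciesD = 0.001, speciesU = 0.0005, speciesA = 0.0005,
           speciesAm = 0.0005, speciesS = 0.0008, speciesSl = 0.0005,
           speciesSb = 0.0005, speciesSs = 0.0005, outgroupH = 0)
  simulation_config(
    seed = seed, species_tree = nuc, accessions_per_species = acc,
    within_species_diversity = div,
    sublineage_spec = list(speciesC = c(2, 0.004)),
    replicons = data.frame(name = c("chr1", "chr2", "chloroplast"),
                           length = c(20000L, 20000L, 4000L),
                           is_organelle = c(FALSE, FALSE, TRUE)),
    organelle_tree = org, mean_depth = 30, depth_dispersion = 0,
    dropout_rate = 0.02, error_rate = 0.002,
    outgroup_species = "outgroupH", outgroup_alignable_fraction = 0.7,
    genome_labels = c(speciesC = "C", speciesM = "M", speciesN = "N",
                      speciesD = "D", speciesU = "U", speciesA = "A",
                      speciesAm = "Am", speciesS = "S", speciesSl = "Sl",
                      speciesSb = "Sb", speciesSs = "Ss", outgroupH = "H")
  )
}

#' Simulate reference sequences
#'
#' One uniformly random sequence over A/C/G/T per configured replicon.
#'
#' @param config A `sim_config`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- vapply(seq_len(nrow(config$replicons)), function(i) {
    paste(sample(BASES, config$replicons$length[i], replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- config$replicons$name
  Biostrings::DNAStringSet(seqs)
}

dna_to_int <- function(s) {
  i <- match(strsplit(as.character(s), "", fixed = TRUE)[[1]], BASES)
  if (anyNA(i)) stop("sequence contains non-ACGT characters")
  i
}

int_to_dna <- function(x) paste(BASES[x], collapse = "")

jc_p <- function(t) 0.75 * (1 - exp(-4 * t / 3))

# Mutate an integer-coded sequence along a branch of length t under JC.
jc_mutate <- function(x, t) {
  if (t <= 0) return(x)
  p <- jc_p(t)
  i <- which(runif(length(x)) < p)
  if (length(i))
    x[i] <- ((x[i] - 1L + sample(3L, length(i), replace = TRUE)) %% 4L) + 1L
  x
}

# Expand a species tree into an accession-level newick string: each species
# leaf becomes a star of its accessions on terminal branches of length t,
# optionally structured into sublineages.  Returns the newick text.
expand_species_tree <- function(tree_text, config) {
  tree <- ape::read.tree(text = tree_text)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- numeric(max(tree$edge)); blen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  leaf_sub <- function(sp) {
    n <- config$accessions_per_species[[sp]]
    t <- config$within_species_diversity[sp]
    t <- if (is.na(t)) 0 else unname(t)
    accs <- sprintf("%s_%d", sp, seq_len(n))
    sl <- config$sublineage_spec[[sp]]
    if (is.null(sl)) {
      if (n == 1) return(list(str = accs, extra = t))
      return(list(str = paste0("(", paste0(accs, ":", fmt(t), collapse = ","), ")"),
                  extra = 0))
    }
    k <- sl[1]; b <- sl[2]
    grp <- split(accs, rep_len(seq_len(k), n))
    parts <- vapply(grp, function(g) {
      if (length(g) == 1) paste0(g, ":", fmt(b + t))
      else paste0("(", paste0(g, ":", fmt(t), collapse = ","), "):", fmt(b))
    }, character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"), extra = 0)
  }
  rec <- function(node) {
    if (node <= ntip) {
      s <- leaf_sub(tree$tip.label[node])
      paste0(s$str, ":", fmt(blen[node] + s$extra))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, character(1)),
                     collapse = ",")
      paste0("(", inner, ")",
             if (blen[node] > 0 || node != ntip + 1L) paste0(":", fmt(blen[node])) else "")
    }
  }
  root <- ntip + 1L
  inner <- paste(vapply(kids[[as.character(root)]], rec, character(1)),
                 collapse = ",")
  paste0("(", inner, ");")
}

# Evolve an integer reference down an accession tree; returns an L x n_acc
# integer matrix with accession column names.
evolve_along_tree <- function(tree, ref_int) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- ref_int
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    seqs[[ch]] <- jc_mutate(seqs[[p]], tree$edge.length[e])
  }
  out <- matrix(0L, nrow = length(ref_int), ncol = ntip,
                dimnames = list(NULL, tree$tip.label))
  for (i in seq_len(ntip)) out[, i] <- seqs[[i]]
  out
}

#' Evolve a panel of accessions from a reference
#'
#' Applies Jukes-Cantor substitution along the accession-expanded species
#' tree (organelle replicons follow `organelle_tree` when configured) and
#' returns the complete truth: every accession's allele at every simulated
#' position, plus expected within-species diversity per site.
#'
#' @param reference A [Biostrings::DNAStringSet] from [simulate_reference].
#' @param config The `sim_config` used.
#' @return A `truth_set`: list with `seqs` (per replicon, integer matrix
#'   sites x accessions, codes 1-4 = A,C,G,T), `deleted` (logical matrices),
#'   `reference` (integer vectors), `panel` (a [species_panel]),
#'   `acc_tree_nuclear` / `acc_tree_organelle` (newick strings of the true
#'   accession trees), and `expected_diversity` (per-species expected
#'   pairwise differences per site under the configured branch lengths).
#' @export
evolve_panel <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nuc_text <- expand_species_tree(config$species_tree, config)
  nuc_tree <- ape::read.tree(text = nuc_text)
  org_text <- if (!is.null(config$organelle_tree))
    expand_species_tree(config$organelle_tree, config) else nuc_text
  org_tree <- ape::read.tree(text = org_text)

  panel <- panel_from_config(config)
  seqs <- list(); deleted <- list(); refs <- list()
  for (i in seq_len(nrow(config$replicons))) {
    nm <- config$replicons$name[i]
    ref_int <- dna_to_int(reference[[nm]])
    tree <- if (config$replicons$is_organelle[i]) org_tree else nuc_tree
    m <- evolve_along_tree(tree, ref_int)
    m <- m[, panel$accession, drop = FALSE]
    seqs[[nm]] <- m
    refs[[nm]] <- ref_int
    d <- matrix(runif(length(m)) < config$deletion_rate, nrow = nrow(m),
                dimnames = dimnames(m))
    deleted[[nm]] <- d
  }
  structure(list(
    seqs = seqs, deleted = deleted, reference = refs, panel = panel,
    acc_tree_nuclear = nuc_text, acc_tree_organelle = org_text,
    species_tree = config$species_tree,
    organelle_tree = config$organelle_tree %||% config$species_tree,
    expected_diversity = expected_diversity(config),
    config = config
  ), class = "truth_set")
}

panel_from_config <- function(config) {
  sp <- names(config$accessions_per_species)
  acc <- unlist(lapply(sp, function(s)
    sprintf("%s_%d", s, seq_len(config$accessions_per_species[[s]]))))
  species <- rep(sp, config$accessions_per_species[sp])
  gl <- config$genome_labels
  species_panel(
    accession = acc, species = species,
    genome = if (is.null(gl)) NULL else gl,
    outgroup = if (is.null(config$outgroup_species)) NULL else
      acc[species == config$outgroup_species]
  )
}

# Expected within-species pairwise differences per site: accession pairs in
# the same sublineage are 2t apart, across sublineages 2t + 2b; the summary
# is the pair-weighted mean of the JC expected difference.
expected_diversity <- function(config) {
  vapply(names(config$accessions_per_species), function(sp) {
    n <- config$accessions_per_species[[sp]]
    if (n < 2) return(NA_real_)
    t <- config$within_species_diversity[sp]
    t <- if (is.na(t)) 0 else unname(t)
    sl <- config$sublineage_spec[[sp]]
    if (is.null(sl)) return(jc_p(2 * t))
    g <- table(rep_len(seq_len(sl[1]), n))
    within <- sum(g * (g - 1) / 2)
    total <- n * (n - 1) / 2
    (within * jc_p(2 * t) + (total - within) * jc_p(2 * t + 2 * sl[2])) / total
  }, numeric(1))
}

#' Access a true allele
#'
#' @param truth A `truth_set`.
#' @param replicon Replicon name.
#' @param pos 1-based position.
#' @param accession Accession id.
#' @return Single base character.
#' @export
true_allele <- function(truth, replicon, pos, accession) {
  BASES[truth$seqs[[replicon]][pos, accession]]
}

#' Emit pileup evidence for a simulated panel
#'
#' Per site x accession, depth is drawn from the configured distribution
#' (0 with probability `dropout_rate`; outgroup accessions additionally
#' lose sites with probability `1 - outgroup_alignable_fraction`).  Each
#' read reports the true allele with probability `1 - error_rate`, else a
#' uniformly chosen different base.  Reads over a deleted site are counted
#' as deletion observations.  Sites with zero depth are not emitted.
#'
#' @param truth A `truth_set` from [evolve_panel].
#' @param config The same `sim_config`.
#' @return Named list (one pileup `data.frame` per accession), sorted by
#'   replicon then position.
#' @export
emit_pileups <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  panel <- truth$panel
  out <- vector("list", nrow(panel))
  names(out) <- panel$accession
  for (a in panel$accession) {
    is_og <- panel$is_outgroup[panel$accession == a]
    per_rep <- lapply(seq_len(nrow(config$replicons)), function(i) {
      nm <- config$replicons$name[i]
      L <- config$replicons$length[i]
      depth <- if (config$depth_dispersion == 0) rpois(L, config$mean_depth)
               else rnbinom(L, mu = config$mean_depth,
                            size = 1 / config$depth_dispersion)
      depth[runif(L) < config$dropout_rate] <- 0L
      if (is_og && config$outgroup_alignable_fraction < 1)
        depth[runif(L) >= config$outgroup_alignable_fraction] <- 0L
      keep <- which(depth > 0)
      if (!length(keep)) return(NULL)
      n <- depth[keep]
      av <- truth$seqs[[nm]][keep, a]
      del <- truth$deleted[[nm]][keep, a]
      k <- length(keep)
      cnt <- matrix(0L, k, 4)
      live <- which(!del)
      if (length(live)) {
        e <- rbinom(length(live), n[live], config$error_rate)
        cnt[cbind(live, av[live])] <- n[live] - e
        tot <- sum(e)
        if (tot > 0) {
          rows <- rep(live, e)
          shift <- sample(3L, tot, replace = TRUE)
          eb <- ((av[rows] - 1L + shift) %% 4L) + 1L
          add <- tabulate((rows - 1L) * 4L + eb, nbins = k * 4L)
          cnt <- cnt + matrix(add, k, 4, byrow = TRUE)
        }
      }
      nDel <- integer(k)
      nDel[del] <- n[del]
      data.frame(replicon = nm, pos = keep,
                 ref = BASES[truth$reference[[nm]][keep]],
                 nA = cnt[, 1], nC = cnt[, 2], nG = cnt[, 3], nT = cnt[, 4],
                 nN = 0L, nDel = nDel, nIns = 0L, stringsAsFactors = FALSE)
    })
    per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
    out[[a]] <- if (length(per_rep)) do.call(rbind, per_rep)
                else data.frame(replicon = character(), pos = integer(),
                                ref = character(), nA = integer(), nC = integer(),
                                nG = integer(), nT = integer(), nN = integer(),
                                nDel = integer(), nIns = integer())
  }
  out
}

#' Run the full simulator
#'
#' Convenience wrapper: reference, truth, and pileups in one call.
#'
#' @param config A `sim_config`.
#' @return List with `reference`, `truth`, `pileups`, `panel`.
#' @export
simulate_panel <- function(config) {
  reference <- simulate_reference(config)
  truth <- evolve_panel(reference, config)
  pileups <- emit_pileups(truth, config)
  list(reference = reference, truth = truth, pileups = pileups,
       panel = truth$panel)
}

#' Write a simulated panel to a directory
#'
#' Emits `reference.fasta`, `manifest.tsv`, one
#' `pileups/<accession>.pileup.tsv` per accession, the true accession trees
#' as Newick, and `truth_snps.tsv` listing every site x accession allele
#' differing from the reference (for downstream checks).
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return The simulation list from [simulate_panel], invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  sim <- simulate_panel(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)
  write_fasta(sim$reference, file.path(dir, "reference.fasta"))
  write_manifest(sim$panel, file.path(dir, "manifest.tsv"))
  for (a in names(sim$pileups))
    write_pileup_summary(sim$pileups[[a]],
                         file.path(dir, "pileups", paste0(a, ".pileup.tsv")))
  writeLines(sim$truth$acc_tree_nuclear, file.path(dir, "true_tree_nuclear.nwk"))
  writeLines(sim$truth$acc_tree_organelle, file.path(dir, "true_tree_organelle.nwk"))
  tv <- lapply(names(sim$truth$seqs), function(nm) {
    m <- sim$truth$seqs[[nm]]
    refv <- sim$truth$reference[[nm]]
    diffs <- which(m != refv, arr.ind = TRUE)
    if (!nrow(diffs)) return(NULL)
    data.frame(replicon = nm, pos = diffs[, 1],
               accession = colnames(m)[diffs[, 2]],
               ref = BASES[refv[diffs[, 1]]],
               allele = BASES[m[diffs]], stringsAsFactors = FALSE)
  })
  tv <- do.call(rbind, tv[!vapply(tv, is.null, logical(1))])
  if (is.null(tv))
    tv <- data.frame(replicon = character(), pos = integer(),
                     accession = character(), ref = character(),
                     allele = character())
  data.table::fwrite(tv[order(tv$replicon, tv$pos, tv$accession), ],
                     file.path(dir, "truth_snps.tsv"), sep = "\t")
  invisible(sim)
}
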