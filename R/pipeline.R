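#' Configure an end-to-end pipeline run
#'
#' @param reference Path to the reference FASTA.
#' @param manifest Path to the panel manifest TSV.
#' @param pileup_dir Directory holding one `<accession>.pileup.tsv` per
#'   panel accession.
#' @param out_dir Output directory for all artifacts.
#' @param partitions Named character vector replicon -> `"nuclear"` or
#'   `"organelle"`; replicons absent from the map default to nuclear.
#' @param min_depth,min_alt_fraction Calling thresholds (defaults 10 and
#'   0.95, strict).
#' @param bootstrap Bootstrap replicates for tree support (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @param focal_pair Optional character vector of two species ids: the
#'   pair whose fixed SNPs feed CAPS design (defaults to the two
#'   non-outgroup species with the most fixed SNPs being skipped — when
#'   `NULL`, CAPS design runs on the first non-outgroup species pair with
#'   at least one fixed SNP).
#' @param enzymes Optional path to an enzyme TSV; default built-in table.
#' @param flank Flank for [diagnostic_sites] (default 20).
#' @param amplicon_size Amplicon window size for
#'   [select_amplicon_window] (default 500).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(reference, manifest, pileup_dir, out_dir,
                            partitions = character(),
                            min_depth = 10, min_alt_fraction = 0.95,
                            bootstrap = 1000, seed = 1,
                            focal_pair = NULL, enzymes = NULL,
                            flank = 20L, amplicon_size = 500L) {
  for (p in c(reference, manifest, pileup_dir))
    if (!file.exists(p)) stop("input does not exist: ", p)
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (min_alt_fraction <= 0 || min_alt_fraction > 1)
    stop("min_alt_fraction must be in (0, 1]")
  if (bootstrap < 1) stop("bootstrap must be >= 1")
  structure(list(reference = reference, manifest = manifest,
                 pileup_dir = pileup_dir, out_dir = out_dir,
                 partitions = partitions, min_depth = min_depth,
                 min_alt_fraction = min_alt_fraction, bootstrap = bootstrap,
                 seed = as.integer(seed), focal_pair = focal_pair,
                 enzymes = enzymes, flank = flank,
                 amplicon_size = amplicon_size),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Calling -> genotype matrices (nuclear and organelle partitions run the
#' identical code path) -> polymorphic / fixed / unique classification ->
#' diversity -> NJ trees with bootstrap and outgroup rooting -> congruence
#' report -> CAPS candidates.  Every artifact is written under
#' `config$out_dir`; a machine-readable `run_log.json` records thresholds,
#' seed and versions.  Outputs are byte-stable for identical inputs,
#' configuration and seed.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("calls", "matrix", "classify", "diversity", "trees", "caps"))
    dir.create(file.path(out, d), showWarnings = FALSE)

  reference <- stage("read_reference", read_fasta(config$reference))
  panel <- stage("read_manifest", read_manifest(config$manifest))
  part_of <- function(rep_) {
    p <- config$partitions[rep_]
    unname(ifelse(is.na(p), "nuclear", p))
  }

  results <- stage("calling", {
    res <- lapply(panel$accession, function(a) {
      f <- file.path(config$pileup_dir, paste0(a, ".pileup.tsv"))
      if (!file.exists(f)) stop("missing pileup file for accession ", a)
      call_accession(read_pileup_summary(f), a,
                     min_depth = config$min_depth,
                     min_alt_fraction = config$min_alt_fraction)
    })
    names(res) <- panel$accession
    res
  })
  stage("write_calls", for (a in panel$accession) {
    write_calls_vcf(results[[a]]$calls,
                    file.path(out, "calls", paste0(a, ".vcf")),
                    contigs = names(reference))
    data.table::fwrite(results[[a]]$status,
                       file.path(out, "calls", paste0(a, ".status.tsv")),
                       sep = "\t")
  })
  summaries <- do.call(rbind, lapply(results, `[[`, "summary"))
  data.table::fwrite(summaries, file.path(out, "calls", "summary.tsv"),
                     sep = "\t")

  reps <- names(reference)
  parts <- split(reps, part_of(reps))
  matrices <- stage("matrix", lapply(parts, function(rr)
    build_matrix(results, panel, partition = part_of(rr[1]), replicons = rr)))
  for (p in names(matrices)) {
    write_matrix_vcf(matrices[[p]], file.path(out, "matrix", paste0(p, ".vcf")))
    gm <- matrices[[p]]
    tsv <- cbind(gm$sites, as.data.frame(gm$alleles))
    data.table::fwrite(tsv, file.path(out, "matrix", paste0(p, ".tsv")),
                       sep = "\t")
  }

  nuc <- matrices[["nuclear"]]
  classify <- stage("classify", {
    sp <- unique(panel$species[!panel$is_outgroup])
    multi <- sp[vapply(sp, function(s)
      sum(panel$species == s & !panel$is_outgroup), integer(1)) >= 2]
    poly <- lapply(multi, function(s) polymorphic_sites(nuc, panel, s))
    names(poly) <- multi
    pairs <- utils::combn(sp, 2, simplify = FALSE)
    fixed <- lapply(pairs, function(pr) fixed_snps(nuc, panel, pr[1], pr[2]))
    names(fixed) <- vapply(pairs, paste, character(1), collapse = "__")
    uniq <- lapply(sp, function(s) unique_substitutions(nuc, panel, s))
    names(uniq) <- sp
    list(polymorphic = poly, fixed = fixed, unique = uniq)
  })
  stage("write_classify", {
    poly_tab <- data.frame(
      species = names(classify$polymorphic),
      n_polymorphic = vapply(classify$polymorphic, nrow, integer(1)))
    data.table::fwrite(poly_tab, file.path(out, "classify", "polymorphic_counts.tsv"),
                       sep = "\t")
    for (s in names(classify$polymorphic))
      write_bed(classify$polymorphic[[s]],
                file.path(out, "classify", paste0("polymorphic_", s, ".bed")))
    fixed_tab <- data.frame(
      pair = names(classify$fixed),
      n_fixed = vapply(classify$fixed, nrow, integer(1)))
    data.table::fwrite(fixed_tab, file.path(out, "classify", "fixed_counts.tsv"),
                       sep = "\t")
    for (pr in names(classify$fixed)) {
      ff <- classify$fixed[[pr]]
      data.table::fwrite(ff, file.path(out, "classify", paste0("fixed_", pr, ".tsv")),
                         sep = "\t")
      write_bed(ff, file.path(out, "classify", paste0("fixed_", pr, ".bed")))
    }
    uniq_tab <- data.frame(
      species = names(classify$unique),
      n_unique = vapply(classify$unique, nrow, integer(1)))
    data.table::fwrite(uniq_tab, file.path(out, "classify", "unique_counts.tsv"),
                       sep = "\t")
    data.table::fwrite(snp_density(nuc), file.path(out, "classify", "snp_density.tsv"),
                       sep = "\t")
  })

  nonempty <- Filter(function(m) nrow(m$sites) > 0, matrices)
  dists <- stage("diversity", lapply(nonempty, pairwise_differences))
  diversity <- stage("diversity", diversity_summary(dists[["nuclear"]], panel))
  stage("write_diversity", {
    for (p in names(dists))
      data.table::fwrite(
        cbind(accession = rownames(dists[[p]]), as.data.frame(dists[[p]])),
        file.path(out, "diversity", paste0("distances_", p, ".tsv")), sep = "\t")
    data.table::fwrite(diversity, file.path(out, "diversity", "within_species.tsv"),
                       sep = "\t")
    vals <- attr(diversity, "values")
    long <- do.call(rbind, lapply(names(vals), function(s)
      data.frame(species = s, pairwise_differences = vals[[s]])))
    data.table::fwrite(long, file.path(out, "diversity", "pairwise_values.tsv"),
                       sep = "\t")
  })

  trees <- stage("trees", lapply(names(nonempty), function(p) {
    tr <- bootstrap_support(nonempty[[p]], n_replicates = config$bootstrap,
                            seed = config$seed)
    if (any(panel$is_outgroup) &&
        all(panel$accession[panel$is_outgroup] %in% tr$tip.label))
      tr <- root_at_outgroup(tr, panel)
    tr
  }))
  names(trees) <- names(nonempty)
  for (p in names(trees))
    write_newick(trees[[p]], file.path(out, "trees", paste0(p, ".nwk")))

  congruence <- NULL
  if (all(c("nuclear", "organelle") %in% names(trees))) {
    congruence <- stage("compare",
                        compare_trees(trees$nuclear, trees$organelle, panel))
    stage("write_compare", {
      sink(file.path(out, "trees", "congruence.txt"))
      print(congruence)
      sink()
      jsonlite::write_json(list(
        rf = congruence$rf,
        species_level_rf = congruence$species_level$rf,
        only_nuclear = lapply(congruence$species_level$only_tree1, identity),
        only_organelle = lapply(congruence$species_level$only_tree2, identity),
        non_monophyletic = congruence$monophyly$species[
          !(congruence$monophyly$tree1 & congruence$monophyly$tree2)]),
        file.path(out, "trees", "congruence.json"), auto_unbox = TRUE)
    })
  }

  caps <- stage("caps", {
    enz <- if (is.null(config$enzymes)) default_enzymes()
           else read_enzymes(config$enzymes)
    pair_names <- names(classify$fixed)
    pick <- if (!is.null(config$focal_pair))
      paste(sort(config$focal_pair), collapse = "__") else NULL
    if (!is.null(pick) && !pick %in% pair_names)
      pick <- paste(rev(sort(config$focal_pair)), collapse = "__")
    if (is.null(pick)) {
      nn <- vapply(classify$fixed, nrow, integer(1))
      pick <- if (any(nn > 0)) pair_names[which(nn > 0)[1]] else NULL
    }
    empty_fixed <- data.frame(replicon = character(), pos = integer(),
                              ref = character(), species_a = character(),
                              species_b = character(), allele_a = character(),
                              allele_b = character())
    if (is.null(pick) || !pick %in% pair_names ||
        nrow(classify$fixed[[pick]]) == 0) {
      list(pair = NULL,
           candidates = diagnostic_sites(empty_fixed, reference, enz,
                                         flank = config$flank))
    } else {
      cand <- diagnostic_sites(classify$fixed[[pick]], reference, enz,
                               flank = config$flank)
      cand <- select_amplicon_window(cand, reference,
                                     target_size = config$amplicon_size)
      list(pair = pick, candidates = cand)
    }
  })
  stage("write_caps", {
    data.table::fwrite(caps$candidates, file.path(out, "caps", "candidates.tsv"),
                       sep = "\t")
    caps_to_gff3(caps$candidates, file.path(out, "caps", "candidates.gff3"))
  })

  stage("run_log", jsonlite::write_json(list(
    package = "snpanel",
    version = as.character(utils::packageVersion("snpanel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(min_depth = config$min_depth,
                      min_alt_fraction = config$min_alt_fraction,
                      strict_fraction = TRUE),
    bootstrap = config$bootstrap,
    partitions = as.list(stats::setNames(part_of(reps), reps)),
    accessions = panel$accession,
    caps_pair = caps$pair %||% NA),
    file.path(out, "run_log.json"), auto_unbox = TRUE, pretty = TRUE))

  invisible(list(panel = panel, results = results, matrices = matrices,
                 classify = classify, distances = dists,
                 diversity = diversity, trees = trees,
                 congruence = congruence, caps = caps))
}
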