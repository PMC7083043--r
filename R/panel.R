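#' Define a species panel
#'
#' Maps accessions to species, species to genome labels, and flags
#' outgroup accessions.  Outgroup accessions are used only for tree
#' rooting; they are excluded from fixed/unique SNP classification and
#' from diversity summaries.
#'
#' @param accession Character vector of unique accession ids (ordered).
#' @param species Character vector, same length: species id per accession.
#' @param genome Optional named character vector species -> genome label
#'   (e.g. C, M, N, D, U); defaults to the species id itself.
#' @param outgroup Optional character vector of outgroup accession ids or
#'   species ids.
#' @return A `species_panel` data frame with columns `accession`,
#'   `species`, `genome`, `is_outgroup`.
#' @export
species_panel <- function(accession, species, genome = NULL, outgroup = NULL) {
  stopifnot(length(accession) == length(species))
  if (anyDuplicated(accession)) stop("accession ids must be unique")
  if (is.null(genome)) genome <- stats::setNames(unique(species), unique(species))
  gl <- unname(genome[species])
  gl[is.na(gl)] <- species[is.na(gl)]
  is_og <- accession %in% outgroup | species %in% outgroup
  out <- data.frame(accession = accession, species = species, genome = gl,
                    is_outgroup = is_og, stringsAsFactors = FALSE)
  og_sp <- unique(out$species[out$is_outgroup])
  if (any(!out$is_outgroup & out$species %in% og_sp))
    stop("outgroup species also contains ingroup accessions")
  class(out) <- c("species_panel", "data.frame")
  out
}

panel_accessions <- function(panel, species = NULL, include_outgroup = TRUE) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(species)) keep <- keep & panel$species %in% species
  if (!include_outgroup) keep <- keep & !panel$is_outgroup
  panel$accession[keep]
}

new_genotype_matrix <- function(sites, alleles, partition) {
  stopifnot(nrow(sites) == nrow(alleles))
  structure(list(sites = sites, alleles = alleles, partition = partition),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", ncol(x$alleles),
      "accessions (", x$partition, "partition )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$alleles)

#' Build the non-redundant cross-accession SNP genotype matrix
#'
#' Candidate sites are the union of SNP positions called in any accession.
#' A site is retained iff every accession of the panel has unambiguous,
#' sufficiently covered evidence there: status `REF_CONFIRMED` or
#' `ALT_CALLED` with a base allele.  Sites where any accession carries an
#' indel event are excluded.  The resulting matrix has no missing cells:
#' each cell is the called alternate base or the reference base.  Sites
#' where every accession shares the same non-reference allele (divergence
#' of the reference alone) are retained but are inert for within-panel
#' classification.
#'
#' @param results Named list (one entry per panel accession) of
#'   [call_accession]/[call_variants] results, each with `calls` and
#'   `status`.
#' @param panel A [species_panel].
#' @param partition Label stored on the matrix, `"nuclear"` or
#'   `"organelle"`.
#' @param replicons Optional character vector restricting the matrix to a
#'   subset of replicons (used to split partitions).
#' @return A `genotype_matrix`.
#' @export
build_matrix <- function(results, panel, partition = "nuclear",
                         replicons = NULL) {
  missing_acc <- setdiff(panel$accession, names(results))
  if (length(missing_acc))
    stop("no call/status tables for accession(s): ",
         paste(missing_acc, collapse = ", "))
  accs <- panel$accession
  empty <- function() new_genotype_matrix(
    sites = data.frame(replicon = character(), pos = integer(),
                       ref = character(), stringsAsFactors = FALSE),
    alleles = matrix(character(), 0, length(accs), dimnames = list(NULL, accs)),
    partition = partition)

  calls <- data.table::rbindlist(lapply(accs, function(a) {
    cc <- results[[a]]$calls
    cc <- cc[cc$variant_class == "SNP", c("replicon", "pos", "ref")]
    if (!is.null(replicons)) cc <- cc[cc$replicon %in% replicons, , drop = FALSE]
    cc
  }))
  if (nrow(calls) == 0) return(empty())
  cand <- unique(calls)
  data.table::setkeyv(cand, c("replicon", "pos"))
  if (anyDuplicated(cand[, c("replicon", "pos")]))
    stop("inconsistent reference bases across accessions at a candidate site")

  status <- data.table::rbindlist(lapply(accs, function(a) {
    st <- results[[a]]$status
    st <- st[, c("replicon", "pos", "status", "allele")]
    st$accession <- a
    if (!is.null(replicons)) st <- st[st$replicon %in% replicons, , drop = FALSE]
    st
  }))
  data.table::setkeyv(status, c("replicon", "pos"))
  st_cand <- status[cand, on = c("replicon", "pos"), nomatch = NULL]

  usable <- st_cand$status == "REF_CONFIRMED" |
    (st_cand$status == "ALT_CALLED" & st_cand$allele %in% BASES)
  indel_here <- st_cand$status == "ALT_CALLED" & !st_cand$allele %in% BASES
  key <- paste(st_cand$replicon, st_cand$pos)
  n_usable <- tapply(usable, key, sum)
  any_indel <- tapply(indel_here, key, any)
  cand_key <- paste(cand$replicon, cand$pos)
  keep <- cand_key %in% names(n_usable)[n_usable == length(accs)] &
    !(cand_key %in% names(any_indel)[any_indel])
  cand <- cand[keep, ]
  if (nrow(cand) == 0) return(empty())

  st_keep <- st_cand[paste(st_cand$replicon, st_cand$pos) %in%
                       paste(cand$replicon, cand$pos), ]
  cell <- ifelse(st_keep$status == "ALT_CALLED", st_keep$allele, NA)
  # wide: rows = sites in cand order, cols = accessions in panel order
  skey <- paste(st_keep$replicon, st_keep$pos)
  row_i <- match(skey, paste(cand$replicon, cand$pos))
  col_i <- match(st_keep$accession, accs)
  A <- matrix(NA_character_, nrow(cand), length(accs),
              dimnames = list(NULL, accs))
  A[cbind(row_i, col_i)] <- cell
  ref_rep <- matrix(rep(cand$ref, length(accs)), ncol = length(accs))
  A[is.na(A)] <- ref_rep[is.na(A)]

  ord <- order(match(cand$replicon, unique(cand$replicon)), cand$pos)
  sites <- as.data.frame(cand)[ord, ]
  rownames(sites) <- NULL
  new_genotype_matrix(sites = sites, alleles = A[ord, , drop = FALSE],
                      partition = partition)
}

species_alleles <- function(gm, panel, species) {
  accs <- panel_accessions(panel, species)
  if (!length(accs)) stop("species not in panel: ", species)
  gm$alleles[, accs, drop = FALSE]
}

count_unique_alleles <- function(A) {
  # rowwise number of distinct bases across a character matrix
  n <- nrow(A)
  if (n == 0) return(integer(0))
  if (ncol(A) <= 1) return(rep(1L, n))
  present <- matrix(vapply(BASES, function(b) rowSums(A == b) > 0, logical(n)),
                    nrow = n)
  as.integer(rowSums(present))
}

#' Sites polymorphic within a species
#'
#' @param gm A [genotype_matrix].
#' @param panel A [species_panel].
#' @param species Species id (needs at least two accessions; otherwise an
#'   empty result with a warning).
#' @return The subset of `gm$sites` (with a `row` index column) at which
#'   at least two distinct alleles occur among that species' accessions.
#' @export
polymorphic_sites <- function(gm, panel, species) {
  A <- species_alleles(gm, panel, species)
  if (ncol(A) < 2) {
    warning("species ", species,
            " has a single accession; polymorphic set is defined empty")
    return(cbind(gm$sites[0, ], row = integer()))
  }
  poly <- count_unique_alleles(A) >= 2
  out <- cbind(gm$sites[poly, , drop = FALSE], row = which(poly))
  rownames(out) <- NULL
  out
}

#' Fixed SNPs between two species
#'
#' A fixed SNP site is monomorphic within each species while the two
#' species carry different alleles; these sites diagnose the two genomes.
#'
#' @param gm A [genotype_matrix].
#' @param panel A [species_panel].
#' @param species_a,species_b The (unordered) species pair.
#' @return Data frame of records: site columns plus `species_a`,
#'   `species_b`, `allele_a`, `allele_b`, and the matrix `row` index.
#' @export
fixed_snps <- function(gm, panel, species_a, species_b) {
  if (identical(species_a, species_b))
    stop("fixed_snps needs two distinct species")
  A <- species_alleles(gm, panel, species_a)
  B <- species_alleles(gm, panel, species_b)
  monoA <- count_unique_alleles(A) == 1
  monoB <- count_unique_alleles(B) == 1
  aA <- A[, 1]
  aB <- B[, 1]
  hit <- monoA & monoB & (aA != aB)
  out <- cbind(gm$sites[hit, , drop = FALSE],
               data.frame(species_a = rep(species_a, sum(hit)),
                          species_b = rep(species_b, sum(hit)),
                          allele_a = aA[hit], allele_b = aB[hit],
                          row = which(hit), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("fixed_snps", "data.frame")
  out
}

#' Unique nucleotide substitutions of a species or species group
#'
#' Sites where the group is monomorphic for an allele that no other
#' (non-outgroup) panel species carries.  Outgroup accessions are excluded
#' from both sides of the comparison.
#'
#' @param gm A [genotype_matrix].
#' @param panel A [species_panel].
#' @param group Character vector of species ids forming the target group.
#' @return Data frame: site columns plus `group`, `diagnostic_allele`,
#'   `row`.
#' @export
unique_substitutions <- function(gm, panel, group) {
  comparison <- setdiff(unique(panel$species[!panel$is_outgroup]), group)
  if (!length(comparison))
    stop("group covers the whole (non-outgroup) panel; nothing to compare")
  G <- species_alleles(gm, panel, group)
  O <- gm$alleles[, panel_accessions(panel, comparison, include_outgroup = FALSE),
                  drop = FALSE]
  mono <- count_unique_alleles(G) == 1
  g <- G[, 1]
  absent <- rowSums(O == g) == 0
  hit <- mono & absent
  out <- cbind(gm$sites[hit, , drop = FALSE],
               data.frame(group = rep(paste(group, collapse = "+"), sum(hit)),
                          diagnostic_allele = g[hit], row = which(hit),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Per-replicon SNP density table
#'
#' Counts of matrix sites per replicon window, a plotting-ready substitute
#' for circular genome plots.
#'
#' @param gm A [genotype_matrix].
#' @param window Window width in bp.
#' @return Data frame: replicon, window start (1-based), end, n_sites.
#' @export
snp_density <- function(gm, window = 1000L) {
  if (nrow(gm$sites) == 0)
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), n_sites = integer()))
  out <- lapply(split(gm$sites$pos, gm$sites$replicon), function(p) {
    w <- (p - 1L) %/% window
    tab <- table(w)
    data.frame(start = as.integer(names(tab)) * window + 1L,
               end = (as.integer(names(tab)) + 1L) * window,
               n_sites = as.integer(tab))
  })
  res <- do.call(rbind, Map(cbind, replicon = names(out), out))
  rownames(res) <- NULL
  res
}
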