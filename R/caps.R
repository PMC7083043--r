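IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
              "H", "V", "N")

#' Built-in restriction enzyme table
#'
#' Twelve common 4-6 bp cutters shipped as a plain TSV
#' (`name`, `site` in IUPAC code, `cut_offset` = bases cut after on the
#' top strand); two carry degenerate recognition sequences (HinfI GANTC,
#' DdeI CTNAG) to exercise IUPAC-aware matching.
#'
#' @return An `enzyme_table` data frame.
#' @export
default_enzymes <- function() {
  read_enzymes(system.file("extdata", "enzymes.tsv", package = "snpanel"))
}

#' Read an enzyme table from TSV
#'
#' @param path TSV with columns `name`, `site`, `cut_offset`.
#' @return An `enzyme_table` data frame.
#' @export
read_enzymes <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site", "cut_offset") %in% names(e)))
  for (i in seq_len(nrow(e))) {
    ch <- strsplit(e$site[i], "")[[1]]
    if (length(ch) < 4) stop("enzyme ", e$name[i], ": recognition sequence < 4 bp")
    if (!all(ch %in% IUPAC_OK))
      stop("enzyme ", e$name[i], ": invalid IUPAC letters in site")
    if (e$cut_offset[i] < 0 || e$cut_offset[i] > nchar(e$site[i]))
      stop("enzyme ", e$name[i], ": cut offset outside recognition site")
  }
  class(e) <- c("enzyme_table", "data.frame")
  e
}

# All recognition matches of an enzyme in an unambiguous sequence, both
# strands.  Returns a data.frame of match starts (plus-strand coordinates)
# with the cut coordinate (number of bases left of the cut).
enzyme_matches <- function(seq, enzyme_site, cut_offset) {
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(enzyme_site)
  len <- nchar(enzyme_site)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
  rc <- Biostrings::reverseComplement(pat)
  if (as.character(rc) == as.character(pat)) {
    rev <- integer(0)                       # palindrome: same matches
  } else {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, subj, fixed = FALSE))
  }
  data.frame(
    start = c(fwd, rev),
    end = c(fwd, rev) + len - 1L,
    cut = c(fwd - 1L + cut_offset, rev - 1L + (len - cut_offset)))
}

#' In-silico restriction digest
#'
#' Cuts at every recognition match on either strand (overlapping matches
#' handled left to right) and returns fragment lengths, which always sum
#' to the input length.
#'
#' @param sequence Character DNA string over unambiguous A/C/G/T.
#' @param enzyme One row of an `enzyme_table` (or a list with `site` and
#'   `cut_offset`).
#' @return Integer vector of fragment lengths.
#' @export
in_silico_digest <- function(sequence, enzyme) {
  if (grepl("[^ACGT]", sequence))
    stop("in_silico_digest requires an unambiguous ACGT sequence")
  L <- nchar(sequence)
  m <- enzyme_matches(sequence, enzyme$site, enzyme$cut_offset)
  cuts <- sort(unique(m$cut))
  cuts <- cuts[cuts >= 1 & cuts <= L - 1]
  as.integer(diff(c(0L, cuts, L)))
}

with_allele <- function(seq, offset, allele) {
  substr(seq, offset, offset) <- allele
  seq
}

# recognition matches that overlap a given 1-based offset
overlapping_matches <- function(seq, site, cut_offset, offset) {
  m <- enzyme_matches(seq, site, cut_offset)
  m[m$start <= offset & m$end >= offset, , drop = FALSE]
}

#' Find CAPS diagnostic enzymes for fixed SNPs
#'
#' For each fixed SNP and enzyme, both allele-substituted local sequences
#' (SNP plus `flank` bases each side) are scanned for recognition matches
#' overlapping the SNP position, IUPAC-aware and on both strands.  A
#' candidate is reported iff exactly one allele carries such a match: the
#' SNP then creates/destroys the site and digestion is allele-specific.
#'
#' @param fixed A [fixed_snps] data frame (or any data frame with columns
#'   replicon, pos, species_a, species_b, allele_a, allele_b).
#' @param reference Reference sequences ([Biostrings::DNAStringSet] or
#'   named character vector).
#' @param enzymes An `enzyme_table`; defaults to [default_enzymes()].
#' @param flank Bases of context on each side of the SNP (must be at least
#'   the longest recognition length); windows are trimmed with a warning
#'   at replicon edges.
#' @return A `caps_candidates` data frame: the fixed-SNP columns plus
#'   `enzyme`, `site`, `cut_offset`, `cut_in_species`.
#' @export
diagnostic_sites <- function(fixed, reference, enzymes = default_enzymes(),
                             flank = 20L) {
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  if (flank < max(nchar(enzymes$site)))
    stop("flank must be >= the longest recognition length")
  rows <- list()
  for (i in seq_len(nrow(fixed))) {
    rep_ <- fixed$replicon[i]; pos <- fixed$pos[i]
    L <- Biostrings::width(reference[rep_])
    lo <- max(1L, pos - flank); hi <- min(L, pos + flank)
    if (lo > pos - flank || hi < pos + flank)
      warning("SNP at ", rep_, ":", pos,
              " is near a replicon edge; window reduced")
    ctx <- as.character(Biostrings::subseq(reference[[rep_]], lo, hi))
    off <- pos - lo + 1L
    seq_a <- with_allele(ctx, off, fixed$allele_a[i])
    seq_b <- with_allele(ctx, off, fixed$allele_b[i])
    for (j in seq_len(nrow(enzymes))) {
      in_a <- nrow(overlapping_matches(seq_a, enzymes$site[j],
                                       enzymes$cut_offset[j], off)) > 0
      in_b <- nrow(overlapping_matches(seq_b, enzymes$site[j],
                                       enzymes$cut_offset[j], off)) > 0
      if (xor(in_a, in_b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = rep_, pos = pos, ref = fixed$ref[i],
          species_a = fixed$species_a[i], species_b = fixed$species_b[i],
          allele_a = fixed$allele_a[i], allele_b = fixed$allele_b[i],
          enzyme = enzymes$name[j], site = enzymes$site[j],
          cut_offset = enzymes$cut_offset[j],
          cut_in_species = if (in_a) fixed$species_a[i] else fixed$species_b[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon = character(), pos = integer(), ref = character(),
               species_a = character(), species_b = character(),
               allele_a = character(), allele_b = character(),
               enzyme = character(), site = character(),
               cut_offset = integer(), cut_in_species = character())
  class(out) <- c("caps_candidates", "data.frame")
  out
}

#' Select amplicon windows and predict digestion patterns
#'
#' Builds a symmetric window of `target_size` bases around each candidate
#' SNP (trimmed at replicon edges), digests both allele-substituted
#' amplicons, and keeps only candidates whose two digestion patterns
#' differ.  Windows smaller than twice the recognition length are
#' rejected.
#'
#' @param candidates A `caps_candidates` data frame from
#'   [diagnostic_sites].
#' @param reference Reference sequences.
#' @param target_size Amplicon size in bp (default 500).
#' @return The candidates with columns `amp_start`, `amp_end`,
#'   `fragments_a`, `fragments_b` (comma-joined lengths) added; rows whose
#'   allele digests are identical are dropped.
#' @export
select_amplicon_window <- function(candidates, reference, target_size = 500L) {
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  keep <- logical(nrow(candidates))
  amp_start <- amp_end <- integer(nrow(candidates))
  fa <- fb <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    rep_ <- candidates$replicon[i]; pos <- candidates$pos[i]
    L <- Biostrings::width(reference[rep_])
    start <- max(1L, pos - (target_size - 1L) %/% 2L)
    end <- min(L, start + target_size - 1L)
    if (end - start + 1L < 2L * nchar(candidates$site[i])) next
    ctx <- as.character(Biostrings::subseq(reference[[rep_]], start, end))
    off <- pos - start + 1L
    enz <- list(site = candidates$site[i], cut_offset = candidates$cut_offset[i])
    dig_a <- in_silico_digest(with_allele(ctx, off, candidates$allele_a[i]), enz)
    dig_b <- in_silico_digest(with_allele(ctx, off, candidates$allele_b[i]), enz)
    if (identical(sort(dig_a), sort(dig_b))) next
    keep[i] <- TRUE
    amp_start[i] <- start; amp_end[i] <- end
    fa[i] <- paste(dig_a, collapse = ",")
    fb[i] <- paste(dig_b, collapse = ",")
  }
  out <- candidates[keep, , drop = FALSE]
  out$amp_start <- amp_start[keep]
  out$amp_end <- amp_end[keep]
  out$fragments_a <- fa[keep]
  out$fragments_b <- fb[keep]
  rownames(out) <- NULL
  out
}
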