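#' Read reference sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by replicon.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Write reference sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet], or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a panel manifest
#'
#' The manifest is a tab-separated file with columns `accession_id`,
#' `species_id`, `genome_label`, `is_outgroup` (0/1 or TRUE/FALSE).
#'
#' @param path Path to the manifest TSV.
#' @return A [species_panel] object.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession_id", "species_id", "genome_label", "is_outgroup")
  if (!all(need %in% names(m)))
    stop("manifest ", path, " must have columns: ", paste(need, collapse = ", "))
  species_panel(
    accession = m$accession_id, species = m$species_id,
    genome = stats::setNames(m$genome_label, m$species_id)[!duplicated(m$species_id)],
    outgroup = m$accession_id[as.logical(m$is_outgroup)]
  )
}

#' Write a panel manifest
#'
#' @param panel A [species_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(panel, path) {
  out <- data.frame(
    accession_id = panel$accession,
    species_id = panel$species,
    genome_label = panel$genome,
    is_outgroup = as.integer(panel$is_outgroup)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PILEUP_COLS <- c("replicon", "pos", "ref", "nA", "nC", "nG", "nT", "nN",
                 "nDel", "nIns")

#' Read a pileup-summary table
#'
#' Tab-separated per-accession pileup evidence with columns
#' `replicon, pos, ref, nA, nC, nG, nT, nN, nDel, nIns`: base counts (and
#' deletion / insertion read observations) at 1-based reference positions.
#' Malformed records raise an error naming the offending line.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of pileup sites.
#' @export
read_pileup_summary <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  p <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!identical(names(p), PILEUP_COLS))
    stop("pileup file ", path, ": expected columns ",
         paste(PILEUP_COLS, collapse = ","))
  validate_pileup(p, file = path)
  p
}

# Shared pileup validation; `file` only labels error messages.  Line numbers
# reported are 1-based data lines (header = line 1).
validate_pileup <- function(p, file = "<pileup>") {
  cnt <- as.matrix(p[, c("nA", "nC", "nG", "nT", "nN", "nDel", "nIns")])
  bad <- which(rowSums(cnt < 0 | !is.finite(cnt)) > 0)
  if (length(bad))
    stop("pileup ", file, ", line ", bad[1] + 1L, ": negative or non-finite count")
  bad <- which(!p$ref %in% BASES)
  if (length(bad))
    stop("pileup ", file, ", line ", bad[1] + 1L, ": ref base not in ACGT")
  bad <- which(p$pos < 1)
  if (length(bad))
    stop("pileup ", file, ", line ", bad[1] + 1L, ": position < 1")
  invisible(p)
}

#' Write a pileup-summary table
#'
#' @param pileup A pileup `data.frame` (see [read_pileup_summary]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_summary <- function(pileup, path) {
  stopifnot(identical(names(pileup), PILEUP_COLS))
  data.table::fwrite(pileup, path, sep = "\t")
  invisible(path)
}

#' Convert samtools-style text pileup to a pileup summary
#'
#' Parses the classic 6-column `samtools mpileup` text format (chrom, pos,
#' ref, depth, read bases, base qualities) into the per-base count table the
#' caller consumes.  Handles `.`/`,` (reference match on either strand),
#' `ACGTNacgtn`, `*` (deletion placeholder, counted as a deletion
#' observation), `+<n><seq>`/`-<n><seq>` indel annotations (counted as
#' insertion / deletion observations on the carrying read), and the `^X` /
#' `$` read start/end marks.
#'
#' @param path Path to an mpileup text file.
#' @return A pileup `data.frame` with the standard columns.
#' @export
pileup_from_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- matrix(0L, nrow = length(lines), ncol = 7,
                dimnames = list(NULL, c("nA", "nC", "nG", "nT", "nN", "nDel", "nIns")))
  rep_ <- character(length(lines)); pos <- integer(length(lines))
  ref <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      stop("mpileup ", path, ", line ", i, ": fewer than 5 fields")
    rep_[i] <- f[1]; pos[i] <- as.integer(f[2]); ref[i] <- toupper(f[3])
    b <- strsplit(f[5], "")[[1]]
    j <- 1L
    while (j <= length(b)) {
      ch <- b[j]
      if (ch == "^") { j <- j + 2L; next }          # start mark + mapping qual
      if (ch == "$") { j <- j + 1L; next }
      if (ch %in% c("+", "-")) {                     # indel annotation
        k <- j + 1L
        while (k <= length(b) && grepl("[0-9]", b[k])) k <- k + 1L
        n <- as.integer(paste(b[(j + 1L):(k - 1L)], collapse = ""))
        col <- if (ch == "+") "nIns" else "nDel"
        out[i, col] <- out[i, col] + 1L
        j <- k + n
        next
      }
      base <- switch(toupper(ch),
                     "." = ref[i], "," = ref[i],
                     "A" = "A", "C" = "C", "G" = "G", "T" = "T", "N" = "N",
                     "*" = "*", NA_character_)
      if (!is.na(base)) {
        if (base == "*") out[i, "nDel"] <- out[i, "nDel"] + 1L
        else if (base == "N") out[i, "nN"] <- out[i, "nN"] + 1L
        else out[i, paste0("n", base)] <- out[i, paste0("n", base)] + 1L
      }
      j <- j + 1L
    }
  }
  p <- data.frame(replicon = rep_, pos = pos, ref = ref, out,
                  stringsAsFactors = FALSE)
  validate_pileup(p, file = path)
  p
}

#' Convert 1-based sites to BED intervals
#'
#' All internal and VCF coordinates are 1-based inclusive; BED output is
#' 0-based half-open.  A single site at 1-based position `p` becomes the
#' interval `[p - 1, p)`.  This is the only place the conversion happens.
#'
#' @param sites Data frame with columns `replicon` and `pos` (1-based).
#' @return Data frame with `chrom`, `start` (0-based), `end`.
#' @export
site_to_bed <- function(sites) {
  data.frame(chrom = sites$replicon, start = sites$pos - 1L, end = sites$pos,
             stringsAsFactors = FALSE)
}

#' Write sites as a BED file
#'
#' @param sites Data frame with `replicon` and 1-based `pos` columns.
#' @param path Output path.
#' @param name Optional per-site name column (character vector).
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path, name = NULL) {
  bed <- site_to_bed(sites)
  if (!is.null(name)) bed$name <- name
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree] and [ape::write.tree]; bootstrap
#' supports ride in internal-node labels, the usual Newick convention.
#'
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo]; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

vcf_header <- function(contigs, samples = NULL, extra = character()) {
  h <- c("##fileformat=VCFv4.2",
         paste0("##source=snpanel-", as.character(utils::packageVersion("snpanel"))),
         extra,
         paste0("##contig=<ID=", contigs, ">"))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  c(h, paste(cols, collapse = "\t"))
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' Haploid GT fields (the panel species are selfing; calls are homozygous by
#' construction), one sample column per accession.  ALT lists every
#' non-reference allele observed at the site.  No date line is written, so
#' identical matrices serialize byte-identically.
#'
#' @param gm A [genotype_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  A <- gm$alleles
  n <- nrow(A)
  lines <- vcf_header(unique(gm$sites$replicon), colnames(A),
                      extra = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
                                paste0("##snpanel_partition=", gm$partition)))
  if (n > 0) {
    body <- vapply(seq_len(n), function(i) {
      ref <- gm$sites$ref[i]
      alts <- sort(setdiff(unique(A[i, ]), ref))
      gt <- match(A[i, ], c(ref, alts)) - 1L
      paste(c(gm$sites$replicon[i], gm$sites$pos[i], ".", ref,
              if (length(alts)) paste(alts, collapse = ",") else ".",
              ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype matrix from a multi-sample VCF written by the package
#'
#' @param path Path to a VCF produced by [write_matrix_vcf].
#' @return A [genotype_matrix].
#' @export
read_matrix_vcf <- function(path) {
  lines <- readLines(path)
  part <- sub("^##snpanel_partition=", "", grep("^##snpanel_partition=", lines, value = TRUE))
  if (!length(part)) part <- "nuclear"
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("VCF ", path, ": missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(new_genotype_matrix(
      sites = data.frame(replicon = character(), pos = integer(), ref = character()),
      alleles = matrix(character(), 0, length(samples), dimnames = list(NULL, samples)),
      partition = part))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  sites <- data.frame(replicon = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
                      stringsAsFactors = FALSE)
  alleles <- t(vapply(seq_len(nrow(f)), function(i) {
    alt <- if (f[i, 5] == ".") character() else strsplit(f[i, 5], ",", fixed = TRUE)[[1]]
    lev <- c(f[i, 4], alt)
    lev[as.integer(f[i, -(1:9)]) + 1L]
  }, character(length(samples))))
  if (length(samples) == 1) alleles <- matrix(alleles, ncol = 1)
  colnames(alleles) <- samples
  new_genotype_matrix(sites = sites, alleles = alleles, partition = part)
}

#' Write per-accession variant calls as VCF
#'
#' SNPs carry their called base as ALT; indel events are written as the
#' symbolic alleles `<DEL>` / `<INS>`.  INFO holds total depth (`DP`) and
#' the alternate-allele fraction (`AF`).
#'
#' @param calls A calls `data.frame` from [call_variants].
#' @param path Output path.
#' @param contigs Replicon names for `##contig` header lines; defaults to
#'   those present in `calls`.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, contigs = NULL) {
  if (is.null(contigs)) contigs <- unique(calls$replicon)
  lines <- vcf_header(contigs,
                      extra = c('##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
                                '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
                                '##ALT=<ID=DEL,Description="Deletion event">',
                                '##ALT=<ID=INS,Description="Insertion event">'))
  if (nrow(calls)) {
    alt <- ifelse(calls$alt %in% BASES, calls$alt, paste0("<", calls$alt, ">"))
    body <- paste(calls$replicon, calls$pos, ".", calls$ref, alt, ".", "PASS",
                  sprintf("DP=%d;AF=%.4f", calls$depth, calls$alt_fraction),
                  sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write CAPS candidates as GFF3 features
#'
#' One `restriction_diagnostic_site` feature per candidate, spanning the
#' amplicon window when present, otherwise the SNP position.
#'
#' @param candidates A `caps_candidates` data frame from [diagnostic_sites]
#'   or [select_amplicon_window].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
caps_to_gff3 <- function(candidates, path) {
  lines <- "##gff-version 3"
  if (nrow(candidates)) {
    start <- if ("amp_start" %in% names(candidates)) candidates$amp_start else candidates$pos
    end <- if ("amp_end" %in% names(candidates)) candidates$amp_end else candidates$pos
    attr_ <- sprintf(
      "ID=caps%05d;enzyme=%s;snp_pos=%d;cut_in=%s;allele_%s=%s;allele_%s=%s",
      seq_len(nrow(candidates)), candidates$enzyme, candidates$pos,
      candidates$cut_in_species,
      candidates$species_a, candidates$allele_a,
      candidates$species_b, candidates$allele_b)
    lines <- c(lines, paste(candidates$replicon, "snpanel",
                            "restriction_diagnostic_site", start, end, ".", ".",
                            ".", attr_, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
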