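#' Call homozygous variants from pileup evidence
#'
#' A site yields a SNP call iff its total depth is at least `min_depth`
#' (default 10) and a single non-reference base accounts for strictly more
#' than `min_alt_fraction` (default 0.95) of that depth.  The depth
#' denominator is `nA + nC + nG + nT + nN + nDel`: N calls and
#' deletion-spanning reads dilute the supporting fraction (insertion
#' observations annotate reads that still report a base, so `nIns` is not
#' added).  Deletion (insertion) events are called by the same rule applied
#' to `nDel` (`nIns`).  The strict fraction guarantees the homozygosity
#' contract: no call is emitted where a second allele holds 5% or more of
#' the reads, so heterozygous-looking evidence (e.g. RNA-editing-like mixed
#' sites) is classified `AMBIGUOUS` and never enters downstream matrices.
#'
#' @param pileup Pileup `data.frame` (see [read_pileup_summary]).
#' @param min_depth Minimum total depth (inclusive), default 10.
#' @param min_alt_fraction Fraction the winning allele must strictly
#'   exceed, default 0.95.
#' @return List with `calls` (replicon, pos, ref, alt, depth, alt_fraction,
#'   variant_class) and `status` (replicon, pos, ref, status, allele): one
#'   status per site, one of `REF_CONFIRMED`, `ALT_CALLED`, `AMBIGUOUS`,
#'   `LOW_DEPTH`; `allele` carries the called base (or `DEL`/`INS`) for
#'   `ALT_CALLED` rows.
#' @export
call_variants <- function(pileup, min_depth = 10, min_alt_fraction = 0.95) {
  validate_pileup(pileup)
  n <- nrow(pileup)
  if (n == 0) {
    return(list(
      calls = data.frame(replicon = character(), pos = integer(),
                         ref = character(), alt = character(),
                         depth = integer(), alt_fraction = numeric(),
                         variant_class = character()),
      status = data.frame(replicon = character(), pos = integer(),
                          ref = character(), status = character(),
                          allele = character())))
  }
  cnt <- cbind(pileup$nA, pileup$nC, pileup$nG, pileup$nT)
  depth <- rowSums(cnt) + pileup$nN + pileup$nDel
  ref_i <- match(pileup$ref, BASES)
  idx <- cbind(seq_len(n), ref_i)
  ref_cnt <- cnt[idx]
  alt_cnt <- cnt
  alt_cnt[idx] <- -1L
  max_alt <- pmax(alt_cnt[, 1], alt_cnt[, 2], alt_cnt[, 3], alt_cnt[, 4])
  alt_base <- BASES[max.col(alt_cnt, ties.method = "first")]
  thr <- min_alt_fraction * depth
  ok <- depth >= min_depth
  snp <- ok & (max_alt > thr)
  del <- ok & (pileup$nDel > thr)
  ins <- ok & (pileup$nIns > thr)
  refc <- ok & (ref_cnt > thr)

  status <- rep("AMBIGUOUS", n)
  status[!ok] <- "LOW_DEPTH"
  status[refc] <- "REF_CONFIRMED"
  status[snp | del | ins] <- "ALT_CALLED"
  allele <- rep(NA_character_, n)
  allele[ins] <- "INS"
  allele[del] <- "DEL"
  allele[snp] <- alt_base[snp]

  is_call <- snp | del | ins
  alt <- allele[is_call]
  frac <- numeric(sum(is_call))
  d <- depth[is_call]
  frac[alt == "DEL"] <- pileup$nDel[is_call][alt == "DEL"] / d[alt == "DEL"]
  frac[alt == "INS"] <- pileup$nIns[is_call][alt == "INS"] / d[alt == "INS"]
  snp_rows <- alt %in% BASES
  frac[snp_rows] <- max_alt[is_call][snp_rows] / d[snp_rows]
  calls <- data.frame(
    replicon = pileup$replicon[is_call], pos = pileup$pos[is_call],
    ref = pileup$ref[is_call], alt = alt, depth = as.integer(d),
    alt_fraction = frac,
    variant_class = ifelse(snp_rows, "SNP", "indel"),
    stringsAsFactors = FALSE)
  status_df <- data.frame(
    replicon = pileup$replicon, pos = pileup$pos, ref = pileup$ref,
    status = status, allele = allele, stringsAsFactors = FALSE)
  list(calls = calls, status = status_df)
}

#' Call a single pileup site
#'
#' Scalar convenience wrapper over [call_variants].
#'
#' @param site One-row pileup `data.frame` (or a list coercible to one).
#' @inheritParams call_variants
#' @return A one-row calls `data.frame`, or `NULL` when no variant passes
#'   the thresholds.
#' @export
call_site <- function(site, min_depth = 10, min_alt_fraction = 0.95) {
  site <- as.data.frame(site)
  stopifnot(nrow(site) == 1)
  res <- call_variants(site, min_depth, min_alt_fraction)
  if (nrow(res$calls) == 0) NULL else res$calls
}

#' Classify a single pileup site
#'
#' @inheritParams call_site
#' @return One of `"REF_CONFIRMED"`, `"ALT_CALLED"`, `"AMBIGUOUS"`,
#'   `"LOW_DEPTH"`, with the called allele as attribute `"allele"` for
#'   `ALT_CALLED`.
#' @export
classify_site_status <- function(site, min_depth = 10, min_alt_fraction = 0.95) {
  site <- as.data.frame(site)
  stopifnot(nrow(site) == 1)
  st <- call_variants(site, min_depth, min_alt_fraction)$status
  structure(st$status, allele = st$allele)
}

#' Call variants for one accession's pileup stream
#'
#' Requires the stream to be position-sorted within replicon (single-pass
#' contract); returns calls, per-site statuses and summary counts.
#'
#' @param pileups Pileup `data.frame` for one accession.
#' @param accession Accession id attached to the outputs.
#' @inheritParams call_variants
#' @return List with `calls`, `status` (both carrying an `accession`
#'   column) and `summary` (one row: accession, n_sites, n_snps, n_indels).
#' @export
call_accession <- function(pileups, accession, min_depth = 10,
                           min_alt_fraction = 0.95) {
  if (nrow(pileups) > 0) {
    o <- order(match(pileups$replicon, unique(pileups$replicon)), pileups$pos)
    if (!identical(o, seq_len(nrow(pileups))))
      stop("pileup stream for ", accession,
           " is not sorted by (replicon, position)")
  }
  res <- call_variants(pileups, min_depth, min_alt_fraction)
  if (nrow(res$calls)) res$calls$accession <- accession
  else res$calls$accession <- character(0)
  if (nrow(res$status)) res$status$accession <- accession
  else res$status$accession <- character(0)
  res$summary <- data.frame(
    accession = accession, n_sites = nrow(res$status),
    n_snps = sum(res$calls$variant_class == "SNP"),
    n_indels = sum(res$calls$variant_class == "indel"),
    stringsAsFactors = FALSE)
  res
}
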