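# Independent brute-force oracles used by unit and acceptance tests.
# Deliberately written as plain scalar re-derivations of the rules, sharing
# no code with the package implementation.

BASES4 <- c("A", "C", "G", "T")

# Scalar site classifier: depth >= min_depth and one allele strictly above
# frac of the depth denominator (bases + N + deletion observations).
brute_status <- function(nA, nC, nG, nT, nN, nDel, nIns, ref,
                         min_depth = 10, frac = 0.95) {
  depth <- nA + nC + nG + nT + nN + nDel
  if (depth < min_depth) return(list(status = "LOW_DEPTH", allele = NA_character_))
  counts <- c(A = nA, C = nC, G = nG, T = nT)
  for (b in BASES4) {
    if (b != ref && counts[[b]] > frac * depth)
      return(list(status = "ALT_CALLED", allele = b))
  }
  if (nDel > frac * depth) return(list(status = "ALT_CALLED", allele = "DEL"))
  if (nIns > frac * depth) return(list(status = "ALT_CALLED", allele = "INS"))
  if (counts[[ref]] > frac * depth)
    return(list(status = "REF_CONFIRMED", allele = NA_character_))
  list(status = "AMBIGUOUS", allele = NA_character_)
}

# Random pileup table mixing smooth and boundary-heavy sites.
random_pileup <- function(n, seed) {
  set.seed(seed)
  ref <- sample(BASES4, n, replace = TRUE)
  depth <- sample(0:40, n, replace = TRUE)
  # ~1/4 of sites forced near the 95% boundary
  mk <- function(i) {
    d <- depth[i]
    if (d == 0) return(c(0, 0, 0, 0, 0, 0, 0))
    if (runif(1) < 0.25 && d >= 2) {
      top <- ceiling(0.95 * d) + sample(c(-1L, 0L, 1L), 1)
      top <- max(0L, min(d, top))
      rest <- d - top
      v <- integer(4)
      v[sample(4, 1)] <- top
      spill <- sample(4, 1)
      v[spill] <- v[spill] + rest
      c(v, 0, 0, 0)
    } else {
      v <- as.vector(stats::rmultinom(1, d, prob = runif(7)))
      c(v[1:4], v[5], v[6], v[7])
    }
  }
  m <- t(vapply(seq_len(n), mk, numeric(7)))
  data.frame(replicon = "chr1", pos = seq_len(n), ref = ref,
             nA = m[, 1], nC = m[, 2], nG = m[, 3], nT = m[, 4],
             nN = m[, 5], nDel = m[, 6], nIns = m[, 7],
             stringsAsFactors = FALSE)
}

# IUPAC-aware sliding-window matcher (independent of Biostrings).
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

revcomp_iupac <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

slide_matches <- function(seq, pat) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pat, "")[[1]]
  k <- length(pc)
  hits <- integer(0)
  if (length(sc) < k) return(hits)
  for (s in seq_len(length(sc) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!sc[s + j - 1] %in% IUPAC_SETS[[pc[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Does any match (either strand) of `pat` overlap 1-based `offset` in seq?
slide_overlap <- function(seq, pat, offset) {
  k <- nchar(pat)
  hits <- slide_matches(seq, pat)
  rc <- revcomp_iupac(pat)
  if (rc != pat) hits <- c(hits, slide_matches(seq, rc))
  any(hits <= offset & hits + k - 1 >= offset)
}

# Small simulation configs reused across test files.
tiny_panel_config <- function(seed = 1, L = 3000L, mean_depth = 30,
                              error_rate = 0.002, dropout_rate = 0.02) {
  simulation_config(
    seed = seed,
    species_tree = "(OG:0.1,((A:0.03,B:0.03):0.02,(C:0.04,D:0.04):0.01):0.04);",
    accessions_per_species = c(A = 3L, B = 2L, C = 3L, D = 2L, OG = 1L),
    within_species_diversity = c(A = 0.002, B = 0.001, C = 0.003, D = 0.001,
                                 OG = 0),
    replicons = data.frame(name = "chr1", length = L, is_organelle = FALSE),
    mean_depth = mean_depth, dropout_rate = dropout_rate,
    error_rate = error_rate, outgroup_species = "OG",
    outgroup_alignable_fraction = 0.9)
}

run_calls <- function(sim, ...) {
  res <- lapply(sim$panel$accession,
                function(a) call_accession(sim$pileups[[a]], a, ...))
  names(res) <- sim$panel$accession
  res
}
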