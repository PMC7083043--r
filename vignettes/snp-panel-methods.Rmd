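---
title: "Methods: homozygous SNP panels, diagnostic markers and phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homozygous SNP panels, diagnostic markers and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
```

This vignette documents the statistical model behind `snpanel`, the
decisions taken where several defensible designs existed, and what the
validation on simulated panels does and does not establish.

## The calling model

Evidence is a per-site pileup: counts of A, C, G, T, N reads plus
deletion- and insertion-supporting observations, for one accession against
one reference. Two thresholds define a call:

* **Depth**: total depth must be at least `min_depth` (default 10,
  inclusive).
* **Fraction**: a single allele must account for *strictly* more than
  `min_alt_fraction` (default 0.95) of the depth. The strictness matters
  at boundaries: 19 alternate reads out of 20 is exactly 0.95 and is
  **not** a call, while 10/10 at the minimum depth is.

The depth denominator is `nA + nC + nG + nT + nN + nDel`. Including N
calls and deletion-spanning reads is the conservative choice: uncertain
evidence dilutes the winning allele's fraction and pushes borderline sites
into `AMBIGUOUS` rather than into calls. Insertion observations annotate
reads that still report a base at the site, so `nIns` is not added to the
denominator (it is still subject to the same fraction rule for calling an
insertion event). With a strict 95% rule, no site where two alleles each
hold 5% of the reads can ever be called — this is the homozygosity
contract appropriate for selfing species, and it automatically suppresses
heterozygous-looking artifacts such as RNA-editing-derived mixed sites in
organellar data. At a multi-allelic site, one non-reference allele alone
must clear the fraction; two alternates splitting the reads give
`AMBIGUOUS`.

Every evaluated site receives exactly one status: `LOW_DEPTH`,
`ALT_CALLED` (with the allele, or `DEL`/`INS`), `REF_CONFIRMED` (the
reference base clears the same fraction), or `AMBIGUOUS`. Indels are
presence/absence events at a position; their length and sequence are not
modeled, and they are reported in calling summaries but never enter the
genotype matrix.

## The non-redundant matrix

Candidate sites are the union of SNP positions called in any accession. A
site is retained iff **every** panel accession has status `REF_CONFIRMED`
or `ALT_CALLED` with a base allele there; any accession with low depth,
ambiguous evidence, no coverage, or an indel call drops the site for the
whole panel. This all-accession rule is the strictest reading of
"unambiguous and sufficiently covered in all accessions" and is what
guarantees a matrix with no missing entries. Consequences worth knowing:

* Accessions of the reference species enter like any other accession;
  their alleles come from `REF_CONFIRMED` statuses.
* Sites where every accession shares the same non-reference allele
  (divergence of the reference alone) stay in the matrix; they are real
  non-redundant SNPs against the reference, but they are inert for
  within-panel classification.
* A distant outgroup with a reduced alignable fraction shrinks the matrix
  (each site must also be scorable in the outgroup), mirroring the
  behaviour of real panels when an outgroup is added.

Classification is then pure set arithmetic on matrix rows: *polymorphic*
(≥ 2 alleles within a species), *fixed* (both species monomorphic,
alleles differ), *unique* (group monomorphic, allele absent from all
other non-outgroup species). Outgroup accessions are excluded from
classification and diversity; they exist for rooting.

## Distances, trees, bootstrap

Distances are raw pairwise mismatch counts (Hamming) by default, matching
the usual "number of pairwise differences" axis of diversity plots; a
per-site rate and a Jukes–Cantor correction are available as options but
are not the default. Any mismatch at a multi-allelic site counts once.

Trees are built with classic neighbor joining (successive joining of the
pair minimizing the Q criterion), which is exact on additive matrices.
The implementation wraps the standard `ape::nj` with two policies layered
on top:

* labels are sorted lexicographically before construction, so results are
  invariant to accession input order, and
* negative branch lengths are clamped to zero, with the clamped total
  recorded on the tree.

Bootstrap support resamples matrix columns with replacement, rebuilds the
NJ tree per replicate, and scores each internal edge of the point
estimate by the percentage of replicates containing the same bipartition.
Bipartitions are canonicalized (the side not containing the
alphabetically first leaf) so support lookup is order-free. Rooting
requires the outgroup to be monophyletic on the unrooted tree and
otherwise fails with the straddling bipartitions listed.

Congruence between two trees is reported as the Robinson–Foulds distance
with the conflicting bipartitions themselves, per-species monophyly
verdicts, and — crucially — the same comparison repeated on
**species-level induced splits**: accession bipartitions on which every
species falls wholly on one side. Within-species distances are nearly
tied, so NJ resolves within-species stars arbitrarily with near-zero
branches; those arbitrary resolutions differ between partitions and
contaminate the accession-level RF. Induced species splits drop them by
construction, which is why planted cytonuclear discordance can be
recovered *exactly* (one nearest-neighbor interchange in the organelle
species tree yields exactly one conflicting species-level split per
tree).

## CAPS marker design

A fixed SNP becomes a CAPS candidate for an enzyme when a recognition
match **overlapping the SNP position** exists in exactly one of the two
allele-substituted sequences (IUPAC-aware, both strands). The overlap
requirement is deliberate: a gained or lost site elsewhere in the window
cannot be caused by the SNP, so only overlapping sites guarantee
allele-specific digestion. Amplicon selection is reduced to a symmetric
window (default 500 bp) trimmed at replicon edges; candidates whose two
allele digests are identical within the window are discarded. Primer
thermodynamics are out of scope. The shipped enzyme table holds twelve
common 4–6 bp cutters, two with degenerate recognition sequences; users
can substitute their own TSV.

In-silico digestion cuts at every match on either strand; cut positions
come from the enzyme's top-strand cut offset (mirrored for reverse-strand
matches), and fragment lengths always sum to the input length.

## The simulator and its defaults

The simulator generates the study conditions the analysis assumes, with
all sources of randomness under one seed:

* **Reference**: uniform random A/C/G/T per replicon.
* **Evolution**: Jukes–Cantor substitution along the species tree
  (per-branch substitution probability 3/4·(1 − e^(−4t/3))), the simplest
  model sufficient for recovery testing; accessions hang off their
  species node in a star with terminal branch =
  `within_species_diversity`, optionally grouped into sublineages behind
  a shared internal branch — a deliberate shortcut standing in for a full
  coalescent that still reproduces the "discrete divergent groups"
  pattern seen in real panels. Organelle replicons follow their own tree
  when configured, which is how cytonuclear discordance is planted. All
  genotypes are homozygous (selfing).
* **Coverage**: Poisson depth (negative binomial when
  `depth_dispersion > 0`, variance μ + dμ²), dropouts with probability
  `dropout_rate`, and for outgroup accessions each site is scorable only
  with probability `outgroup_alignable_fraction` — emulating a distant
  taxon's lower alignment rate.
* **Error**: each read reports the true allele with probability
  1 − `error_rate`, else a uniformly chosen different base. Deletions
  (optional, off by default) convert all reads at a site to deletion
  observations.

The default panel (`default_panel_config()`) is a 12-species diploid
panel: three focal species with five accessions each, seven reused
relatives with two or three, and one single-accession outgroup on a long
branch with alignable fraction 0.7. Internal branches range 0.005–0.06
substitutions/site, within-species terminal branches 0.0005–0.002, one
focal species carries two sublineages (inter-sublineage branch 0.004),
depth is Poisson(30), dropout 0.02, per-read error 0.002. These are
invented but field-realistic magnitudes: depths around 30 and sub-percent
error are typical of expressed-sequence genotyping, and the branch
lengths give the three-clade structure (an einkorn-like pair, a deep
lone lineage, and a radiation holding the rest) that makes the recovery
tests meaningful. The default organelle tree is the nuclear topology with
one species moved by a single nearest-neighbor interchange and branch
lengths halved (organellar genomes evolve more slowly).

**What the simulator does not emulate**: read-level artifacts (mapping
bias, spliced-alignment edge effects, strand bias), base-quality
structure, recombination, heterozygosity, gene-tree discordance from
incomplete lineage sorting, and expression-dependent coverage along
genes. Passing recovery tests therefore certifies the *pipeline logic*
(thresholds, set arithmetic, tree building) under the stated generative
model — not robustness to every failure mode of real RNA-seq data.

## Numerical and degenerate-input policies

* Coordinates are 1-based inclusive everywhere internally and in VCF;
  BED output is 0-based half-open, converted in a single documented
  function (`site_to_bed`).
* `> 0.95` is a strict inequality on exact integer counts; no epsilon is
  involved.
* Ties in NJ are broken deterministically via lexicographic label order;
  bootstrap resampling is seeded; two runs with identical inputs, config
  and seed produce byte-identical artifacts.
* Single-accession species: polymorphic sites are defined empty with a
  warning. Identical species arguments to `fixed_snps`, or a group
  covering the whole panel in `unique_substitutions`, are usage errors.
* The sublineage gap flag needs at least four pairwise values and is
  raised when the largest gap between consecutive sorted values exceeds
  the sum of all the others (more than half the spread in one gap).
* Empty partitions (e.g. an organelle replicon with no retained SNPs)
  skip distance/tree stages rather than erroring the pipeline.

## Validation problem sizes

The test suite validates, among others: calling against a brute-force
reimplementation on 10,000 randomized sites; matrix reconstruction on a
noiseless 6-species × 3-accession, 50 kb panel against the simulator's
truth; classification against exhaustive loops on 20 accessions × 5,000
sites; exact NJ recovery on 100 random additive matrices (n ≤ 8);
species-tree recovery with ≥ 5,000 retained SNPs and 200 bootstrap
replicates on the full default panel; diversity-ordering recovery over 20
seeded replicates of a two-species contrast (terminal branches 0.004 vs
0.001); and CAPS discovery against an IUPAC sliding-window oracle with 50
planted site-gain/loss SNPs over a 6-enzyme panel. These sizes were
chosen to make sampling error negligible relative to the tested effects
while keeping the default test run fast.

## Known limitations

* Maximum-likelihood or Bayesian tree estimation is out of scope; NJ is
  the only estimator, so congruence analyses compare NJ trees.
* Indels are counted, never placed in the matrix or designed against.
* The caller has no genotype likelihoods; the two thresholds are the
  model. Sites systematically miscovered in one accession silently vanish
  from the panel matrix — by design, but worth remembering when comparing
  matrix sizes across panels of different accession counts.
* Real headline counts from any particular empirical panel depend on its
  raw reads and reference; this package reproduces the *method*, and its
  acceptance artifacts are simulation-derived quantities with known
  truth.
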