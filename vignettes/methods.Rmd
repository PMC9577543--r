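---
title: "Methods: cross-species epigenome comparison over orthology-validated regions"
author: "orthoepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species epigenome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(orthoepi)
  library(GenomicRanges)
  library(SummarizedExperiment)
})
```

# Scope and model

`orthoepi` compares histone-modification landscapes (H3K4me3, H3K27me3)
between two closely related genomes whose relationship is given by pairwise
alignment chains, and traces the genetic origins of the differences:
substitutions that create transcription-factor binding motifs, and
species-specific retrotransposon insertions. A third genome can serve as an
outgroup for motif-orthology tracing. Every stage is exercised against
synthetic genome pairs with planted ground truth, because the genome-scale
inputs of a real two-species iPSC study (reference genomes, chains, read
alignments) are far beyond what a test suite can carry; what the tests
establish is therefore correctness of the *procedures* under the generative
model described below, not re-derivation of any published genome-wide count.

## Enrichment scoring and species-specificity

For a region with ChIP count $n_c$ and input count $n_i$ in one sample,

$$E \;=\; \frac{n_c / N_c}{\max(n_i, 1) / N_i},$$

where $N_c, N_i$ are total mapped reads of the two libraries. The score is
a per-region ChIP/input fold enrichment robust to library depth. Design
choices:

* **Input floor of 1 raw read.** Regions with ChIP signal but zero sampled
  input reads would otherwise score infinity. The floor is applied to the
  input only and makes $E$ a conservative underestimate there. Regions with
  *no* reads at all (ChIP plus input, all samples) are uninformative —
  typically unmappable — and are discarded before classification.
* **Thresholds.** A region is A-specific when the species-A mean of $E$
  over replicates is $\ge 3$ and the species-B mean is $< 1.5$
  (symmetrically for B). The pair of thresholds, rather than a single
  cutoff, demands both presence and absence; everything orthology-valid
  that is not species-specific is *shared* (the complement definition).
* **Exact-threshold arithmetic.** $E$ is computed as a single ratio
  $n_c N_i / (N_c \max(n_i, 1))$ so that count configurations landing
  exactly on a threshold are classified without floating-point surprises.

The classifier requires one ChIP and one input sample per (species,
replicate); means are taken within species. Label symmetry (swapping the
species swaps A_specific and B_specific) and monotonicity in the upper
threshold are asserted as properties in the test suite.

## Coordinate lifting and reciprocal orthology

Chains are parsed with full block-arithmetic validation (the block sizes
plus gaps must reproduce the header spans). Lifting an interval:

* bases falling in aligned blocks map linearly; bases in target-side gaps
  are deleted in the query;
* an interval is **mapped** when at least `minMatch` (default 0.95, the
  conventional liftOver setting; the choice is configurable) of its bases
  map under exactly one chain, and its image spans the first to the last
  mapped base;
* if two or more chains each cover `minMatch` of the bases, the interval is
  **duplicated** (mirroring liftOver's single-mapping behavior); a partial
  cover is **partial**, none is **deleted**;
* minus-strand chains yield plus-strand coordinates with the strand flag
  flipped.

Reciprocal validation lifts forward, rejects deleted/duplicated images,
lifts back, and requires the back-lifted interval to equal the original
within `slack` bp per endpoint. The default `slack = 0` reads the
"same as the original region" criterion literally as identity; it is exact
on the package's truth chains. For TE-insertion flank validation the slack
defaults to the tandem-gap tolerance instead, because a target-site
duplication of $k$ bp shifts the inner endpoint of one flank's back-lift by
exactly $k$.

## Motif scanning with exact p-values

A `MotifModel` holds a pseudocounted frequency matrix (pseudocount 0.1 per
cell, a FIMO-like default), a background (uniform unless specified — the
appropriate background for the synthetic genomes, whose ancestors are
uniform i.i.d.), and the log2-odds matrix discretized to an integer grid of
1/1000 of the total score range. The null distribution of window scores is
computed by exact dynamic programming (position-wise convolution of the
binned column scores under the background), and the *same* discretized
matrix scores every window during scanning. P-values are therefore exact
tail probabilities for the scores actually assigned, verifiable by
exhaustive enumeration for short motifs; there is no sampling and no
asymptotic approximation. Hits are windows with $p \le \alpha$ (default
$10^{-4}$; $10^{-3}$ for the short SOX2/POU5F1 motifs) on either strand;
windows containing N are skipped.

For gain/loss statistics, overlapping same-strand hits are resolved
greedily left-to-right so a single planted site counts once. Per motif,
across a species-specific region set with orthologous sequence pairs,
$n_\text{gain}$ counts regions where the modified species has strictly more
hits and $n_\text{loss}$ strictly fewer; ties count as neither. The test is
a 1-df goodness-of-fit chi-square of $(n_\text{gain}, n_\text{loss})$
against a 50:50 split — the natural null that sequence divergence creates
and destroys sites symmetrically when the modification is independent of
the motif. (A 2x2 table across region sets would test a different
hypothesis; the 50:50 form matches the reported per-motif counts.) Motifs
with no events are skipped with a warning rather than assigned a p-value.

## TE-insertion detection and flanking profiles

A repeat whose interval fails to lift is only a *candidate*: assembly gaps
and diverged regions produce the same signal. Validation demands the
geometry of a true insertion: both 1-kb flanks lift, their images are
adjacent on the same sequence and orientation (gap within `tandemGapMax`,
default 50 bp — absorbing TSDs and micro-indels; the tolerance is a design
choice since "in tandem" has no canonical width), and both flanks
reciprocal-validate. Repeats within one flank length of a contig edge are
rejected as `edge`. Candidate repeats are restricted by default to the
young, active families the analysis follows (`Alu*`, `L1*`, `LTR5*` in
classes SINE/LINE/LTR); both filters are configurable.

Flanking meta-profiles use 30 windows of 200 bp (15 per side), ordered 5'
to 3' relative to the element's strand (unstranded elements default to
plus). Signal is reads per million per window, averaged first across
insertions — dropping windows that fail orthology validation from the
divisor rather than zero-filling them, so missing windows do not dilute the
mean — then across replicates within species.

## LTR5 phylogenetics and the motif-orthology trace

Distances are p-distances (mismatches over columns where neither sequence
is gapped) on an externally supplied alignment; the package deliberately
does not implement multiple alignment, and the synthetic generator emits
true alignments. Neighbor joining follows Saitou–Nei exactly, with two
determinism guarantees: ties in the $Q$ criterion are broken by the
lexicographic order of the clusters' smallest taxon labels, and negative
branch-length estimates are clamped to zero with a warning. On any additive
matrix the algorithm provably recovers the generating topology and branch
lengths; the suite verifies this on random trees of 4–8 taxa and, for
5-taxon cases, confirms by exhaustive topology enumeration with
least-squares branch fitting that the recovered topology is the unique
optimum.

The dual pluripotency motif is a SOX2 site upstream of a POU5F1 site on the
same strand with a gap of at most 10 bp — covering the canonical LTR5
arrangement (SOX2 at element positions 681–686, POU5F1 at 692–698, 5-bp
spacer) with slack for indels. The three-genome trace filters LTR5 copies
of genome 1 ($\ge$ 500 bp): (1) reciprocal orthology to genome 2 plus
overlap with an LTR5 annotation there; (2) dual motif present in both
genomes' sequences; (3) lift to genome 3, LTR5 annotation, motif test.
Counts are non-increasing along the chain by construction, and the trace
asserts it.

## Expression statistics

DEG calling is the equal-variance two-sample Student t-test per gene
(chosen over Welch to match the analysis convention; configurable),
BH-adjusted over tested genes, with fold change $(\bar{T}_A + 1)/(\bar{T}_B
+ 1)$ on species means and calls at $q < 0.05$, FC $\ge 2$ or $\le 0.5$.
Genes with all-zero TPM in both species are excluded *before* testing:
they are untestable and would only inflate the BH denominator $m$. Genes
with zero variance in both groups get $p = 1$ when the means agree; when
the means differ the t statistic is undefined and the gene is excluded
with a warning rather than assigned $p = 0$ — at two replicates such genes
are more plausibly degenerate inputs (identical duplicated values) than
real signal. The t-test arithmetic is vectorized but verified against
`stats::t.test` in the unit tests; BH uses `stats::p.adjust`, verified
against a brute-force step-up implementation.

TE expression counts paired-end *second* reads (the mate carrying the
sense-strand sequence) aligned in sense orientation with a repeat, once per
read, RPM-normalized to total mappable reads. Small-RNA quantification
retains 24–35-nt reads (the piRNA range) and weights each alignment of a
read mapping to $n$ loci by $1/n$, conserving one unit of mass per read.
Correlations are Pearson on $\log_2(\text{TPM}+1)$; the log base and
pseudocount are a convention choice (results are invariant to the base;
the +1 keeps zeros finite).

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated.

* **Genomes.** Each chromosome descends from an i.i.d. uniform ancestor
  (default 2 chromosomes of 200 kb — large enough to hold all planted
  variants with non-interfering spacing while keeping the full suite under
  two minutes; the trace examples use 400 kb). Genome B carries
  substitutions at rate 0.012 per bp, the human–chimpanzee regime of
  98–99% identity; the outgroup uses 0.02. Substitutions avoid planted
  motif footprints, so motif presence/absence is controlled exclusively by
  explicit flags — motif loss is simulated by scrambling the 18-bp dual
  footprint, never by chance mutation. Each genome receives its own
  insertions from a three-family TE library (300-bp SINE, 1,200-bp LINE,
  968-bp LTR with the dual motif at positions 681–698), at sites kept 4.5
  kb apart and 5 kb from contig edges so flanks and elements never
  interfere. Optional target-site duplications (default 0) copy the
  insertion-site bases to both sides of the element.
* **Chains.** Built directly from the edit script — every non-inserted
  base maps 1-to-1, every insertion is a one-sided gap — so lifting
  A→B→A is the identity on non-variant regions *by construction*, and the
  involution property is a meaningful end-to-end check of the chain
  parser, the lifting engine and the generator at once.
* **ChIP counts.** Negative binomial with mean = input mean x effect
  (effect 8 for regions modified in that species, 1 otherwise), input mean
  100 reads, equal library sizes, 2 replicates per species, 2,000 regions
  of which 10% are species-specific and 1% read-free. The dispersion
  default is 0.02 (biological CV ~0.14), the replicate concordance of
  deeply sequenced ChIP in isogenic lines; at this noise level the planted
  design is recoverable at $\ge 95\%$ recall with $\le 1\%$ false
  species-specific calls, which is the regime the classifier is specified
  to operate in.
* **Expression.** Log-normal TPMs: per-gene log2 baselines
  $\mathcal{N}(4, 2^2)$, replicate noise $\mathcal{N}(0, 0.35^2)$ — giving
  intraspecies log-scale correlations of 0.96–0.98, matching iPSC replicate
  concordance — and planted 4-fold changes in 2% of genes. DEG *recovery*
  is demonstrated at low replicate noise (sd 0.02): with two replicates and
  a t-test, BH-corrected discovery across 5,000 genes is only powered when
  within-group variance is small, and the low-noise setting isolates the
  caller's correctness from the power question.
* **Motif region pairs.** Orthologous sequence pairs (400 bp, 1.2%
  divergence) where half the "modified" sequences carry one planted
  consensus site whose orthologous bases are scrambled — a pure gain with
  unambiguous truth.

**What the generator does not emulate**, and what passing tests therefore
do not show: mappability structure and GC bias in counts (library sizes are
equal by design), peak-boundary uncertainty (regions are fixed inputs, as
peak calling is upstream of this package), chain construction errors
(chains are exact; real chains contain alignment artifacts that the
`duplicated`/`partial` statuses are designed to absorb but that no test
here quantifies), TE internal structure and 5'-truncation of L1 insertions,
non-uniform background composition for motif scanning, and gene-wise
variance heterogeneity in expression. Conclusions about real data must
come from the procedures' correctness plus these caveats, not from the
synthetic recovery rates alone.

# Numerical and degenerate-input choices

* Score discretization: 1/1000 of the score range per motif; scanning and
  p-values share the grid, so oracle equality is exact. A uniform
  (zero-range) matrix is handled with a unit bin.
* Enrichment scores use single-division arithmetic for exact threshold
  comparisons; zero-ChIP regions score exactly 0.
* NJ tie-breaks are lexicographic on cluster representatives; all-equal
  distance matrices yield a deterministic (arbitrary but fixed) resolution.
* Consensus ties follow the fixed symbol order A < C < G < T < gap;
  consensus gap columns are removed from the output.
* The chi-square gain/loss test is undefined at (0, 0) and the motif is
  skipped with a warning; `p = 1` at perfect symmetry.
* Site placement in the generator uses rejection sampling with restarts
  and raises a generation error when the requested insertion density is
  infeasible rather than silently relaxing constraints.
* Every generator draws from a seed fixed in `simulationParams`; distinct
  stages use fixed small offsets of it, so stages are independently
  reproducible and two runs of the CLI pipeline at the same seed are
  byte-identical.

# Problem sizes

The test suite and the acceptance script run the conditions above: 2,000
regions x 8 samples for peak classification, 1,000 random intervals over
random multi-block chains for the lifting oracle, 20 motifs x 50 sequences
for the scanner oracle, 20 seeds x 60 region pairs for gain/loss
calibration, 100 random trees of 4–8 taxa for NJ, 50 seeds x 5,000 genes
for the null-FDR simulation, and two full CLI pipeline runs for the
determinism check. These sizes were chosen so each property is measured
with meaningful n (binomial standard errors of a few percent or less)
while the whole suite stays fast enough to run on every change.

# Known limitations

* Lifting is per-interval against the chain set; there is no net/chain
  hierarchy, so nested chains of very different scores are all considered
  (the `duplicated` rule is the only arbitration).
* `pairwiseDivergence` is a global affine-gap alignment — appropriate for
  pre-matched 1-to-1 orthologs, not for detecting rearrangements; its
  parameters (match 1, mismatch −1, open 2, extend 0.5) follow common
  defaults since the appropriate scoring for this task is not sharply
  determined.
* The dual-motif rule is an arrangement test (order, strand, spacing); it
  does not model cooperative energetics.
* `callDegs` at n = 2 per group has little power at realistic noise;
  this is a property of the design it reproduces, not of the
  implementation.
* The CLI is a thin wrapper for file-based runs and the determinism
  guarantee; programmatic use of the R functions is the primary interface.
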