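#' ChIP enrichment score
#'
#' The per-region enrichment score is the library-normalized ChIP read count
#' divided by the library-normalized input count,
#' \code{E = (chip/chipTotal) / (input/inputTotal)}. A region with zero ChIP
#' reads scores 0. Zero input counts are floored at 1 raw read (applied to
#' the input only) so that the score stays finite and conservative for
#' regions covered by ChIP reads alone.
#'
#' @param chip,input non-negative read counts (vectors recycle).
#' @param chipTotal,inputTotal total mapped reads of the respective
#'   libraries; must be positive.
#' @return numeric enrichment score(s).
#' @export
enrichmentScore <- function(chip, input, chipTotal, inputTotal) {
  if (any(chip < 0) || any(input < 0)) stop("counts must be non-negative")
  if (any(chipTotal <= 0) || any(inputTotal <= 0))
    stop("library totals must be positive")
  # single division keeps exact-threshold comparisons free of float noise
  (chip * inputTotal) / (chipTotal * pmax(input, 1))
}

#' Classify regions as shared or species-specific
#'
#' Computes per-sample enrichment scores from paired ChIP/input counts,
#' averages them within species, and labels each region. Regions where no
#' read at all (ChIP plus input) mapped in either species are discarded
#' first (\code{discarded_no_reads}); regions failing reciprocal orthology
#' validation are discarded next (\code{discarded_orthology}). A region is
#' A-specific when the species-A mean score is >= \code{tHigh} and the
#' species-B mean is < \code{tLow}; B-specific symmetrically; everything
#' else that survives the filters is \code{shared}.
#'
#' @param se \code{SummarizedExperiment} with a \code{counts} assay and
#'   colData columns \code{species}, \code{assay} (\code{ChIP}/\code{input}),
#'   \code{replicate}, \code{lib_size}. Each (species, replicate) must have
#'   one ChIP and one input sample.
#' @param orthology optional logical vector (one per region): TRUE for
#'   regions with validated 1-to-1 orthology, e.g.
#'   \code{reciprocalValidate(...)$valid}. Default: all valid.
#' @param tHigh,tLow classification thresholds (defaults 3 and 1.5).
#' @return \code{DataFrame} with per-replicate scores, per-species means
#'   (\code{meanA}, \code{meanB}, named by the species labels), and
#'   \code{label} in \{shared, A_specific, B_specific, discarded_no_reads,
#'   discarded_orthology\} (A = first species level).
#' @export
classifyRegions <- function(se, orthology = NULL, tHigh = 3, tLow = 1.5) {
  cd <- SummarizedExperiment::colData(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  species <- unique(as.character(cd$species))
  if (length(species) != 2)
    stop("configuration error: need exactly two species, got ",
         length(species))
  if (is.null(orthology)) orthology <- rep(TRUE, nrow(se))
  stopifnot(length(orthology) == nrow(se))
  scores <- list()
  for (sp in species) {
    reps <- unique(cd$replicate[cd$species == sp])
    if (length(reps) < 1)
      stop("configuration error: no samples for species ", sp)
    for (r in reps) {
      iChip <- which(cd$species == sp & cd$replicate == r &
                       cd$assay == "ChIP")
      iIn <- which(cd$species == sp & cd$replicate == r &
                     cd$assay == "input")
      if (length(iChip) != 1 || length(iIn) != 1)
        stop("configuration error: species ", sp, " replicate ", r,
             " must have one ChIP and one input sample")
      scores[[paste0("E_", sp, "_", r)]] <-
        enrichmentScore(counts[, iChip], counts[, iIn],
                        cd$lib_size[iChip], cd$lib_size[iIn])
    }
  }
  sc <- do.call(cbind, scores)
  spOf <- sub("^E_", "", sub("_[^_]+$", "", colnames(sc)))
  meanA <- rowMeans(sc[, spOf == species[1], drop = FALSE])
  meanB <- rowMeans(sc[, spOf == species[2], drop = FALSE])
  totalReads <- rowSums(counts)
  label <- rep("shared", nrow(se))
  label[meanA >= tHigh & meanB < tLow] <- "A_specific"
  label[meanB >= tHigh & meanA < tLow] <- "B_specific"
  label[!orthology] <- "discarded_orthology"
  label[totalReads == 0] <- "discarded_no_reads"
  out <- DataFrame(sc, meanA = meanA, meanB = meanB, label = label)
  metadata(out) <- list(species = species, tHigh = tHigh, tLow = tLow)
  out
}

#' Call bivalent regions from per-line peak sets
#'
#' Intersects the H3K4me3 and H3K27me3 peak sets within each cell line
#' (bivalency is a property of one cell line, not of pooled samples), then
#' merges the per-line intersections across lines of the same species.
#'
#' @param k4Peaks,k27Peaks named lists of \code{GRanges}, one element per
#'   cell line, with matching names.
#' @param species optional named character vector mapping line names to
#'   species; when given, the result is a list of per-species merged
#'   \code{GRanges}, else a single merged \code{GRanges}.
#' @return \code{GRanges} (or list of them) of bivalent intervals.
#' @export
callBivalent <- function(k4Peaks, k27Peaks, species = NULL) {
  stopifnot(identical(sort(names(k4Peaks)), sort(names(k27Peaks))))
  perLine <- lapply(names(k4Peaks), function(ln)
    GenomicRanges::intersect(k4Peaks[[ln]], k27Peaks[[ln]],
                             ignore.strand = TRUE))
  names(perLine) <- names(k4Peaks)
  perLine <- lapply(perLine, function(gr) gr[width(gr) > 0])
  if (is.null(species))
    return(GenomicRanges::reduce(do.call(c, unname(perLine))))
  stopifnot(all(names(k4Peaks) %in% names(species)))
  out <- lapply(split(names(perLine), species[names(perLine)]),
                function(lns)
                  GenomicRanges::reduce(do.call(c, unname(perLine[lns]))))
  out
}

#' Assign peaks to gene promoters
#'
#' The promoter window spans 2 kb upstream to 0.5 kb downstream of each
#' transcription start site, reflected for minus-strand genes. A peak is
#' assigned to a gene when it overlaps the window by at least 1 bp.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes \code{GRanges} of gene bodies with strand and an mcol
#'   \code{gene_id} (or names).
#' @param upstream,downstream promoter window extent in bp.
#' @return data.frame with columns \code{peak} (index into \code{peaks}) and
#'   \code{gene_id}; one row per (peak, gene) assignment.
#' @export
assignPromoters <- function(peaks, genes, upstream = 2000, downstream = 500) {
  ids <- if (!is.null(mcols(genes)$gene_id)) mcols(genes)$gene_id
         else if (!is.null(names(genes))) names(genes)
         else as.character(seq_along(genes))
  prom <- GenomicRanges::promoters(genes, upstream = upstream,
                                   downstream = downstream)
  prom <- GenomicRanges::trim(prom)
  hits <- GenomicRanges::findOverlaps(peaks, prom, ignore.strand = TRUE)
  data.frame(peak = S4Vectors::queryHits(hits),
             gene_id = ids[S4Vectors::subjectHits(hits)])
}

#' Percent identity between orthologous sequences
#'
#' Global alignment with affine gap penalties (match 1, mismatch -1, gap
#' open 2, gap extend 0.5 by default); identity is the number of matched
#' columns over all alignment columns, gap columns included.
#'
#' @param seqA,seqB character strings or \code{DNAString}s.
#' @param match,mismatch,gapOpening,gapExtension alignment scores (penalties
#'   positive).
#' @return percent identity in [0, 100].
#' @export
pairwiseDivergence <- function(seqA, seqB, match = 1, mismatch = -1,
                               gapOpening = 2, gapExtension = 0.5) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (nchar(seqA) == 0 || nchar(seqB) == 0)
    stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = gapOpening,
                                       gapExtension = gapExtension)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  100 * sum(pc == sc & pc != "-") / length(pc)
}

#' Count overlaps between two interval sets
#'
#' @param setA,setB \code{GRanges}.
#' @return list with \code{nOverlapping} (number of A intervals with >= 1 bp
#'   overlap in B), \code{nA}, \code{nB}.
#' @export
overlapCounts <- function(setA, setB) {
  ov <- GenomicRanges::countOverlaps(setA, setB, ignore.strand = TRUE)
  list(nOverlapping = sum(ov > 0), nA = length(setA), nB = length(setB))
}
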