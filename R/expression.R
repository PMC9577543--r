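#' Call differentially expressed genes
#'
#' Per gene, species means of TPM are compared with an equal-variance
#' two-sample Student t-test; p-values are Benjamini-Hochberg adjusted over
#' all tested genes, and the fold change is computed on species means with
#' a pseudocount of 1, \code{FC = (meanA + 1) / (meanB + 1)}. A gene is
#' called up in A when q < 0.05 and FC >= 2, up in B when q < 0.05 and
#' FC <= 0.5.
#'
#' Genes with all-zero TPM in both species are excluded before testing
#' (they are untestable and would inflate the BH denominator). Genes with
#' zero variance in both groups get p = 1 when the means are equal; when
#' the means differ the t statistic is undefined and the gene is flagged
#' degenerate and excluded from testing, with a warning.
#'
#' @param tpm numeric matrix, genes x samples, TPM values.
#' @param groups data.frame with columns \code{sample}, \code{species}
#'   (two levels; the first is "A" in the fold-change ratio), matching the
#'   columns of \code{tpm}.
#' @param qThreshold,fcThreshold call thresholds (defaults 0.05 and 2).
#' @param varEqual use the equal-variance t-test (default TRUE).
#' @return data.frame with \code{gene}, \code{meanA}, \code{meanB},
#'   \code{foldChange}, \code{p}, \code{q}, \code{label} in \{A_up, B_up,
#'   ns, untested\}.
#' @export
callDegs <- function(tpm, groups, qThreshold = 0.05, fcThreshold = 2,
                     varEqual = TRUE) {
  stopifnot(ncol(tpm) == nrow(groups))
  species <- unique(as.character(groups$species))
  if (length(species) != 2) stop("need exactly two species")
  ia <- which(groups$species == species[1])
  ib <- which(groups$species == species[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 replicates per species")
  meanA <- rowMeans(tpm[, ia, drop = FALSE])
  meanB <- rowMeans(tpm[, ib, drop = FALSE])
  fc <- (meanA + 1) / (meanB + 1)
  varA <- apply(tpm[, ia, drop = FALSE], 1, stats::var)
  varB <- apply(tpm[, ib, drop = FALSE], 1, stats::var)
  allZero <- meanA == 0 & meanB == 0
  degenerate <- varA == 0 & varB == 0 & meanA != meanB
  zeroVarEqual <- varA == 0 & varB == 0 & meanA == meanB
  testable <- !allZero & !degenerate
  if (any(degenerate))
    warning(sum(degenerate),
            " gene(s) with zero variance but unequal means excluded from",
            " testing")
  p <- rep(NA_real_, nrow(tpm))
  idx <- which(testable & !zeroVarEqual)
  na <- length(ia); nb <- length(ib)
  if (varEqual) {
    # vectorized equal-variance Student t (identical to stats::t.test with
    # var.equal = TRUE)
    sp2 <- ((na - 1) * varA[idx] + (nb - 1) * varB[idx]) / (na + nb - 2)
    tstat <- (meanA[idx] - meanB[idx]) / sqrt(sp2 * (1 / na + 1 / nb))
    p[idx] <- 2 * stats::pt(abs(tstat), df = na + nb - 2,
                            lower.tail = FALSE)
  } else {
    for (i in idx)
      p[i] <- stats::t.test(tpm[i, ia], tpm[i, ib],
                            var.equal = FALSE)$p.value
  }
  p[testable & zeroVarEqual] <- 1
  q <- rep(NA_real_, nrow(tpm))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")
  label <- rep("ns", nrow(tpm))
  label[!testable] <- "untested"
  label[testable & q < qThreshold & fc >= fcThreshold] <- "A_up"
  label[testable & q < qThreshold & fc <= 1 / fcThreshold] <- "B_up"
  data.frame(gene = if (!is.null(rownames(tpm))) rownames(tpm)
             else as.character(seq_len(nrow(tpm))),
             meanA = meanA, meanB = meanB, foldChange = fc,
             p = p, q = q, label = label, row.names = NULL)
}

#' Pearson correlation of log-transformed expression
#'
#' Correlation of two expression vectors on the log2(TPM + 1) scale.
#'
#' @param x,y non-negative expression vectors of equal length.
#' @return Pearson R.
#' @export
logCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  stats::cor(log2(x + 1), log2(y + 1))
}

#' Sense-strand TE expression in RPM
#'
#' Counts paired-end second reads (which carry the sense-strand sequence)
#' aligned in sense orientation with annotated repeats, per repeat
#' subfamily, normalized as reads per million mappable reads. A read is
#' counted once even if it overlaps several copies of the same or
#' different subfamilies (first overlapping annotation in position order
#' wins).
#'
#' @param aln alignment data.frame (see \code{\link{readAlignmentTable}};
#'   1-based \code{start}) with \code{mate_role} and \code{strand}.
#' @param repeats \code{GRanges} with \code{repName} and annotated strand.
#' @param totalMapped total reads mappable to the genome (RPM denominator).
#' @return data.frame with \code{repName}, \code{count}, \code{rpm}.
#' @export
teExpressionRpm <- function(aln, repeats, totalMapped) {
  stopifnot(totalMapped > 0)
  subfams <- sort(unique(mcols(repeats)$repName))
  counts <- stats::setNames(numeric(length(subfams)), subfams)
  sec <- aln[aln$mate_role == "second", , drop = FALSE]
  if (nrow(sec)) {
    reads <- GRanges(sec$chrom, IRanges(sec$start, sec$end))
    hits <- GenomicRanges::findOverlaps(reads, repeats,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      sense <- sec$strand[qh] == as.character(strand(repeats))[sh]
      qh <- qh[sense]; sh <- sh[sense]
      first <- !duplicated(qh)       # one count per read
      tab <- table(mcols(repeats)$repName[sh[first]])
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  data.frame(repName = subfams, count = as.numeric(counts),
             rpm = as.numeric(counts) / totalMapped * 1e6,
             row.names = NULL)
}

#' Weighted small-RNA counts over repeat subfamilies
#'
#' Retains reads of 24-35 nt (the piRNA size range) and counts their
#' alignments over repeat annotations with 1/n weighting, where n is the
#' read's number of mapped loci, so each retained read contributes a total
#' mass of at most 1. RPM uses the supplied mappable-read total.
#'
#' @param aln alignment data.frame with columns of
#'   \code{\link{readAlignmentTable}} plus \code{length} (read length, nt).
#' @param repeats \code{GRanges} with \code{repName}.
#' @param totalMapped RPM denominator; defaults to the number of retained
#'   distinct reads.
#' @param minLen,maxLen retained length range (defaults 24 and 35).
#' @return data.frame with \code{repName}, \code{weightedCount},
#'   \code{rpm}.
#' @export
smallRnaCounts <- function(aln, repeats, totalMapped = NULL,
                           minLen = 24L, maxLen = 35L) {
  if (!"length" %in% colnames(aln))
    stop("alignment table needs a 'length' column for small-RNA filtering")
  keep <- aln$length >= minLen & aln$length <= maxLen
  aln <- aln[keep, , drop = FALSE]
  if (is.null(totalMapped)) totalMapped <- length(unique(aln$read_id))
  subfams <- sort(unique(mcols(repeats)$repName))
  w <- stats::setNames(numeric(length(subfams)), subfams)
  if (nrow(aln)) {
    reads <- GRanges(aln$chrom, IRanges(aln$start, aln$end))
    hits <- GenomicRanges::findOverlaps(reads, repeats,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      # an alignment record contributes to one locus; weight 1/n_hits
      first <- !duplicated(qh)
      qh <- qh[first]; sh <- sh[first]
      wts <- 1 / aln$n_hits[qh]
      agg <- tapply(wts, mcols(repeats)$repName[sh], sum)
      w[names(agg)] <- as.numeric(agg)
    }
  }
  data.frame(repName = subfams, weightedCount = as.numeric(w),
             rpm = if (totalMapped > 0)
               as.numeric(w) / totalMapped * 1e6 else rep(0, length(w)),
             row.names = NULL)
}
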