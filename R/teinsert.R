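#' Detect species-specific retrotransposon insertions
#'
#' A repeat copy annotated in genome A is a candidate species-specific
#' insertion when its interval has no orthologous region in genome B (the
#' lift is deleted or unmapped). A candidate is validated when both of its
#' 1-kb flanking regions lift cleanly to genome B, their images lie in
#' tandem (same sequence, same orientation, within \code{tandemGapMax} bp of
#' each other, in order), and each flank lift reciprocal-validates back to
#' the original genome — the signature of an empty pre-insertion site in the
#' counterpart genome.
#'
#' @param repeats \code{GRanges} of repeat annotations in genome A, with
#'   mcols \code{repName} and \code{repClass} (as from
#'   \code{\link{readRepeatMaskerTrack}}).
#' @param chainAB,chainBA \linkS4class{ChainSet}s lifting A to B and back.
#' @param flank flank length in bp (default 1000).
#' @param tandemGapMax largest tolerated gap (or overlap) between the two
#'   lifted flank images, in bp; absorbs target-site duplications and
#'   micro-indels (default 50).
#' @param minMatch minimal mapped fraction for each lift.
#' @param classFilter repeat classes considered; \code{namePatterns} are
#'   regular expressions on \code{repName}, one of which must match. Set
#'   either to NULL to disable the filter.
#' @param seqLengths optional named vector of genome-A sequence lengths for
#'   the contig-edge check; defaults to the chain target sizes.
#' @param slack per-endpoint tolerance for the reciprocal flank validation;
#'   defaults to \code{tandemGapMax}, since a target-site duplication of k
#'   bp shifts the inner end of one flank's back-lift by k bp.
#' @return \code{DataFrame}, one row per repeat passing the class/name
#'   filter: \code{repName}, \code{repClass}, \code{status}
#'   (\code{not_candidate}, \code{candidate}, \code{flank_validated}, or
#'   \code{rejected}), \code{reason} (edge, flank_unmapped,
#'   flank_not_reciprocal, tandem), and \code{flankGap} (bp between the
#'   lifted flank images where defined).
#' @export
findSpeciesSpecificInsertions <- function(repeats, chainAB, chainBA,
                                          flank = 1000L, tandemGapMax = 50L,
                                          minMatch = 0.95,
                                          classFilter = c("SINE", "LINE",
                                                          "LTR"),
                                          namePatterns = c("^Alu", "^L1",
                                                           "^LTR5"),
                                          seqLengths = NULL,
                                          slack = tandemGapMax) {
  if (is.null(seqLengths)) {
    chs <- chains(chainAB)
    seqLengths <- stats::setNames(
      vapply(chs, `[[`, integer(1), "tSize"),
      vapply(chs, `[[`, character(1), "tName"))
    seqLengths <- seqLengths[!duplicated(names(seqLengths))]
  }
  keep <- rep(TRUE, length(repeats))
  if (!is.null(classFilter))
    keep <- keep & mcols(repeats)$repClass %in% classFilter
  if (!is.null(namePatterns)) {
    nm <- mcols(repeats)$repName
    keep <- keep & Reduce(`|`, lapply(namePatterns, grepl, x = nm))
  }
  reps <- repeats[keep]
  n <- length(reps)
  status <- rep("not_candidate", n)
  reason <- rep(NA_character_, n)
  gap <- rep(NA_integer_, n)

  lifted <- liftIntervals(reps, chainAB, minMatch)
  isCand <- lifted$status %in% c("deleted", "partial")
  status[isCand] <- "candidate"

  for (i in which(isCand)) {
    chrom <- as.character(seqnames(reps))[i]
    s <- start(reps)[i]; e <- end(reps)[i]
    L <- seqLengths[[chrom]]
    if (is.null(L) || is.na(L) || s - flank < 1L || e + flank > L) {
      status[i] <- "rejected"; reason[i] <- "edge"; next
    }
    fl <- GRanges(chrom, IRanges(c(s - flank, e + 1L),
                                 c(s - 1L, e + flank)))
    rv <- reciprocalValidate(fl, chainAB, chainBA, minMatch, slack)
    if (any(rv$reason %in% c("forward_deleted", "forward_partial",
                             "forward_duplicated"))) {
      status[i] <- "rejected"; reason[i] <- "flank_unmapped"; next
    }
    if (!all(rv$valid)) {
      status[i] <- "rejected"; reason[i] <- "flank_not_reciprocal"; next
    }
    sameSeq <- rv$chrom[1] == rv$chrom[2]
    sameStr <- rv$strand[1] == rv$strand[2]
    g <- if (rv$strand[1] == "-") rv$start[1] - rv$end[2] - 1L
         else rv$start[2] - rv$end[1] - 1L
    gap[i] <- if (sameSeq) g else NA_integer_
    if (!sameSeq || !sameStr || g < -tandemGapMax || g > tandemGapMax) {
      status[i] <- "rejected"; reason[i] <- "tandem"; next
    }
    status[i] <- "flank_validated"
  }
  out <- DataFrame(repName = mcols(reps)$repName,
                   repClass = mcols(reps)$repClass,
                   chrom = as.character(seqnames(reps)),
                   start = start(reps), end = end(reps),
                   status = status, reason = reason, flankGap = gap)
  metadata(out) <- list(flank = flank, tandemGapMax = tandemGapMax,
                        minMatch = minMatch)
  out
}

#' Flanking windows around insertions
#'
#' Builds the 30 windows of 200 bp (15 upstream, 15 downstream) flanking
#' each insertion, ordered 5' to 3' relative to the inserted element's
#' strand (window 1 is the most distal upstream window, window 30 the most
#' distal downstream one). Unstranded insertions default to plus
#' orientation.
#'
#' @param insertions \code{GRanges} of insertion elements.
#' @param windowWidth window width in bp (default 200).
#' @param nPerSide windows on each side (default 15).
#' @return \code{GRanges} with mcols \code{insertion} (index) and
#'   \code{window} (1..2*nPerSide).
#' @export
flankWindows <- function(insertions, windowWidth = 200L, nPerSide = 15L) {
  n <- length(insertions)
  nW <- 2L * nPerSide
  chrom <- character(n * nW); st <- integer(n * nW)
  insIdx <- integer(n * nW); widx <- integer(n * nW)
  for (i in seq_len(n)) {
    s <- start(insertions)[i]; e <- end(insertions)[i]
    minus <- as.character(strand(insertions))[i] == "-"
    starts <- c(s - windowWidth * (nPerSide:1),
                e + 1L + windowWidth * (0:(nPerSide - 1L)))
    if (minus) starts <- rev(starts)
    k <- (i - 1L) * nW + seq_len(nW)
    chrom[k] <- as.character(seqnames(insertions))[i]
    st[k] <- starts
    insIdx[k] <- i
    widx[k] <- seq_len(nW)
  }
  GRanges(chrom, IRanges(st, width = windowWidth),
          insertion = insIdx, window = widx)
}

#' Flanking-signal meta-profile
#'
#' Averages library-normalized ChIP signal (reads per million) over
#' insertions for each of the 30 flanking windows, then over replicates
#' within species. Windows failing orthology validation are dropped from
#' the insertion average (the divisor adjusts), not zero-filled.
#'
#' @param windows \code{GRanges} from \code{\link{flankWindows}} (mcols
#'   \code{insertion}, \code{window}).
#' @param counts integer matrix, rows parallel to \code{windows}, one
#'   column per sample.
#' @param sampleInfo data.frame with columns \code{species}, \code{assay},
#'   \code{replicate}, \code{lib_size}, rows parallel to the columns of
#'   \code{counts}.
#' @param valid logical vector parallel to \code{windows}; windows with
#'   FALSE are excluded (default: all valid).
#' @return data.frame with columns \code{window}, \code{species},
#'   \code{assay}, \code{meanRpm}.
#' @export
flankProfile <- function(windows, counts, sampleInfo, valid = NULL) {
  stopifnot(nrow(counts) == length(windows),
            ncol(counts) == nrow(sampleInfo))
  if (is.null(valid)) valid <- rep(TRUE, length(windows))
  rpm <- sweep(counts, 2, sampleInfo$lib_size, "/") * 1e6
  widx <- mcols(windows)$window
  res <- list()
  for (sp in unique(sampleInfo$species)) {
    for (as in unique(sampleInfo$assay)) {
      js <- which(sampleInfo$species == sp & sampleInfo$assay == as)
      if (!length(js)) next
      perRep <- sapply(js, function(j)
        tapply(rpm[valid, j], widx[valid], mean))
      res[[length(res) + 1L]] <- data.frame(
        window = as.integer(names(tapply(rpm[valid, js[1]], widx[valid],
                                         mean))),
        species = sp, assay = as,
        meanRpm = rowMeans(as.matrix(perRep)))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$species, out$assay, out$window), ]
}
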