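#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' ChainSet: a set of pairwise genome-alignment chains
#'
#' Container for UCSC-style alignment chains between a target and a query
#' genome. Each chain is a block-structured gapped alignment; all coordinate
#' lifting and orthology decisions in the package run over a \code{ChainSet}.
#'
#' Each element of \code{chains} is a list with fields \code{score},
#' \code{tName}, \code{tSize}, \code{tStrand}, \code{tStart}, \code{tEnd},
#' \code{qName}, \code{qSize}, \code{qStrand}, \code{qStart}, \code{qEnd},
#' \code{id} and a \code{blocks} matrix with columns \code{size}, \code{dt},
#' \code{dq} (the last row has \code{dt = dq = 0}). Coordinates follow the
#' chain convention: 0-based half-open, strand-local on the query side.
#'
#' @slot chains list of chain records (see Details).
#' @export
setClass("ChainSet", representation(chains = "list"))

setValidity("ChainSet", function(object) {
  for (ch in object@chains) {
    need <- c("score", "tName", "tSize", "tStart", "tEnd",
              "qName", "qSize", "qStrand", "qStart", "qEnd", "blocks")
    if (!all(need %in% names(ch)))
      return("chain record missing required fields")
    b <- ch$blocks
    if (!is.matrix(b) || ncol(b) != 3L)
      return("blocks must be a 3-column matrix (size, dt, dq)")
    if (any(b[, "size"] <= 0))
      return("chain block sizes must be positive")
    tSpan <- sum(b[, "size"]) + sum(b[, "dt"])
    qSpan <- sum(b[, "size"]) + sum(b[, "dq"])
    if (tSpan != ch$tEnd - ch$tStart)
      return(sprintf("chain %s: blocks span %d on target but header says %d",
                     as.character(ch$id), tSpan, ch$tEnd - ch$tStart))
    if (qSpan != ch$qEnd - ch$qStart)
      return(sprintf("chain %s: blocks span %d on query but header says %d",
                     as.character(ch$id), qSpan, ch$qEnd - ch$qStart))
  }
  TRUE
})

#' @describeIn ChainSet number of chains
#' @param x a ChainSet
#' @export
setMethod("length", "ChainSet", function(x) length(x@chains))

#' Extract the raw chain records
#' @param x a ChainSet
#' @return list of chain records
#' @export
chains <- function(x) {
  stopifnot(is(x, "ChainSet"))
  x@chains
}

setMethod("show", "ChainSet", function(object) {
  n <- length(object@chains)
  cat("ChainSet with", n, "chain(s)\n")
  if (n > 0) {
    tn <- unique(vapply(object@chains, `[[`, character(1), "tName"))
    qn <- unique(vapply(object@chains, `[[`, character(1), "qName"))
    cat("  target seqs:", paste(utils::head(tn, 5), collapse = ", "),
        if (length(tn) > 5) "..." else "", "\n")
    cat("  query seqs: ", paste(utils::head(qn, 5), collapse = ", "),
        if (length(qn) > 5) "..." else "", "\n")
  }
  invisible(object)
})

#' MotifModel: a position weight matrix with exact p-value machinery
#'
#' A pseudocounted position frequency matrix together with its background
#' model, log-odds scores, and the exact null score distribution computed by
#' dynamic programming over discretized scores. Scores are discretized onto an
#' integer grid (\code{binWidth} units); scanning and p-values both use the
#' discretized matrix, so the reported p-value of a hit is the exact tail
#' probability of its score under the background model.
#'
#' @slot name motif identifier.
#' @slot pfm 4 x w frequency matrix (rows A,C,G,T; columns sum to 1).
#' @slot background length-4 base frequencies (sums to 1).
#' @slot logOdds 4 x w log2(pfm/background) matrix.
#' @slot intLogOdds 4 x w integer score matrix (logOdds / binWidth, rounded).
#' @slot binWidth score discretization step.
#' @slot alpha default p-value threshold for calling hits.
#' @slot scoreThreshold minimal integer score whose tail p-value is <= alpha.
#' @slot tailProb numeric vector: tailProb[k] = P(score >= minScore + k - 1).
#' @slot minScore smallest attainable integer score.
#' @export
setClass("MotifModel", representation(
  name = "character", pfm = "matrix", background = "numeric",
  logOdds = "matrix", intLogOdds = "matrix", binWidth = "numeric",
  alpha = "numeric", scoreThreshold = "integer",
  tailProb = "numeric", minScore = "integer"))

setValidity("MotifModel", function(object) {
  w <- ncol(object@pfm)
  if (w < 3) return("motif width must be >= 3")
  if (!isTRUE(all.equal(colSums(object@pfm), rep(1, w),
                        check.attributes = FALSE)))
    return("pfm columns must sum to 1")
  if (!isTRUE(all.equal(sum(object@background), 1)))
    return("background must sum to 1")
  if (any(object@pfm <= 0)) return("pfm must be strictly positive (pseudocounted)")
  TRUE
})

#' @describeIn MotifModel motif width (number of columns)
#' @param x a MotifModel
#' @export
setMethod("ncol", "MotifModel", function(x) ncol(x@pfm))

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel", object@name, "width", ncol(object@pfm),
      sprintf("alpha %g, score threshold %d (of [%d, %d])\n",
              object@alpha, object@scoreThreshold, object@minScore,
              object@minScore + length(object@tailProb) - 1L))
  invisible(object)
})

#' SyntheticTruth: ground-truth ledger of a simulated dataset
#'
#' Records everything the synthetic-data generator planted: per-genome
#' substitution positions, species-specific TE insertions (with motif flags),
#' true peak labels, and true differential-expression labels, so recovery can
#' be measured exactly.
#'
#' @slot substitutions data.frame of planted substitutions (chrom, ancestral
#'   position, per-genome alleles and coordinates).
#' @slot insertions GRanges of planted insertions in carrier-genome
#'   coordinates, with mcols genome, subfamily, motif, tsd.
#' @slot sharedRepeats GRanges of repeats planted in the common ancestor, in
#'   ancestral coordinates, with per-genome motif flags in mcols.
#' @slot peakLabels character vector of true region labels (or empty).
#' @slot degTable data.frame of true DEG status per gene (or empty).
#' @slot params the generator parameter list.
#' @export
setClass("SyntheticTruth", representation(
  substitutions = "data.frame", insertions = "GRanges",
  sharedRepeats = "GRanges", peakLabels = "character",
  degTable = "data.frame", params = "list"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:",
      nrow(object@substitutions), "substitutions;",
      length(object@insertions), "planted insertions;",
      length(object@sharedRepeats), "ancestral repeats;",
      length(object@peakLabels), "labeled regions;",
      nrow(object@degTable), "genes in DEG ledger\n")
  invisible(object)
})

#' @describeIn SyntheticTruth planted insertions as a GRanges
#' @param truth a SyntheticTruth
#' @export
truthInsertions <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  truth@insertions
}

#' @describeIn SyntheticTruth planted substitutions table
#' @export
truthSubstitutions <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  truth@substitutions
}
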