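#' Pairwise p-distance matrix from an alignment
#'
#' For each pair of aligned sequences, the proportion of mismatching
#' columns among columns where neither sequence has a gap.
#'
#' @param aln aligned sequences of equal length: a character vector, a
#'   \code{DNAStringSet}, or a \code{DNAMultipleAlignment}; names become
#'   taxa labels.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(aln) {
  if (is(aln, "DNAMultipleAlignment")) aln <- as(aln, "DNAStringSet")
  if (is(aln, "DNAStringSet")) aln <- as.character(aln)
  if (length(aln) < 2) stop("alignment needs >= 2 sequences")
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must have equal length")
  nms <- if (!is.null(names(aln))) names(aln)
         else paste0("seq", seq_along(aln))
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      D[i, j] <- D[j, i] <-
        if (any(ok)) sum(m[i, ok] != m[j, ok]) / sum(ok) else 0
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair (i, j)
#' minimizing \code{Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)},
#' with branch lengths from the standard NJ formulas. Ties in Q are broken
#' by the lexicographic order of the clusters' smallest taxon labels, so
#' the output is deterministic. Negative branch-length estimates are
#' clamped to zero with a warning.
#'
#' @param D symmetric distance matrix with zero diagonal and taxa as
#'   dimnames (>= 3 taxa).
#' @param taxa optional taxa labels overriding the dimnames.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(D, taxa = NULL) {
  D <- as.matrix(D)
  if (!is.null(taxa)) dimnames(D) <- list(taxa, taxa)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  if (nrow(D) < 3) stop("need >= 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")

  labels <- rownames(D)
  newick <- labels            # growing subtree strings
  repLab <- labels            # smallest leaf label per cluster (tie-break)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(repLab[ij[1]], repLab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(bi),
                      newick[j], fmt(bj))
    mergedRep <- min(repLab[i], repLab[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    newick <- c(newick[keep], merged)
    repLab <- c(repLab[keep], mergedRep)
  }
  # final three-way join: three-point branch lengths
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  ord <- order(repLab)
  parts <- sprintf("%s:%s", newick, fmt(c(b1, b2, b3)))[ord]
  tr <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","),
                                     ");"))
  if (clamped)
    warning("negative NJ branch length(s) clamped to zero")
  attr(tr, "clamped") <- clamped
  tr
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent symbol among A, C, G, T and gap; ties are
#' broken by the fixed order A < C < G < T < gap. Consensus gap columns are
#' removed from the output sequence.
#'
#' @param aln aligned sequences (character vector or \code{DNAStringSet}).
#' @return consensus sequence (character, gaps removed).
#' @export
majorityConsensus <- function(aln) {
  if (is(aln, "DNAStringSet")) aln <- as.character(aln)
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  symbols <- c("A", "C", "G", "T", "-")
  cons <- apply(m, 2, function(col) {
    cnt <- vapply(symbols, function(s) sum(col == s), numeric(1))
    symbols[which.max(cnt)]   # which.max takes the first = fixed tie order
  })
  paste(cons[cons != "-"], collapse = "")
}

#' Presence of the POU5F1-SOX2 dual motif
#'
#' TRUE when a SOX2 hit and a POU5F1 hit occur on the same strand with the
#' SOX2 site upstream (in the strand's reading direction) and a gap of at
#' most \code{maxSpacing} bp between them — the arrangement of the dual
#' motif in LTR5 elements (SOX2 at 681-686, POU5F1 at 692-698, 5-bp
#' spacer).
#'
#' @param seq character or \code{DNAString}.
#' @param pou5f1Pwm,sox2Pwm \linkS4class{MotifModel}s (see
#'   \code{\link{plantedDualMotifPwms}}).
#' @param maxSpacing maximal gap in bp between the SOX2 end and the POU5F1
#'   start (default 10).
#' @param alpha scan threshold (default: each model's own).
#' @return logical.
#' @export
dualMotifPresent <- function(seq, pou5f1Pwm, sox2Pwm, maxSpacing = 10L,
                             alpha = NULL) {
  hp <- scanPwm(seq, pou5f1Pwm, alpha)
  hs <- scanPwm(seq, sox2Pwm, alpha)
  if (nrow(hp) == 0 || nrow(hs) == 0) return(FALSE)
  for (strd in c("+", "-")) {
    ps <- hp[hp$strand == strd, , drop = FALSE]
    ss <- hs[hs$strand == strd, , drop = FALSE]
    if (nrow(ps) == 0 || nrow(ss) == 0) next
    for (a in seq_len(nrow(ss))) {
      gapv <- if (strd == "+") ps$start - ss$end[a] - 1L
              else ss$start[a] - ps$end - 1L
      if (any(gapv >= 0 & gapv <= maxSpacing)) return(TRUE)
    }
  }
  FALSE
}

#' Three-genome motif-orthology trace for LTR5 copies
#'
#' Follows LTR5 copies of genome 1 through a pipeline of filters that
#' mirrors the orthology trace of the dual pluripotency motif: (1) copies
#' at least \code{minLength} bp are lifted to genome 2, reciprocal-validated
#' and required to overlap an LTR5-class annotation there; (2) the dual
#' motif must be present in the genome-1 copy and then also in the lifted
#' genome-2 sequence; (3) the copies surviving step 2 are lifted to genome
#' 3, required to overlap an LTR5 annotation there, and the motif is tested
#' in the genome-3 sequence. Counts at each step are monotonically
#' non-increasing by construction.
#'
#' @param copies1 \code{GRanges} of LTR5 copies in genome 1.
#' @param genome1,genome2,genome3 \code{DNAStringSet}s.
#' @param chain12,chain21,chain13 \linkS4class{ChainSet}s.
#' @param repeats2,repeats3 repeat annotations (\code{GRanges} with
#'   \code{repName}, \code{repClass}) of genomes 2 and 3.
#' @param pou5f1Pwm,sox2Pwm motif models for the dual-motif test.
#' @param minLength minimal copy length (default 500 bp).
#' @param minMatch,maxSpacing,alpha passed through to lifting and motif
#'   scanning.
#' @param ltr5Pattern regular expression identifying LTR5 annotations.
#' @return list with \code{summary} (named counts at each step:
#'   \code{input}, \code{ortholog2}, \code{motif1}, \code{motifBoth},
#'   \code{ortholog3}, \code{motif3}) and \code{perCopy} (data.frame of
#'   per-copy booleans).
#' @export
traceMotifOrthology <- function(copies1, genome1, genome2, genome3,
                                chain12, chain21, chain13,
                                repeats2, repeats3,
                                pou5f1Pwm, sox2Pwm,
                                minLength = 500L, minMatch = 0.95,
                                maxSpacing = 10L, alpha = NULL,
                                ltr5Pattern = "^LTR5") {
  copies1 <- copies1[width(copies1) >= minLength]
  n <- length(copies1)
  getSeq1 <- function(gr, genome) {
    vapply(seq_along(gr), function(i) {
      as.character(Biostrings::subseq(
        genome[[as.character(seqnames(gr))[i]]],
        start(gr)[i], end(gr)[i]))
    }, character(1))
  }
  ltr2 <- repeats2[grepl(ltr5Pattern, mcols(repeats2)$repName) &
                     mcols(repeats2)$repClass == "LTR"]
  ltr3 <- repeats3[grepl(ltr5Pattern, mcols(repeats3)$repName) &
                     mcols(repeats3)$repClass == "LTR"]

  rv <- reciprocalValidate(copies1, chain12, chain21, minMatch)
  ortho2 <- rv$valid
  img2 <- rep(FALSE, n)
  img2gr <- GRanges(ifelse(is.na(rv$chrom), "NA_", rv$chrom),
                    IRanges(ifelse(is.na(rv$start), 1L, rv$start),
                            ifelse(is.na(rv$end), 1L, rv$end)))
  img2[ortho2] <- GenomicRanges::countOverlaps(img2gr[ortho2], ltr2,
                                               ignore.strand = TRUE) > 0
  step1 <- ortho2 & img2

  motif1 <- rep(FALSE, n); motif2 <- rep(FALSE, n)
  if (any(step1)) {
    s1 <- getSeq1(copies1[step1], genome1)
    motif1[step1] <- vapply(s1, dualMotifPresent, logical(1),
                            pou5f1Pwm = pou5f1Pwm, sox2Pwm = sox2Pwm,
                            maxSpacing = maxSpacing, alpha = alpha,
                            USE.NAMES = FALSE)
  }
  s2need <- step1 & motif1
  if (any(s2need)) {
    s2 <- getSeq1(img2gr[s2need], genome2)
    motif2[s2need] <- vapply(s2, dualMotifPresent, logical(1),
                             pou5f1Pwm = pou5f1Pwm, sox2Pwm = sox2Pwm,
                             maxSpacing = maxSpacing, alpha = alpha,
                             USE.NAMES = FALSE)
  }
  step2 <- s2need & motif2

  ortho3 <- rep(FALSE, n); motif3 <- rep(FALSE, n)
  if (any(step2)) {
    lf3 <- liftIntervals(copies1[step2], chain13, minMatch)
    ok <- lf3$status == "mapped"
    img3 <- GRanges(ifelse(is.na(lf3$chrom), "NA_", lf3$chrom),
                    IRanges(ifelse(is.na(lf3$start), 1L, lf3$start),
                            ifelse(is.na(lf3$end), 1L, lf3$end)))
    hasLtr3 <- rep(FALSE, length(lf3$status))
    hasLtr3[ok] <- GenomicRanges::countOverlaps(img3[ok], ltr3,
                                                ignore.strand = TRUE) > 0
    ortho3[step2] <- ok & hasLtr3
    idx3 <- which(step2)[ok & hasLtr3]
    if (length(idx3)) {
      s3 <- getSeq1(img3[ok & hasLtr3], genome3)
      motif3[idx3] <- vapply(s3, dualMotifPresent, logical(1),
                             pou5f1Pwm = pou5f1Pwm, sox2Pwm = sox2Pwm,
                             maxSpacing = maxSpacing, alpha = alpha,
                             USE.NAMES = FALSE)
    }
  }
  motif3 <- motif3 & ortho3

  perCopy <- data.frame(chrom = as.character(seqnames(copies1)),
                        start = start(copies1), end = end(copies1),
                        ortholog2 = step1, motif1 = step1 & motif1,
                        motifBoth = step2, ortholog3 = ortho3,
                        motif3 = motif3)
  summary <- c(input = n, ortholog2 = sum(step1),
               motif1 = sum(step1 & motif1), motifBoth = sum(step2),
               ortholog3 = sum(ortho3), motif3 = sum(motif3))
  stopifnot(all(diff(summary) <= 0))   # each filter can only shrink the set
  list(summary = summary, perCopy = perCopy)
}
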