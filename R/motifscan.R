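#' Build a motif model with exact p-value machinery
#'
#' Normalizes a position frequency matrix (counts or frequencies) with a
#' pseudocount, forms the log2 odds matrix against the background, and
#' computes the exact null distribution of scores by dynamic programming.
#' Scores are discretized to an integer grid whose step is 1/1000 of the
#' total score range; the same discretized matrix is used for scanning, so
#' p-values are exact tail probabilities for the scores the scanner assigns
#' (no sampling, no approximation beyond the shared grid).
#'
#' @param name motif identifier.
#' @param pfm 4 x w numeric matrix, rows A,C,G,T; counts or frequencies.
#' @param background length-4 base frequencies (A,C,G,T), default uniform.
#' @param pseudocount added to every cell before normalization (default 0.1).
#' @param alpha hit-calling p-value threshold (default 1e-4).
#' @param nbins number of discretization steps across the score range.
#' @return a \linkS4class{MotifModel}.
#' @export
motifModel <- function(name, pfm, background = rep(0.25, 4),
                       pseudocount = 0.1, alpha = 1e-4, nbins = 1000L) {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4)
  if (ncol(pfm) < 3) stop("motif width must be >= 3")
  if (any(pfm < 0)) stop("PFM entries must be non-negative")
  if (any(colSums(pfm) == 0)) stop("degenerate PFM: column of all zeros")
  rownames(pfm) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  freq <- sweep(pfm + pseudocount, 2, colSums(pfm + pseudocount), "/")
  lo <- log2(sweep(freq, 1, background, "/"))
  rng <- max(lo) - min(lo)
  binWidth <- if (rng > 0) rng / nbins else 1
  ilo <- round(lo / binWidth)
  storage.mode(ilo) <- "integer"
  dist <- .scoreNullDist(ilo, background)
  tail <- rev(cumsum(rev(dist$prob)))
  thr <- which(tail <= alpha)
  scoreThreshold <- if (length(thr)) dist$minScore + thr[1] - 1L
                    else dist$minScore + length(tail)  # unattainable
  new("MotifModel", name = name, pfm = freq, background = background,
      logOdds = lo, intLogOdds = ilo, binWidth = binWidth,
      alpha = alpha, scoreThreshold = as.integer(scoreThreshold),
      tailProb = tail, minScore = dist$minScore)
}

# exact null distribution of total integer scores under the background,
# by position-wise convolution
.scoreNullDist <- function(ilo, background) {
  w <- ncol(ilo)
  minS <- sum(apply(ilo, 2, min))
  maxS <- sum(apply(ilo, 2, max))
  span <- maxS - minS + 1L
  prob <- numeric(span)
  # offsets relative to running minimum
  cur <- 1
  curMin <- 0L
  for (j in seq_len(w)) {
    colMin <- min(ilo[, j])
    newLen <- length(cur) + (max(ilo[, j]) - colMin)
    nxt <- numeric(newLen)
    for (b in 1:4) {
      off <- ilo[b, j] - colMin
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * background[b]
    }
    cur <- nxt
    curMin <- curMin + colMin
  }
  prob[seq_along(cur)] <- cur
  list(minScore = as.integer(minS), prob = prob)
}

#' Exact p-value of a motif score
#'
#' Tail probability \code{P(score >= s)} of an integer grid score under the
#' model's background null.
#'
#' @param model a \linkS4class{MotifModel}.
#' @param intScore integer score(s) on the model's grid.
#' @return numeric p-value(s).
#' @export
motifPvalue <- function(model, intScore) {
  k <- intScore - model@minScore + 1L
  p <- rep(0, length(intScore))
  p[k <= 0L] <- 1
  inr <- k >= 1L & k <= length(model@tailProb)
  p[inr] <- model@tailProb[k[inr]]
  p
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encodeSeq <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    seq <- as.character(seq)
  .BASE_CODE[strsplit(toupper(seq), "")[[1]]]
}

# integer window scores along an encoded sequence (NA where window hits N)
.windowScores <- function(code, ilo) {
  w <- ncol(ilo)
  L <- length(code)
  if (L < w) return(integer(0))
  nWin <- L - w + 1L
  s <- integer(nWin)
  bad <- logical(nWin)
  for (j in seq_len(w)) {
    cj <- code[j:(j + nWin - 1L)]
    nab <- is.na(cj)
    bad <- bad | nab
    cj[nab] <- 1L
    s <- s + ilo[cbind(cj, j)]
  }
  s[bad] <- NA_integer_
  s
}

#' Scan a sequence with a motif model
#'
#' Scores every window on both strands with the discretized log-odds matrix
#' and reports windows whose exact p-value is at or below \code{alpha}.
#' Windows containing N are skipped.
#'
#' @param seq character string or \code{DNAString} over A,C,G,T,N.
#' @param model a \linkS4class{MotifModel}.
#' @param alpha p-value threshold; defaults to the model's own.
#' @return data.frame with columns \code{start} (1-based), \code{end},
#'   \code{strand}, \code{score} (log2 odds on the discretized grid) and
#'   \code{p}; zero rows when the sequence is shorter than the motif.
#' @export
scanPwm <- function(seq, model, alpha = NULL) {
  if (is.null(alpha)) alpha <- model@alpha
  thr <- if (alpha == model@alpha) model@scoreThreshold else {
    k <- which(model@tailProb <= alpha)
    if (length(k)) model@minScore + k[1] - 1L
    else model@minScore + length(model@tailProb)
  }
  code <- .encodeSeq(seq)
  w <- ncol(model@intLogOdds)
  L <- length(code)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0))
  if (L < w) return(empty)
  res <- list()
  fwd <- .windowScores(code, model@intLogOdds)
  hit <- which(!is.na(fwd) & fwd >= thr)
  if (length(hit))
    res[[1]] <- data.frame(start = hit, end = hit + w - 1L, strand = "+",
                           score = fwd[hit] * model@binWidth,
                           p = motifPvalue(model, fwd[hit]))
  rcCode <- rev(5L - code)
  rc <- .windowScores(rcCode, model@intLogOdds)
  hit <- which(!is.na(rc) & rc >= thr)
  if (length(hit)) {
    st <- L - (hit + w - 1L) + 1L   # forward-strand start of the rc window
    res[[length(res) + 1L]] <-
      data.frame(start = st, end = st + w - 1L, strand = "-",
                 score = rc[hit] * model@binWidth,
                 p = motifPvalue(model, rc[hit]))
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Count non-overlapping motif hits in a sequence
#'
#' Scans with \code{\link{scanPwm}} and resolves overlapping hits on the same
#' strand greedily from left to right, so one planted site cannot be counted
#' twice.
#'
#' @inheritParams scanPwm
#' @return integer hit count.
#' @export
motifHitCount <- function(seq, model, alpha = NULL) {
  h <- scanPwm(seq, model, alpha)
  if (nrow(h) == 0) return(0L)
  n <- 0L
  for (s in c("+", "-")) {
    hs <- h[h$strand == s, , drop = FALSE]
    if (nrow(hs) == 0) next
    hs <- hs[order(hs$start), , drop = FALSE]
    lastEnd <- -1L
    for (i in seq_len(nrow(hs))) {
      if (hs$start[i] > lastEnd) {
        n <- n + 1L
        lastEnd <- hs$end[i]
      }
    }
  }
  n
}

#' Motif gain/loss counts over species-specific regions
#'
#' For each motif, counts regions where the sequence of the species carrying
#' the modification has strictly more non-overlapping hits than the other
#' species' orthologous sequence (a gain) or strictly fewer (a loss); ties
#' count as neither. A chi-square test against an equal split of gains and
#' losses is attached per motif.
#'
#' @param seqModified character vector: region sequences in the species
#'   carrying the modification.
#' @param seqOther character vector: orthologous sequences in the other
#'   species.
#' @param models list of \linkS4class{MotifModel}.
#' @param alpha scan p-value threshold (defaults to each model's own).
#' @return data.frame with columns \code{motif}, \code{nGain}, \code{nLoss},
#'   \code{chi2}, \code{p}. Motifs with no gain and no loss get NA statistics
#'   (skipped from testing, with a warning).
#' @export
countGainLoss <- function(seqModified, seqOther, models, alpha = NULL) {
  stopifnot(length(seqModified) == length(seqOther))
  out <- lapply(models, function(m) {
    nm <- vapply(seqModified, motifHitCount, integer(1), model = m,
                 alpha = alpha, USE.NAMES = FALSE)
    no <- vapply(seqOther, motifHitCount, integer(1), model = m,
                 alpha = alpha, USE.NAMES = FALSE)
    data.frame(motif = m@name, nGain = sum(nm > no), nLoss = sum(nm < no))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  stat <- mapply(function(g, l) {
    if (g + l == 0) return(c(NA_real_, NA_real_))
    unlist(chi2GainLoss(g, l))
  }, out$nGain, out$nLoss)
  if (any(is.na(stat[1, ])))
    warning("motif(s) with no gain and no loss events skipped from testing: ",
            paste(out$motif[is.na(stat[1, ])], collapse = ", "))
  out$chi2 <- stat[1, ]
  out$p <- stat[2, ]
  out
}

#' Chi-square test of gain/loss asymmetry
#'
#' One-degree-of-freedom goodness-of-fit of the observed (gain, loss) counts
#' against an expected 50:50 split.
#'
#' @param nGain,nLoss non-negative event counts; their sum must be >= 1.
#' @return list with \code{chi2} and \code{p}.
#' @export
chi2GainLoss <- function(nGain, nLoss) {
  stopifnot(nGain >= 0, nLoss >= 0)
  if (nGain + nLoss < 1)
    stop("chi-square undefined for zero gain and loss counts")
  m <- (nGain + nLoss) / 2
  chi2 <- (nGain - m)^2 / m + (nLoss - m)^2 / m
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
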