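#' Read a UCSC chain file
#'
#' Parses block-structured pairwise alignment chains. Header lines carry
#' \code{chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id}; each following line gives an aligned block size and the
#' gaps (\code{dt}, \code{dq}) to the next block, the last line a bare size.
#' Block arithmetic is checked against the header spans; an inconsistent
#' chain is a parse error.
#'
#' @param path path to a chain file.
#' @return a \linkS4class{ChainSet}.
#' @export
readChain <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "" || startsWith(lines[i], "#")) { i <- i + 1L; next }
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12)
      stop(sprintf("line %d: expected chain header, got '%s'", i, lines[i]))
    hdr <- list(score = as.numeric(f[2]),
                tName = f[3], tSize = as.integer(f[4]), tStrand = f[5],
                tStart = as.integer(f[6]), tEnd = as.integer(f[7]),
                qName = f[8], qSize = as.integer(f[9]), qStrand = f[10],
                qStart = as.integer(f[11]), qEnd = as.integer(f[12]),
                id = if (length(f) >= 13) f[13] else NA_character_)
    if (hdr$tStrand != "+")
      stop(sprintf("line %d: target strand must be '+'", i))
    if (!hdr$qStrand %in% c("+", "-"))
      stop(sprintf("line %d: bad query strand '%s'", i, hdr$qStrand))
    i <- i + 1L
    sizes <- integer(0); dts <- integer(0); dqs <- integer(0)
    done <- FALSE
    while (i <= n && lines[i] != "") {
      b <- suppressWarnings(as.integer(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(b)) stop(sprintf("line %d: malformed block line", i))
      if (length(b) == 3L) {
        sizes <- c(sizes, b[1]); dts <- c(dts, b[2]); dqs <- c(dqs, b[3])
      } else if (length(b) == 1L) {
        sizes <- c(sizes, b[1]); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        done <- TRUE
        i <- i + 1L
        break
      } else stop(sprintf("line %d: block line must have 1 or 3 fields", i))
      i <- i + 1L
    }
    if (!done) stop(sprintf("chain '%s' truncated: no final bare block size",
                            hdr$tName))
    hdr$blocks <- cbind(size = sizes, dt = dts, dq = dqs)
    recs[[length(recs) + 1L]] <- hdr
  }
  new("ChainSet", chains = recs)
}

#' Write a ChainSet to a UCSC chain file
#' @param x a \linkS4class{ChainSet}.
#' @param path output path.
#' @export
writeChain <- function(x, path) {
  stopifnot(is(x, "ChainSet"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in x@chains) {
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE),
                       ch$tName, ch$tSize, ch$tStart, ch$tEnd,
                       ch$qName, ch$qSize, ch$qStrand, ch$qStart, ch$qEnd,
                       if (is.na(ch$id)) "1" else as.character(ch$id)), con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1)
      writeLines(sprintf("%d\t%d\t%d",
                         b[-nb, "size"], b[-nb, "dt"], b[-nb, "dq"]), con)
    writeLines(c(sprintf("%d", b[nb, "size"]), ""), con)
  }
  invisible(path)
}

# target-side block starts (0-based) of a chain record
.tBlockStarts <- function(ch) {
  b <- ch$blocks
  ch$tStart + cumsum(c(0L, (b[, "size"] + b[, "dt"])[-nrow(b)]))
}

# query-side block starts in strand-local chain coordinates
.qBlockStarts <- function(ch) {
  b <- ch$blocks
  ch$qStart + cumsum(c(0L, (b[, "size"] + b[, "dq"])[-nrow(b)]))
}

# map target positions (0-based, within aligned blocks) to plus-strand query
# positions; returns NA for unaligned positions
.mapPositions <- function(ch, pos) {
  tbs <- .tBlockStarts(ch)
  qbs <- .qBlockStarts(ch)
  sz <- ch$blocks[, "size"]
  idx <- findInterval(pos, tbs)
  ok <- idx >= 1L & pos < tbs[pmax(idx, 1L)] + sz[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(pos))
  qLocal <- qbs[idx[ok]] + (pos[ok] - tbs[idx[ok]])
  out[ok] <- if (identical(ch$qStrand, "-")) ch$qSize - 1L - qLocal else qLocal
  out
}

# bases of [s,e) falling in aligned blocks of one chain
.mappedBases <- function(ch, s, e) {
  tbs <- .tBlockStarts(ch)
  sz <- ch$blocks[, "size"]
  sum(pmax(0L, pmin(e, tbs + sz) - pmax(s, tbs)))
}

#' Lift intervals through alignment chains
#'
#' Maps each interval from the target genome of the chains to the query
#' genome. An interval is \code{mapped} when at least \code{minMatch} of its
#' bases fall in aligned blocks of exactly one chain; bases falling in
#' target-side gaps are treated as deleted in the query. If two or more
#' distinct chains each cover \code{minMatch} of the bases the interval is
#' \code{duplicated}. Intervals with some but too few aligned bases are
#' \code{partial}; intervals with none (or on a sequence absent from every
#' chain) are \code{deleted}. The mapped interval spans the first to the last
#' mapped base; intervals lifted through minus-strand chains are returned as
#' plus-strand coordinates with the strand flag flipped.
#'
#' @param gr a \code{GRanges} of intervals on the chains' target genome.
#' @param chainSet a \linkS4class{ChainSet}.
#' @param minMatch minimal fraction of bases that must map (default 0.95,
#'   the conventional liftOver setting).
#' @return a \code{DataFrame} with columns \code{status} (mapped, deleted,
#'   partial, duplicated), \code{chrom}, \code{start}, \code{end} (1-based
#'   closed, the GRanges convention), \code{strand} (NA unless mapped) and
#'   \code{matchFraction}.
#' @export
liftIntervals <- function(gr, chainSet, minMatch = 0.95) {
  stopifnot(is(chainSet, "ChainSet"), minMatch > 0, minMatch <= 1)
  chs <- chainSet@chains
  byT <- split(seq_along(chs),
               vapply(chs, `[[`, character(1), "tName"))
  n <- length(gr)
  status <- rep("deleted", n)
  chrom <- rep(NA_character_, n); s0 <- rep(NA_integer_, n)
  e0 <- rep(NA_integer_, n); str <- rep(NA_character_, n)
  mf <- rep(0, n)
  grChrom <- as.character(seqnames(gr))
  grStart <- start(gr) - 1L   # to 0-based
  grEnd <- end(gr)
  grStrand <- as.character(strand(gr))
  for (i in seq_len(n)) {
    cand <- byT[[grChrom[i]]]
    if (is.null(cand)) next
    wlen <- grEnd[i] - grStart[i]
    mapped <- vapply(cand, function(k)
      .mappedBases(chs[[k]], grStart[i], grEnd[i]), numeric(1))
    fr <- mapped / wlen
    good <- which(fr >= minMatch)
    mf[i] <- max(fr)
    if (length(good) >= 2L) { status[i] <- "duplicated"; next }
    if (length(good) == 0L) {
      status[i] <- if (max(mapped) > 0) "partial" else "deleted"
      next
    }
    ch <- chs[[cand[good]]]
    pos <- grStart[i]:(grEnd[i] - 1L)
    q <- .mapPositions(ch, pos)
    q <- q[!is.na(q)]
    status[i] <- "mapped"
    chrom[i] <- ch$qName
    s0[i] <- min(q) + 1L; e0[i] <- max(q) + 1L
    flip <- identical(ch$qStrand, "-")
    str[i] <- if (grStrand[i] == "*") {
      if (flip) "-" else "+"
    } else if (flip) c(`+` = "-", `-` = "+")[[grStrand[i]]] else grStrand[i]
  }
  DataFrame(status = status, chrom = chrom, start = s0, end = e0,
            strand = str, matchFraction = mf)
}

#' Reciprocal one-to-one orthology validation
#'
#' Implements the forward-then-back lifting protocol used to restrict an
#' analysis to regions with validated 1-to-1 orthology: each interval is
#' lifted to the other genome, regions deleted or duplicated there are
#' rejected, and the surviving images are lifted back. An interval is
#' \code{valid} only when the back-lifted interval coincides with the
#' original within \code{slack} bp at each end (default 0: exact identity).
#'
#' @param gr a \code{GRanges} on genome A.
#' @param chainAB chains lifting A to B.
#' @param chainBA chains lifting B back to A.
#' @param minMatch minimal mapped fraction for each lift.
#' @param slack maximal per-endpoint displacement (bp) tolerated on return.
#' @return \code{DataFrame} with \code{valid} (logical), \code{reason}
#'   (\code{"ok"}, \code{"forward_deleted"}, \code{"forward_partial"},
#'   \code{"forward_duplicated"}, \code{"back_deleted"},
#'   \code{"back_partial"}, \code{"back_duplicated"}, \code{"back_mismatch"})
#'   and the forward image columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
reciprocalValidate <- function(gr, chainAB, chainBA, minMatch = 0.95,
                               slack = 0L) {
  fwd <- liftIntervals(gr, chainAB, minMatch)
  n <- length(gr)
  valid <- rep(FALSE, n)
  reason <- ifelse(fwd$status == "mapped", "ok",
                   paste0("forward_", fwd$status))
  isMapped <- fwd$status == "mapped"
  if (any(isMapped)) {
    img <- GRanges(fwd$chrom[isMapped],
                   IRanges(fwd$start[isMapped], fwd$end[isMapped]))
    back <- liftIntervals(img, chainBA, minMatch)
    origChrom <- as.character(seqnames(gr))[isMapped]
    origStart <- start(gr)[isMapped]
    origEnd <- end(gr)[isMapped]
    ok <- back$status == "mapped" &
      !is.na(back$chrom) & back$chrom == origChrom &
      abs(back$start - origStart) <= slack &
      abs(back$end - origEnd) <= slack
    sub <- reason[isMapped]
    sub[back$status != "mapped"] <- paste0("back_",
                                           back$status[back$status != "mapped"])
    sub[back$status == "mapped" & !ok] <- "back_mismatch"
    reason[isMapped] <- sub
    valid[isMapped] <- ok
  }
  DataFrame(valid = valid, reason = reason, chrom = fwd$chrom,
            start = fwd$start, end = fwd$end, strand = fwd$strand)
}
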