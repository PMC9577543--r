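suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# ---- brute-force per-base chain map -----------------------------------------
# walks every block of every chain base by base and returns, per chain, a
# dictionary target position (0-based) -> plus-strand query position
bruteChainMaps <- function(chainSet) {
  lapply(chains(chainSet), function(ch) {
    b <- ch$blocks
    tpos <- ch$tStart; qpos <- ch$qStart
    tp <- integer(0); qp <- integer(0)
    for (k in seq_len(nrow(b))) {
      idx <- seq_len(b[k, "size"]) - 1L
      tp <- c(tp, tpos + idx)
      qLocal <- qpos + idx
      qp <- c(qp, if (identical(ch$qStrand, "-")) ch$qSize - 1L - qLocal
                  else qLocal)
      tpos <- tpos + b[k, "size"] + b[k, "dt"]
      qpos <- qpos + b[k, "size"] + b[k, "dq"]
    }
    list(tName = ch$tName, qName = ch$qName, qStrand = ch$qStrand,
         map = stats::setNames(qp, tp))
  })
}

# classify one interval using the per-base dictionaries (the oracle applies
# the same stated rules but via exhaustive base lookup, not block arithmetic)
bruteLiftOne <- function(chrom, start1, end1, maps, minMatch) {
  pos <- (start1 - 1L):(end1 - 1L)
  wlen <- length(pos)
  hits <- lapply(maps, function(m) {
    if (m$tName != chrom) return(integer(0))
    q <- m$map[as.character(pos)]
    q[!is.na(q)]
  })
  fr <- vapply(hits, length, numeric(1)) / wlen
  good <- which(fr >= minMatch)
  if (length(good) >= 2) return(list(status = "duplicated"))
  if (length(good) == 0) {
    return(list(status = if (max(fr) > 0) "partial" else "deleted"))
  }
  q <- hits[[good]]
  list(status = "mapped", chrom = maps[[good]]$qName,
       start = min(q) + 1L, end = max(q) + 1L,
       strand = if (maps[[good]]$qStrand == "-") "-" else "+",
       matchFraction = fr[good])
}

# random multi-block chain sets on a 10-kb target
randomChainSet <- function(seed, nChains = 3, tNames = c("cA", "cB")) {
  set.seed(seed)
  recs <- lapply(seq_len(nChains), function(i) {
    nb <- sample(1:6, 1)
    sizes <- sample(20:300, nb, replace = TRUE)
    dts <- c(sample(0:100, nb - 1, replace = TRUE), 0L)
    dqs <- c(sample(0:100, nb - 1, replace = TRUE), 0L)
    tSpan <- sum(sizes) + sum(dts)
    qSpan <- sum(sizes) + sum(dqs)
    tStart <- sample(0:(10000 - tSpan), 1)
    qSize <- qSpan + sample(0:2000, 1)
    qStart <- sample(0:(qSize - qSpan), 1)
    list(score = 100, tName = sample(tNames, 1), tSize = 10000L,
         tStrand = "+", tStart = tStart, tEnd = tStart + tSpan,
         qName = paste0("q", i), qSize = qSize,
         qStrand = sample(c("+", "-"), 1),
         qStart = qStart, qEnd = qStart + qSpan,
         id = as.character(i),
         blocks = cbind(size = sizes, dt = dts, dq = dqs))
  })
  new("ChainSet", chains = recs)
}

# ---- brute-force BH step-up -------------------------------------------------
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# ---- brute-force global affine alignment score (Gotoh) ----------------------
bruteAffineScore <- function(a, b, match = 1, mismatch = -1,
                             open = 2, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- brute-force interval intersection via base sets ------------------------
bruteIntersectBp <- function(grA, grB) {
  basesA <- unlist(lapply(seq_along(grA), function(i)
    paste0(seqnames(grA)[i], ":", start(grA)[i]:end(grA)[i])))
  basesB <- unlist(lapply(seq_along(grB), function(i)
    paste0(seqnames(grB)[i], ":", start(grB)[i]:end(grB)[i])))
  sort(intersect(basesA, basesB))
}

grToBaseSet <- function(gr) {
  if (length(gr) == 0) return(character(0))
  sort(unlist(lapply(seq_along(gr), function(i)
    paste0(seqnames(gr)[i], ":", start(gr)[i]:end(gr)[i]))))
}

# ---- least-squares branch lengths on a fixed topology -----------------------
# splits: for each internal edge, which tips fall on the child side
treeDesignMatrix <- function(tree) {
  nt <- length(tree$tip.label)
  pairs <- t(combn(nt, 2))
  X <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- if (child <= nt) child
             else phangorn::Descendants(tree, child, "tips")[[1]]
    inA <- pairs[, 1] %in% below
    inB <- pairs[, 2] %in% below
    X[xor(inA, inB), e] <- 1
  }
  list(pairs = pairs, X = X)
}

lsFitTopology <- function(tree, D) {
  dm <- treeDesignMatrix(tree)
  d <- D[cbind(dm$pairs[, 1], dm$pairs[, 2])]
  fit <- stats::lm.fit(dm$X, d)
  rss <- sum(fit$residuals^2)
  list(rss = rss, lengths = fit$coefficients)
}

# exhaustive topology search: returns the best topology and its RSS
bestTopologyLS <- function(D) {
  taxa <- rownames(D)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  fits <- lapply(trees, function(tr) {
    tr$tip.label -> tl
    Dp <- D[tl, tl]
    lsFitTopology(tr, Dp)
  })
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- which.min(rss)
  list(tree = trees[[best]], rss = rss[best], all_rss = rss)
}

# random additive distance matrix from a random tree (ape), lengths in
# [0.1, 1] so no degenerate zero branches
randomAdditiveMatrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# ---- brute-force PWM scanner ------------------------------------------------
# scores every window on both strands with the model's discretized matrix and
# thresholds on the exact p-value; structurally independent of scanPwm's
# sliding-column accumulation
bruteScan <- function(seq, model, alpha = model@alpha) {
  w <- ncol(model@pfm)
  ilo <- model@intLogOdds
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  L <- length(code)
  out <- list()
  if (L < w) return(data.frame(start = integer(0), strand = character(0)))
  rcCode <- rev(5L - code)
  for (st in c("+", "-")) {
    cc <- if (st == "+") code else rcCode
    for (i in 1:(L - w + 1)) {
      b <- cc[i:(i + w - 1)]
      if (anyNA(b)) next
      sc <- sum(ilo[cbind(b, 1:w)])
      if (motifPvalue(model, sc) <= alpha) {
        start <- if (st == "+") i else L - (i + w - 1) + 1L
        out[[length(out) + 1L]] <- data.frame(start = start, strand = st)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), strand = character(0))
}

# target-frame footprint of every chain gap (dt spans and dq breakpoints),
# for excluding variant regions when sampling "clean" intervals
chainGapRegionsA <- function(chainSet, pad = 0L) {
  rows <- list()
  for (ch in chains(chainSet)) {
    b <- ch$blocks
    tpos <- ch$tStart
    for (k in seq_len(nrow(b))) {
      tpos <- tpos + b[k, "size"]
      if (b[k, "dt"] > 0 || b[k, "dq"] > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = ch$tName, start = tpos + 1L - pad,
                     end = tpos + max(b[k, "dt"], 1L) + pad)
      tpos <- tpos + b[k, "dt"]
    }
  }
  if (!length(rows)) return(GRanges())
  d <- do.call(rbind, rows)
  GRanges(d$chrom, IRanges(pmax(d$start, 1L), d$end))
}

# ---- misc -------------------------------------------------------------------
randSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = "")

revComp <- function(s)
  paste(rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(s, "")[[1]]]),
        collapse = "")
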