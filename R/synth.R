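#' @importFrom Biostrings DNAStringSet
NULL

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.randChars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# complement-like scramble that reliably destroys a motif footprint
.scrambleChars <- function(x) chartr("ACGT", "CAGT", chartr("ACGT", "CATG", x))

#' Consensus sequences of the built-in TE library
#'
#' Three synthetic element families emulating the repeat classes followed in
#' the analysis: a 300-bp SINE (Alu-like), a 1,200-bp LINE (L1-like), and a
#' 968-bp LTR (LTR5-like) that carries a dual pluripotency-factor motif: a
#' SOX2 site at positions 681-686 and a POU5F1 site at positions 692-698
#' (1-based), separated by a 5-bp spacer. Consensi are generated once from a
#' fixed internal seed, so the library is a package constant.
#'
#' @return list with elements \code{name}, \code{class}, \code{consensus}
#'   (character), \code{motifStart}/\code{motifEnd} (dual-motif footprint,
#'   NA for motif-less families).
#' @export
defaultTeLibrary <- function() {
  .withSeed(104729L, {
    sox <- "CATTGT"; spacer <- paste(.randChars(5), collapse = "")
    pou <- "ATGCAAA"
    ltr <- .randChars(968)
    ltr[681:698] <- strsplit(paste0(sox, spacer, pou), "")[[1]]
    list(name = c("AluY", "L1", "LTR5_Hs"),
         class = c("SINE", "LINE", "LTR"),
         consensus = c(paste(.randChars(300), collapse = ""),
                       paste(.randChars(1200), collapse = ""),
                       paste(ltr, collapse = "")),
         motifStart = c(NA, NA, 681L),
         motifEnd = c(NA, NA, 698L))
  })
}

#' PWMs of the planted SOX2 and POU5F1 motifs
#'
#' Strong position frequency matrices matching the dual motif planted in the
#' LTR5-like consensus of \code{\link{defaultTeLibrary}}; used to recover
#' planted motif flags and for the dual-motif orthology trace.
#'
#' @param alpha scan threshold (default 1e-3, suited to these short motifs).
#' @return list with \code{sox2} and \code{pou5f1} \linkS4class{MotifModel}s.
#' @export
plantedDualMotifPwms <- function(alpha = 1e-3) {
  mk <- function(name, consensus) {
    ch <- strsplit(consensus, "")[[1]]
    m <- matrix(5, 4, length(ch), dimnames = list(c("A", "C", "G", "T")))
    m[cbind(match(ch, rownames(m)), seq_along(ch))] <- 85
    motifModel(name, m, alpha = alpha)
  }
  list(sox2 = mk("SOX2", "CATTGT"), pou5f1 = mk("POU5F1", "ATGCAAA"))
}

#' Random motif models
#'
#' Draws position frequency matrices from independent symmetric Dirichlet
#' columns; handy as decoy motifs for calibration checks.
#'
#' @param n number of motifs.
#' @param widths motif widths (recycled).
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration (small = sharper columns).
#' @param alpha scan threshold passed to \code{\link{motifModel}}.
#' @return named list of \linkS4class{MotifModel}.
#' @export
randomMotifModels <- function(n, widths = 6, seed = 1, concentration = 0.5,
                              alpha = 1e-4) {
  widths <- rep_len(widths, n)
  .withSeed(seed, {
    out <- lapply(seq_len(n), function(i) {
      g <- matrix(stats::rgamma(4 * widths[i], shape = concentration),
                  nrow = 4)
      pfm <- sweep(g, 2, colSums(g), "/") * 100
      motifModel(sprintf("random_%02d", i), pfm, alpha = alpha)
    })
    names(out) <- vapply(out, function(m) m@name, character(1))
    out
  })
}

#' Simulation parameters
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults define the study conditions the generators emulate: a genome
#' pair at ~1.2% substitution divergence (the human-chimpanzee regime),
#' species-specific insertions of the three-family TE library, two
#' replicates per species, an 8-fold ChIP enrichment effect for modified
#' regions, and replicate expression noise placing intraspecies log-scale
#' correlations near 0.97.
#'
#' @param seed master RNG seed; fixes every random draw of every generator
#'   (each generator uses a fixed small offset from it).
#' @param nChroms,chromLength number and ancestral length (bp) of
#'   chromosomes.
#' @param substitutionRate per-bp substitution probability between the two
#'   genomes (default 0.012).
#' @param outgroupRate per-bp substitution rate of the third (outgroup)
#'   genome (default 0.02).
#' @param insertionsPerChrom named integer vector: species-specific
#'   insertions planted per chromosome per species, named by TE family.
#' @param sharedLtr5PerChrom LTR5-like copies planted in the common ancestor
#'   (shared by all genomes) per chromosome.
#' @param motifProb probability that a planted/ancestral LTR5 copy carries
#'   an intact dual motif in a given genome (default 0.97).
#' @param tsdLength target-site duplication length for planted insertions
#'   (default 0: exact breakpoints).
#' @param minInsertionSpacing,edgeMargin placement constraints (bp).
#' @param nPeaks,peakLength,fracSpecific,fracNone,enrichmentEffect,
#'   nbDispersion,inputMean,libSize,nReplicates ChIP count model: number of
#'   regions, their width, fraction species-specific (split evenly between
#'   the species), fraction with no reads at all, mean ChIP/input ratio of
#'   modified regions, negative-binomial dispersion, expected input reads
#'   per region, library size, replicates per species.
#' @param nGenes,fracDegs,degFoldChange,exprBaseMean,exprBaseSd,exprNoiseSd
#'   expression model: gene count, planted DEG fraction and fold change,
#'   log2 baseline mean/sd across genes, replicate noise sd (log2).
#' @param nMotifRegions,motifRegionLength,motifPlantProb motif gain/loss
#'   region-pair model.
#' @return validated parameter list (class \code{orthoepi_params}).
#' @export
simulationParams <- function(seed = 1L,
                             nChroms = 2L, chromLength = 200000L,
                             substitutionRate = 0.012, outgroupRate = 0.02,
                             insertionsPerChrom = c(AluY = 4L, L1 = 2L,
                                                    LTR5_Hs = 3L),
                             sharedLtr5PerChrom = 0L,
                             motifProb = 0.97, tsdLength = 0L,
                             minInsertionSpacing = 4500L, edgeMargin = 5000L,
                             nPeaks = 2000L, peakLength = 500L,
                             fracSpecific = 0.10, fracNone = 0.01,
                             enrichmentEffect = 8, nbDispersion = 0.02,
                             inputMean = 100, libSize = 1e7,
                             nReplicates = 2L,
                             nGenes = 5000L, fracDegs = 0.02,
                             degFoldChange = 4, exprBaseMean = 4,
                             exprBaseSd = 2, exprNoiseSd = 0.35,
                             nMotifRegions = 60L, motifRegionLength = 400L,
                             motifPlantProb = 0.5) {
  p <- as.list(environment())
  rates <- c(substitutionRate = substitutionRate, outgroupRate = outgroupRate,
             motifProb = motifProb, fracSpecific = fracSpecific,
             fracNone = fracNone, fracDegs = fracDegs,
             motifPlantProb = motifPlantProb)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  lens <- c(chromLength, peakLength, nPeaks, nGenes, nMotifRegions,
            motifRegionLength)
  if (any(lens <= 0)) stop("lengths and counts must be positive")
  if (seed >= 2^31 - 16) stop("seed too large")
  class(p) <- "orthoepi_params"
  p
}

# pick k sites in [margin, L-margin] pairwise >= spacing apart and >= spacing
# from `avoid` sites; rejection sampling with restarts, generation error if
# the density is infeasible
.placeSites <- function(k, L, margin, spacing, avoid = integer(0)) {
  if (k == 0L) return(integer(0))
  for (restart in 1:50) {
    sites <- integer(0)
    tries <- 0L
    while (length(sites) < k && tries <= 100L * k) {
      tries <- tries + 1L
      s <- sample.int(L - 2L * margin, 1L) + margin
      if (all(abs(c(sites, avoid) - s) >= spacing))
        sites <- c(sites, s)
    }
    if (length(sites) == k) return(sort(sites))
  }
  stop("generation error: insertion density too high to place without overlap")
}

# ancestral position -> carrier coordinate shift from insertions
# bps: sorted breakpoints, lens: inserted lengths at each
.shiftPos <- function(pos, bps, lens) {
  if (length(bps) == 0) return(pos)
  pos + vapply(pos, function(x) sum(lens[bps < x]), numeric(1))
}

# internal genome-set generator; specs: list(name, subRate, nInsPerChrom)
.simulateGenomes <- function(params, specs) {
  lib <- defaultTeLibrary()
  nC <- params$nChroms
  chromNames <- paste0("chr", seq_len(nC))
  genomes <- stats::setNames(vector("list", length(specs)),
                             vapply(specs, `[[`, character(1), "name"))
  chromSeqs <- lapply(genomes, function(x) character(nC))
  insRec <- list()    # per-genome insertion annotation rows
  subRec <- list()
  sharedRec <- list()
  chainsFromRef <- stats::setNames(vector("list", length(specs) - 1L),
                                   names(genomes)[-1])
  for (nm in names(chainsFromRef)) chainsFromRef[[nm]] <- list()
  refName <- specs[[1]]$name

  for (ci in seq_len(nC)) {
    anc <- .randChars(params$chromLength)
    # --- ancestral shared LTR5-like copies
    nShared <- params$sharedLtr5PerChrom
    li <- which(lib$name == "LTR5_Hs")
    elemLen <- nchar(lib$consensus[li])
    sharedSites <- if (nShared > 0)
      .placeSites(nShared, params$chromLength, params$edgeMargin,
                  params$minInsertionSpacing)
    else integer(0)
    # splice shared copies into the ancestor itself
    if (nShared > 0) {
      pieces <- character(0)
      prev <- 0L
      for (s in sharedSites) {
        pieces <- c(pieces, paste(anc[(prev + 1L):s], collapse = ""),
                    lib$consensus[li])
        prev <- s
      }
      pieces <- c(pieces, paste(anc[(prev + 1L):length(anc)], collapse = ""))
      anc <- strsplit(paste(pieces, collapse = ""), "")[[1]]
    }
    ancLen <- length(anc)
    sharedStartsAnc <- if (nShared > 0)
      .shiftPos(sharedSites, sharedSites, rep(0L, nShared)) +
        elemLen * (seq_len(nShared) - 1L) + 1L
    else integer(0)
    # footprint of the dual motif inside each shared copy (ancestral coords)
    fpAnc <- lapply(sharedStartsAnc, function(s)
      (s + lib$motifStart[li] - 1L):(s + lib$motifEnd[li] - 1L))
    avoidSub <- unlist(fpAnc)
    avoidSites <- c(sharedStartsAnc,
                    if (length(sharedStartsAnc))
                      sharedStartsAnc + elemLen else integer(0))

    # --- species-specific insertion sites for every genome, all distinct
    gSites <- list(); gSeqs <- list(); gMeta <- list()
    allSites <- avoidSites
    for (sp in specs) {
      nPer <- sp$nInsPerChrom
      fams <- rep(names(nPer), nPer)
      sites <- if (length(fams))
        .placeSites(length(fams), ancLen, params$edgeMargin,
                    params$minInsertionSpacing, avoid = allSites)
      else integer(0)
      allSites <- c(allSites, sites)
      # families are exchangeable across the random sites
      seqs <- character(length(sites)); motif <- rep(NA, length(sites))
      for (k in seq_along(sites)) {
        fi <- which(lib$name == fams[k])
        el <- strsplit(lib$consensus[fi], "")[[1]]
        motif[k] <- NA
        if (!is.na(lib$motifStart[fi])) {
          motif[k] <- stats::runif(1) < params$motifProb
          if (!motif[k]) {
            fp <- lib$motifStart[fi]:lib$motifEnd[fi]
            el[fp] <- .scrambleChars(el[fp])
          }
        }
        seqs[k] <- paste(el, collapse = "")
      }
      gSites[[sp$name]] <- sites
      gSeqs[[sp$name]] <- seqs
      gMeta[[sp$name]] <- data.frame(family = fams,
                                     class = lib$class[match(fams, lib$name)],
                                     motif = motif,
                                     stringsAsFactors = FALSE)
    }

    # --- per-genome sequence construction
    perGenome <- list()
    for (sp in specs) {
      g <- anc
      # substitutions (avoid shared-motif footprints; motif loss is explicit)
      subPos <- integer(0); altB <- character(0)
      if (sp$subRate > 0) {
        subPos <- which(stats::runif(ancLen) < sp$subRate)
        subPos <- setdiff(subPos, avoidSub)
        if (length(subPos)) {
          old <- g[subPos]
          alt <- vapply(old, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          g[subPos] <- alt
          altB <- alt
        }
      }
      # per-genome motif retention in shared copies
      sharedMotif <- rep(TRUE, nShared)
      if (nShared > 0) {
        sharedMotif <- stats::runif(nShared) < params$motifProb
        for (k in which(!sharedMotif))
          g[fpAnc[[k]]] <- .scrambleChars(g[fpAnc[[k]]])
      }
      # insertions (with optional target-site duplication)
      sites <- gSites[[sp$name]]
      insSeqFull <- character(length(sites))
      bps <- integer(length(sites))
      for (k in seq_along(sites)) {
        tsd <- params$tsdLength
        bps[k] <- sites[k] + tsd
        dup <- if (tsd > 0)
          paste(g[(sites[k] + 1L):(sites[k] + tsd)], collapse = "") else ""
        insSeqFull[k] <- paste0(gSeqs[[sp$name]][k], dup)
      }
      lens <- nchar(insSeqFull)
      pieces <- character(0)
      prev <- 0L
      for (k in seq_along(bps)) {
        pieces <- c(pieces, paste(g[(prev + 1L):bps[k]], collapse = ""),
                    insSeqFull[k])
        prev <- bps[k]
      }
      pieces <- c(pieces, paste(g[(prev + 1L):ancLen], collapse = ""))
      gseq <- paste(pieces, collapse = "")
      perGenome[[sp$name]] <- list(seq = gseq, bps = bps, lens = lens,
                                   subPos = subPos, altB = altB,
                                   sharedMotif = sharedMotif)
      # carrier-coordinate annotations of this genome's insertions
      if (length(sites)) {
        startCar <- bps + c(0, cumsum(lens))[seq_along(bps)] + 1L
        insRec[[length(insRec) + 1L]] <- data.frame(
          genome = sp$name, chrom = chromNames[ci],
          start = startCar,
          end = startCar + nchar(gSeqs[[sp$name]]) - 1L,
          family = gMeta[[sp$name]]$family,
          class = gMeta[[sp$name]]$class,
          motif = gMeta[[sp$name]]$motif,
          tsd = params$tsdLength, stringsAsFactors = FALSE)
      }
      if (length(subPos))
        subRec[[length(subRec) + 1L]] <- data.frame(
          genome = sp$name, chrom = chromNames[ci], ancPos = subPos,
          pos = .shiftPos(subPos, bps, lens),
          ref = anc[subPos], alt = altB, stringsAsFactors = FALSE)
    }
    # shared-repeat ledger with per-genome carrier starts and motif flags
    if (nShared > 0) {
      row <- data.frame(chrom = chromNames[ci], ancStart = sharedStartsAnc,
                        ancEnd = sharedStartsAnc + elemLen - 1L,
                        family = "LTR5_Hs", class = "LTR",
                        stringsAsFactors = FALSE)
      for (sp in specs) {
        pg <- perGenome[[sp$name]]
        row[[paste0("start_", sp$name)]] <-
          .shiftPos(sharedStartsAnc, pg$bps, pg$lens)
        row[[paste0("motif_", sp$name)]] <- pg$sharedMotif
      }
      sharedRec[[length(sharedRec) + 1L]] <- row
    }
    for (sp in specs) chromSeqs[[sp$name]][ci] <- perGenome[[sp$name]]$seq

    # --- truth chains reference -> each other genome
    ref <- perGenome[[refName]]
    for (other in names(chainsFromRef)) {
      oth <- perGenome[[other]]
      allBp <- sort(unique(c(ref$bps, oth$bps)))
      dtL <- vapply(allBp, function(b)
        sum(ref$lens[ref$bps == b]), numeric(1))
      dqL <- vapply(allBp, function(b)
        sum(oth$lens[oth$bps == b]), numeric(1))
      nB <- length(allBp)
      blocks <- cbind(size = c(diff(c(0L, allBp)), ancLen -
                                 if (nB) allBp[nB] else 0L),
                      dt = c(dtL, 0), dq = c(dqL, 0))
      tSize <- nchar(ref$seq); qSize <- nchar(oth$seq)
      chainsFromRef[[other]][[ci]] <- list(
        score = 1000, tName = chromNames[ci], tSize = tSize, tStrand = "+",
        tStart = 0L, tEnd = tSize, qName = chromNames[ci], qSize = qSize,
        qStrand = "+", qStart = 0L, qEnd = qSize,
        id = as.character(ci), blocks = blocks)
    }
  }

  genomes <- lapply(chromSeqs, function(x)
    DNAStringSet(stats::setNames(x, chromNames)))
  subs <- if (length(subRec)) do.call(rbind, subRec)
          else data.frame(genome = character(0), chrom = character(0),
                          ancPos = integer(0), pos = integer(0),
                          ref = character(0), alt = character(0))
  ins <- if (length(insRec)) {
    d <- do.call(rbind, insRec)
    GRanges(d$chrom, IRanges(d$start, d$end), strand = "+",
            genome = d$genome, subfamily = d$family, repClass = d$class,
            motif = d$motif, tsd = d$tsd)
  } else GRanges()
  shared <- if (length(sharedRec)) {
    d <- do.call(rbind, sharedRec)
    gr <- GRanges(d$chrom, IRanges(d$ancStart, d$ancEnd), strand = "+")
    mcols(gr) <- d[, setdiff(colnames(d), c("chrom", "ancStart", "ancEnd")),
                   drop = FALSE]
    gr
  } else GRanges()
  list(genomes = genomes, chainsFromRef = chainsFromRef,
       substitutions = subs, insertions = ins, shared = shared)
}

# invert a plus-strand chain record (swap target and query roles)
.invertChainRecord <- function(ch) {
  b <- ch$blocks
  list(score = ch$score, tName = ch$qName, tSize = ch$qSize, tStrand = "+",
       tStart = ch$qStart, tEnd = ch$qEnd, qName = ch$tName,
       qSize = ch$tSize, qStrand = "+", qStart = ch$tStart, qEnd = ch$tEnd,
       id = ch$id,
       blocks = cbind(size = b[, "size"], dt = b[, "dq"], dq = b[, "dt"]))
}

#' Simulate a diverged genome pair with exact truth chains
#'
#' Generates two genomes from a common ancestor: genome B differs from A by
#' point substitutions at \code{substitutionRate} and each genome carries
#' its own planted TE insertions (absent from the other). The chains are
#' constructed exactly from the edit script, not re-aligned, so reciprocal
#' lifting over non-variant regions is the identity by construction.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @return list with \code{genomeA}, \code{genomeB} (\code{DNAStringSet}),
#'   \code{chainAB}, \code{chainBA} (\linkS4class{ChainSet}), and
#'   \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
simulateGenomePair <- function(params) {
  .withSeed(params$seed, {
    specs <- list(list(name = "A", subRate = 0,
                       nInsPerChrom = params$insertionsPerChrom),
                  list(name = "B", subRate = params$substitutionRate,
                       nInsPerChrom = params$insertionsPerChrom))
    g <- .simulateGenomes(params, specs)
    chAB <- new("ChainSet", chains = g$chainsFromRef$B)
    chBA <- new("ChainSet",
                chains = lapply(g$chainsFromRef$B, .invertChainRecord))
    truth <- new("SyntheticTruth", substitutions = g$substitutions,
                 insertions = g$insertions, sharedRepeats = g$shared,
                 peakLabels = character(0), degTable = data.frame(),
                 params = unclass(params))
    list(genomeA = g$genomes$A, genomeB = g$genomes$B,
         chainAB = chAB, chainBA = chBA, truth = truth)
  })
}

#' Simulate a three-genome set for the motif-orthology trace
#'
#' Reuses the pair machinery with a third genome at its own substitution
#' rate and plants \code{sharedLtr5PerChrom} ancestral LTR5-like copies that
#' are present in all three genomes. Each genome independently retains the
#' dual motif in each shared copy with probability \code{motifProb}.
#'
#' @param params a \code{\link{simulationParams}} list (set
#'   \code{sharedLtr5PerChrom} > 0 to plant shared copies).
#' @return list with \code{genomeA/B/C}, \code{chainAB/BA/AC/CA}, and
#'   \code{truth}.
#' @export
simulateGenomeTrio <- function(params) {
  .withSeed(params$seed + 4L, {
    specs <- list(list(name = "A", subRate = 0,
                       nInsPerChrom = params$insertionsPerChrom),
                  list(name = "B", subRate = params$substitutionRate,
                       nInsPerChrom = params$insertionsPerChrom),
                  list(name = "C", subRate = params$outgroupRate,
                       nInsPerChrom = params$insertionsPerChrom))
    g <- .simulateGenomes(params, specs)
    mk <- function(x) new("ChainSet", chains = x)
    truth <- new("SyntheticTruth", substitutions = g$substitutions,
                 insertions = g$insertions, sharedRepeats = g$shared,
                 peakLabels = character(0), degTable = data.frame(),
                 params = unclass(params))
    list(genomeA = g$genomes$A, genomeB = g$genomes$B, genomeC = g$genomes$C,
         chainAB = mk(g$chainsFromRef$B),
         chainBA = mk(lapply(g$chainsFromRef$B, .invertChainRecord)),
         chainAC = mk(g$chainsFromRef$C),
         chainCA = mk(lapply(g$chainsFromRef$C, .invertChainRecord)),
         truth = truth)
  })
}

#' Repeat annotations of one simulated genome
#'
#' Assembles the RepeatMasker-style track of a simulated genome from the
#' truth ledger: that genome's species-specific insertions plus the shared
#' ancestral copies at their per-genome coordinates.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param genome genome name ("A", "B", or "C").
#' @return \code{GRanges} with mcols \code{repName}, \code{repClass},
#'   \code{motif}, \code{shared}.
#' @export
truthRepeats <- function(truth, genome) {
  ins <- truth@insertions
  own <- ins[mcols(ins)$genome == genome]
  out <- GRanges(seqnames(own), IRanges(start(own), end(own)),
                 strand = strand(own),
                 repName = mcols(own)$subfamily,
                 repClass = mcols(own)$repClass,
                 motif = mcols(own)$motif,
                 shared = rep(FALSE, length(own)))
  sh <- truth@sharedRepeats
  if (length(sh)) {
    scol <- paste0("start_", genome); mcol <- paste0("motif_", genome)
    if (!scol %in% colnames(mcols(sh)))
      stop("no shared-repeat coordinates for genome ", genome)
    w <- width(sh)
    shr <- GRanges(seqnames(sh),
                   IRanges(mcols(sh)[[scol]],
                           mcols(sh)[[scol]] + w - 1L),
                   strand = "+",
                   repName = mcols(sh)$family, repClass = mcols(sh)$class,
                   motif = mcols(sh)[[mcol]],
                   shared = rep(TRUE, length(sh)))
    out <- c(out, shr)
  }
  sort(out, ignore.strand = TRUE)
}

#' Simulate ChIP/input peak counts with planted species-specificity
#'
#' Generates a region set with true labels (shared, A_specific, B_specific,
#' none) and negative-binomial ChIP and input counts per sample. ChIP means
#' are the input mean times the enrichment effect for regions modified in
#' that species (1 otherwise); \code{none} regions receive no reads at all
#' and exercise the zero-read discard rule. Library sizes are equal across
#' samples so the expected enrichment score of a modified region equals the
#' effect.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @param assay assay label stored in the sample sheet (also offsets the
#'   seed so different assays draw independent counts).
#' @return \code{SummarizedExperiment} with a \code{counts} assay, region
#'   \code{rowRanges} (mcol \code{trueLabel}), and colData
#'   \code{species, assay, replicate, lib_size}.
#' @export
simulatePeakCounts <- function(params, assay = "H3K4me3") {
  off <- 1L + (sum(utf8ToInt(assay)) %% 7L)
  .withSeed(params$seed + off, {
    n <- params$nPeaks
    nSpec <- round(n * params$fracSpecific / 2)
    nNone <- round(n * params$fracNone)
    label <- rep("shared", n)
    idx <- sample.int(n)
    label[idx[seq_len(nSpec)]] <- "A_specific"
    label[idx[nSpec + seq_len(nSpec)]] <- "B_specific"
    label[idx[2 * nSpec + seq_len(nNone)]] <- "none"
    regions <- GRanges("simPeaks",
                       IRanges(start = (seq_len(n) - 1L) * 2L *
                                 params$peakLength + 1L,
                               width = params$peakLength),
                       trueLabel = label)
    reps <- seq_len(params$nReplicates)
    cd <- expand.grid(replicate = reps, assayType = c("ChIP", "input"),
                      species = c("A", "B"), stringsAsFactors = FALSE)
    cd <- cd[order(cd$species, cd$replicate, cd$assayType), ]
    sampleNames <- sprintf("%s_rep%d_%s", cd$species, cd$replicate,
                           cd$assayType)
    draw <- function(mu) {
      if (params$nbDispersion <= 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / params$nbDispersion)
    }
    counts <- matrix(0L, n, nrow(cd), dimnames = list(NULL, sampleNames))
    for (j in seq_len(nrow(cd))) {
      sp <- cd$species[j]
      modified <- label == "shared" |
        (sp == "A" & label == "A_specific") |
        (sp == "B" & label == "B_specific")
      mu <- rep(params$inputMean, n)
      if (cd$assayType[j] == "ChIP")
        mu[modified] <- mu[modified] * params$enrichmentEffect
      x <- draw(mu)
      x[label == "none"] <- 0L
      counts[, j] <- x
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), rowRanges = regions,
      colData = DataFrame(sample = sampleNames, species = cd$species,
                          assay = cd$assayType, replicate = cd$replicate,
                          lib_size = rep(params$libSize, nrow(cd)),
                          row.names = sampleNames))
  })
}

#' Simulate replicate TPM tables with planted fold changes
#'
#' Log-normal expression: per-gene baselines are drawn on the log2 scale,
#' planted DEGs get the full fold change added to one species' mean, and
#' replicates add independent log2 noise. With the default noise sd (0.35)
#' intraspecies log-scale Pearson correlations fall in the 0.96-0.98 regime.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @return list with \code{tpm} (genes x samples matrix), \code{groups}
#'   (data.frame sample/species), and \code{truth} (gene, isDeg, direction,
#'   foldChange).
#' @export
simulateExpression <- function(params) {
  .withSeed(params$seed + 2L, {
    n <- params$nGenes
    base <- stats::rnorm(n, params$exprBaseMean, params$exprBaseSd)
    nDeg <- round(n * params$fracDegs)
    isDeg <- rep(FALSE, n)
    dirn <- rep("ns", n)
    idx <- sample.int(n, nDeg)
    isDeg[idx] <- TRUE
    dirn[idx] <- rep_len(c("A_up", "B_up"), nDeg)
    lfc <- log2(params$degFoldChange)
    muA <- base + ifelse(dirn == "A_up", lfc, 0)
    muB <- base + ifelse(dirn == "B_up", lfc, 0)
    reps <- seq_len(params$nReplicates)
    cols <- c(sprintf("A_rep%d", reps), sprintf("B_rep%d", reps))
    tpm <- matrix(0, n, length(cols),
                  dimnames = list(sprintf("gene%05d", seq_len(n)), cols))
    for (r in reps) {
      tpm[, sprintf("A_rep%d", r)] <-
        2^(muA + stats::rnorm(n, 0, params$exprNoiseSd))
      tpm[, sprintf("B_rep%d", r)] <-
        2^(muB + stats::rnorm(n, 0, params$exprNoiseSd))
    }
    list(tpm = tpm,
         groups = data.frame(sample = cols,
                             species = rep(c("A", "B"),
                                           each = length(reps))),
         truth = data.frame(gene = rownames(tpm), isDeg = isDeg,
                            direction = dirn,
                            foldChange = ifelse(isDeg,
                                                params$degFoldChange, 1)))
  })
}

#' Simulate orthologous region-sequence pairs with planted motif gains
#'
#' Builds pairs of orthologous sequences for species-specific regions: the
#' "other" sequence diverges from the modified one by background
#' substitutions, and a fraction of modified-species sequences additionally
#' carry one planted consensus site of the given motif (a true gain).
#'
#' @param params a \code{\link{simulationParams}} list.
#' @param model the \linkS4class{MotifModel} whose consensus is planted.
#' @return list with character vectors \code{seqModified},
#'   \code{seqOther} and logical \code{planted}.
#' @export
simulateMotifRegionPairs <- function(params, model) {
  .withSeed(params$seed + 3L, {
    n <- params$nMotifRegions
    L <- params$motifRegionLength
    w <- ncol(model@pfm)
    consensus <- paste(rownames(model@pfm)[apply(model@pfm, 2, which.max)],
                       collapse = "")
    planted <- stats::runif(n) < params$motifPlantProb
    seqMod <- character(n); seqOth <- character(n)
    for (i in seq_len(n)) {
      base <- .randChars(L)
      oth <- base
      subs <- which(stats::runif(L) < params$substitutionRate)
      if (length(subs))
        oth[subs] <- vapply(oth[subs], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      mod <- base
      if (planted[i]) {
        at <- sample.int(L - w + 1L, 1L)
        mod[at:(at + w - 1L)] <- strsplit(consensus, "")[[1]]
        # the orthologous sequence keeps its background bases there, so the
        # site exists only in the modified species
        oth[at:(at + w - 1L)] <- .scrambleChars(base[at:(at + w - 1L)])
      }
      seqMod[i] <- paste(mod, collapse = "")
      seqOth[i] <- paste(oth, collapse = "")
    }
    list(seqModified = seqMod, seqOther = seqOth, planted = planted)
  })
}
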