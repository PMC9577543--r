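test_that("enrichment scores follow the normalized ratio with the input floor", {
  expect_equal(enrichmentScore(100, 50, 1e6, 1e6), 2)
  expect_equal(enrichmentScore(0, 50, 1e6, 1e6), 0)
  expect_equal(enrichmentScore(30, 0, 1e6, 1e6), 30)  # input floored at 1
  expect_error(enrichmentScore(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(enrichmentScore(1, 0, 0, 1e6), "positive")
  # scale invariance: multiplying counts and totals by c leaves E unchanged
  set.seed(1)
  chip <- rpois(50, 40); input <- rpois(50, 30)
  e1 <- enrichmentScore(chip, input, 1e6, 2e6)
  e2 <- enrichmentScore(chip * 10, input * 10, 1e7, 2e7)
  keep <- input > 0   # the raw-read floor is deliberately not scale-free
  expect_equal(e1[keep], e2[keep])
})

test_that("classification applies the >=3 / <1.5 threshold rule", {
  mk <- function(meanA, meanB) {
    counts <- cbind(A_rep1_ChIP = round(meanA * 100),
                    A_rep1_input = 100L,
                    A_rep2_ChIP = round(meanA * 100),
                    A_rep2_input = 100L,
                    B_rep1_ChIP = round(meanB * 100),
                    B_rep1_input = 100L,
                    B_rep2_ChIP = round(meanB * 100),
                    B_rep2_input = 100L)
    cd <- S4Vectors::DataFrame(
      species = rep(c("A", "B"), each = 4),
      assay = rep(c("ChIP", "input"), 4),
      replicate = rep(rep(1:2, each = 2), 2),
      lib_size = rep(1e6, 8), row.names = colnames(counts))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowRanges = GRanges("c", IRanges(1, 100)), colData = cd)
  }
  expect_equal(classifyRegions(mk(3.5, 1.0))$label, "A_specific")
  expect_equal(classifyRegions(mk(2.9, 1.0))$label, "shared")
  expect_equal(classifyRegions(mk(3.0, 1.49))$label, "A_specific")
  expect_equal(classifyRegions(mk(3.5, 1.5))$label, "shared")
  expect_equal(classifyRegions(mk(1.0, 3.5))$label, "B_specific")
  # orthology discard precedes classification
  expect_equal(classifyRegions(mk(3.5, 1.0), orthology = FALSE)$label,
               "discarded_orthology")
})

test_that("label symmetry: swapping species swaps the specific labels", {
  p <- simulationParams(seed = 41, nPeaks = 400L)
  se <- simulatePeakCounts(p)
  res <- classifyRegions(se)
  swapped <- se[, c(5:8, 1:4)]   # B samples first
  res2 <- classifyRegions(swapped)
  map <- c(A_specific = "B_specific", B_specific = "A_specific",
           shared = "shared", discarded_no_reads = "discarded_no_reads",
           discarded_orthology = "discarded_orthology")
  expect_identical(unname(map[res$label]), res2$label)
  # threshold monotonicity: raising tHigh can only shrink the specific set
  n3 <- sum(classifyRegions(se, tHigh = 3)$label == "A_specific")
  n4 <- sum(classifyRegions(se, tHigh = 4)$label == "A_specific")
  n5 <- sum(classifyRegions(se, tHigh = 5)$label == "A_specific")
  expect_true(n3 >= n4 && n4 >= n5)
})

test_that("species-specific peak recovery meets the planted design", {
  p <- simulationParams(seed = 52)   # 2000 regions, 2 reps, effect 8
  se <- simulatePeakCounts(p)
  res <- classifyRegions(se)
  tl <- mcols(SummarizedExperiment::rowRanges(se))$trueLabel
  spec <- tl %in% c("A_specific", "B_specific")
  recall <- mean(res$label[spec] == tl[spec])
  fpr <- mean(res$label[tl == "shared"] %in% c("A_specific", "B_specific"))
  expect_gte(recall, 0.95)
  expect_lte(fpr, 0.01)
  expect_true(all(res$label[tl == "none"] == "discarded_no_reads"))
})

test_that("bivalent calling equals brute-force base-set intersection", {
  expect_length(callBivalent(list(l1 = GRanges("c", IRanges(1, 100))),
                             list(l1 = GRanges("c", IRanges(200, 300)))),
                0L)
  bv <- callBivalent(list(l1 = GRanges("c", IRanges(1, 100))),
                     list(l1 = GRanges("c", IRanges(51, 150))))
  expect_equal(start(bv), 51)
  expect_equal(end(bv), 100)
  # three lines with nested overlaps vs brute-force union of intersections
  set.seed(8)
  mkset <- function() {
    s <- sort(sample(1:2000, 12))
    GRanges("c", IRanges(s, s + sample(30:200, 12, TRUE)))
  }
  k4 <- list(l1 = mkset(), l2 = mkset(), l3 = mkset())
  k27 <- list(l1 = mkset(), l2 = mkset(), l3 = mkset())
  got <- callBivalent(k4, k27)
  brute <- sort(unique(unlist(lapply(1:3, function(i)
    bruteIntersectBp(k4[[i]], k27[[i]])))))
  expect_identical(grToBaseSet(got), brute)
})

test_that("promoter windows span -2 kb / +0.5 kb around the TSS, strand-aware", {
  genes <- GRanges(c("c", "c"), IRanges(c(10000, 8000), c(15000, 10000)),
                   strand = c("+", "-"), gene_id = c("plus", "minus"))
  # plus-strand TSS 10000: window [8000, 10500)
  hit <- assignPromoters(GRanges("c", IRanges(8501, 9000)), genes[1])
  expect_equal(hit$gene_id, "plus")
  # minus-strand TSS 10000 (gene end): window [9500, 12000)
  hit2 <- assignPromoters(GRanges("c", IRanges(11001, 11100)), genes[2])
  expect_equal(hit2$gene_id, "minus")
  # far-upstream peak unassigned
  expect_equal(nrow(assignPromoters(GRanges("c", IRanges(1, 100)), genes)),
               0L)
  # 1-bp overlap at the window edge counts: window is [TSS-2000, TSS+499]
  edge <- assignPromoters(GRanges("c", IRanges(10499, 10600)), genes[1])
  expect_equal(edge$gene_id, "plus")
  expect_equal(nrow(assignPromoters(GRanges("c", IRanges(10500, 10600)),
                                    genes[1])), 0L)
})

test_that("divergence matches hand values and the affine-gap DP oracle score", {
  s <- randSeq(100)
  expect_equal(pairwiseDivergence(s, s), 100)
  s2 <- strsplit(s, "")[[1]]
  s2[50] <- setdiff(c("A", "C", "G", "T"), s2[50])[1]
  expect_equal(pairwiseDivergence(s, paste(s2, collapse = "")), 99)
  expect_error(pairwiseDivergence("", s), "empty")
  # 5-bp deletion: 95 matched columns of 100 alignment columns
  del <- paste(strsplit(s, "")[[1]][-(40:44)], collapse = "")
  expect_equal(pairwiseDivergence(s, del), 95, tolerance = 1e-6)
  # the alignment engine finds the same optimal score as the Gotoh oracle
  set.seed(21)
  for (i in 1:5) {
    a <- randSeq(60)
    bchars <- strsplit(a, "")[[1]]
    cut <- sample(10:40, 1)
    b <- paste(bchars[-(cut:(cut + 4))], collapse = "")
    sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 2, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), bruteAffineScore(a, b))
  }
})

test_that("overlap counting equals the all-pairs oracle", {
  expect_equal(overlapCounts(GRanges("c", IRanges(1, 10)),
                             GRanges("c", IRanges(20, 30)))$nOverlapping, 0L)
  gr <- GRanges("c", IRanges(c(1, 50), c(10, 80)))
  expect_equal(overlapCounts(gr, gr)$nOverlapping, 2L)
  set.seed(13)
  mk <- function(n) {
    s <- sample(1:5000, n)
    GRanges(sample(c("c1", "c2"), n, TRUE), IRanges(s, s + sample(1:300, n, TRUE)))
  }
  a <- mk(60); b <- mk(40)
  brute <- sum(vapply(seq_along(a), function(i) {
    any(as.character(seqnames(a))[i] == as.character(seqnames(b)) &
          start(a)[i] <= end(b) & end(a)[i] >= start(b))
  }, logical(1)))
  expect_equal(overlapCounts(a, b)$nOverlapping, brute)
})
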