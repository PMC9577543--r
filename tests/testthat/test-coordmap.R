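chainFromText <- function(lines) {
  tf <- withr::local_tempfile(lines = c(lines, ""),
                              .local_envir = parent.frame())
  readChain(tf)
}

test_that("identity chains map intervals to themselves", {
  cs <- chainFromText(c("chain 100 cA 1000 + 0 1000 cB 1000 + 0 1000 1",
                        "1000"))
  r <- liftIntervals(GRanges("cA", IRanges(121, 150)), cs)
  expect_equal(r$status, "mapped")
  expect_equal(c(r$start, r$end), c(121L, 150L))
  expect_equal(r$matchFraction, 1)
})

test_that("target-side gaps delete, query-side gaps shift", {
  # block 100, dt 0 / dq 50, block 100: target [120,150) -> query [170,200)
  cs <- chainFromText(c("chain 100 cA 1000 + 0 200 cB 1000 + 0 250 1",
                        "100 0 50", "100"))
  r <- liftIntervals(GRanges("cA", IRanges(121, 150)), cs)
  expect_equal(r$status, "mapped")
  expect_equal(c(r$start, r$end), c(171L, 200L))   # 0-based [170,200)
  # wholly inside a dt gap -> deleted
  cs2 <- chainFromText(c("chain 100 cA 1000 + 0 250 cB 1000 + 0 200 1",
                         "100 50 0", "100"))
  expect_equal(liftIntervals(GRanges("cA", IRanges(11, 90)), cs2)$status,
               "mapped")
  expect_equal(liftIntervals(GRanges("cA", IRanges(81, 120)), cs2,
                             minMatch = 0.95)$status, "partial")
  expect_equal(liftIntervals(GRanges("cA", IRanges(101, 150)), cs2)$status,
               "deleted")
  # chrom absent from all chains -> deleted, not an error
  expect_equal(liftIntervals(GRanges("zz", IRanges(1, 10)), cs2)$status,
               "deleted")
})

test_that("two chains covering an interval classify it duplicated", {
  cs <- chainFromText(c(
    "chain 100 cA 1000 + 100 300 q1 1000 + 0 200 1", "200",
    "chain 90 cA 1000 + 100 300 q2 1000 + 500 700 2", "200"))
  r <- liftIntervals(GRanges("cA", IRanges(151, 250)), cs)
  expect_equal(r$status, "duplicated")
  # an interval covered well by only one of the chains maps
  cs2 <- chainFromText(c(
    "chain 100 cA 1000 + 100 300 q1 1000 + 0 200 1", "200",
    "chain 90 cA 1000 + 280 480 q2 1000 + 500 700 2", "200"))
  r2 <- liftIntervals(GRanges("cA", IRanges(151, 250)), cs2)
  expect_equal(r2$status, "mapped")
  expect_equal(r2$chrom, "q1")
})

test_that("minus-strand queries normalize to plus-strand coordinates", {
  # oracle: per-base reflection dictionary
  cs <- chainFromText(c("chain 100 cA 1000 + 100 200 cB 1000 - 300 400 1",
                        "40 10 10", "50"))
  maps <- bruteChainMaps(cs)
  r <- liftIntervals(GRanges("cA", IRanges(121, 150)), cs, minMatch = 0.5)
  o <- bruteLiftOne("cA", 121, 150, maps, 0.5)
  expect_equal(r$status, o$status)
  expect_equal(c(r$start, r$end), c(o$start, o$end))
  expect_equal(r$strand, "-")
})

test_that("lifting agrees with the per-base brute-force map on random chains", {
  nAgree <- 0L; nTot <- 0L
  for (s in 1:8) {
    cs <- randomChainSet(seed = 100 + s, nChains = 3)
    maps <- bruteChainMaps(cs)
    set.seed(200 + s)
    starts <- sample(9000, 40)
    widths <- sample(10:400, 40, replace = TRUE)
    gr <- GRanges(sample(c("cA", "cB"), 40, TRUE),
                  IRanges(starts, width = widths))
    res <- liftIntervals(gr, cs, minMatch = 0.9)
    for (i in seq_along(gr)) {
      o <- bruteLiftOne(as.character(seqnames(gr))[i], start(gr)[i],
                        end(gr)[i], maps, 0.9)
      nTot <- nTot + 1L
      same <- res$status[i] == o$status &&
        (o$status != "mapped" ||
           (res$chrom[i] == o$chrom && res$start[i] == o$start &&
              res$end[i] == o$end && res$strand[i] == o$strand))
      if (same) nAgree <- nAgree + 1L
      expect_true(same,
                  info = sprintf("seed %d interval %d: %s vs %s", s, i,
                                 res$status[i], o$status))
    }
  }
  expect_equal(nAgree, nTot)
})

test_that("monotonicity: a fully mapped interval contains its sub-intervals' images", {
  for (s in 1:5) {
    cs <- randomChainSet(seed = 300 + s, nChains = 1)
    ch <- chains(cs)[[1]]
    gr <- GRanges(ch$tName, IRanges(ch$tStart + 1L, ch$tEnd))
    res <- liftIntervals(gr, cs, minMatch = 1e-9)
    sub <- GRanges(ch$tName, IRanges(ch$tStart + 1L,
                                     ch$tStart + chains(cs)[[1]]$blocks[1, "size"]))
    rsub <- liftIntervals(sub, cs, minMatch = 1)
    if (rsub$status == "mapped") {
      expect_gte(rsub$start, res$start)
      expect_lte(rsub$end, res$end)
    }
  }
})

test_that("reciprocal validation is the identity on truth chains", {
  p <- simulationParams(seed = 31, nChroms = 1L)
  pair <- simulateGenomePair(p)
  ins <- truthInsertions(pair$truth)
  set.seed(5)
  # intervals well away from any planted insertion
  cand <- GRanges("chr1", IRanges(sample(180000, 300), width = 400))
  clear <- cand[!overlapsAny(cand + 1500, ins, ignore.strand = TRUE)]
  rv <- reciprocalValidate(clear, pair$chainAB, pair$chainBA)
  expect_true(all(rv$valid))
  # and A -> B -> A returns the original coordinates exactly
  expect_true(all(rv$reason == "ok"))
})

test_that("reciprocal validation rejects duplications and asymmetric gaps", {
  # duplication on the B side: two chains cover the same target span
  cs <- chainFromText(c(
    "chain 100 cA 1000 + 100 300 q1 1000 + 0 200 1", "200",
    "chain 90 cA 1000 + 100 300 q2 1000 + 500 700 2", "200"))
  back <- chainFromText(c("chain 100 q1 1000 + 0 200 cA 1000 + 100 300 1",
                          "200"))
  rv <- reciprocalValidate(GRanges("cA", IRanges(151, 250)), cs, back)
  expect_false(rv$valid)
  expect_equal(rv$reason, "forward_duplicated")
  # asymmetric chains: forward maps, back-lift lands elsewhere
  fwd <- chainFromText(c("chain 100 cA 1000 + 0 200 cB 1000 + 0 200 1",
                         "200"))
  bck <- chainFromText(c("chain 100 cB 1000 + 0 200 cA 1000 + 300 500 1",
                         "200"))
  rv2 <- reciprocalValidate(GRanges("cA", IRanges(11, 60)), fwd, bck)
  expect_false(rv2$valid)
  expect_equal(rv2$reason, "back_mismatch")
  # slack permits small displacement
  rv3 <- reciprocalValidate(GRanges("cA", IRanges(11, 60)), fwd, bck,
                            slack = 300)
  expect_true(rv3$valid)
})

test_that("lifting agrees with rtracklayer liftOver on clean single-chain maps", {
  skip_if_not_installed("rtracklayer")
  cs <- chainFromText(c("chain 100 cA 1000 + 0 200 cB 1000 + 0 250 1",
                        "100 0 50", "100"))
  tf <- withr::local_tempfile(fileext = ".chain")
  writeChain(cs, tf)
  ch <- rtracklayer::import.chain(tf)
  gr <- GRanges("cA", IRanges(c(11, 121), c(60, 150)))
  lifted <- rtracklayer::liftOver(gr, ch)
  mine <- liftIntervals(gr, cs)
  expect_equal(start(unlist(lifted)), mine$start)
  expect_equal(end(unlist(lifted)), mine$end)
})
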