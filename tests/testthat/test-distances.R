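test_that("pairwise distances follow the model formulas", {
  expect_equal(pairwiseDistance("ACGTACGT", "ACGTACGT", "p"), 0)
  expect_equal(pairwiseDistance("ACGTACGT", "ACGTACGT", "JC69"), 0)
  expect_equal(pairwiseDistance("ACGTACGT", "ACGTACGT", "K2P"), 0)
  # 10 sites, 2 mismatches: p = 0.2, JC69 = -(3/4)ln(1 - 4*0.2/3)
  expect_equal(pairwiseDistance("AAAAAAAAAA", "AAAAAAAATT", "p"), 0.2)
  expect_equal(pairwiseDistance("AAAAAAAAAA", "AAAAAAAATT", "JC69"),
               0.2326, tolerance = 1e-4)
  # pairwise deletion: N and gaps drop per pair
  expect_equal(pairwiseDistance("AAN-AAAAAA", "AATTAAAAAT", "p"), 1 / 8)
  # saturation is an error, as is an all-missing pair
  expect_error(pairwiseDistance("AAAA", "TTTT", "JC69"), "undefined")
  expect_error(pairwiseDistance("NNNN", "AAAA", "p"), "comparable")
})

test_that("JC69 correction always inflates relative to p", {
  set.seed(51)
  for (r in 1:20) {
    a <- rndSeq(300)
    b <- mutSeq(a, runif(1, 0.01, 0.4))
    p <- pairwiseDistance(a, b, "p")
    expect_gte(pairwiseDistance(a, b, "JC69"), p)
  }
})

test_that("all three models agree with an independent implementation", {
  set.seed(52)
  seqs <- character(5)
  seqs[1] <- rndSeq(400)
  for (i in 2:5) seqs[i] <- mutSeq(seqs[1], runif(1, 0.05, 0.25))
  names(seqs) <- paste0("t", 1:5)
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s)
    strsplit(tolower(s), "")[[1]])))
  for (mm in list(c("p", "raw"), c("JC69", "JC69"), c("K2P", "K80"))) {
    ref <- as.matrix(ape::dist.dna(bin, model = mm[2],
                                   pairwise.deletion = TRUE))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(pairwiseDistance(seqs[i], seqs[j], mm[1]),
                   ref[i, j], tolerance = 1e-9)
    }
  }
})

test_that("overall mean distance averages pairs and bootstraps columns", {
  # identical rows: zero distance, zero SE
  aln <- setNames(rep(rndSeq(100), 3), paste0("t", 1:3))
  ds <- overallMeanDistance(aln, bootstrapReps = 50, seed = 1)
  expect_equal(dMean(ds), 0)
  expect_equal(bootstrapSE(ds), 0)

  # two sequences: equals the pairwise distance
  set.seed(53)
  a <- rndSeq(500)
  b <- mutSeq(a, 0.1)
  ds2 <- overallMeanDistance(c(x = a, y = b), bootstrapReps = 100,
                             seed = 2)
  expect_equal(dMean(ds2), pairwiseDistance(a, b, "p"))
  expect_identical(ds2@nTaxa, 2L)

  # three sequences: mean of the three pairwise distances
  cc <- mutSeq(a, 0.05)
  ds3 <- overallMeanDistance(c(x = a, y = b, z = cc),
                             bootstrapReps = 10, seed = 3)
  expect_equal(dMean(ds3),
               mean(c(pairwiseDistance(a, b, "p"),
                      pairwiseDistance(a, cc, "p"),
                      pairwiseDistance(b, cc, "p"))))

  # deterministic under a fixed seed
  r1 <- overallMeanDistance(c(x = a, y = b), bootstrapReps = 100, seed = 9)
  r2 <- overallMeanDistance(c(x = a, y = b), bootstrapReps = 100, seed = 9)
  expect_identical(bootstrapSE(r1), bootstrapSE(r2))
})

test_that("bootstrap SE scales like 1/sqrt(alignment length)", {
  set.seed(54)
  meanSE <- vapply(c(250L, 1000L, 4000L), function(L) {
    mean(replicate(50, {
      a <- rndSeq(L)
      b <- mutSeq(a, 0.1)
      bootstrapSE(overallMeanDistance(c(x = a, y = b),
                                      bootstrapReps = 200,
                                      seed = sample.int(1e8, 1)))
    }))
  }, numeric(1))
  expect_lt(abs(meanSE[1] / meanSE[2] - 2), 0.5)   # within +-25% of 2
  expect_lt(abs(meanSE[2] / meanSE[3] - 2), 0.5)
})

test_that("rate calibration is the distance ratio times the cyt-b rate", {
  mk <- function(d, id) methods::new("DistanceSummary", locusId = id,
                                     model = "p", dMean = d,
                                     bootstrapSE = 0, nTaxa = 2L,
                                     nSitesUsed = 100, nBootstrap = 0L)
  expect_equal(muRate(calibrateRate(mk(0.1, "a"), mk(0.1, "cytb"))),
               0.01035)
  expect_equal(muRate(calibrateRate(mk(0, "a"), mk(0.1, "cytb"))), 0)
  expect_equal(muRate(calibrateRate(mk(0.05, "a"), mk(0.1, "cytb"))),
               0.005175)
  expect_error(calibrateRate(mk(0.1, "a"), mk(0, "cytb")), "zero")
  # linear in d_locus and invariant under joint rescaling
  m1 <- muRate(calibrateRate(mk(0.02, "a"), mk(0.08, "c")))
  m2 <- muRate(calibrateRate(mk(0.04, "a"), mk(0.08, "c")))
  expect_equal(m2, 2 * m1)
  m3 <- muRate(calibrateRate(mk(0.2, "a"), mk(0.8, "c")))
  expect_equal(m3, m1)
})

test_that("rate ranking sorts ascending and counts against references", {
  mk <- function(mu, id) methods::new("RateEstimate", locusId = id,
                                      ratio = mu / 0.01035, mu = mu,
                                      referenceRate = 0.01035)
  rates <- list(mk(0.004, "d"), mk(0.002, "b"), mk(0.002, "a"),
                mk(0.009, "e"), mk(0.005, "c"))
  rr <- rankRates(rates, references = c(RAG1 = 0.005, cytb = 0.01035))
  expect_identical(rr$report$locus, c("a", "b", "d", "c", "e"))
  cmp <- rr$comparison
  expect_identical(cmp$n_slower[cmp$reference == "RAG1"], 3L)
  expect_identical(cmp$n_faster[cmp$reference == "RAG1"], 1L)
  expect_identical(cmp$n_tied[cmp$reference == "RAG1"], 1L)
  expect_identical(cmp$n_slower[cmp$reference == "cytb"], 5L)
})
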