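test_that("self-alignment and strand symmetry behave as expected", {
  set.seed(31)
  s <- rndSeq(100)
  h <- localAlign(s, s)
  expect_identical(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(h$identity[1], 1.0)
  expect_equal(h$queryCoverage[1], 1.0)

  # reverse-complemented query is found on the minus strand, same identity
  hrc <- localAlign(rcSeq(s), s)
  expect_identical(hrc$strand[1], "-")
  expect_equal(hrc$identity[1], 1.0)
  expect_equal(hrc$queryCoverage[1], 1.0)

  # sequences shorter than the seed give an empty result, not an error
  expect_identical(nrow(localAlign("ACGT", s)), 0L)
})

test_that("heuristic scores never exceed Smith-Waterman and identity agrees", {
  set.seed(32)
  for (r in 1:10) {
    L <- sample(150:1000, 1)
    d <- runif(1, 0.03, 0.20)
    s <- rndSeq(L)
    q <- mutSeq(s, d)
    h <- localAlign(q, s, strand = "+")
    expect_gt(nrow(h), 0)
    sw <- swOracle(q, s)
    expect_lte(h$score[1], sw$score + 1e-9)
    expect_lt(abs(h$identity[1] - sw$identity), 0.03)
  }
})

test_that("recorded identity and coverage re-derive from the stored alignment", {
  set.seed(33)
  s <- rndSeq(600)
  q <- mutSeq(s, 0.1)
  h <- localAlign(q, s)
  for (i in seq_len(nrow(h))) {
    qa <- strsplit(h$qaln[i], "")[[1]]
    sa <- strsplit(h$saln[i], "")[[1]]
    expect_identical(length(qa), h$alnLength[i])
    expect_identical(sum(qa == sa & qa != "-"), h$matches[i])
    expect_equal(h$identity[i], h$matches[i] / h$alnLength[i])
    expect_equal(h$queryCoverage[i], min(1, h$alnLength[i] / 600))
  }
})

test_that("exon mining applies the strict >600 bp rule strand-aware", {
  chr <- rndSeq(3000)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 700, 1500), width = c(600, 601, 700)),
    strand = c("+", "+", "-"))
  ann$exon_id <- c("short", "boundary", "minus")
  ann$gene_id <- c("g1", "g2", "g3")
  ex <- mineExons(genome, ann)
  expect_identical(ex$exon_id, c("boundary", "minus"))  # 600 bp excluded
  expect_identical(ex$length_bp, c(601L, 700L))
  expect_identical(ex$sequence[2],
                   rcSeq(substr(chr, 1500, 2199)))

  # spans beyond the contig are an error naming the exon
  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 3200))
  bad$exon_id <- "overrun"
  bad$gene_id <- "g4"
  expect_error(mineExons(genome, bad, minLen = 1L), "overrun")
  # unknown chromosome is an error
  bad2 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 700))
  bad2$exon_id <- "x"
  bad2$gene_id <- "g5"
  expect_error(mineExons(genome, bad2), "absent")
})

test_that("single-copy flags and orthology screen reproduce planted truth", {
  sim <- simulateGenomePair(genomeSimConfig(
    nExons = 12, nParalogs = 3, divergence = 0.08, deletionProb = 0.2,
    seed = 77))
  ex <- mineExons(sim$genome1, sim$annotation)
  ex <- markSingleCopy(ex, sim$genome1)
  expect_identical(ex$single_copy[match(sim$truth$exon_id, ex$exon_id)],
                   sim$truth$single_copy)
  hits <- screenOrthologs(ex, sim$genome2)
  expect_setequal(hits$exon_id, sim$truth$exon_id[sim$truth$survives])
  # retained hits carry the thresholds they claim
  expect_true(all(hits$identity > 0.80))
  expect_true(all(hits$coverage > 0.50))
})

test_that("orthology thresholds are strict and monotone", {
  # boundary: identity exactly at the threshold is rejected
  expect_false(NPCLtools:::orthoPass(0.80, 0.60, 0.80, 0.50))
  expect_false(NPCLtools:::orthoPass(0.85, 0.50, 0.80, 0.50))
  expect_true(NPCLtools:::orthoPass(0.85, 0.60, 0.80, 0.50))

  sim <- simulateGenomePair(genomeSimConfig(
    nExons = 8, nParalogs = 0, divergence = 0.08, deletionProb = 0,
    seed = 55))
  ex <- mineExons(sim$genome1, sim$annotation)
  loose <- screenOrthologs(ex, sim$genome2, minIdentity = 0.80)
  tight <- screenOrthologs(ex, sim$genome2, minIdentity = 0.95)
  tighter <- screenOrthologs(ex, sim$genome2, minIdentity = 0.80,
                             minCoverage = 0.99)
  expect_true(all(tight$exon_id %in% loose$exon_id))
  expect_true(all(tighter$exon_id %in% loose$exon_id))
  expect_lt(nrow(tight), nrow(loose))  # 8% divergence fails a 95% screen
})
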