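test_that("complementarity scoring matches hand enumeration and symmetry", {
  expect_identical(complementarityScore("AAAAAA"), 0L)   # A cannot pair A
  expect_identical(complementarityScore("GAATTC"), 6L)   # palindrome
  expect_error(complementarityScore("ACGN"), "non-DNA")

  set.seed(41)
  for (r in 1:25) {
    a <- rndSeq(sample(6:22, 1))
    b <- rndSeq(sample(6:22, 1))
    expect_identical(complementarityScore(a, b), bruteCompScore(a, b))
    expect_identical(complementarityScore(a, b, anchor3prime = TRUE),
                     bruteCompScore(a, b, anchor3 = TRUE))
    # the definition is symmetric in its arguments
    expect_identical(complementarityScore(a, b),
                     complementarityScore(b, a))
  }
})

test_that("primer enumeration equals brute force and respects bounds", {
  set.seed(42)
  tmpl <- rndSeq(140)
  got <- enumeratePrimers(tmpl, window = c(20, 79))
  expect_setequal(paste(got$start, got$length),
                  brutePrimers(tmpl, 20, 79))
  # all emitted primers satisfy the constraints
  expect_true(all(got$length >= 18 & got$length <= 25))
  expect_true(all(got$gc_fraction >= 0.20 & got$gc_fraction <= 0.80))
  expect_true(all(got$self_any < 6))
  expect_true(all(got$self_3prime < 3))
  # GC bound: a 15% GC 20-mer is excluded
  lowgc <- paste0(paste(rep("AT", 20), collapse = ""), "GGG")
  expect_identical(nrow(enumeratePrimers(lowgc, c(1, 1))), 0L)
  # case invariance and flanking invariance
  expect_identical(enumeratePrimers(tolower(tmpl), window = c(20, 79)),
                   got)
  tmpl2 <- paste0(rndSeq(30), substr(tmpl, 20, 140))
  got2 <- enumeratePrimers(tmpl2, window = c(31, 90))
  expect_identical(got2$sequence, got$sequence)
})

test_that("Tm follows the closed form on GC count and length", {
  p <- enumeratePrimers(paste(rep("ACGT", 20), collapse = ""), c(1, 4))
  expect_equal(p$tm, 64.9 + 41 * (p$gc_fraction * p$length - 16.4) /
                 p$length)
})

test_that("conservation scores come from aligned columns over windows", {
  tmpl <- rndSeq(120)
  hit <- list(qaln = tmpl, saln = tmpl, qstart = 1, qend = 120,
              strand = "+")
  expect_equal(conservationScore(hit, c(1, 20), c(101, 120), 120), 1.0)
  # 40 window bases, 4 mismatches -> 0.9
  qry <- tmpl
  for (pos in c(3, 7, 105, 118)) {
    old <- substr(qry, pos, pos)
    substr(qry, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  hit2 <- list(qaln = tmpl, saln = qry, qstart = 1, qend = 120,
               strand = "+")
  expect_equal(conservationScore(hit2, c(1, 20), c(101, 120), 120), 0.9)
  # windows outside the aligned span are undefined
  hit3 <- list(qaln = substr(tmpl, 10, 120), saln = substr(tmpl, 10, 120),
               qstart = 10, qend = 120, strand = "+")
  expect_true(is.na(conservationScore(hit3, c(1, 20), c(101, 120), 120)))
})

test_that("pair design obeys the product bound and ranks by conservation", {
  set.seed(43)
  # a locus below the minimum product yields no candidates
  expect_identical(nrow(designPairs(rndSeq(699))), 0L)

  tmpl <- rndSeq(1000)
  hit <- list(qaln = tmpl, saln = tmpl, qstart = 1, qend = 1000,
              strand = "+")
  dp <- designPairs(tmpl, hit = hit, locusId = "toy")
  expect_gt(nrow(dp), 0)
  expect_true(all(dp$product_length >= 700 & dp$product_length <= 1200))
  expect_true(all(dp$pair_3prime < 3))
  expect_equal(dp$conservation[1], 1.0)  # identical template/query
  expect_equal(dp$product_length,
               dp$rev_end - dp$fwd_start + 1L)

  # a planted mutation inside the top pair's forward window drops the
  # score by exactly 1 / (total primer-window bases)
  top <- dp[1, ]
  qry <- tmpl
  pos <- top$fwd_start + 2L
  old <- substr(qry, pos, pos)
  substr(qry, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  hit2 <- list(qaln = tmpl, saln = qry, qstart = 1, qend = 1000,
               strand = "+")
  sc <- conservationScore(hit2, c(top$fwd_start, top$fwd_end),
                          c(top$rev_start, top$rev_end), 1000)
  expect_equal(sc, 1 - 1 / (top$fwd_length + top$rev_length))

  # ranking is a total order: the ordering keys admit no duplicate
  keys <- paste(dp$conservation, abs(dp$product_length - 950),
                dp$fwd_start, dp$fwd_length, dp$rev_start, dp$rev_length)
  expect_false(any(duplicated(keys)))
})

test_that("emitted pairs re-validate under an independent checker", {
  set.seed(44)
  tmpl <- rndSeq(900)
  dp <- designPairs(tmpl, maxPairs = 25)
  expect_gt(nrow(dp), 0)
  for (i in seq_len(nrow(dp))) {
    f <- dp$fwd_seq[i]
    r <- dp$rev_seq[i]
    expect_identical(f, substr(tmpl, dp$fwd_start[i], dp$fwd_end[i]))
    expect_identical(r, rcSeq(substr(tmpl, dp$rev_start[i], dp$rev_end[i])))
    for (s in c(f, r)) {
      len <- nchar(s)
      gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / len
      expect_true(len >= 18 && len <= 25)
      expect_true(gc >= 0.20 && gc <= 0.80)
      expect_lt(bruteCompScore(s, s, FALSE), 6)
      expect_lt(bruteCompScore(s, s, TRUE), 3)
    }
    expect_lt(max(bruteCompScore(f, r, TRUE), bruteCompScore(r, f, TRUE)),
              3)
    expect_true(dp$product_length[i] >= 700 && dp$product_length[i] <= 1200)
  }
})
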