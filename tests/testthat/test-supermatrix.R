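test_that("concatenation sums partitions and pads missing taxa", {
  set.seed(71)
  l1 <- setNames(c(rndSeq(30), rndSeq(30), rndSeq(30)),
                 c("t1", "t2", "t3"))
  l2 <- setNames(c(rndSeq(20), rndSeq(20)), c("t1", "t3"))
  sm <- concatenateLoci(list(a = l1, b = l2))
  expect_identical(ncol(as.matrix(sm)), 50L)
  p <- lociPartitions(sm)
  expect_identical(p$start, c(1L, 31L))
  expect_identical(p$end, c(30L, 50L))
  # taxon missing a locus is gap-padded there
  expect_true(all(as.matrix(sm)["t2", 31:50] == "-"))

  # single locus: supermatrix equals the input
  sm1 <- concatenateLoci(list(only = l1))
  expect_identical(apply(as.matrix(sm1), 1, paste, collapse = ""),
                   l1)

  # duplicate taxon within one locus is an error
  bad <- setNames(c(rndSeq(10), rndSeq(10)), c("t1", "t1"))
  expect_error(concatenateLoci(list(x = bad)), "duplicate taxon")
})

test_that("splitting recovers inputs and locus order only permutes partitions", {
  set.seed(72)
  loci <- list(a = setNames(c(rndSeq(15), rndSeq(15)), c("t1", "t2")),
               b = setNames(c(rndSeq(25), rndSeq(25)), c("t1", "t2")),
               c = setNames(c(rndSeq(10), rndSeq(10)), c("t1", "t2")))
  sm <- concatenateLoci(loci)
  back <- splitSuperMatrix(sm)
  for (nm in names(loci)) {
    expect_identical(apply(back[[nm]], 1, paste, collapse = ""),
                     loci[[nm]])
  }
  # permuting locus order leaves each taxon's character multiset intact
  sm2 <- concatenateLoci(loci[c(3, 1, 2)])
  for (tx in c("t1", "t2")) {
    expect_identical(sort(as.matrix(sm)[tx, ]),
                     sort(as.matrix(sm2)[tx, ]))
  }
  # raw vs gap-stripped lengths
  lens <- supermatrixLengths(sm)
  expect_identical(lens$raw, 50L)
  expect_identical(lens$complete, 50L)
})

test_that("NJ solves the three-point formulas and is exact on additive input", {
  # 3 taxa: closed form branch lengths
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d3)
  co <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(co, d3, tolerance = 1e-9)

  # additive 4-taxon distances from ((A,B),(C,D)) with internal edge 1
  el <- c(A = 2, B = 3, C = 4, D = 5)
  d4 <- matrix(0, 4, 4, dimnames = list(names(el), names(el)))
  d4["A", "B"] <- d4["B", "A"] <- el["A"] + el["B"]
  d4["C", "D"] <- d4["D", "C"] <- el["C"] + el["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    d4[x, y] <- d4[y, x] <- el[x] + el[y] + 1
  tr4 <- njTree(d4)
  co4 <- ape::cophenetic.phylo(tr4)[names(el), names(el)]
  expect_equal(co4, d4, tolerance = 1e-9)
  # the AB|CD split is recovered
  splits <- ape::prop.part(tr4)
  expect_true(any(vapply(splits, function(s)
    setequal(tr4$tip.label[s], c("A", "B")) ||
      setequal(tr4$tip.label[s], c("C", "D")), logical(1))))

  # random additive matrices reproduce the generating tree exactly
  set.seed(73)
  for (r in 1:5) {
    gen <- ape::unroot(ape::rtree(6))
    dg <- ape::cophenetic.phylo(gen)
    tg <- njTree(dg)
    expect_equal(as.numeric(ape::dist.topo(gen, tg)), 0)
    expect_equal(ape::cophenetic.phylo(tg)[rownames(dg), colnames(dg)],
                 dg, tolerance = 1e-8)
  }

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  m <- d3
  m[1, 2] <- 99
  expect_error(njTree(m), "symmetric")
})

test_that("bootstrap support is deterministic, bounded and finds clear clades", {
  set.seed(74)
  base <- rndSeq(500)
  cladeB <- mutSeq(base, 0.35)
  aln <- c(A1 = base, A2 = mutSeq(base, 0.02), A3 = mutSeq(base, 0.02),
           B1 = cladeB, B2 = mutSeq(cladeB, 0.02),
           B3 = mutSeq(cladeB, 0.02))
  bs1 <- bootstrapSupport(aln, reps = 100, seed = 99)
  bs2 <- bootstrapSupport(aln, reps = 100, seed = 99)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 100))
  # the A|B split must be near-unanimous
  expect_gte(max(bs1$support), 95)
  expect_true(any(bs1$strong))
  expect_error(bootstrapSupport(aln, reps = 0), "reps")
})

test_that("validation summaries compute PSR per marker, order and overall", {
  cells <- rbind(
    good = c(rep(1L, 19), rep(0L, 4)),          # 19/23 = 82.6%
    bad  = c(rep(1L, 18), rep(0L, 5)),          # 18/23 = 78.3%
    void = rep(NA_integer_, 23))
  colnames(cells) <- sprintf("sp%02d", 1:23)
  vm <- validationMatrix(cells, orders = rep(c("o1", "o2"),
                                             length.out = 23))
  expect_warning(panel <- summarizeValidation(vm, threshold = 0.80),
                 "void")
  pm <- perMarkerPSR(panel)
  expect_equal(pm$psr[pm$marker == "good"], 19 / 23)
  expect_equal(pm$psr[pm$marker == "bad"], 18 / 23)
  expect_identical(panelMarkers(panel), "good")
  expect_equal(overallPSR(panel), 37 / 46)
  # counts always partition the cells
  expect_identical(pm$n_success + pm$n_failure + pm$n_not_attempted,
                   rep(23L, 3) * 1.0)
  po <- panel@perOrder
  expect_identical(sum(po$n_attempted), 46)
})
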