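test_that("polymorphism summaries follow the standard estimators", {
  # monomorphic sample
  h0 <- haplotypeAlignment(setNames(rep(rndSeq(50), 4), paste0("h", 1:4)))
  s0 <- popgenSummary(h0)
  expect_identical(s0@S, 0L)
  expect_identical(s0@H, 1L)
  expect_equal(s0@Hd, 0)
  expect_equal(s0@piPerSite, 0)
  expect_true(is.na(tajimaD(s0)))

  # n = 4 with haplotype counts (2,1,1): Hd = (4/3)(1 - 0.375)
  base <- rndSeq(60)
  v1 <- base
  substr(v1, 5, 5) <- if (substr(base, 5, 5) == "A") "C" else "A"
  v2 <- base
  substr(v2, 9, 9) <- if (substr(base, 9, 9) == "G") "T" else "G"
  s1 <- popgenSummary(haplotypeAlignment(
    c(a = base, b = base, c = v1, d = v2)))
  expect_identical(s1@H, 3L)
  expect_equal(s1@Hd, (4 / 3) * (1 - 0.375))

  # 3 sequences, L = 10, pairwise diffs {1,2,3}: k_hat = 2, pi = 0.2
  s2 <- popgenSummary(haplotypeAlignment(
    c(a = "AAAAAAAAAA", b = "TAAAAAAAAA", c = "TTTAAAAAAA"), "l", "p"))
  expect_equal(s2@kHat, 2.0)
  expect_equal(s2@piPerSite, 0.2)
  expect_identical(s2@S, 3L)
})

test_that("summaries are invariant to relabeling and reordering", {
  set.seed(61)
  h <- simulateCoalescentSample(coalescentConfig(n = 8, theta = 4,
                                                 L = 300, seed = 3))
  s <- popgenSummary(h)
  seqs <- as.character(haplotypes(h))
  perm <- sample(seq_along(seqs))
  s2 <- popgenSummary(haplotypeAlignment(
    setNames(seqs[perm], paste0("z", seq_along(seqs)))))
  expect_identical(s2@S, s@S)
  expect_identical(s2@H, s@H)
  expect_equal(s2@Hd, s@Hd)
  expect_equal(s2@piPerSite, s@piPerSite)
})

test_that("Tajima's D matches its defining formula", {
  # zero numerator
  n <- 10
  a1 <- sum(1 / (1:9))
  expect_equal(tajimasD(S = 5, kHat = 5 / a1, n = n), 0)
  # frozen value for n = 4, S = 3, k_hat = 2 (a1 = 11/6, a2 = 49/36)
  expect_equal(tajimasD(3, 2.0, 4), 2.01, tolerance = 0.01)
  # equality with an independent evaluation on random triples
  set.seed(62)
  for (r in 1:200) {
    n <- sample(4:60, 1)
    S <- sample(1:80, 1)
    khat <- runif(1, 0, S)
    expect_equal(tajimasD(S, khat, n), tajimaOracle(S, khat, n),
                 tolerance = 1e-9)
  }
  expect_true(is.na(tajimasD(0, 0, 10)))
  expect_error(tajimasD(3, 1, 3), "n >= 4")
})

test_that("HKA fits expectations exactly when observations sit on them", {
  theta <- c(0.004, 0.009)
  T <- 5
  n <- c(12, 12)
  Lp <- c(600, 800)
  Ld <- c(600, 800)
  a1 <- sum(1 / (1:11))
  S <- theta * Lp * a1
  D <- theta * Ld * (T + 13 / 24)
  fit <- hkaTest(data.frame(S = S, n = n, D = D, L_poly = Lp, L_div = Ld))
  expect_lt(fit@X2, 1e-6)
  expect_equal(fit@pValue, 1, tolerance = 1e-4)
  expect_equal(fit@thetaSite, theta, tolerance = 1e-3)
  expect_equal(fit@T, T, tolerance = 1e-2)
  expect_identical(fit@df, 1L)
})

test_that("HKA minimized X2 matches a grid-search oracle to 3 decimals", {
  tab <- data.frame(S = c(10, 2), n = c(10, 10), D = c(20, 22),
                    L_poly = c(500, 500), L_div = c(500, 500))
  fit <- hkaTest(tab)
  oracle <- hkaGridOracle(tab$S, tab$D, tab$n, tab$L_poly, tab$L_div)
  expect_equal(fit@X2, oracle$X2, tolerance = 5e-4)
  # minimizer optimality: fitted X2 never exceeds any oracle grid point
  expect_lte(fit@X2, oracle$X2 + 5e-4)
})

test_that("HKA scaling: doubling counts and lengths doubles per-locus theta", {
  # observations on the model surface, so the minimum is exact
  theta <- c(0.006, 0.003)
  T <- 4.5
  n <- c(10, 10)
  Lp <- c(500, 400)
  a1 <- sum(1 / (1:9))
  tab <- data.frame(S = theta * Lp * a1, n = n,
                    D = theta * Lp * (T + 11 / 20),
                    L_poly = Lp, L_div = Lp)
  f1 <- hkaTest(tab)
  tab2 <- data.frame(S = 2 * tab$S, n = tab$n, D = 2 * tab$D,
                     L_poly = 2 * tab$L_poly, L_div = 2 * tab$L_div)
  f2 <- hkaTest(tab2)
  expect_equal(f2@thetaLocus, 2 * f1@thetaLocus, tolerance = 1e-3)
  expect_equal(f2@T, f1@T, tolerance = 1e-3)
  expect_error(hkaTest(tab[1, , drop = FALSE]), "at least 2 loci")
})

test_that("per-population reports include pooled rows with monotone S", {
  set.seed(63)
  mk <- function(locus, pop, seed)
    local({
      h <- simulateCoalescentSample(coalescentConfig(n = 6, theta = 3,
                                                     L = 200, seed = seed))
      h@locusId <- locus
      h@populationId <- pop
      h
    })
  dataset <- list(mk("l1", "p1", 1), mk("l1", "p2", 2),
                  mk("l2", "p1", 3), mk("l2", "p2", 4))
  rep <- perPopulationReport(dataset)
  expect_identical(nrow(rep), 6L)  # 4 per-population + 2 pooled rows
  for (lc in c("l1", "l2")) {
    pooledS <- rep$S[rep$locus == lc & rep$population == "pooled"]
    perPopS <- rep$S[rep$locus == lc & rep$population != "pooled"]
    expect_gte(pooledS, max(perPopS))
  }
  # a planted monomorphic locus reports NA for Tajima's D
  mono <- haplotypeAlignment(setNames(rep(rndSeq(80), 5), paste0("h", 1:5)),
                             locusId = "mono", populationId = "p1")
  repM <- perPopulationReport(list(mono))
  expect_true(all(is.na(repM$tajima_D)))
})
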