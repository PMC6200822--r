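# Independent oracles and small fixture builders. Everything here is
# deliberately written from first principles (or delegated to an
# unrelated library) so that it never shares code with the package
# implementation it checks.

BASES <- c("A", "C", "G", "T")

rndSeq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

# independent per-site mutator (uniform to the 3 alternatives)
mutSeq <- function(s, d) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(runif(length(x)) < d)
  if (length(i))
    x[i] <- vapply(x[i], function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
  paste(x, collapse = "")
}

rcSeq <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
}

# Smith-Waterman oracle: exact local alignment via Biostrings, same
# scoring scheme as the package's aligner defaults.
swOracle <- function(q, s, match = 1, mismatch = -2, gapOpen = 5,
                     gapExt = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = gapOpen,
                                      gapExtension = gapExt)
  list(score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) /
         nchar(as.character(Biostrings::pattern(pa))))
}

# brute-force antiparallel complementarity score (enumerates offsets)
bruteCompScore <- function(a, b, anchor3 = FALSE) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  la <- length(a)
  lb <- length(b)
  best <- 0L
  for (s in (-(lb - 1)):(la - 1)) {
    lo <- max(1, s + 1)
    hi <- min(la, s + lb)
    if (lo > hi) next
    if (anchor3 && hi != la) next
    sc <- 0L
    for (i in lo:hi) {
      j <- lb - (i - s - 1)       # antiparallel partner in b
      sc <- sc + if (identical(unname(comp[a[i]]), b[j])) 1L else -1L
    }
    best <- max(best, sc)
  }
  best
}

# brute-force valid-primer enumeration over a window
brutePrimers <- function(template, from, to, lenMin = 18, lenMax = 25,
                         gcMin = 0.20, gcMax = 0.80, selfAnyMax = 6,
                         self3Max = 3) {
  out <- character(0)
  for (st in from:to) for (len in lenMin:lenMax) {
    en <- st + len - 1
    if (en > nchar(template)) next
    s <- substr(template, st, en)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!ch %in% BASES)) next
    gc <- sum(ch %in% c("G", "C")) / len
    if (gc < gcMin || gc > gcMax) next
    if (bruteCompScore(s, s, FALSE) >= selfAnyMax) next
    if (bruteCompScore(s, s, TRUE) >= self3Max) next
    out <- c(out, paste(st, len))
  }
  out
}

# independent Tajima's D evaluation (Tajima 1989 constants, re-derived)
tajimaOracle <- function(S, khat, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# HKA X2 objective, written independently from the package
hkaX2Oracle <- function(theta, T, S, D, n, Lp, Ld) {
  x <- 0
  for (i in seq_along(S)) {
    j <- seq_len(n[i] - 1)
    a1 <- sum(1 / j)
    a2 <- sum(1 / j^2)
    cS <- theta[i] * Lp[i]
    cD <- theta[i] * Ld[i]
    cf <- (n[i] + 1) / (2 * n[i])
    ES <- cS * a1
    VS <- ES + cS^2 * a2
    ED <- cD * (T + cf)
    VD <- ED + (cD * cf)^2
    x <- x + (S[i] - ES)^2 / VS + (D[i] - ED)^2 / VD
  }
  x
}

# refining grid-search minimizer of the two-locus HKA objective
hkaGridOracle <- function(S, D, n, Lp, Ld, thetaRange = c(5e-4, 0.03),
                          TRange = c(0.2, 40)) {
  best <- c(NA, NA, NA, Inf)
  g1 <- seq(thetaRange[1], thetaRange[2], length.out = 30)
  g2 <- g1
  gT <- seq(TRange[1], TRange[2], length.out = 30)
  scan <- function(g1, g2, gT, best) {
    for (a in g1) for (b in g2) for (T in gT) {
      v <- hkaX2Oracle(c(a, b), T, S, D, n, Lp, Ld)
      if (v < best[4]) best <- c(a, b, T, v)
    }
    best
  }
  best <- scan(g1, g2, gT, best)
  w1 <- diff(range(g1))
  wT <- diff(range(gT))
  for (zoom in 1:4) {
    w1 <- w1 / 6
    wT <- wT / 6
    best <- scan(seq(max(best[1] - w1, 1e-6), best[1] + w1, length.out = 21),
                 seq(max(best[2] - w1, 1e-6), best[2] + w1, length.out = 21),
                 seq(max(best[3] - wT, 1e-3), best[3] + wT, length.out = 21),
                 best)
  }
  list(theta = best[1:2], T = best[3], X2 = best[4])
}

# small deterministic validation matrix builder
toyValidationMatrix <- function(nSuccess, nFailure, nNA = 0, nrowM = NULL) {
  total <- nSuccess + nFailure + nNA
  if (is.null(nrowM)) {
    nrowM <- max(1L, as.integer(floor(sqrt(total))))
    while (total %% nrowM != 0L) nrowM <- nrowM - 1L
  }
  vals <- c(rep(1L, nSuccess), rep(0L, nFailure), rep(NA_integer_, nNA))
  cells <- matrix(vals, nrow = nrowM)
  dimnames(cells) <- list(sprintf("m%03d", seq_len(nrow(cells))),
                          sprintf("sp%03d", seq_len(ncol(cells))))
  validationMatrix(cells,
                   orders = rep(sprintf("ord%d", 1:2),
                                length.out = ncol(cells)))
}
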