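#' Construct a HaplotypeAlignment
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector of
#'   phased haplotypes of equal length (n >= 2).
#' @param locusId,populationId identifiers.
#' @param ploidy haplotypes per individual (2 for nuclear loci, 1 for
#'   mtDNA); bookkeeping only.
#' @return A [HaplotypeAlignment-class] object.
#' @export
haplotypeAlignment <- function(seqs, locusId = "locus",
                               populationId = "pop", ploidy = 2L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- paste0("hap", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  methods::new("HaplotypeAlignment", seqs = seqs, locusId = locusId,
               populationId = populationId, ploidy = as.integer(ploidy))
}

#' Tajima (1989) constants for a sample of n sequences
#'
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`;
#' `b1 = (n+1)/(3(n-1))`; `b2 = 2(n^2+n+3)/(9n(n-1))`; `c1 = b1 - 1/a1`;
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`; `e1 = c1/a1`;
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n sample size (>= 2; the test itself needs n >= 4).
#' @return named list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 2)
  a1 <- harmonicA1(n)
  a2 <- harmonicA2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from summary quantities
#'
#' `D = (kHat - S/a1) / sqrt(e1 S + e2 S (S-1))`: the normalized
#' difference between the pairwise-difference and segregating-sites
#' estimators of theta. Undefined (`NA`) for monomorphic data (S = 0);
#' requires n >= 4.
#'
#' @param S number of segregating sites.
#' @param kHat mean pairwise differences.
#' @param n number of sampled haplotypes.
#' @return Tajima's D, or `NA_real_` when S = 0.
#' @export
tajimasD <- function(S, kHat, n) {
  if (S == 0) return(NA_real_)
  if (n < 4) stop("Tajima's D requires n >= 4")
  k <- tajimaConstants(n)
  (kHat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Polymorphism summary of a haplotype alignment
#'
#' Computes the segregating sites S (columns with at least two distinct
#' A/C/G/T bases; gap/N excluded per column), the number of distinct
#' haplotypes H, haplotype diversity `Hd = n(1 - sum p_i^2)/(n - 1)`,
#' the mean pairwise difference count kHat (pairwise deletion) and the
#' per-site nucleotide diversity `pi = kHat / L_used` where `L_used` is
#' the mean number of comparable sites per pair. Tajima's D is attached
#' (`NA` when S = 0).
#'
#' @param haps a [HaplotypeAlignment-class] (or DNAStringSet / named
#'   character vector, coerced with default ids).
#' @return A [PopGenStats-class] object.
#' @examples
#' h <- haplotypeAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
#'                           c = "ACCTACGTAC", d = "ACCTACTTAC"))
#' popgenSummary(h)
#' @export
popgenSummary <- function(haps) {
  if (!methods::is(haps, "HaplotypeAlignment"))
    haps <- haplotypeAlignment(haps)
  m <- asAlignmentMatrix(haplotypes(haps))
  n <- nrow(m)
  L <- ncol(m)
  S <- sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% DNA_BASES])) >= 2L
  }))
  seqs <- apply(m, 1L, paste, collapse = "")
  tab <- table(seqs)
  H <- length(tab)
  p <- as.numeric(tab) / n
  Hd <- if (H == 1L) 0 else n * (1 - sum(p^2)) / (n - 1)
  ind <- pairSiteIndicators(m)
  comp <- rowSums(ind$comp)
  if (any(comp == 0L)) stop("pair(s) with zero comparable sites")
  kHat <- mean(rowSums(ind$mis))
  piPerSite <- kHat / mean(comp)
  D <- if (n >= 4L) tajimasD(S, kHat, n) else NA_real_
  methods::new("PopGenStats", locusId = haps@locusId,
               populationId = haps@populationId, n = as.integer(n),
               L = as.integer(L), S = as.integer(S), H = as.integer(H),
               Hd = Hd, kHat = kHat, piPerSite = piPerSite, tajimaD = D)
}

#' Per-locus, per-population polymorphism report
#'
#' One row per locus x population plus one pooled row per locus (all
#' populations combined). Nucleotide diversity is reported both per site
#' and x10^-3 for display comparability.
#'
#' @param dataset list of [HaplotypeAlignment-class] objects.
#' @return data.frame with locus, population, n, L, S, H, Hd, k_hat,
#'   pi, pi_x1000, tajima_D; pooled rows have population `"pooled"`.
#' @export
perPopulationReport <- function(dataset) {
  statRow <- function(st) {
    data.frame(locus = st@locusId, population = st@populationId,
               n = st@n, L = st@L, S = st@S, H = st@H, Hd = st@Hd,
               k_hat = st@kHat, pi = st@piPerSite,
               pi_x1000 = 1000 * st@piPerSite, tajima_D = st@tajimaD,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(dataset, function(h) statRow(popgenSummary(h)))
  loci <- vapply(dataset, function(h) h@locusId, character(1))
  pooled <- lapply(unique(loci), function(lc) {
    hs <- dataset[loci == lc]
    seqs <- do.call(c, lapply(hs, haplotypes))
    names(seqs) <- make.unique(names(seqs))
    pooledHap <- haplotypeAlignment(as.character(seqs), locusId = lc,
                                    populationId = "pooled",
                                    ploidy = hs[[1]]@ploidy)
    statRow(popgenSummary(pooledHap))
  })
  out <- do.call(rbind, c(rows, pooled))
  rownames(out) <- NULL
  out
}
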