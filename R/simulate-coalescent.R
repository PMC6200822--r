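#' Configuration for the infinite-sites coalescent sampler
#'
#' @param n sample size (haplotypes, >= 2).
#' @param theta population mutation parameter per locus (> 0), on the
#'   standard coalescent scale where `E[S] = theta * a1(n)` and the mean
#'   pairwise difference count has expectation theta.
#' @param L locus length in sites (mutations occupy distinct columns).
#' @param nLoci number of independent replicate loci.
#' @param seed master RNG seed; per-locus child seeds derive from it so
#'   any locus subset is reproducible independently.
#' @return A named list of class `coalescentConfig`.
#' @export
coalescentConfig <- function(n = 10L, theta = 5, L = 1000L, nLoci = 1L,
                             seed = 1L) {
  stopifnot(n >= 2, theta > 0, L >= 1, nLoci >= 1)
  structure(list(n = as.integer(n), theta = theta, L = as.integer(L),
                 nLoci = as.integer(nLoci), seed = as.integer(seed)),
            class = "coalescentConfig")
}

# One neutral coalescent genealogy (no recombination), Hudson's
# algorithm: k lineages coalesce at rate k(k-1)/2 in units of 2N
# generations. Returns the branches as (leaf set, length).
coalescentBranches <- function(n) {
  active <- lapply(seq_len(n), identity)   # leaf sets
  birth <- rep(0, n)                       # time each lineage arose
  t <- 0
  branches <- list()
  k <- n
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    for (p in pick)
      branches[[length(branches) + 1L]] <-
        list(leaves = active[[p]], len = t - birth[p])
    merged <- c(active[[pick[1]]], active[[pick[2]]])
    active[pick] <- NULL
    birth <- birth[-pick]
    active[[length(active) + 1L]] <- merged
    birth <- c(birth, t)
    k <- k - 1L
  }
  branches
}

#' Simulate haplotype samples under the infinite-sites coalescent
#'
#' Hudson's algorithm without recombination: exponential coalescence
#' times with rate `k(k-1)/2` (time in units of 2N generations),
#' mutations dropped as a Poisson process at rate `theta/2` per lineage
#' per unit time, each mutation occupying a distinct alignment column
#' (columns drawn without replacement from the L positions; exceeding L
#' is an infinite-sites violation error). Each mutated column carries the
#' derived base in exactly the leaves below its branch.
#'
#' @param cfg a [coalescentConfig()].
#' @return A single [HaplotypeAlignment-class] when `nLoci = 1`,
#'   otherwise a list of them (one per locus).
#' @export
simulateCoalescentSample <- function(cfg = coalescentConfig()) {
  stopifnot(inherits(cfg, "coalescentConfig"))
  one <- function(locusSeed, locusId) {
    withSeed(locusSeed, {
      br <- coalescentBranches(cfg$n)
      lens <- vapply(br, `[[`, numeric(1), "len")
      total <- sum(lens)
      S <- stats::rpois(1L, cfg$theta / 2 * total)
      if (S > cfg$L)
        stop("infinite-sites violation: ", S, " mutations exceed L = ",
             cfg$L, " sites (increase L)")
      anc <- strsplit(randomDNA(cfg$L), "", fixed = TRUE)[[1]]
      haps <- matrix(rep(anc, each = cfg$n), nrow = cfg$n)
      if (S > 0) {
        cols <- sample.int(cfg$L, S)                 # distinct positions
        which_br <- sample.int(length(br), S, replace = TRUE,
                               prob = lens / total)
        for (s in seq_len(S)) {
          col <- cols[s]
          derived <- sample(setdiff(DNA_BASES, anc[col]), 1L)
          haps[br[[which_br[s]]]$leaves, col] <- derived
        }
      }
      seqs <- apply(haps, 1L, paste, collapse = "")
      names(seqs) <- sprintf("hap%02d", seq_len(cfg$n))
      haplotypeAlignment(seqs, locusId = locusId, populationId = "sim",
                         ploidy = 2L)
    })
  }
  if (cfg$nLoci == 1L) return(one(cfg$seed, "locus1"))
  lapply(seq_len(cfg$nLoci), function(i)
    one(childSeed(cfg$seed, i), sprintf("locus%d", i)))
}
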