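# Per-pair site classification under pairwise deletion: columns where
# either base is not A/C/G/T (N, gap) are excluded for that pair.

PURINES <- c("A", "G")

# mismatch / transition / transversion / comparable indicator matrices,
# one row per unordered pair, one column per alignment site.
pairSiteIndicators <- function(m) {
  n <- nrow(m)
  prs <- utils::combn(n, 2L)
  P <- ncol(prs)
  good <- m %in% DNA_BASES
  dim(good) <- dim(m)
  comp <- good[prs[1L, ], , drop = FALSE] & good[prs[2L, ], , drop = FALSE]
  a <- m[prs[1L, ], , drop = FALSE]
  b <- m[prs[2L, ], , drop = FALSE]
  mis <- comp & (a != b)
  pur_a <- a %in% PURINES
  dim(pur_a) <- dim(a)
  pur_b <- b %in% PURINES
  dim(pur_b) <- dim(b)
  ts <- mis & (pur_a == pur_b)   # A<->G or C<->T
  list(pairs = prs, comp = comp, mis = mis, ts = ts, tv = mis & !ts)
}

# Model transforms: counts -> distance. Returns NaN where undefined.
distFromCounts <- function(model, comp, mis, ts, tv) {
  p <- mis / comp
  if (model == "p") return(p)
  if (model == "JC69") {
    arg <- 1 - 4 * p / 3
    return(ifelse(arg > 0, -0.75 * log(arg), NaN))
  }
  # K2P
  P <- ts / comp
  Q <- tv / comp
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  ifelse(a1 > 0 & a2 > 0, -0.5 * log(a1) - 0.25 * log(a2), NaN)
}

#' Pairwise genetic distance between two aligned sequences
#'
#' Distances are computed after pairwise deletion of columns containing
#' N or '-'. Models: `"p"` (proportion of differing sites), `"JC69"`
#' (`-(3/4) ln(1 - 4p/3)`) and `"K2P"` (from transition and transversion
#' proportions P, Q: `-(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`).
#'
#' @param a,b aligned DNA strings of equal length.
#' @param model distance model.
#' @return distance in substitutions/site. Errors if no comparable sites
#'   remain or the model correction is undefined (e.g. p >= 0.75 under
#'   JC69).
#' @examples
#' pairwiseDistance("AAAAAAAAAA", "AAAAAAAATT", "JC69")  # p = 0.2
#' @export
pairwiseDistance <- function(a, b, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  m <- asAlignmentMatrix(c(x = toupper(a), y = toupper(b)))
  ind <- pairSiteIndicators(m)
  comp <- sum(ind$comp)
  if (comp == 0L) stop("no comparable sites after pairwise deletion")
  d <- distFromCounts(model, comp, sum(ind$mis), sum(ind$ts), sum(ind$tv))
  if (is.nan(d))
    stop("distance undefined under ", model,
         " (saturation: log argument <= 0)")
  d
}

#' Overall mean pairwise distance of an alignment with bootstrap SE
#'
#' The overall mean distance is the mean of all unordered pairwise
#' distances. The standard error is estimated by bootstrapping alignment
#' columns: sites are resampled with replacement, the mean distance is
#' recomputed for each replicate, and the SE is the standard deviation
#' over replicates. Deterministic under a fixed seed.
#'
#' @param alignment a [Biostrings::DNAStringSet], named character vector
#'   or character matrix of aligned sequences (>= 2).
#' @param model distance model, see [pairwiseDistance()].
#' @param bootstrapReps number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param locusId identifier stored in the result.
#' @param onUndefined `"error"` (default) fails listing the offending
#'   pairs; `"drop"` removes them with a warning (from the point estimate
#'   and each replicate).
#' @return A [DistanceSummary-class] object.
#' @export
overallMeanDistance <- function(alignment, model = c("p", "JC69", "K2P"),
                                bootstrapReps = 1000L, seed = NULL,
                                locusId = "locus",
                                onUndefined = c("error", "drop")) {
  model <- match.arg(model)
  onUndefined <- match.arg(onUndefined)
  m <- asAlignmentMatrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  L <- ncol(m)
  ind <- pairSiteIndicators(m)
  comp <- rowSums(ind$comp)
  if (any(comp == 0L))
    stop("pair(s) with zero comparable sites: ",
         paste(apply(ind$pairs[, comp == 0L, drop = FALSE], 2L,
                     function(p) paste(rownames(m)[p], collapse = "-")),
               collapse = ", "))
  d <- distFromCounts(model, comp, rowSums(ind$mis), rowSums(ind$ts),
                      rowSums(ind$tv))
  bad <- is.nan(d)
  if (any(bad)) {
    pairNames <- apply(ind$pairs[, bad, drop = FALSE], 2L,
                       function(p) paste(rownames(m)[p], collapse = "-"))
    if (onUndefined == "error")
      stop("undefined ", model, " distance for pair(s): ",
           paste(pairNames, collapse = ", "))
    warning("dropping pair(s) with undefined distance: ",
            paste(pairNames, collapse = ", "))
  }
  use <- !bad
  dMean <- mean(d[use])

  # Site bootstrap via column-weight matrix products, in blocks.
  compM <- ind$comp * 1
  misM <- ind$mis * 1
  tsM <- ind$ts * 1
  tvM <- ind$tv * 1
  reps <- as.integer(bootstrapReps)
  boot <- numeric(reps)
  withSeed(seed, {
    done <- 0L
    while (done < reps) {
      nb <- min(250L, reps - done)
      W <- matrix(0, nrow = L, ncol = nb)
      for (r in seq_len(nb)) {
        idx <- sample.int(L, L, replace = TRUE)
        W[, r] <- tabulate(idx, nbins = L)
      }
      compR <- compM %*% W
      misR <- misM %*% W
      tsR <- tsM %*% W
      tvR <- tvM %*% W
      dR <- distFromCounts(model, compR, misR, tsR, tvR)
      dR[compR == 0] <- NaN
      boot[done + seq_len(nb)] <-
        apply(dR, 2L, function(col) mean(col[use & !is.nan(col)]))
      done <- done + nb
    }
  })
  methods::new("DistanceSummary", locusId = locusId, model = model,
               dMean = dMean, bootstrapSE = stats::sd(boot),
               nTaxa = nrow(m), nSitesUsed = mean(comp),
               nBootstrap = reps)
}

#' Calibrate a locus substitution rate against cytochrome b
#'
#' The locus rate is the ratio of its overall mean distance to the
#' cytochrome-b distance on the same taxa, multiplied by the reference
#' cyt-b rate of 0.01035 substitutions/site/million years.
#'
#' @param dLocus,dCytb [DistanceSummary-class] objects for the locus and
#'   for cytochrome b.
#' @param muCytb reference cyt-b rate, substitutions/site/My.
#' @return A [RateEstimate-class] object.
#' @examples
#' a <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTAC", s2 = "ACGAACGTAC"))
#' d <- overallMeanDistance(a, bootstrapReps = 10, seed = 1)
#' calibrateRate(d, d)  # identical distances: mu = 0.01035
#' @export
calibrateRate <- function(dLocus, dCytb, muCytb = 0.01035) {
  if (dMean(dCytb) == 0)
    stop("calibration undefined: cyt b mean distance is zero")
  ratio <- dMean(dLocus) / dMean(dCytb)
  methods::new("RateEstimate", locusId = locusId(dLocus), ratio = ratio,
               mu = ratio * muCytb, referenceRate = muCytb)
}

#' Rank calibrated rates and compare against reference loci
#'
#' Sorts rate estimates ascending by rate (stable, ties by locus id) and
#' counts how many loci are slower than, faster than, or tied with each
#' reference rate.
#'
#' @param rates list of [RateEstimate-class] objects.
#' @param references named numeric vector of reference rates in
#'   substitutions/site/My (e.g. `c(cytb = 0.01035)`).
#' @return list with `report` (data.frame sorted by rate) and
#'   `comparison` (data.frame of slower/faster/tied counts per
#'   reference).
#' @export
rankRates <- function(rates, references = c(cytb = 0.01035)) {
  stopifnot(length(rates) > 0)
  df <- data.frame(
    locus = vapply(rates, locusId, character(1)),
    ratio = vapply(rates, distanceRatio, numeric(1)),
    mu = vapply(rates, muRate, numeric(1)), stringsAsFactors = FALSE)
  df <- df[order(df$mu, df$locus), , drop = FALSE]
  rownames(df) <- NULL
  comparison <- data.frame(
    reference = names(references), rate = unname(references),
    n_slower = vapply(references, function(r) sum(df$mu < r), integer(1)),
    n_faster = vapply(references, function(r) sum(df$mu > r), integer(1)),
    n_tied = vapply(references, function(r) sum(df$mu == r), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(report = df, comparison = comparison)
}
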