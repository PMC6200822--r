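#' Primer constraint set
#'
#' The constraints applied to every candidate oligo: length 18-25 bases,
#' GC content 20-80%, self-complementarity score below 6.00 and
#' 3'-anchored self score below 3.00; primer pairs must additionally have
#' a 3'-anchored cross-complementarity score below 3.00 and a product of
#' 700-1200 bp. Scores use the +1/-1 antiparallel ungapped scheme of
#' [complementarityScore()], on the same scale as the thresholds.
#'
#' @param lenRange integer length bounds (inclusive).
#' @param gcRange GC fraction bounds (inclusive).
#' @param selfAnyMax strict upper bound on the self-complementarity score.
#' @param self3Max strict upper bound on the 3'-anchored self score.
#' @param pair3Max strict upper bound on the pair 3' score.
#' @param productRange product length bounds (inclusive), bases.
#' @return A named list of class `primerConstraints`.
#' @export
primerConstraints <- function(lenRange = c(18L, 25L),
                              gcRange = c(0.20, 0.80),
                              selfAnyMax = 6.0, self3Max = 3.0,
                              pair3Max = 3.0,
                              productRange = c(700L, 1200L)) {
  stopifnot(lenRange[1] >= 1, lenRange[2] >= lenRange[1],
            gcRange[1] >= 0, gcRange[2] <= 1,
            productRange[1] <= productRange[2])
  structure(list(lenRange = as.integer(lenRange), gcRange = gcRange,
                 selfAnyMax = selfAnyMax, self3Max = self3Max,
                 pair3Max = pair3Max,
                 productRange = as.integer(productRange)),
            class = "primerConstraints")
}

#' Antiparallel ungapped complementarity score
#'
#' The score is the maximum over all antiparallel ungapped offsets of the
#' sum of +1 per Watson-Crick complementary pair and -1 per
#' non-complementary pair in the overlap, floored at 0. With
#' `anchor3prime = TRUE` only offsets whose overlap includes the
#' 3'-terminal base of `a` are considered (the "3' complementarity" used
#' to screen primer pairs for extension-prone annealing). Self scores use
#' `b = a`.
#'
#' @param a,b DNA strings (A/C/G/T only).
#' @param anchor3prime require the overlap to cover the 3' end of `a`.
#' @return Integer score >= 0.
#' @examples
#' complementarityScore("AAAAAA", "AAAAAA")   # 0: A cannot pair with A
#' complementarityScore("GAATTC", "GAATTC")   # 6: perfect palindrome
#' @export
complementarityScore <- function(a, b = a, anchor3prime = FALSE) {
  .cppCompScore(toupper(a), toupper(b), isTRUE(anchor3prime))
}

# Melting temperature, closed form (reported, never filtered):
# Tm = 64.9 + 41 * (nGC - 16.4) / L.
primerTm <- function(nGC, len) 64.9 + 41 * (nGC - 16.4) / len

#' Enumerate all valid primers starting in a template window
#'
#' Returns every substring of the template with 5' start inside `window`
#' and an allowed length, that satisfies all single-primer constraints:
#' length, GC fraction (#G + #C over length), self-complementarity
#' (< `selfAnyMax`) and 3'-anchored self-complementarity (< `self3Max`).
#' Tm is reported from the closed form `64.9 + 41 (nGC - 16.4) / L` but
#' is not a filter. Enumeration is case-insensitive and independent of
#' sequence outside the window except that primers must fit on the
#' template.
#'
#' @param template DNA string (the sense strand of a locus).
#' @param window integer `c(start, end)` of allowed 5' start positions
#'   (1-based inclusive); default is the whole template.
#' @param constraints a [primerConstraints()] list.
#' @return data.frame with `sequence`, `start`, `end`, `length`,
#'   `gc_fraction`, `tm`, `self_any`, `self_3prime`, sorted by start then
#'   length. Windows shorter than the minimum primer length give zero
#'   rows.
#' @export
enumeratePrimers <- function(template, window = NULL,
                             constraints = primerConstraints()) {
  template <- toupper(as.character(template))
  L <- nchar(template)
  if (is.null(window)) window <- c(1L, L)
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > L || window[1] > window[2])
    stop("window must lie within the template")
  lens <- constraints$lenRange[1]:constraints$lenRange[2]
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  isGC <- cumsum(chars %in% c("G", "C"))
  rows <- list()
  for (len in lens) {
    starts <- window[1]:window[2]
    starts <- starts[starts + len - 1L <= L]
    if (!length(starts)) next
    ends <- starts + len - 1L
    ngc <- isGC[ends] - ifelse(starts > 1L, isGC[starts - 1L], 0L)
    gc <- ngc / len
    ok <- gc >= constraints$gcRange[1] & gc <= constraints$gcRange[2]
    # primers must be unambiguous DNA
    seqs <- substring(template, starts, ends)
    ok <- ok & !grepl("[^ACGT]", seqs)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = seqs[ok], start = starts[ok], end = ends[ok],
      length = len, gc_fraction = gc[ok],
      tm = primerTm(ngc[ok], len), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      gc_fraction = numeric(0), tm = numeric(0),
                      self_any = integer(0), self_3prime = integer(0)))
  out <- do.call(rbind, rows)
  sc <- .cppSelfScores(out$sequence)
  out$self_any <- sc[, 1]
  out$self_3prime <- sc[, 2]
  out <- out[out$self_any < constraints$selfAnyMax &
               out$self_3prime < constraints$self3Max, , drop = FALSE]
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-template-position identity profile from an ortholog hit's aligned
# strings: 1 identical column, 0 mismatch or gap, NA outside the aligned
# span. Template positions are on the sense sequence passed to the
# aligner; minus-strand hits are walked in reverse.
identityProfile <- function(hit, templateLength) {
  prof <- rep(NA_real_, templateLength)
  qa <- strsplit(hit$qaln, "", fixed = TRUE)[[1]]
  sa <- strsplit(hit$saln, "", fixed = TRUE)[[1]]
  strand <- if (!is.null(hit$strand)) hit$strand else "+"
  ci <- 0L
  for (col in seq_along(qa)) {
    if (qa[col] != "-") {
      ci <- ci + 1L
      pos <- if (strand == "+") hit$qstart + ci - 1L else hit$qend - ci + 1L
      prof[pos] <- as.numeric(qa[col] == sa[col] && sa[col] != "-")
    }
  }
  prof
}

#' Cross-genome conservation score of a primer pair
#'
#' Fraction of identical aligned columns within the union of the two
#' primer-binding windows, computed from a template-to-query alignment;
#' gap columns count as non-identical. If the alignment does not cover
#' both windows the score is undefined (`NA`) and the pair ranks below
#' every scored pair.
#'
#' @param hit one row of [screenOrthologs()] output (or any list with
#'   `qaln`, `saln`, `qstart`, `qend`, and optionally `strand`).
#' @param fwdWindow,revWindow integer `c(start, end)` template windows of
#'   the forward and reverse primer binding sites (1-based inclusive, on
#'   the template sense strand).
#' @param templateLength length of the template sequence.
#' @return A value in `[0, 1]`, or `NA` if a window is not covered.
#' @export
conservationScore <- function(hit, fwdWindow, revWindow, templateLength) {
  prof <- identityProfile(hit, templateLength)
  idx <- c(fwdWindow[1]:fwdWindow[2], revWindow[1]:revWindow[2])
  vals <- prof[idx]
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Design and rank primer pairs for a locus
#'
#' Enumerates valid forward primers (sense strand) and reverse primers
#' (reverse complements of sense-strand windows), forms all pairs whose
#' product length lies in `productRange`, rejects pairs with 3'-anchored
#' cross-complementarity >= `pair3Max`, and ranks the survivors by
#' cross-genome conservation score (descending), then product length
#' closest to 950 bp, then leftmost forward start (further deterministic
#' keys break residual ties). Product length is the inclusive span from
#' the forward 5' start to the reverse primer's 5' end on the template.
#'
#' On paper-scale loci full pair enumeration is combinatorial, so at most
#' `maxCandidatesPerSide` primers per side (the best by per-window
#' conservation, ties by position) enter pairing and at most `maxPairs`
#' ranked pairs are returned; small loci below the caps are enumerated
#' exhaustively.
#'
#' @param template the locus sense sequence (character), >= 700 bp for a
#'   non-empty result.
#' @param hit optional ortholog hit row (see [conservationScore()]); when
#'   supplied, pairing is restricted to the aligned (HSP) region and
#'   conservation scores are computed, otherwise conservation is `NA`.
#' @param constraints a [primerConstraints()] list (includes the product
#'   range).
#' @param locusId identifier copied into the report.
#' @param maxCandidatesPerSide,maxPairs enumeration caps.
#' @return data.frame, one ranked row per pair: forward/reverse primer
#'   fields, `product_length`, `pair_3prime`, `conservation`.
#' @export
designPairs <- function(template, hit = NULL,
                        constraints = primerConstraints(),
                        locusId = "locus", maxCandidatesPerSide = 200L,
                        maxPairs = 100L) {
  template <- toupper(as.character(template))
  L <- nchar(template)
  empty <- data.frame(locus_id = character(0), fwd_seq = character(0),
                      fwd_start = integer(0), fwd_end = integer(0),
                      fwd_length = integer(0), fwd_gc = numeric(0),
                      fwd_tm = numeric(0), rev_seq = character(0),
                      rev_start = integer(0), rev_end = integer(0),
                      rev_length = integer(0), rev_gc = numeric(0),
                      rev_tm = numeric(0), product_length = integer(0),
                      pair_3prime = integer(0), conservation = numeric(0))
  region <- c(1L, L)
  prof <- NULL
  if (!is.null(hit)) {
    region <- c(hit$qstart, hit$qend)
    prof <- identityProfile(hit, L)
  }
  if (region[2] - region[1] + 1L < constraints$productRange[1]) {
    message("locus ", locusId, ": region shorter than minimum product (",
            constraints$productRange[1], " bp); no candidates")
    return(empty)
  }
  fwd <- enumeratePrimers(template, window = region,
                          constraints = constraints)
  fwd <- fwd[fwd$end <= region[2], , drop = FALSE]
  # Reverse primers are revcomp oligos: the 3'-anchored self score is not
  # strand-invariant, so enumerate sense windows without that filter and
  # re-apply every self filter on the reverse-complement sequence.
  relaxed <- constraints
  relaxed$self3Max <- Inf
  rvs <- enumeratePrimers(template, window = region, constraints = relaxed)
  rvs <- rvs[rvs$end <= region[2], , drop = FALSE]
  if (nrow(rvs)) {
    rvs$sequence <- revCompVec(rvs$sequence)
    rsc <- .cppSelfScores(rvs$sequence)
    rvs$self_any <- rsc[, 1]
    rvs$self_3prime <- rsc[, 2]
    rvs <- rvs[rvs$self_any < constraints$selfAnyMax &
                 rvs$self_3prime < constraints$self3Max, , drop = FALSE]
  }
  if (!nrow(fwd) || !nrow(rvs)) return(empty)

  # per-primer window conservation sums (NA when uncovered), via cumsums
  csum <- function(s, e) {
    if (is.null(prof)) return(rep(NA_real_, length(s)))
    cs <- c(0, cumsum(ifelse(is.na(prof), 0, prof)))
    cn <- c(0L, cumsum(is.na(prof)))
    tot <- cs[e + 1L] - cs[s]
    nas <- cn[e + 1L] - cn[s]
    ifelse(nas > 0L, NA_real_, tot)
  }
  fwd$csum <- csum(fwd$start, fwd$end)
  rvs$csum <- csum(rvs$start, rvs$end)
  rev <- rvs

  # Cap each side by per-window conservation; positional tie-breaks pull
  # forward candidates left and reverse candidates right so capped sides
  # stay product-compatible. If a cap still leaves no in-range pair, it
  # is enlarged (x4) until pairs appear or the sides are exhausted.
  cap <- function(df, k, rightward) {
    if (nrow(df) <= k) return(df)
    sc <- df$csum / df$length
    posKey <- if (rightward) -df$start else df$start
    df[order(-ifelse(is.na(sc), -1, sc), posKey,
             df$length), , drop = FALSE][seq_len(k), ]
  }
  pr <- constraints$productRange
  k <- max(1L, as.integer(maxCandidatesPerSide))
  repeat {
    fwdC <- cap(fwd, k, rightward = FALSE)
    revC <- cap(rev, k, rightward = TRUE)
    idx <- expand.grid(f = seq_len(nrow(fwdC)), r = seq_len(nrow(revC)))
    product <- revC$end[idx$r] - fwdC$start[idx$f] + 1L
    keep <- product >= pr[1] & product <= pr[2] &
      revC$start[idx$r] > fwdC$end[idx$f]
    idx <- idx[keep, , drop = FALSE]
    product <- product[keep]
    if (nrow(idx) || (nrow(fwdC) == nrow(fwd) && nrow(revC) == nrow(rev)))
      break
    k <- k * 4L
  }
  fwd <- fwdC
  rev <- revC
  if (!nrow(idx)) return(empty)

  consv <- (fwd$csum[idx$f] + rev$csum[idx$r]) /
    (fwd$length[idx$f] + rev$length[idx$r])
  ord <- order(-ifelse(is.na(consv), -1, consv), abs(product - 950L),
               fwd$start[idx$f], fwd$length[idx$f], rev$start[idx$r],
               rev$length[idx$r])
  idx <- idx[ord, , drop = FALSE]
  product <- product[ord]
  consv <- consv[ord]

  # lazy 3'-complementarity filter down the ranking
  kept <- integer(0)
  p3 <- integer(0)
  i <- 1L
  block <- 512L
  while (length(kept) < maxPairs && i <= nrow(idx)) {
    j <- min(i + block - 1L, nrow(idx))
    sc <- .cppPair3Scores(fwd$sequence[idx$f[i:j]],
                          rev$sequence[idx$r[i:j]])
    ok <- which(sc < constraints$pair3Max)
    take <- ok[seq_len(min(length(ok), maxPairs - length(kept)))]
    kept <- c(kept, i - 1L + take)
    p3 <- c(p3, sc[take])
    i <- j + 1L
  }
  if (!length(kept)) return(empty)
  f <- fwd[idx$f[kept], ]
  r <- rev[idx$r[kept], ]
  data.frame(locus_id = locusId, fwd_seq = f$sequence,
             fwd_start = f$start, fwd_end = f$end, fwd_length = f$length,
             fwd_gc = f$gc_fraction, fwd_tm = f$tm,
             rev_seq = r$sequence, rev_start = r$start, rev_end = r$end,
             rev_length = r$length, rev_gc = r$gc_fraction, rev_tm = r$tm,
             product_length = product[kept], pair_3prime = p3,
             conservation = consv[kept], stringsAsFactors = FALSE,
             row.names = NULL)
}
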