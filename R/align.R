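#' Aligner parameter set
#'
#' BLASTN-like defaults for the internal seed-and-extend local aligner:
#' match +1, mismatch -2, gap open -5, gap extend -2 (a gap of length g
#' costs `gapOpen + g * gapExtend`), 11-mer seeds, X-drop 20. `bandPad`
#' widens the diagonal band around each seed cluster; `minScore` and
#' `maxHits` prune the hit list.
#'
#' @param match,mismatch substitution scores (mismatch negative).
#' @param gapOpen,gapExtend affine gap penalties (negative).
#' @param k seed length (exact k-mer match), 4..15.
#' @param xdrop score drop-off terminating band extension.
#' @param bandPad extra diagonals allowed on each side of a seed cluster.
#' @param minScore minimum reported hit score; defaults to `k * match`.
#' @param maxHits maximum hits returned per strand.
#' @return A named list of class `alignParams`.
#' @export
alignParams <- function(match = 1L, mismatch = -2L, gapOpen = -5L,
                        gapExtend = -2L, k = 11L, xdrop = 20L,
                        bandPad = 32L, minScore = NULL, maxHits = 50L) {
  stopifnot(match > 0, mismatch < 0, gapOpen <= 0, gapExtend < 0,
            k >= 4, k <= 15, xdrop > 0, bandPad >= 4)
  if (is.null(minScore)) minScore <- k * match
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend), k = as.integer(k),
                 xdrop = as.integer(xdrop), bandPad = as.integer(bandPad),
                 minScore = as.integer(minScore),
                 maxHits = as.integer(maxHits)),
            class = "alignParams")
}

#' Seeded local alignment of a query against a subject sequence
#'
#' Internal BLASTN-like aligner: exact k-mer seeds are grouped into
#' diagonal bands and each band is extended by a banded affine-gap local
#' dynamic program with X-drop row termination. Because the search space
#' is a strict subset of the full dynamic program, reported scores never
#' exceed the Smith-Waterman optimum under the same scoring scheme.
#'
#' Identity is `matches / alnLength` over alignment columns (gap columns
#' count in the denominator only); `queryCoverage` is
#' `min(1, alnLength / nchar(query))`.
#'
#' @param query,subject DNA strings (character scalars or XString-like).
#' @param params an [alignParams()] list.
#' @param strand `"both"` (default) also scans the reverse complement of
#'   the query; `"+"` / `"-"` restrict to one orientation.
#' @return A data.frame of hits sorted by score (descending), with
#'   columns `qstart`, `qend`, `sstart`, `send` (1-based inclusive, query
#'   coordinates always on the input query), `strand`, `score`,
#'   `alnLength`, `matches`, `identity`, `queryCoverage`, and the aligned
#'   strings `qaln` / `saln`. Sequences shorter than `k` give an empty
#'   result.
#' @examples
#' s <- paste(rep("ACGTTGCA", 20), collapse = "")
#' localAlign(s, s)[, 1:9]
#' @export
localAlign <- function(query, subject, params = alignParams(),
                       strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  query <- toupper(as.character(query))
  subject <- toupper(as.character(subject))
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("query and subject must be non-empty")
  qlen <- nchar(query)
  one <- function(qseq, str) {
    h <- .cppLocalAlign(qseq, subject, params$match, params$mismatch,
                        params$gapOpen, params$gapExtend, params$k,
                        params$xdrop, params$bandPad, params$minScore,
                        params$maxHits)
    if (nrow(h) == 0L) return(cbind(h, strand = character(0)))
    h$strand <- str
    if (str == "-") {  # map coords back onto the input query
      qs <- qlen - h$qend + 1L
      qe <- qlen - h$qstart + 1L
      h$qstart <- qs
      h$qend <- qe
    }
    h
  }
  res <- list()
  if (strand %in% c("both", "+")) res <- c(res, list(one(query, "+")))
  if (strand %in% c("both", "-"))
    res <- c(res, list(one(revComp(query), "-")))
  out <- do.call(rbind, res)
  if (nrow(out)) {
    out$identity <- out$matches / out$alnLength
    out$queryCoverage <- pmin(1, out$alnLength / qlen)
    out <- out[order(-out$score, out$sstart), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$identity <- numeric(0)
    out$queryCoverage <- numeric(0)
  }
  out[, c("qstart", "qend", "sstart", "send", "strand", "score",
          "alnLength", "matches", "identity", "queryCoverage",
          "qaln", "saln")]
}

#' Mine long exons from an annotated genome
#'
#' Returns the annotated exons strictly longer than `minLen - 1` bases
#' (default keeps exons > 600 bp, i.e. length >= 601) with their
#' sequences extracted strand-aware: minus-strand exons are stored
#' 5'->3' after reverse complementation, so downstream primer design
#' always operates on the sense sequence.
#'
#' @param genome a [Biostrings::DNAStringSet] (chromosomes/contigs).
#' @param annotation a [GenomicRanges::GRanges] of exons with `exon_id`
#'   and `gene_id` metadata (e.g. from [readGff3Exons()]).
#' @param minLen minimum exon length kept (inclusive); 601 implements the
#'   "> 600 bp" rule.
#' @return A [GenomicRanges::GRanges] with metadata columns `exon_id`,
#'   `gene_id`, `sequence` (character, sense strand) and `length_bp`.
#' @export
mineExons <- function(genome, annotation, minLen = 601L) {
  sn <- as.character(GenomicRanges::seqnames(annotation))
  missing_seq <- setdiff(unique(sn), names(genome))
  if (length(missing_seq))
    stop("annotation references sequences absent from genome: ",
         paste(missing_seq, collapse = ", "))
  keep <- GenomicRanges::width(annotation) >= minLen
  ex <- annotation[keep]
  if (length(ex) == 0L) return(ex)
  sn <- as.character(GenomicRanges::seqnames(ex))
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  too_long <- en > Biostrings::width(genome)[match(sn, names(genome))]
  if (any(too_long))
    stop("exon span exceeds contig length: ",
         paste(ex$exon_id[too_long], collapse = ", "))
  seqs <- character(length(ex))
  for (i in seq_along(ex)) {
    s <- Biostrings::subseq(genome[[sn[i]]], st[i], en[i])
    if (as.character(GenomicRanges::strand(ex))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  ex$sequence <- seqs
  ex$length_bp <- nchar(seqs)
  ex
}

# Orthology / duplicate acceptance rule: both thresholds strict
# ("more than 80%", "more than 50%").
orthoPass <- function(identity, coverage, minIdentity, minCoverage) {
  identity > minIdentity & coverage > minCoverage
}

#' Flag single-copy exons by a within-genome duplicate scan
#'
#' An exon is single-copy iff its only within-genome hit passing the
#' homology thresholds (identity > `minIdentity`, query coverage >
#' `minCoverage`) is its own locus. The self-hit is recognised by
#' genomic overlap with the exon's own span on its own chromosome.
#'
#' @param exons output of [mineExons()] (must carry `sequence` and
#'   coordinates on `genome`).
#' @param genome the same genome the exons were mined from.
#' @param minIdentity,minCoverage strict thresholds of the homology rule.
#' @param params aligner parameters, see [alignParams()].
#' @return `exons` with an added logical metadata column `single_copy`.
#' @export
markSingleCopy <- function(exons, genome, minIdentity = 0.80,
                           minCoverage = 0.50, params = alignParams()) {
  single <- logical(length(exons))
  sn <- as.character(GenomicRanges::seqnames(exons))
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  for (i in seq_along(exons)) {
    dup <- FALSE
    for (chrom in names(genome)) {
      hits <- localAlign(exons$sequence[i], genome[[chrom]],
                         params = params, strand = "both")
      if (nrow(hits) == 0L) next
      pass <- orthoPass(hits$identity, hits$queryCoverage,
                        minIdentity, minCoverage)
      hits <- hits[pass, , drop = FALSE]
      if (nrow(hits) == 0L) next
      is_self <- chrom == sn[i] &
        pmin(hits$send, en[i]) - pmax(hits$sstart, st[i]) + 1 >
          0.5 * (en[i] - st[i] + 1)
      if (any(!is_self)) { dup <- TRUE; break }
    }
    single[i] <- !dup
  }
  exons$single_copy <- single
  exons
}

#' Screen single-copy exons for orthologs in a query genome
#'
#' For each template exon, the best local-alignment hit against the query
#' genome (both strands, highest score, ties broken by lower subject
#' coordinate) is retained as the orthologous exon iff its identity
#' exceeds `minIdentity` and its template coverage exceeds `minCoverage`
#' (both strict). Exons not flagged single-copy are excluded up front.
#'
#' @param exons output of [markSingleCopy()] (or [mineExons()], in which
#'   case all exons are treated as single-copy).
#' @param queryGenome a [Biostrings::DNAStringSet] to scan.
#' @param minIdentity,minCoverage strict orthology thresholds (defaults
#'   0.80 and 0.50).
#' @param params aligner parameters, see [alignParams()].
#' @param keepSecondary if TRUE, attach all passing hits as an attribute
#'   `"secondary"` for diagnostics.
#' @return A data.frame with one row per retained exon: `exon_id`,
#'   `gene_id`, `query_id`, `strand`, `qstart`, `qend`, `sstart`, `send`,
#'   `score`, `alnLength`, `matches`, `identity`, `coverage`, `qaln`,
#'   `saln`.
#' @export
screenOrthologs <- function(exons, queryGenome, minIdentity = 0.80,
                            minCoverage = 0.50, params = alignParams(),
                            keepSecondary = FALSE) {
  if (!is.null(exons$single_copy)) exons <- exons[exons$single_copy]
  rows <- list()
  secondary <- list()
  for (i in seq_along(exons)) {
    best <- NULL
    for (chrom in names(queryGenome)) {
      hits <- localAlign(exons$sequence[i], queryGenome[[chrom]],
                         params = params, strand = "both")
      if (nrow(hits) == 0L) next
      hits$query_id <- chrom
      top <- hits[1L, , drop = FALSE]   # sorted by score, then sstart
      if (is.null(best) || top$score > best$score ||
          (top$score == best$score && top$sstart < best$sstart))
        best <- top
      if (keepSecondary) secondary[[length(secondary) + 1L]] <- hits
    }
    if (is.null(best)) next
    if (orthoPass(best$identity, best$queryCoverage,
                  minIdentity, minCoverage)) {
      rows[[length(rows) + 1L]] <- data.frame(
        exon_id = exons$exon_id[i], gene_id = exons$gene_id[i],
        query_id = best$query_id, strand = best$strand,
        qstart = best$qstart, qend = best$qend,
        sstart = best$sstart, send = best$send, score = best$score,
        alnLength = best$alnLength, matches = best$matches,
        identity = best$identity, coverage = best$queryCoverage,
        qaln = best$qaln, saln = best$saln,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exon_id = character(0), gene_id = character(0),
               query_id = character(0), strand = character(0),
               qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0), score = integer(0),
               alnLength = integer(0), matches = integer(0),
               identity = numeric(0), coverage = numeric(0),
               qaln = character(0), saln = character(0),
               stringsAsFactors = FALSE)
  if (keepSecondary)
    attr(out, "secondary") <- if (length(secondary))
      do.call(rbind, secondary) else NULL
  out
}
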