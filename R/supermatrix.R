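#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Taxon ids are matched across loci; a taxon missing a locus is padded
#' with `'-'` over that partition. Column count equals the sum of locus
#' alignment lengths, and the partition table records each locus's span
#' (1-based inclusive), ready for [writeRaxmlPartitions()].
#'
#' @param loci named list of per-locus alignments (DNAStringSet, named
#'   character vector, or character matrix with taxon rownames).
#' @return A [SuperMatrix-class] object. A duplicated taxon id within one
#'   locus is an error.
#' @export
concatenateLoci <- function(loci) {
  stopifnot(length(loci) >= 1L)
  if (is.null(names(loci)))
    names(loci) <- paste0("locus", seq_along(loci))
  mats <- lapply(loci, asAlignmentMatrix)
  for (nm in names(mats)) {
    if (anyDuplicated(rownames(mats[[nm]])))
      stop("duplicate taxon id within locus ", nm)
  }
  taxa <- unique(unlist(lapply(mats, rownames)))
  lens <- vapply(mats, ncol, integer(1))
  total <- sum(lens)
  out <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  at <- 1L
  parts <- data.frame(locus = names(mats), start = integer(length(mats)),
                      end = integer(length(mats)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(mats)) {
    span <- at:(at + lens[i] - 1L)
    out[rownames(mats[[i]]), span] <- mats[[i]]
    parts$start[i] <- at
    parts$end[i] <- at + lens[i] - 1L
    at <- at + lens[i]
  }
  methods::new("SuperMatrix", matrix = out, partitions = parts)
}

#' Split a supermatrix back into per-locus alignments
#'
#' Inverse of [concatenateLoci()] up to gap-padding of missing taxa:
#' returns one character matrix per partition.
#'
#' @param sm a [SuperMatrix-class].
#' @return Named list of character matrices.
#' @export
splitSuperMatrix <- function(sm) {
  p <- lociPartitions(sm)
  m <- as.matrix(sm)
  out <- lapply(seq_len(nrow(p)), function(i)
    m[, p$start[i]:p$end[i], drop = FALSE])
  names(out) <- p$locus
  out
}

#' Gap-stripped and raw column counts of a supermatrix
#'
#' @param sm a [SuperMatrix-class].
#' @return list with `raw` (all columns) and `complete` (columns where
#'   every taxon has an A/C/G/T base).
#' @export
supermatrixLengths <- function(sm) {
  m <- as.matrix(sm)
  good <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  list(raw = ncol(m), complete = sum(colSums(good) == nrow(m)))
}

#' Pairwise p-distance matrix of aligned sequences
#'
#' Proportion of differing sites per pair under pairwise deletion;
#' convenience input for [njTree()].
#'
#' @param alignment alignment accepted by [overallMeanDistance()], or a
#'   [SuperMatrix-class].
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
pDistanceMatrix <- function(alignment) {
  if (methods::is(alignment, "SuperMatrix"))
    alignment <- as.matrix(alignment)
  m <- asAlignmentMatrix(alignment)
  ind <- pairSiteIndicators(m)
  comp <- rowSums(ind$comp)
  if (any(comp == 0L)) stop("pair(s) with zero comparable sites")
  p <- rowSums(ind$mis) / comp
  out <- matrix(0, nrow(m), nrow(m),
                dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(ncol(ind$pairs))) {
    i <- ind$pairs[1L, k]
    j <- ind$pairs[2L, k]
    out[i, j] <- out[j, i] <- p[k]
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; exact on additive
#' distance matrices (topology and branch lengths). Deterministic given
#' the input row order.
#'
#' @param d symmetric zero-diagonal distance matrix (>= 3 taxa) or a
#'   `dist` object.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
njTree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
    if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  } else if (attr(d, "Size") < 3L) {
    stop("neighbor joining needs at least 3 taxa")
  }
  ape::nj(stats::as.dist(as.matrix(d)))
}

#' Bootstrap split support for a supermatrix tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree for
#' each replicate with `treeFun`, and reports for each internal edge of
#' the full-data tree the percentage of replicate trees containing that
#' split. Supports >= `strongThreshold` (default 70) are flagged strong
#' (metadata, not a filter). Deterministic under a fixed seed.
#'
#' @param sm a [SuperMatrix-class] or character matrix of aligned
#'   sequences.
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param treeFun function(character matrix) -> phylo; default is NJ on
#'   the p-distance matrix.
#' @param strongThreshold support percentage flagged as strong.
#' @return list with `tree` (phylo, node labels = support percentages),
#'   `support` (numeric per internal node, in `[0, 100]`) and `strong`
#'   (logical).
#' @export
bootstrapSupport <- function(sm, reps = 100L, seed = NULL,
                             treeFun = NULL, strongThreshold = 70) {
  if (reps < 1L) stop("reps must be >= 1")
  m <- if (methods::is(sm, "SuperMatrix")) as.matrix(sm) else
    asAlignmentMatrix(sm)
  if (is.null(treeFun))
    treeFun <- function(x) njTree(pDistanceMatrix(x))
  ref <- treeFun(m)
  L <- ncol(m)
  boots <- withSeed(seed, lapply(seq_len(reps), function(r) {
    treeFun(m[, sample.int(L, L, replace = TRUE), drop = FALSE])
  }))
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / reps
  out <- ref
  out$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = out, support = support,
       strong = support >= strongThreshold)
}

#' Summarize a PCR validation matrix
#'
#' PSR (PCR success rate) is successes / attempted reactions. Computes
#' the overall PSR, per-marker and per-order PSR, and the universal
#' panel of markers with PSR >= `threshold`. Markers with no attempted
#' reactions have undefined PSR and are excluded with a warning.
#'
#' @param vm a [ValidationMatrix-class].
#' @param threshold PSR cutoff for the universal panel (default 0.80).
#' @return A [MarkerPanel-class] object.
#' @export
summarizeValidation <- function(vm, threshold = 0.80) {
  cells <- vm@cells
  att <- !is.na(cells)
  succ <- cells == 1L & att
  perMarker <- data.frame(
    marker = rownames(cells),
    n_success = rowSums(succ),
    n_failure = rowSums(att & cells == 0L),
    n_not_attempted = rowSums(!att),
    stringsAsFactors = FALSE, row.names = NULL)
  perMarker$psr <- ifelse(rowSums(att) > 0,
                          perMarker$n_success / rowSums(att), NA_real_)
  none <- is.na(perMarker$psr)
  if (any(none))
    warning("marker(s) with no attempted reactions excluded from the ",
            "panel: ", paste(perMarker$marker[none], collapse = ", "))
  byOrder <- split(seq_len(ncol(cells)), vm@orders)
  perOrder <- data.frame(
    order = names(byOrder),
    n_success = vapply(byOrder, function(ix) sum(succ[, ix]), numeric(1)),
    n_attempted = vapply(byOrder, function(ix) sum(att[, ix]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  perOrder$psr <- ifelse(perOrder$n_attempted > 0,
                         perOrder$n_success / perOrder$n_attempted,
                         NA_real_)
  panel <- perMarker$marker[!none & perMarker$psr >= threshold]
  methods::new("MarkerPanel", perMarker = perMarker, perOrder = perOrder,
               overallPSR = sum(succ) / sum(att), panel = panel,
               threshold = threshold)
}
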