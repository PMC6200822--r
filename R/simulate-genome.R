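#' Configuration for the genome-pair simulator
#'
#' Describes a template genome (annotated exons separated by introns) and
#' a query genome derived from it by per-site Jukes-Cantor substitution,
#' with planted paralog duplications in the template and locus deletions
#' in the query — the features the exon-mining / single-copy /
#' orthology-screening chain must recognise.
#'
#' @param nExons number of planted exon loci.
#' @param exonLenRange inclusive exon length bounds (default 800-1200 bp,
#'   comfortably above the > 600 bp mining rule and the 700 bp minimum
#'   product).
#' @param divergence per-site substitution probability between the two
#'   genomes (default 0.08, well inside the 80% identity screen).
#' @param nParalogs number of exons that receive a duplicated copy
#'   elsewhere in the template genome.
#' @param paralogDivergence per-site divergence of the planted paralog
#'   copies (default 0.05: detectable duplicates).
#' @param intronLenRange inclusive bounds of the intergenic/intron
#'   spacers between loci.
#' @param deletionProb probability that a locus is absent from the query
#'   genome.
#' @param minusStrandProb probability a planted exon is annotated on the
#'   minus strand (stored reverse-complemented in the template genome).
#' @param seed master RNG seed.
#' @return A named list of class `genomeSimConfig`.
#' @export
genomeSimConfig <- function(nExons = 50L, exonLenRange = c(800L, 1200L),
                            divergence = 0.08, nParalogs = 5L,
                            paralogDivergence = 0.05,
                            intronLenRange = c(200L, 400L),
                            deletionProb = 0.10, minusStrandProb = 0.3,
                            seed = 1L) {
  stopifnot(nExons >= 1, exonLenRange[1] > 0,
            exonLenRange[2] >= exonLenRange[1],
            divergence >= 0, divergence <= 1,
            nParalogs >= 0, nParalogs <= nExons,
            paralogDivergence >= 0, paralogDivergence <= 1,
            intronLenRange[1] > 0, deletionProb >= 0, deletionProb <= 1,
            minusStrandProb >= 0, minusStrandProb <= 1)
  structure(list(nExons = as.integer(nExons),
                 exonLenRange = as.integer(exonLenRange),
                 divergence = divergence, nParalogs = as.integer(nParalogs),
                 paralogDivergence = paralogDivergence,
                 intronLenRange = as.integer(intronLenRange),
                 deletionProb = deletionProb,
                 minusStrandProb = minusStrandProb,
                 seed = as.integer(seed)),
            class = "genomeSimConfig")
}

#' Simulate an annotated genome pair with planted truth
#'
#' Generates a template genome (`genome1`) of `nExons` random exons
#' separated by random spacers, with exon annotations; a query genome
#' (`genome2`) containing, for each non-deleted locus, a copy of the exon
#' mutated by the Jukes-Cantor kernel at the configured divergence,
#' embedded in fresh random spacers; and planted paralog copies of some
#' template exons. The truth table records, per exon: coordinates in both
#' genomes, the single-copy flag (FALSE for duplicated exons), the
#' deletion flag, the orthology-survival flag (single-copy and not
#' deleted) and the realized per-site divergence.
#'
#' @param cfg a [genomeSimConfig()].
#' @return list with `genome1`, `genome2` (DNAStringSet, one sequence
#'   `chr1` each), `annotation` (GRanges of template exons with
#'   `exon_id`/`gene_id`), `truth` (data.frame) and `config`.
#' @seealso [writeGenomeSim()] to emit FASTA/GFF3/TSV files.
#' @export
simulateGenomePair <- function(cfg = genomeSimConfig()) {
  stopifnot(inherits(cfg, "genomeSimConfig"))
  withSeed(cfg$seed, {
    nE <- cfg$nExons
    lens <- sample(cfg$exonLenRange[1]:cfg$exonLenRange[2], nE,
                   replace = TRUE)
    exons <- randomDNA(lens)
    strands <- ifelse(runif(nE) < cfg$minusStrandProb, "-", "+")
    dup_idx <- if (cfg$nParalogs > 0) sort(sample.int(nE, cfg$nParalogs))
               else integer(0)
    deleted <- runif(nE) < cfg$deletionProb

    ilen <- function() sample(cfg$intronLenRange[1]:cfg$intronLenRange[2], 1L)

    # genome 1: spacer exon spacer exon ... (+ paralog copies appended)
    pieces1 <- character(0)
    g1s <- integer(nE)
    g1e <- integer(nE)
    pos <- 0L
    for (i in seq_len(nE)) {
      sp <- randomDNA(ilen())
      emb <- if (strands[i] == "-") revComp(exons[i]) else exons[i]
      pieces1 <- c(pieces1, sp, emb)
      g1s[i] <- pos + nchar(sp) + 1L
      g1e[i] <- g1s[i] + lens[i] - 1L
      pos <- g1e[i]
    }
    for (i in dup_idx) {
      sp <- randomDNA(ilen())
      copy <- mutateJC(exons[i], cfg$paralogDivergence)
      pieces1 <- c(pieces1, sp, copy)
      pos <- pos + nchar(sp) + nchar(copy)
    }
    pieces1 <- c(pieces1, randomDNA(ilen()))
    genome1 <- Biostrings::DNAStringSet(paste(pieces1, collapse = ""))
    names(genome1) <- "chr1"

    # genome 2: mutated orthologs of non-deleted loci, fresh spacers
    pieces2 <- character(0)
    g2s <- rep(NA_integer_, nE)
    g2e <- rep(NA_integer_, nE)
    realized <- rep(NA_real_, nE)
    pos <- 0L
    for (i in seq_len(nE)) {
      if (deleted[i]) next
      sp <- randomDNA(ilen())
      ortho <- mutateJC(exons[i], cfg$divergence)
      realized[i] <- mean(strsplit(ortho, "")[[1]] !=
                            strsplit(exons[i], "")[[1]])
      pieces2 <- c(pieces2, sp, ortho)
      g2s[i] <- pos + nchar(sp) + 1L
      g2e[i] <- g2s[i] + lens[i] - 1L
      pos <- g2e[i]
    }
    pieces2 <- c(pieces2, randomDNA(ilen()))
    genome2 <- Biostrings::DNAStringSet(paste(pieces2, collapse = ""))
    names(genome2) <- "chr1"

    ann <- GenomicRanges::GRanges(
      seqnames = "chr1", ranges = IRanges::IRanges(g1s, g1e),
      strand = strands)
    ann$exon_id <- sprintf("exon%03d", seq_len(nE))
    ann$gene_id <- sprintf("gene%03d", seq_len(nE))

    single_copy <- !(seq_len(nE) %in% dup_idx)
    truth <- data.frame(
      exon_id = ann$exon_id, gene_id = ann$gene_id, length_bp = lens,
      strand = strands, g1_start = g1s, g1_end = g1e,
      g2_start = g2s, g2_end = g2e, single_copy = single_copy,
      deleted = deleted, survives = single_copy & !deleted,
      divergence = realized, stringsAsFactors = FALSE)

    list(genome1 = genome1, genome2 = genome2, annotation = ann,
         truth = truth, config = cfg)
  })
}

#' Write a simulated genome pair to standard files
#'
#' Emits `genome1.fasta`, `genome1.gff3`, `genome2.fasta` and
#' `truth.tsv` under `dir`.
#'
#' @param sim output of [simulateGenomePair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeGenomeSim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaSet(sim$genome1, file.path(dir, "genome1.fasta"))
  writeFastaSet(sim$genome2, file.path(dir, "genome2.fasta"))
  writeGff3Exons(sim$annotation, file.path(dir, "genome1.gff3"))
  writeTsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
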