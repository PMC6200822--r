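#' Read exon annotations from a GFF3 file
#'
#' Imports a GFF3 annotation via [rtracklayer::import()] and returns the
#' exon features only, with the parent gene resolved. Coordinates stay in
#' the 1-based inclusive convention used throughout the package (the
#' native GRanges convention, matching GFF3 itself). Exons lacking a
#' `Parent` attribute are skipped with a warning; a feature with
#' `start > end` is a format error.
#'
#' @param path path to a GFF3 file containing `exon` features with
#'   `Parent` attributes (and optionally `ID`).
#' @return A [GenomicRanges::GRanges] of exons with metadata columns
#'   `exon_id` and `gene_id`.
#' @export
readGff3Exons <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  # Pre-validate coordinates: rtracklayer would mask the start > end case.
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(f, function(v)
      length(v) >= 5 && suppressWarnings(as.numeric(v[4]) > as.numeric(v[5])),
      logical(1)))
    if (length(bad))
      stop("GFF3 format error: start > end for feature on line ",
           which(!startsWith(raw, "#") & nzchar(raw))[bad[1]])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  orphan <- is.na(parent)
  if (any(orphan)) {
    warning(sum(orphan), " exon feature(s) without a Parent attribute ",
            "skipped")
    gr <- gr[!orphan]
    parent <- parent[!orphan]
  }
  exon_id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  miss <- is.na(exon_id)
  if (any(miss))
    exon_id[miss] <- paste0(parent[miss], ".exon",
                            seq_len(sum(miss)))
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr))
  out$exon_id <- exon_id
  out$gene_id <- parent
  out
}

# Hand-emitted GFF3 writer used by the genome simulator: one gene + one
# exon feature per planted locus, with ID/Parent attributes.
writeGff3Exons <- function(exons, path, source = "NPCLtools") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(exons)) {
    sn <- as.character(GenomicRanges::seqnames(exons))[i]
    st <- GenomicRanges::start(exons)[i]
    en <- GenomicRanges::end(exons)[i]
    sd <- as.character(GenomicRanges::strand(exons))[i]
    if (sd == "*") sd <- "+"
    gid <- exons$gene_id[i]
    eid <- exons$exon_id[i]
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       sn, source, st, en, sd, gid), con)
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       sn, source, st, en, sd, eid, gid), con)
  }
  invisible(path)
}
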