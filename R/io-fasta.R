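#' Read a FASTA file into a normalized DNAStringSet
#'
#' Wraps [Biostrings::readDNAStringSet()] and enforces the pipeline's
#' sequence contract: sequences are uppercased, and any character other
#' than A/C/G/T/N/- (including IUPAC ambiguity codes) is mapped to `N`,
#' with one warning reporting how many characters were converted.
#' Record ids (the first whitespace-delimited token of each header) must
#' be unique and sequences non-empty.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b", "GGCC"), tf)
#' readFastaSet(tf)
#' @export
readFastaSet <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file")
  if (!startsWith(trimws(first), ">"))
    stop("FASTA format error at line 1: expected '>' header")
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e)
                  stop("FASTA format error in ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA record ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("FASTA format error: empty sequence for record ",
         names(x)[Biostrings::width(x) == 0L][1])
  chr <- toupper(as.character(x))
  n_sub <- sum(vapply(chr, function(s)
    sum(!strsplit(s, "", fixed = TRUE)[[1]] %in%
          c("A", "C", "G", "T", "N", "-")), integer(1)))
  if (n_sub > 0) {
    warning(n_sub, " non-ACGTN characters converted to N in ", path)
    chr <- vapply(chr, function(s)
      gsub("[^ACGTN-]", "N", s), character(1), USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' Deterministic writer (stable input order, fixed line width) so that
#' identical inputs yield byte-identical files.
#'
#' @param x a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
writeFastaSet <- function(x, path, width = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = width)
  invisible(path)
}
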