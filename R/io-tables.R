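#' Read a PCR validation matrix from TSV
#'
#' The expected layout is: a header line `marker<TAB>species1<TAB>...`,
#' a second line `order<TAB>order1<TAB>...` giving the taxonomic order of
#' each species, then one row per marker with cells in `{1, 0, NA}`
#' (success / failure / not attempted).
#'
#' @param path path to the TSV file.
#' @return A [ValidationMatrix-class] object.
#' @seealso [summarizeValidation()], [validationMatrix()]
#' @export
readValidationMatrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("validation matrix needs header, order ",
                               "line and at least one marker row")
  f <- strsplit(lines, "\t", fixed = TRUE)
  w <- lengths(f)
  if (length(unique(w)) != 1L)
    stop("validation matrix format error: ragged rows (line ",
         which(w != w[1])[1], ")")
  species <- f[[1]][-1]
  if (tolower(f[[2]][1]) != "order")
    stop("validation matrix format error: second line must be the ",
         "'order' line")
  orders <- f[[2]][-1]
  rows <- f[-(1:2)]
  markers <- vapply(rows, `[`, character(1), 1L)
  cells <- t(vapply(rows, function(v) {
    x <- v[-1]
    x[x %in% c("NA", "")] <- NA
    suppressWarnings(as.integer(x))
  }, integer(length(species))))
  if (any(!is.na(cells) & !(cells %in% c(0L, 1L))))
    stop("validation matrix cells must be 1, 0 or NA")
  dimnames(cells) <- list(markers, species)
  validationMatrix(cells, orders)
}

#' Construct a ValidationMatrix
#'
#' @param cells integer matrix (markers x species) over `{1, 0, NA}`,
#'   with dimnames.
#' @param orders character vector of per-species order labels.
#' @return A [ValidationMatrix-class] object.
#' @export
validationMatrix <- function(cells, orders) {
  storage.mode(cells) <- "integer"
  methods::new("ValidationMatrix", cells = cells, orders = orders)
}

#' Write aligned sequences in relaxed PHYLIP format
#'
#' Header is `"<ntax> <ncols>"`; each row is `name<space>sequence` with
#' names up to 64 characters (longer names are truncated with a warning).
#'
#' @param x a [Biostrings::DNAStringSet], named character vector of equal
#'   lengths, or a [SuperMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhylip <- function(x, path) {
  if (methods::is(x, "SuperMatrix"))
    x <- apply(as.matrix(x), 1L, paste, collapse = "")
  if (methods::is(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  if (is.null(names(x))) stop("sequences must be named")
  if (length(unique(nchar(x))) != 1L)
    stop("PHYLIP requires equal-length sequences")
  nm <- names(x)
  if (any(nchar(nm) > 64L)) {
    warning("taxon names longer than 64 characters truncated")
    nm <- substr(nm, 1L, 64L)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(x), nchar(x[[1]])), con)
  writeLines(paste(nm, unname(x)), con)
  invisible(path)
}

#' Write or read a Newick tree
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so all
#' tree I/O goes through one place; branch lengths survive a round trip
#' to at least 1e-9.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @return `writeNewick()` returns `path` invisibly; `readNewick()`
#'   returns a `phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Write a data frame as TSV
#'
#' Deterministic TSV writer used for all tabular reports (no quoting, no
#' row names, `NA` written literally).
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One line per locus: `DNA, <locus> = <start>-<end>` using the partition
#' table of a [SuperMatrix-class], ready for an external ML run on the
#' matching PHYLIP export.
#'
#' @param sm a [SuperMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRaxmlPartitions <- function(sm, path) {
  p <- lociPartitions(sm)
  writeLines(sprintf("DNA, %s = %d-%d", p$locus, p$start, p$end), path)
  invisible(path)
}
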