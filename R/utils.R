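# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream. A `NULL` seed evaluates the expression
#' in the current stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a master seed; kept < 2^31.
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647L)
}

# Random DNA string(s) of given length(s), uniform over A/C/G/T.
randomDNA <- function(lens) {
  vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Jukes-Cantor substitution kernel: each site independently replaced, with
# probability d, by one of the three alternative bases (uniformly).
mutateJC <- function(seq, d) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < d)
  if (length(hit)) {
    x[hit] <- vapply(x[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1))
  }
  paste(x, collapse = "")
}

revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# vectorized reverse complement for plain character vectors
revCompVec <- function(seqs) {
  if (!length(seqs)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Coerce aligned sequences (DNAStringSet, named character, or character
# matrix with taxa as rows) to a character matrix of single bases.
asAlignmentMatrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    return(toupper(x))
  }
  if (methods::is(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  if (!is.character(x)) stop("cannot interpret input as an alignment")
  if (length(unique(nchar(x))) != 1L)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(m) <- if (!is.null(names(x))) names(x) else
    paste0("seq", seq_along(x))
  m
}

# Watterson's harmonic sums used by several statistics.
harmonicA1 <- function(n) sum(1 / seq_len(n - 1))
harmonicA2 <- function(n) sum(1 / seq_len(n - 1)^2)
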