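#' @useDynLib phasir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate rnbinom runif setNames
#' @importFrom utils head packageVersion write.table
NULL

# Canonical internal alphabet is DNA (U -> T); reports convert back to RNA.

#' Canonicalize small RNA sequences
#'
#' Uppercases and converts U to T so that RNA- and DNA-alphabet inputs compare
#' equal. Sequences are validated against the {A,C,G,T,U,N} alphabet.
#'
#' @param x character vector of sequences.
#' @param allow_n keep sequences containing N (`TRUE`) or treat them as a
#'   format error (`FALSE`, the default used at read collapsing).
#' @param what label used in error messages to name the offending record.
#' @return character vector in the DNA (T) alphabet.
#' @export
canonicalize_seq <- function(x, allow_n = TRUE, what = "sequence") {
  nms <- names(x)
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  names(x) <- nms
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("invalid characters in %s at record(s) %s",
                 what, paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  if (!allow_n) {
    nn <- grepl("N", x, fixed = TRUE)
    if (any(nn)) {
      stop(sprintf("%s at record(s) %s contains N (rejected)",
                   what, paste(utils::head(which(nn), 5L), collapse = ", ")))
    }
  }
  x
}

#' Convert a DNA-alphabet sequence to RNA for display
#' @param x character vector (T alphabet).
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

# reverse complement on plain character vectors (T alphabet)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# read a genome argument: path to FASTA, DNAStringSet, or named character
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(canonicalize_seq(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  genome
}

# 0-based half-open substring of a chromosome
genome_slice <- function(genome, chrom, start0, end0) {
  s <- genome[[chrom]]
  start0 <- max(0L, start0)
  end0 <- min(length(s), end0)
  if (end0 <= start0) return("")
  as.character(Biostrings::subseq(s, start = start0 + 1L, width = end0 - start0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
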