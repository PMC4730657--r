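# Folding contract: given sequences, return one dot-bracket structure each.
# Default engine is ViennaRNA's RNAfold (minimum free energy); the bundled
# Nussinov base-pair-maximization traceback is a deterministic fallback so the
# hairpin machinery works without an external folder.

#' Predict RNA secondary structure (dot-bracket)
#'
#' @param seqs character vector of sequences (T or U alphabet).
#' @param engine `"auto"` uses RNAfold when found on the PATH, otherwise the
#'   built-in base-pair-maximization fold; `"rnafold"` and `"nussinov"` force
#'   an engine.
#' @return character vector of dot-bracket strings, same length/order as
#'   `seqs`; RNAfold minimum free energies are attached as attribute `mfe`
#'   when that engine ran.
#' @export
fold_sequences <- function(seqs, engine = c("auto", "rnafold", "nussinov")) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("RNAfold"))) "rnafold" else "nussinov"
  }
  seqs <- canonicalize_seq(seqs)
  if (length(seqs) == 0L) return(character(0))
  if (engine == "nussinov") {
    return(vapply(seqs, .nussinov_fold, "", USE.NAMES = FALSE))
  }
  fold_rnafold(seqs)
}

fold_rnafold <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(paste0(">s", seq_along(seqs), "\n", as_rna(seqs)), fa)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", fa), stdout = TRUE))
  # records of 3 lines: >id / sequence / structure (mfe)
  struct_lines <- out[seq(3L, length(out), by = 3L)]
  db <- sub("^([.()]+).*$", "\\1", struct_lines)
  mfe <- as.numeric(sub("^[.()]+\\s+\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1",
                        struct_lines))
  if (length(db) != length(seqs) || any(nchar(db) != nchar(seqs)))
    stop("unexpected RNAfold output")
  attr(db, "mfe") <- mfe
  db
}

#' Pair table of a dot-bracket structure
#'
#' @param db a single dot-bracket string.
#' @return integer vector `p` with `p[i]` the 1-based partner of position `i`,
#'   or `NA` if unpaired.
#' @export
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  p <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") stop("invalid dot-bracket character: ", ch[i])
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  p
}
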