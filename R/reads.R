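#' Collapse raw sRNA sequence streams into distinct reads
#'
#' One record per distinct (U/T-canonicalized) sequence with a per-library
#' abundance vector. Reads containing N are rejected as low quality.
#'
#' @param libs named list, one element per library. Each element is either a
#'   character vector of read sequences (one entry per sequenced read) or a
#'   named integer vector of pre-collapsed counts (names are sequences).
#' @return an object of class `srna_reads`: a list with `sequence` (character,
#'   T alphabet), `length` (integer), `abundance` (integer matrix, reads x
#'   libraries) and `normalized` (`NULL` until [normalize_rp15m()] is run).
#' @seealso [length_filter()], [normalize_rp15m()], [size_profile()]
#' @export
collapse_reads <- function(libs) {
  stopifnot(is.list(libs), length(libs) > 0L)
  if (is.null(names(libs)) || any(!nzchar(names(libs))))
    stop("libraries must be named")
  counts <- lapply(names(libs), function(lib) {
    x <- libs[[lib]]
    if (!is.null(names(x)) && is.numeric(x)) {
      seqs <- canonicalize_seq(names(x), allow_n = FALSE,
                               what = sprintf("library '%s'", lib))
      tab <- tapply(as.integer(x), seqs, sum)
    } else {
      seqs <- canonicalize_seq(x, allow_n = FALSE,
                               what = sprintf("library '%s'", lib))
      tab <- table(seqs)
    }
    if (any(tab < 0)) stop("negative counts in library ", lib)
    tab
  })
  all_seqs <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  ab <- matrix(0L, nrow = length(all_seqs), ncol = length(libs),
               dimnames = list(NULL, names(libs)))
  for (j in seq_along(counts)) {
    idx <- match(names(counts[[j]]), all_seqs)
    ab[idx, j] <- as.integer(counts[[j]])
  }
  new_srna_reads(all_seqs, ab)
}

new_srna_reads <- function(sequence, abundance, normalized = NULL) {
  structure(list(sequence = sequence,
                 length = nchar(sequence),
                 abundance = abundance,
                 normalized = normalized),
            class = "srna_reads")
}

#' @export
print.srna_reads <- function(x, ...) {
  cat(sprintf("srna_reads: %d distinct sequences, %d libraries (%s)\n",
              length(x$sequence), ncol(x$abundance),
              paste(colnames(x$abundance), collapse = ", ")))
  cat(sprintf("  lengths %d..%d nt; total abundance %s%s\n",
              min(x$length), max(x$length),
              format(sum(x$abundance), big.mark = ","),
              if (is.null(x$normalized)) "" else "; normalized (RP15M)"))
  invisible(x)
}

#' @export
length.srna_reads <- function(x) length(x$sequence)

#' @export
`[.srna_reads` <- function(x, i, ...) {
  new_srna_reads(x$sequence[i], x$abundance[i, , drop = FALSE],
                 if (!is.null(x$normalized)) x$normalized[i, , drop = FALSE])
}

#' @export
as.data.frame.srna_reads <- function(x, ...) {
  data.frame(sequence = x$sequence, length = x$length, x$abundance,
             check.names = FALSE)
}

#' Remove reads outside a length window
#'
#' Reads shorter than `min_len` or longer than `max_len` nucleotides are
#' removed; typical sRNA-seq practice keeps 18-30 nt.
#'
#' @param reads an `srna_reads` object.
#' @param min_len,max_len inclusive bounds in nucleotides.
#' @return the surviving reads, input order preserved.
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 30L) {
  if (min_len <= 0L || max_len <= 0L) stop("length bounds must be positive")
  if (min_len > max_len) stop("min_len must be <= max_len")
  stopifnot(inherits(reads, "srna_reads"))
  reads[reads$length >= min_len & reads$length <= max_len]
}

#' Normalize abundances to reads per 15 million
#'
#' Each library's raw counts are scaled by 15,000,000 / library total, so that
#' abundances are comparable within and across libraries.
#'
#' @param reads an `srna_reads` object.
#' @param library_totals named numeric vector of per-library totals used as
#'   the scaling denominator; defaults to the column sums of the abundance
#'   matrix (in which case each normalized column sums to exactly 15 million).
#' @return `reads` with the `normalized` matrix filled in.
#' @export
normalize_rp15m <- function(reads, library_totals = NULL) {
  stopifnot(inherits(reads, "srna_reads"))
  totals <- library_totals %||% colSums(reads$abundance)
  totals <- totals[colnames(reads$abundance)]
  if (any(is.na(totals)) || any(totals <= 0))
    stop("every library total must be a positive number")
  reads$normalized <- sweep(reads$abundance, 2L, 15e6 / totals, `*`)
  reads
}

#' Read-size profile per library
#'
#' Percentage of abundance and of distinct reads in each size class
#' (`sizes`), per library; both vectors sum to 100.
#'
#' @param reads an `srna_reads` object (already length-filtered).
#' @param sizes integer vector of size classes; default 18..30 nt.
#' @return a `size_profile`: list of two matrices (`abundance_pct`,
#'   `distinct_pct`), sizes x libraries.
#' @export
size_profile <- function(reads, sizes = 18:30) {
  stopifnot(inherits(reads, "srna_reads"))
  libs <- colnames(reads$abundance)
  ab <- matrix(0, length(sizes), length(libs), dimnames = list(sizes, libs))
  di <- ab
  for (j in seq_along(libs)) {
    a <- reads$abundance[, j]
    if (sum(a) == 0) stop("library '", libs[j], "' is empty")
    keep <- a > 0
    ab[, j] <- 100 * vapply(sizes, function(s) sum(a[keep & reads$length == s]),
                            0) / sum(a)
    di[, j] <- 100 * vapply(sizes, function(s) sum(keep & reads$length == s),
                            0) / sum(keep)
  }
  structure(list(abundance_pct = ab, distinct_pct = di),
            class = "size_profile")
}

#' @export
print.size_profile <- function(x, ...) {
  cat("size_profile (% of abundance per size class):\n")
  print(round(x$abundance_pct, 2))
  invisible(x)
}

#' Read an sRNA FASTA/FASTQ file into a per-library sequence stream
#'
#' FASTA headers in the collapsed dialect `id_xN` are expanded to a named
#' count vector (sequence -> N); plain FASTA/FASTQ yields one entry per read.
#'
#' @param path file path.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension).
#' @return a character vector of sequences, or a named integer count vector
#'   for collapsed FASTA; suitable as one element of [collapse_reads()]'s
#'   `libs` argument.
#' @export
read_srna_file <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  seqs <- canonicalize_seq(as.character(ss), what = basename(path))
  ids <- sub("\\s.*$", "", names(ss))
  n <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", ids)))
  if (format == "fasta" && all(grepl("_x\\d+$", ids)) && !anyNA(n)) {
    return(setNames(n, seqs))
  }
  seqs
}

#' Write distinct reads as collapsed FASTA (`id_xN` dialect)
#'
#' @param reads an `srna_reads` object.
#' @param path output file.
#' @param library library whose counts provide N; default sums all libraries.
#' @export
write_collapsed_fasta <- function(reads, path, library = NULL) {
  n <- if (is.null(library)) rowSums(reads$abundance)
       else reads$abundance[, library]
  keep <- n > 0
  ss <- Biostrings::DNAStringSet(reads$sequence[keep])
  names(ss) <- sprintf("s%06d_x%d", which(keep), n[keep])
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Per-library summary table (raw/mapped, abundance/distinct)
#'
#' @param reads all distinct reads with abundances.
#' @param mapped_reads subset of `reads` that mapped to the genome (an
#'   `srna_reads` object), or `NULL` to omit mapped columns.
#' @return data.frame with one row per library plus a Total row.
#' @export
library_summary <- function(reads, mapped_reads = NULL) {
  libs <- colnames(reads$abundance)
  df <- data.frame(
    tissue = libs,
    raw_abundance = colSums(reads$abundance),
    raw_distinct = colSums(reads$abundance > 0))
  if (!is.null(mapped_reads)) {
    df$mapped_abundance <- colSums(mapped_reads$abundance)[libs]
    df$mapped_distinct <- colSums(mapped_reads$abundance > 0)[libs]
  }
  tot <- df[1L, ]
  tot$tissue <- "Total"
  for (cn in setdiff(names(df), "tissue")) tot[[cn]] <- sum(df[[cn]])
  rbind(df, tot)
}
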