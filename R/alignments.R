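#' Load genome alignments of sRNA reads
#'
#' Accepts SAM/BAM (via Rsamtools) or 6-column BED (via rtracklayer). Internal
#' coordinates are 0-based half-open: a hit occupies `[left, left + length)`.
#' SAM/BAM 1-based POS is converted; unmapped records are skipped with a
#' message. Multi-mapped reads yield one hit per placement.
#'
#' @param path alignment file (`.sam`, `.bam`, `.bed`).
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return an `alignment_hits` data.frame with columns `read_id`, `chrom`,
#'   `strand` (`+`/`-`), `left` (0-based), `length`, and `seq` when available.
#' @export
load_alignments <- function(path, format = c("auto", "sam", "bam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot infer alignment format from '", path, "'"))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  hits <- if (format == "bed") load_bed_hits(path) else load_sam_hits(path, format)
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

load_sam_hits <- function(path, format) {
  bam <- if (format == "sam") {
    tryCatch(Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE),
             error = function(e) stop("malformed SAM file '", path, "': ",
                                      conditionMessage(e)))
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "qwidth", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = NA))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !is.na(x$pos)
  if (any(!mapped)) {
    message(sum(!mapped), " unmapped record(s) skipped in ", basename(path))
  }
  data.frame(read_id = x$qname[mapped],
             chrom = as.character(x$rname[mapped]),
             strand = as.character(x$strand[mapped]),
             left = x$pos[mapped] - 1L,
             length = x$qwidth[mapped],
             seq = canonicalize_seq(as.character(x$seq[mapped])),
             stringsAsFactors = FALSE)
}

load_bed_hits <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e)))
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else sprintf("bed%06d", seq_along(gr))
  data.frame(read_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             left = GenomicRanges::start(gr) - 1L,
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Build an `alignment_hits` table in code
#'
#' @param chrom,strand,left,length,read_id,seq parallel vectors; `left` is the
#'   0-based leftmost genomic coordinate, the hit occupies
#'   `[left, left + length)`.
#' @return an `alignment_hits` data.frame.
#' @export
alignment_hits <- function(chrom, strand, left, length,
                           read_id = NULL, seq = NULL) {
  stopifnot(all(strand %in% c("+", "-")), all(left >= 0))
  df <- data.frame(
    read_id = read_id %||% sprintf("r%06d", seq_along(left)),
    chrom = as.character(chrom), strand = as.character(strand),
    left = as.integer(left), length = as.integer(length),
    stringsAsFactors = FALSE)
  if (!is.null(seq)) df$seq <- canonicalize_seq(seq)
  class(df) <- c("alignment_hits", "data.frame")
  df
}

#' Write hits as 6-column BED (0-based half-open; round-trips with
#' [load_alignments()])
#' @param hits an `alignment_hits` data.frame.
#' @param path output file.
#' @export
write_bed <- function(hits, path) {
  gr <- hits_to_granges(hits)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Convert hits to a GRanges (1-based, as GenomicRanges requires)
#' @param hits an `alignment_hits` data.frame.
#' @return a `GRanges` with a `name` column.
#' @export
hits_to_granges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$left + 1L, width = hits$length),
    strand = hits$strand,
    name = hits$read_id,
    score = 0L)
}
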