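# Phased siRNA (PHAS) locus detection: register assignment with the +2
# antisense offset, a sliding-window scan (9 cycles = 189 bp, stepping 3
# cycles = 63 bp for 21-nt phasing), a hypergeometric phasing P value, a
# phasing score, window merging, structural-RNA exclusion and miRNA trigger
# assignment.

#' Phasing-analysis parameters
#'
#' Defaults implement 21-nt phasing analysis: a nine-cycle (189 bp) window
#' stepped by three cycles (63 bp); a window is reported when it holds at
#' least `min_unique` distinct read positions, at least half the distinct
#' reads are 21 nt, and at least `min_register_reads` distinct positions share
#' one register; merged loci are kept at P <= 0.001. A +2 nt offset is added
#' to antisense 5' ends because sRNA duplexes carry 2-nt 3' overhangs.
#'
#' @param phase phase length D in nt (21).
#' @param window_cycles,step_cycles window and step in cycles (9 and 3).
#' @param min_unique minimum distinct offset-corrected 5' positions per window.
#' @param min_phase_len_fraction minimum fraction of distinct reads of length
#'   `phase`.
#' @param min_register_reads minimum distinct positions in the best register.
#' @param p_cutoff locus P-value cutoff (alpha).
#' @param antisense_offset nt added to minus-strand 5' positions.
#' @param trigger_score_cutoff maximum [alignment_score()] for trigger search.
#' @param max_position_fraction drop a locus when a single position carries
#'   more than this fraction of locus abundance (single-peak false-positive
#'   proxy).
#' @param in_register_tol tolerance (nt) when matching a trigger cleavage site
#'   to the locus register.
#' @return a `phasing_params` list with derived `window_nt` and `step_nt`.
#' @export
phasing_params <- function(phase = 21L, window_cycles = 9L, step_cycles = 3L,
                           min_unique = 10L, min_phase_len_fraction = 0.5,
                           min_register_reads = 3L, p_cutoff = 0.001,
                           antisense_offset = 2L, trigger_score_cutoff = 5,
                           max_position_fraction = 0.8,
                           in_register_tol = 1L) {
  stopifnot(phase > 0L, window_cycles > 0L, step_cycles > 0L,
            min_unique > 0L, min_register_reads > 0L, p_cutoff > 0)
  p <- list(phase = as.integer(phase),
            window_cycles = as.integer(window_cycles),
            step_cycles = as.integer(step_cycles),
            min_unique = as.integer(min_unique),
            min_phase_len_fraction = min_phase_len_fraction,
            min_register_reads = as.integer(min_register_reads),
            p_cutoff = p_cutoff,
            antisense_offset = as.integer(antisense_offset),
            trigger_score_cutoff = trigger_score_cutoff,
            max_position_fraction = max_position_fraction,
            in_register_tol = as.integer(in_register_tol))
  p$window_nt <- p$window_cycles * p$phase
  p$step_nt <- p$step_cycles * p$phase
  class(p) <- "phasing_params"
  p
}

#' @export
print.phasing_params <- function(x, ...) {
  cat(sprintf(
    "phasing_params: D=%d nt, window %d cycles (%d bp), step %d cycles (%d bp)\n",
    x$phase, x$window_cycles, x$window_nt, x$step_cycles, x$step_nt))
  cat(sprintf(
    "  filters: >=%d unique, >=%.0f%% %d-nt, >=%d in register; alpha=%g; antisense offset +%d\n",
    x$min_unique, 100 * x$min_phase_len_fraction, x$phase,
    x$min_register_reads, x$p_cutoff, x$antisense_offset))
  invisible(x)
}

#' Offset-corrected position and register of hits
#'
#' Plus-strand positions are the 5' ends (`left`); minus-strand 5' positions
#' get the +2 offset so both strands of a phased duplex fall in one register.
#'
#' @param hits `alignment_hits` data.frame (vectorized over rows).
#' @param params [phasing_params()].
#' @return data.frame with columns `position` and `register`
#'   (`position %% phase`).
#' @export
assign_register <- function(hits, params = phasing_params()) {
  pos <- hits$left + ifelse(hits$strand == "-", params$antisense_offset, 0L)
  data.frame(position = as.integer(pos),
             register = as.integer(pos %% params$phase))
}

#' Hypergeometric phasing P value
#'
#' With `n` distinct occupied positions among `T = 2 * window_cycles * phase`
#' possible offset-corrected positions in a window (both strands) and a
#' register class of `m = 2 * window_cycles` positions, the P value is
#' `P(X >= k)` for `X ~ Hypergeometric(T, m, n)`, computed in log space with
#' log-gamma (log binomial coefficient) arithmetic.
#'
#' @param n distinct positions in the window.
#' @param k distinct positions in the best register.
#' @param params [phasing_params()] supplying the window geometry.
#' @return the upper tail probability `P(X >= k)` in (0, 1].
#' @export
phasing_pvalue <- function(n, k, params = phasing_params()) {
  Tpop <- 2L * params$window_cycles * params$phase
  m <- 2L * params$window_cycles
  if (k > n || n > Tpop) stop("need k <= n <= population size")
  if (k < 0L) stop("k must be non-negative")
  if (k == 0L) return(1)
  xs <- k:min(n, m)
  xs <- xs[n - xs <= Tpop - m]
  if (!length(xs)) return(0)
  lg <- lchoose(m, xs) + lchoose(Tpop - m, n - xs) - lchoose(Tpop, n)
  mx <- max(lg)
  min(1, exp(mx + log(sum(exp(lg - mx)))))
}

#' Phasing score of a window
#'
#' `score = (k - 2) * ln(1 + 10 * P / (1 + U))` where `P` is the summed
#' (normalized) abundance of in-register phase-length reads and `U` the summed
#' abundance of all other reads in the window; 0 when `k` is below
#' `min_register_reads`.
#'
#' @param phased_abundance `P`, abundance of in-register phase-length reads.
#' @param other_abundance `U`, abundance of all other reads in the window.
#' @param k distinct positions in the best register.
#' @param params [phasing_params()].
#' @return non-negative phasing score.
#' @export
phasing_score <- function(phased_abundance, other_abundance, k,
                          params = phasing_params()) {
  if (phased_abundance < 0 || other_abundance < 0)
    stop("abundances must be non-negative")
  if (k < params$min_register_reads) return(0)
  (k - 2) * log(1 + 10 * phased_abundance / (1 + other_abundance))
}

#' Sliding-window phasing scan
#'
#' Windows of `window_cycles * phase` nt start at multiples of
#' `step_cycles * phase` on each chromosome. A window is reported when (a) it
#' holds at least `min_unique` distinct offset-corrected 5' positions
#' (strand-distinct), (b) at least `min_phase_len_fraction` of its distinct
#' reads are `phase` nt long, and (c) the best register holds at least
#' `min_register_reads` distinct positions (ties break to the smallest
#' register).
#'
#' @param hits `alignment_hits`; an optional `norm` column (per-hit summed
#'   normalized abundance) feeds the phasing score, otherwise each distinct
#'   read counts 1.
#' @param params [phasing_params()].
#' @return a `window_stats` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `n_unique`, `n21_fraction`, `register`, `k`, `p_value`,
#'   `phasing_score`.
#' @export
window_scan <- function(hits, params = phasing_params()) {
  D <- params$phase
  ab <- hits$norm %||% rep(1, NROW(hits))
  reg <- assign_register(hits, params)
  tup <- data.frame(chrom = hits$chrom, strand = hits$strand,
                    pos = reg$position, register = reg$register,
                    length = hits$length, ab = ab,
                    stringsAsFactors = FALSE)
  # distinct (chrom, strand, pos, length), abundance summed over reads
  key <- paste(tup$chrom, tup$strand, tup$pos, tup$length)
  tup <- within(
    aggregate(ab ~ chrom + strand + pos + register + length, tup, sum), {})
  nshift <- ceiling(params$window_nt / params$step_nt)
  S <- params$step_nt
  rows <- vector("list", nshift)
  for (s in seq_len(nshift) - 1L) {
    ws <- (tup$pos %/% S - s) * S
    ok <- ws >= 0L & tup$pos < ws + params$window_nt
    rows[[s + 1L]] <- cbind(tup[ok, , drop = FALSE], ws = ws[ok])
  }
  ex <- do.call(rbind, rows)
  if (NROW(ex) == 0L) return(empty_window_stats())
  # a window needs at least min_unique rows to satisfy the unique-position
  # filter; drop smaller groups before the per-window pass
  gkey <- paste(ex$chrom, ex$ws)
  gsz <- table(gkey)
  ex <- ex[gsz[gkey] >= params$min_unique, , drop = FALSE]
  if (NROW(ex) == 0L) return(empty_window_stats())
  out <- lapply(split(ex, list(ex$chrom, ex$ws), drop = TRUE), function(g) {
    poskey <- paste(g$strand, g$pos)
    upos <- !duplicated(poskey)
    n <- sum(upos)
    if (n < params$min_unique) return(NULL)
    # distinct reads for the length filter: (strand, pos, length) tuples
    frac <- mean(g$length == D)
    if (frac < params$min_phase_len_fraction) return(NULL)
    rc <- table(g$register[upos])
    k <- max(rc)
    if (k < params$min_register_reads) return(NULL)
    r <- min(as.integer(names(rc)[rc == k]))
    inreg <- g$register == r & g$length == D
    data.frame(chrom = g$chrom[1L], start = g$ws[1L],
               end = g$ws[1L] + params$window_nt,
               n_unique = n, n21_fraction = frac, register = r,
               k = as.integer(k),
               p_value = phasing_pvalue(n, as.integer(k), params),
               phasing_score = phasing_score(sum(g$ab[inreg]),
                                             sum(g$ab[!inreg]),
                                             as.integer(k), params),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_window_stats())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

empty_window_stats <- function() {
  df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   n_unique = integer(0), n21_fraction = numeric(0),
                   register = integer(0), k = integer(0),
                   p_value = numeric(0), phasing_score = numeric(0))
  class(df) <- c("window_stats", "data.frame")
  df
}

#' Merge reported windows into PHAS loci
#'
#' Overlapping or bookended reported windows on one chromosome merge into one
#' locus; the locus P value is the minimum member P value (register taken from
#' that window, ties to the smallest start), the phasing score the maximum.
#' Loci with P value above `alpha` are discarded.
#'
#' @param windows a `window_stats` data.frame.
#' @param alpha locus P-value cutoff (default from `params`).
#' @param params [phasing_params()].
#' @return a `phas_loci` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `register`, `p_value`, `phasing_score`, `n_windows`.
#' @export
merge_windows <- function(windows, alpha = NULL, params = phasing_params()) {
  alpha <- alpha %||% params$p_cutoff
  loci <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      best <- which(cur$p_value == min(cur$p_value))
      best <- best[which.min(cur$start[best])]
      data.frame(chrom = ch, start = min(cur$start), end = max(cur$end),
                 register = cur$register[best],
                 p_value = cur$p_value[best],
                 phasing_score = max(cur$phasing_score),
                 n_windows = nrow(cur), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(w))) {
      if (is.null(cur)) {
        cur <- w[i, , drop = FALSE]
      } else if (w$start[i] <= max(cur$end)) {
        cur <- rbind(cur, w[i, , drop = FALSE])
      } else {
        loci[[length(loci) + 1L]] <- flush(cur)
        cur <- w[i, , drop = FALSE]
      }
    }
    if (!is.null(cur)) loci[[length(loci) + 1L]] <- flush(cur)
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               register = integer(0), p_value = numeric(0),
               phasing_score = numeric(0), n_windows = integer(0))
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phas_loci", "data.frame")
  out
}

#' Drop loci overlapping structural-RNA annotation
#'
#' Loci overlapping an interval labeled tRNA/rRNA/snoRNA by at least 1 bp are
#' removed (the automated counterpart of manual structural-RNA screening).
#'
#' @param loci `phas_loci`.
#' @param annotation `GRanges` with a `type` metadata column, or a data.frame
#'   with `chrom`, `start`, `end` (0-based half-open) and `type`.
#' @param types annotation types to exclude.
#' @return surviving loci; removals are reported with a message.
#' @export
exclude_structural <- function(loci, annotation,
                               types = c("tRNA", "rRNA", "snoRNA")) {
  if (NROW(annotation) == 0L || NROW(loci) == 0L) return(loci)
  if (!methods::is(annotation, "GRanges")) {
    annotation <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(start = annotation$start + 1L, end = annotation$end),
      type = annotation$type)
  }
  annotation <- annotation[annotation$type %in% types]
  if (length(annotation) == 0L) return(loci)
  lg <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  drop <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(lg, annotation, ignore.strand = TRUE)))
  if (length(drop)) {
    message(length(drop), " locus/loci removed as structural RNA overlap")
    loci <- loci[-drop, , drop = FALSE]
    rownames(loci) <- NULL
  }
  loci
}

#' Drop single-position-dominated loci
#'
#' A locus where one offset-corrected position carries more than
#' `max_position_fraction` of the locus abundance is a likely false positive
#' (one extreme peak can satisfy the window filters alone).
#'
#' @param loci `phas_loci`.
#' @param hits `alignment_hits` (optionally with `norm`).
#' @param params [phasing_params()].
#' @return surviving loci.
#' @export
filter_single_peak <- function(loci, hits, params = phasing_params()) {
  if (NROW(loci) == 0L) return(loci)
  ab <- hits$norm %||% rep(1, NROW(hits))
  reg <- assign_register(hits, params)
  keep <- vapply(seq_len(nrow(loci)), function(i) {
    sel <- hits$chrom == loci$chrom[i] & reg$position >= loci$start[i] &
      reg$position < loci$end[i]
    if (!any(sel)) return(TRUE)
    by_pos <- tapply(ab[sel], paste(hits$strand[sel], reg$position[sel]), sum)
    max(by_pos) / sum(by_pos) <= params$max_position_fraction
  }, TRUE)
  if (any(!keep)) {
    message(sum(!keep), " locus/loci removed by the single-peak filter")
  }
  out <- loci[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign candidate miRNA triggers to PHAS loci
#'
#' Scans the genomic sequence of each locus plus one window span on both
#' strands for miRNA complementary sites with alignment score at or below
#' `trigger_score_cutoff`; a hit is in-register when its predicted cleavage
#' site matches the locus register modulo the phase length within
#' `in_register_tol` nt (minus-strand cleavage sites are duplex-corrected
#' before the comparison). Hits are sorted by in-register status, score, and
#' preference for 22-nt miRNAs.
#'
#' @param loci `phas_loci`.
#' @param mirnas named character vector of mature miRNA sequences (5' to 3'),
#'   or a `mirna_calls` object.
#' @param genome genome FASTA path / `DNAStringSet`.
#' @param params [phasing_params()].
#' @return `loci` with a `triggers` list-column of per-locus data.frames
#'   (`mirna`, `score`, `strand`, `cleavage` 0-based genomic, `in_register`).
#' @export
assign_triggers <- function(loci, mirnas, genome, params = phasing_params()) {
  if (inherits(mirnas, "mirna_calls")) {
    ids <- ifelse(is.na(mirnas$known),
                  sprintf("novel-%02d", seq_len(nrow(mirnas))), mirnas$known)
    mirnas <- setNames(chartr("U", "T", mirnas$sequence), ids)
  }
  mirnas <- setNames(canonicalize_seq(mirnas), names(mirnas))
  genome <- as_genome(genome)
  D <- params$phase
  loci$triggers <- vector("list", NROW(loci))
  for (i in seq_len(NROW(loci))) {
    rs <- max(0L, loci$start[i] - params$window_nt)
    re <- min(length(genome[[loci$chrom[i]]]), loci$end[i] + params$window_nt)
    fwd <- genome_slice(genome, loci$chrom[i], rs, re)
    Lr <- nchar(fwd)
    res <- list()
    for (id in names(mirnas)) {
      L <- nchar(mirnas[[id]])
      if (Lr < L) next
      for (str in c("+", "-")) {
        tx <- if (str == "+") fwd else revcomp(fwd)
        h <- scan_targets(mirnas[[id]], setNames(tx, "locus"),
                          cutoff = params$trigger_score_cutoff)
        if (!nrow(h)) next
        # cleavage in genomic 0-based coordinates, duplex-corrected register
        cl_local <- h$cleavage                      # 1-based on tx
        if (str == "+") {
          g0 <- rs + cl_local - 1L
          reg_pos <- g0
        } else {
          g0 <- rs + (Lr - cl_local)
          reg_pos <- g0 - (D - 1L) + params$antisense_offset
        }
        d <- (reg_pos - loci$register[i]) %% D
        inreg <- pmin(d, D - d) <= params$in_register_tol
        res[[length(res) + 1L]] <- data.frame(
          mirna = id, length = L, score = h$score, strand = str,
          cleavage = g0, in_register = inreg, stringsAsFactors = FALSE)
      }
    }
    tr <- if (length(res)) do.call(rbind, res) else
      data.frame(mirna = character(0), length = integer(0),
                 score = numeric(0), strand = character(0),
                 cleavage = integer(0), in_register = logical(0))
    tr <- tr[order(-tr$in_register, tr$score, abs(tr$length - 22L)), ,
             drop = FALSE]
    rownames(tr) <- NULL
    loci$triggers[[i]] <- tr
  }
  loci
}

#' Per-library phasiRNA abundance matrix of PHAS loci
#'
#' Entry (locus, library) is the summed normalized abundance of in-register
#' phase-length reads falling inside the locus.
#'
#' @param loci `phas_loci`.
#' @param reads `srna_reads` with normalized abundances
#'   (see [normalize_rp15m()]).
#' @param hits `alignment_hits` with a `seq` column linking hits to `reads`.
#' @param params [phasing_params()].
#' @param scale divide each row by its maximum (heat-map export).
#' @return numeric matrix, loci x libraries, rownames `chrom:start..end`
#'   (1-based inclusive).
#' @export
tissue_matrix <- function(loci, reads, hits, params = phasing_params(),
                          scale = FALSE) {
  if (is.null(reads$normalized)) stop("run normalize_rp15m() first")
  if (is.null(hits$seq)) stop("hits need a 'seq' column")
  libs <- colnames(reads$normalized)
  M <- matrix(0, NROW(loci), length(libs),
              dimnames = list(sprintf("%s:%d..%d", loci$chrom,
                                      loci$start + 1L, loci$end), libs))
  reg <- assign_register(hits, params)
  for (i in seq_len(NROW(loci))) {
    sel <- hits$chrom == loci$chrom[i] &
      reg$position >= loci$start[i] & reg$position < loci$end[i] &
      hits$length == params$phase & reg$register == loci$register[i]
    if (!any(sel)) next
    ridx <- unique(match(hits$seq[sel], reads$sequence))
    ridx <- ridx[!is.na(ridx)]
    if (length(ridx))
      M[i, ] <- colSums(reads$normalized[ridx, , drop = FALSE])
  }
  if (scale) {
    mx <- apply(M, 1L, max)
    M[mx > 0, ] <- M[mx > 0, , drop = FALSE] / mx[mx > 0]
  }
  M
}

#' Run the full PHAS detection pipeline
#'
#' [window_scan()] then [merge_windows()], optional structural-RNA exclusion,
#' and the single-peak filter.
#'
#' @param hits `alignment_hits` (optionally with `norm`).
#' @param params [phasing_params()].
#' @param annotation optional structural-RNA annotation for
#'   [exclude_structural()].
#' @return a `phas_scan` list: `windows`, `loci`, `params`.
#' @export
phas_scan <- function(hits, params = phasing_params(), annotation = NULL) {
  windows <- window_scan(hits, params)
  loci <- merge_windows(windows, params = params)
  if (!is.null(annotation)) loci <- exclude_structural(loci, annotation)
  loci <- filter_single_peak(loci, hits, params)
  structure(list(windows = windows, loci = loci, params = params),
            class = "phas_scan")
}

#' @export
print.phas_scan <- function(x, ...) {
  cat(sprintf("phas_scan: %d reported window(s) -> %d locus/loci at P <= %g\n",
              nrow(x$windows), nrow(x$loci), x$params$p_cutoff))
  if (nrow(x$loci)) {
    print.data.frame(utils::head(x$loci[, c("chrom", "start", "end",
                                            "register", "p_value",
                                            "phasing_score")], 10L))
  }
  invisible(x)
}

#' @export
summary.phas_scan <- function(object, ...) {
  cat(sprintf("PHAS scan with D=%d nt: %d window(s), %d locus/loci\n",
              object$params$phase, nrow(object$windows), nrow(object$loci)))
  if (nrow(object$loci)) {
    cat(sprintf("  locus span %d..%d bp; min P %.3g; max score %.2f\n",
                min(object$loci$end - object$loci$start),
                max(object$loci$end - object$loci$start),
                min(object$loci$p_value), max(object$loci$phasing_score)))
  }
  invisible(object)
}
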