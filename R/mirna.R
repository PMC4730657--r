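# miRNA locus calling: exact catalog matching, precursor excision, hairpin
# evaluation against community annotation criteria, locus dominance.

#' Default hairpin / calling thresholds
#'
#' Community annotation criteria for plant miRNAs: at most `max_mismatch`
#' unpaired mature positions in the miRNA:miRNA* duplex, at most `max_bulge`
#' nt of asymmetric bulge, at least `min_paired_fraction` of the mature paired,
#' and the mature must not span the terminal loop. All are configuration keys.
#'
#' @param min_len,max_len mature length bounds (nt).
#' @param abundance_floor minimum raw abundance summed over libraries for a
#'   read to seed a candidate (lower to 1 to keep rare miRNAs).
#' @param flank nt of genomic flank excised on the far side of the mature when
#'   building candidate precursors.
#' @param locus_flank nt around the precursor span considered the "locus" for
#'   the dominance check.
#' @param max_mismatch,max_bulge,min_paired_fraction hairpin pass criteria.
#' @param engine folding engine passed to [fold_sequences()].
#' @return named list of thresholds.
#' @export
mirna_thresholds <- function(min_len = 20L, max_len = 24L,
                             abundance_floor = 5L, flank = 250L,
                             locus_flank = 3000L, max_mismatch = 5L,
                             max_bulge = 3L, min_paired_fraction = 0.6,
                             engine = "auto") {
  list(min_len = min_len, max_len = max_len,
       abundance_floor = abundance_floor, flank = flank,
       locus_flank = locus_flank, max_mismatch = max_mismatch,
       max_bulge = max_bulge, min_paired_fraction = min_paired_fraction,
       engine = engine)
}

#' Exact matching against a known-miRNA catalog
#'
#' A read is annotated if and only if its canonicalized sequence is identical
#' to a catalog mature sequence; no partial or near matches.
#'
#' @param reads an `srna_reads` object or character vector of sequences.
#' @param catalog FASTA path, `DNAStringSet`, or named character vector of
#'   mature miRNA sequences (miRBase-style ids as names).
#' @return character vector of catalog ids (`NA` where unmatched), one per
#'   read, named by the read sequence.
#' @export
match_known <- function(reads, catalog) {
  seqs <- if (inherits(reads, "srna_reads")) reads$sequence
          else canonicalize_seq(reads)
  cat_seqs <- read_catalog(catalog)
  if (length(cat_seqs) == 0L) stop("catalog is empty")
  setNames(names(cat_seqs)[match(seqs, cat_seqs)], seqs)
}

read_catalog <- function(catalog) {
  if (methods::is(catalog, "DNAStringSet") || methods::is(catalog, "RNAStringSet")) {
    catalog <- setNames(as.character(catalog), names(catalog))
  } else if (is.character(catalog) && length(catalog) == 1L &&
             file.exists(catalog)) {
    ss <- Biostrings::readBStringSet(catalog)
    catalog <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  setNames(canonicalize_seq(catalog, what = "catalog"), names(catalog))
}

#' Excise candidate precursor windows around a genomic hit
#'
#' Two windows are tried, placing the mature near the 5' arm
#' (`[left - 20, left + length + flank)`) and near the 3' arm
#' (`[left - flank, left + length + 20)`), clipped to the chromosome.
#' Minus-strand hits are reverse-complemented so the precursor reads 5' to 3'.
#'
#' @param genome FASTA path, `DNAStringSet` or named character vector.
#' @param hit one-row `alignment_hits` data.frame (or list with `chrom`,
#'   `strand`, `left`, `length`).
#' @param flank flanking length in nt (> 0).
#' @return character vector of 1-2 precursor sequences with attributes
#'   `mature_offset` (1-based start of the mature within each precursor) and
#'   `span` (matrix of 0-based genomic `[start, end)` per window).
#' @export
excise_precursor <- function(genome, hit, flank = 250L) {
  if (flank <= 0L) stop("flank must be positive")
  genome <- as_genome(genome)
  chrom <- as.character(hit$chrom)
  if (!chrom %in% names(genome)) stop("hit chromosome not in genome: ", chrom)
  clen <- length(genome[[chrom]])
  left <- as.integer(hit$left); rl <- as.integer(hit$length)
  if (left < 0L || left + rl > clen) stop("hit outside chromosome bounds")
  win <- rbind(c(max(0L, left - 20L), min(clen, left + rl + flank)),
               c(max(0L, left - flank), min(clen, left + rl + 20L)))
  win <- unique(win)
  seqs <- character(nrow(win)); off <- integer(nrow(win))
  for (i in seq_len(nrow(win))) {
    s <- genome_slice(genome, chrom, win[i, 1L], win[i, 2L])
    off0 <- left - win[i, 1L]
    if (hit$strand == "-") {
      s <- revcomp(s)
      off0 <- nchar(s) - (off0 + rl)
    }
    seqs[i] <- s
    off[i] <- off0 + 1L
  }
  structure(seqs, mature_offset = off, span = win)
}

#' Evaluate a precursor hairpin for miRNA annotation criteria
#'
#' Folds the precursor (or uses a supplied structure), locates the
#' miRNA:miRNA* duplex as the longest coherent antiparallel helix pairing the
#' mature, and scores it: unpaired mature positions are duplex mismatches,
#' asymmetric interior loops contribute the bulge size, and the mature must
#' not fold back on itself (span the terminal loop). The candidate passes when
#' `duplex_mismatches <= max_mismatch`, `max_asym_bulge <= max_bulge`, and
#' `mature_paired_fraction >= min_paired_fraction`.
#'
#' @param precursor precursor sequence (5' to 3').
#' @param mature_offset 1-based start of the mature within the precursor.
#' @param mature_len mature length in nt.
#' @param thresholds see [mirna_thresholds()].
#' @param structure optional precomputed dot-bracket string (skips folding).
#' @return a `hairpin_report` list: `structure`, `mature_paired_fraction`,
#'   `duplex_mismatches`, `max_asym_bulge`, `terminal_loop_branched`,
#'   `duplex_overhang_ok`, `star_span` (1-based within precursor, or `NA`),
#'   `pass`.
#' @export
evaluate_hairpin <- function(precursor, mature_offset, mature_len,
                             thresholds = mirna_thresholds(),
                             structure = NULL) {
  precursor <- canonicalize_seq(precursor)
  n <- nchar(precursor)
  m0 <- as.integer(mature_offset); L <- as.integer(mature_len)
  if (m0 < 1L || m0 + L - 1L > n) stop("mature span outside precursor")
  db <- structure %||% fold_sequences(precursor, engine = thresholds$engine)
  if (nchar(db) != n) stop("structure length != precursor length")
  p <- pair_table(db)
  midx <- m0:(m0 + L - 1L)
  partners <- p[midx]
  paired <- which(!is.na(partners))
  spans_loop <- any(partners[paired] %in% midx)

  rep0 <- list(structure = db, mature_paired_fraction = 0,
               duplex_mismatches = L, max_asym_bulge = NA_integer_,
               terminal_loop_branched = FALSE, duplex_overhang_ok = FALSE,
               star_span = c(NA_integer_, NA_integer_), pass = FALSE)
  class(rep0) <- "hairpin_report"
  if (spans_loop || length(paired) < 2L) return(rep0)

  # longest run of strictly decreasing partners = the duplex helix
  run <- longest_decreasing_run(partners[paired])
  helix <- paired[run]
  frac <- length(helix) / L
  mism <- L - length(helix)
  asym <- 0L
  if (length(helix) >= 2L) {
    i1 <- midx[helix][-length(helix)]; i2 <- midx[helix][-1L]
    gm <- i2 - i1 - 1L
    gs <- p[i1] - p[i2] - 1L
    asym <- max(abs(gm - gs))
  }
  star_lo <- p[midx[helix[length(helix)]]]
  star_hi <- min(n, p[midx[helix[1L]]] + 2L)  # 2-nt 3' overhang of the star
  if (star_lo > star_hi) { tmp <- star_lo; star_lo <- star_hi; star_hi <- tmp }
  overhang_ok <- p[midx[helix[1L]]] + 2L <= n &&
    (star_hi < m0 || star_lo > m0 + L - 1L)

  # hairpin loops strictly between the duplex arms
  gap <- if (star_lo > m0 + L - 1L) c(m0 + L, star_lo - 1L)
         else c(star_hi + 1L, m0 - 1L)
  branched <- FALSE
  if (gap[2L] > gap[1L]) {
    inner <- substr(db, gap[1L], gap[2L])
    branched <- length(gregexpr("\\(\\.*\\)", inner)[[1L]]) > 1L &&
      gregexpr("\\(\\.*\\)", inner)[[1L]][1L] != -1L
  }
  out <- list(structure = db,
              mature_paired_fraction = frac,
              duplex_mismatches = mism,
              max_asym_bulge = asym,
              terminal_loop_branched = branched,
              duplex_overhang_ok = overhang_ok,
              star_span = c(star_lo, star_hi),
              pass = frac >= thresholds$min_paired_fraction &&
                mism <= thresholds$max_mismatch &&
                asym <= thresholds$max_bulge)
  class(out) <- "hairpin_report"
  out
}

#' @export
print.hairpin_report <- function(x, ...) {
  cat(sprintf(
    "hairpin_report: %s (paired %.2f, mismatches %d, bulge %s, %s loop)\n",
    if (x$pass) "PASS" else "fail", x$mature_paired_fraction,
    x$duplex_mismatches, as.character(x$max_asym_bulge),
    if (x$terminal_loop_branched) "branched" else "linear"))
  invisible(x)
}

longest_decreasing_run <- function(v) {
  best_s <- 1L; best_l <- 1L; s <- 1L
  if (length(v) >= 2L) for (i in 2L:length(v)) {
    if (v[i] < v[i - 1L]) {
      if (i - s + 1L > best_l) { best_l <- i - s + 1L; best_s <- s }
    } else s <- i
  }
  best_s:(best_s + best_l - 1L)
}

#' Locus dominance of a candidate read
#'
#' The fraction of the locus abundance carried by the candidate, and whether
#' it is the single most abundant distinct read at the locus (strict: ties are
#' not top).
#'
#' @param locus_hits data.frame of hits at the locus with columns `read_id`
#'   and `abundance` (per distinct read; reads hitting multiple positions in
#'   the locus are counted once).
#' @param candidate read id of the candidate.
#' @return list with `dominance_fraction` and `is_top`.
#' @export
locus_dominance <- function(locus_hits, candidate) {
  if (NROW(locus_hits) == 0L) stop("empty locus")
  ab <- tapply(locus_hits$abundance, locus_hits$read_id, max)
  if (!candidate %in% names(ab)) stop("candidate not among locus hits")
  cand <- ab[[candidate]]
  total <- sum(ab)
  others <- ab[names(ab) != candidate]
  list(dominance_fraction = unname(cand / total),
       is_top = length(others) == 0L || cand > max(others))
}

#' 5'-nucleotide composition of mature candidates
#'
#' @param x `mirna_calls`, `srna_reads`, or character vector of sequences.
#' @return named numeric fractions over A, C, G, U summing to 1.
#' @export
five_prime_composition <- function(x) {
  seqs <- if (inherits(x, "mirna_calls")) x$sequence
          else if (inherits(x, "srna_reads")) x$sequence
          else canonicalize_seq(x)
  if (length(seqs) == 0L) stop("empty candidate set")
  first <- as_rna(substr(seqs, 1L, 1L))
  tab <- table(factor(first, levels = c("A", "C", "G", "U")))
  as.numeric(tab / sum(tab)) |> setNames(c("A", "C", "G", "U"))
}

#' Attach genome-derived read sequences to hits lacking them
#' @param hits `alignment_hits` without a `seq` column (e.g. from BED).
#' @param genome genome FASTA path / `DNAStringSet`.
#' @return hits with a `seq` column (minus-strand hits reverse-complemented).
#' @export
attach_read_seq <- function(hits, genome) {
  genome <- as_genome(genome)
  seqs <- vapply(seq_len(nrow(hits)), function(i) {
    s <- genome_slice(genome, hits$chrom[i], hits$left[i],
                      hits$left[i] + hits$length[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }, "")
  hits$seq <- seqs
  hits
}

#' Call miRNA loci from reads and genome alignments
#'
#' Candidate seeds are 20-24 nt reads at or above the abundance floor. For
#' each genomic placement the candidate must be the single most abundant read
#' in its locus (precursor span +/- `locus_flank`), and at least one excised
#' precursor window must pass [evaluate_hairpin()]. Placements sharing a
#' mature sequence collapse into one call with a loci count.
#'
#' @param reads `srna_reads` (collapsed, length-filtered).
#' @param hits `alignment_hits` with a `seq` column (see [attach_read_seq()]).
#' @param genome genome FASTA path / `DNAStringSet`.
#' @param catalog optional known-miRNA catalog for [match_known()].
#' @param thresholds see [mirna_thresholds()].
#' @return a `mirna_calls` data.frame: `sequence` (RNA alphabet), `length`,
#'   `loci`, `abundance` (summed raw), per-library counts, `known`,
#'   `dominance_fraction`; per-placement detail in `attr(, "details")`.
#' @export
call_mirnas <- function(reads, hits, genome, catalog = NULL,
                        thresholds = mirna_thresholds()) {
  stopifnot(inherits(reads, "srna_reads"), is.data.frame(hits))
  if (is.null(hits$seq)) stop("hits need a 'seq' column; see attach_read_seq()")
  genome <- as_genome(genome)
  th <- thresholds
  total_ab <- rowSums(reads$abundance)
  names(total_ab) <- reads$sequence

  hit_ab <- total_ab[hits$seq]
  hit_ab[is.na(hit_ab)] <- 0
  seed <- which(hits$length >= th$min_len & hits$length <= th$max_len &
                  hit_ab >= th$abundance_floor)
  empty <- mirna_calls_frame(NULL, colnames(reads$abundance))
  if (length(seed) == 0L) return(empty)

  # dominance prefilter (cheap) before any folding
  hits_gr <- hits_to_granges(hits)
  pad <- th$locus_flank + th$flank + 20L
  regions <- GenomicRanges::GRanges(
    hits$chrom[seed],
    IRanges::IRanges(start = pmax(1L, hits$left[seed] + 1L - pad),
                     end = hits$left[seed] + hits$length[seed] + pad))
  ov <- GenomicRanges::findOverlaps(regions, hits_gr,
                                    ignore.strand = TRUE)
  keep <- logical(length(seed))
  dom_frac <- numeric(length(seed))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (i in seq_along(seed)) {
    loc <- sh[qh == i]
    dom <- locus_dominance(
      data.frame(read_id = hits$seq[loc], abundance = hit_ab[loc]),
      candidate = hits$seq[seed[i]])
    keep[i] <- dom$is_top
    dom_frac[i] <- dom$dominance_fraction
  }
  seed <- seed[keep]; dom_frac <- dom_frac[keep]
  if (length(seed) == 0L) return(empty)

  # excise all precursor windows, fold in one batch
  pre <- lapply(seed, function(i) excise_precursor(genome, hits[i, ], th$flank))
  all_seq <- unlist(lapply(pre, as.character), use.names = FALSE)
  all_db <- fold_sequences(all_seq, engine = th$engine)
  counts <- vapply(pre, length, 0L)
  db_split <- split(all_db, rep(seq_along(pre), counts))

  placements <- list()
  for (i in seq_along(seed)) {
    hp_best <- NULL
    offs <- attr(pre[[i]], "mature_offset")
    spans <- attr(pre[[i]], "span")
    for (w in seq_along(pre[[i]])) {
      hp <- evaluate_hairpin(pre[[i]][w], offs[w], hits$length[seed[i]],
                             th, structure = db_split[[i]][w])
      if (is.null(hp_best) ||
          (hp$pass && !hp_best$pass) ||
          (hp$pass == hp_best$pass &&
           hp$duplex_mismatches < hp_best$duplex_mismatches)) {
        hp_best <- hp
        hp_best$precursor <- pre[[i]][w]
        hp_best$precursor_span <- spans[w, ]
      }
    }
    if (hp_best$pass) {
      j <- seed[i]
      placements[[length(placements) + 1L]] <- list(
        seq = hits$seq[j], chrom = hits$chrom[j], strand = hits$strand[j],
        left = hits$left[j], length = hits$length[j],
        dominance = dom_frac[i], hairpin = hp_best)
    }
  }
  if (length(placements) == 0L) return(empty)

  by_seq <- split(placements, vapply(placements, `[[`, "", "seq"))
  libs <- colnames(reads$abundance)
  rows <- lapply(by_seq, function(pl) {
    s <- pl[[1L]]$seq
    ridx <- match(s, reads$sequence)
    c(list(sequence = s, length = nchar(s), loci = length(pl),
           abundance = unname(total_ab[s]),
           dominance_fraction = max(vapply(pl, `[[`, 0, "dominance"))),
      as.list(setNames(as.numeric(reads$abundance[ridx, ]), libs)))
  })
  calls <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  rownames(calls) <- NULL
  calls$known <- if (is.null(catalog)) NA_character_
                 else unname(match_known(calls$sequence, catalog))
  calls <- calls[order(-calls$abundance), , drop = FALSE]
  details <- by_seq[calls$sequence]
  calls$sequence <- as_rna(calls$sequence)
  attr(calls, "details") <- details
  class(calls) <- c("mirna_calls", "data.frame")
  calls
}

mirna_calls_frame <- function(x, libs) {
  df <- data.frame(sequence = character(0), length = integer(0),
                   loci = integer(0), abundance = numeric(0),
                   dominance_fraction = numeric(0))
  for (l in libs) df[[l]] <- numeric(0)
  df$known <- character(0)
  class(df) <- c("mirna_calls", "data.frame")
  df
}

#' @export
print.mirna_calls <- function(x, ...) {
  cat(sprintf("mirna_calls: %d mature miRNA(s)\n", nrow(x)))
  if (nrow(x)) {
    known <- sum(!is.na(x$known))
    cat(sprintf("  %d known, %d novel; 5' U fraction %.2f\n",
                known, nrow(x) - known,
                unname(five_prime_composition(chartr("U", "T", x$sequence))["U"])))
    show_cols <- intersect(c("sequence", "length", "loci", "abundance",
                             "known"), names(x))
    print.data.frame(utils::head(as.data.frame(x)[, show_cols, drop = FALSE],
                                 10L))
  }
  invisible(x)
}
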