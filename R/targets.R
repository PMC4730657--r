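# Position-weighted miRNA-target complementarity scoring (plant scheme):
# mismatch 1, G:U wobble 0.5, penalties doubled at miRNA positions 2-13,
# ungapped. Cleavage is predicted between miRNA positions 10 and 11.

target_weights <- function(L) {
  w <- rep(1, L)
  w[seq_len(L) >= 2 & seq_len(L) <= 13] <- 2
  w
}

pair_state <- function(a, b) {
  # a, b: single characters (T alphabet), antiparallel opposition
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

#' Score an ungapped miRNA:target duplex
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param site target site sequence 3' to 5', paired opposite the miRNA
#'   (position i of `site` faces position i of `mirna`).
#' @return a `target_alignment` list: `states` (per-position
#'   match/GU/mismatch), `score` (penalties: match 0, G:U 0.5, mismatch 1,
#'   doubled at miRNA positions 2-13), `state_string` (`|` match, `o` G:U,
#'   `x` mismatch), `mirna`, `site`.
#' @export
alignment_score <- function(mirna, site) {
  m <- strsplit(canonicalize_seq(mirna), "")[[1L]]
  s <- strsplit(canonicalize_seq(site), "")[[1L]]
  if (length(m) != length(s)) stop("site length must equal miRNA length")
  states <- pair_state(m, s)
  pen <- c(match = 0, GU = 0.5, mismatch = 1)[states]
  score <- sum(pen * target_weights(length(m)))
  structure(list(mirna = paste(m, collapse = ""),
                 site = paste(s, collapse = ""),
                 states = unname(states),
                 state_string = paste(c(match = "|", GU = "o",
                                        mismatch = "x")[states], collapse = ""),
                 score = unname(score)),
            class = "target_alignment")
}

#' @export
print.target_alignment <- function(x, ...) {
  cat(sprintf("target_alignment: score %.1f\n", x$score))
  cat("  miRNA 5'-", as_rna(x$mirna), "-3'\n", sep = "")
  cat("          ", x$state_string, "\n", sep = "")
  cat("  site  3'-", as_rna(x$site), "-5'\n", sep = "")
  invisible(x)
}

#' Predicted cleavage coordinate on the target
#'
#' Cleavage occurs between the target bases opposite miRNA positions 10 and
#' 11; the returned coordinate is the 5' end of the 3' cleavage fragment,
#' i.e. the base paired with miRNA position 11. Coordinates follow whatever
#' convention `target_coord_of_pos1` uses (the target runs 3' to 5' along the
#' miRNA, so the coordinate decreases by 10).
#'
#' @param alignment a `target_alignment`.
#' @param target_coord_of_pos1 target coordinate paired with miRNA position 1.
#' @return the cleavage coordinate (`target_coord_of_pos1 - 10`).
#' @export
cleavage_site <- function(alignment, target_coord_of_pos1) {
  if (nchar(alignment$mirna) < 11L) stop("miRNA shorter than 11 nt")
  target_coord_of_pos1 - 10L
}

#' Scan transcripts for miRNA target sites
#'
#' Slides an ungapped window of miRNA length over each transcript, scores
#' every window with [alignment_score()]'s scheme, and reports windows at or
#' below the cutoff with their predicted cleavage coordinate.
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param transcripts named character vector / `DNAStringSet` / FASTA path of
#'   transcript sequences (5' to 3').
#' @param cutoff maximum score (default 3, the reporting cutoff; trigger
#'   searches conventionally use 5).
#' @return data.frame with one row per hit: `transcript`, `start`, `end`
#'   (1-based site coordinates on the transcript), `score`, `state_string`,
#'   `cleavage` (1-based coordinate of the 5' base of the 3' fragment).
#' @export
scan_targets <- function(mirna, transcripts, cutoff = 3) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  tx <- as_genome(transcripts)
  m <- strsplit(canonicalize_seq(mirna), "")[[1L]]
  L <- length(m)
  w <- target_weights(L)
  out <- list()
  for (nm in names(tx)) {
    tseq <- strsplit(as.character(tx[[nm]]), "")[[1L]]
    n <- length(tseq)
    if (n < L) next
    nwin <- n - L + 1L
    pen <- numeric(nwin)
    # miRNA position i faces transcript coordinate s + L - i (1-based window s)
    for (i in seq_len(L)) {
      tb <- tseq[seq_len(nwin) + (L - i)]
      st <- pair_state(m[i], tb)
      pen <- pen + c(match = 0, GU = 0.5, mismatch = 1)[st] * w[i]
    }
    hit <- which(pen <= cutoff)
    if (length(hit)) {
      out[[nm]] <- data.frame(
        transcript = nm, start = hit, end = hit + L - 1L,
        score = pen[hit],
        cleavage = hit + L - 11L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      cleavage = integer(0), state_string = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$state_string <- vapply(seq_len(nrow(res)), function(i) {
    site <- substr(as.character(tx[[res$transcript[i]]]), res$start[i],
                   res$end[i])
    alignment_score(paste(m, collapse = ""),
                    paste(rev(strsplit(canonicalize_seq(site), "")[[1L]]),
                          collapse = ""))$state_string
  }, "")
  res[order(res$transcript, res$score, res$start), , drop = FALSE]
}

#' Write a target-hit table to TSV
#' @param hits data.frame from [scan_targets()].
#' @param mirna_id label for the miRNA column.
#' @param path output file.
#' @export
write_target_table <- function(hits, mirna_id, path) {
  df <- cbind(mirna = mirna_id, hits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
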