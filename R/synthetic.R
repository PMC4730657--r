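# Deterministic synthetic data: toy genomes with planted miRNA hairpins and
# 21-nt phased loci obeying 2-nt 3'-overhang duplex geometry, multi-library
# overdispersed abundances, 24-nt-dominated background, and truth tables.

default_libraries <- c("leaf", "stem", "callus", "male_flower",
                       "female_flower")

# size mix emulating plant sRNA profiles: 24-nt (hc-siRNA) dominant,
# secondary 21-nt peak
default_size_mix <- function() {
  setNames(c(0.02, 0.03, 0.04, 0.20, 0.08, 0.08, 0.40,
             0.05, 0.03, 0.02, 0.02, 0.02, 0.01), 18:30)
}

#' Generate a reproducible random genome
#'
#' @param length chromosome length (nt).
#' @param gc_fraction GC content in (0, 1).
#' @param seed RNG seed.
#' @param name chromosome name.
#' @return a named `DNAStringSet` of one chromosome.
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed = 1L, name = "chr1") {
  if (length <= 0L) stop("length must be positive")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  g <- Biostrings::DNAStringSet(paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  names(g) <- name
  g
}

#' Start a synthetic scenario
#'
#' @param genome_length,gc_fraction,seed passed to [make_genome()].
#' @param libraries library (tissue) names.
#' @return a `synth_scenario`: genome, truth table, planted reads.
#' @export
synth_scenario <- function(genome_length, gc_fraction = 0.5, seed = 1L,
                           libraries = default_libraries) {
  structure(list(genome = make_genome(genome_length, gc_fraction, seed),
                 libraries = libraries,
                 truth = empty_truth(),
                 reads = NULL),
            class = "synth_scenario")
}

empty_truth <- function() {
  data.frame(id = character(0), kind = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             register = integer(0), trigger = character(0),
             cleavage = integer(0), stringsAsFactors = FALSE)
}

check_clear <- function(sim, start, end) {
  if (NROW(sim$truth) &&
      any(sim$truth$start < end & sim$truth$end > start))
    stop("position overlaps a previously planted feature")
}

replace_slice <- function(sim, start0, insert) {
  g <- sim$genome[[1L]]
  Biostrings::subseq(g, start0 + 1L, start0 + nchar(insert)) <-
    Biostrings::DNAString(insert)
  sim$genome[[1L]] <- g
  sim
}

#' Plant a miRNA hairpin into a scenario genome
#'
#' Writes `mature + loop + reverse complement of mature` (with `mismatches`
#' engineered non-pairing substitutions in the star arm) at `position`, and
#' records the mature span and abundance profile in the truth table.
#'
#' @param sim a `synth_scenario`.
#' @param mature_seq mature miRNA sequence (20-24 nt).
#' @param position 0-based genomic start of the mature.
#' @param loop_len terminal loop length (nt).
#' @param mismatches number of engineered unpaired duplex positions.
#' @param abundance_profile named per-library mean raw counts of the mature
#'   read (defaults to 150 in every library: a dominant mature).
#' @return the updated scenario.
#' @export
plant_hairpin <- function(sim, mature_seq, position, loop_len = 8L,
                          mismatches = 0L, abundance_profile = NULL) {
  stopifnot(inherits(sim, "synth_scenario"))
  mature <- canonicalize_seq(mature_seq)
  L <- nchar(mature)
  star <- revcomp(mature)
  if (mismatches > 0L) {
    # substitute star bases by their complements at interior positions:
    # neither Watson-Crick nor G:U pairing with the opposing mature base
    at <- round(seq(4L, L - 3L, length.out = mismatches))
    s <- strsplit(star, "")[[1L]]
    s[at] <- chartr("ACGT", "TGCA", s[at])
    star <- paste(s, collapse = "")
  }
  insert <- paste0(mature, paste(sample(c("A", "C", "T"), loop_len,
                                        replace = TRUE), collapse = ""), star)
  end0 <- position + nchar(insert)
  if (position < 0L || end0 > length(sim$genome[[1L]]))
    stop("hairpin outside genome")
  check_clear(sim, position, end0)
  sim <- replace_slice(sim, position, insert)
  tid <- sprintf("t%03d", NROW(sim$truth) + 1L)
  row <- data.frame(id = tid, kind = "mirna", chrom = names(sim$genome)[1L],
                    start = position, end = end0, strand = "+",
                    register = NA_integer_, trigger = NA_character_,
                    cleavage = NA_integer_, stringsAsFactors = FALSE)
  row$profile <- list(abundance_profile %||%
                        setNames(rep(150, length(sim$libraries)),
                                 sim$libraries))
  row$mature <- mature
  sim$truth <- rbind_truth(sim$truth, row)
  sim
}

rbind_truth <- function(truth, row) {
  if (!NROW(truth)) return(row)
  for (cn in setdiff(names(row), names(truth))) {
    truth[[cn]] <- if (is.list(row[[cn]])) vector("list", NROW(truth))
                   else rep(NA, NROW(truth))
  }
  for (cn in setdiff(names(truth), names(row))) {
    row[[cn]] <- if (is.list(truth[[cn]])) list(NULL) else NA
  }
  rbind(truth, row[names(truth)])
}

#' Plant a phased (PHAS) locus with its miRNA trigger site
#'
#' Inserts the reverse complement of the trigger miRNA so that the predicted
#' cleavage site (between miRNA positions 10 and 11) sits exactly at
#' `position`, then emits plus-strand 21-mers with 5' ends at
#' `position + 21 j` and minus-strand duplex partners with left ends 2 nt
#' upstream (2-nt 3' overhangs), each surviving dropout independently.
#' Abundances are negative-binomial draws around the per-library profile.
#'
#' @param sim a `synth_scenario`.
#' @param trigger_mirna trigger miRNA sequence (conventionally 22 nt).
#' @param cycles number of phased cycles (>= 3).
#' @param position 0-based cleavage coordinate (= 5' end of phasiRNA 0).
#' @param abundance_profile named per-library mean counts per phasiRNA
#'   (default 40 in every library).
#' @param dropout per-read loss probability in [0, 1).
#' @param seed RNG seed for abundance draws and dropout.
#' @param dispersion negative-binomial size parameter.
#' @return the updated scenario (reads appended to `sim$reads`).
#' @export
plant_phas <- function(sim, trigger_mirna, cycles, position,
                       abundance_profile = NULL, dropout = 0, seed = 1L,
                       dispersion = 2) {
  stopifnot(inherits(sim, "synth_scenario"))
  if (cycles < 3L) stop("cycles must be >= 3")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  trig <- canonicalize_seq(trigger_mirna)
  Lt <- nchar(trig)
  D <- 21L
  site_start <- position + 11L - Lt       # site end is position + 10
  span_end <- position + cycles * D
  if (site_start < 2L || span_end + D > length(sim$genome[[1L]]))
    stop("phased locus outside genome")
  check_clear(sim, site_start, span_end)
  sim <- replace_slice(sim, site_start, revcomp(trig))
  profile <- abundance_profile %||%
    setNames(rep(40, length(sim$libraries)), sim$libraries)
  set.seed(seed)
  tid <- sprintf("t%03d", NROW(sim$truth) + 1L)
  reads <- list()
  chrom <- names(sim$genome)[1L]
  for (j in seq_len(cycles) - 1L) {
    for (str in c("+", "-")) {
      left <- position + D * j - if (str == "-") 2L else 0L
      if (left < 0L) next
      if (runif(1) < dropout) next
      s <- genome_slice(sim$genome, chrom, left, left + D)
      if (str == "-") s <- revcomp(s)
      ab <- rnbinom(length(profile), mu = unname(profile), size = dispersion)
      if (all(ab == 0)) ab[sample(length(ab), 1L)] <- 1L
      reads[[length(reads) + 1L]] <- c(
        list(read_id = sprintf("%s_c%02d%s", tid, j, ifelse(str == "+", "p", "m")),
             seq = s, chrom = chrom, strand = str, left = left, length = D,
             truth_id = tid),
        setNames(as.list(ab), names(profile)))
    }
  }
  reads <- do.call(rbind, lapply(reads, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  row <- data.frame(id = tid, kind = "phas", chrom = chrom,
                    start = site_start, end = span_end, strand = "*",
                    register = position %% D, trigger = as_rna(trig),
                    cleavage = position, stringsAsFactors = FALSE)
  row$profile <- list(profile)
  row$mature <- NA_character_
  sim$truth <- rbind_truth(sim$truth, row)
  sim$reads <- if (is.null(sim$reads)) reads else rbind(sim$reads, reads)
  sim
}

#' Emit the multi-library dataset for a scenario
#'
#' Draws mature-miRNA reads for planted hairpins, adds uniformly placed
#' background reads with a 24-nt-dominated size mix and heavily overdispersed
#' low abundances (most distinct background reads are near-singletons, as in
#' real libraries), and returns collapsed reads plus their true placements.
#' Optionally writes per-library FASTQ, a BED of true placements, and a truth
#' TSV.
#'
#' @param sim a `synth_scenario` (after planting).
#' @param background_count number of background read placements.
#' @param size_mix named probability vector over sizes 18..30 for background
#'   read lengths.
#' @param seed RNG seed.
#' @param bg_mu,bg_size negative-binomial mean and size for per-library
#'   background abundances.
#' @param dir if non-`NULL`, directory to write `<library>.fastq`,
#'   `placements.bed`, `truth.tsv` and `genome.fa` into.
#' @return list with `reads` (an `srna_reads`), `hits` (`alignment_hits` with
#'   `seq`), `truth` (data.frame), `libraries`, and `files` (paths or `NULL`).
#' @export
emit_libraries <- function(sim, background_count = 0L, size_mix = NULL,
                           seed = 1L, bg_mu = 0.3, bg_size = 0.15,
                           dir = NULL) {
  stopifnot(inherits(sim, "synth_scenario"))
  set.seed(seed)
  libs <- sim$libraries
  chrom <- names(sim$genome)[1L]
  glen <- length(sim$genome[[1L]])
  rows <- list()
  if (!is.null(sim$reads)) rows[[1L]] <- sim$reads

  # mature reads of planted hairpins
  mi <- which(sim$truth$kind == "mirna")
  for (i in mi) {
    prof <- sim$truth$profile[[i]]
    ab <- rnbinom(length(prof), mu = unname(prof), size = 5)
    ab <- pmax(ab, 1L)
    rows[[length(rows) + 1L]] <- as.data.frame(c(
      list(read_id = paste0(sim$truth$id[i], "_mat"),
           seq = sim$truth$mature[i], chrom = chrom, strand = "+",
           left = sim$truth$start[i], length = nchar(sim$truth$mature[i]),
           truth_id = sim$truth$id[i]),
      setNames(as.list(ab), names(prof))), check.names = FALSE)
  }

  if (background_count > 0L) {
    mix <- size_mix %||% default_size_mix()
    sizes <- as.integer(sample(names(mix), background_count, replace = TRUE,
                               prob = mix))
    lefts <- floor(runif(background_count) * (glen - max(sizes) - 1L))
    strands <- sample(c("+", "-"), background_count, replace = TRUE)
    seqs <- substring(as.character(sim$genome[[1L]]), lefts + 1L,
                      lefts + sizes)
    neg <- strands == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    ab <- matrix(rnbinom(background_count * length(libs),
                         mu = bg_mu, size = bg_size),
                 nrow = background_count,
                 dimnames = list(NULL, libs))
    zero <- rowSums(ab) == 0
    if (any(zero)) {
      ab[cbind(which(zero), sample(length(libs), sum(zero), replace = TRUE))] <- 1L
    }
    bg <- data.frame(read_id = sprintf("bg%06d", seq_len(background_count)),
                     seq = seqs, chrom = chrom, strand = strands,
                     left = lefts, length = sizes, truth_id = "background",
                     stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(bg, ab)
  }

  all_reads <- do.call(rbind, rows)
  ab_mat <- as.matrix(all_reads[, libs, drop = FALSE])
  storage.mode(ab_mat) <- "integer"

  # collapse to distinct sequences
  seqs <- all_reads$seq
  u <- sort(unique(seqs))
  idx <- match(seqs, u)
  ab_dist <- rowsum(ab_mat, idx)
  reads <- new_srna_reads(u, `dimnames<-`(as.matrix(ab_dist),
                                          list(NULL, libs)))
  hits <- alignment_hits(all_reads$chrom, all_reads$strand, all_reads$left,
                         all_reads$length, read_id = all_reads$read_id,
                         seq = all_reads$seq)
  hits$truth_id <- all_reads$truth_id

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(genome = file.path(dir, "genome.fa"),
                  bed = file.path(dir, "placements.bed"),
                  truth = file.path(dir, "truth.tsv"),
                  fastq = file.path(dir, paste0(libs, ".fastq")))
    Biostrings::writeXStringSet(sim$genome, files$genome)
    write_bed(hits, files$bed)
    tr <- sim$truth
    tr$profile <- vapply(tr$profile, function(p)
      paste(sprintf("%s=%g", names(p), p), collapse = ";"), "")
    write.table(tr, files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    for (j in seq_along(libs)) {
      n <- ab_mat[, j]
      keep <- n > 0
      ss <- Biostrings::DNAStringSet(rep(all_reads$seq[keep], n[keep]))
      names(ss) <- sprintf("%s.%d", rep(all_reads$read_id[keep], n[keep]),
                           sequence(n[keep]))
      Biostrings::writeXStringSet(
        ss, files$fastq[j], format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(ss))))
    }
  }
  list(reads = reads, hits = hits, truth = sim$truth, libraries = libs,
       files = files)
}

#' Fixed multi-stage benchmark scenario
#'
#' The package's standard parameter-recovery setting: a 2 Mb toy genome with
#' planted miRNA hairpins (one of them carrying a single engineered duplex
#' mismatch), 21-nt phased loci of 6 cycles (12 distinct phased positions
#' across both strands, no dropout), and uniformly placed background reads.
#' Feature positions are spread deterministically across the genome.
#'
#' @param seed RNG seed driving the genome, abundances and background.
#' @param genome_length toy genome length (nt).
#' @param n_phas,n_mirna number of planted phased loci and hairpins.
#' @param cycles phased cycles per locus.
#' @param background number of background read placements.
#' @return the list returned by [emit_libraries()], plus `genome`, `truth`,
#'   and `triggers` (named vector of planted trigger sequences).
#' @export
benchmark_scenario <- function(seed = 1L, genome_length = 2000000L,
                               n_phas = 20L, n_mirna = 5L, cycles = 6L,
                               background = 50000L) {
  sim <- synth_scenario(genome_length, seed = seed)
  nfeat <- n_phas + n_mirna
  slots <- floor(seq(10000, genome_length - 10000, length.out = nfeat))
  set.seed(seed + 1L)
  slots <- slots + sample(-500:500, nfeat, replace = TRUE)
  mirna_slots <- slots[seq_len(n_mirna)]
  phas_slots <- slots[n_mirna + seq_len(n_phas)]
  for (i in seq_len(n_mirna)) {
    sim <- plant_hairpin(sim, random_mirna(21L, seed = seed + 10L + i),
                         position = mirna_slots[i],
                         mismatches = as.integer(i == 1L))
  }
  triggers <- character(n_phas)
  for (i in seq_len(n_phas)) {
    triggers[i] <- random_mirna(22L, seed = seed + 100L + i)
    sim <- plant_phas(sim, triggers[i], cycles = cycles,
                      position = phas_slots[i], seed = seed + 200L + i)
  }
  out <- emit_libraries(sim, background_count = background,
                        seed = seed + 999L)
  out$genome <- sim$genome
  out$triggers <- setNames(triggers, sprintf("trigger%02d", seq_len(n_phas)))
  out
}

#' Random mature miRNA sequence (5' U biased)
#' @param length mature length.
#' @param seed RNG seed.
#' @param first first nucleotide (default U, the dominant 5' nucleotide of
#'   plant miRNAs).
#' @return a sequence in the T alphabet.
#' @export
random_mirna <- function(length = 21L, seed = 1L, first = "T") {
  set.seed(seed)
  paste0(canonicalize_seq(first),
         paste(sample(c("A", "C", "G", "T"), length - 1L, replace = TRUE),
               collapse = ""))
}
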