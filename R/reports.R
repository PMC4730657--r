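# Run configuration, pipeline driver, report writers, and the qRT-PCR
# relative-expression helper.

#' Relative expression by the comparative ddCt method
#'
#' `2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))`: target vs
#' reference gene, normalized to a calibrator sample.
#'
#' @param ct_target,ct_ref Ct of target and reference in the sample.
#' @param ct_target_cal,ct_ref_cal Ct of target and reference in the
#'   calibrator.
#' @return relative expression (1 when ddCt = 0). Vectorized.
#' @export
delta_delta_ct <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  if (any(!is.finite(c(ct_target, ct_ref, ct_target_cal, ct_ref_cal))))
    stop("Ct values must be finite")
  2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))
}

#' Published cassava sRNA library summary (five tissues)
#'
#' The per-tissue raw/mapped abundance and distinct-read counts of the cassava
#' study's five libraries (leaf, stem, callus, male flower, female flower),
#' as printed, for consistency checks against [library_summary()]-shaped
#' output.
#'
#' @return data.frame with one row per tissue (no Total row): `tissue`,
#'   `raw_abundance`, `raw_distinct`, `mapped_abundance`, `mapped_distinct`.
#' @export
cassava_library_summary <- function() {
  data.frame(
    tissue = c("Leaf", "Stem", "Callus", "Male flower", "Female flower"),
    raw_abundance = c(29767700, 40192798, 37982146, 41360377, 34271994),
    raw_distinct = c(4027285, 7767697, 7680781, 8686961, 5324434),
    mapped_abundance = c(16821250, 24091871, 21214752, 24975854, 22895600),
    mapped_distinct = c(1677655, 3418587, 3221019, 4017652, 2493861),
    stringsAsFactors = FALSE)
}

#' Resolve a run configuration
#'
#' Defaults cover every stage; a YAML file (and/or an override list) may set
#' any known key; unknown keys are rejected. The resolved configuration gets a
#' stable content hash that reports embed.
#'
#' @param path optional YAML configuration file.
#' @param overrides optional named list applied after the file.
#' @return a `run_config` list with a `hash` attribute.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    genome = NULL, alignments = NULL, catalog = NULL, annotation = NULL,
    libraries = default_libraries,
    min_read_len = 18L, max_read_len = 30L,
    normalize_to = 15e6,
    mirna = mirna_thresholds(),
    phasing = unclass(phasing_params()),
    target_cutoff = 3,
    simulate = list(genome_length = 200000L, gc_fraction = 0.5,
                    n_phas = 3L, n_mirna = 3L, background = 2000L),
    outdir = "phasir_out")
  apply_keys <- function(cfg, upd, where) {
    for (k in names(upd)) {
      if (!k %in% names(cfg)) stop("unknown configuration key: ", where, k)
      if (is.list(cfg[[k]]) && is.list(upd[[k]]) && !is.null(names(upd[[k]]))) {
        cfg[[k]] <- apply_keys(cfg[[k]], upd[[k]], paste0(where, k, "."))
      } else cfg[[k]] <- upd[[k]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_keys(cfg, yaml::read_yaml(path), "")
  }
  if (!is.null(overrides)) cfg <- apply_keys(cfg, overrides, "")
  cfg$phasing <- do.call(phasing_params, cfg$phasing[
    setdiff(names(cfg$phasing), c("window_nt", "step_nt"))])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  class(cfg) <- "run_config"
  cfg
}

#' Attach per-hit normalized abundance
#' @param hits `alignment_hits` with `seq`.
#' @param reads normalized `srna_reads`.
#' @return hits with a `norm` column (summed normalized abundance per read).
#' @export
attach_norm <- function(hits, reads) {
  if (is.null(reads$normalized)) stop("run normalize_rp15m() first")
  tot <- rowSums(reads$normalized)
  hits$norm <- tot[match(hits$seq, reads$sequence)]
  hits$norm[is.na(hits$norm)] <- 0
  hits
}

#' Write PHAS loci (or miRNA loci) as GFF3
#'
#' Internal 0-based half-open coordinates convert to 1-based inclusive GFF3.
#'
#' @param loci `phas_loci` data.frame.
#' @param path output file.
#' @param type GFF3 feature type.
#' @export
write_phas_gff3 <- function(loci, path, type = "siRNA_locus") {
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  gr$type <- type
  gr$ID <- sprintf("PHAS%03d", seq_along(gr))
  if (!is.null(loci$p_value)) gr$pvalue <- format(loci$p_value, digits = 4)
  if (!is.null(loci$register)) gr$register <- loci$register
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the PHAS locus report table
#'
#' Layout: genomic location `chrN:start..end` (1-based inclusive), best
#' trigger annotation and sequence, locus annotation, register, P value,
#' phasing score.
#'
#' @param loci `phas_loci`, optionally after [assign_triggers()].
#' @param path output file.
#' @param annotation_labels optional character vector of locus annotations.
#' @export
write_phas_table <- function(loci, path, annotation_labels = NULL) {
  n <- NROW(loci)
  best <- lapply(seq_len(n), function(i) {
    tr <- loci$triggers[[i]] %||% NULL
    if (is.null(tr) || !nrow(tr)) return(c(NA_character_, NA_character_))
    c(tr$mirna[1L], NA_character_)
  })
  df <- data.frame(
    location = sprintf("%s:%d..%d", loci$chrom, loci$start + 1L, loci$end),
    mirna_annotation = vapply(best, `[`, "", 1L),
    locus_annotation = annotation_labels %||% rep("unannotated", n),
    register = loci$register, p_value = loci$p_value,
    phasing_score = loci$phasing_score, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a miRNA call table (precursor id, annotation, sequence, loci,
#' length, abundance, per-library counts)
#' @param calls `mirna_calls`.
#' @param path output file.
#' @export
write_mirna_table <- function(calls, path) {
  df <- cbind(precursor_id = sprintf("syn-m%04d", seq_len(NROW(calls))),
              annotation = ifelse(is.na(calls$known), "novel", calls$known),
              calls[, setdiff(names(calls), "known"), drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole pipeline on a configuration
#'
#' Stages: input (or simulation) -> size profile -> miRNA calling -> PHAS
#' detection (with triggers and tissue matrix). Writes the report bundle
#' (library summary, size profiles, miRNA table + GFF3, PHAS table + GFF3,
#' window table, tissue matrix, run log) into `cfg$outdir`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the file
#'   manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  result <- tryCatch({
    if (is.null(cfg$genome) || is.null(cfg$alignments)) {
      # synthetic scenario
      sim <- synth_scenario(cfg$simulate$genome_length,
                            cfg$simulate$gc_fraction,
                            seed = cfg$seed, libraries = cfg$libraries)
      glen <- cfg$simulate$genome_length
      slots <- floor(seq(2000, glen - 2000,
                         length.out = cfg$simulate$n_mirna +
                           cfg$simulate$n_phas))
      for (i in seq_len(cfg$simulate$n_mirna)) {
        sim <- plant_hairpin(sim, random_mirna(21L, seed = cfg$seed + i),
                             position = slots[i])
      }
      for (i in seq_len(cfg$simulate$n_phas)) {
        sim <- plant_phas(sim, random_mirna(22L, seed = cfg$seed + 100L + i),
                          cycles = 10L,
                          position = slots[cfg$simulate$n_mirna + i],
                          seed = cfg$seed + 200L + i)
      }
      emitted <- emit_libraries(sim, cfg$simulate$background,
                                seed = cfg$seed + 999L)
      genome <- sim$genome
      reads <- emitted$reads
      hits <- emitted$hits
    } else {
      genome <- as_genome(cfg$genome)
      hits <- load_alignments(cfg$alignments)
      if (is.null(hits$seq)) hits <- attach_read_seq(hits, genome)
      libs <- list()
      libs[["library1"]] <- hits$seq
      reads <- collapse_reads(libs)
    }

    stage <- "profile"
    reads <- length_filter(reads, cfg$min_read_len, cfg$max_read_len)
    hits <- hits[hits$length >= cfg$min_read_len &
                   hits$length <= cfg$max_read_len, , drop = FALSE]
    reads <- normalize_rp15m(reads)
    prof <- size_profile(reads)
    summ <- library_summary(reads)
    write.table(summ, file.path(cfg$outdir, "library_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round(prof$abundance_pct, 4),
                file.path(cfg$outdir, "size_profile_abundance.tsv"),
                sep = "\t", quote = FALSE)
    write.table(round(prof$distinct_pct, 4),
                file.path(cfg$outdir, "size_profile_distinct.tsv"),
                sep = "\t", quote = FALSE)

    stage <- "mirna"
    calls <- call_mirnas(reads, hits, genome, catalog = cfg$catalog,
                         thresholds = cfg$mirna)
    write_mirna_table(calls, file.path(cfg$outdir, "mirna_calls.tsv"))

    stage <- "phas"
    hits <- attach_norm(hits, reads)
    scan <- phas_scan(hits, cfg$phasing, annotation = cfg$annotation)
    loci <- scan$loci
    if (nrow(calls)) loci <- assign_triggers(loci, calls, genome, cfg$phasing)
    write_phas_table(loci, file.path(cfg$outdir, "phas_loci.tsv"))
    if (nrow(loci))
      write_phas_gff3(loci, file.path(cfg$outdir, "phas_loci.gff3"))
    write.table(scan$windows, file.path(cfg$outdir, "phas_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- tissue_matrix(loci, reads, hits, cfg$phasing)
    write.table(mat, file.path(cfg$outdir, "tissue_matrix.tsv"),
                sep = "\t", quote = FALSE)

    log <- c(sprintf("phasir %s", as.character(utils::packageVersion("phasir"))),
             sprintf("R %s", getRversion()),
             sprintf("seed %d", cfg$seed),
             sprintf("config_hash %s", attr(cfg, "hash")))
    writeLines(log, file.path(cfg$outdir, "run_log.txt"))
    list(reads = reads, hits = hits, profile = prof, summary = summ,
         mirna = calls, phas = scan, loci = loci, tissue_matrix = mat,
         outdir = cfg$outdir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
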