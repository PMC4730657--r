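test_that("catalog matching is exact, over U/T spelling", {
  cat <- c(miR1 = "UGGAGCUCCCUUCAUUCCAAU", miR2 = "UUGACAGAAGAGAGUGAGCAC")
  m <- match_known(c("TGGAGCTCCCTTCATTCCAAT",   # identical (DNA spelling)
                     "TGGAGCTCCCTTCATTCCAAA"),  # one terminal base off
                   cat)
  expect_equal(unname(m), c("miR1", NA))
  expect_error(match_known("ACGT", character(0)), "empty")

  # brute-force string comparison oracle on random reads
  set.seed(8)
  catalog <- setNames(replicate(50, random_seq(21)), paste0("c", 1:50))
  reads <- c(replicate(480, random_seq(21)), sample(catalog, 20))
  m2 <- match_known(reads, catalog)
  oracle <- vapply(reads, function(r) {
    hit <- names(catalog)[catalog == r]
    if (length(hit)) hit[1] else NA_character_
  }, "")
  expect_equal(unname(m2), unname(oracle))
})

test_that("precursor excision windows have the stated geometry", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_seq(10000, seed = 2)))
  hit <- list(chrom = "chr1", strand = "+", left = 1000L, length = 21L)
  pre <- excise_precursor(g, hit, flank = 250L)
  expect_equal(nchar(pre), c(291L, 291L))
  expect_equal(attr(pre, "mature_offset"), c(21L, 251L))
  # mature is where the offset says
  expect_equal(substr(pre[1], 21, 41),
               substr(as.character(g[[1]]), 1001, 1021))

  # 5' clipping at the chromosome edge
  pre2 <- excise_precursor(g, list(chrom = "chr1", strand = "+", left = 5L,
                                   length = 21L), flank = 250L)
  expect_equal(attr(pre2, "span")[, 1], c(0L, 0L))

  # minus-strand excision equals the reverse complement of the plus slice
  hitm <- list(chrom = "chr1", strand = "-", left = 1000L, length = 21L)
  prem <- excise_precursor(g, hitm, flank = 250L)
  sp <- attr(prem, "span")
  plus_slice <- substr(as.character(g[[1]]), sp[1, 1] + 1, sp[1, 2])
  expect_equal(prem[1], rc(plus_slice))

  expect_error(excise_precursor(g, list(chrom = "chr1", strand = "+",
                                        left = 9995L, length = 21L)),
               "bounds")
})

test_that("a perfect hairpin passes and a shuffled one fails", {
  hp <- perfect_hairpin(strrep("G", 20), loop = strrep("A", 8))
  r <- evaluate_hairpin(hp, 1, 20)
  expect_true(r$pass)
  expect_equal(r$duplex_mismatches, 0L)
  expect_false(r$terminal_loop_branched)
  expect_equal(r$mature_paired_fraction, 1.0)

  # fixed shuffle destroys pairing of the mature
  set.seed(42)
  shuf <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
  rs <- evaluate_hairpin(shuf, 1, 20)
  expect_false(rs$pass)
  expect_lt(rs$mature_paired_fraction, 0.6)

  expect_error(evaluate_hairpin(hp, 40, 20), "outside")
})

test_that("one engineered unpaired duplex base gives one mismatch", {
  sim <- synth_scenario(2000L, seed = 3)
  mature <- random_mirna(21L, seed = 31)
  sim <- plant_hairpin(sim, mature, position = 600L, mismatches = 1L)
  pre <- excise_precursor(sim$genome,
                          list(chrom = "chr1", strand = "+", left = 600L,
                               length = 21L), flank = 60L)
  r <- evaluate_hairpin(pre[1], attr(pre, "mature_offset")[1], 21L)
  expect_equal(r$duplex_mismatches, 1L)
  expect_true(r$pass)

  # independent structure inspection: the star arm differs from the perfect
  # reverse complement at exactly one position
  ins <- substr(as.character(sim$genome[[1]]), 601, 600 + 21 + 8 + 21)
  star <- substr(ins, 21 + 8 + 1, 21 + 8 + 21)
  diffs <- sum(strsplit(star, "")[[1]] != strsplit(rc(mature), "")[[1]])
  expect_equal(diffs, 1L)
})

test_that("locus dominance uses strict-top tie breaking", {
  hits <- data.frame(read_id = c("cand", "a", "b"),
                     abundance = c(90, 5, 5))
  d <- locus_dominance(hits, "cand")
  expect_equal(d$dominance_fraction, 0.9)
  expect_true(d$is_top)

  tie <- data.frame(read_id = c("cand", "a"), abundance = c(50, 50))
  expect_false(locus_dominance(tie, "cand")$is_top)

  set.seed(12)
  rnd <- data.frame(read_id = paste0("r", 1:40),
                    abundance = sample(1:100, 40))
  dr <- locus_dominance(rnd, "r1")
  expect_equal(dr$dominance_fraction,
               rnd$abundance[1] / sum(rnd$abundance))
  expect_error(locus_dominance(rnd[0, ], "r1"), "empty")
})

test_that("5' nucleotide composition is a tally over A/C/G/U", {
  x <- c("UAAA", "UCCC", "UGGG", "AGGG")
  comp <- five_prime_composition(x)
  expect_equal(unname(comp["U"]), 0.75)
  expect_equal(sum(comp), 1)
  expect_equal(unname(five_prime_composition(c("UUU", "UAA"))["U"]), 1)
  set.seed(5)
  seqs <- replicate(200, random_seq(21))
  tally <- table(factor(chartr("T", "U", substr(seqs, 1, 1)),
                        levels = c("A", "C", "G", "U"))) / 200
  expect_equal(unname(five_prime_composition(seqs)), as.numeric(tally))
})

test_that("planted hairpins are called; catalog entries annotated as known", {
  em <- small_scenario(seed = 5, background = 1500, n_phas = 0, n_mirna = 2)
  reads <- normalize_rp15m(length_filter(em$reads))
  hits <- em$hits
  planted <- chartr("U", "T", em$truth$mature[em$truth$kind == "mirna"])
  catalog <- setNames(planted[1], "mes-miR-test")

  calls <- call_mirnas(reads, hits, em$genome, catalog = catalog)
  called <- chartr("U", "T", calls$sequence)
  expect_true(all(planted %in% called))
  expect_equal(calls$known[match(planted[1], called)], "mes-miR-test")
  expect_true(is.na(calls$known[match(planted[2], called)]))
  expect_true(all(calls$dominance_fraction[match(planted, called)] > 0.5))

  # determinism
  calls2 <- call_mirnas(reads, hits, em$genome, catalog = catalog)
  expect_equal(as.data.frame(calls2), as.data.frame(calls))

  # every emitted candidate passed the hairpin criteria by construction
  det <- attr(calls, "details")
  expect_true(all(vapply(det, function(pl)
    all(vapply(pl, function(p) p$hairpin$pass, TRUE)), TRUE)))
  # loci equals the number of recorded passing placements
  expect_equal(calls$loci,
               unname(vapply(det[chartr("U", "T", calls$sequence)],
                             length, 0L)))
})
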