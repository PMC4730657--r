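test_that("collapsing counts distinct sequences per library", {
  r <- collapse_reads(list(L = c(rep("AAAA", 3), "CCCC")))
  expect_equal(length(r), 2L)
  expect_equal(unname(r$abundance[match("AAAA", r$sequence), "L"]), 3L)
  expect_equal(unname(r$abundance[match("CCCC", r$sequence), "L"]), 1L)

  # same sequence in two libraries -> one record with a two-entry abundance
  r2 <- collapse_reads(list(a = "ACGT", b = c("ACGU", "GGGG")))
  expect_equal(length(r2), 2L)
  expect_equal(unname(r2$abundance[match("ACGT", r2$sequence), ]), c(1L, 1L))

  # distinct count equals the set-size oracle on random 21-mers
  set.seed(11)
  seqs <- vapply(1:2000, function(i)
    random_seq(21), "")
  r3 <- collapse_reads(list(x = seqs))
  expect_equal(length(r3), length(unique(seqs)))
  expect_equal(sum(r3$abundance), length(seqs))
})

test_that("collapsing rejects N-containing and invalid records by name", {
  expect_error(collapse_reads(list(L = c("ACGT", "ANGT"))), "N")
  expect_error(collapse_reads(list(L = "ACXT")), "invalid characters")
})

test_that("collapse -> expand -> collapse is idempotent", {
  r <- collapse_reads(list(L = c(rep("AAAA", 3), "CCCC", rep("GGTT", 2))))
  expanded <- rep(r$sequence, r$abundance[, "L"])
  r2 <- collapse_reads(list(L = expanded))
  expect_equal(r2$sequence, r$sequence)
  expect_equal(r2$abundance, r$abundance)
})

test_that("length filter keeps exactly the 18-30 nt range", {
  r <- collapse_reads(list(L = c(strrep("A", 17), strrep("C", 18),
                                 strrep("G", 30), strrep("T", 31))))
  kept <- length_filter(r)
  expect_setequal(kept$length, c(18L, 30L))

  empty <- length_filter(r, 40, 50)
  expect_equal(length(empty), 0L)

  # brute-force recount on random lengths
  set.seed(3)
  lens <- sample(15:33, 1000, replace = TRUE)
  seqs <- vapply(lens, function(L) random_seq(L), "")
  rr <- collapse_reads(list(L = seqs))
  expect_equal(sum(length_filter(rr)$abundance),
               sum(lens >= 18 & lens <= 30))

  # idempotent
  expect_equal(length_filter(length_filter(rr))$sequence,
               length_filter(rr)$sequence)
  expect_error(length_filter(rr, -1, 10), "positive")
})

test_that("RP15M normalization scales by 15e6 / library total", {
  r <- collapse_reads(list(L = "ACGTACGTACGTACGTACGTA"))
  r$abundance[1, 1] <- 2L
  n <- normalize_rp15m(r, library_totals = c(L = 30e6))
  expect_equal(unname(n$normalized[1, 1]), 1.0)

  n2 <- normalize_rp15m(r, library_totals = c(L = 2))
  expect_equal(unname(n2$normalized[1, 1]), 15e6)

  # conservation on a synthetic library
  set.seed(4)
  rr <- collapse_reads(list(A = replicate(300, random_seq(21)),
                            B = replicate(200, random_seq(24))))
  nn <- normalize_rp15m(rr)
  expect_equal(unname(colSums(nn$normalized)), c(15e6, 15e6),
               tolerance = 1e-3)
  expect_error(normalize_rp15m(rr, library_totals = c(A = 0, B = 1)),
               "positive")
})

test_that("size profiles are percentage vectors summing to 100", {
  r <- collapse_reads(list(L = c(rep("ACGTACGTACGTACGTACGTA", 1))))
  p <- size_profile(r)
  expect_equal(unname(p$abundance_pct["21", "L"]), 100)

  # 3 distinct 21-mers (7,2,1) + one 24-mer (10): 50/50 abundance, 75/25 distinct
  libs <- list(L = c(rep("AAAAAAAAAAAAAAAAAAAAA", 7),
                     rep("CCCCCCCCCCCCCCCCCCCCC", 2),
                     rep("GGGGGGGGGGGGGGGGGGGGG", 1),
                     rep("TTTTTTTTTTTTTTTTTTTTTTTT", 10)))
  p2 <- size_profile(collapse_reads(libs))
  expect_equal(unname(p2$abundance_pct[c("21", "24"), "L"]), c(50, 50))
  expect_equal(unname(p2$distinct_pct[c("21", "24"), "L"]), c(75, 25))

  # mixed library matches a brute-force tally and sums to 100
  set.seed(9)
  lens <- sample(18:30, 400, replace = TRUE)
  seqs <- vapply(lens, function(L) random_seq(L), "")
  rr <- collapse_reads(list(M = seqs))
  pp <- size_profile(rr)
  expect_equal(sum(pp$abundance_pct[, "M"]), 100, tolerance = 1e-6)
  expect_equal(sum(pp$distinct_pct[, "M"]), 100, tolerance = 1e-6)
  tally <- 100 * table(factor(rr$length, levels = 18:30)) / length(rr)
  expect_equal(unname(pp$distinct_pct[, "M"]), as.numeric(tally))

  r_empty <- rr
  r_empty$abundance[, 1] <- 0L
  expect_error(size_profile(r_empty), "M")
})

test_that("collapsed FASTA dialect round-trips counts", {
  r <- collapse_reads(list(L = c(rep("ACGTACGTACGTACGTACGTA", 5),
                                 rep("TTTTGGGGCCCCAAAATTTTG", 2))))
  f <- withr::local_tempfile(fileext = ".fa")
  write_collapsed_fasta(r, f, library = "L")
  counts <- read_srna_file(f)
  r2 <- collapse_reads(list(L = counts))
  expect_equal(r2$abundance, r$abundance)
  expect_equal(r2$sequence, r$sequence)
})

test_that("library summary adds a consistent Total row", {
  r <- collapse_reads(list(A = c("AAAA", "AAAA", "CCCC"), B = "GGGG"))
  s <- library_summary(r)
  expect_equal(nrow(s), 3L)
  expect_equal(s$raw_abundance[3], sum(s$raw_abundance[1:2]))
  expect_equal(s$raw_distinct[3], sum(s$raw_distinct[1:2]))
})
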