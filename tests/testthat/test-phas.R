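pp <- phasing_params()

test_that("window geometry follows cycles x phase", {
  expect_equal(pp$window_nt, 189L)
  expect_equal(pp$step_nt, 63L)
  expect_error(phasing_params(phase = 0), "phase")
})

test_that("register assignment applies the +2 antisense offset", {
  h <- alignment_hits("chr1", c("+", "-"), c(105L, 103L), c(21L, 21L))
  r <- assign_register(h, pp)
  expect_equal(r$position, c(105L, 105L))
  expect_equal(r$register, c(0L, 0L))

  # a phased duplex population shares a single register after correction
  sim <- synth_scenario(5000L, seed = 6)
  sim <- plant_phas(sim, random_mirna(22L, seed = 61), cycles = 12L,
                    position = 1000L + 8L, dropout = 0, seed = 62)
  hits <- alignment_hits(sim$reads$chrom, sim$reads$strand,
                         as.integer(sim$reads$left),
                         as.integer(sim$reads$length))
  expect_equal(nrow(hits), 24L)
  regs <- assign_register(hits, pp)$register
  expect_equal(length(unique(regs)), 1L)
  expect_equal(unique(regs), (1000L + 8L) %% 21L)
})

test_that("hypergeometric p-value matches enumeration and phyper", {
  # toy case W=1: population 42, register class 2, draws 2, both in register
  toy <- phasing_params(window_cycles = 1L)
  expect_equal(phasing_pvalue(2, 2, toy), 1 / choose(42, 2))
  expect_equal(phasing_pvalue(5, 0, toy), 1)
  expect_error(phasing_pvalue(2, 3, toy), "k <= n")
  expect_error(phasing_pvalue(500, 1, pp), "population")

  # direct binomial-coefficient enumeration at default scale
  Tpop <- 2 * 9 * 21; m <- 2 * 9
  for (n in c(10, 15, 25)) {
    for (k in c(1, 3, 5, 8)) {
      direct <- sum(vapply(k:min(n, m), function(x)
        choose(m, x) * choose(Tpop - m, n - x), 0)) / choose(Tpop, n)
      expect_equal(phasing_pvalue(n, k, pp), direct, tolerance = 1e-12)
      expect_equal(phasing_pvalue(n, k, pp),
                   phyper(k - 1, m, Tpop - m, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }

  # non-increasing in k for fixed n
  ps <- vapply(0:10, function(k) phasing_pvalue(12, k, pp), 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("phasing score follows the log abundance-ratio form", {
  expect_equal(phasing_score(1, 0, 3, pp), log(11))
  expect_equal(phasing_score(0, 5, 7, pp), 0)
  expect_equal(phasing_score(3, 2, 2, pp), 0)   # below min_register_reads
  sc <- vapply(3:12, function(k) phasing_score(8, 3, k, pp), 0)
  expect_true(all(diff(sc) >= 0))
  expect_error(phasing_score(-1, 0, 3, pp), "non-negative")
})

test_that("window filters apply at their stated boundaries", {
  # 9 distinct 21-nt positions in one window: below the >=10 unique filter
  h9 <- alignment_hits("chr1", rep("+", 9), 21L * (0:8), rep(21L, 9))
  expect_equal(nrow(window_scan(h9, pp)), 0L)

  # 12 distinct positions but only 5 of length 21: fails the 50 % filter
  h12 <- alignment_hits("chr1", rep("+", 12), seq(0L, 110L, by = 10L),
                        c(rep(21L, 5), rep(24L, 7)))
  expect_equal(nrow(window_scan(h12, pp)), 0L)

  # a phased duplex population (6 cycles, both strands) passes all filters
  hd <- alignment_hits("chr1", rep(c("+", "-"), 6),
                       as.integer(rbind(100L + 21L * (0:5),
                                        98L + 21L * (0:5))),
                       rep(21L, 12))
  w <- window_scan(hd, pp)
  expect_gt(nrow(w), 0L)
  expect_true(all(w$register == 100L %% 21L))
  expect_true(any(w$k == 12L))
})

test_that("window scan equals a brute-force evaluation of every window", {
  set.seed(23)
  n <- 600
  hits <- alignment_hits("chr1", sample(c("+", "-"), n, TRUE),
                         sample(0:9800, n, TRUE),
                         sample(c(21L, 21L, 24L), n, TRUE))
  got <- window_scan(hits, pp)

  pos <- hits$left + ifelse(hits$strand == "-", 2L, 0L)
  key <- paste(hits$strand, pos, hits$length)
  u <- !duplicated(key)
  want <- list()
  for (ws in seq(0L, 9990L, by = 63L)) {
    sel <- u & pos >= ws & pos < ws + 189L
    if (!sum(sel)) next
    poskey <- paste(hits$strand, pos)[sel]
    nuniq <- length(unique(poskey))
    if (nuniq < 10) next
    if (mean(hits$length[sel] == 21L) < 0.5) next
    regs <- pos[sel][!duplicated(poskey)] %% 21L
    k <- max(table(regs))
    if (k < 3) next
    want[[length(want) + 1]] <- c(ws, nuniq, k)
  }
  expect_equal(nrow(got), length(want))
  if (length(want)) {
    wm <- do.call(rbind, want)
    expect_equal(got$start, wm[, 1])
    expect_equal(got$n_unique, wm[, 2])
    expect_equal(got$k, wm[, 3])
  }
})

test_that("window scan is invariant to hit input order", {
  set.seed(24)
  n <- 400
  hits <- alignment_hits("chr1", sample(c("+", "-"), n, TRUE),
                         sample(0:4000, n, TRUE), rep(21L, n))
  w1 <- window_scan(hits, pp)
  w2 <- window_scan(hits[sample(n), ], pp)
  expect_equal(w2, w1)
  expect_equal(merge_windows(w2, params = pp), merge_windows(w1, params = pp))
})

test_that("overlapping and bookended windows merge into loci", {
  w <- data.frame(chrom = "chr1", start = c(0L, 63L), end = c(189L, 252L),
                  n_unique = 12L, n21_fraction = 1, register = 5L,
                  k = c(10L, 8L), p_value = c(1e-6, 1e-4),
                  phasing_score = c(10, 5))
  l <- merge_windows(w, params = pp)
  expect_equal(nrow(l), 1L)
  expect_equal(c(l$start, l$end), c(0L, 252L))
  expect_equal(l$p_value, 1e-6)
  expect_equal(l$phasing_score, 10)

  w2 <- w; w2$start <- c(0L, 1063L); w2$end <- c(189L, 1252L)
  expect_equal(nrow(merge_windows(w2, params = pp)), 2L)

  # loci above alpha are discarded
  w3 <- w; w3$p_value <- c(0.01, 0.02)
  expect_equal(nrow(merge_windows(w3, params = pp)), 0L)

  # randomized window sets match the IRanges reduce oracle
  set.seed(25)
  starts <- sort(sample(seq(0L, 5000L, by = 63L), 30))
  wr <- data.frame(chrom = "chr1", start = starts, end = starts + 189L,
                   n_unique = 12L, n21_fraction = 1, register = 1L, k = 5L,
                   p_value = 1e-6, phasing_score = 1)
  lr <- merge_windows(wr, params = pp)
  ired <- IRanges::reduce(IRanges::IRanges(starts + 1L, starts + 189L))
  expect_equal(lr$start, IRanges::start(ired) - 1L)
  expect_equal(lr$end, IRanges::end(ired))
})

test_that("structural-RNA overlap removes loci", {
  loci <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                     end = c(400L, 5300L), register = 0L,
                     p_value = 1e-6, phasing_score = 1, n_windows = 1L)
  class(loci) <- c("phas_loci", "data.frame")
  ann <- data.frame(chrom = "chr1", start = 200L, end = 250L, type = "rRNA")
  expect_message(kept <- exclude_structural(loci, ann), "structural")
  expect_equal(kept$start, 5000L)

  expect_equal(exclude_structural(loci, ann[0, ]), loci)

  # brute-force overlap oracle
  set.seed(26)
  rs <- sample(0:20000, 30)
  rloci <- data.frame(chrom = "chr1", start = rs, end = rs + 300L,
                      register = 0L, p_value = 1e-6, phasing_score = 1,
                      n_windows = 1L)
  class(rloci) <- c("phas_loci", "data.frame")
  as_ <- sample(0:20000, 10)
  rann <- data.frame(chrom = "chr1", start = as_, end = as_ + 150L,
                     type = sample(c("rRNA", "tRNA", "gene"), 10, TRUE))
  keep_oracle <- vapply(seq_len(30), function(i) {
    str <- rann[rann$type %in% c("rRNA", "tRNA"), , drop = FALSE]
    !any(str$start < rloci$end[i] & str$end > rloci$start[i])
  }, TRUE)
  got <- suppressMessages(exclude_structural(rloci, rann))
  expect_equal(got$start, rloci$start[keep_oracle])
})

test_that("triggers are found and register-checked at planted loci", {
  sim <- synth_scenario(50000L, seed = 27)
  trig <- random_mirna(22L, seed = 271)
  cleav <- 20000L + 13L
  sim <- plant_phas(sim, trig, cycles = 10L, position = cleav, seed = 272)
  hits <- alignment_hits(sim$reads$chrom, sim$reads$strand,
                         as.integer(sim$reads$left),
                         as.integer(sim$reads$length))
  sc <- phas_scan(hits, pp)
  expect_equal(nrow(sc$loci), 1L)
  expect_equal(sc$loci$register, cleav %% 21L)

  loci <- assign_triggers(sc$loci, setNames(trig, "trig22"), sim$genome, pp)
  tr <- loci$triggers[[1]]
  expect_gte(nrow(tr), 1L)
  expect_equal(tr$mirna[1], "trig22")
  expect_equal(tr$score[1], 0)
  expect_true(tr$in_register[1])
  expect_equal(tr$cleavage[1], cleav)

  # a poor site (score > cutoff) is absent
  bad <- chartr("ACGT", "CAGT", trig)
  loci2 <- assign_triggers(sc$loci, c(bad22 = bad), sim$genome,
                           phasing_params(trigger_score_cutoff = 0))
  expect_equal(nrow(loci2$triggers[[1]]), 0L)

  # no candidate miRNAs: empty trigger table, locus retained
  loci3 <- assign_triggers(sc$loci, setNames(character(0), character(0)),
                           sim$genome, pp)
  expect_equal(nrow(loci3$triggers[[1]]), 0L)
  expect_equal(nrow(loci3), 1L)
})

test_that("tissue matrix sums in-register phase-length normalized abundance", {
  sim <- synth_scenario(30000L, seed = 28)
  prof <- c(leaf = 100, stem = 0.001, callus = 0.001,
            male_flower = 0.001, female_flower = 0.001)
  sim <- plant_phas(sim, random_mirna(22L, seed = 281), cycles = 8L,
                    position = 9000L, abundance_profile = prof, seed = 282)
  em <- emit_libraries(sim, background_count = 0L, seed = 283)
  reads <- normalize_rp15m(em$reads,
                           library_totals = setNames(rep(1e6, 5),
                                                     em$libraries))
  hits <- attach_norm(em$hits, reads)
  sc <- phas_scan(hits, pp)
  M <- tissue_matrix(sc$loci, reads, hits, pp)
  expect_equal(dim(M), c(nrow(sc$loci), 5L))
  expect_true(all(M[1, "leaf"] > M[1, colnames(M) != "leaf"]))

  Ms <- tissue_matrix(sc$loci, reads, hits, pp, scale = TRUE)
  expect_equal(unname(apply(Ms, 1, max)), rep(1, nrow(Ms)))
})

test_that("non-overlapping windows never yield more loci than stepped ones", {
  for (seed in 29:31) {
    set.seed(seed)
    n <- 500
    hits <- alignment_hits("chr1", sample(c("+", "-"), n, TRUE),
                           sample(0:20000, n, TRUE),
                           sample(c(21L, 24L), n, TRUE, prob = c(0.7, 0.3)))
    l3 <- merge_windows(window_scan(hits, pp), params = pp)
    pp9 <- phasing_params(step_cycles = 9L)
    l9 <- merge_windows(window_scan(hits, pp9), params = pp9)
    expect_lte(nrow(l9), nrow(l3))
  }
})

test_that("a high-dropout sparse locus is not called", {
  sim <- synth_scenario(20000L, seed = 32)
  sim <- plant_phas(sim, random_mirna(22L, seed = 321), cycles = 4L,
                    position = 8000L, dropout = 0.9, seed = 322)
  hits <- if (is.null(sim$reads)) alignment_hits(character(0), character(0),
                                                 integer(0), integer(0))
          else alignment_hits(sim$reads$chrom, sim$reads$strand,
                              as.integer(sim$reads$left),
                              as.integer(sim$reads$length))
  sc <- if (nrow(hits)) phas_scan(hits, pp) else NULL
  expect_true(is.null(sc) || nrow(sc$loci) == 0L)
})
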