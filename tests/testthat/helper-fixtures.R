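# shared fixture builders (all data generated in code)

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# perfect hairpin: mature + loop + reverse complement of the mature
perfect_hairpin <- function(mature, loop = "AACAACAA") {
  paste0(mature, loop, rc(mature))
}

# a small planted scenario shared by miRNA / PHAS integration tests
small_scenario <- function(seed = 5L, background = 2000L,
                           n_phas = 1L, n_mirna = 1L) {
  sim <- synth_scenario(100000L, seed = seed)
  if (n_mirna > 0) {
    for (i in seq_len(n_mirna)) {
      sim <- plant_hairpin(sim, random_mirna(21L, seed = seed + 10L + i),
                           position = 4000L + 12000L * (i - 1L))
    }
  }
  trig <- character(n_phas)
  if (n_phas > 0) {
    for (i in seq_len(n_phas)) {
      trig[i] <- random_mirna(22L, seed = seed + 40L + i)
      sim <- plant_phas(sim, trig[i], cycles = 10L,
                        position = 50000L + 3000L * (i - 1L) + i,
                        seed = seed + 70L + i)
    }
  }
  em <- emit_libraries(sim, background_count = background, seed = seed + 99L)
  em$genome <- sim$genome
  em$sim <- sim
  em$triggers <- trig
  em
}

write_test_sam <- function(path, records,
                           sq = "@SQ\tSN:chr1\tLN:100000") {
  writeLines(c("@HD\tVN:1.6\tSO:unknown", sq, records), path)
  path
}
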