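---
title: "Methods: sRNA profiling, miRNA annotation and PHAS locus detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sRNA profiling, miRNA annotation and PHAS locus detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasir)
```

# The problem

Plant small RNA libraries mix several biogenesis classes: ~21-nt miRNAs
excised from stem-loop precursors, 21-nt phased secondary siRNAs
(phasiRNAs) laid down head-to-tail downstream of a miRNA cleavage site, and
a large background of 24-nt heterochromatic siRNAs. Starting from collapsed
reads and their genome placements, `phasir` (i) profiles library composition,
(ii) calls miRNA loci with hairpin-structure criteria, (iii) scores
miRNA–target complementarity and predicts cleavage sites, and (iv) detects
*PHAS* loci with a sliding-window register statistic and assigns candidate
miRNA triggers.

# Read handling

Reads are canonicalized to a single alphabet (U→T internally; reports print
RNA). Collapsing produces one record per distinct sequence with a
per-library abundance vector; reads containing N are rejected as low
quality, the conservative reading of upstream quality filtering. Length
filtering keeps 18–30 nt. Abundances are normalized to **reads per 15
million** (RP15M): `normalized = raw × 15e6 / library_total`, so per-library
normalized sums are exactly 15 million when the totals are the column sums.
Coordinates are 0-based half-open everywhere internally; GFF3 output
converts to 1-based inclusive. Multi-mapped reads contribute one hit per
placement with full abundance (1/k weighting is available via the hit
table, not the default).

# miRNA calling

Candidate seeds are 20–24-nt reads with summed raw abundance at or above an
abundance floor (default 5; set 1 to keep rare miRNAs). For each genomic
placement:

1. **Dominance.** All hits within the precursor span ± 3 kb form the locus;
   the candidate must be the *single* most abundant distinct read there
   (ties fail, so ambiguous loci are never called).
2. **Precursor excision.** Two windows are tried, mature near the 5′ arm
   (`[left − 20, left + len + flank)`) and near the 3′ arm, with
   `flank = 250` nt — long enough for typical plant pre-miRNAs, short
   enough that folding stays local. Minus-strand hits are
   reverse-complemented first.
3. **Hairpin evaluation.** The window is folded (RNAfold minimum free
   energy when available; a bundled base-pair-maximization fold otherwise)
   and the miRNA:miRNA* duplex is located as the longest coherent
   antiparallel helix pairing the mature. Pass requires
   `mature_paired_fraction ≥ 0.6`, `duplex_mismatches ≤ 5` (unpaired mature
   positions), `max_asym_bulge ≤ 3` nt, and the mature must not fold onto
   itself (span the terminal loop). Branched terminal loops are flagged but
   do not fail a candidate, since authentic precursors with branched loops
   exist. All thresholds are configuration keys
   (`mirna_thresholds()`).

Placements sharing one mature sequence collapse into a single call whose
`loci` count is the number of passing placements; catalog annotation is by
exact sequence identity only.

**Known limitation.** These are structure-only criteria. Random ~290-nt
genomic windows fold into miRNA-like hairpins at a rate of roughly 0.4 %
per candidate under minimum-free-energy folding, so at genome scale a small
number of false hairpin calls is expected when many low-information seeds
survive the abundance floor. This is the reason community annotation
practice also asks for miRNA* (star) read evidence; here star support is
recorded when present but deliberately not required, so very deep scans
should treat novel single-locus calls as provisional.

# Target scoring

The scorer implements the standard plant position-weighted scheme: per
position, match 0, G:U wobble 0.5, mismatch 1.0, all doubled at miRNA
positions 2–13 (the 5′ pairing core); alignment is ungapped. Reporting
cutoffs: ≤ 3.0 for target tables, ≤ 5.0 for trigger searches. Whether an
"expectation score" from other tools shares this scale is left as
configuration, not asserted. Cleavage is placed between miRNA positions 10
and 11; the reported coordinate is the 5′ end of the 3′ cleavage fragment,
which depends only on the 5′ anchoring (a 22-nt and a 21-nt miRNA with the
same 5′ end predict the same site).

# PHAS detection

## Register assignment

A hit's phasing position is its 5′ end; minus-strand positions receive a
**+2 nt offset** because sRNA duplexes carry 2-nt 3′ overhangs, which puts
both strands of a phased duplex into one residue class mod 21 (the
*register*).

## Window scan

Windows of `W × D` = 9 × 21 = 189 bp start at multiples of `S × D` = 63 bp
(grid anchored at coordinate 0 of each chromosome; the anchoring is a
convention, and the 3-cycle step makes the scan insensitive to it). A
window is reported when

* ≥ 10 distinct offset-corrected 5′ positions (strand-distinct) are
  occupied,
* ≥ 50 % of the distinct reads are 21 nt, and
* the best register holds ≥ 3 distinct positions (ties break to the
  smallest register index, for determinism).

"Unique reads" is interpreted as distinct offset-corrected positions of
distinct sequences: abundance is deliberately ignored by the filters
(position-distinctness is what the null model draws) and used only by the
phasing score and tissue matrix.

## The phasing P value

With `T = 2 W D = 378` possible positions in a window (both strands; the
two-strand population is the default and a configuration choice) of which
`m = 2 W = 18` lie in any one register, and `n` occupied positions of which
`k` share the best register, significance is the hypergeometric upper tail

$$P = \sum_{x=k}^{\min(n,m)} \frac{\binom{m}{x}\binom{T-m}{n-x}}{\binom{T}{n}}.$$

It is computed in log space with log-gamma (log-binomial-coefficient)
arithmetic and a log-sum-exp reduction, accurate to better than 1e-12
relative; unit tests pin it against direct coefficient enumeration and
against hypergeometric sampling. No multiple-register correction is applied
across the 21 registers, matching common practice in this pipeline family.

## Phasing score, merging and screening

The per-window score is `(k − 2) · ln(1 + 10 P /(1 + U))` with `P` the
summed normalized abundance of in-register 21-nt reads and `U` everything
else; it is 0 below 3 in-register positions. Overlapping or bookended
reported windows merge into loci (P value = member minimum, register from
that window, score = member maximum); loci above α = 0.001 are discarded.
Two automated proxies replace manual inspection: loci overlapping
tRNA/rRNA/snoRNA annotation by ≥ 1 bp are removed, and loci where a single
position carries > 80 % of the abundance are dropped as single-peak
artifacts.

## Trigger assignment

Each locus ± one window span is scanned on both strands for miRNA
complementary sites with score ≤ 5. A site is *in register* when its
predicted cleavage coordinate matches the locus register mod 21 within
± 1 nt (the tolerance is configurable; minus-strand sites are
duplex-corrected by the same 2-nt overhang geometry before the comparison).
Hits are ordered by in-register status, then score, preferring 22-nt
miRNAs on ties — triggers of phasiRNA production are characteristically
22 nt.

# The synthetic-data generator

`synth_scenario()` builds a uniform random genome (GC fraction 0.5 by
default); `plant_hairpin()` writes `mature + loop + reverse complement`
stems (engineered mismatches substitute star bases by their complements, so
they can neither Watson-Crick nor wobble pair); `plant_phas()` inserts a
trigger complementary site whose predicted cleavage coordinate seeds
plus-strand 21-mers at `cleavage + 21 j` with minus-strand partners 2 nt
upstream. `emit_libraries()` adds uniformly placed background reads with a
24-nt-dominated size mix and draws abundances from negative binomials.

Chosen study conditions, fixed once: five tissue libraries; planted mature
abundance mean 150 per library (a clearly dominant mature, as in locus
plots of real miRNA loci); phasiRNA abundance mean 40 per library with
dispersion 2; background abundance mean 0.3 per library with dispersion
0.15, making most distinct background reads near-singletons concentrated in
one library, as in real collapsed libraries. The benchmark scenario
(`benchmark_scenario()`) plants 20 phased loci of 6 cycles (12 distinct
phased positions) and 5 hairpins (one with a single engineered duplex
mismatch) on a 2 Mb genome with 50,000 background placements — sizes chosen
so a full parameter-recovery run completes in minutes on one core while
windows still see realistic background densities.

What the generator does **not** emulate: sequencing error, adapter
artifacts, multi-mapping families (each planted read is unique), length
heterogeneity within a phased locus, strand-biased phasiRNA accumulation,
and genome repeat structure. Passing recovery tests therefore demonstrates
correctness of the statistics and geometry, not robustness to alignment
ambiguity or repeat-rich genomes.

# Numerical and degenerate-input choices

* Hypergeometric tail in log space; `P(X ≥ 0) = 1` exactly; `k > n` or
  `n > T` are errors, not clamps.
* Register ties break to the smallest index; dominance ties fail the
  candidate; equal-score target sites are all reported.
* Empty inputs: empty read sets filter to empty; an empty library or
  transcript set errors by name; a locus with no candidate triggers keeps
  an empty trigger table rather than disappearing.
* Folding: RNAfold output is used as-is (one minimum-energy structure); the
  fallback maximizes base pairs with a 3-nt minimum hairpin loop and a
  deterministic traceback, so tests are reproducible without an external
  folder.

# Problem sizes in the test-suite

Unit tests run on toy chromosomes (2–100 kb) with hundreds to a few
thousand reads; the acceptance checks run the 2 Mb benchmark once for PHAS
and miRNA recovery and once background-only, plus a 10^6-draw sampling
check of the phasing statistic. The full suite completes in a few minutes
on one core.
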