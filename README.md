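# haplospat

Spatial distribution analysis of mitochondrial haplotypes for invasion
genetics.

When an invasive insect spreads from a single introduction, its mtDNA
haplotypes should be distributed across the landscape more or less at
random: common haplotypes common everywhere, rare ones scattered by
chance. Multiple independent incursions leave a different signature —
dominant haplotypes missing from some regions, locally over-represented
rare haplotypes. `haplospat` tests for that signature in a
haplotype-by-location count table, and provides the surrounding workflow:
haplotype calling from COI amplicons with pseudogene (NUMT) screening,
diversity statistics, a null-model self-validation harness, and
distance-based population structure (pairwise Φ~ST~, hierarchical AMOVA).
A synthetic-data generator makes every stage testable without external
data.

## The test

Given an *R* × *C* table of counts *Z*~obs,ij~ of haplotype *i* at
location *j*, the null model redistributes the *N* observations at random
while holding every row and column total fixed (Patefield's algorithm),
which controls simultaneously for unequal sampling effort per location
and unequal haplotype abundance. Over *M* random tables it accumulates
the per-cell null means Z̄~ran,ij~ and evaluates

- the whole-table departure statistic
  χ²~obs~ = Σ~ij~ (Z~obs,ij~ − Z̄~ran,ij~)² / Z̄~ran,ij~,
  referred to the randomized distribution of the same statistic;
- the per-cell effect statistic TS~DIFF~ = Z~obs,ij~ − Z̄~ran,ij~
  (positive = over-represented, negative = under-represented);
- two-tailed permutation P-values
  P = min(N~GreaterEqual~, N~LessEqual~)/M × 2, with inclusive tails and
  capped at 1.0 (a P of exactly 0 means no random table reached the
  observed value);
- Benjamini–Hochberg FDR calls over all R×C cell tests jointly
  (default rate 0.10).

This is a non-parametric alternative to Fisher's exact test for sparse
tables, in the spirit of null-model analyses of species co-occurrence
matrices.

## Worked example

Simulate a study-scale dataset (25 haplotypes, 11 locations, 226
individuals) with spatial segregation, and test it:

```r
library(haplospat)

m  <- simulate_matrix(sim_config(segregation_strength = 0.2, seed = 11))
st <- spatial_test(m, M = 10000, fdr = 0.10, seed = 12)
st
#> Fixed-margin randomization test of haplotype x location counts
#>   table: 17 haplotypes x 11 locations, N = 226
#>   null means: monte_carlo; M = 10000 random tables
#>   chi2_obs = 517, two-tailed permutation P = 0
#>   cells significant at FDR 0.10: 11 of 187

head(summary(st)$cells, 5)
#>   haplotype location observed expected ts_diff p direction
#> 1    Hap_02   Loc_01       14   5.3951  8.6049 0      over
#> 6    Hap_02   Loc_06        1   9.9085 -8.9085 0     under
#> 7    Hap_15   Loc_06        6   0.8832  5.1168 0      over
#> 8    Hap_21   Loc_06        5   0.7118  4.2882 0      over
#> 9    Hap_17   Loc_08        7   0.8620  6.1380 0      over
```

The whole-table χ²~obs~ = 517 exceeds every one of the 10,000 randomized
statistics (P = 0), and the cell-level calls name the combinations
driving it: haplotype Hap_02 is over-represented at Loc_01 (14 observed
vs 5.4 expected) while simultaneously depleted at Loc_06 — exactly the
pattern of location-biased haplotype frequencies the generator planted.
`plot(st)` draws the four-state over/under × significant/non-significant
heat table.

The null model validates itself by repeated analysis of null pseudo-data
(rejection rate at α = 0.05 should be 0.05 and the P-value histogram
flat):

```r
tpl <- simulate_matrix(sim_config(seed = 5), require_full = TRUE)
validate_null(tpl, n_tests = 200, reps_per_test = 500, seed = 6)
#> Null-model self-validation
#>   200 pseudo-datasets x 500 randomizations each (margin allocation)
#>   rejection rate at alpha = 0.05: 0.0450 (expected 0.05)
#>   P-value uniformity chi2 = 25.80 (P = 0.136), 20 bins
#>   pseudo-tables discarded for empty margins: 5285
```

Sequence-level entry points: `read_fasta_with_metadata()`,
`call_haplotypes()`, `qc_report()` (stop-codon and amino-acid
conservation screens under the invertebrate mitochondrial code),
`haplotype_diversity()` / `nucleotide_diversity()` (Nei estimators with
standard errors), `pairwise_phist()` / `amova()` for population
structure, and `run_pipeline()` to chain everything with one seed.

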