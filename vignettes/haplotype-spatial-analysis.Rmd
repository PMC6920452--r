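---
title: "Testing spatial randomness of mtDNA haplotype distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing spatial randomness of mtDNA haplotype distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplospat)
```

## The scientific question

Invasion genetics often has to decide between two histories that produce
superficially similar data: a single introduction whose descendants
spread across a landscape, versus several independent introductions
seeding different regions. Under a single spreading introduction,
maternally inherited mtDNA haplotypes should be distributed across
sampling locations essentially at random once sampling effort and
overall haplotype abundance are accounted for. Multiple incursions leave
location-specific distortions: dominant haplotypes absent where a
different founder arrived, rare haplotypes locally over-represented.

`haplospat` turns that contrast into a formal test on a
haplotype-by-location contingency table, together with the supporting
workflow: haplotype calling from COI amplicons with pseudogene
screening, diversity estimation, a self-validation harness for the null
model, and distance-based population structure summaries.

## The fixed-margin randomization test

Let $Z_{obs,ij}$ be the number of individuals carrying haplotype $i$
sampled at location $j$, with $N$ individuals in total. The null
hypothesis is that haplotypes occur independently of location. Plain
independence tests are unreliable here because the table is sparse (many
singleton haplotypes) and sampling effort is very uneven across
locations. The null model therefore *conditions on both margins*: random
tables are drawn uniformly from all tables with exactly the observed row
and column totals, using Patefield's AS159 algorithm
(`stats::r2dtable()` behind `sample_random_table()`).

Over $M$ random tables (default 10,000) the ensemble accumulates
per-cell null means $\bar Z_{ran,ij}$ and tail counts. Three statistics
follow:

* **Whole table.**
  $\chi^2_{obs} = \sum_{ij} (Z_{obs,ij} - \bar Z_{ran,ij})^2 / \bar
  Z_{ran,ij}$, referred not to a $\chi^2$ distribution but to the
  randomized distribution of the same statistic (each random table
  scored against the ensemble mean).
* **Per cell.** $TS_{DIFF} = Z_{obs,ij} - \bar Z_{ran,ij}$; its sign is
  the direction of the departure. Because the margins are fixed, every
  row and column of $TS_{DIFF}$ sums to exactly zero when the analytic
  means are used.
* **P-values.** Two-tailed permutation form
  $P = \min(N_{GreaterEqual}, N_{LessEqual}) / M \times 2$ with
  *inclusive* tails. Since both tail counts include the equality term,
  $P$ can exceed 1 and is then capped at 1.0. Conversely $P = 0$ is a
  legitimate outcome meaning no random table reached the observed value;
  it is reported as written rather than floored, matching the
  conventional "P = 0.000" report for permutation tests.

Cell-level multiplicity is controlled with the Benjamini–Hochberg
step-up procedure applied jointly to all $R \times C$ cell P-values
(`fdr_calls()`, backed by `p.adjust(method = "BH")`). The default rate
is 0.10; it is a plain argument because reasonable analyses also use
0.05.

### Monte-Carlo versus analytic null means

The faithful procedure estimates $\bar Z_{ran,ij}$ from the same table
stream used for the tail counts (two passes over one seeded stream).
`means = "analytic"` instead substitutes the closed form $r_i c_j / N$,
in which case $\chi^2_{obs}$ is exactly the Pearson statistic — this is
the internal oracle used by the test suite, and is also faster. The
difference matters numerically: the Monte-Carlo mean carries sampling
noise of order $\sigma_{ij}/\sqrt M$ per cell, which propagates to a
standard deviation of roughly one unit (sparse 25 × 11 tables at
$M = 10^4$) in the whole-table statistic. Agreement between the two
modes is therefore checked at three standard errors of the
hypergeometric cell variance, not at a fixed small tolerance.

Cells whose Monte-Carlo mean is zero would make the statistic undefined;
after empty rows/columns are dropped this can only happen for extremely
sparse cells never visited by the stream. `build_null_ensemble()` treats
it as an error; the high-throughput validation harness drops such cells
from the statistic for that replicate, which leaves the null calibration
intact (the same rule is applied to observed and randomized tables).

### Zero margins and degenerate tables

Rows or columns with zero total are dropped with a warning when the
`contingency_matrix` is built ($\chi^2$ is undefined for them). Forced
tables — a single row or column — are handled explicitly: every
randomization equals the observation, all tail counts equal $M$, and all
P-values cap at 1.

## Validating the null model

`validate_null()` re-derives the test's operating characteristics
empirically. Pseudo-observed tables are generated under the null by
allocating the template's $N$ observations to cells independently with
probability proportional to the product of the template's marginal
frequencies (`allocation = "margin"`; a uniform-over-cells option
exists). This is the independence hypothesis with expected margins
matching the template. Realizations with an empty row or column are
discarded and redrawn — the test is undefined for them — and the
discard count is reported rather than silently absorbed. Each accepted
pseudo-table is tested with the full whole-table machinery, and the
harness reports the rejection rate at $\alpha$, the P-value histogram,
and a goodness-of-fit statistic for rectangularity.

At the study's scale (25 haplotypes × 11 locations, $N = 226$, dominant
haplotypes plus many rare ones) roughly 1 in 30 pseudo-tables survives
the empty-margin rule, because singleton haplotypes are often allocated
nowhere; this reproduces the exclusion phenomenon expected for sparse
templates. Rejection is declared at $P \le \alpha$ (ties on the discrete
permutation scale count), with $\alpha = 0$ defined to reject nothing.

Problem sizes: the package's own checks run the harness at 1,000
pseudo-datasets × 1,000 randomizations, which brackets the nominal 0.05
within three binomial standard errors (±0.021); unit tests use smaller
harnesses with correspondingly wider binomial bands.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 25 haplotypes, 11 locations,
226 observations. The default haplotype frequency spectrum places 80% of
individuals on five dominant haplotypes with the top two carrying 68%
(0.40, 0.28, 0.05, 0.04, 0.03) and spreads the remaining 20% equally
over twenty rare haplotypes — the dominant-plus-singletons shape typical
of a recently established invasive population. Sampling effort per
location defaults to uniform but is a parameter
(`location_weights`), since real surveys are uneven.

Spatial structure is a single knob: each location's spectrum is drawn
from $\mathrm{Dirichlet}(\text{global spectrum} / s)$ with
$s$ = `segregation_strength`. $s = 0$ is the independence null;
increasing $s$ shrinks the Dirichlet concentration and produces
increasingly location-specific haplotype frequencies, emulating multiple
incursions. Power saturates quickly: at $N = 226$ the whole-table test
already rejects ~80% of tables at $s = 0.02$, so ordering checks use
strengths well below 0.1.

Sequence-level simulation (`simulate_coi_dataset()`) builds a 548-bp
ancestral open reading frame free of in-frame stops under the
invertebrate mitochondrial code (TAA/TAG stop, TGA = Trp), then derives
haplotypes by transition substitutions placed preferentially (90%) at
third codon positions — under this code all third-position transitions
between sense codons are synonymous, so most simulated differences are
silent, as in real conspecific COI variation. Decoy NUMT-like sequences
(a copy of a true haplotype with one internal codon replaced by a stop)
can be injected at a configurable rate and are labelled in the metadata,
so the sensitivity of the stop-codon screen is measurable against truth.

What the generator does **not** emulate: coalescent genealogies,
realistic mutation-rate heterogeneity, migration through time,
sequencing error other than the stop-codon decoys, and alignment
artefacts (amplicons are same-locus and position-aligned by
construction). Passing tests on synthetic data therefore demonstrate the
correctness of the statistical machinery under the stated sampling
model, not robustness to those real-data complications.

## Haplotype calling and pseudogene QC

`call_haplotypes()` collapses identical sequences; any difference —
including an ambiguous N, deliberately treated as a mismatch so
uncertain reads are not merged — separates haplotypes. Labels are
assigned deterministically (`Hap_01`, … by decreasing count, ties by
first appearance), with a user label map available for published naming
schemes. Unequal lengths are an error unless trimming to the common
window is requested; the package assumes same-locus amplicons sharing a
start position and does not align.

The NUMT screens in `qc_report()` follow standard practice for COI
datasets: premature stop codons under the invertebrate mitochondrial
code; classification of amino-acid substitutions relative to the
dominant haplotype by fixed side-chain categories (hydrophobic, small,
polar, charged — Taylor-style sets, under which L/V and I/M are
conservative hydrophobic pairs and A/G a conservative small pair); and
support metrics (variant sites shared with other haplotypes, number of
independent confirming sequences). Translation uses the genetic-code
table directly rather than an initiator-aware translator, because
amplicons start mid-gene and initiator rules would mistranslate internal
codons. The reading frame is a parameter (default 0), as amplicon frame
depends on the primers used.

## Diversity and structure

Haplotype diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}(1 - \sum p_i^2)$ with Nei's (1987, eq. 8.12) sampling
variance. Nucleotide diversity is the mean pairwise p-distance over all
$\binom{n}{2}$ pairs (N sites excluded pairwise), with Nei's eq.-10.7
variance that includes both sampling and stochastic terms. Computing
$\pi$ from the haplotype catalog (frequency-weighted haplotype
distances) and from raw sequences (all pairs) agree to machine
precision, and this identity is enforced in the tests. Distances are
p-distances throughout: at conspecific COI divergences (well below 1%)
model-based corrections change nothing at the reported precision, and a
composite-likelihood model would add dependence without benefit.

Population structure uses the distance-based AMOVA framework on squared
pairwise-difference counts: pairwise $\Phi_{ST} = \sigma^2_{among} /
\sigma^2_{total}$ from the two-population decomposition with
significance by permuting individuals between populations
($P = \Pr(\Phi_{perm} \ge \Phi_{obs})$, with the +1 correction), and the
three-level hierarchical decomposition (among groups / among populations
within groups / within populations) with the standard coefficient
algebra and per-level permutation schemes. Negative variance components
are reported as computed and flagged, not truncated — truncation would
break the percentage identity (the percentages always sum to 100).
Populations of size 1 yield a warning but still a statistic, as small
samples (n = 2 countries) do occur in real surveys. With all
between-haplotype distances set to 0/1, $\Phi_{ST}$ reduces exactly to
the frequency-based $F_{ST}$, which the test suite verifies against a
first-principles oracle. Exact numerical parity with third-party AMOVA
software is targeted only to ~2 decimal places, since their internal
conventions (distance squaring, handling of negative components) are not
fully published.

## Design notes and limitations

* **Seeds.** Every stochastic entry point takes an explicit integer
  seed; compound procedures derive independent child seeds per replicate
  from one root seed, so all results are bit-reproducible and individual
  replicates replayable.
* **Direction convention.** Over-representation is $TS_{DIFF} > 0$,
  under-representation $< 0$; the boundary case 0 is direction-less.
* **Column subsetting.** `spatial_test(keep_columns = )` allows
  excluding locations from the spatial analysis without touching the
  input matrix; the default analyses every column present.
* **Pooling.** `pool_locations()` sums columns within user groups (e.g.
  one country versus the rest); row totals and the grand total are
  preserved, so the pooled test conditions on the same haplotype
  abundances.
* The test is two-tailed by construction; mid-P variants and exact
  enumeration for large tables are out of scope.
* The harness validates Type I behaviour and (via the segregation knob)
  gross power ordering; it is not a formal power analysis for specific
  incursion scenarios.
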