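---
title: "Methods: consensus calling, rates and spectra for mutation-accumulation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling, rates and spectra for mutation-accumulation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamut)
```

## The experimental model

A mutation-accumulation (MA) assay repeatedly bottlenecks many
independent lines of a haploid microbe through single colonies. With an
effective population size near one, selection is nearly powerless and
all but the most deleterious spontaneous mutations accumulate as if
neutral. After T generations the lines are whole-genome sequenced and
the mutations that separate each line from the ancestor are counted.
`mamut` implements the downstream computation: it consumes per-site
read-count configurations (8 numbers per site per line: forward and
reverse reads for each of A, C, G, T) produced independently by two
alignment algorithms, plus indel-evidence records, and produces a
mutation catalog, rates, spectra and derived population-genetic
quantities.

Two structural assumptions run through the package: the genome is
circular (all distances and bins respect wrap-around), and lines are
haploid, so each line has a single true base per site and heterozygous
signals indicate error or mixed colonies.

## Consensus calling and its thresholds

The caller compares each focal line against the consensus of all other
lines, which stands in for the unsequenced ancestor. The indel criteria
are fully specified by the published scheme this pipeline follows: a
consensus indel needs ≥ 30% of the reads spanning the position in the
line to indicate the same indel (size and motif), at least two forward
and two reverse supporting reads, confirmation by both aligners
independently, and removal of identical events shared by more than half
the lines (progenitor variants or assembly errors). Large indels
detected by paired-end realignment need at least six forward and six
reverse reads and twenty supporting reads overall.

The BPS-side thresholds are cited to prior work rather than printed, so
this package fixes them as defaults that mirror the indel logic and
exposes every one in `calling_thresholds()`:

| parameter | default | rationale |
|---|---|---|
| `focal_frac` | 0.80 | haploid lines should be near-monomorphic; 80% tolerates ~1–2% error at 100× while rejecting mixed colonies |
| `min_fwd`, `min_rev` | 2, 2 | the printed indel strand rule, applied per aligner |
| `others_frac` | 0.80 | the cross-line consensus must be near-unanimous before a difference is called a mutation |
| `min_depth` | 10 | sites below 10× in any line (either aligner) are excluded from calls and from the analyzed-site count n |
| `indel_frac` | 0.30 | printed criterion 1 |
| `progenitor_frac` | 0.50 | printed criterion 3, strict inequality: an event in 24 of 47 lines is removed, 23 of 47 retained |

Three interpretation decisions were genuinely open and are resolved as
follows. The progenitor (> 50%) rule is printed only for indels but is
applied to substitutions too, because its stated justification —
ancestral variants and reference-assembly errors — applies to both
event types. Ties for the focal consensus base (e.g. a 50/50 site)
yield no call rather than an arbitrary winner. Indel identity means
exact equality of (position, type, size, motif); motifs are compared
after left-normalisation by construction of the evidence format.

The depth mask is experiment-wide (a site is analyzed only if every
line clears `min_depth` in both aligners), so the analyzed-site count n
is shared by all lines. n is always reported next to any rate because
published per-site rates depend on it and it is rarely printed.

## Rates

Per line, the rate is μ = m/(nT) and its standard error treats m as
Poisson: SE = √(μ/(nT)) = √m/(nT). Pooled over N lines, the estimate is
the unweighted mean of line rates with SE s/√N, where s is the sample
(N−1) standard deviation. Generations per transfer are accounted by the
harmonic mean of measured divisions per transfer (log2 of colony CFU
counts), multiplied by the number of transfers — the harmonic mean is
the right average because a transfer's contribution to elapsed
generations is inversely weighted by its division count.

A per-genome rate is the per-site rate times a site count. The package
deliberately parameterises which count (`per_genome_rate(rate,
n_effective)`): multiplying the published per-site rate by the raw
genome length does not reproduce the published per-genome figure, which
implies an analyzed-site denominator somewhat below the genome size.
Where the analyzed-site counts are unavailable (the transcribed-counts
catalog), the workflow uses the genome length and labels it so.

On calibration: the ±2·SE interval of the pooled estimator has nominal
normal coverage of 95.4%, but with N = 47 lines the relevant Student-t
quantile (≈ 2.01–2.06) slightly exceeds 2, so true coverage sits just
below 95%. The acceptance script recomputes this coverage over 200
Poisson replicates at the study's design values (μ = 10⁻⁹, n = 5×10⁶,
T = 3000); values a little under 95% are the expected behaviour of the
2-SE rule, not an estimator defect.

## Spectrum

Substitutions are collapsed into six strand-symmetric classes
(A:T→G:C, G:C→A:T, A:T→T:A, A:T→C:G, G:C→T:A, G:C→C:G). A change is a
transition when purine maps to purine or pyrimidine to pyrimidine, and
A/T-ward when the ancestral pair is G:C and the derived pair is A:T or
T:A — so G:C→C:G is neither A/T-ward nor a transition. Conditional
class rates divide by the number of genomic sites of the source pair
(A+T or G+C), which matters in GC-skewed genomes.

Two transition/transversion summaries are reported and labelled: the
pooled ratio (total transitions / total transversions) and the mean of
per-line ratios. They differ — the per-line mean is dominated by lines
with few transversions and is undefined for transversion-free lines,
which are excluded from the mean. Published tables typically print the
per-line mean; both are available.

The deletion-bias test is a Pearson χ² of observed deletion/insertion
counts against an equal split, without Yates continuity correction:
with correction the statistic for 73 vs 33 would be 14.35 rather than
the 15.09 that the uncorrected statistic gives, so the uncorrected form
is the one consistent with the published analysis. `chi_square_gof()`
is therefore plain Σ(O−E)²/E with df = k−1.

## Genomic context

The coding/noncoding test compares observed coding BPS counts with an
expectation proportional to coding site totals (overlapping genes count
a site once). The expected nonsynonymous:synonymous ratio is computed
by enumerating all 3L single-nucleotide changes over every coding site
and classifying each against the bacterial genetic code (translation
table 11, identical to the standard code at the amino-acid level); the
enumeration is unweighted by the observed spectrum, the plainest
reading of an "expected ratio", and a spectrum-weighted variant is
available via `spectrum_weighted = TRUE`.

BPS density is tallied in consecutive 50-kb bins (final partial bin
retained; a 5.19-Mb genome gives 104 bins). The published
terminus-enrichment statistic's exact construction is not recoverable
(df = 103 pins down only that all 104 bins entered), so
`terminus_test()` implements a one-sample t comparing the terminus
bin's count to the distribution of bin counts, t = (x_term − mean) /
(SD/√K), df = K−1, and offers an `exclude_terminus` variant; the
workflow reports both, labelled.

## Clustered mutations

The detector chains same-line events whose consecutive circular
distances are strictly below the window (default 50 nt); chains of
three or more form one cluster. The analytic expectation tiles the
genome into non-overlapping windows (floor division), sets λ = BPS
total / genome size / lines × window, and evaluates
P = 1 − cdf(1, λ)^n in log space (`-expm1(n * ppois(1, λ, log.p =
TRUE))`) to avoid catastrophic cancellation at small λ. The detector
(pairwise distances) and the expectation (fixed tiles) are different
constructs; both are exposed.

Evaluating the expectation at the study's stated inputs (779 BPSs,
5.19×10⁶ sites, 47 lines, 50-nt windows, 103,800 windows) gives
≈ 1.3×10⁻³. The published probability for the same construction is
1.96×10⁻⁴, which does not follow from the formula at those inputs
under any window size stated; the package follows the formula as
written and reports the discrepancy rather than reproducing the printed
number. The Monte-Carlo oracle — scattering the per-line BPS count
uniformly and counting replicates with any doubly-hit window — agrees
with the analytic value to within binomial error, which localises the
discrepancy to the published arithmetic rather than the implementation.

## Effective population size

π_S is estimated from third positions of fourfold-degenerate codons
whose first two positions are identical across all sequences, the
conservative site filter when the source's exact criterion is not
restated: at such sites any third-position base is synonymous, so all
variation is silent by construction. Gapped or ambiguous columns are
excluded. π_S is the mean over eligible sites of the fraction of
sequence pairs that differ, and N_e = π_S/(2μ) for haploids.

## The synthetic-data generator

`generate_reference()`, `plant_mutations()` and `simulate_counts()` /
`emit_pileups()` emulate the study conditions: per-site depth is
Poisson around the configured coverage (~100× in the study), the
forward/reverse split is Binomial(depth, ½), errors substitute a
uniform random other base per read, and every quantity is reproducible
from a single seed. Planted indels surface as evidence records — short
(≤ 10 bp) ones in both aligner streams except with the configured
discordance probability, long ones as paired-end records only,
mirroring how realignment callers see events that defeat short-read
mappers. Default totals follow the study's marginal counts (779 BPSs,
73 deletions, 33 insertions over 47 lines).

What the generator does not model: mapping bias, GC-coverage coupling,
contamination, base-quality structure, or reads as such (no FASTQ).
Consequently, passing recovery tests demonstrates that the calling
logic implements its criteria correctly under the stated noise model —
not that the thresholds are optimal for any particular real library.
Pileups at mutated sites carry the derived base; indel sites keep
reference-like counts with the indel signal confined to the evidence
records, which matches the separation of the two calling paths.

The transcribed-counts catalog (`build_paper_fixture()`) is the other
data source: a catalog whose marginals equal the published totals
exactly. Splits the publication does not print are filled by
deterministic rules — six BPS classes by largest-remainder allocation
equalising the A/T-ward fraction across transitions and transversions;
per-line counts by even largest-remainder split (means and totals are
then exact by construction; per-line maxima and SEMs are not
reproduced, as they depend on unpublished per-line catalogs); short
indel sizes cycle 1/2/3 bp and long sizes take a base-4-plus-remainder
ladder constrained so the summed deletion and insertion lengths
reproduce the published nucleotide-turnover figures (0.0989 nt lost
per generation per line; the closest integer-valued solution gives a
175.8-fold deletion:insertion ratio against the published 175.93).
Cluster placement plants one BPS triple, nine BPS pairs and eight indel
pairs across 16 distinct lines (34% of lines), with all other intra-line
distances ≥ 100 kb so no accidental clusters arise.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; circular distance is
  the minimum of linear and wrap-around distance.
* Zero-depth or tied-consensus sites: no call, never a guess.
* A pooled Ts/Tv with zero transversions is flagged undefined rather
  than infinite.
* χ² tests demand strictly positive expected counts; the terminus test
  refuses zero-variance bins.
* Rate computations coerce site × generation products to double before
  multiplying (5×10⁶ × 3×10³ overflows 32-bit integers).
* VCF output left-anchors indels on the base before the event, per VCF
  4.2 convention; a deletion starting at position 1 of the circular
  genome cannot be left-anchored linearly and is rejected.

## Problem sizes used in the checks

The test-suite simulations use genomes of 10⁴–10⁵ sites with 5–10
lines, chosen so each property (perfect recovery at 100×/1% error,
threshold monotonicity, permutation symmetry) is exercised on inputs
large enough to be non-trivial while the whole suite stays fast; the
Monte-Carlo cross-checks use 10⁴ replicates, putting binomial error
well below the 3-SE acceptance band. Rates and spectra on the
transcribed catalog are exact integer computations, so their size is
fixed by the experiment itself.

## Known limitations

* The caller consumes abstracted per-site counts; alignment artefacts
  that corrupt both aligners coherently are invisible to the
  dual-aligner criterion.
* The analyzed-site count uses one experiment-wide depth mask; per-line
  masks would give per-line n and slightly different pooled weights.
* The NS/S enumeration skips codons containing non-ACGT characters
  (with a warning) rather than modelling ambiguity.
* π_S from draft-genome strain sets is sensitive to the site filter;
  the fourfold/conserved-context choice here is conservative and can
  undercount silent sites relative to looser definitions.
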