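---
title: "Detecting meiotic crossovers from linked-read gamete sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting meiotic crossovers from linked-read gamete sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkrec)
library(dplyr)
```

## The problem

A haploid gamete carries one recombined copy of each chromosome. When pooled
gamete DNA is prepared as a droplet-barcoded (linked-read) library, the short
reads of each high-molecular-weight (HMW) DNA molecule share a droplet
barcode and can be regrouped computationally. Most reconstructed molecules
derive entirely from one parental haplotype; the rare molecule that spans a
meiotic crossover switches haplotype partway along its length. Counting and
locating these haplotype-switching molecules across a pool of thousands of
gametes yields an individualized genome-wide recombination map from a single
sequencing library, without offspring genotyping.

`linkrec` implements the full chain: read screening, hard filtering of
candidate heterozygous variants, molecule reconstruction, molecule-based
haplotype phasing, per-molecule haplotype scoring, crossover calling, and
windowed map statistics, together with a simulator that generates the whole
data layer with known ground truth.

## Model and procedure

### Molecule reconstruction

Reads sharing a barcode are grouped per chromosome, sorted by start, and
split greedily whenever the gap to the previous read exceeds `max_read_gap`
(default 50 kb) or the span would exceed `max_molecule_length` (default
200 kb). Both defaults are engineering choices -- suitable values depend on
the library -- and are exposed everywhere. Molecules with fewer than 6 reads
are dropped as under-covered; the extreme-high cutoff defaults to the
dataset's 99.5th percentile of reads per molecule, a guard against collapsed
repeats and heavy barcode collision for which no fixed number is defensible
across libraries.

The span cap matters because two molecules from the same genomic
neighbourhood can share a droplet (a *barcode collision*); if they come from
opposite haplotypes the fused reconstruction mimics a recombinant molecule.
The simulator reproduces this mechanism exactly (molecules grouped into
GEMs, one barcode per GEM), which is how the false-positive analyses below
are built.

### Phasing by minimum error correction

Each (molecule, variant) pair with at least one covering read becomes an
allele-matrix entry; a molecule whose reads support both alleles of a
variant receives a `conflict` entry and is excluded from classification,
since a haploid molecule cannot legitimately show both alleles and such
patterns arise from collisions. Phasing two-colors variant alleles to
minimize the minimum-error-correction (MEC) cost: the number of entries that
must be flipped so every molecule is consistent with a single haplotype.
This is the standard single-individual fragment-phasing objective; phase is
defined per block (connected component of variants sharing molecules) up to
an H1/H2 relabelling.

MEC optimization is NP-hard in general, so the solver is a deterministic
heuristic stack chosen to be strong at this problem's shape:

1. **Vote-graph initialisation.** Within each molecule, observed variants up
   to three observed steps apart contribute signed links (+1 same allele,
   -1 different). Variants are phased in genomic order by the weighted
   majority over links to already-assigned neighbours; variants with no
   assigned neighbour are deferred, and a stalled pass seeds a new block.
   Majority voting (rather than single-edge propagation) matters: a genuine
   recombinant molecule contributes a handful of sign-flipped links at its
   crossover, and a single such link must not seed a flipped run.
2. **Coordinate descent.** Alternating molecule-assignment and
   variant-majority updates; each half-step is a minimizer given the other,
   so the MEC cost is non-increasing.
3. **Suffix-flip refinement.** A contiguous mis-phased segment is locally
   self-consistent and survives single-variant moves. Candidate boundaries
   are ranked by the signed sum of link consistencies spanning them
   (computed with a difference array in linear time); suffix flips are
   accepted when they reduce the true MEC cost.
4. **Small-block polish.** Blocks of at most 25 variants additionally get a
   single-variant flip search and 12 seeded random restarts, which in
   practice reaches the exhaustive optimum on instances small enough to
   verify (the test suite checks equality against full enumeration up to
   12 variants).

All tie-breaks are driven by one seed (default 1729), so results are
reproducible. Note one subtlety verified in the tests: when recombinant
molecules are present, the *global MEC optimum* can legitimately differ from
the generating haplotypes at variants dominated by a crossover molecule's
minor side; this does not affect crossover calls and disappears as coverage
grows.

### Variant quality control

Two layers remove variants that would corrupt phasing:

* **Hard filter** (before phasing): heterozygous, biallelic records passing
  `MQB >= 0.4`, `BQB >= 0.4`, `MQSB >= 0.8`, `RPB >= 0.4`, indel fraction
  outside `[0.1, 0.9]` rejected, `5 <= DP <= 220`, `GQ >= 30`,
  `QUAL >= 100`. All comparisons are applied strictly in the rejecting
  direction, so a value exactly at a threshold passes; a missing annotation
  passes its sub-filter (callers differ in what they emit) and is counted.
* **Molecule-balance filter** (after phasing and a first scoring pass):
  variants whose two alleles are supported by very unequal molecule counts
  (minor fraction below 0.25), by fewer than 4 molecules, or whose molecule
  or read coverage deviates from the chromosome mean by more than 3 standard
  deviations are removed, and molecules are re-scored on the reduced set.
  The fraction/count defaults are our choices (no published values exist);
  they are deliberately conservative because a biased variant can convert a
  clean molecule into a fake switch.

### Molecule scoring and crossover calling

For each molecule, each informative entry contributes `1 - eps` if its
allele matches the candidate haplotype and `eps` otherwise, with
`eps = 10^(-Q/10)` from the entry's (capped) base quality. Three models are
compared: pure H1, pure H2, and the best one-switch mixture over the
position-sorted entries (both switch directions, leftmost maximizer on
ties). Posteriors use prior mass `(1 - pi, 1 - pi, pi)`, where `pi` is the
expected recombinant-molecule frequency; `expected_recombinant_stats()`
supplies it from map length, genome size and molecule length (about
3.3e-4 for a mammalian genome-wide map), and the calling threshold is
`p_mix >= 0.95`. This likelihood is this package's own explicit definition
of the scoring step; the exact score used by the original droplet-vendor
pipeline is unpublished, so the parameters are exposed rather than
hard-coded.

A `RECOMBINANT` molecule becomes a crossover call only if each side of the
best switch carries at least 3 informative variants and at least 70% of the
reads with informative observations on each side are phased to that side's
haplotype ("reads" here means reads carrying informative allele
observations, the only reads the rule can be evaluated on). These rules
tolerate isolated low-quality base calls while rejecting noisy mosaics.
Exactly one crossover per molecule is emitted: double crossovers within one
~60 kb molecule are biologically negligible and excluded by the one-switch
model. The crossover interval runs from the last informative variant of the
first segment to the first informative variant of the second; its length is
the *resolution* of the call. Finally, 100 kb windows in which classed
molecules split worse than 30/70 between haplotypes are masked (signatures
of structural variation or mis-assembly), and calls inside them are
discarded with a reason code.

### Maps and statistics

`build_map()` bins crossover midpoints into windows (default 50 kb, optional
sliding step) and estimates each window's rate as
`cM = 100 * n_crossovers / n_molecules`, molecules counted by window overlap
(a midpoint mode exists). `detect_coldspots()` reports crossover-free
intervals of at least 500 kb. `clustering_permutation_test()` compares
observed per-window counts with uniform placements over the mappable
regions: the clustering statistic is the dispersion index of window counts
with an add-one empirical p-value (`p = (b + 1) / (n_perm + 1)`, never 0 and
exactly calibrated under the null), per-window empirical p-values with
Benjamini-Hochberg correction give hotspot calls at FDR 0.05, and a Wilcoxon
rank-sum p of observed versus pooled permuted counts is reported alongside.
The construction of the null is this package's definition; the add-one rule
and the exclusion of masked regions from the null prevent zero p-values and
artifactual clustering respectively. `feature_proximity_test()` compares the
median distance from crossovers to the nearest feature (CpG islands, say)
against uniformly permuted positions with the same add-one convention.

## The simulator and what it does (not) capture

`simulate_gamete_readset()` generates the post-alignment data layer
directly: a read table, read-level allele observations, the variant truth
phase, and per-molecule truth. Emitting the aligned-read dialect rather
than FASTQ is deliberate -- the pipeline's contract starts after alignment,
and desk-scale testing should not require an aligner.

Defaults are the study conditions of a mammalian-style gamete library:

| parameter | default | rationale |
|---|---|---|
| `molecule_len_bp` | 60 kb, fixed | the average HMW molecule size the expected-count arithmetic uses; an exponential option exists |
| `reads_per_molecule` | Poisson(8), min 1 | the observed average of about eight linked-reads per molecule after filtering |
| `read_len_bp` | 150 | standard short-read length |
| `het_spacing_bp` | 50 | between the ~44 and ~63 bp median inter-heterozygous-site distances of a hybrid mouse and a freshwater stickleback; regular grid by default, exponential option |
| `base_error_rate` | 1e-3 (Q30) | typical post-filter substitution error |
| `molecules_per_gem` | 1 | collision-free baseline; 7 and 10 reproduce the empirical and worst-case droplet loads for false-positive studies |

Two-stage generation mirrors the validation design: non-recombinant
molecules are drawn from H1/H2 at random; each planted crossover gets one
molecule drawn to span it (so the crossover sits uniformly within the
molecule), with the haplotype order randomized. Crossover positions are
drawn away from the chromosome ends by half a molecule length to avoid
truncation artifacts of the single-chromosome desk scale (under 1% of the
genome; real chromosome ends do clip molecules, but a 10 Mb toy chromosome
would overstate that effect ~300-fold relative to a real genome).

What the simulator does *not* emulate: alignment and mapping error,
structural variants, indels, GC- or PRDM9-driven placement of crossovers,
non-uniform molecule coverage, and chimeric library artifacts other than
barcode collision. Tests passing on simulated data therefore validate the
algorithmic chain -- reconstruction, phasing, scoring, calling, statistics --
not robustness to reference or alignment pathology, which on real data is
handled by the upstream variant hard filter and the balance/mask layers.

## Problem sizes and performance

The test suite and the reproduction script run pools of 10,000
non-recombinant plus 500 recombinant molecules on a 10 Mb chromosome
(200,000 heterozygous sites, ~420,000 reads, ~1.3 M allele observations),
ten replicates averaged; one replicate takes roughly half a minute on a
single core. These sizes give about 63x molecule coverage -- two orders of
magnitude below a real 1700-gamete pool, which is why the
molecule-balance filter (tuned as counts, not rates) visibly bites in
simulation; at real coverage it is essentially inactive except at
genuinely distorted sites.

At these conditions the end-to-end sensitivity for planted crossovers is
close to 90%. The residual misses are dominated by geometry, not defects:
a crossover sitting before the third observed variant from a molecule's
edge cannot satisfy the three-variants-per-side rule in principle (with
`N` uniformly observed sites per molecule the rule caps sensitivity near
`1 - 6/(N + 1)`), and molecules excluded for conflict entries (the
collision guard) or low read counts lose their crossovers by design.

## Degenerate inputs and numerical choices

* Empty read tables, zero crossovers, and chromosomes without features are
  all legal inputs with defined outputs (empty molecules, all-zero maps,
  infinite feature distances).
* Base qualities are capped at Q60 in scoring so one overconfident base
  cannot dominate a likelihood; error probabilities are floored at 1e-12.
* Likelihoods are computed in log space with per-molecule normalization
  before exponentiation.
* Equal-likelihood switch points report the leftmost; at floating-point
  precision distinct switch points can tie exactly, in which case any
  maximizer is acceptable (the tests compare attained likelihoods, not
  indices, in that case).
* Permutation p-values use the add-one rule and are therefore in
  `(0, 1]`; `n_perm = 0` is an error.
* `filter_molecules()` with `min_reads = 0, max_reads = Inf` is the
  identity; the percentile-based high cutoff uses a type-1 (data-value)
  quantile so it never drops more than the nominal tail.

## Known limitations

* Phasing quality degrades when per-variant molecule coverage falls below a
  handful of observations; the vote graph then has single-link joints and
  the suffix-flip refinement becomes the main defence against segment
  flips. Below ~20x molecule coverage, results should be treated with
  caution.
* The one-switch mixture cannot represent gene conversion or double
  crossovers within a molecule; both are out of scope.
* BAM ingest extracts allele observations only from gapless (all-match
  CIGAR) alignments; indel-spanning reads contribute to molecule
  reconstruction but not to the allele matrix. The TSV read-table dialect
  is the primary interchange format.
* Sensitivity estimates from the simulator are optimistic for organisms
  whose heterozygous sites are much sparser than the read length, exactly
  as the geometric cap above predicts; raising sequencing depth (reads per
  molecule) is the practical remedy.
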