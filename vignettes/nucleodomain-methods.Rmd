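---
title: "Methods: mapping nucleolus-associated domains from DamID and rDNA-anchored Hi-C"
author: "nucleodomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping nucleolus-associated domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices and numerical conventions. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# The measurement model

Nucleolar-DamID expresses two constructs: a Dam methyltransferase fused
to histone H2B with a nucleolar localization signal (H2B-Dam-NoLS), and
the same fusion without it (H2B-Dam). Dam deposits m6A at GATC sites in
chromatin near the protein; sequencing reads from DpnI-digested DNA
therefore report, per GATC fragment, how often that locus visited the
nucleolar periphery relative to the free-diffusion control. The signal
of interest is the library-normalized log2 ratio

$$\mathrm{score}_i \;=\; \log_2
  \frac{(n_i + \psi)/N_n}{(d_i + \psi)/N_d},$$

with $n_i, d_i$ the per-fragment counts, $N_n, N_d$ the library sizes
and $\psi$ a pseudocount. This transparent library-size scheme is
specified in full (pseudocount $\psi = 1$ read, mask floor 2 reads per
fragment, both configurable) rather than inheriting an external
pipeline's internal normalization, so results are exactly reproducible
from the formula above.

Conventions worth stating once:

* **Fragment boundaries** sit two bases into each GATC motif — the DpnI
  cleavage point between GA and TC. The motif is palindromic, so one
  forward scan defines both strands' fragments, and fragments tile each
  chromosome exactly.
* **Read assignment** uses the 5'-most coordinate of the read, which is
  robust to read length.
* **Coordinates** are 1-based closed inside R (the GenomicRanges
  convention); all BED/bedgraph I/O passes through `rtracklayer`, which
  converts to the 0-based half-open external convention.
* **Binning** (default 100 kb) takes the length-weighted mean of
  fragment scores; a fragment straddling two bins contributes to both
  in proportion to overlap. A bin is masked when at least half its
  length is covered by masked fragments.

# NAD calling

The caller thresholds the binned track at the `minQuant` = 0.70
quantile of unmasked scores and takes maximal runs of consecutive
above-threshold bins as candidates (masked bins break runs; an optional
`mergeGap` can bridge short sub-threshold gaps but defaults to 0 since
nothing in the measurement motivates bridging). The null model permutes
the unmasked scores within each chromosome — preserving each
chromosome's score distribution — and re-runs the same detection
`nShuffles` = 100 times. The FDR of a run is the mean null count of
runs at least as extreme divided by the observed count, clamped to
$[0,1]$; runs with FDR < 0.01 are emitted, and only regions significant
in both replicates become NADs.

**Run statistic.** Runs are *ranked* by their score sum
(mean × length). Ranking by the mean alone cannot work under this
permutation scheme: shuffling scatters NAD-level bins across the
chromosome as singleton runs whose mean matches a genuine domain's, so
every observed run would receive FDR near 1. The sum separates long
coherent domains from null singletons while the *reported* domain score
remains the mean member log2 ratio. The emitted boundaries are at bin
resolution; no sub-bin refinement at GATC-fragment resolution is
attempted, so domains shorter than one bin are not callable.

**Seeding.** The permutation null refuses to run without an explicit
seed; all simulation streams likewise derive from a single configured
seed, and every generator is bit-reproducible under a fixed seed.

# rDNA-anchored Hi-C

The mouse reference lacks rRNA gene sequence, so `appendRdna()`
concatenates one rRNA gene unit to the end of a chromosome (chromosome
12 in the real genome; the last toy chromosome in simulation) — leaving
every pre-existing coordinate unchanged — and records the interval. A
pair is an rDNA contact iff *exactly one* end falls in that interval:
pairs with both ends inside are intra-rDNA and tallied separately,
pairs with both ends outside are ignored, and
retained + both-inside + both-outside + malformed always equals the
input count (a conservation invariant the tests enforce).

Genomic ends are accumulated in 5-kb bins. Normalized scores multiply
raw counts by per-bin **Knight–Ruiz** weights. The KR solver is the
standard inner–outer conjugate-gradient iteration on the symmetric
scaling problem $\operatorname{diag}(x)A\operatorname{diag}(x)\mathbf 1
= \mathbf 1$; rows with fewer than 10% nonzero entries are masked
first, convergence is declared at a residual norm of $10^{-10}$
(row-sum coefficient of variation far below $10^{-6}$), and a stalled
iteration falls back to symmetric iterative proportional (Sinkhorn)
scaling with a warning. Balancing is computed per chromosome on the
full cis matrix; callers may instead supply precomputed weights.

**Replicate-common contacts** are re-specified here as bins present
with raw count ≥ 1 in every replicate (threshold configurable), scored
by the mean of the replicate normalized scores — a transparent stand-in
for an external package's undocumented internals. **Quintiles** split
each chromosome into five equal-length segments from coordinate 0;
mouse chromosomes are acrocentric with the centromere at the assembly
start, so quintile 1 is the centromere-proximal fifth. "Unique
contacts" deduplicate at the bin level, matching the per-chromosome
unique-contact counts the analyses report.

# Compartments and switches

The A/B eigenvector uses the standard construction: per chromosome,
observed/expected by distance-stratified means, Pearson correlation of
the O/E columns, leading eigenvector, sign oriented so that correlation
with a reference signal (for example gene density) is positive —
positive = A. Low-coverage rows and zero-variance O/E columns are
masked; a structureless (uniform O/E) matrix therefore abstains
entirely rather than emitting noise.

Switch classification between two states compares signs first
(B to A / A to B) and then magnitudes. Two lowercase conventions exist
in the field's figure legends and they conflict; both are implemented
and the choice is explicit:

* `convention = "weaker"` (default): a lowercase letter denotes the
  weaker value (closer to zero), so a B bin whose eigenvector rises
  toward zero is "B to b".
* `convention = "decrease"`: the same-sign labels mirror, marking the
  direction of the signed change instead.

`deltaMin` (default 0) sets the minimum |change| below which a bin is
stable; it defaults to 0 because no threshold is inherent to the
definition.

# Layer algebra

All classifications are bp-level set algebra, not whole-domain voting:
NAD/LAD = NAD ∩ LAD, NAD-only = NAD \\ LAD, LAD-only = LAD \\ NAD,
iNAD/iLAD = the complement. The four layers are mutually disjoint and
tile the genome exactly — a validity condition of the
`LayerPartition` class, not merely a convention. Cell-type-specific
pieces are differences merged and filtered to ≥ 1 analysis bin
(default 100 kb) to suppress slivers from boundary jitter; the
minimum-length rule is configurable since no canonical value exists.
Genes belong to a domain iff their midpoint (half-open convention:
`floor((start+end)/2)` in 0-based coordinates) falls inside — avoiding
double-counting of boundary-straddling genes. RPKM is
$c \cdot 10^9 / (N \cdot L)$ with union-exon length $L$; a gene is
"expressed" iff RPKM is *strictly* greater than 1, so RPKM exactly 1 is
"low" (an explicit tie-break).

Boundary metaprofiles orient both boundaries of every domain so the
interior lies on the positive axis (the left boundary as-is, the right
flipped); boundaries whose full flanks (default 500 kb, 10-kb position
bins) do not fit in the chromosome are dropped and counted. The profile
of a domain set's own indicator function is an exact unit step — the
self-consistency oracle the tests use. The 20-kb fold-change track uses
one shared pseudocount on the normalized scale
($\psi = \mathrm{pc}/\sqrt{N_aN_b}$, pc = 1 read), which makes the
statistic exactly antisymmetric under condition swap and exactly
invariant to global scaling of either condition.

# The synthetic-data generator

The generator defines the desk-scale study conditions; it is the means
by which every pipeline stage is verified without external data.

* **Genome**: three 30-Mb chromosomes by default. The background
  sequence is random DNA scrubbed of chance GATC occurrences, with GATC
  motifs then planted by a Poisson process (mean spacing 500 bp,
  overlapping placements rejected) — so motif counts are exactly the
  planted counts and fragment statistics are analytically predictable.
  A 45-kb rRNA gene unit (the approximate length of the real repeat
  unit) is appended to the last chromosome.
* **Domain layout**: 24 alternating Mb-scale domains by default;
  `exampleCellTypeLayouts()` provides a two-cell-type architecture
  designed so that 53% of NAD bp is LAD, 40% of LAD bp is NAD, 16% of
  NAD bp is specific to the first state (8% to the second), and 78% of
  the state-specific NAD-only bp carries neither label in the second
  state — fractions realistic for mouse stem and neural progenitor
  cells.
* **DamID**: negative-binomial counts (dispersion 0.2, configurable;
  Poisson in the zero-dispersion limit) with mean proportional to
  fragment length, times a 4-fold enrichment inside planted NADs for
  the nucleolar sample, renormalized to 2M reads per sample. No
  replicate-to-replicate noise model beyond independent count draws is
  imposed: replicate variability is a free parameter of the simulation,
  and independent draws already reproduce a realistic replicate
  correlation (computed by the acceptance script).
* **Hi-C**: pairs are generated directly (alignment is out of scope):
  cis separations follow $P(s)\propto s^{-\alpha}$ with $\alpha = 1$ on
  $[1\,\mathrm{kb}, L]$; same-compartment pairs of a 2-Mb A/B
  checkerboard are oversampled 2-fold by rejection; 10% of pairs are
  rDNA-anchored, their genomic ends drawn from per-bin weights boosted
  5-fold in planted NADs and 2-fold in the centromere-proximal fifth.
  The anchored fraction and checkerboard strength are generator
  parameters the field's data motivate but no single published value
  fixes; 1M pairs on 90 Mb gives per-bin depths comparable, after
  scaling, to a deeply sequenced Hi-C library.
* **ChIP and expression**: gamma-distributed 50-bp bin signal around
  per-layer means; Poisson exon counts calibrated so the expected RPKM
  equals the layer mean (0.2 for NAD layers, 5 for iNAD/iLAD, against a
  20M-read library) — encoding the observation that NAD genes are
  lowly expressed.

**What the generator does not emulate**: sequencing error, mappability,
PCR duplicates, diploid genotypes, trans-chromosomal compartment
structure, TADs/loops, copy number of the rDNA repeat, and any coupling
between DamID noise and local GC or chromatin state. Passing tests
therefore demonstrate correctness of the *algorithms* under the stated
statistical assumptions, not robustness to every artifact of real
sequencing data.

# Problem sizes and runtime

The test and acceptance workloads run on a single CPU in minutes: the
full study conditions use the 3 × 30 Mb genome (about 180,000 GATC
fragments, 901 100-kb bins), 2M DamID reads per sample, 100
permutations for the FDR null, 1M Hi-C pairs, 200 × 200 matrices for
the balancing checks, and 10 seeds for the null false-positive rate.
These sizes were chosen so that at least 20 Mb of domains are planted
per genome and every recovery tolerance is binding rather than
trivially satisfied.

# Known limitations

* Domain boundaries are bin-resolution; NADs narrower than one bin are
  invisible.
* The permutation null assumes exchangeability of bin scores within a
  chromosome; long-range autocorrelation in real tracks makes the null
  conservative for short runs.
* KR balancing requires total support of the masked submatrix; highly
  fragmented contact maps may fall back to Sinkhorn scaling.
* The compartment eigenvector is the leading eigenvector only; on
  chromosomes where long-arm/short-arm structure dominates, the second
  eigenvector may carry the checkerboard and the caller abstains rather
  than guessing.
* `fractionByCategory` treats masked bins (and bp outside any bin) as
  an explicit "NA" category so that fractions always sum to one.
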