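---
title: "Methods: CG-stratified 8-mer spectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CG-stratified 8-mer spectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A genome of length $L$ contains $L - k + 1$ windows of length $k$ per
chromosome.  For $k = 8$ the motif universe has $4^8 = 65{,}536$ members.
Counting every A/C/G/T window on one strand gives each motif an occurrence
count $H_i$, and the *frequency of appearance* of an appearance count $x$
is

$$\mathrm{FA}(x) = \frac{N_x}{4^k},$$

where $N_x$ is the number of motifs whose count equals $x$.  Plotted
against $x$ this is the k-mer spectrum.  In vertebrate genomes CpG
(the CG dinucleotide) is strongly under-represented because methylated
cytosine deaminates to thymine; motifs carrying CG therefore appear far
less often than their base composition predicts, and the spectrum splits
into components.  The package stratifies the universe by the number of
overlapping occurrences of any dinucleotide XY — zero (0XY), exactly one
(1XY), two or more (2XY) — and analyses each stratum's spectrum separately.

Internal motif composition is summarised by the weighted relative
frequency of each sub-motif (m-mer, $m \in \{3, 4\}$) within a motif set:

$$\mathrm{RF} = \frac{4^m}{8-m+1}\,
\frac{\sum_i N_{mi} H_i}{\sum_i H_i},$$

with $N_{mi}$ the overlap-counted occurrences of the m-mer among the
$8-m+1$ windows of the $i$-th 8-mer.  Every 8-mer contributes exactly
$8-m+1$ windows, so $\sum \mathrm{RF} = 4^m$ identically — the invariant the
test suite asserts to $10^{-9}$.

A stratum's usage divergence from the overall set is quantified three ways:

* **Symmetric relative entropy** (bits):
  $\sum_i [\,p_i \log_2 \tfrac{2p_i}{p_i+q_i} + q_i \log_2
  \tfrac{2q_i}{p_i+q_i}\,]$, which equals twice the Jensen–Shannon
  divergence and is bounded by 2 for probability vectors.
* **Distance deviation** $S_1 = \sqrt{\sum d_i^2/(n-1)}$ with
  $d_i = \sqrt{p_i^2+q_i^2}\sin\alpha_i$ the signed perpendicular distance
  of the scatter point $(q_i, p_i)$ from the diagonal $p = q$.
* **Angular deviation** $S_2 = \sqrt{\sum \alpha_i^2/(n-1)}$ with
  $\alpha_i = \pi/4 - \arctan(p_i/q_i)$.

Peak positions of smoothed stratum spectra, $\hat x_i = \arg\max_x f_i(x)$,
are compared by $D_{ij} = |\hat x_i - \hat x_j|$ and tested with a
label-shuffling permutation test.

## Numerical and design choices

**Counting.**  Single-strand, no reverse-complement merging (complementary
m-mers such as GCG and CGC are genuinely distinct observations here).
Windows containing N are skipped; windows never span sequence or excision
boundaries, so multi-chromosome genomes are counted per sequence and
summed.  Motifs are indexed by their base-4 expansion (A=0, C=1, G=2, T=3,
first base most significant), which coincides with alphabetical order.

**Spectra and smoothing.**  Spectra use bin size 1.  Nullomers ($x = 0$)
are recorded but excluded from the dense grid that smoothing and peak
finding operate on, which runs from $x = 1$ to the largest observed count.
Smoothing is a centred moving average (default window 10, one pass) under
the valid-window convention: each pass shortens the grid by window − 1
points and the x grid is re-centred the same way, so an even window yields
half-integer grid positions.  Peak ties are broken toward the smallest x.
A window longer than the grid is an error rather than a silent fallback —
short grids happen for heavily suppressed strata on small genomes, and the
right response is a longer genome or a smaller window, chosen knowingly.

**Entropy normalisation.**  Raw RF values exceed 1, so before the entropy
is computed each vector has its zeros replaced by half its smallest
non-zero entry and is then rescaled to sum to 1.  The rescale step is
switchable (`renormalize = FALSE` keeps raw floored values) because the
floored-only variant is a defensible alternative reading; the default is
the probability-normalised form, which keeps the metric inside its [0, 2]
range and makes the twice-Jensen–Shannon identity exact.  $S_1$ and $S_2$
by contrast consume *raw* RF pairs, matching the geometry of the usage
scatter plots they summarise; pairs at the origin (0, 0) have no direction
and are dropped with a warning, and $n$ is the number of retained
components (64 or 256 when nothing is dropped).  $S_2$ is invariant under a
common positive rescaling of both vectors; $S_1$ scales linearly.

**Permutation test.**  The shuffling unit is the motif: the member 8-mers
of both strata are pooled, each keeping its genome count $H_i$, and each
replicate reassigns subset labels uniformly while preserving the two
subset sizes.  Both FA curves are rebuilt per replicate on a shared dense
grid and smoothed with the observed configuration (enforced), and
$p = \#\{D^b \ge D^{\mathrm{obs}}\}/B$ with the inequality non-strict.
Because peak distances are integer-valued, ties make this estimator
conservative; the test suite therefore checks calibration through the
exchangeable randomized-rank p-value (observed draw included, ties
randomized), which is exactly uniform under the null, and separately
asserts that the reported p dominates it.  With a fixed seed the whole
result, null distribution included, is bit-reproducible.

**CpG islands.**  Sliding 1000 bp windows with 500 bp step; a window
qualifies when GC $\ge$ 0.5 and CpG observed/expected $\ge$ 0.6 (both
inclusive), with O/E in the Gardiner–Garden form
$N_{CG} \cdot W / (N_C N_G)$ and the final partial window evaluated at its
actual length.  Qualifying windows are merged into maximal intervals.
Excision returns the complement *segments* as separate sequences so no
chimeric k-mer windows are created across junctions.  A gene-body
post-filter needs annotation the caller cannot supply itself, so it is
exposed only as an optional user-provided exclusion mask (`exclude`,
default off).

## The synthetic generator

`sim_markov_genome()` draws a first-order Markov chain whose rows all equal
the base composition except the C row.  A naive construction — multiply
the C$\to$G entry by the odds factor and renormalise the row — overshoots
the target: renormalisation inflates the other C$\to$x entries and
deflates the stationary G frequency, so the realised stationary CpG O/E
for a requested 0.25 comes out near 0.34.  The generator instead
calibrates the C$\to$G scale by root finding so that the *stationary* O/E
$= T_{CG}/\pi_G$ equals the requested `cg_odds` exactly
(`markov_theory()` exposes the matrix, the stationary law and the
calibrated scale).  At 10 Mb the measured O/E of a draw sits within ~1% of
the target.

Default study conditions, chosen once as a realistic stand-in for a small
fungal-like genome: 10 Mb, yeast-like composition (GC 0.38), `cg_odds`
0.25 for the suppressed condition and 1.0 for the i.i.d.-like control,
fixed small seeds.  Island fixtures embed 2 kb segments of GC 0.65,
O/E 1.0 material — canonical island composition — at a ~2% genomic load.
Smaller 0.5–2 Mb draws are used where only mechanics are under test.

What the generator emulates: genome length, base composition, CpG
suppression, and locally GC-rich CpG-retaining islands.  What it does not:
repeats, isochores, chromosome-scale heterogeneity, mutation-selection
balance, or any positional correlation beyond first order.  Passing
qualitative tests on this generator therefore demonstrates that the
*machinery* responds to CpG suppression the way the theory predicts — peak
ordering $N_2(p) < N_1(p) < N_0(p)$, divergence ranking 2CG > 1CG > 0CG,
island-removal restoring the background 2CG peak — not that any particular
real genome shows those patterns.  One known divergence: on the
homogeneous synthetic background, strong suppression concentrates the
small 2CG stratum into so few appearance-count bins that its modal FA
rises above the broad 0CG spectrum; the peak-height ordering
$\mathrm{FA}_2(p) < \mathrm{FA}_0(p)$ reported for real yeast (where
suppression is mild and counts are spread by genuine sequence
heterogeneity) does not transfer to these conditions, and the
corresponding check documents that honestly by failing.

## Problem sizes

The test suite generates its fixtures at run time: one 10 Mb suppressed
genome, one 10 Mb uniform i.i.d. genome and one 10 Mb island-bearing
genome are shared across tests through a cache, alongside many sub-Mb
draws; the calibration study runs 200 permutation tests at B = 99 on
1000-motif splits.  The acceptance script analyses one 10 Mb suppressed
genome with B = 2000 permutation replicates and a 100-island recovery
experiment.  These sizes were picked so spectra have stable peaks while a
full run stays in the couple-of-minutes range on one core.

## Limitations

* Reproducing the published cross-species numbers requires the underlying
  assemblies; `reproduce_species_table()` runs the identical computation on
  any local FASTA, but the package ships no genome data.
* The smoothing-pass count used for published peak positions is not fully
  determined; peak positions can shift by a few bins across 1–5 passes, so
  the yeast check sweeps passes and asks whether the reported distances are
  attained anywhere in the sweep.
* k is capped by memory at about 15 (dense $4^k$ tables); strata are
  defined for dinucleotide content only.
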