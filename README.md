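# kmerstrat

CG-stratified 8-mer spectrum analysis of genome sequences.

## What this is for

Across eukaryotes, the distribution of 8-mer occurrence counts (the k-mer
*spectrum*) ranges from unimodal (yeast, worm, zebrafish) to trimodal
(human chromosomes), and the split tracks CpG dinucleotide content:
motifs with zero CGs behave like the random expectation, while motifs with
one or two-plus CGs are depleted and left-shifted because methylated
cytosine mutates away.  `kmerstrat` is for genome researchers who want to
quantify that structure: it partitions the 65,536-motif universe into
0XY / 1XY / 2XY strata for any dinucleotide XY, compares each stratum's
spectrum and internal 3-/4-mer usage against the genome-wide baseline, and
tests whether stratum peaks are separated beyond chance.

The quantities at its core:

- **FA spectrum** — for appearance count `x`, `FA(x) = N_x / 4^k`, the
  fraction of the motif universe occurring exactly `x` times.
- **m-mer relative frequency** —
  `RF = 4^m / (8 - m + 1) * sum(N_mi * H_i) / sum(H_i)`, the
  genome-weighted usage of each m-mer inside a motif set, scaled so
  `sum(RF) = 4^m`.
- **Usage divergence** — a symmetric relative entropy
  (= 2 x Jensen-Shannon divergence, bits), the distance deviation
  `S1 = sqrt(sum(d_i^2) / (n - 1))` and the angular deviation
  `S2 = sqrt(sum(alpha_i^2) / (n - 1))` of the stratum-vs-overall usage
  scatter about the diagonal `p = q`.
- **Peak distance** — `D_ij = |argmax f_i - argmax f_j|` between smoothed
  stratum spectra, with a label-shuffling permutation p-value
  `p = #(D_b >= D_obs) / B`.

It also detects CpG islands (1000 bp / 500 bp sliding windows, GC >= 0.5,
observed/expected CpG >= 0.6), excises them for re-analysis, and ships a
seeded synthetic-genome generator (i.i.d. or first-order Markov with a
calibrated stationary CpG O/E, plus embedded ground-truth islands) so the
whole pipeline is testable without downloads.

## Worked example

```r
library(kmerstrat)

g <- sim_markov_genome(1e7, cg_odds = 0.25, seed = 1)  # 10 Mb, CpG O/E 0.25
fit <- kmerstrat(g, dinucleotides = "CG", B = 2000, seed = 2)
summary(fit)
```

```
Stratified 8-mer spectrum analysis
  windows counted: 9,999,993 | overall peak at x = 16.5 
  CG: peaks N0(p)=124.5 N1(p)=16.5 N2(p)=5.5

Peak distances:
  CG D(0-1)=108  D(0-2)=119  D(1-2)=11 
   p-values: 0  0  0 

Usage divergence (stratum vs overall):
 dinucleotide class m     nsre      s1     s2
           CG     0 3 0.001219 0.03972 0.2802
           CG     1 3 0.309251 0.68066 0.3593
           CG     2 3 0.863893 1.30278 0.5430
           CG     0 4 0.001420 0.05033 0.3374
           CG     1 4 0.479349 0.86703 0.4379
           CG     2 4 1.219016 1.60763 0.6270
```

Reading it: the suppressed genome puts the 0CG peak at the random
expectation (~10^7/65536 ≈ 153 before suppression of neighbours), while
1CG and 2CG peaks sit far left (16.5 and 5.5) — the characteristic
left-shift of CpG-bearing motifs.  All three pairwise peak separations are
stronger than any of 2000 label-shuffled replicates (p reported as 0,
i.e. < 1/B).  Divergence scores rank 2CG > 1CG > 0CG for every metric and
both m, i.e. the more CGs a motif carries, the more biased its internal
m-mer usage is relative to the genome-wide baseline.  `coef(fit)` returns
that table; `plot(fit)` draws the three smoothed stratum curves.

Real genomes work the same way: `read_genome("sacCer3.fa")` then
`kmerstrat(...)`, or `reproduce_species_table("sacCer3.fa")` for a
one-call table of CG peak distances and permutation p-values.

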