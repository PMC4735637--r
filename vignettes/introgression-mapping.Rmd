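---
title: "Mapping a dominant colour locus and detecting ancient balancing selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant colour locus and detecting ancient balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
library(dplyr)
```

## The problem

A discrete, female-limited colour dimorphism segregating in a fly population
behaves like a single dominant X-linked factor. `introscan` implements the
computational chain needed to (i) map such a locus by introgression
pool-sequencing, (ii) localise the divergent interval with windowed Dxy and an
HKA-like polymorphism/divergence scan, (iii) characterise the two deeply
diverged haplogroups segregating at the locus (neighbour-joining clustering,
Hudson FST, fixed differences, incomplete lineage sorting), and (iv) put a
calibrated date on the haplogroup split. A seeded simulator generates every
input, so the whole pipeline can be exercised and tested without any external
data.

## The mapping statistic

The design crosses a dominant "dark" allele into a "light" inbred background
through repeated backcrosses with phenotypic selection. Two pools are
sequenced: heterozygous carrier females from backcross generation *n*
(one recombinant carrier X, one light paternal X each) and a later
introgression line made homozygous for the dark allele. At every
*diagnostic SNP* — a site where the dark line is fixed for an allele absent
from the light line, with a minimum count of 10 in every line — the ancestry
proportion is the fraction of pooled reads carrying the dark allele.

Under this design the expectations at the causal locus are 50% in the
heterozygous pool and 100% in the homozygous line, so the combined score
(mean of the two pools' 100-kb window means) should be near 75% there, and
lower elsewhere because each backcross halves the unlinked dark ancestry:
the carrier chromosome carries dark ancestry with probability
$(1-r)^n$ at recombination fraction $r$ after $n$ selected backcross meioses
(`backcross_expectation()`), i.e. $(1/2)^n$ when unlinked, and half that for
the pool once the light paternal X is included.

Windows tile the chromosome from coordinate 1 (1-based inclusive; the
anchoring is a package convention since any choice is defensible). Windows
with fewer than 1 parental fixed difference per 1,000 sites are excluded as
potentially identical-by-descent; "fewer than" is read strictly, so a window
at exactly the threshold is retained. Missing data propagate as missing,
never as zero. Candidate windows fall within ±0.05 of the 75% expectation
(configurable), and are ranked by closeness to it.

## Divergence and HKA scans

Per SNP, with $p_i$ the frequency of the reference-matching allele in line
$i$ (minimum coverage 2) and $q_i = 1 - p_i$,

$$D_{xy} = p_1 q_2 + p_2 q_1,$$

the probability that two reads drawn from the two lines differ. This is the
standard two-population per-site form consistent with the $p$/$q$ definitions
used by pooled-count pipelines; it is smoothed over sliding windows of
501 SNPs (SNP-indexed, truncated — never padded — at chromosome ends, with a
flag marking truncated windows). Sites are re-indexed after all filters, so
windows always contain exactly `2 * half_width + 1` retained SNPs except at
the ends.

The HKA-like scan classifies SNPs as *polymorphic* (Dxy between the two
focal lines > 0) or *divergent* (both lines fixed for the same allele and
the outgroup fixed for the other). Within sliding windows of 101 classified
SNPs, observed class counts are compared with expectations from the
chromosome-wide class proportions by a Pearson chi-squared test with 1
degree of freedom. Chromosome-wide proportions include the focal window —
the bias is negligible at chromosome scale — and no continuity or
multiple-testing correction is applied to the reported per-window p-values
(a Bonferroni column is emitted as a convenience only). The locus-level test
is the corresponding 2×2 contingency chi-squared on raw per-locus tallies;
locus lengths in this design are near-identical, so no length normalisation
is applied.

## Haplotype statistics

Haplotype alignments use uncorrected p-distances with pairwise deletion
(gaps and ambiguities are missing data — a long indel is never counted as a
stack of differences). Neighbour joining (via **ape**, with negative branch
lengths clamped to zero) clusters haplotypes; haplogroups are defined by the
bipartition at the longest internal branch, with a deterministic
lexicographic tie-break. Per-site differentiation uses the Hudson estimator

$$F_{ST} = 1 - H_w / H_b, \qquad
  H_w = \tfrac12\sum_{g} 2 p_g q_g \tfrac{n_g}{n_g - 1}, \quad
  H_b = p_1 q_2 + p_2 q_1,$$

which permits slightly negative values in finite samples — the expected
behaviour for undifferentiated groups. Fixed differences are sites where
each haplogroup is monomorphic for a different allele; every fixed
difference is necessarily also a segregating site of the pooled ingroup.
The incomplete-lineage-sorting scan flags windows where between-haplogroup
divergence exceeds the smaller haplogroup-to-outgroup divergence — the
signature of alleles that coalesce deeper than the species split.

## Clock dating

Bayesian relaxed-clock dating is out of scope; the package provides a
deliberately simple strict-clock alternative: mean between-clade distances,
Jukes–Cantor corrected ($d = -\tfrac34\ln(1 - \tfrac43 p)$, defined for
$p < 0.75$), scaled linearly so that a calibration split (by default 11
million years, a standard age for the melanogaster-subgroup crown) maps to
its known age. Uncertainty comes from ≥1,000 seeded site bootstraps
(alignment columns resampled with replacement); within bootstrap replicates
near-saturated resampled distances are clamped just below the Jukes–Cantor
domain boundary rather than discarded. Bootstrap standard errors are
analogous to, but not identical with, posterior credible intervals, so
agreement with MCMC-based dates is expected only approximately.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates, per replicate: two inbred parental X
chromosomes (SNP density 0.005/bp, half of SNPs fixed between parents), a
BC7-style heterozygous carrier pool and a homozygous introgression line
(Poisson crossovers, uniform placement, no interference, female-only
recombination for the X design), and pooled sequencing (Poisson depth,
binomial allele sampling, optional symmetric error — default 0, representing
counts after quality filtering). The causal site is always a parental fixed
difference, as it must be for a diagnostic-SNP design to see it.

Scaling choices (the package's own): the simulated chromosome is 2 Mb
(1 Mb where only local behaviour matters), a compressed stand-in for a
whole chromosome arm, with 0.1 Morgans/Mb so that the arm-scale genetic map
is concentrated onto the scaled-down physical length; pool size is 30
females; depths mirror a realistic design (17–80×). The homozygous line
draws an independent carrier haplotype per chromosome copy: founder
haplotypes of a maintained line are decorrelated by recombination over
generations, and a discrete-founder mode (`n_founders`) is provided for
freshly founded lines. With discrete founders the homozygous pool's window
scores become strongly stochastic (a single founder breakpoint moves a
window by ~1/2`n_founders`), which is worth knowing when interpreting real
introgression-line data.

`simulate_balanced_locus()` places mutations site-by-site on a fixed
four-branch genealogy (two haplogroup crowns, an outgroup branch, plus
shared ingroup polymorphism assigned hypergeometrically) under infinite
sites. Between-haplogroup excess divergence is constant inside a core
interval and decays exponentially into the flanks; the outgroup's distance
to haplogroup A is held constant along the locus, so the core shows
incomplete lineage sorting (outgroup closer to A than B is to A) while the
flanks do not. Defaults: 3-kb locus, 500-bp core, 18+18 haplotypes, 0.07
between-haplogroup core divergence, 0.005 within-haplogroup diversity, 0.05
A–outgroup divergence, 400-bp flank decay — magnitudes typical of an old
balanced polymorphism with a close outgroup.

This is not a coalescent simulator: there is no recombination within the
locus, no demography, no indels, and within-group genealogy is collapsed
into exchangeable polymorphism. Passing tests therefore demonstrate that the
estimators recover planted signals of the stated form, not that they are
robust to gene conversion, recombination gradients or complex demography in
real data.

## Numerical and design choices

* Sliding windows truncate at the ends (every SNP gets a value, flagged);
  empty tiling windows are `NA`, never 0.
* The candidate band (±0.05 around 0.75) is a configurable package choice —
  the conformity notion is qualitative in the underlying design.
* The IBD boundary is strict (`< 1/1000` excluded, `= 1/1000` retained).
* Neighbour-joining ties and the haplogroup label (`"A"` contains the
  lexicographically smallest id) are deterministic for reproducibility.
* All randomness flows through explicit `seed` arguments; `run_pipeline()`
  writes a manifest (config echo, seed, per-file checksums) and reruns are
  byte-identical.
* Problem sizes in the tests and the acceptance analysis (1–2-Mb
  chromosomes, 200 replicates for the ancestry expectations, 50 replicates
  for localisation, 10 neutral chromosomes for the HKA calibration) are the
  package's chosen desk-scale study conditions.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 4, chrom_length = 5e5, n_boot = 100)
res <- run_pipeline(cfg, out_dir = tempfile("demo"))
res$candidates
plot_ancestry_scan(res$windows)
```

## Known limitations

* The locus-scale HKA windows (101 classified SNPs) are wider than a short
  locus; locus-level contrasts should use `locus_hka()` on per-locus
  tallies.
* The strict-clock dating inherits all strict-clock caveats; rate variation
  between branches biases the estimates, and the calibration identity is
  exact only on ultrametric inputs.
* Hudson FST at sites with fewer than two called sequences per group is
  undefined and omitted.
* The simulator's homozygous-line independence approximation understates
  between-copy correlation of very young lines; use `n_founders` to model
  those explicitly.
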