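---
title: "Methods: bin maps, linkage maps and QTL scans from low-coverage F2 resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin maps, linkage maps and QTL scans from low-coverage F2 resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binqtl)
```

binqtl turns whole-genome resequencing of an F2 mapping population —
two inbred parents sequenced deeply, a couple of hundred progeny sequenced
at a few reads per site — into a recombination-bin genotype map, a Kosambi
linkage map, segregation-distortion scans, permutation-thresholded QTL
scans, and a GradedPool-Seq bulked-segregant analysis. This vignette
explains the models behind each stage, the tunable parameters, what the
bundled simulator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## The genotyping problem and the HMM

At ~7x coverage a single site in a single individual is uninformative: a
heterozygote sampled three times may show only one allele. The pipeline
therefore treats each progeny chromosome as a hidden three-state Markov
chain over the parent-informative markers (states AA, AB, BB for
female-homozygous, heterozygous, male-homozygous) and imputes whole
*genotype blocks* rather than single-site genotypes.

**Emissions.** A cell with `n_A` reads of the female allele and `n_B` of
the male allele (depth `d = n_A + n_B`) has

* `P(obs | AA) = C(d, n_B) eps^n_B (1-eps)^n_A`
* `P(obs | AB) = C(d, n_A) 0.5^d`
* `P(obs | BB) = C(d, n_A) eps^n_A (1-eps)^n_B`

where `eps` is the per-read miscall probability (default 0.01 — the order
of magnitude of sequencing error plus alignment artefacts). Depth 0 is a
uniform emission. Genotype-only VCF records are converted to pseudo-depths
(hom = 2 reads, het = 1+1) and flagged, so the same machinery runs on
GT-only inputs with appropriately weak evidence.

**Transitions.** A physical gap of `g` bp is converted to `d_M = g * rho /
1e8` Morgans at a background rate `rho` (cM/Mb, default 3 — the genome-wide
average of a ~900 cM / ~300 Mb map), to a per-gamete switch probability by
Haldane's `r = (1 - exp(-2 d_M)) / 2`, and to the diploid transition matrix
as the product chain of the two independent gametes
(`AA -> (AA, AB, BB) = ((1-r)^2, 2r(1-r), r^2)`, `AB -> AB = (1-r)^2 +
r^2`). `rho` only has to be the right order of magnitude: it sets the
prior cost of a crossover relative to the cost of explaining discordant
reads as errors.

**Decoding.** Viterbi in log space with the stationary F2 start
distribution (1/4, 1/2, 1/4). Hard decoding is used (rather than posterior
marginals) because the downstream objects — blocks, crossovers, bins — are
discrete; ties in the predecessor choice are broken toward staying in the
current state, then toward the lower state index, so decoding is fully
deterministic. An all-missing chromosome yields a single `unknown` block
that is excluded from crossover counting and propagates as unknown bin
genotypes. The test suite pins Viterbi against exhaustive enumeration of
all `3^T` paths on hundreds of random small chromosomes.

## Crossovers and bins

A crossover is the boundary between two adjacent blocks with different
states; its breakpoint interval is (last marker of the left block, first
marker of the right block) and its point estimate is the interval midpoint
— unbiased absent further information, with the interval retained in the
output. Pooling all individuals' breakpoint midpoints per chromosome and
cutting at each one partitions the marker-covered genome into candidate
bins; within a bin no individual recombines, so bins are the effective
markers of the map.

Candidate bins shorter than `min_bin_bp` (default 30 kb) are treated as
likely artefacts of gene conversion or local misalignment and are merged
into the flanking bin with which they share the larger number of identical
individual genotype calls (tie: left neighbour). Merging rather than
outright dropping keeps the bins a partition of the covered genome. After
a merge an individual can, rarely, recombine inside a bin; its bin
genotype is then the state covering the larger share of the bin (tie: the
earlier block).

## Linkage map

De novo marker ordering is deliberately *not* performed: with a reference
genome the bins are ordered by physical position, which is the same
validation the field applies to de novo maps (genetic-vs-physical
concordance). A diagnostic flags adjacent bins with `r > 0.3` as potential
ordering conflicts. Bins with more than 20% unknown genotypes are excluded
from the map (the conventional missing-data threshold for map software).

Adjacent-bin recombination fractions are estimated by maximum likelihood
for codominant F2 markers. All genotype classes except the double
heterozygote determine their recombinant-gamete count; AB/AB arises from
two parental gametes (probability `2p^2`, `p = (1-r)/2`) or two
recombinant gametes (`2q^2`, `q = r/2`) and is split by EM with expected
count `2q^2 / (p^2 + q^2)`. Convergence: `|delta r| < 1e-8` or 200
iterations from `r0 = 0.25`; the estimate is clamped to [0, 0.5] and the
tests require agreement with a 1e-4-step grid search of the exact
likelihood. Distances are Kosambi, `d = 25 ln((1+2r)/(1-2r))` cM, which
accounts for moderate interference and is the field's default for F2
maps; the forward and inverse functions round-trip to 1e-12. An estimate
of exactly 0.5 would give an infinite increment; map construction caps the
fraction at 0.4999 with a warning (on simulated data adjacent bins never
get there).

## Segregation distortion

Each bin is tested twice: the *zygotic* test compares genotype counts to
1:2:1 (Pearson chi-square, df = 2, no continuity correction) and the
*gametic* test compares the 2n allele counts to 1:1 (df = 1). Treating
alleles as independent overstates gametic significance when the distortion
is really zygotic; that caveat is inherent to the construction and is
documented rather than corrected, because the two tests are used as
complementary tracks. No multiple-testing correction is applied to the
calling threshold (`P < 0.01` on raw p-values); a Bonferroni column is
emitted for reference. A segregation-distortion region (SDR) is a maximal
run of consecutive significant bins (either stage, zero gap tolerance);
single-bin SDRs are allowed. The region direction is the modal bin
direction, where a bin is labelled `female`/`male` by whichever parental
allele exceeds frequency 0.5.

## QTL scanning

The scan is Haley–Knott-style regression on bin genotype codes
(`x = +1/0/-1` for AA/AB/BB, `z = 1` for AB): within-bin position is
unidentifiable on a bin map, so bins are the natural scan grid and the
"peak bin" is the natural QTL location. At each bin,
`LOD = (n/2) log10(RSS0 / RSS1)` compares the full model (optionally with
covariates) against the covariate-only null refitted on the same
individuals; individuals with unknown genotype are dropped at that bin
only. Composite interval mapping adds up to `n_cov = 3` background bins
chosen by forward selection on scan peaks; when a bin is tested, covariates
within `window_cm = 10` cM of it are excluded so the covariate cannot
absorb the local signal. Both values are configuration keys; the defaults
are the common practice for CIM-style scans at this population size.

Genome-wide thresholds come from 1000 permutations of the phenotype
against whole genotype rows (preserving inter-marker correlation), taking
the empirical 95th percentile (type-7 quantile) of the per-permutation
maximum LOD. Fewer than 20 permutations are refused. Declared QTLs are
fitted jointly; the model PVE is `100 (1 - RSS_full / RSS_null)` and each
QTL's share is its drop-one sum of squares over the total. The support
interval is the peak bin plus both flanking bins, and same-trait QTLs with
overlapping support intervals are merged.

## GradedPool-Seq

Individuals are ranked by phenotype (ties broken by stable ID order) and
split into `k = 4` contiguous blocks of `floor(n/k)` or `ceiling(n/k)`
(larger blocks first); pool 1 holds the highest phenotypes. Pooling is in
silico: member individuals' allele depths are summed per variant, which is
equivalent in expectation to sequencing a physical bulk at the same total
depth. Variants with total depth < 10 or any empty pool are filtered.

The per-variant test is a Ridit / ordered-category midrank test: pools are
ordered categories, the column totals form the reference distribution, the
ridit of a pool is its mid-cumulative probability, and the two allele rows
are compared by mean ridit standardised with the tie-corrected two-sample
rank-sum variance (two-sided normal p). This is pinned in the tests
against an independently computed midrank Mann–Whitney statistic on the
expanded reads; `-log10(p)` is also computed on the log scale so extreme
z-scores do not underflow. Windows of 400 kb advanced by 100 kb (the step
is a configuration key; only the window size is canonical) are scored by
the mean `-log10(p)` of their unfiltered variants (Fisher's combination is
available behind a switch), windows with fewer than 5 variants are
skipped, and the candidate region is the peak window extended by 200 kb on
each side, clipped to the chromosome.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults *are* the study conditions the pipeline targets:
200 F2 individuals; 12 chromosomes of 25 Mb at a uniform 3 cM/Mb (a 900 cM
/ 300 Mb genome, matching the ~904 and ~874 cM maps and ~306 Mb covered
span of the motivating design); parent-homozygous bi-allelic markers
placed uniformly at random (100 per chromosome by default, so inter-marker
gaps vary); Poisson(7) read depth per marker with a 1% miscall rate; and
meiosis as a Poisson crossover process without interference (counts
`~Poisson(L/100)`, positions uniform), so two-locus recombination follows
Haldane's function exactly. Crossover interference is not modelled — the
analysis pipeline nowhere assumes it, and Kosambi distances are a mapping
convention, not a claim about the simulated meiosis.

Selection is by rejection sampling so population sizes stay exact: a
gametic locus with weights `(w_A, w_B)` retains a gamete with the weight of
its allele (equilibrium allele-B frequency `w_B / (w_A + w_B)`); a zygotic
locus retains a zygote with probability `w_A^nA * w_B^nB` over its two
alleles. Phenotypes are `baseline + sum_q (a_q x_q + d_q z_q) + N(0,
sigma^2)` with each QTL acting through the nearest simulated marker, which
keeps the ground truth discrete and recovery tests unambiguous. All
randomness flows through the single seed in the configuration; identical
seeds give bit-identical populations.

Not emulated: read-level artefacts (duplicates, mapping bias, indels),
linked selection, epistasis, genotyping-quality variation along the
genome, and — important for interpreting the BSA results — any variant
density near the millions of SNPs a real resequencing study segregates.
Passing the recovery tests therefore shows the *algorithms* behave
correctly under the study's sampling design, not that real data are this
clean.

## Problem sizes, calibration and known limitations

The test and acceptance suites use sizes chosen to exercise the study
design while staying desk-scale: the full default genome for the
bin-accuracy check (bin-genotype accuracy vs truth is ~99.8% at 7x / 1%
error); 50 replicates at 40 markers/chromosome for QTL power (a PVE-20%
QTL against its own 1000-permutation threshold) and SDR power (a
`w_B = 0.5` gametic locus); 100 null replicates for the genome-wide
type-I rate; and 2,400 well-spaced null bins for the distortion
false-positive rate.

Two statistical caveats are deliberate:

* **Ridit calibration is read-level.** The rank test models reads as
  independent draws from each pool. Reads within an individual share its
  genotype, so under individual-based pooling the statistic is
  overdispersed and its p-values are anti-conservative — a known property
  of bulked-segregant tests, inherited from the method being emulated.
  The null-uniformity check is therefore performed at the level the
  statistic models (pooled counts binomial in the read depth); the
  window/candidate stage, which ranks rather than thresholds, is what the
  recovery test exercises end to end.

* **BSA localisation at n = 200 is read-depth-limited.** With quartile
  pools of 50 individuals merged in silico from 7x data, the realised
  allele-frequency contrast is nearly flat over ~1 Mb around a QTL, and
  between-window read noise lets the peak window wander several hundred
  kb. In 25-50-replicate recovery runs at 3,000 variants/chromosome the
  400 kb + 200 kb candidate region covers a PVE-30% QTL in roughly
  two-thirds to three-quarters of replicates; at 30x pool depth coverage
  is essentially complete.
  The candidate region should accordingly be read as a peak estimate with
  few-hundred-kb uncertainty at these depths, not as a confidence
  interval.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  chrom_lengths_bp = rep(25e6, 3), n_markers_per_chrom = 60,
  n_individuals = 150,
  qtls = data.frame(chrom = "chr2", pos_bp = 12e6, a = 1, d = 0),
  noise_sd = sqrt(2), seed = 1)          # one QTL at PVE 20%
truth <- simulate_f2_population(cfg)
obs <- simulate_observations(truth, mean_depth = 7, error_rate = 0.01)

blocks <- decode_population(obs)
binmap <- build_bins(blocks, obs$markers)
map <- build_linkage_map(binmap)
map_summary(map)

y <- truth$phenotypes$value
scan <- scan_cim(y, binmap)
thr <- permutation_threshold(y, binmap, n_perm = 1000, seed = 2)
fit_qtl(y, binmap, find_qtl_peaks(scan, thr), scan)
```

The same flow, driven from files with provenance headers, is available as
`run_pipeline(pipeline_config(...))` and as the thin command-line wrapper
in `inst/scripts/run_pipeline.R`.
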