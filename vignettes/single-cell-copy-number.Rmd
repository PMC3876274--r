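---
title: "Copy-number and allelic-state profiling of single WGA tumor cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number and allelic-state profiling of single WGA tumor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scellcn)
```

# The problem and the model

A single disseminated tumor cell yields picograms of DNA; sequencing it
requires whole-genome amplification (WGA), which produces reads carrying a
fixed adapter prefix and coverage that is uneven at the scale of
amplification fragments ("amplicons"), on top of the usual GC bias and PCR
duplication. At a few gigabases of sequence, coverage is shallow — roughly
a third of the genome touched at all. The pipeline therefore estimates DNA
dosage from *focal read depth in variable bins* rather than per-base depth:

* Bins each hold a fixed count $B$ of *uniquely mappable positions* —
  positions whose $k$-mer (the post-trim read length, $k = 69$ by default)
  occurs exactly once in the genome, counting both strands. Reads can only
  be placed confidently at such positions, so fixing their count per bin
  equalises the bins' information content; physical width then varies
  inversely with local mappability.
* Per-bin logR is $\log_2$ of the pseudocounted read count over the
  genome-wide mean of retained bins. The pseudocount (1) keeps empty bins
  finite; bins with GC < 28% are discarded as unreliably amplified before
  the mean is taken.
* A Loess regression of logR on per-bin GC absorbs the smooth GC-dependent
  amplification bias; the corrected track is median-normalised so the
  dominant (usually diploid) state sits at 0.
* Piecewise-constant fitting (PCF) segments the corrected track per
  chromosome: the exact minimiser of
  $\sum_{\text{seg}} \mathrm{SSE}(\text{seg}) + \gamma \cdot \#\text{breakpoints}$
  subject to a minimum of $k_{\min}$ bins per segment.
* Absolute copy number uses $CN = 2^{\log R} \times \Psi$, with the average
  ploidy $\Psi = CN_{\mathrm{ref}} \cdot 2^{-\overline{\log R}_{\mathrm{ref}}}$
  anchored on a large reference region of known copy number and no large
  aberrations. Integer calls round half-up and floor at 0.
* Digital SNP B-allele fractions (alternate reads over total, at sites with
  at least 8 reads) supply the allelic dimension: loss of heterozygosity
  and, crucially, copy-neutral LOH (cnLOH), which dosage alone cannot see.

Two properties of this construction are worth noting. First, because
$\Psi$ is estimated from the same corrected logR track used for the calls,
the systematic downward shift of segment-mean logR that comes from
averaging a left-skewed $\log_2$ count distribution cancels in
$2^{\log R}\times\Psi$: the reference region absorbs it. The estimated
$\Psi$ therefore reads slightly above the true ploidy at shallow depth
(2.2–2.3 for a diploid cell around 15 reads per bin) while the integer
calls remain correct; $\Psi$ should be read as a scaling constant, not an
unbiased ploidy estimate. Second, logR is invariant to rescaling all
counts only when the pseudocount is 0; with the default pseudocount of 1
the invariance is asymptotic in depth. This is the standard trade-off for
keeping empty bins in the model.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| trim | 32 | bp | WGA adapter prefix removed from each read (101 → 69 bp) |
| read_length | 69 | bp | mappability $k$-mer and alignment footprint |
| bin target $B$ | config | unique positions | 50 kb of unique positions at full-genome scale; scaled to 2000–4000 for the desk-scale genomes here |
| pseudocount | 1 | counts | added to every bin before logR |
| gc_min | 0.28 | fraction | bins below this GC are discarded |
| span / degree | 0.3 / 2 | — | Loess GC fit (tricube weights); package defaults, exposed in the configuration |
| $\gamma$ (sequencing) | 25 | SSE units | PCF penalty for binned logR |
| $k_{\min}$ (sequencing) | 5 | bins | minimum segment length |
| $\gamma$, $k_{\min}$ (aCGH) | 60, 25 | — | probe-mode PCF settings |
| floor (aCGH) | −2 | log2 | outlier clamp before recentring |
| min_depth (BAF) | 8 | reads | informative-site threshold |
| BAF low/high | 0.15 / 0.85 | — | "extreme" site thresholds for LOH |
| loh_site_fraction / min_sites | 0.9 / 10 | — | segment-level LOH rule |

The BAF thresholds are package choices: allele dropout during WGA makes any
single site unreliable, so allelic states are called at segment level from
the fraction of extreme informative sites, rather than per site. A segment
is LOH when ≥ 90% of ≥ 10 informative sites are extreme; cnLOH when LOH
coincides with integer CN 2; imbalanced when the mean mirrored BAF
($\max(b, 1-b)$) exceeds 0.65 without LOH.

## What γ = 25 can and cannot detect

PCF inserts a breakpoint pair around an interior event only when the SSE
reduction exceeds $2\gamma$. The reduction for an island of $n_1$ bins
shifted by $\Delta$ inside a segment of $n$ bins is
$n_1(1 - n_1/n)\Delta^2$ — independent of sequencing depth. At
$\gamma = 25$ a one-copy gain from diploid ($\Delta = \log_2 1.5 \approx
0.585$) needs roughly 150 effective bins; a one-copy deletion
($\Delta = 1$) about 50; a two-copy amplification ($\Delta = 1$) likewise.
On a full genome with ~50,000 bins this is sub-megabase resolution for
deletions; on the desk-scale demo genomes (1000–2500 bins) it means small
one-copy gains are intentionally left unsegmented, and the demo's
subclone-private event is therefore planted as a two-copy amplification.
The chromothripsis-like region oscillates in ~20-bin pieces and is only
partially resolved at demo scale — expected, and a faithful miniature of
the resolution limits of the real analysis.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests.

* **Genome.** I.i.d. bases with per-position $P(G\,\text{or}\,C)$
  interpolated along control points. The default landscape alternates
  between 0.36 and 0.54 on a ~250 kb period: GC varies on the isochore
  scale, far below chromosome arms, so GC is essentially uncorrelated with
  planted arm-level events. (An early design with a single chromosome-wide
  GC gradient confounded the Loess fit with real dosage — the fit absorbed
  part of a planted gain. The oscillating landscape is the fix, and it is
  also the more realistic choice.) Planted duplications are exact copies
  and create the multi-mapping regions the mappability stage must find.
* **Tumor truth.** Clones with fractions summing to 1 (with optional
  normal admixture); events are allele-specific interval operations on a
  diploid baseline: arm/focal copy changes, cnLOH (B lost, A doubled —
  total CN unchanged), and a chromothripsis-like "shatter" that expands
  into oscillating one-copy gains/losses on alternating alleles. Plans
  that drive an allele below 0 copies are rejected. Clone fractions are
  fixed — no growth dynamics — and a DTC is a pure single clone.
* **WGA reads.** Each constant-CN interval is tiled with amplicons
  (Normal lengths, mean 10 kb, truncated at 500 bp); every
  amplicon-by-copy pair draws an independent mean-1 Gamma multiplier whose
  *variance* is `amplification_dispersion` (a mean-1 lognormal of the same
  variance sits behind a flag). Dispersion 0 disables amplification noise
  and recovers Poisson-like bin counts, which the tests exploit. Sampling
  weight is amplicon width × summed multipliers × $e^{\beta(gc - \bar{gc})}$
  — a log-linear GC effect that Loess can invert. Reads are the 32-base
  adapter plus the genomic 69-mer (reverse-complemented on the minus
  strand); a `duplicate_rate` fraction of reads are exact copies of
  earlier reads. Defaults: dispersion 0.25, GC slope 0.6, duplicates 5% —
  moderate values chosen once as plausible for kit-amplified single cells;
  WGA artifact magnitudes are reported only qualitatively in the
  literature.
* **SNP counts.** Site depth is Poisson with mean scaled by local total
  CN (optionally Gamma-overdispersed); alternate counts are Binomial with
  success probability equal to the copy fraction of the parental allele
  carrying the alternate base (assigned to parental copy B for a random
  half of sites, so ref/alt mirror symmetry is testable). Sequencing
  errors are off by default.
* **Bulk probe track.** Probes on a grid report
  $\log_2(\text{mixture CN}/2)$ plus Gaussian noise; each probe carries a
  germline genotype (het fraction 0.33), homozygous probes reporting BAF
  0/1.

What the generator does **not** emulate: real sequencing error and quality
models, paired ends, insert-size structure, mappability driven by repeats
rather than exact duplications, and reference-genome artifacts. Passing
tests therefore demonstrate the pipeline's statistical correctness under a
faithful noise *structure* (amplicon-correlated counts, GC bias,
duplicates, allele dropout at depth), not performance on any particular
real dataset.

# Numerical and design decisions

* **logR definition.** "Dividing the read count by the average" is
  implemented as $\log_2$ of that ratio — forced by the downstream
  $CN = 2^{\log R}\Psi$ formula. The averaging denominator uses retained
  (GC-filtered) bins, matching the stated order pseudocount → filter →
  ratio; the alternative (mean before filtering) changes logR by a
  constant that the median normalisation would absorb anyway.
* **PCF objective and ties.** The penalty is charged per breakpoint;
  charging per segment shifts all candidates by $+\gamma$ and selects the
  same segmentation. Ties break toward fewer breakpoints, then the
  lexicographically smallest breakpoint vector; the dynamic program
  achieves this with a suffix-cost table plus forward-greedy
  reconstruction, and the exhaustive oracle (length ≤ 15) enumerates with
  the identical ordering. Objectives agree with the oracle to 1e-9
  (differing only in float summation order); refitting the objective from
  returned breakpoints reproduces it to the same tolerance.
* **Mappability.** Uniqueness counts both strands — an aligner places
  reads from either strand — behind a toggle since the convention is not
  universal. Windows containing non-ACGT bases are never unique. The
  production scan uses a 64-bit rolling-hash dictionary (collision
  probability ~$n^2/2^{64}$, negligible below hundreds of Mb) and is
  checked exactly against a brute-force string-dictionary oracle on
  genomes up to 200 kb.
* **Binning.** Bins tile contiguously (a bin closes immediately after its
  $B$-th unique position; the next starts where it ended) — keeping a
  partition rather than letting bins span first-to-last unique position.
  Terminal partial bins are dropped so all bins are exchangeable. The
  width summary removes the top 1% widest bins (deserts) and reports mean
  and sample SD.
* **Duplicates and coverage.** The duplicate key is (chromosome, 5′
  start, strand) — the standard single-end convention; the first read by
  name is kept. Coverage statistics are computed after deduplication (the
  processing order implies post-dedup figures). `depth_genome` is
  alignment count × footprint / genome length; the identity
  `depth_covered × breadth = depth_genome` holds by construction and is
  asserted to 1e-12.
* **aCGH mode.** Order: floor at −2 → recentre to mean 0 → optional Loess
  GC correction (then recentre again) → PCF. Segmentation must consume the
  processed values, so it always runs last; the full order is the
  package's stated choice. Note
  the floor and the recentring interact: recentring a track whose mean is
  positive can push already-floored outliers below −2. On the degenerate
  all-below-floor input the result is a flat zero track.
* **cnLOH segmentation.** A cnLOH region need not coincide with any
  dosage segment (its total CN is unchanged), so classification first
  refines the copy-number segments with a PCF on mirrored BAF in
  site-index space ($\gamma = 3$, $k_{\min} = 10$ sites) and classifies
  the refined pieces. Without refinement, a cnLOH interval embedded in a
  long diploid segment dilutes below the site-fraction threshold and is
  missed.
* **B allele.** BAF is the alternate-allele fraction (alt convention);
  state calls are mirror-symmetric by construction, verified by a
  ref↔alt relabeling test.
* **Concordance.** Defined on gain/neutral/loss status (baseline 2, or
  round($\Psi$) behind a flag), bp-weighted over the intersected extent —
  a package definition, since "concordant profiles" has no universal
  denominator; published headline percentages computed on other
  denominators are therefore not directly comparable. Event matching uses
  bp Jaccard ≥ 0.5 within the same direction; a matched primary event is
  clonal when its summed clone fraction is ≥ 0.8, subclonal below.
* **Reference region.** Supplied explicitly in all analyses here. At full
  scale an automatic fallback would pick the longest segment nearest the
  modal segment logR; the demo genomes are small enough that an explicit
  region is both clearer and safer.
* **Degenerate inputs.** Chromosomes with fewer than $k_{\min}$ bins are
  emitted unsegmented with a warning; a degenerate GC range skips the
  Loess fit (median-centring only); an all-filtered bin set is an error;
  zero requested reads yields empty, well-formed outputs.

# Problem sizes and validation studies

The reference validation cell is a 10 Mb two-chromosome genome, ~2500 bins
of 4000 unique positions (~4 kb), ~15 deduplicated reads per bin, with a
planted arm gain (CN 3), focal deletion (CN 1), cnLOH region, and a CN-2
reference region — sizes chosen so the whole study simulates and analyses
in well under a minute while keeping every stage in its intended operating
regime. On it the pipeline assigns the true integer copy number to ≈ 99%
of the binned genome (bp-weighted) across seeds and labels essentially the
whole cnLOH region LOH-or-cnLOH. Concordance calibration on constructed
noise-free pairs returns $1 - f$ exactly for private fractions
$f \in \{0.01, 0.1, 0.25\}$. The demo patient in `analysis/` is smaller
(2 × 2 Mb, ~2000 bins, 30,000 reads) and intentionally shows the
resolution limits discussed above. All simulation-backed tests fix their
seeds; stage seeds derive from one global seed via a name hash so stages
rerun independently yet deterministically.

# Limitations

* Exact-match toy mapping (no mismatches/gaps) stands in for a real
  aligner; with error-free simulated reads it recovers true positions
  exactly, but it is not meant for real FASTQs.
* Allele-specific integer CN (major/minor alleles) is not estimated from
  single-cell BAF; states are categorical.
* Bulk-tumor deconvolution (inferring subclone fractions from bulk data)
  is out of scope: primary-tumor truth enters as simulated clone tracks.
* $O(n^2)$ PCF is exact but sized for ≤ ~10^4 bins per chromosome; a full
  50,000-bin genome segments in seconds per chromosome, but much denser
  tracks would want the fast heuristic from the segmentation literature.
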