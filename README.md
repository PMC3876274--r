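# scellcn — single-cell copy-number and SNP-BAF profiling of WGA tumor cells

Disseminated tumor cells (DTCs) are single tumor cells recovered from bone
marrow. Profiling one cell requires whole-genome amplification (WGA), which
leaves adapter sequence on the reads and introduces strong, uneven
amplicon-level coverage bias, and the resulting sequencing is shallow — a
few gigabases covering 30–40% of the genome. `scellcn` implements a focal
read-depth pipeline built for exactly this regime, plus the comparison of a
cell's profile against its patient's bulk primary tumor, for anyone who
wants to ask whether a disseminated cell descends from the dominant tumor
clone or from a subclone.

## The method

1. **Variable bins.** For the post-trim read length *k* (default 69 bp), a
   genome position is *uniquely mappable* if its k-mer occurs exactly once
   genome-wide, counting both strands. Each chromosome is tiled left to
   right with non-overlapping bins that each contain a fixed count *B* of
   uniquely mappable positions, so physical bin width varies inversely with
   local mappability and every bin has the same statistical footing.
2. **logR.** Per-bin read counts (5′ starts of deduplicated, uniquely
   mapped reads) get a pseudocount of 1; bins with GC below 28% are
   discarded; `logR = log2(count / mean count)` over retained bins. A Loess
   fit of logR on per-bin GC removes WGA/PCR GC bias, and the track is
   median-normalised to 0.
3. **Segmentation.** Exact penalised least-squares piecewise-constant
   fitting (PCF): the global minimiser of `sum SSE(segment) + gamma *
   #breakpoints` with a minimum segment length, solved by dynamic
   programming (gamma = 25 for sequencing bins; gamma = 60 with k_min = 25
   probes and a −2 floor plus zero-recentring in aCGH probe mode).
4. **Absolute copy number.** `CN = 2^logR × Ψ`, with the average ploidy Ψ
   anchored on a large reference region of known copy number:
   `Ψ = CN_ref × 2^(−mean logR_ref)`. Integer calls round half-up.
5. **Allelic state.** Digital B-allele fractions at known SNPs covered by
   ≥ 8 reads; segments (refined by PCF on mirrored BAF) are classified
   balanced / imbalanced / LOH / copy-neutral LOH (LOH at integer CN 2).
6. **Comparison.** Gain/neutral/loss status tracks, bp-weighted
   concordance, and per-event labels — clonal-shared, subclonal-shared,
   private — against the primary tumor's clones.

A synthetic-data generator produces everything the pipeline consumes —
genomes with controlled GC landscapes and planted duplications, clone trees
with arm/focal/cnLOH/chromothripsis-like events, WGA reads with gamma
amplicon noise, GC bias, PCR duplicates and a fixed 32-base adapter prefix,
SNP allele counts, and bulk probe tracks — so every stage is tested against
known truth.

## Worked example

The coverage identity, straight from two cells' summary statistics — a cell
at genome-relative depth 2.92× with 33.9% breadth, another at 2.03× and
38.7%:

```r
library(scellcn)
round(depth_on_covered(2.92, 0.339), 2)   # 8.61  (depth over covered bases)
round(depth_on_covered(2.03, 0.387), 2)   # 5.25
```

The full demo patient (two tumor clones + normal admixture; the DTC is a
pure cell of the minor subclone):

```r
res <- run_pipeline(list(), outdir = "demo_run")
res$profile$segments[, c("chrom","start","end","mean","cn_integer")]
```

prints the recovered profile (seed 1):

```
  chrom   start     end       mean cn_integer
1  chr1       0  182000 -0.2554586          2
2  chr1  182000  360000 -1.2998623          1
3  chr1  360000  598000 -0.2861885          2
4  chr1  598000  872000  0.6865658          4
5  chr1  872000 1118000 -0.2890830          2
6  chr1 1118000 1998000  0.3862700          3
7  chr2       0 1998000 -0.2354601          2
```

— the planted clonal focal deletion (chr1 200–360 kb, CN 1), the subclone's
private amplification (600–840 kb, CN 4) and the clonal arm gain (chr1 from
1.1 Mb, CN 3), with Ψ estimated at 2.26 from the chr2 reference region. The
planted copy-neutral LOH (chr2 100–500 kb) is invisible in depth but called
`cnLOH` from BAF (`res$states`), and the status-track comparison reports
92.6% concordance with the primary, with the amplification and cnLOH
labeled as subclone-derived (`res$events`).

The numbered scripts under `analysis/` walk the same analysis step by step
(simulation, preprocessing, binning, copy number, allelic states,
comparison) and write their tables under `results/analysis/`.

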