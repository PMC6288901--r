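# TADconcord

Concordance and feature-enrichment metrics for topologically associating
domain (TAD) partitions.

TAD callers applied to the same Hi-C contact matrix disagree widely in
the number, size and boundaries of the domains they report, and the
same caller disagrees with itself across matrix resolutions,
normalizations and sequencing depths. TADconcord is for anyone who
needs to quantify that disagreement — method developers benchmarking a
new caller, and analysts deciding which published partition to trust.
It implements, per chromosome:

* the **Measure of Concordance** between two partitions, with inter-TAD
  gaps treated as clusters so callers that tile the chromosome and
  callers that leave gaps are comparable:

  MoC(P, Q) = 1 if N_P = N_Q = 1, and otherwise
  (1 / (√(N_P·N_Q) − 1)) · ( Σᵢ Σⱼ ‖F_ij‖² / (‖P_i‖·‖Q_j‖) − 1 ),

  where the clusters of P and Q have sizes ‖P_i‖, ‖Q_j‖ in bp and
  pairwise overlaps ‖F_ij‖; symmetric, in [0, 1];
* **boundary and TAD conservation** within a tolerance radius in bins,
  cross-resolution boundary containment, consolidation of boundaries
  shared across callers, conservation ratios, and TAD-size scaling
  slopes;
* **Hi-C preprocessing**: map-resolution selection (smallest bin size
  with ≥ 80% of bins making ≥ 1000 contacts), binomial read
  subsampling, iterative matrix correction, and Poisson regression on
  local genomic features (mappability, GC, fragment length);
* **feature enrichment**: structural-protein (CTCF/cohesin-style) peak
  profiles and fold changes at boundaries, tagged-boundary fractions,
  shared-vs-private boundary enrichment, and within-TAD
  H3K27me3/H3K36me3 log-ratio significance with a 10-shuffle
  permutation null and Benjamini–Hochberg FDR;
* **hierarchy levels** of nested/overlapping domain sets (longest
  containment chains, with duplicates and partial overlaps discarded);
* seeded **synthetic-data generators** (partitions, contact matrices,
  peak sets, mark tracks, controlled perturbations) so every statistic
  can be calibrated against planted truth.

Inputs are plain text: three-column 1-based partitions, BED peaks,
bedGraph signal tracks, and sparse triplet contact matrices. A thin
command-line wrapper lives at `inst/scripts/tadconcord`.

## Worked example

Plant a truth partition on a 20-Mb chromosome, degrade it the way an
imperfect caller would, and score the result:

```r
library(TADconcord)

cfg   <- simulationConfig(chromLength = 2e7)       # 10-kb bins, 500-kb TADs
truth <- simulatePartition(cfg, seed = 1)
truth
#> TadPartition 'truth' on chrS: 40 domain(s), bin size 10 kb, chrom length 20 Mb
#>   span 1-20000000, mean domain size 500 kb

called <- perturbPartition(truth, jitterBins = 2, splitProb = 0.1, seed = 2)
moc(truth, called)
#> [1] 0.9005604

conservedBoundaries(truth, called, radiusBins = 2)$fractionA
#> [1] 1

peaks <- simulatePeaks(cfg, truth, seed = 3)       # boundary-enriched peaks
boundaryFoldChange(called, peaks)$foldChange
#> [1] 0.5381101

marks <- simulateMarks(cfg, truth, seed = 4)       # exclusive mark tracks
histoneLrSignificance(called, marks$sig27, marks$sig36, seed = 5,
                      correction = "none")$fractionSignificant
#> [1] 0.7045455
```

Reading: boundary jitter of up to 2 bins plus occasional splits leaves
the partitions highly concordant (MoC 0.90) and every truth boundary
recoverable within ±2 bins. The called boundaries still sit on the
planted peak enrichment (fold change 0.54 above flanking background —
lower than the truth partition would score, since jittered boundaries
miss part of the planted peak windows), and 70% of the called TADs show
a significant bias toward one histone mark (80% of the planted TADs
carry one). The package vignette
(`vignettes/tad-concordance.Rmd`) documents every statistic, the
generator's assumptions, and the numerical conventions.

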