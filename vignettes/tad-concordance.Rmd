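---
title: "Evaluating TAD partitions: concordance, conservation and feature enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating TAD partitions: concordance, conservation and feature enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TADconcord)
```

Topologically associating domains (TADs) are chromosomal segments whose
loci contact each other more often than they contact flanking regions.
Dozens of callers identify such domains from binned Hi-C contact
matrices, and their outputs disagree substantially in domain number,
size, and boundary placement. TADconcord implements the statistics used
to compare such outputs quantitatively — against each other, across
matrix resolutions and normalizations, and against orthogonal chromatin
features — together with the Hi-C preprocessing steps those comparisons
presuppose and a synthetic-data generator that plants known structure so
every statistic can be calibrated without external data.

All coordinates are 1-based closed, the convention of the uniform
three-column caller-output format (`chr1 1 10000` is the first 10-kb
bin). BED and bedGraph files are 0-based half-open on disk and converted
on read and write. All statistics are per chromosome; multi-chromosome
files must be read one chromosome at a time.

## The Measure of Concordance

Two TAD partitions of the same chromosome are compared by treating base
pairs as clustered elements: every TAD is a cluster and, because some
callers leave inter-TAD gaps while others tile the chromosome, every
inter-TAD gap is treated as a cluster as well, so both sides cluster the
same element set. With $N_P$ and $N_Q$ clusters of sizes $\|P_i\|$ and
$\|Q_j\|$ (bp) and overlap sizes $\|F_{ij}\|$,

$$\mathrm{MoC}(P,Q) = \begin{cases}
1 & \text{if } N_P = N_Q = 1\\[4pt]
\dfrac{1}{\sqrt{N_P N_Q}-1}\left(\displaystyle\sum_{i=1}^{N_P}\sum_{j=1}^{N_Q}
\frac{\|F_{ij}\|^2}{\|P_i\|\,\|Q_j\|} - 1\right) & \text{otherwise.}
\end{cases}$$

The statistic is symmetric and bounded in $[0,1]$: identical partitions
score exactly 1, and a single whole-span cluster against any multi-cluster
partition scores exactly 0, because the inner sum telescopes to 1. Three
implementation choices deserve note:

* **Span harmonization.** If the two partitions cover different spans,
  the union span is used and the uncovered tail becomes a gap cluster on
  the deficient side; MoC requires clusterings of the same element set.
* **Degenerate case.** When exactly one side has a single cluster the
  general branch applies (and yields 0); the special branch is reserved
  for $N_P = N_Q = 1$.
* **Bound snapping.** The double sum is evaluated in floating point, so
  values that are exactly 0 or 1 in exact arithmetic can land within
  ~1e-16 of the bound; results within 1e-12 of 0 or 1 are snapped to the
  bound, and the result is clamped to $[0,1]$.

## Boundaries, conservation, and sharing

A boundary is represented as a *junction between bins*: junction $j$
sits between bin $j$ and bin $j+1$, at genomic offset $j \times$
bin size. Each domain contributes its left and right junction; the
junction shared by a domain end and the following domain start is a
single unique boundary once deduplicated. Distances between boundaries
are measured in integer bins, so a tolerance radius of 5 bins at 10 kb
is ±50 kb.

At equal bin size, a boundary of one caller is **conserved** if the
other caller has a boundary within the radius; a TAD is conserved if
both of its boundaries match the start and end, within the radius, of
exactly one TAD of the other caller — a TAD spanning two domains whose
outer edges coincide with it is therefore not conserved. Across
resolutions, a boundary called at the bigger bin size is conserved if at
least one boundary called at the smaller bin size falls inside the
genomic interval of the coarse bin delimited by that boundary.

Boundaries of several callers are consolidated by **single-linkage**
clustering: sorted junctions are chained while consecutive gaps stay
within the radius. The consolidation rule is a convention (no canonical
definition exists for "the same boundary seen by $k$ callers"), so a
complete-linkage option — capping the cluster diameter at the radius —
is provided; the choice is recorded in the result's `params`. Each
cluster reports the number of distinct callers represented, which
supports both the histogram of boundaries found by a given number of
callers and the shared/not-shared split of the enrichment analyses.

The **conservation ratio** divides the number of conserved TADs by the
smaller of the two TAD counts (the maximum attainable number). The two
per-side conserved counts can differ slightly under the exactly-one
rule; the minimum of the two is used so the ratio is symmetric.

## Hi-C preprocessing

**Map resolution.** The resolution of a contact matrix is the smallest
bin size at which at least 80% of bins make at least 1000 contacts. The
marginal count of a bin is its row sum in the symmetric matrix with the
diagonal counted once, and the denominator is *all* bins in the
chromosome span at that bin size; an explicit exclusion list of regions
(e.g. unmappable stretches) can remove bins from both counts. Read
subsampling is binomial thinning of the binned counts — each contact is
retained independently with the requested probability — which is
equivalent in distribution to subsampling the read-pair list before
binning.

**Iterative correction** assumes equal visibility of all bins: observed
counts factorise into per-bin biases times true contact probabilities.
Each iteration divides every row by its mean over unmasked bins and
accumulates the biases; iteration stops when the variance of the log
bias update drops below `tol` (default 1e-5) or after `maxIter`
(default 1000) iterations. Bins with zero marginal count are masked and
reported as `NA` biases. The default tolerance leaves tiny residual
imbalance on very small matrices (a handful of bins); passing a tighter
`tol` iterates to machine-level balance.

**Local-genomic-feature normalization** models the three systematic
bias sources — mappability, GC content, and restriction fragment
length — with a Poisson regression of pairwise counts on the log
products of the two bins' fragment-length and GC features, with log
mappability product as offset. The normalized matrix holds the
residuals of the fit. "Residual" is deliberately configurable: the
default is the observed/fitted ratio, which is non-negative and can
live in a `ContactMatrix`; raw Pearson residuals are available but are
returned as a plain sparse matrix because they can be negative.
Covariates that are constant across bins carry no information; they are
dropped from the model with a warning (with everything constant the fit
is intercept-only and the output is proportional to the input). The fit
uses every off-diagonal bin pair including zeros and is intended for
matrices up to roughly a thousand bins per chromosome arm at desk
scale.

## Feature enrichment at boundaries and within domains

**Structural-protein profiles (SPP).** For each boundary, ChIP-seq peak
midpoints are counted in 5-kb intervals across a ±500-kb window
centred on the boundary junction. Midpoint assignment avoids double
counting a peak that straddles two intervals. Boundaries within 500 kb
of either chromosome end would have truncated windows that bias the
flank estimate and are dropped (the count is reported). The **fold
change** compares the mean SPP within ±10 kb of the boundary to the
mean SPP in two 100-kb flanking regions 400 kb away, minus 1. The
default estimate averages the SPP across boundaries first and then
takes the ratio (per-boundary ratios, averaged afterwards, are
available; with few peaks many per-boundary flanks are zero and must be
excluded, which the pooled estimate avoids). Uniform peak density gives
a value near 0; a threefold boundary rate gives a value near 2. The
calibration equals the planted enrichment only when the flanking
regions are themselves background — with domains shorter than the
500-kb flank offset the flanks of one boundary contain its neighbours'
enrichment windows and the measured fold change is systematically
smaller; the calibration tests therefore use partitions whose domains
exceed the flank offset.

A boundary is **tagged** by a factor when at least one peak overlaps
its boundary bin or one of the two adjacent bins. The boundary bin of a
junction is taken as the bin to its right (the start bin of the
following domain); the final junction of the span keeps the bin to its
left.

**Histone-mark log ratio.** Each chromosome is tiled into intervals of
10% of the caller's mean TAD size, rounded down to a bin multiple (at
least one bin). Per interval, $LR = \log_{10}((m_{27}+\varepsilon_{27})/
(m_{36}+\varepsilon_{36}))$, where $m$ are coverage-weighted mean
signals. The pseudo-count is 1% of each track's global mean — small
enough not to damp real ratios, large enough to keep LR finite over
signal deserts — and is configurable. A TAD's observed statistic is the
mean LR of the intervals whose midpoints fall inside it (midpoint
membership avoids edge-interval ambiguity). The null shuffles the LR
values over interval positions 10 times and recomputes per-TAD means;
the empirical p value is two-sided via deviation from the
chromosome-wide mean LR, with a +1/+1 correction so p never reaches 0
with only 10 shuffles. Benjamini–Hochberg adjustment across TADs gives
q, and the fraction of TADs with $q < 0.1$ is reported.

The correction has a consequence worth knowing: the smallest attainable
p is $1/11 \approx 0.0909$, so after BH adjustment the whole analysis
sits just under the 0.1 threshold — the minimum-p TADs are significant
only when they make up more than $10/11 \approx 91\%$ of all tested
TADs. The reported fraction is therefore nearly binary under the
default settings: close to 1 when essentially every TAD is biased,
close to 0 otherwise. Intermediate fractions (a partly biased
chromosome) are resolvable with `correction = "none"`, which allows
p = 0 for TADs more extreme than all shuffles; both variants are
exposed, and the null calibration tests show the default respects the
FDR target. A one-sided variant (`sided = "high"`) is also available.
Tracks must cover the tiled span; uncovered positions are an error by
default and can be zero-filled explicitly (`gaps = "zero"`), so silent
coverage gaps cannot masquerade as signal.

## Hierarchy levels

Callers that output nested or overlapping domains are summarised by
nesting level. A domain's level is the length of the longest
containment chain below it: level 1 (innermost) domains contain no
other domain, and a level-$i$ domain contains at least one
level-$(i-1)$ domain. This definition also settles domains containing
members of several earlier levels (they join the level after the
deepest). Containment allows equality on at most one endpoint: exact
coincidence is a duplicate (discarded and reported), and partial
overlaps — neither containment nor disjointness — are never promoted to
a level, so only perfectly nested structures are retained. Partial
overlaps are filtered greedily in (start, −length) order against the
already-retained set, which keeps the retained family laminar and
deterministic. Levels with fewer than `minDomains` (default 10) domains
are kept in the object but flagged so that per-level summaries (domain
count, mean size, boundary fold change, tagged fraction, LR-significant
fraction) exclude them.

## What the synthetic generator emulates — and what it does not

`simulationConfig()` fixes the generative conditions once; the
defaults describe a 50-Mb chromosome binned at 10 kb:

| parameter | default | rationale |
|---|---|---|
| `meanTadSize` | 500 kb | centre of the commonly reported 100 kb–5 Mb TAD range |
| `sizeSdlog` | 0.3 | log-normal, right-skewed sizes without sub-resolution domains |
| `alpha` | 1 | power-law contact decay exponent typical of intra-chromosomal maps |
| `gamma` | 2 | twofold within-TAD contact enrichment per nesting level |
| `depth` | 5e6 | intra-chromosomal reads at which 10-kb bins are informative |
| `backgroundPeakRate` | 2e-4 /bp | one expected peak per 5-kb SPP interval, so profile statistics are well resolved at desk scale |
| `rho` | 2 | planted boundary peak surplus; boundary windows reach 3× background, the regime of the fold-change analyses |
| `markCoherence` | 0.8 | most, not all, TADs carry a dominant mark |
| `markHigh`/`markLow` | 4 / 0.25 | dominant vs recessive mark mean on the fold-change-over-control scale |
| `noiseSdlog` | 0.25 | multiplicative per-bin signal noise |

Partitions tile the chromosome contiguously with log-normal, bin-aligned
domain sizes; a terminal remainder shorter than half the mean is
absorbed into the last domain. Planted hierarchies are laminar with
exactly one child per parent per level, inset by one bin per side —
this keeps every level at the same domain count so level recovery can
be checked exactly; it does not emulate the branching hierarchies real
callers produce (branching laminar families are exercised separately by
the randomised hierarchy tests). Contact matrices are Poisson draws
around a decay-times-block-enrichment mean; peaks are a homogeneous
Poisson background plus boundary surplus; marks are mutually exclusive
per TAD with log-normal noise. Every generator is deterministic under a
fixed seed.

Real data differ in ways the generator deliberately ignores: no
unmappable or copy-number-altered regions (hence no masked bins), no
restriction-fragment granularity, no trans contacts, no
distance-dependent noise structure beyond Poisson counting, and
boundary peaks placed symmetrically around junctions rather than at
motif-oriented sites. Passing the calibration suite therefore shows the
statistics are implemented correctly and are well calibrated under
their own assumptions — not that any particular caller will reproduce
these numbers on experimental data.

`perturbPartition()` degrades a truth partition by jittering interior
boundaries (clamped so domains keep at least one bin and their order),
splitting domains, and merging contiguous neighbours; it drives the
monotone-degradation harnesses: mean MoC against the truth strictly
decreases as jitter grows.

## Problem sizes and numerical choices

The test suite runs entirely on generated data, with sizes chosen to
keep the full run under a minute on a single core: concordance and
conservation properties on partitions of up to ~100 domains with
brute-force oracles; iterative correction on random positive matrices
up to 200 bins; regression normalization on 80-bin matrices in a
large-count regime; fold-change calibration on partitions with over
1000 eligible boundaries; FDR calibration on 100 null replicates of a
10-Mb chromosome and 20 fully biased replicates of a 100-Mb chromosome;
hierarchy recovery on 100 random laminar families against a
containment-DAG longest-path oracle.

Numerical conventions collected in one place: MoC values within 1e-12
of a bound are snapped; iterative correction stops on the variance of
the log bias update; fold changes with a zero flank mean return `NA`
(never an infinity); empirical p values use the +1/+1 correction by
default; interval membership and peak assignment use midpoints;
boundary distances are integer bin differences, with ties at the radius
counted as conserved (`<=`).

## Limitations

The toolkit evaluates caller *outputs*; it does not call TADs, embed
caller-similarity matrices, or benchmark runtime. Statistics are
per-chromosome by design. The LR permutation test inherits the
paper-scale shuffle count (10), whose granularity limits attainable p
values; increasing `nShuffles` refines them at linear cost. The
fold-change calibration assumes boundary spacing larger than the flank
offset, as discussed above.
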