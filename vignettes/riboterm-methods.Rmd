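---
title: "riboterm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboterm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It is written for a reader who wants to judge
whether the method's assumptions fit their data, or to modify the pipeline
responsibly.

## The signal model

A transcription-terminating riboswitch produces two transcript pools. In
the OFF state, transcripts start at the TSS and end at a tightly
constrained position just past the riboswitch 3' end, where the intrinsic
terminator hairpin releases the polymerase. In the ON state, transcripts
read through into the downstream gene. A dataset whose conditions sample
both states therefore shows a condition-dependent step in coverage — and,
more sharply, a condition-dependent pileup of transcript 3' ends — at the
terminator.

RNA-seq obscures this because libraries are fragmented before sequencing:
every read's synthesis origin marks a fragment terminus, and nearly all
fragment termini are internal breakpoints, not transcript ends. The key
structural fact is that each internal fragmentation event creates a
*matched neighboring pair* of termini: the 3' end of one fragment at
position $b-1$ and the 5' end of the next at $b$. In a signed per-position
count (R-read origins $+1$, F-read origins $-1$) these pairs contribute
$+1$ and $-1$ at adjacent positions. A smoothing convolution with a
symmetric kernel makes them largely cancel, while the unmatched pileup at a
genuine transcript end survives at full strength.

## Ingest: orientation filtering and the coverage partition

Only read pairs in the `EQ` orientation (mates spanning an identical
interval on opposite strands, typical when the fragment is about one read
length) or `FR` orientation (left-most aligned base shared with or
exclusive to the forward-oriented read, right-most base exclusive to the
reverse-oriented read) are used. Same-strand (`TANDEM`), reversed (`RF`)
and other configurations indicate artifacts and are discarded; pairs with
one unmapped mate are kept only under `allowSingleReads` and then
contribute coverage but never termini.

Each retained pair deposits two fragment termini — the F read's left-most
and the R read's right-most mapped base — and partitions the rest of its
fragment interval into *overlapped* (bases mapped by both mates),
*read* (bases mapped by exactly one mate), *inferred* (unmapped bases
between the mates) and *clipped* (bases covered only by soft-clipped read
regions) coverage. Terminus positions are excluded from the other
categories, so at every base the five categories sum exactly to the number
of retained fragments covering it; this partition identity is enforced by
a brute-force interval-stabbing oracle in the test suite. Soft-clipped
pairs are excluded from terminus counting (their synthesis origin is
uncertain) unless `allowSoftClips`; their coverage still counts.

Loci are analyzed per readset only when mean total coverage across the
riboswitch reaches `minCovDepth` (default 15). "Depth" here is the
five-category sum, i.e. fragment depth including the inferred interior —
the quantity the partition identity makes reproducible.

## The kernel and peak detection

The kernel is a discretized Gaussian: 51 weights
$w_i \propto \exp(-i^2/2\sigma^2)$, $\sigma = 1.5$ nt, normalized to sum
to one. $\sigma$ sets the selectivity for how sharply coverage must
change: 1.5 nt passes changes localized within about 6 nt, matching the
tight positional constraint of intrinsic termination while tolerating
small jitter from library preparation. Convolution uses zero padding;
reference windows carry up to 1,000 nt of flanking sequence, so edge
effects never reach the riboswitch neighborhood.

One quantitative property worth stating precisely: a lone terminus spike
of height 1 convolves to a summit of $w_0 = 0.2660$, while a matched
adjacent $+1/-1$ fragmentation pair produces a response whose maximum is
the largest *difference* of adjacent weights, $w_1 - w_2 = 0.1038$,
reached one base off the pair (differences of shifted Gaussians peak near
$\pm\sigma$, not at the center; the response at the pair itself is
$w_0 - w_1 = 0.0530$). A single isolated fragmentation event can
therefore produce a marginal peak just above the default zero band of
$(-0.1, 0.1)$ — a 2.6-fold attenuation relative to a lone spike rather
than total cancellation. Such marginal peaks are exactly what the
per-locus noise model is for: they populate the noise set and candidate
termination peaks must stand out against them.

Peak detection applies three rules. A summit is a local extremum whose
amplitude lies on or outside the open zero band (ties on plateaus break to
the left-most position). The peak region extends to each side while the
absolute amplitude is monotonically non-increasing away from the summit
(non-strict, so 1-nt flat shoulders are included), stays outside the open
zero band — a value of exactly ±0.1 does not stop extension — and keeps
the summit's sign. Bounds are inclusive-exclusive: the left bound is the
left-most valid base, the right bound the first base that fails. Where the
verbatim rules would let two adjacent peaks share a valley base, the base
is assigned to the upstream peak, a deterministic tie-break that keeps
peak regions disjoint. The implementation is checked against a literal,
brute-force re-implementation of these rules on a thousand random tracks.

## Scoring candidate termination peaks

Positive peaks (3'-end pileups) inside the noise-set region are tested
individually. The region is defined relative to riboswitch size by
`extProp = c(-0.3, 1.0)`: it excludes the first 30% of the riboswitch
(where aptamer-domain structure generates locus-specific artifacts),
includes the remainder, and extends one full riboswitch length past the
3' end.

For each peak under test, a bivariate normal is fitted to the
(width, |amplitude|) of every *other* peak in the region — both signs,
since start-like and artifact peaks share the generative noise processes —
excluding the peak itself (leave-one-out). At least 3 noise peaks are
required to support a 2-D covariance; smaller sets fail the peak with
reason `insufficient_noise_set` rather than aborting the locus. Singular
covariances (identical noise peaks) are regularized with $10^{-9}$ on the
diagonal.

The peak's pseudo p-value is $p = \exp(-d^2/2)$, with $d^2$ the squared
Mahalanobis distance from the noise model. For a bivariate normal this is
exactly the probability that a random draw has lower density than the
observed point, so it behaves as a proper tail probability in $(0, 1]$ —
raw density would not. Its null calibration (5% of null peaks at
$p < 0.05$) is verified on 10,000 simulated peaks in the test suite, and
its equivalence to Monte-Carlo density ranking is checked directly.

A passing termination call additionally requires a fractional coverage
change of at most $-$`minDrop` (default $-0.20$): the difference in total
coverage between the peak's exclusive right bound and inclusive left
bound, divided by mean riboswitch coverage. The exclusive bound is
evaluated as written (clamped to the last window base); on a step-shaped
drop this lands on the post-drop plateau, which is the intent. Fail
reasons are recorded in order: wrong sign, outside region, insufficient
noise set, not significant, insufficient drop.

## Cross-condition clustering and the three-criterion call

All detected peaks — passing or not, both signs — whose summits fall
within ±0.5× riboswitch size of the riboswitch 3' end are pooled across
conditions, positioned in relative units (position − 3' end)/size, and
clustered by complete-linkage agglomeration cut at cophenetic distance
0.04: no cluster may span more than 4% of the riboswitch length. Input
order is canonicalized by sorting positions first, making the partition
exactly permutation-invariant (in one dimension, complete-linkage
clusters are contiguous runs, so sorting is lossless).

A cluster is significant only if all three criteria hold:

1. it contains at least one passing termination peak;
2. its members' fractional coverage changes are stochastically smaller
   than those of all other peaks at the locus — a one-tailed
   Mann–Whitney U test at $p < 0.05$. The published procedure phrases
   this as a comparison "to the mean of all other peaks"; since a rank
   test cannot compare to a single mean, the distributional sample-vs-
   sample reading is implemented. Exact null distributions are used for
   tie-free samples of at most 8 per group, midrank normal approximation
   with continuity correction otherwise;
3. its variance is significantly larger than noise — Levene's classical
   (mean-centered) test comparing the size-$n$ cluster against size-$n$
   samples drawn without replacement from all other peaks at the locus,
   each shuffled pass yielding $\lfloor N/n \rfloor$ disjoint samples,
   reshuffling until at least 60 comparisons are made; the median of the
   collected p-values must be below 0.05. The resampling runs on a
   dedicated seeded RNG (default 1729) that never touches the caller's
   RNG stream, so results are reproducible and order-independent.
   Comparisons with an undefined Levene statistic (constant absolute
   deviations) are dropped; a cluster of fewer than two peaks cannot be
   tested and is never significant.

A locus is called `termination_evidence` when any cluster is significant;
`no_candidate_peaks` when the region of interest holds no peaks under any
condition; `low_coverage` when no readset passes the depth filter; and
`inconclusive` otherwise. Per-condition ON/OFF readouts (whether any
passing termination peak was observed under a condition) are reported
alongside, but the locus-level call rests only on the cluster criteria.

No multiple-testing correction is applied across loci: each step uses raw
$p < 0.05$, deliberately mirroring the published procedure. Users
screening many loci should treat the verdicts as a ranked shortlist for
inspection, not as family-wise-controlled discoveries.

## The synthetic-data generator

The simulator generates the conditions under which the method is
validated: a 3,000-nt random-sequence contig carrying a 150-nt riboswitch
at [1200, 1350), TSS at 1,000, and a terminator at 1,360 (10 nt past the
3' end, where intrinsic terminator release sites typically fall) with
1-nt Gaussian positional jitter. Each transcript starts at the TSS and,
with probability equal to the condition's termination efficiency, ends at
the jittered terminator; otherwise it runs to the window end. Transcripts
are cut left-to-right at breakpoints spaced by lognormal fragment lengths
(meanlog $\log 300$, sdlog 0.35, truncated to [100, 1000] nt — a biased
unimodal distribution typical of paired-end library preparation), so
every internal breakpoint appears as a matched neighboring terminus pair
by construction. Each fragment yields an F read over its first 150 bases
and an R read over its last 150 (an EQ pair when the fragment is
shorter), written as properly-paired SAM against the window reference.
The standard experiment uses termination efficiencies 0.9 (condition A)
and 0.1 (condition B), four readsets per condition, and 60 transcripts
per readset, giving roughly 60× riboswitch depth.

What the simulator deliberately does not emulate: sequencing errors and
quality variation, PCR duplicates, rRNA contamination, strand-specific
library artifacts, mapping ambiguity (alignments are synthesized, not
re-derived by an aligner), and genome-scale locus multiplicity. Passing
the end-to-end tests therefore demonstrates that the statistical machinery
recovers a programmed termination signal from realistic fragmentation
noise at realistic depth — not that the method is robust to alignment
artifacts or contamination, which on real data are handled upstream by
the aligner and by the orientation and soft-clip filters.

## Numerical conventions and degenerate inputs

* All internal coordinates are 0-based half-open; the Infernal and
  Prodigal parsers convert from 1-based inclusive at the boundary, and
  minus-strand hits are normalized to `start < end` with strand `-`.
* Reference windows near contig ends are clipped (smaller or asymmetric
  neighborhoods); minus-strand windows are reverse complemented so the
  riboswitch always reads 5'→3'.
* Overlapping hits from different covariance models are retained as
  distinct loci; no deduplication of read pairs is performed.
* Mates mapping to different locus windows are treated as single reads
  within each window; windows are analyzed independently.
* A pair whose terminus would fall outside the window is skipped and
  counted.
* Empty inputs degrade gracefully: an empty tblout yields an empty locus
  table with a warning; an empty readset yields all-zero coverage and a
  `low_coverage` verdict; a locus with no peaks in the region of interest
  is reported as `no_candidate_peaks`.

## Validation scale

The packaged validation (test suite and `scripts/acceptance.R`) uses 20
seeded end-to-end runs of the standard two-condition experiment for
terminator recovery (expecting the programmed locus significant with the
cluster centroid within ±0.05 relative units of the truth in at least 95%
of runs), 20 constant-read-through runs for specificity (no significant
locus in at least 95%), a 10,000-peak null calibration of the pseudo
p-value, property suites of 1,000 random instances each for the coverage
partition and peak-detection rules, and exact Mann–Whitney enumeration up
to total sample size 10. These sizes give tight binomial error on the
rates while keeping a full validation run in the minutes range on one
CPU.

## Known limitations

* Paired-end data only; single-end termini lose half the pairing signal
  the method depends on.
* Absence of evidence is not evidence of another mechanism: a dataset
  whose conditions never evoke the OFF (or ON) state cannot show
  condition dependence, and will typically fail the mean or variance
  test.
* The noise model assumes enough comparator peaks near the locus; very
  clean, deep loci with few noise peaks can fail with
  `insufficient_noise_set`.
* Raw per-step significance thresholds, as published; no FDR control.
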