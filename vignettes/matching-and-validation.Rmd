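---
title: "Proximity matching of array probes and CNV callset validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity matching of array probes and CNV callset validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermatch)
```

## The problem

CNV calling from SNP arrays consumes per-probe intensity summaries (log-R
ratio, B-allele frequency) that are tied to the physical probes of one array
product. Cohorts genotyped on different products cannot be pooled the way
genotype data can, because intensity signals cannot be imputed. The standard
workaround — calling CNVs only on the consensus probes present on every
array — throws away most of the denser array whenever products diverge,
degrading resolution and sensitivity.

The premise of proximity matching is that two probes a few kilobases apart
almost always interrogate the same copy-number state, since the CNVs worth
calling on arrays span tens of kilobases to megabases. Pairing each probe of
the sparser array with a *nearby* probe of the denser one (rather than an
identically positioned one) retains nearly all of the sparse array's
footprint while keeping a strict 1:1 correspondence that downstream callers
require.

## The matching procedure

`run_markermatch()` orients the two manifests (the smaller becomes the
*reference*, ties broken by label), then:

1. **Exact stage.** The positional intersection on (chromosome, position).
   Co-located probes (arrays do carry multiple assays at one coordinate) are
   resolved per reference probe, visited in name order: an identically named
   candidate is preferred, otherwise the lexicographically smallest
   remaining name. Each matching probe is consumed at most once. The exact
   stage is invariant to `d_max` and `method`.
2. **Nearby stage.** Remaining reference probes are visited in ascending
   (chromosome, position, name) order. The candidate set for a probe is
   every unconsumed matching-manifest probe on the same chromosome within
   `d_max` bp — the bound is *inclusive*. The candidate minimizing the
   method metric's absolute difference is selected and consumed.

Greedy output depends on iteration order, which prior descriptions of this
style of algorithm leave unstated; we pin ascending genomic order because it
is deterministic, matches the loop's natural description, and makes runs
reproducible to the byte. Ties in the metric are broken by smaller genomic
distance, then smaller candidate name — again purely for determinism.
Candidates missing the annotation a BAF/LRR method needs are skipped rather
than treated as difference zero (a missing value is not evidence of
similarity); a reference probe missing that annotation is left unmatched.
Both skip counts are reported.

The exact stage keys on coordinates rather than names by default because
probe names for the same locus differ across products; a name-keyed mode
exists for same-product comparisons. The packaged implementation searches
candidates through a windowed scan over per-chromosome sorted positions
(binary search for the window ends), making genome-scale runs a matter of
minutes; the test suite holds a deliberately naive full-rescan
implementation against which the optimized matcher must be byte-identical
on randomized instances, co-located loci and missing annotations included.

## Parameters

* `d_max` (bp, default grid 10 bp – 5 Mb in 12 log-spaced steps): the
  maximum allowable distance. Too small reverts to the consensus
  intersection; too large pairs probes across unrelated neighbourhoods.
  Because probe spacing on dense arrays is of order 1 kb and arrays are
  designed around CNVs ≥ tens of kb, coverage typically saturates in the
  1–100 kb range; `select_dmax()` formalizes the choice (below).
* `method` (`distance`, `baf`, `lrr_mean`, `lrr_sd`): the metric minimized
  among candidates. `distance` (the "position" method; both spellings are
  accepted) is the geometric choice; the intensity-annotation methods
  prefer candidates whose signal distributions resemble the reference
  probe's, at the cost of requiring those annotations to be present.

## Callset validation

`classify_calls()` builds a *partial* confusion matrix: TP and FP are
counted on the test side (a test call is TP when some truth call from the
same sample, of the same type, overlaps it), FN on the truth side
(uncovered truth calls). True negatives are deliberately absent — without
the true copy-number state of every genomic segment, TN is undefined.
Consequences: `tp + fp` equals the number of test calls exactly, and
many-to-one overlaps are allowed on both sides. FN is counted per truth
call, not per base pair.

The default overlap criterion is ≥ 1 bp of shared sequence in 1-based
inclusive coordinates, with `min_fraction` available to demand that a
single truth call cover a given fraction of the test call; the criterion
is configurable because published evaluations vary in how much reciprocal
overlap they require, and raising `min_fraction` can only reduce TP.

From TP/FP/FN the seven metrics follow their defining formulas:
sensitivity $tp/(tp+fn)$, FNR, PPV $tp/(tp+fp)$, FDR, F1 (harmonic mean of
PPV and sensitivity), FMI (their geometric mean), JI $tp/(tp+fp+fn)$. A
zero denominator yields a missing value, never 0 — a stratum with no
duplications has no duplication PPV. The identities $f1 = 2\,ji/(1+ji)$
and $fmi \ge f1 \ge ji$ are enforced by property tests.

QC tiers bundle call-level minima (SNP support, length, confidence;
boundary-inclusive) with per-sample caps (LRR sd, BAF drift, waviness
factor, call count); a failing sample loses all calls. The shipped `low`
(≥ 10 SNPs, ≥ 20 kb) and `medium` (additionally confidence ≥ 10 and sample
caps at PennCNV-conventional working values: LRR sd ≤ 0.30, BAF drift
≤ 0.01, WF ≤ 0.05, ≤ 100 calls) presets are provisional defaults — the
machinery, not the constants, is the contract; calibrate tiers to your
cohort.

Size strata are half-open $[lo, hi)$ bins (`<100kb`, `100kb–500kb`,
`500kb–1Mb`, `≥1Mb`): labels like "CNV < 100 kb" are strict on both sides
and leave the boundary unassigned, so we pin a boundary length of exactly
100 kb to the upper bin. Region strata (telomeric, centromeric, segmental
duplications, or any BED track; 0-based half-open on disk, converted on
load) filter *both* callsets to region-overlapping calls before
classification.

## Parameter-selection curves

`build_metric_curves()` smooths each metric across the `d_max` grid by
local regression on the $\log_{10}(d_{max})$ axis (loess, degree 2, span
0.75 — wide enough to average over a 12-point grid without flattening a
plateau), then scales against the same metric of a full-manifest reference
callset. Scaling is a ratio (`metric / full-set metric`); the scaling
function is pluggable since a difference or normalized difference are
equally defensible conventions. `select_dmax()` replaces visual inspection
with a plateau-onset rule: the smallest grid `d_max` within 5% (default)
of the curve maximum. With fewer than four grid points smoothing is
skipped with a warning.

## What the simulators emulate — and what they do not

`simulate_array_pair()` reproduces, at 1:100 scale, the geometry that makes
proximity matching worthwhile: a 6,000-probe reference vs a ~24,000-probe
matching array on a 24 Mb genome (so probe spacings of ~4 kb and ~1 kb),
19% exact positional overlap, and jittered counterparts (sd 3 kb) for the
rest, plus independent extras. Annotation distributions are chosen to look
like real products — BAF from a mixture of point masses near 0/1 and a
Beta(2, 2) bulk so BAF matching has variation to exploit; LRR mean
Normal(−0.002, 0.002); LRR sd log-Normal with median 0.10. Counterparts
never collide with an existing position, so the intended correspondence is
unambiguous and the exact stage recovers precisely the shared fraction.

`simulate_callset_pair()` draws truth calls per sample (Poisson count,
default mean 10 over 500 samples ≈ 5,000 truth calls; log-uniform sizes
10 kb–2 Mb; 40% duplications; non-overlapping within a sample), detects
each with probability 0.80, jitters detected boundaries (sd 500 bp, clamped
so a detected call still overlaps its source and nothing else), and adds
Poisson false positives (mean 8/9 per sample, placed off-truth) so the
expected test-set PPV is 0.90. The generator returns its own TP/FP/FN
bookkeeping, which classification must reproduce exactly under the default
rule.

What passing these tests shows: the matcher implements its stated greedy
semantics exactly; the validation arithmetic is correct; coverage and gap
behaviour respond to `d_max` in the direction the method claims. What they
do not show: performance on real cohorts. The simulators draw probe
positions uniformly (real arrays cluster probes in genic regions), make
annotations independent of position, and contain no intensity signal, no
HMM caller, no wave artifacts, and no array-specific batch effects. Batch
effects in particular are only mitigated, not removed, by probe
harmonization.

## Numerical and interface conventions

* Chromosomes: 1–22, X, Y, MT in that order; `chr` prefixes stripped;
  other contigs dropped with a count. All name sorts are byte-order
  (radix), independent of locale.
* Coordinates: probes and CNV calls are 1-based inclusive
  (`length = end − start + 1`); BED input is converted on load.
* Quantiles: linear interpolation (R type 7), pinned so gap/BAF/LRR
  summaries are reproducible.
* Missing annotations are `NA`, never 0 — 0 is a legal BAF.
* rawcnv I/O: copy number 2 is rejected (not a CNV), copy numbers above 4
  are rejected with a warning (the caller's state model tops out at 4);
  malformed lines are collected with line numbers rather than aborting the
  parse. Write-then-parse reproduces a callset field-for-field.
* Problem sizes in the shipped tests — matcher oracle instances up to
  300 × 600 probes, 1,000 randomized invariant cases, 10,000 random
  confusion triples, one 6,000 × 24,000 manifest pair and one ~5,000-call
  recovery study — were chosen so the full suite exercises every code path
  in about a minute and a half on a single core.

## Known limitations

Greedy 1:1 matching is order-dependent by construction; a different
iteration order can change contested assignments (the Hungarian algorithm
would optimize globally, but the sequential-greedy loop *is* the method).
Orientation always makes the smaller manifest the reference; an override
exists (`orient = FALSE`) for deliberate reversals. The validation
framework evaluates callsets as given: it does not merge adjacent calls,
deduplicate overlapping calls within a set, or correct for genomic waves,
and beta-regression modelling of metric response to QC cutoffs is left to
general-purpose regression packages.
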