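---
title: "Models and methods behind triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

`triomics` integrates three sequencing-derived views of a two-group
cell-line panel — mRNA abundance, CpG-island methylation and DNA copy
number — into per-gene records and gene signatures.  This vignette
explains each model, its assumptions, the tunable parameters, and the
reasoning behind the numerical choices that were genuinely open.

## The expression layer

### Normalization and filtering

Counts are mapped to `log2(((c + 1) / T) * 1e6)`.  The +1 pseudocount
keeps zero counts finite and, at a library of one million reads, maps
a zero count to exactly log2 RPM = 0.  The denominator `T` is the
per-sample sum of counts over annotated genes; total mapped reads may
differ from this sum in real data, so an externally supplied total can
be passed to `normalize_rpm()`.  The abundance filter keeps a gene
only if at least one group combines a mean raw count above 50 (about
1 RPM at these depths, the point below which the mean–variance
relation makes quantification unreliable) with at least 5 raw counts
in *every* sample of that same group; genes with zero counts
everywhere are removed first and audited separately.

### The moderated t

With `d = n1 + n2 - 2` residual df, each gene's pooled variance `s²`
follows, under normality, a scaled chi-square around the true
variance.  Assuming the true variances follow a scaled inverse
chi-square prior with parameters `(d0, s0²)`, the marginal
distribution of `log s²` has closed-form mean and variance, and
matching the observed mean and variance of `log s²` yields `d0` (by
inverting the trigamma function with Newton steps) and `s0²`.  The
posterior variance `s̃² = (d0 s0² + d s²)/(d0 + d)` then replaces `s²`
in the t statistic, referred to a t distribution on `d + d0` df
(capped at the pooled residual df across genes — at `d0 = ∞` this is
indistinguishable from the normal reference).  Two boundary cases are
handled explicitly: when the spread of `log s²` does not exceed
chi-square sampling variation the prior absorbs all weight
(`d0 = ∞`, `s0² = mean(s²)`), which makes the moderated t collapse to
the ordinary t exactly when all genes share one variance; and genes
with zero `s²` are offset to `1e-5` times the median before fitting.
The test suite verifies the whole path against an independent
implementation of the same empirical-Bayes method (limma) to 1e-8.

### Storey q-values

`pi0`, the null proportion, is estimated from the p-value tail on the
grid `lambda = 0.05 … 0.95` with a df-3 smoothing spline evaluated at
the largest `lambda`, clamped to (0, 1].  Below 20 tests the grid is
meaningless and `pi0 = 1` is used (the conservative Benjamini–Hochberg
limit).  Sorted p-values are then converted by the step-down rule
`q(i) = min over j >= i of pi0 * m * p(j) / j`, which guarantees
monotonicity and `q <= 1`.

### Cluster stability (R and D indices)

Samples are clustered with distance `1 - Pearson` on whole profiles
and average linkage.  To ask whether a k-cluster cut is an artifact of
small n, Gaussian noise with variance equal to the *median per-gene
across-sample variance* (one global value, not per gene) is added to
every cell and the samples re-clustered; over 100 iterations the R
index is the mean proportion of originally co-clustered pairs that
stay together, and the D index the mean number of pairs whose
co-membership flips.  A perfectly stable cut gives R = 1, D = 0.  The
perturbation re-uses the same matrix that produced the original cut —
whether the original analysis re-filtered between iterations is
unknowable, and re-using the matrix is the only choice that makes
"re-clustering the same data" well defined.

## The methylation layer

### Fragment universe and 3-letter alignment

MspI cuts C^CGG, so every fragment boundary is one base into a CCGG
motif and every fragment starts with CGG and ends with C.  Real
libraries gel-select inserts; the two gel cuts reported for this
protocol (150–175 and 175–225 bp including adaptors) imply unknown
insert sizes, so the adaptor allowance is a parameter: the default
windows 30–55 and 55–105 bp correspond to a 120 bp total adaptor
footprint and can be changed in `digest_reference()`.  Each retained
fragment contributes two read templates of at most 50 nt, one per
strand, anchored at the MspI ends (shorter when the next site is
closer than 50 nt).

Bisulfite converts unmethylated C to T, so alignment happens in a
reduced alphabet: forward templates have C replaced by T, reverse
templates G replaced by A (the plus-strand image of C→T on the minus
strand), and reads have all Cs replaced by T.  Reverse-strand reads
are emitted as sequenced (reverse-complemented); the index therefore
keys reverse templates by the reverse complement of their G→A form,
which equals the C→T form of the minus-strand read.  Up to 2
mismatches are tolerated, found via three 16-mer seed blocks (with at
most 2 mismatches at least one block is intact).  Reads compatible
with more than one fragment, or matching templates whose converted
sequences collide, are discarded as multi-mapping; the audit preserves
read conservation (aligned + multi-mapped + unaligned = input).

### Site calls and island summaries

Placements are re-expanded to the original bases: at each CpG cytosine
the read base contributes C (methylated) or T (converted) — G/A for
minus-strand cytosines — and anything else is audited.  The site ratio
is C/(C+T).  An island's percent methylation in a sample is 100 times
the unweighted mean ratio over sites with coverage ≥ 10 (weighting by
coverage is a defensible alternative; unweighted matches "averaging
all CpG sites").  The default keeps an island if it has at least one
qualifying site in every sample; `strict = TRUE` additionally demands
every covered site reach 10×, mirroring the stricter phrasing used
when the filter is described at the island level.  Differential
methylation reuses the moderated t on the percent matrix; at 50×
target coverage the end-to-end pipeline recovers planted island levels
with a mean absolute error well under 5 percentage points, the error
being binomial counting noise.

### Island–gene association

An island is associated with every gene whose TSS (the 5' end of the
longest annotated transcript) lies within 5 kb of the island start;
distance is reported unsigned, with the signed offset retained.  Many-
to-many associations are kept — a single island can serve two
head-to-head promoters.

## The copy-number layer

Tag starts are counted in fixed half-open windows.
`choose_window_size()` picks the width so the expected reference count
per window is ≥ 30 tags, since the ratio noise (≈ `sqrt(2/N)/ln 2` at
N tags per window) must sit well below the one-copy signal.  Ratios
are `log2(t + 0.5) − log2(r + 0.5)` (the 0.5 offset handles empty
windows), centred by the per-chromosome median and then the global
median.  This normalization assumes most of each chromosome is
copy-neutral; when a large fraction of a chromosome is aberrant in one
direction the median itself shifts and segment means are biased toward
zero — the recovery simulations therefore plant events on about 10% of
the chromosome, and users with highly aneuploid genomes should prefer
longer chromosomes or an external baseline.

### Segmentation

Segmentation is a recursive t-test splitter parameterized by the
printed values: split acceptance p < 1e-4, minimum 10 windows per
segment, minimum change 0.3 pooled SDs.  The candidate generator scans
*two* breakpoints jointly — every sub-interval against its complement
— rather than one: a single-breakpoint scan must first cut through the
middle of an interior event, diluting the contrast with flanking
background and (at one-copy signal-to-noise) pushing the best split
past the 1e-4 threshold, so interior events of 30 windows in 100 are
systematically missed.  The interval-vs-complement scan tests the
event against its full background directly.  After recursion, adjacent
segments whose difference no longer meets the same split criteria are
re-merged (making the output order-independent), and each boundary is
re-scanned locally for the position maximizing the between-segment t,
which removes most of the few-window localization jitter of the greedy
scan.  Planted one- and two-copy events spanning 30 windows are
recovered with breakpoints within ±2 windows and classified correctly
in ≥ 95% of simulations at ~50 tags/window.

### Classification

The one-copy thresholds are −1 = log2(1/2) and 0.59 ≈ log2(3/2).  A
true one-copy event sits *exactly at* its threshold, so a test that
demands the segment mean be significantly beyond the threshold can
never call a clean one-copy event (its power is at most ~50% there).
`classify_segments()` therefore calls a segment amplified when two
one-sided t-tests at p < 1e-4 agree that it is (i) significantly
above zero and (ii) *not* significantly below the one-copy threshold
— i.e. the segment is changed, and its mean is statistically
consistent with at least a one-copy gain.  Deletions mirror this
against −1.  A segment at +0.3 with tight error is significantly
changed but rejected by the threshold-consistency test, hence neutral;
a flat segment fails the change test.  Both printed constants and the
printed test level are used unchanged.

### Recurrent regions and gene values

Within a sample, genomically adjacent same-class segments are merged.
Across samples, all aberration breakpoints induce atomic intervals; an
atom supported by ≥ 2 samples in the same direction is kept, and
adjacent atoms with identical support merge into maximal recurrent
regions (the test suite checks this against a brute-force per-position
oracle).  A gene overlapping a region is assigned to it (flagged
partial if it straddles a boundary), and its per-sample copy value is
the containing merged segment's mean log2 ratio, or 0 where that
sample is neutral — so group means over these values are directly
comparable across genes.

## Integration and signatures

Records join one gene to each associated island.  A record is
*inverse* when the gene passes the expression cut (p < 0.05 and linear
fold change > 1.5), the island is differentially methylated
(p < 0.05), and the methylation difference opposes the fold change in
sign.  Sign concordance is also the outlier rule: among
doubly-significant genes, those whose methylation moves *with*
expression are flagged as outliers (a robust-regression residual rule
is available behind `method = "residual"`); sign concordance is the
only per-gene criterion under which "inversely correlated" is well
defined, and a zero methylation difference is ambiguous rather than an
outlier.  The methylation signature partitions the inverse set by
direction; a gene with several islands is signature-flagged if any
qualifying island satisfies the rule.  The CNA signature demands
consistency: a differentially expressed gene qualifies only if its
region is aberrant in *every* sample of one group and neutral in
*every* sample of the other.

The inverse relationship is summarized by Pearson r between log2 fold
change and mean methylation difference, with the two-sided t-test
against zero and a Fisher-z 95% interval; distance structure is
reported as the median island-to-TSS distance, 250 bp histogram bins
over 0–5 kb, and the Spearman trend between distance and |log2FC|.

## Enrichment

Gene ranking uses the signal-to-noise statistic
`(m1 − m2)/(sd1' + sd2')` with each class SD floored at `0.2·|mean|`
(0.2 when the mean is zero); an ordinary-t ranking is available.  The
enrichment score is the weighted Kolmogorov–Smirnov running sum
(weight exponent 1 by default; 0 recovers the classic KS statistic,
verified against exhaustive enumeration).  The null is phenotype
permutation: group labels are reassigned, genes re-ranked, and ES
recomputed; when the requested permutation count reaches the number of
distinct label assignments the null is enumerated exhaustively.  NES
divides ES by the mean same-sign null |ES|; the nominal p is the
same-sign tail; FDR q compares each NES to the pooled null NES
distribution across sets, normalized by the observed NES distribution.
Set sizes are bounded to 15–500 after intersection with the expression
universe.  Over-representation of a focus list in a pathway is the
upper-tail hypergeometric probability via `phyper`.

## The synthetic-data module

The generator is the package's study-condition bed, not a tuning
surface.  It emulates:

* a toy genome (default for pipeline runs: one 200 kb chromosome, 20
  islands, 40 genes; the generator itself defaults to 1 Mb) in which
  every island is a run of 3–6 MspI fragments of 36–100 bp with CpGs
  planted every ~8 bp, so islands are MspI-bounded and size-selectable
  by construction; background sequence is uniform random, providing
  decoy CCGG fragments and background CpGs;
* promoter proximity: 80% of islands (configurable) sit within 5 kb of
  a TSS with exponentially distributed offsets (median a few hundred
  bp), matching the promoter-proximal concentration of regulatory
  islands;
* expression: negative-binomial counts (dispersion 0.05, log-normal
  baselines, library-size factors 0.8–1.2×) with a planted DE fraction
  of 0.15 and |log2FC| in 1–4, split symmetrically between groups;
* methylation: islands default to 10% methylated (CpG islands are
  mostly unmethylated), non-island CpGs to 75% (genomic background is
  mostly methylated); for 90% of island-linked DE genes the island is
  raised to 85% in the group where the gene is silenced, giving the
  planted inverse coupling with a ≥ 40-point difference;
* copy number: one region amplified (ratio 2) in every group-1 sample
  and one deleted (ratio 0.5) in every group-2 sample, plus 2 private
  aberrations per sample; genes in the consistent regions receive a
  dosage expression shift of `log2(ratio)`;
* bisulfite chemistry: CpG cytosines survive conversion with
  probability equal to the local methylation level; all other
  cytosines convert with efficiency 1.0 by default (the protocol's
  extended ~14 h conversion justifies treating conversion as
  complete), with the efficiency and a flat substitution-error rate
  exposed as parameters.

Every generator is a pure function of (configuration, seed); the
pipeline derives per-stage seeds deterministically from one master
seed, so whole runs are byte-reproducible.  What the synthetic data do
*not* model: sequence-composition biases (GC, mappability), PCR
duplicates, non-CpG methylation, allele-specific copy number, and the
correlated biological variability of real cell lines.  Passing tests
demonstrate that the statistics recover what they are defined to
recover under the stated noise models — not that real libraries meet
those models.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately small instances — 100 kb–1 Mb
toy genomes, 5,000-gene null simulations, 200-replicate segmentation
sweeps, 100–150 permutations per GSEA null draw — chosen so the full
suite exercises every stage in a couple of minutes on one CPU while
keeping each statistical check's Monte-Carlo error well inside its
assertion margin.  Ties in hierarchical clustering are resolved by
`hclust`'s deterministic ordering of the input; equal-height merges are
measure-zero for continuous data.  The trigamma inversion starts at
`0.5 + 1/x` and converges in a handful of Newton steps; breakpoints in
the segmenter resolve ties by the first minimal p-value.  Degenerate
inputs fail loudly and early: zero library totals, constant sample
profiles, empty p-value vectors, empty MspI libraries, non-positive
depths and dispersions all raise errors naming the offending sample or
parameter.

## Known limitations

* The fragment-anchored aligner is not a general bisulfite aligner: it
  places reads only at MspI fragment ends (exactly the reduced
  representation), tolerates ≤ 2 mismatches, and has no indel model.
* The copy-number layer assumes a mostly-neutral genome per chromosome
  (median normalization) and an explicit diploid-like reference
  sample.
* The CNA signature's all-samples consistency rule is conservative by
  design; relaxing it to "k of n samples" is a one-line change in
  `build_signatures()` but is not the documented behavior.
* GSEA supports phenotype permutation only; gene-set permutation (the
  small-n fallback) is out of scope.
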