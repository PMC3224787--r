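---
title: "Methods and design of segexplore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of segexplore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`segexplore` summarizes labeled genomic segmentations and relates them to
annotations, gene models, sequence and signal. This vignette explains the
statistics it computes, the assumptions behind them, the parameters that
matter, what the synthetic data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable convention
exists.

## Data model

A *segmentation* is a set of non-overlapping labeled intervals; an
*annotation* permits overlap and uses its name column as an optional
grouping variable. Both are held as `GRanges` (1-based, closed intervals,
the Bioconductor convention); BED's 0-based half-open coordinates are
converted on read and reconverted on write, GFF/GTF coordinates pass
through. Localizing the conversion to the I/O layer keeps every internal
length, gap and distance computation in a single convention. Chromosome
names are matched as exact strings — no `chr` aliasing — because silent
aliasing hides input mistakes; when two inputs mention disjoint chromosome
sets a warning lists the chromosomes seen on only one side.

Zero-length records (BED `start == end`) are rejected: they carry no bases
and would poison per-base statistics. Strand `.`/`*` is accepted anywhere
and treated as `+` where orientation matters (aggregation axes), with a
warning, since BED strand is optional.

Signal tracks are per-base numeric vectors, run-length encoded per
chromosome, with `NA` marking bases the source bedGraph/wiggle does not
cover. This keeps "no data" distinct from "value 0" throughout.

## Length, transition and composition summaries

`lengthDistribution()` is exact over all segments; the per-label fractions
of segments and of covered bases each sum to 1 by construction. On a
segmentation whose segments all share one fixed length the two fraction
columns coincide exactly — a useful sanity property that the test suite
checks on uniform 200 bp fixtures.

`transitionMatrix()` counts, per chromosome and in coordinate order, every
ordered pair of consecutive segments, regardless of the unlabeled gap
between them: "immediately following" is read at segment granularity.
Because segmentations need not tile the genome, both readings of adjacency
are defensible; the `maxGap` argument (default unlimited) restricts
counting to pairs separated by at most that many uncovered bases, exposing
the stricter interpretation. Frequencies are row-conditional, so each row
with at least one outgoing transition is a probability distribution. The
DOT graph writer includes an edge only when its frequency reaches
`minFreq`, which keeps dense matrices legible.

`nucleotideFrequency()` pools counts over all segments of a label. A
segment of length L contributes L mononucleotide and L−1 dinucleotide
positions; windows never span the boundary between segments, because the
frequencies are meant to describe segment interiors. Positions holding
bases outside ACGT are excluded from numerator and denominator alike, so an
all-ambiguous label reports missing (`NA`) frequencies rather than NaNs.
Counting is on the plus strand without reverse-complement collapsing.
Soft-masked lowercase bases count as their uppercase equivalents by
default; `maskLower = TRUE` treats them as ambiguous, since masking
conventions vary between genome builds. Pooled counts are the default
because they weight every base equally; `perSegmentMean = TRUE` instead
averages each segment's own frequency vector, which differs when segment
lengths vary — both are offered because either could be meant by a "mean
frequency across segments".

## Aggregation enrichment

All three aggregation modes reduce to the same statistic. For label ℓ at
axis position x,

> e(ℓ, x) = log2((f_obs(ℓ, x) + 1) / (f_rand(ℓ) + 1)),

where `f_obs` is the fraction of contributing anchors (or bases) at x that
carry ℓ and `f_rand` is ℓ's *relative abundance*: its covered bases divided
by all bases covered by the segmentation — not by genome size. Abundance
among labeled bases is the natural reading of "expected at random given the
relative abundance of each label", and it makes `e` sum-comparable across
segmentations of different genome coverage. The +1 offsets bound the
statistic (e ∈ [log2(1/(f_rand+1)), log2(2/(f_rand+1))]) and keep it defined
when `f_obs = 0`.

Bases at an offset that no segment covers stay in the denominator but count
toward no label, so per-offset frequencies may sum to less than 1; this
reflects that a segmentation is not obliged to explain every base. The
`coveredOnly` switch restricts denominators to covered bases for users who
prefer conditional frequencies.

*Point mode* anchors at the midpoint base of each feature and uses
single-base offsets `-flank..flank` (default flank 5000, matching the
granularity at which TSS profiles are usually drawn). Minus-strand features
have their axis reversed so positive offsets are always downstream in
transcription direction. Offsets that fall off a chromosome end are dropped
from that offset's denominator only.

*Region mode* linearly rescales each region onto a fixed axis: the base at
fractional position p contributes to bin `floor(p * bins)`. With
`flank > 0` ideal flank windows are added as separate components and binned
the same way, with out-of-chromosome bases dropped per base (the axis
mapping is kept from the ideal window so clipping does not distort bins).

*Gene mode* decomposes each gene into eight idealized components — 5′
flank; initial, internal and terminal exons and introns; 3′ flank — pooling
every instance of a component across genes after rescaling each instance to
`bins` bins (default 50 per component, uniform; mean component lengths are
a property of the input, not of the axis). Rules for degenerate structures,
chosen to avoid double counting: a 2-exon gene's single intron is the
initial intron only; a single-exon gene's exon is the initial exon only.
Multi-transcript genes use the longest transcript by exonic bases, ties
broken by leftmost start, so each gene contributes one deterministic
idealized structure. Gene-mode profiles are invariant under mirroring the
fixture's coordinates and strands, which the test suite verifies.

## Overlap, edit distance, signal distribution

`segmentationOverlap()` counts, per (label, group): overlap bases (computed
against the group's *merged* coverage, so bases doubly covered within a
group count once), segments of the label overlapping at least one group
record by `minOverlap` bases (default 1), and group records overlapped.
Recall(ℓ, g) is the fraction of g's records overlapped by ℓ. Precision is
computed, by default, among the segments of ℓ that overlap *any* record of
the annotation: when groups are e.g. active/inactive TSSs, this asks "given
that a segment sits on a TSS, how often is that TSS active", which is the
predictive question such group structures encode. The
`precisionDenominator = "label"` flag switches to all segments of ℓ.

`compareSegmentations()` defines the edit distance between label x of one
segmentation and label y of another as the number of bases in the symmetric
difference of their covered base sets, with the Jaccard similarity reported
alongside. This is a declared interpretation — a base-set metric with the
triangle inequality — rather than a claim about any other tool's internal
definition.

`signalDistribution()` pools every data-bearing base covered by a label and
reports mean and variance. Variance is the population variance (divide by
n): the bases are a complete enumeration of the label's coverage, not a
sample; `sampleVariance = TRUE` divides by n−1. Numerically the moments are
accumulated over run-length encoded runs in two passes (weighted mean
first, then centered second moment), which is robust against cancellation
at any fixture scale. Cells where a label covers no data-bearing base are
flagged missing (`NA`) with a warning, never silently zero. For display,
each track's row of means is rescaled to [0, 1] (a constant row maps to
0.5, the uninformative midpoint), standard deviations are expressed
relative to the largest SD over all cells, and rows and columns are ordered
by average-linkage hierarchical clustering on Euclidean distances of the
normalized rows — `stats::hclust` is deterministic for fixed input, which
the tests rely on.

## Flattening and distances

`flattenSegmentations()` assigns every base the subset of inputs covering
it and emits maximal runs of constant subset as segments, labeled by the
sorted input names joined with `-` (input names may not contain the
separator, so labels parse back unambiguously). Coverage within one input
is a set — overlapping records count once. Bases covered by no input emit
no segment: the output describes what the inputs assert, and gap segments
would only restate the complement. Total output bases therefore equal the
union coverage of the inputs, a conservation law the tests check against an
independent per-base scan.

`featureDistance()` reports 0 when a segment intersects a feature and
otherwise the signed gap (negative = nearest feature upstream of the
segment start, positive = downstream), with ties broken by leftmost feature
start then lexicographic name for determinism. An abutting feature has gap
0; distances of zero therefore mean "touching or overlapping". Segments on
chromosomes without features report `NA`.

`preprocess()`/`loadPreprocessed()` wrap a versioned binary container
(magic string + version + serialized object) so repeated analyses skip text
parsing; no cross-version compatibility is promised, and a wrong magic or
version raises an explicit mismatch error.

## Synthetic data generator

The generators exist so that every operation is testable with known ground
truth and no downloads. `makeGenome()` draws i.i.d. bases at a requested GC
fraction. `makeSegmentation()` alternates geometric gaps and segments so
realized coverage converges to the request; labels are uniform i.i.d. or a
first-order Markov chain with a supplied transition matrix, restarted
uniformly on each chromosome — exactly matching how transitions are counted,
so the supplied matrix is the estimand. `makeGenes()` places
non-overlapping single-transcript genes with geometric exon/intron lengths
on random strands. `makeSignal()` emits per-label planted means plus
Gaussian noise over covered bases. All generators are bit-reproducible from
one integer seed; `makeFixtureSet()` derives sub-stream seeds from a single
master seed.

What the fixtures do *not* emulate: repeat structure, isochores, GC skew,
autocorrelated signal, length distributions with heavy tails, overlapping
isoforms, or biologically structured label placement. Passing tests
therefore demonstrate correctness of the computations — counting, binning,
set algebra, estimator recovery — not robustness to every pathology of real
genomes; conclusions about real data still require looking at real data.

## Test and verification scale

The suite checks every interval operation against independent per-base
brute-force recomputation (plain R vectors, no interval machinery) on
twenty seed-pinned random fixtures of roughly 10–15 kb over two
chromosomes, exact for integer counts and to 1e-9 for frequencies; Markov
transition recovery uses a ~1.2 Mb, ~10,000-segment fixture (max per-cell
error observed well under 0.01 against a ±0.03 bound implied by multinomial
sampling error); planted signal means are recovered exactly without noise
and within three standard errors at unit noise. These sizes give tight
statistical bounds while keeping the whole suite fast enough to run
habitually.

## Known limitations

- No statistical hypothesis testing of enrichment or overlap — the
  statistics here are descriptive; R's testing ecosystem composes naturally
  downstream.
- No BigWig/BigBed or tabix support; signal must fit the bedGraph/wiggle
  text formats.
- Logical filtering beyond flattening (intersections, subtractions with
  predicates) is out of scope; dedicated interval toolkits do this better
  upstream.
- Gene mode trusts its GTF: unusual models (trans-splicing, overlapping
  exons within one transcript) are rejected or reduced to the
  representative transcript.
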