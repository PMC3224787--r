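# segexplore

Exploratory analysis of genomic segmentations in R.

Many functional-genomics experiments partition a genome into labeled
segments: chromatin-state calls, ChIP-seq peak combinations, gene-expression
classes tiled around TSSs. A **segmentation** is a set of non-overlapping
intervals, each carrying one label from a small vocabulary; an
**annotation** relaxes this so records may overlap (transcripts, peaks) and
carry an optional group name. `segexplore` summarizes segmentations and
relates them to annotations, gene models, genome sequence and continuous
signal tracks, then collates everything into tab-delimited tables, plots and
a single HTML report.

The toolkit covers:

- **length-distribution** — per-label segment counts, lengths, and the
  fraction of segments and of covered bases per label;
- **nucleotide-frequency** — per-label mono- and dinucleotide composition
  from a FASTA genome;
- **transition** — the matrix `freq(row follows column)` over consecutive
  segments, plus a Graphviz DOT transition graph;
- **aggregation** — label enrichment around point features (e.g. TSSs),
  across rescaled regions, or along the eight idealized gene components
  (5′ flank; initial, internal, terminal exons and introns; 3′ flank). The
  enrichment at offset *x* for label *ℓ* is

  ```
  e(ℓ, x) = log2( (f_obs(ℓ, x) + 1) / (f_rand(ℓ) + 1) )
  ```

  where `f_obs` is the frequency at which ℓ is observed at that offset over
  all anchors and `f_rand` is ℓ's share of all segmentation-covered bases
  (its abundance at random);
- **overlap** — bases/segments of overlap per (label, group) with
  precision–recall per annotation group;
- **compare** — base-set edit distance (symmetric difference) and Jaccard
  similarity between the labels of two segmentations;
- **signal-distribution** — per-(track, label) signal mean and variance,
  with a row-normalized, hierarchically clustered heat map;
- **flatten** — combine several interval sets into one segmentation whose
  labels encode which inputs cover each base (`A`, `A-B`, `B`, ...);
- **feature-distance** — signed distance from every segment to its nearest
  feature;
- **preprocess** — binary caching of parsed interval sets;
- **html-report** — one page collating the outputs of any subset of
  commands;
- **fixtures** — seeded generators for synthetic genomes, segmentations,
  gene models, TSS sets and signal tracks with known ground truth.

Inputs: BED or GFF for segmentations and annotations (the name column is the
label / optional group), GTF for gene models, FASTA for sequence, bedGraph
or wiggle for signal. Coordinates are handled as `GRanges` internally; BED's
0-based half-open convention is converted at the I/O boundary.

## Worked example

Everything below is synthetic and self-contained — no downloads:

```r
library(segexplore)

fx  <- makeFixtureSet("fxdemo", chromSizes = c(chr1 = 30000L, chr2 = 20000L),
                      nLabels = 3, seed = 17, nGenes = 8)
seg <- readSegmentation(fx$segmentation)
seg
#> Segmentation: 224 segments, 3 labels on 2 chromosome(s)
#>   labels: L3, L1, L2

lengthDistribution(seg)@table
#>   label count bases min median mean max frac_segments frac_bases
#> 1    L3    73 12505   2    129  171 692         0.326      0.327
#> 2    L1    66 11714   1    144  177 615         0.295      0.306
#> 3    L2    85 14041   2    128  165 780         0.379      0.367
```

Each row summarizes one label: 73 `L3` segments cover 12,505 bases, i.e.
32.6% of all segments and 32.7% of all covered bases (both columns sum
to 1). The planted per-label signal means (0, 1, 2 for `L1`, `L2`, `L3` with
unit Gaussian noise) are recovered by `signalDistribution()`:

```r
tr <- readSignal(fx$signal)
signalDistribution(seg, tr)@stats
#>    track label     n    mean variance   sd
#> 1 signal    L3 12505 2.00226     1.00 1.00
#> 2 signal    L1 11714 0.00311     1.02 1.01
#> 3 signal    L2 14041 1.01123     1.02 1.01
```

Aggregation along idealized gene components reports, per component bin, the
observed label frequency against its background abundance:

```r
genes <- readGenes(fx$genes)
prof  <- aggregateGenes(seg, genes, bins = 10, flank = 400)
subset(prof@table, component == "initial exon" & label == "L1")[1:3, ]
#>    group    component bin label count n_features  f_obs f_rand enrichment
#> 41 genes initial exon   0    L1    22        183 0.1202  0.306     -0.222
#> 42 genes initial exon   1    L1    26        178 0.1461  0.306     -0.189
#> 43 genes initial exon   2    L1    26        179 0.1453  0.306     -0.190
```

Here `L1` occupies 12% of the bases in the first initial-exon bin versus a
30.6% background share, a log2 enrichment of −0.22 (depletion). Since these
random fixtures plant no exon preference, values hover near 0.

The same analyses run from a shell through the thin CLI wrapper
(`inst/scripts/segexplore`):

```sh
segexplore length-distribution seg.bed -o out/length
segexplore transition seg.bed --min-freq 0.3 -o out/trans
segexplore html-report out/length out/trans -o out
```

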