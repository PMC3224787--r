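#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames granges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqnames<- seqlevels<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- Rle runValue runLength
NULL

## Central data containers. Coordinates are held as GRanges (1-based, closed);
## BED's 0-based half-open convention is converted at the I/O boundary.

#' Segmentation: non-overlapping labeled genomic intervals
#'
#' A segmentation partitions parts of a genome into segments, each carrying
#' exactly one label from a small vocabulary. Within each chromosome the
#' segments are sorted and pairwise non-overlapping. Construct one with
#' [Segmentation()] or read one from BED/GFF with [readSegmentation()].
#'
#' @slot ranges `GRanges` with a `label` character metadata column, sorted,
#'   non-overlapping within each chromosome.
#' @slot labels character vector: the ordered vocabulary of distinct labels.
#' @slot source provenance string (file path or construction note).
#' @export
setClass("Segmentation",
  representation(ranges = "GRanges", labels = "character", source = "character"))

#' Annotation: possibly-overlapping grouped genomic intervals
#'
#' The relaxed counterpart of a [Segmentation-class]: records may overlap
#' (transcripts, peaks, TSS windows). The BED/GFF name column, when present,
#' is an optional grouping variable; without it all records fall into a single
#' default group.
#'
#' @slot ranges `GRanges` with a `group` character metadata column, sorted
#'   within each chromosome (overlaps permitted).
#' @slot groups character vector: ordered distinct group names.
#' @slot source provenance string.
#' @export
setClass("Annotation",
  representation(ranges = "GRanges", groups = "character", source = "character"))

#' SignalTrack: per-base continuous values with missing data
#'
#' Continuous genomic signal (e.g. ChIP-seq intensity) materialized per base
#' as run-length encoded vectors; bases not covered by the source bedGraph or
#' wiggle file are `NA` (missing).
#'
#' @slot values `RleList`, one numeric Rle per chromosome; `NA` marks missing.
#' @slot name track name.
#' @export
setClass("SignalTrack",
  representation(values = "RleList", name = "character"))

#' GeneModel: exon structure of one gene
#'
#' One idealized transcript per gene (the longest by exonic bases, leftmost
#' start on ties), from which the aggregation machinery derives the idealized
#' components: 5' flank, initial/internal/terminal exons and introns, 3'
#' flank. See [geneComponents()].
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons `IRanges` of the representative transcript's exons, in left--
#'   to-right genomic order, non-overlapping.
#' @slot transcripts named list of `IRanges`, all transcripts of the gene.
#' @export
setClass("GeneModel",
  representation(geneId = "character", chrom = "character", strand = "character",
                 exons = "IRanges", transcripts = "list"))

#' AggregationProfile: label enrichment along an offset or bin axis
#'
#' Per label and per offset/bin: the observed label frequency `f_obs`, the
#' background frequency `f_rand` (the label's share of all segmentation-
#' covered bases), and the enrichment
#' `e = log2((f_obs + 1) / (f_rand + 1))`.
#'
#' @slot table data.frame with columns group, component, bin, label, count,
#'   n_features, f_obs, f_rand, enrichment.
#' @slot mode one of `"point"`, `"region"`, `"gene"`.
#' @slot labels label vocabulary of the segmentation aggregated.
#' @slot params list of the parameters used (flank, bins, ...).
#' @export
setClass("AggregationProfile",
  representation(table = "data.frame", mode = "character",
                 labels = "character", params = "list"))

#' LengthStats: per-label segment length distribution
#'
#' @slot table data.frame: label, count, bases, min, median, mean, max,
#'   frac_segments, frac_bases.
#' @slot lengths named list of integer vectors (segment lengths per label),
#'   kept for the violin plot.
#' @export
setClass("LengthStats",
  representation(table = "data.frame", lengths = "list"))

#' TransitionMatrix: label-to-label transition counts and frequencies
#'
#' `counts[from, to]` is the number of times label `to` immediately follows
#' label `from` along each chromosome; `freqs` is row-conditional, so every
#' row with a nonzero count sums to 1.
#'
#' @slot counts integer matrix, rows = preceding label, cols = following.
#' @slot freqs numeric matrix, row-normalized counts.
#' @slot labels label order of both dimensions.
#' @export
setClass("TransitionMatrix",
  representation(counts = "matrix", freqs = "matrix", labels = "character"))

#' NucFreqTable: per-label nucleotide and dinucleotide composition
#'
#' @slot mono numeric matrix labels x ACGT, frequencies (rows sum to 1 where
#'   any unambiguous base exists, else NA).
#' @slot di numeric matrix labels x 16 ordered dinucleotides.
#' @slot monoCounts,diCounts the underlying integer count matrices.
#' @slot ambiguous named integer vector: excluded ambiguous-base positions.
#' @export
setClass("NucFreqTable",
  representation(mono = "matrix", di = "matrix",
                 monoCounts = "matrix", diCounts = "matrix",
                 ambiguous = "integer"))

#' OverlapTable: segmentation-vs-annotation overlap with precision/recall
#'
#' @slot bases numeric matrix label x group: bases of overlap (bases doubly
#'   covered within a group count once).
#' @slot segmentHits integer matrix: segments of the label overlapping >= 1
#'   record of the group by at least `minOverlap` bases.
#' @slot recordHits integer matrix: records of the group overlapped by >= 1
#'   segment of the label.
#' @slot pr data.frame: label, group, precision, recall.
#' @slot labelTotals,groupTotals totals (segments per label, records and
#'   merged bases per group, bases per label).
#' @slot params list: mode, minOverlap, precision denominator choice.
#' @export
setClass("OverlapTable",
  representation(bases = "matrix", segmentHits = "matrix", recordHits = "matrix",
                 pr = "data.frame", labelTotals = "list", groupTotals = "list",
                 params = "list"))

#' EditDistanceMatrix: base-set distances between two segmentations' labels
#'
#' `distance[x, y]` is the number of bases in the symmetric difference of the
#' base sets covered by label `x` of the first segmentation and label `y` of
#' the second; `jaccard` is the Jaccard similarity of the same two sets.
#'
#' @slot distance numeric matrix labels1 x labels2.
#' @slot jaccard numeric matrix labels1 x labels2.
#' @slot labels1,labels2 label vocabularies of the two segmentations.
#' @export
setClass("EditDistanceMatrix",
  representation(distance = "matrix", jaccard = "matrix",
                 labels1 = "character", labels2 = "character"))

#' SignalStats: per-track, per-label signal mean and variance
#'
#' @slot stats data.frame: track, label, n, mean, variance, sd (NA where the
#'   label covers no data-bearing base).
#' @slot normalized numeric matrix track x label: row-normalized means in
#'   [0, 1] (constant rows map to 0.5).
#' @slot sdRel numeric matrix: standard deviation relative to the maximum SD
#'   over all cells, for the heat map's SD bars.
#' @slot rowOrder,colOrder integer orders from average-linkage hierarchical
#'   clustering of the row-normalized matrix.
#' @export
setClass("SignalStats",
  representation(stats = "data.frame", normalized = "matrix", sdRel = "matrix",
                 rowOrder = "integer", colOrder = "integer"))

## ---- validity -------------------------------------------------------------

setValidity("Segmentation", function(object) {
  gr <- object@ranges
  msg <- character()
  if (is.null(mcols(gr)$label))
    msg <- c(msg, "ranges must carry a 'label' metadata column")
  else {
    if (!all(mcols(gr)$label %in% object@labels))
      msg <- c(msg, "every interval label must be in the label vocabulary")
    bad <- .firstOverlapViolation(gr)
    if (!is.null(bad))
      msg <- c(msg, sprintf(
        "segments must not overlap: %s [%d, %d] overlaps [%d, %d]",
        bad$chrom, bad$s1, bad$e1, bad$s2, bad$e2))
  }
  if (anyDuplicated(object@labels))
    msg <- c(msg, "label vocabulary must be distinct")
  if (length(msg)) msg else TRUE
})

setValidity("Annotation", function(object) {
  gr <- object@ranges
  msg <- character()
  if (is.null(mcols(gr)$group))
    msg <- c(msg, "ranges must carry a 'group' metadata column")
  else if (!all(mcols(gr)$group %in% object@groups))
    msg <- c(msg, "every record group must be in the group vocabulary")
  if (anyDuplicated(object@groups))
    msg <- c(msg, "group vocabulary must be distinct")
  if (length(msg)) msg else TRUE
})

setValidity("GeneModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be in genomic order")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

## find the first sorted-adjacent overlapping pair, or NULL
.firstOverlapViolation <- function(gr) {
  if (length(gr) < 2L) return(NULL)
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  same <- as.character(seqnames(gr))[-length(gr)] ==
          as.character(seqnames(gr))[-1L]
  hit <- which(same & end(gr)[-length(gr)] >= start(gr)[-1L])
  if (!length(hit)) return(NULL)
  i <- hit[1L]
  list(chrom = as.character(seqnames(gr))[i],
       s1 = start(gr)[i], e1 = end(gr)[i],
       s2 = start(gr)[i + 1L], e2 = end(gr)[i + 1L])
}

## ---- constructors ---------------------------------------------------------

#' Construct a Segmentation from a GRanges
#'
#' @param ranges `GRanges` with a `label` metadata column (or `label` given).
#' @param label optional character vector of per-interval labels.
#' @param labels optional explicit label vocabulary (defaults to order of
#'   first appearance).
#' @param source provenance string.
#' @return A [Segmentation-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), c(50, 80)))
#' seg <- Segmentation(gr, label = c("A", "B"))
#' labelSet(seg)
#' @export
Segmentation <- function(ranges, label = NULL, labels = NULL,
                         source = "constructed") {
  if (!is.null(label)) mcols(ranges)$label <- as.character(label)
  mcols(ranges)$label <- as.character(mcols(ranges)$label)
  ranges <- .sortByChrom(ranges)
  if (is.null(labels)) labels <- unique(mcols(ranges)$label)
  new("Segmentation", ranges = ranges, labels = labels, source = source)
}

#' Construct an Annotation from a GRanges
#'
#' @param ranges `GRanges`, optionally with a `group` metadata column.
#' @param group optional character vector of per-record groups; records
#'   without a group fall into the default group `"all"`.
#' @param groups optional explicit group vocabulary.
#' @param source provenance string.
#' @return An [Annotation-class].
#' @export
Annotation <- function(ranges, group = NULL, groups = NULL,
                       source = "constructed") {
  if (!is.null(group)) mcols(ranges)$group <- as.character(group)
  if (is.null(mcols(ranges)$group))
    mcols(ranges)$group <- rep("all", length(ranges))
  mcols(ranges)$group <- as.character(mcols(ranges)$group)
  ranges <- .sortByChrom(ranges)
  if (is.null(groups)) groups <- unique(mcols(ranges)$group)
  new("Annotation", ranges = ranges, groups = groups, source = source)
}

.sortByChrom <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

## ---- accessors ------------------------------------------------------------

#' @rdname intervals
#' @export
setMethod("intervals", "Segmentation", function(x) x@ranges)

#' @rdname intervals
#' @export
setMethod("intervals", "Annotation", function(x) x@ranges)

#' @rdname labelSet
#' @export
setMethod("labelSet", "Segmentation", function(x) x@labels)

#' @rdname groupSet
#' @export
setMethod("groupSet", "Annotation", function(x) x@groups)

#' @describeIn Segmentation number of segments.
#' @param x a `Segmentation`.
#' @export
setMethod("length", "Segmentation", function(x) length(x@ranges))

#' @describeIn Annotation number of records.
#' @param x an `Annotation`.
#' @export
setMethod("length", "Annotation", function(x) length(x@ranges))

#' Track name of a SignalTrack
#' @param x a `SignalTrack`.
#' @return The track name.
#' @export
trackName <- function(x) x@name

#' Per-chromosome signal values
#' @param x a `SignalTrack`.
#' @return The underlying `RleList` (NA = missing).
#' @export
signalValues <- function(x) x@values

## ---- show -----------------------------------------------------------------

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d segments, %d labels on %d chromosome(s)\n",
              length(object@ranges), length(object@labels),
              length(unique(as.character(seqnames(object@ranges))))))
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "Annotation", function(object) {
  cat(sprintf("Annotation: %d records, %d group(s) on %d chromosome(s)\n",
              length(object@ranges), length(object@groups),
              length(unique(as.character(seqnames(object@ranges))))))
  cat("  groups:", paste(object@groups, collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "SignalTrack", function(object) {
  nd <- sum(vapply(object@values,
                   function(r) sum(runLength(r)[!is.na(runValue(r))]),
                   numeric(1)))
  cat(sprintf("SignalTrack '%s': %d chromosome(s), %.0f data-bearing bases\n",
              object@name, length(object@values), nd))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s: %s(%s), %d exon(s), %d transcript(s)\n",
              object@geneId, object@chrom, object@strand,
              length(object@exons), length(object@transcripts)))
})

setMethod("show", "AggregationProfile", function(object) {
  cat(sprintf("AggregationProfile (%s mode): %d labels, %d rows\n",
              object@mode, length(object@labels), nrow(object@table)))
})
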