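#' @importFrom Biostrings readDNAStringSet readBStringSet DNAStringSet
#'   alphabetFrequency dinucleotideFrequency DNA_BASES
#' @importFrom IRanges Views
#' @importFrom stats median
NULL

#' Segment length distribution by label
#'
#' For every label: segment count, total bases, min/median/mean/max segment
#' length, the fraction of all segments carrying that label and the fraction
#' of all covered bases. Both fraction columns sum to 1 over labels.
#'
#' @param seg a [Segmentation-class].
#' @return A [LengthStats-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 21), c(10, 50)))
#' lengthDistribution(Segmentation(gr, label = c("A", "B")))@table
#' @export
lengthDistribution <- function(seg) {
  gr <- intervals(seg)
  if (!length(gr)) stop("empty segmentation", call. = FALSE)
  labs <- labelSet(seg)
  w <- width(gr)
  lab <- mcols(gr)$label
  lengths <- lapply(labs, function(l) w[lab == l])
  names(lengths) <- labs
  cnt <- vapply(lengths, length, integer(1))
  bases <- vapply(lengths, sum, numeric(1))
  tab <- data.frame(
    label = labs,
    count = cnt,
    bases = bases,
    min = vapply(lengths, function(x) if (length(x)) min(x) else NA_real_, numeric(1)),
    median = vapply(lengths, function(x) if (length(x)) median(x) else NA_real_, numeric(1)),
    mean = vapply(lengths, function(x) if (length(x)) mean(x) else NA_real_, numeric(1)),
    max = vapply(lengths, function(x) if (length(x)) max(x) else NA_real_, numeric(1)),
    frac_segments = cnt / sum(cnt),
    frac_bases = bases / sum(bases),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("LengthStats", table = tab, lengths = lengths)
}

## read a genome FASTA; optionally replace soft-masked (lowercase) bases by N
.readGenome <- function(genome, maskLower = FALSE) {
  if (is(genome, "DNAStringSet")) {
    names(genome) <- sub("\\s.*$", "", names(genome))
    return(genome)
  }
  if (maskLower) {
    b <- readBStringSet(genome)
    b <- chartr("acgtryswkmbdhvn", "NNNNNNNNNNNNNNN", b)
    g <- DNAStringSet(b)
  } else {
    g <- readDNAStringSet(genome)
  }
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Mono- and dinucleotide frequencies by label
#'
#' Counts are pooled over all segments of a label. A segment of length L
#' contributes L mononucleotide positions and L-1 dinucleotide positions;
#' dinucleotide windows never span the boundary between two segments.
#' Positions holding bases outside ACGT are excluded from both numerator and
#' denominator. Lowercase (soft-masked) bases count as their uppercase
#' equivalents unless `maskLower = TRUE`. Only the plus strand is counted;
#' segment strand is ignored.
#'
#' @param seg a [Segmentation-class].
#' @param genome FASTA file path or a `DNAStringSet` (names matched to the
#'   segmentation's chromosomes as exact strings).
#' @param maskLower exclude soft-masked bases (treat as ambiguous).
#' @param perSegmentMean if `TRUE`, report the mean over segments of each
#'   segment's own frequencies instead of pooled counts (differs when segment
#'   lengths vary).
#' @return A [NucFreqTable-class].
#' @export
nucleotideFrequency <- function(seg, genome, maskLower = FALSE,
                                perSegmentMean = FALSE) {
  g <- .readGenome(genome, maskLower)
  gr <- intervals(seg)
  labs <- labelSet(seg)
  chroms <- unique(as.character(seqnames(gr)))
  absent <- setdiff(chroms, names(g))
  if (length(absent))
    stop("chromosome(s) missing from FASTA: ",
         paste(absent, collapse = ", "), call. = FALSE)
  dinucs <- paste0(rep(DNA_BASES, each = 4L), DNA_BASES)
  monoC <- matrix(0, length(labs), 4L, dimnames = list(labs, DNA_BASES))
  diC <- matrix(0, length(labs), 16L, dimnames = list(labs, dinucs))
  monoM <- matrix(0, length(labs), 4L, dimnames = list(labs, DNA_BASES))
  diM <- matrix(0, length(labs), 16L, dimnames = list(labs, dinucs))
  nSegMono <- nSegDi <- stats::setNames(numeric(length(labs)), labs)
  ambig <- stats::setNames(integer(length(labs)), labs)
  chn <- as.character(seqnames(gr))
  for (ch in chroms) {
    idx <- which(chn == ch)
    if (max(end(gr)[idx]) > length(g[[ch]]))
      stop(sprintf("segment beyond end of chromosome %s (%d > %d)",
                   ch, max(end(gr)[idx]), length(g[[ch]])), call. = FALSE)
    seqs <- DNAStringSet(Views(g[[ch]], start(gr)[idx], end(gr)[idx]))
    af <- alphabetFrequency(seqs)[, DNA_BASES, drop = FALSE]
    df <- dinucleotideFrequency(seqs, step = 1L)[, dinucs, drop = FALSE]
    lb <- mcols(gr)$label[idx]
    for (l in unique(lb)) {
      li <- lb == l
      monoC[l, ] <- monoC[l, ] + colSums(af[li, , drop = FALSE])
      diC[l, ] <- diC[l, ] + colSums(df[li, , drop = FALSE])
      ambig[l] <- ambig[l] +
        sum(width(seqs)[li]) - sum(af[li, , drop = FALSE])
      rsA <- rowSums(af[li, , drop = FALSE]); rsD <- rowSums(df[li, , drop = FALSE])
      okA <- rsA > 0; okD <- rsD > 0
      if (any(okA)) {
        monoM[l, ] <- monoM[l, ] +
          colSums(af[li, , drop = FALSE][okA, , drop = FALSE] / rsA[okA])
        nSegMono[l] <- nSegMono[l] + sum(okA)
      }
      if (any(okD)) {
        diM[l, ] <- diM[l, ] +
          colSums(df[li, , drop = FALSE][okD, , drop = FALSE] / rsD[okD])
        nSegDi[l] <- nSegDi[l] + sum(okD)
      }
    }
  }
  normRows <- function(cnt, denomSeg = NULL) {
    if (is.null(denomSeg)) {
      rs <- rowSums(cnt)
      out <- cnt / ifelse(rs > 0, rs, NA_real_)
    } else out <- cnt / ifelse(denomSeg > 0, denomSeg, NA_real_)
    out
  }
  if (perSegmentMean) {
    mono <- normRows(monoM, nSegMono)
    di <- normRows(diM, nSegDi)
  } else {
    mono <- normRows(monoC)
    di <- normRows(diC)
  }
  new("NucFreqTable", mono = mono, di = di,
      monoCounts = monoC, diCounts = diC, ambiguous = ambig)
}

#' Label transition counts and frequencies
#'
#' A transition is counted for every ordered pair of consecutive segments on
#' the same chromosome in coordinate order, regardless of the unlabeled gap
#' between them; `maxGap` restricts counting to pairs separated by at most
#' that many uncovered bases. Frequencies are row-conditional: each row with
#' at least one transition sums to 1. Segments never pair across chromosomes,
#' so the total transition count equals the number of segments minus the
#' number of chromosomes bearing at least one segment (when `maxGap` is
#' unrestricted).
#'
#' @param seg a [Segmentation-class].
#' @param maxGap maximum allowed gap in bases between consecutive segments
#'   (default `Inf`, i.e. pure segment order).
#' @return A [TransitionMatrix-class].
#' @export
transitionMatrix <- function(seg, maxGap = Inf) {
  gr <- intervals(seg)
  if (!length(gr)) stop("empty segmentation", call. = FALSE)
  labs <- labelSet(seg)
  cnt <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  chn <- as.character(seqnames(gr))
  lab <- mcols(gr)$label
  for (ch in unique(chn)) {
    idx <- which(chn == ch)
    if (length(idx) < 2L) next
    from <- lab[idx[-length(idx)]]
    to <- lab[idx[-1L]]
    gap <- start(gr)[idx[-1L]] - end(gr)[idx[-length(idx)]] - 1L
    keep <- gap <= maxGap
    if (any(keep)) {
      t2 <- table(factor(from[keep], levels = labs),
                  factor(to[keep], levels = labs))
      cnt <- cnt + unclass(t2)
    }
  }
  rs <- rowSums(cnt)
  freqs <- cnt / ifelse(rs > 0, rs, 1)
  new("TransitionMatrix", counts = cnt, freqs = freqs, labels = labs)
}

#' Write a transition graph in Graphviz DOT format
#'
#' Nodes are labels; a directed edge from x to y is included when the
#' frequency of y immediately following x is at least `minFreq`, with the
#' frequency as edge weight and pen width.
#'
#' @param tm a [TransitionMatrix-class].
#' @param path output `.dot` file.
#' @param minFreq minimum row-conditional frequency for an edge (in `[0,1]`).
#' @return `path`, invisibly.
#' @export
writeTransitionGraph <- function(tm, path, minFreq = 0) {
  stopifnot(minFreq >= 0, minFreq <= 1)
  labs <- tm@labels
  lines <- c("digraph transitions {",
             sprintf('  "%s";', labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    f <- tm@freqs[i, j]
    if (tm@counts[i, j] > 0L && f >= minFreq)
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [label="%.3f", weight=%d, penwidth=%.2f];',
        labs[i], labs[j], f, max(1L, round(100 * f)), 0.5 + 4 * f))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
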