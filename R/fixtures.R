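#' @importFrom Biostrings writeXStringSet
#' @importFrom stats rgeom rnorm runif
NULL

## evaluate expr under set.seed(seed) without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random genome FASTA
#'
#' Independent bases drawn with P(C) = P(G) = gc/2 and P(A) = P(T) =
#' (1-gc)/2; bit-reproducible for a given seed.
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return A `DNAStringSet` (written to `path` when given), invisibly when
#'   writing.
#' @export
makeGenome <- function(chromSizes, gc = 0.4, seed = 1L, path = NULL) {
  stopifnot(all(chromSizes >= 1), gc >= 0, gc <= 1)
  g <- .withSeed(seed, {
    seqs <- vapply(chromSizes, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = ""), character(1))
    DNAStringSet(seqs)
  })
  names(g) <- names(chromSizes)
  if (!is.null(path)) {
    writeXStringSet(g, path)
    return(invisible(g))
  }
  g
}

#' Generate a random segmentation
#'
#' Alternates geometric-length gaps and segments along each chromosome so
#' that the realized base coverage approaches `coverage` and segment lengths
#' average `meanLength` (or are exactly `fixedLength` when given). Labels are
#' drawn independently and uniformly, or as a Markov chain when
#' `transitions` is supplied (rows = preceding label; the chain restarts with
#' a uniform draw on each chromosome, matching how transitions are counted).
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param labels character vector of labels.
#' @param meanLength mean segment length in bases.
#' @param coverage target fraction of bases covered, in `(0, 1]`.
#' @param seed integer seed.
#' @param path optional BED output path.
#' @param transitions optional row-stochastic matrix `labels x labels`.
#' @param fixedLength if given, every segment has exactly this length.
#' @return A [Segmentation-class]; also written to `path` when given.
#' @export
makeSegmentation <- function(chromSizes, labels = c("A", "B", "C", "D"),
                             meanLength = 200, coverage = 0.8, seed = 1L,
                             path = NULL, transitions = NULL,
                             fixedLength = NULL) {
  stopifnot(coverage > 0, coverage <= 1, meanLength >= 1)
  if (sum(chromSizes) * coverage < 1)
    stop("infeasible parameters: coverage x genome size below one segment",
         call. = FALSE)
  if (!is.null(transitions)) {
    stopifnot(nrow(transitions) == length(labels),
              ncol(transitions) == length(labels))
    if (any(abs(rowSums(transitions) - 1) > 1e-8))
      stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  segLen <- if (!is.null(fixedLength)) fixedLength else meanLength
  gapMean <- segLen * (1 - coverage) / coverage
  res <- .withSeed(seed, {
    chs <- character(); ss <- integer(); ee <- integer(); ll <- character()
    for (ch in names(chromSizes)) {
      n <- chromSizes[[ch]]
      pos <- 1L
      state <- NA_integer_
      while (pos <= n) {
        gap <- if (gapMean > 0) rgeom(1L, 1 / (gapMean + 1)) else 0L
        s <- pos + gap
        L <- if (!is.null(fixedLength)) fixedLength
             else rgeom(1L, 1 / meanLength) + 1L
        e <- s + L - 1L
        if (e > n) break
        state <- if (is.null(transitions)) sample.int(length(labels), 1L)
                 else if (is.na(state)) sample.int(length(labels), 1L)
                 else sample.int(length(labels), 1L,
                                 prob = transitions[state, ])
        chs <- c(chs, ch); ss <- c(ss, s); ee <- c(ee, e)
        ll <- c(ll, labels[state])
        pos <- e + 1L
      }
    }
    list(chs = chs, ss = ss, ee = ee, ll = ll)
  })
  if (!length(res$chs))
    stop("infeasible parameters: no segment fits", call. = FALSE)
  gr <- GRanges(res$chs, IRanges(res$ss, res$ee))
  mcols(gr)$label <- res$ll
  seg <- Segmentation(gr, labels = labels,
                      source = sprintf("makeSegmentation(seed=%d)", seed))
  if (!is.null(path)) writeIntervals(seg, path, "bed")
  seg
}

#' Generate random gene models as GTF
#'
#' Places non-overlapping single-transcript genes with geometric exon and
#' intron lengths on random strands; errors when `nGenes` cannot be placed.
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param nGenes number of genes to place.
#' @param exonCountRange integer range of exons per gene (inclusive).
#' @param seed integer seed.
#' @param path optional GTF output path.
#' @param exonMean,intronMean,gapMean mean exon / intron / intergenic-gap
#'   lengths in bases.
#' @return A list of [GeneModel-class]; also written to `path` when given.
#' @export
makeGenes <- function(chromSizes, nGenes = 20, exonCountRange = c(1L, 6L),
                      seed = 1L, path = NULL, exonMean = 150,
                      intronMean = 300, gapMean = 400) {
  genes <- .withSeed(seed, {
    out <- list()
    gi <- 0L
    for (ch in names(chromSizes)) {
      n <- chromSizes[[ch]]
      pos <- 1L
      while (gi < nGenes) {
        pos <- pos + rgeom(1L, 1 / (gapMean + 1)) + 1L
        nEx <- sample(seq.int(exonCountRange[1L], exonCountRange[2L]), 1L)
        exLen <- rgeom(nEx, 1 / exonMean) + 1L
        inLen <- if (nEx > 1L) rgeom(nEx - 1L, 1 / intronMean) + 1L else integer()
        tot <- sum(exLen) + sum(inLen)
        if (pos + tot - 1L > n) break
        s <- pos + c(0L, cumsum(exLen[-nEx] + inLen))
        e <- s + exLen - 1L
        gi <- gi + 1L
        id <- sprintf("gene%03d", gi)
        out[[id]] <- new("GeneModel", geneId = id, chrom = ch,
                         strand = sample(c("+", "-"), 1L),
                         exons = IRanges(s, e),
                         transcripts = list(t1 = IRanges(s, e)))
        pos <- max(e) + 1L
      }
    }
    out
  })
  if (length(genes) < nGenes)
    stop(sprintf("could not place %d genes (placed %d): chromosomes too small",
                 nGenes, length(genes)), call. = FALSE)
  if (!is.null(path)) writeGenesGtf(genes, path)
  genes
}

#' Write gene models as GTF
#'
#' One exon feature per exon per transcript, carrying `gene_id` and
#' `transcript_id` attributes.
#'
#' @param genes list of [GeneModel-class].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
writeGenesGtf <- function(genes, path) {
  lines <- character()
  for (g in genes) {
    for (tn in names(g@transcripts)) {
      ir <- g@transcripts[[tn]]
      lines <- c(lines, sprintf(
        '%s\tsegexplore\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.%s";',
        g@chrom, start(ir), end(ir), g@strand, g@geneId, g@geneId, tn))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcription start sites of gene models as a point annotation
#'
#' One single-base record per gene at the 5' end of its representative
#' transcript, on the gene's strand; the group is taken from `groupOf`.
#'
#' @param genes list of [GeneModel-class].
#' @param path optional BED output path.
#' @param groupOf function mapping a GeneModel to a group string.
#' @return An [Annotation-class].
#' @export
makeTss <- function(genes, path = NULL, groupOf = function(g) "TSS") {
  stopifnot(length(genes) > 0)
  ch <- vapply(genes, function(g) g@chrom, character(1))
  st <- vapply(genes, function(g) g@strand, character(1))
  tss <- vapply(genes, function(g)
    if (g@strand == "-") max(end(g@exons)) else min(start(g@exons)),
    numeric(1))
  gr <- GRanges(ch, IRanges(tss, tss), strand = st)
  mcols(gr)$group <- vapply(genes, groupOf, character(1))
  ann <- Annotation(gr, source = "makeTss")
  if (!is.null(path)) writeIntervals(ann, path, "bed")
  ann
}

#' Generate a signal track with planted per-label means
#'
#' Over every base covered by the segmentation the signal equals the label's
#' effect plus Gaussian noise; uncovered bases are missing. With
#' `noiseSd = 0` [signalDistribution()] recovers the effect map exactly.
#'
#' @param seg a [Segmentation-class].
#' @param effectMap named numeric vector: label -> mean signal.
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param path optional bedGraph output path.
#' @param name track name.
#' @return A [SignalTrack-class]; also written to `path` when given.
#' @export
makeSignal <- function(seg, effectMap, noiseSd = 0, seed = 1L, path = NULL,
                       name = "signal") {
  gr <- intervals(seg)
  missing <- setdiff(unique(mcols(gr)$label), names(effectMap))
  if (length(missing))
    stop("effectMap lacks label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sizes <- .chromSizes(seg)
  vals <- .withSeed(seed, {
    out <- list()
    chn <- as.character(seqnames(gr))
    for (ch in names(sizes)) {
      v <- Rle(NA_real_, sizes[[ch]])
      for (k in which(chn == ch)) {
        L <- width(gr)[k]
        base <- effectMap[[mcols(gr)$label[k]]]
        x <- if (noiseSd > 0) base + rnorm(L, 0, noiseSd) else Rle(base, L)
        v[start(gr)[k]:end(gr)[k]] <- x
      }
      out[[ch]] <- v
    }
    out
  })
  tr <- new("SignalTrack", values = as(vals, "RleList"), name = name)
  if (!is.null(path)) writeSignal(tr, path)
  tr
}

#' Write a signal track as bedGraph
#'
#' Runs of equal value become one record each; missing runs are omitted.
#'
#' @param track a [SignalTrack-class].
#' @param path output bedGraph path.
#' @return `path`, invisibly.
#' @export
writeSignal <- function(track, path) {
  grl <- list()
  for (ch in names(signalValues(track))) {
    v <- signalValues(track)[[ch]]
    rv <- runValue(v); rl <- runLength(v)
    e <- cumsum(rl); s <- e - rl + 1L
    ok <- !is.na(rv)
    if (!any(ok)) next
    g <- GRanges(ch, IRanges(s[ok], e[ok]))
    mcols(g)$score <- rv[ok]
    grl[[ch]] <- g
  }
  if (!length(grl)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  all <- unlist(GRangesList(grl), use.names = FALSE)
  rtracklayer::export(all, path, format = "bedGraph")
  invisible(path)
}

#' Generate a complete fixture set on disk
#'
#' Emits a synthetic genome (FASTA), a segmentation (BED), gene models (GTF),
#' a TSS point annotation (BED) and a signal track (bedGraph) that are
#' mutually consistent, all derived from one integer seed (sub-generators use
#' seed + 1, seed + 2, ...).
#'
#' @param outdir output directory (created if needed).
#' @param chromSizes named integer vector of chromosome lengths.
#' @param nLabels number of segmentation labels (named L1, L2, ...).
#' @param seed integer master seed.
#' @param gc genome GC fraction.
#' @param meanLength,coverage segmentation parameters.
#' @param nGenes genes to place.
#' @param noiseSd signal noise; per-label effects are 0, 1, 2, ....
#' @return Named list of the file paths written.
#' @export
makeFixtureSet <- function(outdir, chromSizes = c(chr1 = 60000L, chr2 = 40000L),
                           nLabels = 4L, seed = 17L, gc = 0.4,
                           meanLength = 200, coverage = 0.8, nGenes = 15L,
                           noiseSd = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  labels <- paste0("L", seq_len(nLabels))
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    segmentation = file.path(outdir, "segmentation.bed"),
    genes = file.path(outdir, "genes.gtf"),
    tss = file.path(outdir, "tss.bed"),
    signal = file.path(outdir, "signal.bedgraph"))
  makeGenome(chromSizes, gc = gc, seed = seed + 1L, path = paths$genome)
  seg <- makeSegmentation(chromSizes, labels, meanLength = meanLength,
                          coverage = coverage, seed = seed + 2L,
                          path = paths$segmentation)
  genes <- makeGenes(chromSizes, nGenes = nGenes, seed = seed + 3L,
                     path = paths$genes)
  makeTss(genes, path = paths$tss)
  effects <- setNames(seq_len(nLabels) - 1, labels)
  makeSignal(seg, effects, noiseSd = noiseSd, seed = seed + 4L,
             path = paths$signal)
  paths
}
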