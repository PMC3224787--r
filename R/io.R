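#' @importFrom rtracklayer import export
NULL

.importTrack <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e)
      stop(sprintf("parse error in %s (%s): %s", path, format,
                   conditionMessage(e)), call. = FALSE))
}

.labelFromGff <- function(gr) {
  mc <- mcols(gr)
  lab <- rep(NA_character_, length(gr))
  for (col in c("Name", "name", "ID", "type", "group"))
    if (!is.null(mc[[col]])) {
      v <- as.character(mc[[col]])
      lab[is.na(lab) & !is.na(v)] <- v[is.na(lab) & !is.na(v)]
    }
  lab
}

.checkNoZeroWidth <- function(gr, path) {
  if (any(width(gr) < 1L))
    stop(sprintf("zero-length record (start == end) in %s at %s:%d",
                 path, as.character(seqnames(gr))[width(gr) < 1L][1L],
                 start(gr)[width(gr) < 1L][1L] - 1L), call. = FALSE)
  invisible(gr)
}

#' Read a segmentation from BED or GFF
#'
#' The name column of the file supplies the segment label. BED coordinates
#' (0-based, half-open) are converted to the internal 1-based closed
#' convention; GFF coordinates pass through. Intervals must be non-overlapping
#' within each chromosome: the first offending pair is named in the error.
#' Zero-length records are rejected.
#'
#' @param path file path.
#' @param format `"bed"` or `"gff"`; default guessed from the file extension.
#' @return A [Segmentation-class].
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100\tA", "chr1\t100\t250\tB"), bed)
#' seg <- readSegmentation(bed)
#' intervals(seg)
#' @export
readSegmentation <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  gr <- .importTrack(path, format)
  if (format == "bed") {
    if (is.null(mcols(gr)$name))
      stop("missing name column: segmentations need a BED name field for the segment label",
           call. = FALSE)
    lab <- as.character(mcols(gr)$name)
  } else {
    lab <- .labelFromGff(gr)
    if (anyNA(lab))
      stop("missing name column: GFF records lack Name/ID attributes", call. = FALSE)
  }
  .checkNoZeroWidth(gr, path)
  gr2 <- granges(gr)
  mcols(gr2)$label <- lab
  Segmentation(gr2, source = path)
}

#' Read an annotation from BED or GFF
#'
#' Overlapping records are permitted. The name column, when present, is an
#' optional grouping variable; a 3-column BED yields the single default group
#' `"all"`.
#'
#' @inheritParams readSegmentation
#' @return An [Annotation-class].
#' @export
readAnnotation <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  gr <- .importTrack(path, format)
  grp <- if (format == "bed") {
    if (is.null(mcols(gr)$name)) rep("all", length(gr))
    else as.character(mcols(gr)$name)
  } else {
    g <- .labelFromGff(gr)
    g[is.na(g)] <- "all"
    g
  }
  .checkNoZeroWidth(gr, path)
  gr2 <- granges(gr)
  mcols(gr2)$group <- grp
  Annotation(gr2, source = path)
}

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         bed = "bed",
         gff = , gff2 = , gff3 = , gtf = "gff",
         bedgraph = , bg = "bedGraph",
         wig = , wiggle = "wig",
         stop("cannot guess format from extension: ", path, call. = FALSE))
}

#' Read gene models from GTF
#'
#' Exon features are grouped by `transcript_id`, transcripts by `gene_id`.
#' Each gene keeps one representative transcript for the idealized-component
#' decomposition: the longest by exonic bases, with ties broken by leftmost
#' start. Transcripts without exons are skipped with a warning.
#'
#' @param path GTF file path.
#' @return A list of [GeneModel-class] objects, named by gene id.
#' @export
readGenes <- function(path) {
  gr <- .importTrack(path, "gtf")
  gr <- gr[as.character(mcols(gr)$type) == "exon"]
  if (!length(gr)) {
    warning("no exon features in ", path, call. = FALSE)
    return(list())
  }
  gid <- as.character(mcols(gr)$gene_id)
  tid <- as.character(mcols(gr)$transcript_id)
  if (anyNA(gid) || anyNA(tid))
    stop("parse error: exon features must carry gene_id and transcript_id",
         call. = FALSE)
  st <- .effectiveStrand(strand(gr), "exon")
  genes <- list()
  for (g in unique(gid)) {
    idx <- which(gid == g)
    txs <- list()
    for (tr in unique(tid[idx])) {
      ei <- idx[tid[idx] == tr]
      ir <- IRanges(start(gr)[ei], end(gr)[ei])
      txs[[tr]] <- ir[order(start(ir))]
    }
    nz <- vapply(txs, length, integer(1)) > 0L
    if (!all(nz)) {
      warning(sprintf("gene %s: skipping %d transcript(s) with zero exons",
                      g, sum(!nz)), call. = FALSE)
      txs <- txs[nz]
    }
    if (!length(txs)) next
    sizes <- vapply(txs, function(ir) sum(width(ir)), numeric(1))
    starts <- vapply(txs, function(ir) min(start(ir)), numeric(1))
    pick <- order(-sizes, starts)[1L]
    genes[[g]] <- new("GeneModel", geneId = g,
                      chrom = as.character(seqnames(gr))[idx[1L]],
                      strand = st[idx[1L]],
                      exons = txs[[pick]], transcripts = txs)
  }
  genes
}

#' Read a continuous signal track from bedGraph or wiggle
#'
#' Per-base values are materialized into one run-length encoded vector per
#' chromosome; bases not covered by any record are missing (`NA`). bedGraph
#' records must be non-overlapping within a chromosome.
#'
#' @param path file path.
#' @param format `"bedGraph"` or `"wig"`; default guessed from the extension.
#' @param name track name; defaults to the file base name.
#' @param chromSizes optional named vector of chromosome lengths; defaults to
#'   the maximum end coordinate seen per chromosome.
#' @return A [SignalTrack-class].
#' @export
readSignal <- function(path, format = c("auto", "bedGraph", "wig"),
                       name = NULL, chromSizes = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (is.null(name))
    name <- sub("\\.(bedgraph|bg|wig|wiggle)$", "", basename(path),
                ignore.case = TRUE)
  nonEmpty <- length(readLines(path, n = 1L)) > 0L
  if (!nonEmpty)
    return(new("SignalTrack", values = RleList(compress = FALSE), name = name))
  gr <- .importTrack(path, format)
  bad <- .firstOverlapViolation(`mcols<-`(granges(gr), value = NULL))
  if (!is.null(bad))
    stop(sprintf("overlapping signal records in %s: %s [%d, %d] and [%d, %d]",
                 path, bad$chrom, bad$s1, bad$e1, bad$s2, bad$e2),
         call. = FALSE)
  sizes <- .chromSizes(gr, sizes = chromSizes)
  vals <- list()
  chn <- as.character(seqnames(gr))
  o <- order(chn, start(gr))
  gr <- gr[o]; chn <- chn[o]
  for (ch in names(sizes)) {
    n <- sizes[[ch]]
    idx <- which(chn == ch)
    s <- start(gr)[idx]; e <- pmin(end(gr)[idx], n)
    v <- as.numeric(mcols(gr)$score)[idx]
    prev <- c(0L, e[-length(e)])
    if (!length(idx)) { vals[[ch]] <- Rle(NA_real_, n); next }
    runlen <- as.integer(rbind(s - prev - 1L, e - s + 1L))
    runval <- as.numeric(rbind(NA_real_, v))
    if (e[length(e)] < n) {
      runlen <- c(runlen, n - e[length(e)])
      runval <- c(runval, NA_real_)
    }
    keep <- runlen > 0L
    vals[[ch]] <- Rle(runval[keep], runlen[keep])
  }
  new("SignalTrack", values = as(vals, "RleList"), name = name)
}

#' Write a segmentation or annotation to BED or GFF
#'
#' Writing then reading back reproduces the same intervals and labels
#' (coordinates reconverted to the file format's convention).
#'
#' @param x a [Segmentation-class] or [Annotation-class].
#' @param path output path.
#' @param format `"bed"` or `"gff"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(x, path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  gr <- intervals(x)
  nm <- if (is(x, "Segmentation")) mcols(gr)$label else mcols(gr)$group
  out <- granges(gr)
  if (format == "bed") {
    mcols(out)$name <- nm
    rtracklayer::export(out, path, format = "bed")
  } else {
    mcols(out)$Name <- nm
    mcols(out)$type <- "region"
    mcols(out)$source <- "segexplore"
    rtracklayer::export(out, path, format = "gff3")
  }
  invisible(path)
}
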