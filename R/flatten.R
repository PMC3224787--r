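#' @importFrom GenomicRanges reduce disjoin findOverlaps nearest GRangesList
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Flatten several interval sets into combination labels
#'
#' Combines segmentations and/or annotations into a single segmentation whose
#' label at every base encodes which of the inputs cover that base. Each
#' output segment is a maximal run of bases covered by the same subset of
#' inputs; its label is the sorted input names in that subset joined by
#' `sep`. Bases covered by no input produce no segment. Within one input,
#' overlapping records count once (coverage is a set, not a multiset).
#'
#' This is how, for example, separate ChIP-seq peak calls for several histone
#' modifications become a single segmentation whose labels are modification
#' combinations.
#'
#' @param inputs list of [Segmentation-class] / [Annotation-class] objects.
#' @param names character vector parallel to `inputs`; names must not contain
#'   `sep`. Defaults to names of `inputs` or `"input1"`, ....
#' @param sep separator joining input names into combination labels.
#' @return A [Segmentation-class].
#' @examples
#' a <- Annotation(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)))
#' b <- Annotation(GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15)))
#' fl <- flattenSegmentations(list(A = a, B = b))
#' intervals(fl)   # [1,5] "A", [6,10] "A-B", [11,15] "B"
#' @export
flattenSegmentations <- function(inputs, names = NULL, sep = "-") {
  if (!length(inputs)) stop("empty input list", call. = FALSE)
  if (is.null(names)) names <- base::names(inputs)
  if (is.null(names)) names <- paste0("input", seq_along(inputs))
  if (length(names) != length(inputs))
    stop("names must parallel inputs", call. = FALSE)
  if (any(grepl(sep, names, fixed = TRUE)))
    stop("input names must not contain the separator '", sep, "'",
         call. = FALSE)
  covs <- lapply(inputs, function(x)
    reduce(granges(intervals(x)), ignore.strand = TRUE))
  all <- unlist(GRangesList(lapply(covs, function(g) { mcols(g) <- NULL; g })))
  if (!length(all))
    stop("inputs cover no bases", call. = FALSE)
  bins <- disjoin(all, ignore.strand = TRUE)
  member <- matrix(FALSE, length(bins), length(inputs))
  for (i in seq_along(covs)) {
    h <- findOverlaps(bins, covs[[i]], ignore.strand = TRUE)
    member[unique(queryHits(h)), i] <- TRUE
  }
  lab <- apply(member, 1L, function(m)
    paste(sort(names[m]), collapse = sep))
  o <- order(as.character(seqnames(bins)), start(bins))
  bins <- bins[o]; lab <- lab[o]
  # merge adjacent bins with identical label subset
  n <- length(bins)
  newRun <- c(TRUE, !(as.character(seqnames(bins))[-1L] ==
                        as.character(seqnames(bins))[-n] &
                      lab[-1L] == lab[-n] &
                      start(bins)[-1L] == end(bins)[-n] + 1L))
  runEnd <- c(which(newRun)[-1L] - 1L, n)   # last bin of each merged run
  out <- GRanges(as.character(seqnames(bins))[newRun],
                 IRanges(start(bins)[newRun], end(bins)[runEnd]))
  mcols(out)$label <- lab[newRun]
  Segmentation(out, source = sprintf("flatten(%s)", paste(names, collapse = ",")))
}

#' Distance from each segment to its nearest feature
#'
#' Reports, for every segment, the nearest feature on the same chromosome and
#' a signed distance: 0 when the segment overlaps the feature, negative when
#' the nearest feature lies upstream of the segment start (to its left),
#' positive when downstream; the magnitude is the gap in bases between the
#' closer pair of ends. Ties between equally near features are broken by
#' leftmost feature start, then lexicographic feature name. Segments on
#' chromosomes with no feature report `NA` distance and feature name.
#'
#' @param seg a [Segmentation-class].
#' @param features an [Annotation-class]; record groups serve as feature
#'   names.
#' @return data.frame with columns chrom, start, end (BED convention,
#'   0-based half-open), label, feature_name, distance.
#' @export
featureDistance <- function(seg, features) {
  sgr <- intervals(seg)
  fgr <- intervals(features)
  if (!length(sgr) || !length(fgr))
    stop("both the segmentation and the feature set must be non-empty",
         call. = FALSE)
  .warnChromMismatch(seg, features, "segmentation", "features")
  fname <- mcols(fgr)$group
  n <- length(sgr)
  dist <- rep(NA_real_, n)
  feat <- rep(NA_character_, n)
  schr <- as.character(seqnames(sgr))
  fchr <- as.character(seqnames(fgr))
  for (ch in unique(schr)) {
    si <- which(schr == ch)
    fi <- which(fchr == ch)
    if (!length(fi)) next
    fs <- start(fgr)[fi]; fe <- end(fgr)[fi]; fn <- fname[fi]
    for (k in si) {
      s <- start(sgr)[k]; e <- end(sgr)[k]
      d <- ifelse(fe < s, fe - s + 1L,          # upstream: negative
           ifelse(fs > e, fs - e - 1L, 0L))     # downstream / overlap
      best <- abs(d) == min(abs(d))
      pick <- which(best)[order(fs[best], fn[best])][1L]
      dist[k] <- d[pick]
      feat[k] <- fn[pick]
    }
  }
  data.frame(chrom = schr, start = start(sgr) - 1L, end = end(sgr),
             label = mcols(sgr)$label, feature_name = feat,
             distance = dist, stringsAsFactors = FALSE)
}

.CACHE_MAGIC <- "SEGEXPL1"
.CACHE_VERSION <- 1L

#' Cache a segmentation or annotation in binary form
#'
#' Writes an internal versioned binary container so that repeated analyses
#' can skip text parsing. The format carries a magic string and a version
#' number; [loadPreprocessed()] refuses caches written by an incompatible
#' version. No external compatibility is promised.
#'
#' @param x a [Segmentation-class] or [Annotation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
preprocess <- function(x, path) {
  stopifnot(is(x, "Segmentation") || is(x, "Annotation"))
  validObject(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.CACHE_MAGIC), con)
  writeBin(.CACHE_VERSION, con, size = 4L)
  serialize(x, con)
  invisible(path)
}

#' @rdname preprocess
#' @return `loadPreprocessed()` returns the cached object, structurally
#'   identical to what [preprocess()] was given.
#' @export
loadPreprocessed <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.CACHE_MAGIC)))
  if (!identical(magic, .CACHE_MAGIC))
    stop("version mismatch: not a segexplore cache (bad magic bytes)",
         call. = FALSE)
  ver <- readBin(con, "integer", 1L, size = 4L)
  if (!identical(ver, .CACHE_VERSION))
    stop("version mismatch: cache version ", ver,
         ", this build reads version ", .CACHE_VERSION, call. = FALSE)
  x <- unserialize(con)
  validObject(x)
  x
}
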