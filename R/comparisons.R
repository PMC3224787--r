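#' @importFrom GenomicRanges intersect setdiff union
#' @importFrom stats dist hclust
NULL

.labelCoverage <- function(seg) {
  gr <- intervals(seg)
  lapply(setNames(labelSet(seg), labelSet(seg)), function(l)
    reduce(granges(gr[mcols(gr)$label == l]), ignore.strand = TRUE))
}

#' Overlap of an annotation by a segmentation, with precision and recall
#'
#' For every (segment label, annotation group) pair: the bases of overlap
#' (bases covered by several records of one group count once), the number of
#' that label's segments overlapping at least one record of the group by at
#' least `minOverlap` bases, and the number of the group's records overlapped
#' by at least one such segment. Precision and recall follow the TSS-activity
#' construction: `recall(s, g)` is the fraction of group-g records overlapped
#' by label s, and `precision(s, g)` is, among the segments of s that overlap
#' any record of the annotation, the fraction that overlap a record of group
#' g. `precisionDenominator = "label"` switches the denominator to all
#' segments of the label.
#'
#' @param seg a [Segmentation-class].
#' @param ann an [Annotation-class].
#' @param mode `"bases"` or `"segments"`: which fraction the heat map (and
#'   TSV `fraction` column) reports — overlap bases over the label's total
#'   bases, or overlapping segments over the label's total segments.
#' @param minOverlap minimum intersection (bases) for a segment to count as
#'   overlapping a record.
#' @param precisionDenominator `"overlapping"` (default, see above) or
#'   `"label"`.
#' @return An [OverlapTable-class].
#' @export
segmentationOverlap <- function(seg, ann, mode = c("bases", "segments"),
                                minOverlap = 1L,
                                precisionDenominator = c("overlapping", "label")) {
  mode <- match.arg(mode)
  precisionDenominator <- match.arg(precisionDenominator)
  stopifnot(minOverlap >= 1L)
  .warnChromMismatch(seg, ann, "segmentation", "annotation")
  sgr <- intervals(seg)
  agr <- intervals(ann)
  labs <- labelSet(seg)
  grps <- groupSet(ann)
  bases <- matrix(0, length(labs), length(grps), dimnames = list(labs, grps))
  segHits <- recHits <- matrix(0L, length(labs), length(grps),
                               dimnames = list(labs, grps))
  covByLabel <- .labelCoverage(seg)
  hits <- findOverlaps(sgr, agr, minoverlap = minOverlap,
                       ignore.strand = TRUE)
  hLab <- mcols(sgr)$label[queryHits(hits)]
  hGrp <- mcols(agr)$group[subjectHits(hits)]
  for (g in grps) {
    gCov <- reduce(granges(agr[mcols(agr)$group == g]),
                   ignore.strand = TRUE)
    for (l in labs)
      bases[l, g] <- sum(width(intersect(covByLabel[[l]], gCov, ignore.strand = TRUE)))
  }
  for (l in labs) for (g in grps) {
    sel <- hLab == l & hGrp == g
    segHits[l, g] <- length(unique(queryHits(hits)[sel]))
    recHits[l, g] <- length(unique(subjectHits(hits)[sel]))
  }
  segTotal <- vapply(labs, function(l) sum(mcols(sgr)$label == l), integer(1))
  segAnyHit <- vapply(labs, function(l)
    length(unique(queryHits(hits)[hLab == l])), integer(1))
  recTotal <- vapply(grps, function(g) sum(mcols(agr)$group == g), integer(1))
  prDen <- if (precisionDenominator == "overlapping") segAnyHit else segTotal
  pr <- expand.grid(label = labs, group = grps, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  pr$precision <- mapply(function(l, g)
    if (prDen[l] > 0) segHits[l, g] / prDen[l] else NA_real_,
    pr$label, pr$group)
  pr$recall <- mapply(function(l, g)
    if (recTotal[g] > 0) recHits[l, g] / recTotal[g] else NA_real_,
    pr$label, pr$group)
  new("OverlapTable", bases = bases, segmentHits = segHits,
      recordHits = recHits, pr = pr,
      labelTotals = list(segments = segTotal, bases = .labelBases(seg),
                         overlappingAny = segAnyHit),
      groupTotals = list(records = recTotal),
      params = list(mode = mode, minOverlap = minOverlap,
                    precisionDenominator = precisionDenominator))
}

#' Base-set edit distances between the labels of two segmentations
#'
#' For every pair (label x of `seg1`, label y of `seg2`): the number of bases
#' in the symmetric difference of the base sets the two labels cover, and the
#' Jaccard similarity of the same sets. Distance 0 means identical coverage.
#'
#' @param seg1,seg2 [Segmentation-class] objects.
#' @return An [EditDistanceMatrix-class].
#' @export
compareSegmentations <- function(seg1, seg2) {
  .warnChromMismatch(seg1, seg2, "first segmentation", "second segmentation")
  cov1 <- .labelCoverage(seg1)
  cov2 <- .labelCoverage(seg2)
  l1 <- labelSet(seg1); l2 <- labelSet(seg2)
  d <- j <- matrix(NA_real_, length(l1), length(l2), dimnames = list(l1, l2))
  w1 <- vapply(cov1, function(x) sum(width(x)), numeric(1))
  w2 <- vapply(cov2, function(x) sum(width(x)), numeric(1))
  for (x in l1) for (y in l2) {
    wi <- sum(width(intersect(cov1[[x]], cov2[[y]], ignore.strand = TRUE)))
    wu <- w1[x] + w2[y] - wi
    d[x, y] <- w1[x] + w2[y] - 2 * wi
    j[x, y] <- if (wu > 0) wi / wu else NA_real_
  }
  new("EditDistanceMatrix", distance = d, jaccard = j,
      labels1 = l1, labels2 = l2)
}

#' Per-label signal mean and variance, with a clustered display matrix
#'
#' For every (track, label) pair, the mean and variance of the track's values
#' over all data-bearing bases covered by that label, pooled across segments
#' (missing-signal bases excluded). Variance is the population variance by
#' default (the bases are a complete enumeration, not a sample). For display,
#' per-track rows of means are linearly rescaled to `[0, 1]` (constant rows
#' map to 0.5), standard deviations are expressed relative to the largest SD
#' over all cells, and row/column orders come from average-linkage
#' hierarchical clustering on Euclidean distances of the normalized rows.
#'
#' @param seg a [Segmentation-class].
#' @param tracks a [SignalTrack-class] or list of them.
#' @param sampleVariance if `TRUE`, divide by n-1 instead of n.
#' @return A [SignalStats-class].
#' @export
signalDistribution <- function(seg, tracks, sampleVariance = FALSE) {
  if (is(tracks, "SignalTrack")) tracks <- list(tracks)
  if (!length(tracks)) stop("at least one signal track required", call. = FALSE)
  nm <- vapply(tracks, trackName, character(1))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  labs <- labelSet(seg)
  sizes <- do.call(.chromSizes, c(list(seg), tracks))
  codes <- .labelRle(seg, sizes)
  rows <- list()
  for (ti in seq_along(tracks)) {
    tv <- signalValues(tracks[[ti]])
    for (li in seq_along(labs)) {
      n <- 0; s1 <- 0
      runs <- list()
      for (ch in names(codes)) {
        if (!ch %in% names(tv)) next
        v <- tv[[ch]]
        cl <- codes[[ch]]
        if (length(v) < length(cl)) v <- c(v, Rle(NA_real_, length(cl) - length(v)))
        sel <- v[cl == li]
        rv <- runValue(sel); rl <- runLength(sel)
        ok <- !is.na(rv)
        if (any(ok)) {
          runs[[length(runs) + 1L]] <- cbind(rv[ok], rl[ok])
          n <- n + sum(rl[ok])
          s1 <- s1 + sum(rv[ok] * rl[ok])
        }
      }
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          track = nm[ti], label = labs[li], n = 0L, mean = NA_real_,
          variance = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
        next
      }
      mu <- s1 / n
      ss <- sum(vapply(runs, function(m) sum(m[, 2] * (m[, 1] - mu)^2),
                       numeric(1)))
      va <- if (sampleVariance) {
        if (n > 1) ss / (n - 1) else NA_real_
      } else ss / n
      rows[[length(rows) + 1L]] <- data.frame(
        track = nm[ti], label = labs[li], n = n, mean = mu, variance = va,
        sd = sqrt(va), stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, rows)
  if (any(stats$n == 0))
    warning(sprintf("%d (track, label) cell(s) cover no data-bearing base; flagged missing",
                    sum(stats$n == 0)), call. = FALSE)
  means <- matrix(stats$mean, length(tracks), length(labs), byrow = TRUE,
                  dimnames = list(nm, labs))
  sds <- matrix(stats$sd, length(tracks), length(labs), byrow = TRUE,
                dimnames = list(nm, labs))
  norm <- t(apply(means, 1L, function(r) {
    rng <- range(r, na.rm = TRUE)
    if (!is.finite(rng[1])) return(rep(NA_real_, length(r)))
    if (rng[1] == rng[2]) return(ifelse(is.na(r), NA_real_, 0.5))
    (r - rng[1]) / (rng[2] - rng[1])
  }))
  dim(norm) <- dim(means); dimnames(norm) <- dimnames(means)
  maxSd <- suppressWarnings(max(sds, na.rm = TRUE))
  sdRel <- if (is.finite(maxSd) && maxSd > 0) sds / maxSd else sds * 0
  rowOrder <- .clusterOrder(norm)
  colOrder <- .clusterOrder(t(norm))
  new("SignalStats", stats = stats, normalized = norm, sdRel = sdRel,
      rowOrder = rowOrder, colOrder = colOrder)
}

## deterministic average-linkage leaf order; degenerate sizes pass through
.clusterOrder <- function(m) {
  if (nrow(m) < 3L) return(seq_len(nrow(m)))
  d <- dist(m)
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE) + 1
  as.integer(hclust(d, method = "average")$order)
}
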