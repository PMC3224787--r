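#' @importFrom stats setNames
NULL

## background frequency f_rand per label: the label's share of all bases
## covered by the segmentation (not of the genome)
.fRand <- function(seg) {
  b <- .labelBases(seg)
  b / sum(b)
}

.GENE_COMPONENTS <- c("5' flank", "initial exon", "initial intron",
                      "internal exons", "internal introns", "terminal intron",
                      "terminal exon", "3' flank")

#' Idealized components of a gene model
#'
#' Decomposes the representative transcript into the eight idealized gene
#' components: 5' flank, initial exon, initial intron, internal exons,
#' internal introns, terminal intron, terminal exon, 3' flank. "Initial" and
#' "terminal" are in transcription direction, so the initial exon of a
#' minus-strand gene is its rightmost. A 2-exon gene's single intron counts
#' as the initial intron only, and a single-exon gene's exon as the initial
#' exon only (no double counting). Flanks are ideal `flank`-base windows and
#' may extend beyond chromosome bounds; consumers clip per base.
#'
#' @param gene a [GeneModel-class].
#' @param flank flank size in bases.
#' @return data.frame with columns component, start, end (1-based genomic
#'   coordinates), one row per component instance, possibly zero rows for
#'   missing components.
#' @export
geneComponents <- function(gene, flank = 5000) {
  ex <- gene@exons
  n <- length(ex)
  minus <- gene@strand == "-"
  rows <- list()
  add <- function(comp, s, e) {
    if (e >= s)
      rows[[length(rows) + 1L]] <<- data.frame(
        component = comp, start = s, end = e, stringsAsFactors = FALSE)
  }
  # exons in transcription order
  txOrder <- if (minus) rev(seq_len(n)) else seq_len(n)
  add("initial exon", start(ex)[txOrder[1L]], end(ex)[txOrder[1L]])
  if (n >= 2L)
    add("terminal exon", start(ex)[txOrder[n]], end(ex)[txOrder[n]])
  if (n >= 3L)
    for (k in txOrder[2:(n - 1L)])
      add("internal exons", start(ex)[k], end(ex)[k])
  # introns: gaps between genomically consecutive exons, in tx order
  if (n >= 2L) {
    gs <- end(ex)[-n] + 1L
    ge <- start(ex)[-1L] - 1L
    keep <- ge >= gs
    gs <- gs[keep]; ge <- ge[keep]
    m <- length(gs)
    if (m) {
      iOrder <- if (minus) rev(seq_len(m)) else seq_len(m)
      add("initial intron", gs[iOrder[1L]], ge[iOrder[1L]])
      if (m >= 2L)
        add("terminal intron", gs[iOrder[m]], ge[iOrder[m]])
      if (m >= 3L)
        for (k in iOrder[2:(m - 1L)])
          add("internal introns", gs[k], ge[k])
    }
  }
  gStart <- min(start(ex)); gEnd <- max(end(ex))
  if (flank >= 1L) {
    if (minus) {
      add("5' flank", gEnd + 1L, gEnd + flank)
      add("3' flank", gStart - flank, gStart - 1L)
    } else {
      add("5' flank", gStart - flank, gStart - 1L)
      add("3' flank", gEnd + 1L, gEnd + flank)
    }
  }
  out <- do.call(rbind, rows)
  out$component <- factor(out$component, levels = .GENE_COMPONENTS)
  out[order(out$component), , drop = FALSE]
}

## assemble the AggregationProfile table from accumulated counts
## counts: list group -> list comp -> matrix nlab x nbin
## denom:  list group -> list comp -> numeric nbin
.profileTable <- function(counts, denom, binsOf, labs, fRand) {
  rows <- list()
  for (grp in names(counts)) for (comp in names(counts[[grp]])) {
    cnt <- counts[[grp]][[comp]]
    den <- denom[[grp]][[comp]]
    bins <- binsOf[[comp]]
    fObs <- sweep(cnt, 2L, ifelse(den > 0, den, NA_real_), "/")
    for (li in seq_along(labs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, component = comp, bin = unname(bins),
        label = labs[li], count = unname(cnt[li, ]),
        n_features = unname(den),
        f_obs = unname(fObs[li, ]), f_rand = unname(fRand[li]),
        enrichment = unname(enrichment(fObs[li, ], fRand[li])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label enrichment around point features
#'
#' Aggregates a segmentation around anchor points (e.g. TSSs): for every
#' offset in `-flank..flank` relative to each feature's anchor base (the
#' midpoint of multi-base records), the frequency `f_obs` at which each label
#' is observed is compared to the label's background abundance `f_rand` via
#' `e = log2((f_obs+1)/(f_rand+1))`. Minus-strand features have their offset
#' axis reversed, so positive offsets are always downstream in transcription
#' direction. Offsets falling outside the chromosome are excluded from that
#' offset's denominator. A profile is computed per feature group.
#'
#' @param seg a [Segmentation-class].
#' @param features an [Annotation-class] of point (or short) features.
#' @param flank window half-width in bases (offsets `-flank..flank`).
#' @param chromSizes optional named chromosome lengths.
#' @param coveredOnly if `TRUE`, per-offset denominators count only features
#'   whose base at the offset is covered by some segment; by default
#'   uncovered bases stay in the denominator, so frequencies over labels at
#'   an offset may sum to less than 1.
#' @return An [AggregationProfile-class] (`mode = "point"`, `bin` = offset).
#' @export
aggregatePoints <- function(seg, features, flank = 5000, chromSizes = NULL,
                            coveredOnly = FALSE) {
  stopifnot(flank >= 1)
  fgr <- intervals(features)
  segChroms <- unique(as.character(seqnames(intervals(seg))))
  if (!any(as.character(seqnames(fgr)) %in% segChroms))
    stop("no features on any segmentation chromosome", call. = FALSE)
  sizes <- .chromSizes(seg, features, sizes = chromSizes)
  labs <- labelSet(seg)
  codesRle <- .labelRle(seg, sizes)
  fRand <- .fRand(seg)
  offsets <- seq.int(-flank, flank)
  noff <- length(offsets)
  groups <- groupSet(features)
  anchors <- (start(fgr) - 1L + end(fgr)) %/% 2L + 1L  # midpoint base
  st <- .effectiveStrand(strand(fgr), "feature")
  sign <- ifelse(st == "-", -1L, 1L)
  chn <- as.character(seqnames(fgr))
  grpv <- mcols(fgr)$group
  counts <- denom <- list()
  for (grp in groups) {
    cnt <- matrix(0, length(labs), noff)
    den <- numeric(noff)
    for (ch in unique(chn[grpv == grp])) {
      if (!ch %in% names(sizes)) next
      idx <- which(chn == ch & grpv == grp)
      iv <- as.integer(codesRle[[ch]])
      pos <- matrix(anchors[idx], length(idx), noff) +
             outer(sign[idx], offsets)
      valid <- pos >= 1L & pos <= sizes[[ch]]
      code <- matrix(NA_integer_, length(idx), noff)
      code[valid] <- iv[pos[valid]]
      den <- den + if (coveredOnly)
        colSums(valid & !is.na(code) & code > 0L) else colSums(valid)
      for (li in seq_along(labs))
        cnt[li, ] <- cnt[li, ] + colSums(code == li, na.rm = TRUE)
    }
    counts[[grp]] <- list(point = cnt)
    denom[[grp]] <- list(point = den)
  }
  tab <- .profileTable(counts, denom, list(point = offsets), labs, fRand)
  new("AggregationProfile", table = tab, mode = "point", labels = labs,
      params = list(flank = flank, coveredOnly = coveredOnly))
}

#' Label enrichment across rescaled regions
#'
#' Each region is linearly rescaled onto a fixed axis of `bins` bins: the
#' base at fractional position p of its region contributes to bin
#' `floor(p * bins)`. Minus-strand regions are traversed in transcription
#' direction. With `flank > 0`, ideal flank windows of that many bases are
#' added upstream and downstream (components `"5' flank"` and `"3' flank"`),
#' each rescaled to the same number of bins; bases beyond chromosome bounds
#' are dropped from their bins. Profiles are computed per region group.
#'
#' @param seg a [Segmentation-class].
#' @param regions an [Annotation-class] of regions.
#' @param bins number of bins on the region axis.
#' @param flank flank size in bases (0 = body only).
#' @param chromSizes optional named chromosome lengths.
#' @return An [AggregationProfile-class] (`mode = "region"`).
#' @export
aggregateRegions <- function(seg, regions, bins = 50, flank = 0,
                             chromSizes = NULL) {
  stopifnot(bins >= 1)
  fgr <- intervals(regions)
  segChroms <- unique(as.character(seqnames(intervals(seg))))
  if (!any(as.character(seqnames(fgr)) %in% segChroms))
    stop("no features on any segmentation chromosome", call. = FALSE)
  sizes <- .chromSizes(seg, regions, sizes = chromSizes)
  labs <- labelSet(seg)
  codesRle <- .labelRle(seg, sizes)
  fRand <- .fRand(seg)
  comps <- if (flank > 0) c("5' flank", "body", "3' flank") else "body"
  groups <- groupSet(regions)
  st <- .effectiveStrand(strand(fgr), "region")
  chn <- as.character(seqnames(fgr))
  grpv <- mcols(fgr)$group
  ivCache <- list()
  getIv <- function(ch) {
    if (is.null(ivCache[[ch]]))
      ivCache[[ch]] <<- as.integer(codesRle[[ch]])
    ivCache[[ch]]
  }
  counts <- denom <- list()
  for (grp in groups) {
    cnt <- lapply(comps, function(x) matrix(0, length(labs), bins))
    den <- lapply(comps, function(x) numeric(bins))
    names(cnt) <- names(den) <- comps
    for (k in which(grpv == grp)) {
      ch <- chn[k]
      if (!ch %in% names(sizes)) next
      iv <- getIv(ch)
      minus <- st[k] == "-"
      inst <- data.frame(component = "body", start = start(fgr)[k],
                         end = end(fgr)[k])
      if (flank > 0) {
        gS <- start(fgr)[k]; gE <- end(fgr)[k]
        inst <- rbind(inst, data.frame(
          component = c("5' flank", "3' flank"),
          start = if (minus) c(gE + 1L, gS - flank) else c(gS - flank, gE + 1L),
          end = if (minus) c(gE + flank, gS - 1L) else c(gS - 1L, gE + flank)))
      }
      for (r in seq_len(nrow(inst))) {
        upd <- .binOneInstance(iv, sizes[[ch]], inst$start[r], inst$end[r],
                               minus, bins,
                               cnt[[inst$component[r]]],
                               den[[inst$component[r]]], length(labs))
        cnt[[inst$component[r]]] <- upd$cnt
        den[[inst$component[r]]] <- upd$den
      }
    }
    counts[[grp]] <- cnt
    denom[[grp]] <- den
  }
  binsOf <- setNames(rep(list(seq_len(bins) - 1L), length(comps)), comps)
  tab <- .profileTable(counts, denom, binsOf, labs, fRand)
  new("AggregationProfile", table = tab, mode = "region", labels = labs,
      params = list(bins = bins, flank = flank))
}

## bin the bases of one (possibly partly out-of-chromosome) instance
.binOneInstance <- function(iv, size, s, e, minus, bins, cnt, den, nlab) {
  if (e < s) return(list(cnt = cnt, den = den))
  idealL <- e - s + 1L
  pos <- s:e
  idx0 <- if (minus) rev(seq_len(idealL)) - 1L else seq_len(idealL) - 1L
  ok <- pos >= 1L & pos <= size
  if (!any(ok)) return(list(cnt = cnt, den = den))
  pos <- pos[ok]; idx0 <- idx0[ok]
  codes <- iv[pos]
  bin <- pmin(bins - 1L, (idx0 * bins) %/% idealL) + 1L
  den <- den + tabulate(bin, nbins = bins)
  covered <- codes > 0L
  if (any(covered)) {
    add <- rowsum(.tabulateRows(bin[covered], bins), codes[covered])
    cnt[as.integer(rownames(add)), ] <-
      cnt[as.integer(rownames(add)), , drop = FALSE] + add
  }
  list(cnt = cnt, den = den)
}

## one-hot rows for rowsum accumulation: n x bins incidence matrix
.tabulateRows <- function(bin, bins) {
  m <- matrix(0L, length(bin), bins)
  m[cbind(seq_along(bin), bin)] <- 1L
  m
}

#' Label enrichment along idealized gene components
#'
#' Pools, across genes, the eight idealized components (see
#' [geneComponents()]); each component instance is rescaled to a fixed axis
#' of `bins` bins exactly as in region mode, and minus-strand genes are
#' traversed in transcription direction. Missing components (a 2-exon gene
#' has no internal exon) contribute nothing.
#'
#' @param seg a [Segmentation-class].
#' @param genes list of [GeneModel-class], e.g. from [readGenes()].
#' @param bins bins per component.
#' @param flank flank size in bases for the 5'/3' flank components.
#' @param chromSizes optional named chromosome lengths.
#' @return An [AggregationProfile-class] (`mode = "gene"`, single group
#'   `"genes"`).
#' @export
aggregateGenes <- function(seg, genes, bins = 50, flank = 5000,
                           chromSizes = NULL) {
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  stopifnot(bins >= 1)
  geneGr <- GRanges(
    vapply(genes, function(g) g@chrom, character(1)),
    IRanges(vapply(genes, function(g) min(start(g@exons)), numeric(1)),
            vapply(genes, function(g) max(end(g@exons)), numeric(1))))
  sizes <- .chromSizes(seg, geneGr, sizes = chromSizes)
  labs <- labelSet(seg)
  codesRle <- .labelRle(seg, sizes)
  fRand <- .fRand(seg)
  cnt <- lapply(.GENE_COMPONENTS, function(x) matrix(0, length(labs), bins))
  den <- lapply(.GENE_COMPONENTS, function(x) numeric(bins))
  names(cnt) <- names(den) <- .GENE_COMPONENTS
  ivCache <- list()
  for (g in genes) {
    ch <- g@chrom
    if (!ch %in% names(sizes)) next
    if (is.null(ivCache[[ch]])) ivCache[[ch]] <- as.integer(codesRle[[ch]])
    iv <- ivCache[[ch]]
    minus <- g@strand == "-"
    inst <- geneComponents(g, flank = flank)
    for (r in seq_len(nrow(inst))) {
      comp <- as.character(inst$component[r])
      upd <- .binOneInstance(iv, sizes[[ch]], inst$start[r], inst$end[r],
                             minus, bins, cnt[[comp]], den[[comp]],
                             length(labs))
      cnt[[comp]] <- upd$cnt
      den[[comp]] <- upd$den
    }
  }
  binsOf <- setNames(rep(list(seq_len(bins) - 1L), length(.GENE_COMPONENTS)),
                     .GENE_COMPONENTS)
  tab <- .profileTable(list(genes = cnt), list(genes = den), binsOf, labs,
                       fRand)
  new("AggregationProfile", table = tab, mode = "gene", labels = labs,
      params = list(bins = bins, flank = flank))
}
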