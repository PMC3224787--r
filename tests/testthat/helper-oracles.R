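## Construction helpers and independent brute-force oracles. The oracles work
## on plain R vectors (one element per base) so they share no code with the
## interval machinery they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

mkgr <- function(starts, ends, chrom = "chr1", strand = "*") {
  GRanges(chrom, IRanges(starts, ends), strand = strand)
}

mkseg <- function(starts, ends, labels, chrom = "chr1", vocab = NULL) {
  Segmentation(mkgr(starts, ends, chrom), label = labels, labels = vocab)
}

mkann <- function(starts, ends, groups = NULL, chrom = "chr1", strand = "*") {
  Annotation(mkgr(starts, ends, chrom, strand), group = groups)
}

## per-base label vector (NA = uncovered) for one chromosome of a
## Segmentation-like table: starts/ends 1-based closed
base_labels <- function(starts, ends, labels, size) {
  v <- rep(NA_character_, size)
  for (k in seq_along(starts)) v[starts[k]:ends[k]] <- labels[k]
  v
}

seg_base_labels <- function(seg, sizes) {
  gr <- intervals(seg)
  chn <- as.character(seqnames(gr))
  out <- list()
  for (ch in names(sizes)) {
    i <- which(chn == ch)
    out[[ch]] <- base_labels(start(gr)[i], end(gr)[i],
                             mcols(gr)$label[i], sizes[[ch]])
  }
  out
}

## brute-force flatten: per-base subset membership, then merged runs
oracle_flatten <- function(inputs, names, sizes, sep = "-") {
  rows <- NULL
  for (ch in names(sizes)) {
    n <- sizes[[ch]]
    mem <- matrix(FALSE, n, length(inputs))
    for (i in seq_along(inputs)) {
      gr <- intervals(inputs[[i]])
      idx <- which(as.character(seqnames(gr)) == ch)
      for (k in idx)
        mem[max(1, start(gr)[k]):min(n, end(gr)[k]), i] <- TRUE
    }
    lab <- apply(mem, 1, function(m)
      if (any(m)) paste(sort(names[m]), collapse = sep) else NA_character_)
    # merge runs
    r <- rle(lab)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    keep <- !is.na(r$values)
    if (any(keep))
      rows <- rbind(rows, data.frame(chrom = ch, start = s[keep],
                                     end = e[keep], label = r$values[keep]))
  }
  rows
}

## brute-force transitions: consecutive sorted segments per chromosome
oracle_transitions <- function(seg, labs) {
  gr <- intervals(seg)
  cnt <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (ch in unique(as.character(seqnames(gr)))) {
    i <- which(as.character(seqnames(gr)) == ch)
    i <- i[order(start(gr)[i])]
    if (length(i) < 2) next
    l <- mcols(gr)$label[i]
    for (k in seq_len(length(i) - 1))
      cnt[l[k], l[k + 1]] <- cnt[l[k], l[k + 1]] + 1L
  }
  cnt
}

## brute-force nearest-feature distances (signed)
oracle_feature_distance <- function(seg, features) {
  sgr <- intervals(seg); fgr <- intervals(features)
  out <- numeric(length(sgr))
  for (k in seq_along(sgr)) {
    ch <- as.character(seqnames(sgr))[k]
    fi <- which(as.character(seqnames(fgr)) == ch)
    if (!length(fi)) { out[k] <- NA_real_; next }
    best <- Inf
    for (f in fi) {
      if (start(fgr)[f] <= end(sgr)[k] && end(fgr)[f] >= start(sgr)[k]) d <- 0
      else if (end(fgr)[f] < start(sgr)[k]) d <- end(fgr)[f] - start(sgr)[k] + 1
      else d <- start(fgr)[f] - end(sgr)[k] - 1
      if (abs(d) < abs(best)) best <- d
    }
    out[k] <- best
  }
  out
}

## brute-force per-cell overlap: nested loops over interval pairs
oracle_overlap <- function(seg, ann, minOverlap = 1) {
  sgr <- intervals(seg); agr <- intervals(ann)
  labs <- labelSet(seg); grps <- groupSet(ann)
  bases <- matrix(0, length(labs), length(grps), dimnames = list(labs, grps))
  segHits <- recHits <- matrix(0L, length(labs), length(grps),
                               dimnames = list(labs, grps))
  for (g in grps) {
    ai <- which(mcols(agr)$group == g)
    # merged per-group base set, per chromosome
    for (l in labs) {
      si <- which(mcols(sgr)$label == l)
      tot <- 0
      for (ch in unique(as.character(seqnames(sgr))[si])) {
        n <- max(end(sgr), end(agr))
        covA <- rep(FALSE, n)
        for (a in ai[as.character(seqnames(agr))[ai] == ch])
          covA[start(agr)[a]:end(agr)[a]] <- TRUE
        for (s in si[as.character(seqnames(sgr))[si] == ch])
          tot <- tot + sum(covA[start(sgr)[s]:end(sgr)[s]])
      }
      bases[l, g] <- tot
      hitSeg <- 0L
      for (s in si) {
        ov <- FALSE
        for (a in ai) {
          if (as.character(seqnames(sgr))[s] != as.character(seqnames(agr))[a]) next
          w <- min(end(sgr)[s], end(agr)[a]) - max(start(sgr)[s], start(agr)[a]) + 1
          if (w >= minOverlap) { ov <- TRUE; break }
        }
        if (ov) hitSeg <- hitSeg + 1L
      }
      segHits[l, g] <- hitSeg
      hitRec <- 0L
      for (a in ai) {
        ov <- FALSE
        for (s in si) {
          if (as.character(seqnames(sgr))[s] != as.character(seqnames(agr))[a]) next
          w <- min(end(sgr)[s], end(agr)[a]) - max(start(sgr)[s], start(agr)[a]) + 1
          if (w >= minOverlap) { ov <- TRUE; break }
        }
        if (ov) hitRec <- hitRec + 1L
      }
      recHits[l, g] <- hitRec
    }
  }
  list(bases = bases, segHits = segHits, recHits = recHits)
}

## brute-force pairwise label base-set symmetric difference
oracle_compare <- function(seg1, seg2, sizes) {
  l1 <- labelSet(seg1); l2 <- labelSet(seg2)
  b1 <- seg_base_labels(seg1, sizes)
  b2 <- seg_base_labels(seg2, sizes)
  d <- matrix(0, length(l1), length(l2), dimnames = list(l1, l2))
  for (x in l1) for (y in l2) {
    s <- 0
    for (ch in names(sizes)) {
      inx <- !is.na(b1[[ch]]) & b1[[ch]] == x
      iny <- !is.na(b2[[ch]]) & b2[[ch]] == y
      s <- s + sum(xor(inx, iny))
    }
    d[x, y] <- s
  }
  d
}

## brute-force signal stats: loop over every covered base
oracle_signal_stats <- function(seg, track, sizes) {
  labs <- labelSet(seg)
  bl <- seg_base_labels(seg, sizes)
  vals <- lapply(names(sizes), function(ch) {
    v <- as.numeric(signalValues(track)[[ch]])
    length(v) <- sizes[[ch]]   # pad with NA
    v
  })
  names(vals) <- names(sizes)
  out <- NULL
  for (l in labs) {
    xs <- numeric(0)
    for (ch in names(sizes)) {
      sel <- !is.na(bl[[ch]]) & bl[[ch]] == l & !is.na(vals[[ch]])
      xs <- c(xs, vals[[ch]][sel])
    }
    out <- rbind(out, data.frame(
      label = l, n = length(xs),
      mean = if (length(xs)) mean(xs) else NA_real_,
      variance = if (length(xs)) mean((xs - mean(xs))^2) else NA_real_))
  }
  out
}

## brute-force point aggregation: per-feature base lookup
oracle_aggregate_points <- function(seg, features, flank, sizes) {
  labs <- labelSet(seg)
  bl <- seg_base_labels(seg, sizes)
  fgr <- intervals(features)
  offs <- -flank:flank
  cnt <- matrix(0, length(labs), length(offs), dimnames = list(labs, offs))
  den <- setNames(numeric(length(offs)), offs)
  for (k in seq_along(fgr)) {
    ch <- as.character(seqnames(fgr))[k]
    if (!ch %in% names(sizes)) next
    anchor <- (start(fgr)[k] - 1 + end(fgr)[k]) %/% 2 + 1
    sgn <- if (as.character(strand(fgr))[k] == "-") -1 else 1
    for (j in seq_along(offs)) {
      p <- anchor + sgn * offs[j]
      if (p < 1 || p > sizes[[ch]]) next
      den[j] <- den[j] + 1
      l <- bl[[ch]][p]
      if (!is.na(l)) cnt[l, j] <- cnt[l, j] + 1
    }
  }
  list(cnt = cnt, den = den)
}

## brute-force region binning: assign every base to floor(p*bins)
oracle_aggregate_regions <- function(seg, regions, bins, sizes) {
  labs <- labelSet(seg)
  bl <- seg_base_labels(seg, sizes)
  fgr <- intervals(regions)
  cnt <- matrix(0, length(labs), bins, dimnames = list(labs, NULL))
  den <- numeric(bins)
  for (k in seq_along(fgr)) {
    ch <- as.character(seqnames(fgr))[k]
    if (!ch %in% names(sizes)) next
    pos <- start(fgr)[k]:end(fgr)[k]
    if (as.character(strand(fgr))[k] == "-") pos <- rev(pos)
    L <- length(pos)
    for (i in seq_len(L)) {
      p <- pos[i]
      if (p < 1 || p > sizes[[ch]]) next
      b <- min(bins - 1, floor((i - 1) * bins / L)) + 1
      den[b] <- den[b] + 1
      l <- bl[[ch]][p]
      if (!is.na(l)) cnt[l, b] <- cnt[l, b] + 1
    }
  }
  list(cnt = cnt, den = den)
}

## brute-force mono/dinucleotide counting by string scan
oracle_nucfreq <- function(seg, fastaSeqs) {
  labs <- labelSet(seg)
  gr <- intervals(seg)
  bases <- c("A", "C", "G", "T")
  dinucs <- paste0(rep(bases, each = 4), bases)
  mono <- matrix(0, length(labs), 4, dimnames = list(labs, bases))
  di <- matrix(0, length(labs), 16, dimnames = list(labs, dinucs))
  for (k in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[k]
    l <- mcols(gr)$label[k]
    s <- toupper(substr(fastaSeqs[[ch]], start(gr)[k], end(gr)[k]))
    chars <- strsplit(s, "")[[1]]
    for (c1 in chars) if (c1 %in% bases) mono[l, c1] <- mono[l, c1] + 1
    if (length(chars) > 1)
      for (i in seq_len(length(chars) - 1)) {
        dn <- paste0(chars[i], chars[i + 1])
        if (dn %in% dinucs) di[l, dn] <- di[l, dn] + 1
      }
  }
  list(mono = mono, di = di)
}

## a small random annotation over one or more chromosomes
random_annotation <- function(sizes, n, groups = c("g1", "g2"), seed = 1) {
  set.seed(seed)
  ch <- sample(names(sizes), n, replace = TRUE)
  s <- vapply(ch, function(c2) sample.int(sizes[[c2]] - 10L, 1L), integer(1))
  w <- sample.int(200L, n, replace = TRUE)
  e <- pmin(s + w, vapply(ch, function(c2) sizes[[c2]], integer(1)))
  Annotation(GRanges(ch, IRanges(s, e),
                     strand = sample(c("+", "-"), n, TRUE)),
             group = sample(groups, n, TRUE))
}

## independent derivation of idealized gene components from exon coordinates
oracle_gene_components <- function(es, ee, strand, flank) {
  n <- length(es)
  comp <- list()
  push <- function(name, s, e) {
    if (e >= s) comp[[length(comp) + 1]] <<- list(name = name, s = s, e = e)
  }
  ord <- order(es)
  es <- es[ord]; ee <- ee[ord]
  exNames <- if (n == 1) "initial exon"
    else if (n == 2) {
      if (strand == "+") c("initial exon", "terminal exon")
      else c("terminal exon", "initial exon")
    } else {
      mid <- rep("internal exons", n - 2)
      if (strand == "+") c("initial exon", mid, "terminal exon")
      else c("terminal exon", mid, "initial exon")
    }
  if (n == 1 && strand == "-") exNames <- "initial exon"
  for (k in seq_len(n)) push(exNames[k], es[k], ee[k])
  if (n >= 2) {
    is <- ee[-n] + 1; ie <- es[-1] - 1
    keep <- ie >= is
    is <- is[keep]; ie <- ie[keep]
    m <- length(is)
    if (m >= 1) {
      inNames <- if (m == 1) "initial intron"
        else if (m == 2) {
          if (strand == "+") c("initial intron", "terminal intron")
          else c("terminal intron", "initial intron")
        } else {
          mid <- rep("internal introns", m - 2)
          if (strand == "+") c("initial intron", mid, "terminal intron")
          else c("terminal intron", mid, "initial intron")
        }
      if (m == 1 && strand == "-") inNames <- "initial intron"
      for (k in seq_len(m)) push(inNames[k], is[k], ie[k])
    }
  }
  if (flank >= 1) {
    if (strand == "+") {
      push("5' flank", es[1] - flank, es[1] - 1)
      push("3' flank", ee[n] + 1, ee[n] + flank)
    } else {
      push("5' flank", ee[n] + 1, ee[n] + flank)
      push("3' flank", es[1] - flank, es[1] - 1)
    }
  }
  comp
}

## brute-force gene-mode aggregation over all genes and components
oracle_aggregate_genes <- function(seg, genes, bins, flank, sizes) {
  labs <- labelSet(seg)
  bl <- seg_base_labels(seg, sizes)
  comps <- c("5' flank", "initial exon", "initial intron", "internal exons",
             "internal introns", "terminal intron", "terminal exon",
             "3' flank")
  cnt <- lapply(comps, function(x)
    matrix(0, length(labs), bins, dimnames = list(labs, NULL)))
  den <- lapply(comps, function(x) numeric(bins))
  names(cnt) <- names(den) <- comps
  for (g in genes) {
    ch <- g@chrom
    if (!ch %in% names(sizes)) next
    inst <- oracle_gene_components(start(g@exons), end(g@exons), g@strand,
                                   flank)
    for (ins in inst) {
      pos <- ins$s:ins$e
      if (g@strand == "-") pos <- rev(pos)
      L <- length(pos)
      for (i in seq_len(L)) {
        p <- pos[i]
        if (p < 1 || p > sizes[[ch]]) next
        b <- min(bins - 1, floor((i - 1) * bins / L)) + 1
        den[[ins$name]][b] <- den[[ins$name]][b] + 1
        l <- bl[[ch]][p]
        if (!is.na(l)) cnt[[ins$name]][l, b] <- cnt[[ins$name]][l, b] + 1
      }
    }
  }
  list(cnt = cnt, den = den)
}
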