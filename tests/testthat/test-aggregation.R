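test_that("the enrichment statistic obeys its defining identities", {
  expect_identical(enrichment(0.3, 0.3), 0)
  expect_equal(enrichment(3 / 4, 1 / 4), log2(1.4), tolerance = 1e-15)
  # monotone in f_obs for fixed f_rand, and within its analytic bounds
  fr <- 0.2
  es <- enrichment(seq(0, 1, by = 0.05), fr)
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= log2(1 / (fr + 1)) - 1e-12))
  expect_true(all(es <= log2(2 / (fr + 1)) + 1e-12))
})

test_that("a uniform single-label segmentation aggregates to zero enrichment", {
  seg <- mkseg(1, 1000, "A")
  feats <- mkann(c(200, 500, 800), c(200, 500, 800), groups = "p")
  prof <- aggregatePoints(seg, feats, flank = 50,
                          chromSizes = c(chr1 = 1000L))
  expect_true(all(prof@table$f_obs == 1))
  expect_true(all(prof@table$f_rand == 1))
  expect_true(all(prof@table$enrichment == 0))
})

test_that("point aggregation matches per-feature base lookup on random fixtures", {
  sizes <- c(chr1 = 9000L, chr2 = 6000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C"), meanLength = 90,
                          coverage = 0.7, seed = 51)
  feats <- random_annotation(sizes, 60, seed = 52)
  flank <- 30
  prof <- aggregatePoints(seg, feats, flank = flank, chromSizes = sizes)
  want <- oracle_aggregate_points(seg, feats, flank, sizes)
  for (grp in groupSet(feats)) {
    # oracle pools groups; rerun it per group
    sub <- Annotation(intervals(feats)[mcols(intervals(feats))$group == grp])
    wg <- oracle_aggregate_points(seg, sub, flank, sizes)
    tg <- prof@table[prof@table$group == grp, ]
    for (l in labelSet(seg)) {
      tl <- tg[tg$label == l, ]
      tl <- tl[order(tl$bin), ]
      expect_equal(tl$count, unname(wg$cnt[l, ]))
      expect_equal(tl$n_features, unname(wg$den))
      expect_equal(tl$f_obs, unname(wg$cnt[l, ] / wg$den), tolerance = 1e-9)
    }
  }
})

test_that("mean enrichment over offsets is near zero for random anchors", {
  sizes <- c(chr1 = 40000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B"), meanLength = 100,
                          coverage = 0.9, seed = 61)
  set.seed(62)
  pos <- sample.int(38000L, 500L) + 1000L
  feats <- Annotation(GRanges("chr1", IRanges(pos, pos)))
  prof <- aggregatePoints(seg, feats, flank = 20, chromSizes = sizes,
                          coveredOnly = TRUE)
  for (l in labelSet(seg)) {
    e <- prof@table$enrichment[prof@table$label == l]
    expect_lt(abs(mean(e)), 0.05)
  }
})

test_that("region aggregation rescales bases onto the bin axis", {
  seg <- mkseg(c(1, 51), c(50, 100), c("A", "B"))
  reg <- mkann(1, 100, groups = "r")
  prof <- aggregateRegions(seg, reg, bins = 2, chromSizes = c(chr1 = 100L))
  tab <- prof@table
  expect_equal(tab$f_obs[tab$label == "A" & tab$bin == 0], 1)
  expect_equal(tab$f_obs[tab$label == "B" & tab$bin == 1], 1)
  expect_equal(tab$f_obs[tab$label == "A" & tab$bin == 1], 0)
  # single region fully covered by one label
  prof1 <- aggregateRegions(mkseg(1, 100, "A"), reg, bins = 5,
                            chromSizes = c(chr1 = 100L))
  expect_true(all(prof1@table$f_obs[prof1@table$label == "A"] == 1))
})

test_that("region binning matches brute-force per-base assignment", {
  sizes <- c(chr1 = 10000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C", "D"),
                          meanLength = 70, coverage = 0.65, seed = 71)
  regs <- random_annotation(sizes, 100, groups = "r", seed = 72)
  bins <- 40
  prof <- aggregateRegions(seg, regs, bins = bins, chromSizes = sizes)
  want <- oracle_aggregate_regions(seg, regs, bins, sizes)
  tab <- prof@table[prof@table$component == "body", ]
  for (l in labelSet(seg)) {
    tl <- tab[tab$label == l, ]
    tl <- tl[order(tl$bin), ]
    expect_equal(tl$count, unname(want$cnt[l, ]))
    expect_equal(tl$n_features, want$den)
  }
})

test_that("gene components capture the degenerate exon-count rules", {
  ex2 <- IRanges(c(101L, 301L), c(200L, 400L))
  g2 <- new("GeneModel", geneId = "g2", chrom = "chr1", strand = "+",
            exons = ex2, transcripts = list(t = ex2))
  comp2 <- geneComponents(g2, flank = 10)
  cc <- as.character(comp2$component)
  expect_true(all(c("initial exon", "terminal exon", "initial intron") %in% cc))
  expect_false(any(c("internal exons", "internal introns",
                     "terminal intron") %in% cc))

  ex1 <- IRanges(101L, 200L)
  g1 <- new("GeneModel", geneId = "g1", chrom = "chr1", strand = "+",
            exons = ex1, transcripts = list(t = ex1))
  comp1 <- geneComponents(g1, flank = 10)
  cc1 <- as.character(comp1$component)
  expect_true("initial exon" %in% cc1)
  expect_false("terminal exon" %in% cc1)
  expect_false(any(grepl("intron", cc1)))
})

test_that("a gene fully covered by one label has f_obs 1 in every component bin", {
  ex <- IRanges(c(1001L, 1301L, 1601L), c(1100L, 1400L, 1700L))
  g <- new("GeneModel", geneId = "g", chrom = "chr1", strand = "+",
           exons = ex, transcripts = list(t = ex))
  seg <- mkseg(1, 5000, "A")
  prof <- aggregateGenes(seg, list(g = g), bins = 10, flank = 100,
                         chromSizes = c(chr1 = 5000L))
  tab <- prof@table
  withData <- tab$n_features > 0
  expect_true(all(tab$f_obs[withData & tab$label == "A"] == 1))
  expect_true(any(withData))
})

test_that("exon/intron-true labels localize to their components across genes", {
  sizes <- c(chr1 = 120000L)
  genes <- makeGenes(sizes, nGenes = 30, exonCountRange = c(2L, 5L),
                     seed = 81, gapMean = 800)
  # label exon bases E and intron bases I, everything from the genes
  rows <- list()
  for (g in genes) {
    ex <- g@exons
    for (k in seq_along(ex))
      rows[[length(rows) + 1L]] <- data.frame(
        s = start(ex)[k], e = end(ex)[k], l = "E")
    if (length(ex) > 1)
      for (k in seq_len(length(ex) - 1))
        if (start(ex)[k + 1] > end(ex)[k] + 1)
          rows[[length(rows) + 1L]] <- data.frame(
            s = end(ex)[k] + 1, e = start(ex)[k + 1] - 1, l = "I")
  }
  df <- do.call(rbind, rows)
  seg <- Segmentation(GRanges("chr1", IRanges(df$s, df$e)), label = df$l,
                      labels = c("E", "I"))
  prof <- aggregateGenes(seg, genes, bins = 8, flank = 200,
                         chromSizes = sizes)
  tab <- prof@table
  exonComps <- c("initial exon", "internal exons", "terminal exon")
  intronComps <- c("initial intron", "internal introns", "terminal intron")
  te <- tab[tab$component %in% exonComps & tab$n_features > 0, ]
  ti <- tab[tab$component %in% intronComps & tab$n_features > 0, ]
  expect_true(all(te$f_obs[te$label == "E"] == 1))
  expect_true(all(te$f_obs[te$label == "I"] == 0))
  expect_true(all(ti$f_obs[ti$label == "I"] == 1))
  expect_true(all(ti$f_obs[ti$label == "E"] == 0))
  expect_true(all(te$enrichment[te$label == "E"] > 0))
})

test_that("gene profiles are invariant under coordinate mirroring", {
  size <- 20000L
  ex <- IRanges(c(2001L, 2501L, 3001L), c(2200L, 2700L, 3300L))
  g <- new("GeneModel", geneId = "g", chrom = "chr1", strand = "+",
           exons = ex, transcripts = list(t = ex))
  seg <- mkseg(c(1801L, 2001L, 2201L), c(2000L, 2200L, 3400L),
               c("U", "E", "X"))
  # mirrored fixture: pos' = size + 1 - pos, strand flipped
  flipIr <- function(ir) IRanges(size + 1L - end(ir), size + 1L - start(ir))
  exM <- flipIr(ex)
  exM <- exM[order(start(exM))]
  gM <- new("GeneModel", geneId = "g", chrom = "chr1", strand = "-",
            exons = exM, transcripts = list(t = exM))
  grM <- intervals(seg)
  segM <- Segmentation(GRanges("chr1", flipIr(ranges(grM))),
                       label = mcols(grM)$label, labels = labelSet(seg))
  p1 <- aggregateGenes(seg, list(g = g), bins = 10, flank = 300,
                       chromSizes = c(chr1 = size))
  p2 <- aggregateGenes(segM, list(g = gM), bins = 10, flank = 300,
                       chromSizes = c(chr1 = size))
  expect_equal(p1@table$count, p2@table$count)
  expect_equal(p1@table$n_features, p2@table$n_features)
  expect_equal(p1@table$enrichment, p2@table$enrichment)
})

test_that("aggregation requires features on a segmentation chromosome", {
  seg <- mkseg(1, 100, "A")
  far <- Annotation(GRanges("chrZ", IRanges(1, 10)))
  expect_error(aggregatePoints(seg, far, flank = 5), "no features")
  expect_error(aggregateGenes(seg, list()), "empty gene list")
})

test_that("minus-strand point features reverse the offset axis", {
  # label B only downstream (right) of the anchor; minus-strand feature
  # at the same spot must see B at negative offsets instead
  seg <- mkseg(c(1, 101), c(100, 200), c("A", "B"))
  plus <- Annotation(GRanges("chr1", IRanges(100, 100), strand = "+"))
  minus <- Annotation(GRanges("chr1", IRanges(100, 100), strand = "-"))
  pp <- aggregatePoints(seg, plus, flank = 10, chromSizes = c(chr1 = 200L))
  pm <- aggregatePoints(seg, minus, flank = 10, chromSizes = c(chr1 = 200L))
  tp <- pp@table[pp@table$label == "B", ]
  tm <- pm@table[pm@table$label == "B", ]
  expect_equal(tp$count[tp$bin > 0], rep(1, 10))   # B downstream for +
  expect_equal(tm$count[tm$bin < 0], rep(1, 10))   # B upstream-offsets for -
  expect_equal(sum(tm$count[tm$bin > 0]), 0)
})
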