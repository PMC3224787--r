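test_that("overlap of identical interval sets gives perfect precision and recall", {
  seg <- mkseg(c(1, 51), c(20, 80), c("A", "A"))
  ann <- mkann(c(1, 51), c(20, 80), groups = c("g", "g"))
  ov <- segmentationOverlap(seg, ann)
  expect_equal(ov@pr$precision, 1)
  expect_equal(ov@pr$recall, 1)
  expect_equal(ov@bases["A", "g"], 50, ignore_attr = TRUE)
})

test_that("disjoint sets give zero overlap everywhere", {
  seg <- mkseg(1, 20, "A")
  ann <- mkann(100, 120, groups = "g")
  ov <- segmentationOverlap(seg, ann, precisionDenominator = "label")
  expect_equal(ov@bases["A", "g"], 0, ignore_attr = TRUE)
  expect_equal(ov@pr$precision, 0)
  expect_equal(ov@pr$recall, 0)
})

test_that("overlap counts match nested-loop recomputation on random fixtures", {
  sizes <- c(chr1 = 12000L, chr2 = 8000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C", "D"),
                          meanLength = 100, coverage = 0.6, seed = 91)
  ann <- random_annotation(sizes, 40, groups = c("g1", "g2"), seed = 92)
  ov <- suppressWarnings(segmentationOverlap(seg, ann))
  want <- oracle_overlap(seg, ann)
  expect_equal(unclass(ov@bases), want$bases, ignore_attr = TRUE)
  expect_equal(unclass(ov@segmentHits), want$segHits, ignore_attr = TRUE)
  expect_equal(unclass(ov@recordHits), want$recHits, ignore_attr = TRUE)
  # recall definition against totals
  for (g in groupSet(ann)) {
    tot <- sum(mcols(intervals(ann))$group == g)
    got <- ov@pr$recall[ov@pr$group == g]
    expect_equal(got, unname(want$recHits[, g] / tot), tolerance = 1e-9)
  }
})

test_that("minOverlap thresholds segment hits", {
  seg <- mkseg(c(1, 31), c(10, 60), c("A", "A"))
  ann <- mkann(c(8, 55), c(12, 70), groups = c("g", "g"))
  ov1 <- segmentationOverlap(seg, ann, minOverlap = 1)
  expect_equal(sum(ov1@segmentHits), 2)
  ov5 <- segmentationOverlap(seg, ann, minOverlap = 5)
  expect_equal(sum(ov5@segmentHits), 1)   # only the 6-base intersection stays
})

test_that("single-group overlap bases never exceed a label's own bases", {
  sizes <- c(chr1 = 9000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B"), meanLength = 80,
                          coverage = 0.6, seed = 95)
  ann <- random_annotation(sizes, 30, groups = "only", seed = 96)
  ov <- segmentationOverlap(seg, ann)
  expect_true(all(ov@bases[, "only"] <= ov@labelTotals$bases))
})

test_that("edit distance is a base-set symmetric difference", {
  s1 <- mkseg(1, 10, "x")
  s2 <- mkseg(6, 15, "y")
  cm <- compareSegmentations(s1, s2)
  expect_equal(cm@distance["x", "y"], 10, ignore_attr = TRUE)
  expect_equal(cm@jaccard["x", "y"], 5 / 15, ignore_attr = TRUE)
  # compared with itself: diagonal distance zero, Jaccard one
  seg <- makeSegmentation(c(chr1 = 5000L), labels = c("A", "B"),
                          meanLength = 60, coverage = 0.5, seed = 101)
  self <- compareSegmentations(seg, seg)
  expect_equal(unname(diag(self@distance)), c(0, 0))
  expect_equal(unname(diag(self@jaccard)), c(1, 1))
})

test_that("edit distances match per-base marking and satisfy the triangle inequality", {
  sizes <- c(chr1 = 7000L)
  s1 <- makeSegmentation(sizes, labels = c("A", "B", "C"), meanLength = 90,
                         coverage = 0.7, seed = 103)
  s2 <- makeSegmentation(sizes, labels = c("P", "Q"), meanLength = 120,
                         coverage = 0.5, seed = 104)
  cm <- compareSegmentations(s1, s2)
  expect_equal(unclass(cm@distance), oracle_compare(s1, s2, sizes),
               ignore_attr = TRUE)
  # triangle inequality among base sets of s1's labels
  self <- compareSegmentations(s1, s1)
  d <- self@distance
  for (a in 1:3) for (b in 1:3) for (c in 1:3)
    expect_lte(d[a, c], d[a, b] + d[b, c] + 1e-9)
})

test_that("signal statistics recover planted values exactly", {
  seg <- mkseg(c(1, 11), c(10, 20), c("A", "B"))
  tr <- makeSignal(seg, c(A = 4, B = 7), noiseSd = 0)
  ss <- signalDistribution(seg, tr)
  expect_equal(ss@stats$mean, c(4, 7))
  expect_equal(ss@stats$sd, c(0, 0))
  # two bases with values 1 and 3: mean 2, population variance 1
  seg1 <- mkseg(1, 2, "A")
  v <- RleList(chr1 = Rle(c(1, 3)))
  tr1 <- new("SignalTrack", values = v, name = "t")
  ss1 <- signalDistribution(seg1, tr1)
  expect_equal(ss1@stats$mean, 2)
  expect_equal(ss1@stats$variance, 1)
  ssSample <- signalDistribution(seg1, tr1, sampleVariance = TRUE)
  expect_equal(ssSample@stats$variance, 2)
})

test_that("signal means and variances match per-base accumulation", {
  sizes <- c(chr1 = 6000L, chr2 = 4000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C"), meanLength = 80,
                          coverage = 0.6, seed = 111)
  tr <- makeSignal(seg, c(A = 0, B = 2, C = -1), noiseSd = 1.5, seed = 112)
  ss <- signalDistribution(seg, tr)
  want <- oracle_signal_stats(seg, tr, sizes)
  expect_equal(ss@stats$n, want$n)
  expect_equal(ss@stats$mean, want$mean, tolerance = 1e-9)
  expect_equal(ss@stats$variance, want$variance, tolerance = 1e-9)
})

test_that("row normalization maps each track to [0,1] and is shift-invariant", {
  sizes <- c(chr1 = 5000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C"), meanLength = 60,
                          coverage = 0.7, seed = 115)
  t1 <- makeSignal(seg, c(A = 0, B = 1, C = 3), noiseSd = 0.5, seed = 116,
                   name = "t1")
  t2 <- makeSignal(seg, c(A = 5, B = 2, C = 2), noiseSd = 0.5, seed = 117,
                   name = "t2")
  ss <- signalDistribution(seg, list(t1, t2))
  expect_equal(unname(apply(ss@normalized, 1, min)), c(0, 0))
  expect_equal(unname(apply(ss@normalized, 1, max)), c(1, 1))
  # adding a constant to one track changes no displayed cell of its row
  t1shift <- makeSignal(seg, c(A = 100, B = 101, C = 103), noiseSd = 0.5,
                        seed = 116, name = "t1")
  ss2 <- signalDistribution(seg, list(t1shift, t2))
  expect_equal(ss2@normalized, ss@normalized, tolerance = 1e-9)
  expect_equal(ss2@rowOrder, ss@rowOrder)
  expect_equal(ss2@colOrder, ss@colOrder)
})

test_that("constant rows normalize to 0.5 and empty cells are flagged missing", {
  seg <- mkseg(c(1, 11), c(10, 20), c("A", "B"))
  flat <- makeSignal(seg, c(A = 3, B = 3), noiseSd = 0)
  ss <- signalDistribution(seg, flat)
  expect_equal(unname(ss@normalized[1, ]), c(0.5, 0.5))
  # a track with data only where no segment lies -> missing cells + warning
  v <- RleList(chr1 = Rle(c(NA_real_, NA_real_), c(20, 30)))
  empty <- new("SignalTrack", values = v, name = "empty")
  expect_warning(ss2 <- signalDistribution(seg, empty), "missing")
  expect_true(all(ss2@stats$n == 0))
  expect_true(all(is.na(ss2@stats$mean)))
})

test_that("clustered orders are deterministic permutations", {
  sizes <- c(chr1 = 4000L)
  seg <- makeSegmentation(sizes, labels = c("A", "B", "C", "D"),
                          meanLength = 50, coverage = 0.7, seed = 121)
  trs <- lapply(1:3, function(i)
    makeSignal(seg, setNames(rnorm(4, 0, 2), c("A", "B", "C", "D")),
               noiseSd = 0.2, seed = 121 + i, name = paste0("t", i)))
  set.seed(1)
  ss <- signalDistribution(seg, trs)
  expect_setequal(ss@rowOrder, 1:3)
  expect_setequal(ss@colOrder, 1:4)
  ssAgain <- signalDistribution(seg, trs)
  expect_identical(ss@rowOrder, ssAgain@rowOrder)
  expect_identical(ss@colOrder, ssAgain@colOrder)
})
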