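test_that("BED coordinates convert to the internal convention and back", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tA", "chr1\t100\t250\tB"), bed)
  seg <- readSegmentation(bed)
  gr <- intervals(seg)
  expect_equal(start(gr), c(1L, 101L))
  expect_equal(end(gr), c(100L, 250L))
  expect_equal(width(gr), c(100L, 150L))
  expect_equal(mcols(gr)$label, c("A", "B"))
  expect_equal(labelSet(seg), c("A", "B"))
  out <- withr::local_tempfile(fileext = ".bed")
  writeIntervals(seg, out)
  seg2 <- readSegmentation(out)
  expect_equal(as.character(seqnames(intervals(seg2))),
               as.character(seqnames(gr)))
  expect_equal(start(intervals(seg2)), start(gr))
  expect_equal(end(intervals(seg2)), end(gr))
  expect_equal(mcols(intervals(seg2))$label, mcols(gr)$label)
})

test_that("GFF record of start 1 end 100 spans 100 internal bases", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tregion\t1\t100\t.\t+\t.\tName=A",
               "chr1\tsrc\tregion\t151\t200\t.\t+\t.\tName=B"), gff)
  seg <- readSegmentation(gff)
  expect_equal(width(intervals(seg)), c(100L, 50L))
  expect_equal(start(intervals(seg)), c(1L, 151L))
  expect_equal(mcols(intervals(seg))$label, c("A", "B"))
  # GFF round trip
  out <- withr::local_tempfile(fileext = ".gff3")
  writeIntervals(seg, out, "gff")
  seg2 <- readSegmentation(out)
  expect_equal(start(intervals(seg2)), start(intervals(seg)))
  expect_equal(end(intervals(seg2)), end(intervals(seg)))
  expect_equal(mcols(intervals(seg2))$label, mcols(intervals(seg))$label)
})

test_that("overlapping intervals are rejected for segmentations but kept in annotations", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tA", "chr1\t50\t150\tB"), bed)
  expect_error(readSegmentation(bed), "overlap")
  ann <- readAnnotation(bed)
  expect_equal(length(ann), 2L)
  expect_equal(groupSet(ann), c("A", "B"))
})

test_that("segmentations require a name column; annotations default to one group", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t300"), bed)
  expect_error(readSegmentation(bed), "name column")
  ann <- readAnnotation(bed)
  expect_equal(groupSet(ann), "all")
  expect_equal(mcols(intervals(ann))$group, c("all", "all"))
})

test_that("annotation groups come from the name column", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tTSS_active", "chr1\t20\t30\tTSS_inactive",
               "chr1\t40\t50\tTSS_active"), bed)
  ann <- readAnnotation(bed)
  expect_setequal(groupSet(ann), c("TSS_active", "TSS_inactive"))
})

test_that("zero-length records are rejected", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5\t5\tA", bed)
  expect_error(readSegmentation(bed), "zero-length")
  expect_error(readAnnotation(bed), "zero-length")
})

test_that("GTF exons are grouped into gene models with derived structure", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr2\tx\texon\t11\t20\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";'),
    gtf)
  genes <- readGenes(gtf)
  expect_named(genes, c("g1", "g2"))
  g1 <- genes[["g1"]]
  expect_equal(start(g1@exons), c(101L, 301L, 501L))
  comp <- geneComponents(g1, flank = 50)
  expect_equal(comp$start[comp$component == "initial exon"], 101)
  expect_equal(comp$start[comp$component == "terminal exon"], 501)
  expect_equal(comp$start[comp$component == "internal exons"], 301)
  # introns are exactly the inter-exon gaps
  expect_equal(comp[comp$component == "initial intron", c("start", "end")],
               data.frame(start = 201, end = 300), ignore_attr = TRUE)
  expect_equal(comp[comp$component == "terminal intron", c("start", "end")],
               data.frame(start = 401, end = 500), ignore_attr = TRUE)
})

test_that("minus-strand genes order components in transcription direction", {
  ex <- IRanges(c(101L, 301L, 501L), c(200L, 400L, 600L))
  g <- new("GeneModel", geneId = "g", chrom = "chr1", strand = "-",
           exons = ex, transcripts = list(t1 = ex))
  comp <- geneComponents(g, flank = 100)
  expect_equal(comp$start[comp$component == "initial exon"], 501)
  expect_equal(comp$start[comp$component == "terminal exon"], 101)
  expect_equal(comp$start[comp$component == "5' flank"], 601)
  expect_equal(comp$end[comp$component == "3' flank"], 100)
})

test_that("multi-transcript genes keep the longest transcript by exonic bases", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "g"; transcript_id "g.short";',
    'chr1\tx\texon\t101\t300\t.\t+\t.\tgene_id "g"; transcript_id "g.long";'),
    gtf)
  genes <- readGenes(gtf)
  expect_equal(end(genes[["g"]]@exons), 300L)
  expect_equal(length(genes[["g"]]@transcripts), 2L)
})

test_that("bedGraph values are materialized per base with missing elsewhere", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t4\t2.5", bg)
  tr <- readSignal(bg, chromSizes = c(chr1 = 10L))
  v <- as.numeric(signalValues(tr)[["chr1"]])
  expect_equal(v[1:4], rep(2.5, 4))
  expect_true(all(is.na(v[5:10])))
})

test_that("fixedStep wiggle is read with 1-based starts", {
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "1", "2", "3"), wig)
  tr <- readSignal(wig)
  expect_equal(as.numeric(signalValues(tr)[["chr1"]]), c(1, 2, 3))
})

test_that("an empty signal file yields an all-missing track", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(), bg)
  tr <- readSignal(bg)
  expect_equal(length(signalValues(tr)), 0L)
})

test_that("overlapping bedGraph records are rejected", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), bg)
  expect_error(readSignal(bg), "overlap")
})

test_that("the Segmentation validity names the first offending pair", {
  gr <- mkgr(c(1, 50), c(100, 150))
  expect_error(Segmentation(gr, label = c("A", "B")),
               "\\[1, 100\\].*\\[50, 150\\]")
})
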