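test_that("tile matrix bins insertions with correct boundary handling", {
  # 0-based half-open [4998, 5003): insertions at 0-based 4998 and 5002
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4999, 5003),
                               barcode = "B1", count = 1L)
  tm <- buildTileMatrix(gr, c(chr1 = 20000), tileWidth = 5000L)
  m <- SummarizedExperiment::assay(tm)
  expect_equal(unname(m[1, 1]), 1)
  expect_equal(unname(m[2, 1]), 1)
  expect_equal(sum(m), 2)

  empty <- buildTileMatrix(gr[0], c(chr1 = 20000))
  expect_equal(sum(SummarizedExperiment::assay(empty)), 0)

  beyond <- GenomicRanges::GRanges("chr1", IRanges::IRanges(19999, 20050),
                                   barcode = "B1", count = 1L)
  expect_error(buildTileMatrix(beyond, c(chr1 = 20000)), "beyond")
  expect_error(buildTileMatrix(gr, c(chr9 = 1e5)), "missing")
})

test_that("tile matrix column sums equal simulated per-tile insertion truth", {
  sim <- simulateSpatialAtac(simConfig(seed = 13, nSpots = 8,
                                       readsPerSpot = 200, umiErrorRate = 0))
  ann <- attachBarcodes(sim$genomeAlignments,
                        buildReadBarcodeTable(sim$barcodeAlignments))$records
  frags <- makeFragments(deduplicateAlignments(ann), tn5Shift = c(0L, 0L))
  cl <- contigLengths(sim$genome)
  tm <- buildTileMatrix(frags, cl, tileWidth = 5000L)
  expect_equal(sum(SummarizedExperiment::assay(tm)), 2 * length(frags))

  # independent per-tile oracle from the molecule truth table
  mol <- sim$truth$molecules
  insPos0 <- c(mol$pos, mol$pos + mol$alignedLength - 1L)
  insContig <- c(mol$contig, mol$contig)
  oracle <- table(paste0(insContig, ":", insPos0 %/% 5000L))
  rowTotals <- Matrix::rowSums(SummarizedExperiment::assay(tm))
  tileKey <- paste0(as.character(GenomicRanges::seqnames(tm)), ":",
                    (GenomicRanges::start(tm) - 1L) %/% 5000L)
  expected <- as.numeric(oracle[tileKey])
  expected[is.na(expected)] <- 0
  expect_equal(unname(rowTotals), expected)
})

test_that("gene scores count body plus strand-aware promoter insertions", {
  genes <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                  IRanges::IRanges(c(10001, 50001),
                                                   c(20000, 60000)),
                                  strand = c("+", "-"),
                                  name = c("geneA", "geneB"))
  mkFrag <- function(pos) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                           barcode = "B1", count = 1L)
  }
  inBody <- geneScore(mkFrag(15000), genes)
  expect_equal(unname(SummarizedExperiment::assay(inBody)["geneA", 1]), 2)

  # 1,500 bp upstream of a forward-strand TSS counts; 2,500 does not
  up1500 <- geneScore(mkFrag(10001 - 1500), genes)
  expect_equal(unname(SummarizedExperiment::assay(up1500)["geneA", 1]), 2)
  up2500 <- geneScore(mkFrag(10001 - 2500), genes)
  expect_equal(unname(SummarizedExperiment::assay(up2500)["geneA", 1]), 0)
  # for the minus-strand gene the promoter is 3' in coordinates
  dn1500 <- geneScore(mkFrag(60000 + 1500), genes)
  expect_equal(unname(SummarizedExperiment::assay(dn1500)["geneB", 1]), 2)

  # additivity over fragment streams
  set.seed(4)
  frA <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(sample.int(70000, 50),
                                                 width = 100),
                                barcode = "B1", count = 1L)
  frB <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(sample.int(70000, 60),
                                                 width = 100),
                                barcode = "B1", count = 1L)
  both <- suppressWarnings(c(frA, frB))
  expect_equal(SummarizedExperiment::assay(geneScore(both, genes)),
               SummarizedExperiment::assay(geneScore(frA, genes)) +
                 SummarizedExperiment::assay(geneScore(frB, genes)))
})

test_that("a simulated accessible promoter ranks first among 50 genes", {
  set.seed(17)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1e4, by = 2e4,
                                                       length.out = 50),
                                                   width = 5000),
                                  strand = "+",
                                  name = sprintf("g%02d", 1:50))
  bgPos <- sample.int(1.1e6, 2000)
  hotTss <- GenomicRanges::start(genes)[25]
  hotPos <- hotTss + sample.int(3000, 500) - 1500
  fr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(pmax(1, c(bgPos, hotPos)),
                                                width = 80),
                               barcode = "B1", count = 1L)
  gs <- geneScore(fr, genes)
  totals <- Matrix::rowSums(SummarizedExperiment::assay(gs))
  expect_equal(names(which.max(totals)), "g25")
})

test_that("concordance flags concordant DE genes and reports correlation", {
  set.seed(23)
  dat <- simulateConcordanceData(nGenes = 200, nDE = 50)
  res <- concordanceAnalysis(dat$geneScores, dat$geneExpression, dat$clusters)
  called <- res$gene[res$pass]
  precision <- mean(called %in% dat$trueDE)
  expect_gte(precision, 0.9)
  expect_gte(sum(res$pass), 40)
  # concordant genes correlate positively across cluster means
  expect_gt(median(res$correlation[res$pass], na.rm = TRUE), 0.8)

  # tightening thresholds never adds genes (monotonicity)
  strict <- concordanceAnalysis(dat$geneScores, dat$geneExpression,
                                dat$clusters, lfcMin = 1.5, pMax = 0.01)
  expect_true(all(strict$gene[strict$pass] %in% called))

  # a gene with no between-cluster differences does not pass
  flat <- matrix(5, nrow = 2, ncol = length(dat$clusters),
                 dimnames = list(c("gA", "gB"), names(dat$clusters)))
  resFlat <- concordanceAnalysis(flat, flat, dat$clusters)
  expect_false(any(resFlat$pass))

  # identical per-cluster mean profiles in both modalities correlate at 1
  prof <- flat
  prof["gA", ] <- c(C1 = 2, C2 = 6, C3 = 12)[dat$clusters]
  resProf <- concordanceAnalysis(prof, prof, dat$clusters)
  expect_equal(resProf$correlation[resProf$gene == "gA"], 1)

  expect_error(concordanceAnalysis(flat, flat,
                                   setNames(rep("C1", ncol(flat)),
                                            colnames(flat))),
               "clusters")
})

test_that("vectorized rank-sum p-values match wilcox.test", {
  set.seed(6)
  m1 <- matrix(rpois(50, 5), nrow = 5)
  m2 <- matrix(rpois(40, 8), nrow = 5)
  p <- spatac:::rankSumP(m1, m2)
  pRef <- vapply(1:5, function(i) {
    suppressWarnings(stats::wilcox.test(m1[i, ], m2[i, ],
                                        exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(p, pRef, tolerance = 1e-10)
})
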