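test_that("window tiling, GC and blacklist handling behave as specified", {
  genome <- cnGenome(c(chr1 = 10000L))
  w <- makeGenomeWindows(genome, width = 3000, step = 1000)
  expect_equal(length(w), 8L)
  expect_equal(GenomicRanges::start(w) - 1L, seq(0L, 7000L, 1000L))
  expect_true(all(GenomicRanges::width(w) == 3000L))

  expect_error(makeGenomeWindows(genome, width = 2500, step = 1000),
               "multiple")

  # all-GC sequence has gc_fraction exactly 1
  gcOnly <- Biostrings::DNAStringSet(c(chrG = strrep("GC", 3000)))
  wG <- makeGenomeWindows(gcOnly, width = 3000, step = 1000)
  expect_true(all(S4Vectors::mcols(wG)$gc_fraction == 1))

  # a fully blacklisted window is dropped; partial blacklist shortens
  # effective length and changes GC accounting
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3500))
  wB <- makeGenomeWindows(genome, width = 3000, step = 1000, blacklist = bl)
  expect_false(any(GenomicRanges::start(wB) == 1L))  # [0,3000) fully masked
  first <- wB[GenomicRanges::start(wB) == 3001L]
  expect_equal(S4Vectors::mcols(first)$eff_length, 2500)

  # a contig shorter than one window yields a single whole-contig window
  small <- makeGenomeWindows(cnGenome(c(chrS = 2000L)), width = 3000,
                             step = 1000)
  expect_equal(length(small), 1L)
  expect_equal(GenomicRanges::width(small), 2000L)
})

test_that("uniform insertion density gives CN exactly 2; doubling gives 4", {
  genome <- cnGenome(c(chr1 = 20000L, chr2 = 20000L), seed = 3)
  w <- makeGenomeWindows(genome, width = 3000, step = 1000)
  frags <- gridFragments(contigLengths(genome), spacing = 200L)
  wcn <- suppressWarnings(windowCn(w, frags))
  expect_equal(S4Vectors::mcols(wcn)$log2fc, rep(0, length(wcn)))
  expect_equal(S4Vectors::mcols(wcn)$cn, rep(2, length(wcn)))

  # exactly doubling one region's density forces CN 4 there
  extra <- gridFragments(c(chr1 = 20000), spacing = 200L)
  both <- suppressWarnings(c(frags, extra))
  wcn2 <- suppressWarnings(windowCn(w, both))
  onChr1 <- as.character(GenomicRanges::seqnames(wcn2)) == "chr1"
  dens <- S4Vectors::mcols(wcn2)$insertions_per_bp
  expect_equal(unname(dens[onChr1] / dens[!onChr1][1]), rep(2, sum(onChr1)))

  # and the ratio_of_means mode agrees on a constant background
  wcn3 <- suppressWarnings(windowCn(w, frags, fcMode = "ratio_of_means"))
  expect_equal(S4Vectors::mcols(wcn3)$cn, rep(2, length(w)))
})

test_that("gene CN averages overlapping windows", {
  w <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(1, 1001), width = 1000),
                              gc_fraction = 0.5, eff_length = 1000,
                              insertions_per_bp = 0.1,
                              log2fc = c(log2(3), 2), cn = c(6, 8))
  S4Vectors::mcols(w)$cn <- c(6, 8)
  gene1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 900),
                                  name = "inOne")
  expect_equal(unname(geneCn(gene1, w)), 6)
  gene2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1200),
                                  name = "spansTwo")
  expect_equal(unname(geneCn(gene2, w)), 7)
  far <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 100),
                                name = "lost")
  expect_error(suppressWarnings(geneCn(far, w)), "lost")
})

test_that("CN is invariant to sequencing depth and centers at 2 when diploid", {
  genome <- cnGenome(c(chr1 = 30000L, chr2 = 30000L, chr3 = 30000L), seed = 5)
  w <- makeGenomeWindows(genome, width = 3000, step = 1000)
  set.seed(11)
  cl <- contigLengths(genome)
  n <- 6000
  ctg <- sample(names(cl), n, replace = TRUE)
  frags <- GenomicRanges::GRanges(ctg,
                                  IRanges::IRanges(
                                    floor(runif(n) * (cl[ctg] - 200)) + 1,
                                    width = 150),
                                  barcode = "B1", count = 1L)
  wcn <- suppressWarnings(windowCn(w, frags))
  expect_gte(median(S4Vectors::mcols(wcn)$cn), 1.8)
  expect_lte(median(S4Vectors::mcols(wcn)$cn), 2.2)

  # duplicating every fragment (2x depth) leaves CN unchanged up to the
  # empty-window pseudocount (1 insertion per window-length)
  deeper <- suppressWarnings(c(frags, frags))
  wcn2 <- suppressWarnings(windowCn(w, deeper))
  expect_equal(S4Vectors::mcols(wcn2)$cn, S4Vectors::mcols(wcn)$cn,
               tolerance = 1e-3)
})

test_that("per-spot CN separates diploid and amplified spot populations", {
  genome <- cnGenome(c(chr1 = 50000L, chr2 = 50000L), seed = 7)
  cl <- contigLengths(genome)
  w <- makeGenomeWindows(genome, width = 5000, step = 1000)
  amp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 15000))

  set.seed(19)
  drawSpot <- function(bc, cnTrue, nIns = 500) {
    nFrag <- ceiling(nIns / 2)
    ampLen <- 5000; rest <- sum(cl) - ampLen
    pIn <- ampLen * cnTrue / 2 / (rest + ampLen * cnTrue / 2)
    inAmp <- runif(nFrag) < pIn
    pos <- integer(nFrag)
    ctg <- character(nFrag)
    pos[inAmp] <- sample(10001:14900, sum(inAmp), TRUE)
    ctg[inAmp] <- "chr1"
    outCtg <- sample(names(cl), sum(!inAmp), TRUE)
    pos[!inAmp] <- floor(runif(sum(!inAmp)) * (cl[outCtg] - 200)) + 1
    ctg[!inAmp] <- outCtg
    GenomicRanges::GRanges(ctg, IRanges::IRanges(pos, width = 100),
                           barcode = bc, count = 1L)
  }
  spots <- c(lapply(sprintf("DIP%02d", 1:20), drawSpot, cnTrue = 2),
             lapply(sprintf("AMP%02d", 1:20), drawSpot, cnTrue = 40))
  frags <- suppressWarnings(do.call(c, spots))
  cn <- spotCn(frags, amp, w)
  dip <- cn[grepl("^DIP", names(cn))]
  ampd <- cn[grepl("^AMP", names(cn))]
  expect_gte(aucScore(ampd, dip), 0.95)

  # forced cases: no amplicon insertions -> 0; background-free -> NA
  soloBg <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1000, 1100),
                                   barcode = "BGONLY", count = 1L)
  soloAmp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12000, 12100),
                                    barcode = "AMPONLY", count = 1L)
  cn2 <- spotCn(suppressWarnings(c(frags, soloBg, soloAmp)), amp, w)
  expect_equal(unname(cn2["BGONLY"]), 0)
  expect_true(is.na(cn2["AMPONLY"]))
})
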