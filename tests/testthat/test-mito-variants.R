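mkMitoRecords <- function(n = 1, readName = sprintf("m%03d", seq_len(n)),
                          pos = 0L, strand = "+", seq = NULL, qual = NULL,
                          barcode = "B1", len = 10L) {
  if (is.null(seq)) seq <- strrep("A", len)
  out <- data.frame(readName = readName, contig = "chrM", pos = as.integer(pos),
                    strand = strand, alignedLength = nchar(seq), mapped = TRUE,
                    barcode = barcode, umi = "U", seq = seq,
                    qual = if (is.null(qual)) "*" else qual,
                    stringsAsFactors = FALSE)
  out$cigar <- paste0(nchar(out$seq), "M")
  out
}

test_that("allele counting walks matches, mismatches, quality and CIGAR", {
  ref <- "ACGTACGTAC"
  rec <- mkMitoRecords(seq = "ACGTACGTAC")
  ac <- countAlleles(rec, ref)
  cnt <- alleleCounts(ac)
  expect_equal(nrow(cnt), 10L)
  expect_true(all(cnt$count == 1L))
  expect_equal(cnt$base, strsplit(ref, "")[[1]][cnt$pos])
  expect_true(all(cnt$strand == "+"))

  # single mismatch G->A at position 5 (ref base at 5 is A... use pos 3 G->T)
  rec2 <- mkMitoRecords(seq = "ACTTACGTAC")
  cnt2 <- alleleCounts(countAlleles(rec2, ref))
  expect_equal(cnt2$base[cnt2$pos == 3], "T")

  # quality floor excludes low-quality calls when QUAL is present
  rec3 <- mkMitoRecords(seq = "ACGTACGTAC",
                        qual = paste0(strrep("I", 9), "#"))
  cnt3 <- alleleCounts(countAlleles(rec3, ref, minBaseQuality = 20))
  expect_equal(nrow(cnt3), 9L)
  expect_false(10L %in% cnt3$pos)

  # soft clips and deletions consume the right coordinates
  rec4 <- mkMitoRecords(seq = "GGACGTC", pos = 0L)
  rec4$cigar <- "2S3M2D2M"
  cnt4 <- alleleCounts(countAlleles(rec4, ref))
  expect_equal(sort(cnt4$pos), c(1L, 2L, 3L, 6L, 7L))
  expect_equal(cnt4$base[cnt4$pos %in% 6:7], c("T", "C"))

  expect_error(countAlleles(mkMitoRecords(pos = 5L), ref), "reference end")
})

test_that("pileup counts match a simulated truth pileup", {
  sim <- simulateSpatialAtac(simConfig(
    seed = 33, nSpots = 6, readsPerSpot = 30, duplicateRate = 0,
    mito = list(contigLength = 400, coveragePerSpot = 10,
                variants = data.frame(position = 150, alt = "A",
                                      heteroplasmy = 0.4, strandBias = 0.5))))
  rec <- sim$genomeAlignments
  rec$barcode <- sim$truth$reads$barcode
  mrec <- rec[rec$contig == "chrM", ]
  ac <- countAlleles(mrec, sim$genome[["chrM"]])
  cnt <- alleleCounts(ac)
  # per-position coverage equals the interval-stabbing oracle
  oracle <- integer(400)
  for (i in seq_len(nrow(mrec))) {
    span <- (mrec$pos[i] + 1L):(mrec$pos[i] + mrec$alignedLength[i])
    oracle[span] <- oracle[span] + 1L
  }
  covByPos <- tapply(cnt$count, cnt$pos, sum)
  expect_equal(as.numeric(covByPos[as.character(which(oracle > 0))]),
               as.numeric(oracle[oracle > 0]))
  # alt counts at the variant position equal the simulator's record
  tru <- sim$truth$mitoVariants
  altHere <- cnt[cnt$pos == 150 & cnt$base == "A", ]
  altByBc <- tapply(altHere$count, altHere$barcode, sum)
  for (b in tru$barcode) {
    expect_equal(unname(altByBc[b]),
                 if (tru$altCount[tru$barcode == b] == 0) NA_real_ else
                   as.numeric(tru$altCount[tru$barcode == b]))
  }
})

test_that("strand correlation separates balanced variants from artifacts", {
  # hand-built pileup: 20 barcodes, ref C everywhere, variant with identical
  # forward and reverse alt counts -> correlation exactly 1
  ref <- strrep("C", 50)
  bcs <- sprintf("B%02d", 1:20)
  altN <- rep(2:6, 4)
  mk <- function(pos, strand, base, count, bc) {
    data.frame(barcode = bc, pos = pos, strand = strand, base = base,
               count = count, stringsAsFactors = FALSE)
  }
  cnt <- rbind(
    mk(10L, "+", "C", 20L, bcs), mk(10L, "-", "C", 20L, bcs),
    mk(10L, "+", "A", altN, bcs), mk(10L, "-", "A", altN, bcs),
    # position 20: alt only on the forward strand (artifact)
    mk(20L, "+", "C", 20L, bcs), mk(20L, "-", "C", 20L, bcs),
    mk(20L, "+", "G", altN, bcs)
  )
  ac <- methods::new("MitoAlleleCounts", counts = cnt,
                     reference = Biostrings::DNAString(ref),
                     contig = "chrM", barcodes = bcs)
  v <- callMitoVariants(ac)
  balanced <- v[v$position == 10 & v$alt == "A", ]
  expect_equal(balanced$strand_correlation, 1)
  expect_true(balanced$pass)
  expect_equal(balanced$n_supporting_barcodes, 20L)
  artifact <- v[v$position == 20 & v$alt == "G", ]
  expect_true(is.na(artifact$strand_correlation))
  expect_false(artifact$pass)

  # raising the threshold never adds pass variants
  vHi <- callMitoVariants(ac, strandCorrMin = 0.9)
  expect_true(all(vHi$position[vHi$pass] %in% v$position[v$pass]))

  # barcode permutation leaves calls unchanged
  perm <- cnt[sample.int(nrow(cnt)), ]
  acPerm <- methods::new("MitoAlleleCounts", counts = perm,
                         reference = Biostrings::DNAString(ref),
                         contig = "chrM", barcodes = bcs)
  expect_equal(callMitoVariants(acPerm), v)

  # fewer supporting barcodes than the floor -> undefined, fail
  vFloor <- callMitoVariants(ac, minBarcodes = 25L)
  expect_true(all(is.na(vFloor$strand_correlation)))
})

test_that("per-spot heteroplasmy is alt over coverage with NA when uncovered", {
  ref <- strrep("C", 30)
  cnt <- data.frame(
    barcode = c("B1", "B1", "B1", "B2"),
    pos = c(5L, 5L, 5L, 9L),
    strand = c("+", "-", "+", "+"),
    base = c("T", "T", "C", "C"),
    count = c(4L, 2L, 4L, 7L), stringsAsFactors = FALSE)
  ac <- methods::new("MitoAlleleCounts", counts = cnt,
                     reference = Biostrings::DNAString(ref),
                     contig = "chrM", barcodes = c("B1", "B2"))
  h <- heteroplasmyPerSpot(list(position = 5, alt = "T"), ac)
  expect_equal(unname(h["B1"]), 0.6)
  expect_true(is.na(h["B2"]))

  # heteroplasmies of ref plus all alts sum to 1 for a covered barcode
  hRef <- heteroplasmyPerSpot(list(position = 5, alt = "C"), ac)
  expect_equal(unname(h["B1"] + hRef["B1"]), 1)
})
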