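# shared fixture builders and independent oracles

# minimal alignment record table with sane defaults
mkRecords <- function(n = 1, readName = sprintf("r%03d", seq_len(n)),
                      contig = "chr1", pos = 100L, strand = "+",
                      alignedLength = 75L, barcode = "B1", umi = "AAAAAAAAAAAA",
                      contigLengths = c(chr1 = 1e6, chr2 = 1e6, chrM = 2e4)) {
  out <- data.frame(readName = rep_len(readName, n),
                    contig = rep_len(contig, n),
                    pos = rep_len(as.integer(pos), n),
                    strand = rep_len(strand, n),
                    alignedLength = rep_len(as.integer(alignedLength), n),
                    mapped = rep_len(TRUE, n),
                    barcode = rep_len(barcode, n),
                    umi = rep_len(umi, n),
                    stringsAsFactors = FALSE)
  attr(out, "contigLengths") <- contigLengths
  out
}

# write a small SAM file from raw lines
writeSamLines <- function(lines, header = c("@HD\tVN:1.6",
                                            "@SQ\tSN:chr1\tLN:1000000",
                                            "@SQ\tSN:chr2\tLN:1000000")) {
  path <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), path)
  path
}

samLine <- function(name = "r1", flag = 0L, contig = "chr1", pos1 = 101L,
                    cigar = "75M", seq = "*", qual = "*", tags = character(0)) {
  paste(c(name, flag, contig, pos1, 60, cigar, "*", 0, 0, seq, qual, tags),
        collapse = "\t")
}

# Independent brute-force oracle for directional UMI clustering: builds the
# full directed edge relation (Hamming distance 1 and count_u >= 2*count_v-1)
# and grows clusters by recursive DFS from seeds in (-count, umi) order.
bruteDirectional <- function(umis, counts) {
  n <- length(umis)
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && ham(umis[i], umis[j]) == 1 && counts[i] >= 2 * counts[j] - 1) {
      edge[i, j] <- TRUE
    }
  }
  assigned <- rep(NA_integer_, n)
  visit <- function(i, seed) {
    assigned[i] <<- seed
    for (j in which(edge[i, ] & is.na(assigned))) visit(j, seed)
  }
  for (i in order(-counts, umis)) if (is.na(assigned[i])) visit(i, i)
  # summarize: per cluster, head UMI and total count
  out <- lapply(split(seq_len(n), assigned), function(idx) {
    list(head = umis[idx[order(-counts[idx], umis[idx])[1]]],
         total = sum(counts[idx]))
  })
  heads <- vapply(out, `[[`, character(1), "head")
  totals <- vapply(out, `[[`, numeric(1), "total")
  sort(setNames(totals, heads))
}

# cluster summary of deduplicateAlignments output restricted to one group
dedupSummary <- function(umis, counts) {
  rec <- mkRecords(n = length(umis), umi = umis)
  rec$count <- as.integer(counts)
  dd <- deduplicateAlignments(rec, umiMerge = "directional")
  sort(setNames(as.numeric(dd$count), dd$umi))
}

# rank-based AUROC (Mann-Whitney)
aucScore <- function(scorePos, scoreNeg) {
  r <- rank(c(scorePos, scoreNeg))
  nP <- length(scorePos); nN <- length(scoreNeg)
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

# small deterministic genome helper: constant-GC random contigs
cnGenome <- function(contigs, gc = 0.45, seed = 1) {
  set.seed(seed)
  seqs <- vapply(contigs, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

# fragments giving every window the same insertion density: regular grid
gridFragments <- function(contigLengths, spacing = 500L, barcode = "B1") {
  pieces <- lapply(names(contigLengths), function(cn) {
    p <- seq(1L, contigLengths[[cn]] - 100L, by = spacing)
    GenomicRanges::GRanges(cn, IRanges::IRanges(p, width = 101L),
                           barcode = barcode, count = 1L)
  })
  suppressWarnings(do.call(c, pieces))
}

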