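#' Synthesize paired-end-style fragments from single-end alignments
#'
#' Each deduplicated single-end record becomes one fragment interval. The
#' read's 5' end is the genuine Tn5 insertion site; the 3' end is synthetic,
#' taken from the aligned span. Tn5 duplication-offset correction is applied
#' strand-aware: with shifts `(p, m)` (default `(+4, -5)`, the community
#' convention), a forward read at 0-based `pos` with aligned length `L`
#' yields `[pos + p, pos + L + m)` and a reverse read yields
#' `[pos - m, pos + L - p)` — the same two shifts applied end-for-end, so the
#' 5' end always moves by `p` and the 3' end by `m`. Use `tn5Shift = c(0, 0)`
#' for uncorrected intervals.
#'
#' Records whose shifted interval is empty (`start >= end`, very short
#' alignments) are dropped and counted in `metadata()$n_dropped_short`.
#'
#' @param records Deduplicated, annotated alignment data.frame (a `count`
#'   column is used as multiplicity; absent means 1).
#' @param tn5Shift Integer length-2 vector `(plus_shift, minus_shift)`.
#' @return A `GRanges` (1-based closed; equivalently 0-based half-open
#'   `[start-1, end)`) with strand of the source read and metadata columns
#'   `barcode`, `count`. Dropped-record count is in
#'   `S4Vectors::metadata()$n_dropped_short`.
#' @export
makeFragments <- function(records, tn5Shift = c(4L, -5L)) {
  stopifnot(length(tn5Shift) == 2L)
  p <- as.integer(tn5Shift[1L]); m <- as.integer(tn5Shift[2L])
  if (nrow(records) == 0L) {
    gr <- GRanges(character(), IRanges(), strand = character(),
                  barcode = character(), count = integer())
    metadata(gr)$n_dropped_short <- 0L
    metadata(gr)$n_reads_dropped_short <- 0L
    return(gr)
  }
  if (anyNA(records$barcode)) stop("records must carry barcode annotations")
  cnt <- if (is.null(records$count)) rep(1L, nrow(records)) else records$count
  fwd <- records$strand == "+"
  start0 <- ifelse(fwd, records$pos + p, records$pos - m)
  end0 <- ifelse(fwd, records$pos + records$alignedLength + m,
                 records$pos + records$alignedLength - p)
  ok <- start0 < end0 & start0 >= 0L
  gr <- GRanges(records$contig[ok],
                IRanges(start = start0[ok] + 1L, end = end0[ok]),
                strand = records$strand[ok],
                barcode = records$barcode[ok],
                count = as.integer(cnt[ok]))
  cl <- attr(records, "contigLengths")
  if (!is.null(cl)) {
    GenomeInfoDb::seqlevels(gr) <- names(cl)
    GenomeInfoDb::seqlengths(gr) <- cl
  }
  metadata(gr)$n_dropped_short <- sum(!ok)
  metadata(gr)$n_reads_dropped_short <- sum(cnt[!ok])
  gr
}

#' Build the sorted fragments stream and per-spot QC
#'
#' Converts deduplicated records to fragments ([makeFragments()]), keeps only
#' barcodes present in the spot layout (optionally only in-tissue spots),
#' sorts per the fragments-file convention, and computes per-spot QC:
#' fragment count, mitochondrial fraction, and (when TSS annotations are
#' supplied) TSS enrichment. No fragment-size filtering is applied and QC
#' thresholds are reported, not enforced — retention of nearly all barcodes
#' is deliberate; filtering is the caller's decision.
#'
#' @param records Deduplicated annotated alignment data.frame.
#' @param layout Spot layout data.frame ([readSpotLayout()]).
#' @param keepOffTissue Keep spots with `in_tissue = FALSE` (default `FALSE`).
#' @param tn5Shift Passed to [makeFragments()].
#' @param mitoContig Name of the mitochondrial contig (default `"chrM"`).
#' @param tss Optional TSS `GRanges` for [tssEnrichment()].
#' @return A list with `fragments` (sorted `GRanges`), `qc` (data.frame
#'   `barcode`, `n_fragments`, `n_reads`, `frac_mito`, `tss_enrichment`, one
#'   row per retained layout barcode), and `summary` (named counts: reads in,
#'   reads kept, reads dropped off-layout, reads dropped by short alignments).
#' @export
buildFragmentsFile <- function(records, layout, keepOffTissue = FALSE,
                               tn5Shift = c(4L, -5L), mitoContig = "chrM",
                               tss = NULL) {
  keepSpots <- if (keepOffTissue) layout$barcode else
    layout$barcode[layout$in_tissue]
  frags <- makeFragments(records, tn5Shift = tn5Shift)
  nShortReads <- metadata(frags)$n_reads_dropped_short
  onLayout <- mcols(frags)$barcode %in% keepSpots
  nOffLayout <- sum(mcols(frags)$count[!onLayout])
  frags <- sortFragments(frags[onLayout])

  dt <- data.table::data.table(barcode = mcols(frags)$barcode,
                               contig = as.character(seqnames(frags)),
                               count = mcols(frags)$count)
  perSpot <- dt[, .(n_fragments = .N, n_reads = sum(count),
                    frac_mito = {
                      tot <- sum(count)
                      if (tot == 0) 0 else sum(count[contig == mitoContig]) / tot
                    }), by = barcode]
  qc <- data.frame(barcode = keepSpots, stringsAsFactors = FALSE)
  qc <- merge(qc, as.data.frame(perSpot), by = "barcode", all.x = TRUE,
              sort = TRUE)
  qc$n_fragments[is.na(qc$n_fragments)] <- 0L
  qc$n_reads[is.na(qc$n_reads)] <- 0L
  qc$frac_mito[is.na(qc$frac_mito)] <- 0
  if (!is.null(tss)) {
    tssScores <- tssEnrichment(frags, tss)
    qc$tss_enrichment <- unname(tssScores[qc$barcode])
    qc$tss_enrichment[is.na(qc$tss_enrichment)] <- 0
  } else {
    qc$tss_enrichment <- NA_real_
  }
  nIn <- sum(if (is.null(records$count)) rep(1L, nrow(records)) else records$count)
  list(
    fragments = frags,
    qc = qc,
    summary = c(n_reads_in = nIn,
                n_reads_kept = sum(mcols(frags)$count),
                n_reads_dropped_off_layout = nOffLayout,
                n_reads_dropped_short = nShortReads)
  )
}

#' Insertion sites of a fragment stream
#'
#' Both fragment ends count as insertions under `countMode = "both"` (the
#' fragments-file-compatible default, carrying the documented bias that only
#' the 5' end of a single-end read is a genuine insertion). With
#' `countMode = "five-prime"` only the genuine end is used, which requires
#' stranded fragments (as produced in memory by [makeFragments()]; the
#' on-disk fragment format does not store strand).
#'
#' @param fragments Fragment `GRanges`.
#' @param countMode `"both"` or `"five-prime"`.
#' @return A data.table with columns `contig`, `pos` (1-based insertion
#'   base), `barcode`, `count`.
#' @export
insertionSites <- function(fragments, countMode = c("both", "five-prime")) {
  countMode <- match.arg(countMode)
  ctg <- as.character(seqnames(fragments))
  bc <- mcols(fragments)$barcode
  cnt <- mcols(fragments)$count
  if (countMode == "both") {
    data.table::data.table(
      contig = c(ctg, ctg),
      pos = c(start(fragments), end(fragments)),
      barcode = c(bc, bc),
      count = c(cnt, cnt)
    )
  } else {
    str <- as.character(strand(fragments))
    if (any(str == "*")) {
      stop("five-prime counting needs stranded fragments (in-memory only)")
    }
    data.table::data.table(
      contig = ctg,
      pos = ifelse(str == "+", start(fragments), end(fragments)),
      barcode = bc,
      count = cnt
    )
  }
}

#' Per-spot TSS enrichment
#'
#' Aggregates insertion counts in a strand-oriented window around all
#' transcription start sites, normalizes by the mean count in the outermost
#' `flank` positions of each side, and scores each spot as the normalized
#' mean over a small center window across the TSS. A flat insertion profile
#' therefore scores ~1; promoter pile-up scores proportionally higher. Spots
#' with zero flank signal score 0, with a warning.
#'
#' @param fragments Fragment `GRanges`.
#' @param tss `GRanges` of TSS points (width-1 ranges; strand used to orient
#'   the profile).
#' @param window Half-width of the profile in bp (default 2000).
#' @param flank Width of the outer background flank on each side (default
#'   100); must be `< window`.
#' @param centerWidth Width of the window across the TSS whose normalized
#'   mean is the score (default 101, i.e. TSS +/- 50 bp; averaging makes the
#'   score stable at realistic insertion counts).
#' @param countMode Passed to [insertionSites()].
#' @return Named numeric vector of scores, one per barcode present in
#'   `fragments`.
#' @export
tssEnrichment <- function(fragments, tss, window = 2000L, flank = 100L,
                          centerWidth = 101L, countMode = "both") {
  if (length(tss) == 0L) stop("tss must be non-empty")
  if (window <= flank) stop("window must exceed flank")
  half <- (centerWidth - 1L) %/% 2L
  ins <- insertionSites(fragments, countMode)
  barcodes <- sort(unique(ins$barcode))
  if (length(barcodes) == 0L) return(setNames(numeric(0), character(0)))

  insGr <- GRanges(ins$contig, IRanges(ins$pos, width = 1L))
  tssStrand <- as.character(strand(tss))
  tssWin <- suppressWarnings(GRanges(seqnames(tss),
                                     IRanges(pmax(1L, start(tss) - window),
                                             start(tss) + window)))
  hits <- findOverlaps(insGr, tssWin, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    warning("no insertions near any TSS; all scores 0")
    return(setNames(rep(0, length(barcodes)), barcodes))
  }
  rel <- ins$pos[queryHits(hits)] - start(tss)[subjectHits(hits)]
  flip <- tssStrand[subjectHits(hits)] == "-"
  rel[flip] <- -rel[flip]
  prof <- data.table::data.table(
    barcode = ins$barcode[queryHits(hits)],
    rel = rel,
    count = ins$count[queryHits(hits)]
  )[abs(rel) <= window]

  scoreOne <- function(b, r, cnt) {
    inFlank <- (r >= -window & r <= -window + flank - 1L) |
      (r <= window & r >= window - flank + 1L)
    flankMean <- sum(cnt[inFlank]) / (2L * flank)
    if (flankMean == 0) return(NA_real_)
    centerMean <- sum(cnt[abs(r) <= half]) / centerWidth
    centerMean / flankMean
  }
  sc <- prof[, .(score = scoreOne(barcode[1L], rel, count)), by = barcode]
  out <- setNames(rep(0, length(barcodes)), barcodes)
  out[sc$barcode] <- sc$score
  if (anyNA(out)) {
    warning(sum(is.na(out)), " spot(s) with zero flank signal scored 0")
    out[is.na(out)] <- 0
  }
  out
}

#' Per-spot mitochondrial read fraction
#'
#' Read-weighted fraction of each spot's fragments on the mitochondrial
#' contig; spots with no fragments score 0.
#'
#' @param fragments Fragment `GRanges`.
#' @param mitoContig Mitochondrial contig name (default `"chrM"`).
#' @return Named numeric vector in `[0, 1]`, one entry per barcode.
#' @export
mitoFraction <- function(fragments, mitoContig = "chrM") {
  dt <- data.table::data.table(
    barcode = mcols(fragments)$barcode,
    mito = as.character(seqnames(fragments)) == mitoContig,
    count = mcols(fragments)$count
  )
  res <- dt[, .(frac = if (sum(count) == 0) 0 else sum(count[mito]) / sum(count)),
            by = barcode]
  setNames(res$frac, res$barcode)
}
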