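#' Tile the genome into GC-annotated sliding windows
#'
#' Builds 3-Mb windows sliding in 1-Mb increments (the defaults) across each
#' contig. Blacklisted bases and ambiguous (N) bases are excluded from the
#' GC calculation and from the effective length used later for insertion
#' density; windows whose blacklisted-or-N fraction exceeds
#' `maxBlacklistFrac` are dropped. A contig shorter than one window yields a
#' single whole-contig window; otherwise only full-width windows are tiled,
#' with starts at multiples of `step`.
#'
#' @param genome A `DNAStringSet` or a FASTA path.
#' @param width Window width in bp (default 3e6); must be a multiple of
#'   `step`.
#' @param step Slide increment in bp (default 1e6).
#' @param blacklist `GRanges` of excluded regions (e.g. from
#'   [readBlacklist()]); default none.
#' @param maxBlacklistFrac Drop windows whose excluded fraction exceeds this
#'   (default 0.5).
#' @return A `GRanges` of windows with metadata columns `gc_fraction`
#'   (GC over included bases) and `eff_length` (included bases). The
#'   blacklist is carried in `S4Vectors::metadata()$blacklist` for use by
#'   [windowCn()] and [spotCn()].
#' @export
makeGenomeWindows <- function(genome, width = 3e6, step = 1e6,
                              blacklist = GRanges(),
                              maxBlacklistFrac = 0.5) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (width %% step != 0) stop("width must be a multiple of step")
  width <- as.integer(width); step <- as.integer(step)
  blacklist <- reduce(blacklist)

  res <- lapply(names(genome), function(cn) {
    L <- length(genome[[cn]])
    starts0 <- if (L < width) 0L else seq.int(0L, L - width, by = step)
    ends0 <- pmin(starts0 + width, L)
    win <- GRanges(cn, IRanges(starts0 + 1L, ends0))
    blc <- blacklist[as.character(seqnames(blacklist)) == cn]

    # per-window excluded bases (blacklist union N) and GC over the rest
    seqCtg <- genome[[cn]]
    v <- Views(seqCtg, start(win), end(win))
    freqAll <- Biostrings::letterFrequency(v, c("G", "C", "A", "T", "N"))
    gcAll <- freqAll[, "G"] + freqAll[, "C"]
    atgcAll <- gcAll + freqAll[, "A"] + freqAll[, "T"]
    nAll <- freqAll[, "N"]

    gcBl <- numeric(length(win)); atgcBl <- numeric(length(win))
    nBl <- numeric(length(win)); blBases <- numeric(length(win))
    if (length(blc) > 0L) {
      hits <- findOverlaps(win, blc)
      if (length(hits) > 0L) {
        qs <- pmax(start(win)[queryHits(hits)], start(blc)[subjectHits(hits)])
        qe <- pmin(end(win)[queryHits(hits)], end(blc)[subjectHits(hits)])
        fr <- Biostrings::letterFrequency(Views(seqCtg, qs, qe),
                                          c("G", "C", "A", "T", "N"))
        for (k in seq_along(qs)) {
          i <- queryHits(hits)[k]
          gcBl[i] <- gcBl[i] + fr[k, "G"] + fr[k, "C"]
          atgcBl[i] <- atgcBl[i] + sum(fr[k, c("G", "C", "A", "T")])
          nBl[i] <- nBl[i] + fr[k, "N"]
          blBases[i] <- blBases[i] + (qe[k] - qs[k] + 1L)
        }
      }
    }
    effLen <- GenomicRanges::width(win) - blBases - (nAll - nBl)
    excludedFrac <- 1 - effLen / GenomicRanges::width(win)
    gcInc <- gcAll - gcBl
    atgcInc <- atgcAll - atgcBl
    mcols(win)$gc_fraction <- ifelse(atgcInc > 0, gcInc / atgcInc, NA_real_)
    mcols(win)$eff_length <- effLen
    win[excludedFrac <= maxBlacklistFrac & effLen > 0]
  })
  out <- suppressWarnings(do.call(c, res))
  GenomeInfoDb::seqlevels(out) <- names(genome)
  sl <- contigLengths(genome)
  GenomeInfoDb::seqlengths(out) <- sl[GenomeInfoDb::seqlevels(out)]
  metadata(out)$blacklist <- blacklist
  out
}

#' Window copy number from GC-matched background
#'
#' For each window the insertion density (insertions per included bp) is
#' compared to the `nMatch` windows nearest in GC content anywhere in the
#' genome, excluding the window itself and windows genomically overlapping
#' it (genomic neighbors of an amplified locus would contaminate its
#' background). The log2 fold change is the mean over background windows of
#' `log2((d_w + eps_w) / (d_b + eps_b))` with a pseudocount of one insertion
#' over the window's included length, and copy number follows the diploid
#' baseline `CN = 2 * 2^log2FC`.
#'
#' Insertions falling in blacklisted regions are not counted. When fewer
#' than `nMatch + 1` windows exist, `nMatch` is lowered to the available
#' count with a warning.
#'
#' @param windows Windows from [makeGenomeWindows()].
#' @param fragments Fragment `GRanges`.
#' @param nMatch Number of GC-matched background windows (default 200).
#' @param countMode Passed to [insertionSites()].
#' @param fcMode `"pairs"` (mean of per-pair log ratios, the default,
#'   robust to single outlier background windows) or `"ratio_of_means"`
#'   (log ratio of the window density to the mean background density).
#' @return `windows` with metadata columns `insertions_per_bp`, `log2fc`,
#'   `cn` filled in.
#' @export
windowCn <- function(windows, fragments, nMatch = 200L, countMode = "both",
                     fcMode = c("pairs", "ratio_of_means")) {
  fcMode <- match.arg(fcMode)
  n <- length(windows)
  if (n < 2L) stop("need at least 2 windows")
  if (n < nMatch + 1L) {
    warning("only ", n, " windows available; lowering nMatch from ", nMatch,
            " to ", n - 1L)
    nMatch <- n - 1L
  }
  counts <- countWindowInsertions(windows, fragments, countMode)
  effLen <- mcols(windows)$eff_length
  dens <- counts / effLen
  eps <- 1 / effLen
  gc <- mcols(windows)$gc_fraction

  ov <- findOverlaps(windows, windows)
  ovList <- split(subjectHits(ov), queryHits(ov))

  log2fc <- vapply(seq_len(n), function(i) {
    excluded <- ovList[[as.character(i)]]
    cand <- setdiff(seq_len(n), excluded)
    if (length(cand) == 0L) return(NA_real_)
    cand <- cand[order(abs(gc[cand] - gc[i]), cand)]
    bg <- cand[seq_len(min(nMatch, length(cand)))]
    if (fcMode == "pairs") {
      mean(log2((dens[i] + eps[i]) / (dens[bg] + eps[bg])))
    } else {
      log2((dens[i] + eps[i]) / mean(dens[bg] + eps[bg]))
    }
  }, numeric(1))

  mcols(windows)$insertions_per_bp <- dens
  mcols(windows)$log2fc <- log2fc
  mcols(windows)$cn <- 2 * 2^log2fc
  windows
}

# insertions per window, excluding blacklisted positions
countWindowInsertions <- function(windows, fragments, countMode = "both") {
  ins <- insertionSites(fragments, countMode)
  insGr <- GRanges(ins$contig, IRanges(ins$pos, width = 1L))
  blacklist <- metadata(windows)$blacklist
  if (!is.null(blacklist) && length(blacklist) > 0L) {
    keep <- countOverlaps(insGr, blacklist) == 0L
    insGr <- insGr[keep]
  }
  countOverlaps(windows, insGr)
}

#' Gene-level copy number
#'
#' Mean window CN over all windows overlapping the gene by at least 1 bp.
#'
#' @param genes `GRanges` of gene intervals (a `name` metadata column is
#'   used in messages and output names when present).
#' @param windows Windows with `cn` filled by [windowCn()].
#' @return Numeric vector of gene CN values, named by gene when names are
#'   available. A gene overlapped by no window is a hard error naming it.
#' @export
geneCn <- function(genes, windows) {
  if (is.null(mcols(windows)$cn)) stop("run windowCn() first")
  hits <- findOverlaps(genes, windows, minoverlap = 1L)
  nms <- if (!is.null(mcols(genes)$name)) mcols(genes)$name else
    as.character(seq_along(genes))
  uncovered <- setdiff(seq_along(genes), unique(queryHits(hits)))
  if (length(uncovered) > 0L) {
    stop("no window overlaps gene '", nms[uncovered[1L]], "'")
  }
  cnByGene <- tapply(mcols(windows)$cn[subjectHits(hits)], queryHits(hits), mean)
  setNames(as.numeric(cnByGene[as.character(seq_along(genes))]), nms)
}

#' Per-spot amplicon copy number
#'
#' A depth-invariant per-spot ratio estimator for a known amplified locus:
#' each spot's insertion density inside the amplicon is divided by the same
#' spot's density over the rest of the windowed genome (windows overlapping
#' the amplicon excluded), times the diploid baseline 2. Spots with no
#' background insertions get `NA` (undefined, excluded from spatial maps);
#' spots with background but no amplicon signal get 0.
#'
#' @param fragments Fragment `GRanges`.
#' @param amplicon A length-1 `GRanges` for the amplified interval.
#' @param windows Windows from [makeGenomeWindows()] (CN columns not
#'   required).
#' @param layout Optional spot layout; when given, the result covers exactly
#'   the layout barcodes.
#' @param countMode Passed to [insertionSites()].
#' @return Named numeric vector of per-spot copy number.
#' @export
spotCn <- function(fragments, amplicon, windows, layout = NULL,
                   countMode = "both") {
  if (length(amplicon) != 1L) stop("amplicon must be a single interval")
  blacklist <- metadata(windows)$blacklist
  if (is.null(blacklist)) blacklist <- GRanges()

  ampWindows <- windows[countOverlaps(windows, amplicon) > 0L]
  covered <- reduce(granges(windows), ignore.strand = TRUE)
  excludedRegion <- reduce(c(granges(ampWindows), granges(amplicon)),
                           ignore.strand = TRUE)
  bgRegion <- GenomicRanges::setdiff(covered, excludedRegion,
                                     ignore.strand = TRUE)
  effectiveLen <- function(region) {
    sum(GenomicRanges::width(region)) -
      sum(GenomicRanges::width(GenomicRanges::intersect(region, blacklist,
                                                        ignore.strand = TRUE)))
  }
  ampLen <- effectiveLen(granges(amplicon))
  bgLen <- effectiveLen(bgRegion)
  if (ampLen <= 0 || bgLen <= 0) stop("amplicon or background has zero effective length")

  ins <- insertionSites(fragments, countMode)
  insGr <- GRanges(ins$contig, IRanges(ins$pos, width = 1L))
  if (length(blacklist) > 0L) {
    keep <- countOverlaps(insGr, blacklist) == 0L
    ins <- ins[keep]; insGr <- insGr[keep]
  }
  inAmp <- countOverlaps(insGr, amplicon, ignore.strand = TRUE) > 0L
  inBg <- countOverlaps(insGr, bgRegion, ignore.strand = TRUE) > 0L
  dt <- data.table::data.table(barcode = ins$barcode, amp = inAmp, bg = inBg)
  res <- dt[, .(nAmp = sum(amp), nBg = sum(bg)), by = barcode]
  cn <- ifelse(res$nBg == 0L, NA_real_,
               2 * (res$nAmp / ampLen) / (res$nBg / bgLen))
  out <- setNames(cn, res$barcode)
  if (!is.null(layout)) {
    full <- setNames(rep(NA_real_, nrow(layout)), layout$barcode)
    shared <- intersect(names(out), layout$barcode)
    full[shared] <- out[shared]
    out <- full
  }
  out
}
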