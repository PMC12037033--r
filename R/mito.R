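#' Stranded per-spot allele counts on the mitochondrial contig
#'
#' `MitoAlleleCounts` holds a per-spot, per-strand base pileup over the
#' mitochondrial contig: one row per (barcode, position, strand, base) with
#' a positive count, plus the reference sequence. Positions are 1-based, the
#' convention for mitochondrial variant nomenclature (nuclear interval types
#' in this package are 0-based half-open at the file level).
#'
#' @slot counts A `data.frame` with columns `barcode`, `pos` (1-based),
#'   `strand` (`"+"`/`"-"`), `base` (A/C/G/T), `count` (> 0).
#' @slot reference The mitochondrial reference as a `DNAString`.
#' @slot contig Contig name.
#' @slot barcodes All barcodes observed (superset of those in `counts`).
#' @exportClass MitoAlleleCounts
setClass("MitoAlleleCounts",
  representation(counts = "data.frame", reference = "DNAString",
                 contig = "character", barcodes = "character"))

setValidity("MitoAlleleCounts", function(object) {
  cnt <- object@counts
  need <- c("barcode", "pos", "strand", "base", "count")
  if (!all(need %in% names(cnt))) {
    return(paste("counts needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(cnt) > 0L) {
    if (any(cnt$count <= 0L)) return("all counts must be positive")
    if (any(cnt$pos < 1L | cnt$pos > length(object@reference))) {
      return("positions must lie on the reference")
    }
    if (!all(cnt$base %in% c("A", "C", "G", "T"))) {
      return("bases must be A/C/G/T")
    }
    if (!all(cnt$strand %in% c("+", "-"))) return("strand must be + or -")
  }
  TRUE
})

#' @describeIn countAlleles Compact display of a pileup object.
#' @param object A `MitoAlleleCounts`.
#' @export
setMethod("show", "MitoAlleleCounts", function(object) {
  cat("MitoAlleleCounts on", object@contig,
      sprintf("(%d bp reference)\n", length(object@reference)))
  cat(" ", length(object@barcodes), "barcodes;",
      nrow(object@counts), "nonzero (barcode, pos, strand, base) cells;",
      format(sum(object@counts$count), big.mark = ","), "base calls\n")
})

#' @rdname countAlleles
#' @param x A `MitoAlleleCounts`.
#' @export
alleleCounts <- function(x) x@counts

#' @rdname countAlleles
#' @export
mitoReference <- function(x) x@reference

#' @rdname countAlleles
#' @export
mitoBarcodes <- function(x) x@barcodes

#' Count stranded per-spot alleles on the mitochondrial contig
#'
#' Builds the base pileup that mitochondrial variant calling works from:
#' every aligned base of every barcode-annotated read (match/mismatch CIGAR
#' operations only; insertions, deletions and clips are skipped) increments
#' the (barcode, strand, position, base) cell. Bases below the quality floor
#' are excluded when per-base qualities are available.
#'
#' @param records Alignment data.frame restricted to the mitochondrial
#'   contig, read with `keepSeq = TRUE` so SEQ/QUAL/CIGAR are present, and
#'   carrying barcode annotations. A record extending past the reference end
#'   is a hard error.
#' @param reference Mitochondrial reference sequence (`DNAString`, character
#'   string, or single-sequence `DNAStringSet`).
#' @param contig Contig name recorded in the result (default `"chrM"`).
#' @param minBaseQuality Phred floor below which base calls are ignored when
#'   QUAL is present (default 20).
#' @return A [`MitoAlleleCounts`][MitoAlleleCounts-class] object.
#' @export
countAlleles <- function(records, reference, contig = "chrM",
                         minBaseQuality = 20L) {
  reference <- asDNAString(reference)
  refLen <- length(reference)
  if (nrow(records) > 0L) {
    if (is.null(records$seq)) stop("records need a 'seq' column (keepSeq = TRUE)")
    if (anyNA(records$barcode)) stop("records must carry barcode annotations")
    if (any(records$pos + records$alignedLength > refLen)) {
      stop("record extends past the reference end")
    }
  }
  weight <- if (is.null(records$count)) rep(1L, nrow(records)) else records$count
  cig <- if (!is.null(records$cigar)) records$cigar else
    paste0(records$alignedLength, "M")

  simple <- cig == paste0(nchar(records$seq), "M")
  pieces <- list()
  if (any(simple)) {
    pieces[[1L]] <- expandSimple(records[simple, , drop = FALSE],
                                 weight[simple], minBaseQuality)
  }
  if (any(!simple)) {
    pieces[[2L]] <- expandCigar(records[!simple, , drop = FALSE],
                                weight[!simple], cig[!simple], minBaseQuality)
  }
  dt <- data.table::rbindlist(pieces)
  if (nrow(dt) > 0L) {
    dt <- dt[base %in% c("A", "C", "G", "T") & qualOk]
    dt <- dt[, .(count = sum(count)), by = .(barcode, pos, strand, base)]
  } else {
    dt <- data.table::data.table(barcode = character(), pos = integer(),
                                 strand = character(), base = character(),
                                 count = integer())
  }
  methods::new("MitoAlleleCounts",
               counts = as.data.frame(dt),
               reference = reference,
               contig = contig,
               barcodes = sort(unique(records$barcode)))
}

# expand reads whose CIGAR is a single full-length match
expandSimple <- function(records, weight, minBaseQuality = 0L) {
  lens <- nchar(records$seq)
  n <- sum(lens)
  hasQual <- records$qual != "*" & !is.na(records$qual)
  qualOk <- rep(TRUE, n)
  if (any(hasQual)) {
    qv <- as.integer(charToRaw(paste(records$qual[hasQual], collapse = ""))) - 33L
    idx <- rep(hasQual, lens)
    qualOk[idx] <- qv >= minBaseQuality
  }
  data.table::data.table(
    barcode = rep(records$barcode, lens),
    pos = rep(records$pos + 1L, lens) + sequence(lens) - 1L,
    strand = rep(records$strand, lens),
    base = unlist(strsplit(records$seq, "", fixed = TRUE)),
    count = rep(weight, lens),
    qualOk = qualOk
  )
}

# general CIGAR walk; only M/=/X positions are counted
expandCigar <- function(records, weight, cig, minBaseQuality = 0L) {
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    qp <- 1L; rp <- records$pos[i] + 1L
    refPos <- integer(0); qryPos <- integer(0)
    for (k in seq_along(ops[[i]])) {
      op <- ops[[i]][k]; l <- lens[[i]][k]
      if (op %in% c("M", "=", "X")) {
        refPos <- c(refPos, rp:(rp + l - 1L))
        qryPos <- c(qryPos, qp:(qp + l - 1L))
        qp <- qp + l; rp <- rp + l
      } else if (op %in% c("I", "S")) {
        qp <- qp + l
      } else if (op %in% c("D", "N")) {
        rp <- rp + l
      }
    }
    bases <- strsplit(records$seq[i], "", fixed = TRUE)[[1L]][qryPos]
    qok <- rep(TRUE, length(qryPos))
    if (!is.na(records$qual[i]) && records$qual[i] != "*") {
      qv <- as.integer(charToRaw(records$qual[i])) - 33L
      qok <- qv[qryPos] >= minBaseQuality
    }
    out[[i]] <- data.table::data.table(
      barcode = records$barcode[i], pos = refPos,
      strand = records$strand[i], base = bases,
      count = weight[i], qualOk = qok
    )
  }
  data.table::rbindlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

asDNAString <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("reference must be a single sequence")
    return(x[[1L]])
  }
  DNAString(x)
}

#' Call mitochondrial substitutions with a strand-correlation pass filter
#'
#' For every (position, alternate base) with any alternate-allele support,
#' the strand correlation is the Pearson correlation — across spots with
#' nonzero coverage at the position — between forward-strand and
#' reverse-strand alternate counts. Genuine heteroplasmic variants show
#' concordant support on both strands across spots; strand-specific
#' artifacts do not. A variant passes when its strand correlation reaches
#' `strandCorrMin` (default 0.25). The correlation is undefined — and the
#' variant fails — when either strand's counts have zero variance across
#' spots or when fewer than `minBarcodes` spots carry the allele.
#'
#' @param counts A [`MitoAlleleCounts`][MitoAlleleCounts-class] from
#'   [countAlleles()].
#' @param strandCorrMin Pass-filter threshold on strand correlation
#'   (default 0.25).
#' @param minBarcodes Minimum spots carrying the alternate allele for the
#'   correlation to be considered defined (default 5; guards against
#'   spurious correlations at tiny n).
#' @param corOn Correlate raw counts (default) or per-spot frequencies.
#' @return A data.frame of candidate variants: `position` (1-based), `ref`,
#'   `alt`, `strand_correlation` (NA when undefined), `mean_heteroplasmy`
#'   (total alternate over total coverage), `n_supporting_barcodes`, `pass`.
#' @export
callMitoVariants <- function(counts, strandCorrMin = 0.25, minBarcodes = 5L,
                             corOn = c("counts", "frequencies")) {
  corOn <- match.arg(corOn)
  cnt <- data.table::as.data.table(alleleCounts(counts))
  if (nrow(cnt) == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), strand_correlation = numeric(),
                      mean_heteroplasmy = numeric(),
                      n_supporting_barcodes = integer(), pass = logical()))
  }
  refChars <- strsplit(as.character(mitoReference(counts)), "")[[1L]]
  cnt[, refBase := refChars[pos]]

  covByBc <- cnt[, .(cov = sum(count)), by = .(pos, barcode)]
  altTab <- cnt[base != refBase]
  cand <- unique(altTab[, .(pos, base)])
  data.table::setorder(cand, pos, base)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    p <- cand$pos[i]; a <- cand$base[i]
    covHere <- covByBc[pos == p]
    altHere <- altTab[pos == p & base == a]
    byBc <- merge(covHere,
                  altHere[, .(fwd = sum(count[strand == "+"]),
                              rev = sum(count[strand == "-"])), by = barcode],
                  by = "barcode", all.x = TRUE)
    byBc[is.na(fwd), fwd := 0L][is.na(rev), rev := 0L]
    nSupport <- sum(byBc$fwd + byBc$rev > 0L)
    sc <- NA_real_
    if (nSupport >= minBarcodes) {
      f <- byBc$fwd; r <- byBc$rev
      if (corOn == "frequencies") { f <- f / byBc$cov; r <- r / byBc$cov }
      if (stats::sd(f) > 0 && stats::sd(r) > 0) sc <- cor(f, r)
    }
    data.frame(position = p, ref = refChars[p], alt = a,
               strand_correlation = sc,
               mean_heteroplasmy = sum(byBc$fwd + byBc$rev) / sum(byBc$cov),
               n_supporting_barcodes = nSupport,
               pass = !is.na(sc) && sc >= strandCorrMin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-spot heteroplasmy of one mitochondrial variant
#'
#' Fraction of a spot's coverage at the variant position carrying the
#' alternate allele, both strands pooled. Spots with zero coverage get `NA`
#' (undefined; excluded from spatial maps).
#'
#' @param variant A one-row data.frame (or list) with `position` and `alt`,
#'   e.g. one row of [callMitoVariants()] output.
#' @param counts A [`MitoAlleleCounts`][MitoAlleleCounts-class].
#' @return Named numeric vector in `[0, 1]` (or `NA`), one entry per barcode
#'   known to `counts`.
#' @export
heteroplasmyPerSpot <- function(variant, counts) {
  p <- as.integer(variant$position)
  a <- as.character(variant$alt)
  cnt <- data.table::as.data.table(alleleCounts(counts))
  here <- cnt[pos == p]
  res <- here[, .(cov = sum(count), alt = sum(count[base == a])), by = barcode]
  out <- setNames(rep(NA_real_, length(mitoBarcodes(counts))),
                  mitoBarcodes(counts))
  out[res$barcode] <- res$alt / res$cov
  out
}
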