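#' Build the read-name to barcode/UMI table
#'
#' From a barcode-resolved alignment stream (where an upstream tool has
#' already corrected spot barcodes and UMIs and written them as per-record
#' tags), collect one row per read name carrying BOTH annotations. Reads
#' lacking either annotation are dropped silently and counted in the summary.
#' A read name seen with two conflicting (barcode, UMI) pairs is a hard
#' error: it means the two streams are not describing the same library.
#'
#' @param barcodeAlignments Alignment data.frame from [readAlignments()]
#'   (typically read with `requireMapped = FALSE`: annotation, not mapping,
#'   is what matters here).
#' @return A list with `assignments` (data.frame `readName`, `barcode`,
#'   `umi`, one row per annotated read name) and `summary` (named integer
#'   vector: `n_records`, `n_assigned`, `n_dropped_unannotated`).
#' @export
buildReadBarcodeTable <- function(barcodeAlignments) {
  dt <- data.table::as.data.table(
    barcodeAlignments[, c("readName", "barcode", "umi")])
  annotated <- dt[!is.na(barcode) & !is.na(umi)]
  tab <- unique(annotated, by = c("readName", "barcode", "umi"))
  conflict <- tab[, .N, by = readName][N > 1L]
  if (nrow(conflict) > 0L) {
    stop("read '", conflict$readName[1L],
         "' carries conflicting (barcode, umi) annotations")
  }
  # a read never annotated AND never unannotated can't exist; reads that
  # appear both annotated and unannotated count as assigned
  nDropped <- sum(!(unique(dt[is.na(barcode) | is.na(umi), readName]) %in%
                      tab$readName))
  list(
    assignments = as.data.frame(tab),
    summary = c(n_records = nrow(dt),
                n_assigned = nrow(tab),
                n_dropped_unannotated = nDropped)
  )
}

#' Attach spot barcodes and UMIs to genome alignments
#'
#' Joins the genome alignment stream to the read-name table by read name.
#' Records absent from the table are dropped and counted; surviving records
#' carry both annotations.
#'
#' @param genomeAlignments Alignment data.frame from [readAlignments()].
#' @param table Output of [buildReadBarcodeTable()], or its `assignments`
#'   data.frame.
#' @return A list with `records` (annotated alignment data.frame) and
#'   `summary` (`n_in`, `n_annotated`, `n_dropped_no_table_entry`).
#' @export
attachBarcodes <- function(genomeAlignments, table) {
  if (is.list(table) && !is.data.frame(table)) table <- table$assignments
  cl <- attr(genomeAlignments, "contigLengths")
  dt <- data.table::as.data.table(genomeAlignments)
  tt <- data.table::as.data.table(table)
  dt[, c("barcode", "umi") := NULL]
  merged <- tt[dt, on = "readName", nomatch = NULL]
  keep <- c("readName", "contig", "pos", "strand", "alignedLength", "mapped",
            "barcode", "umi",
            intersect(c("cigar", "seq", "qual"), names(merged)))
  out <- as.data.frame(merged[, ..keep])
  attr(out, "contigLengths") <- cl
  list(
    records = out,
    summary = c(n_in = nrow(dt),
                n_annotated = nrow(out),
                n_dropped_no_table_entry = nrow(dt) - nrow(out))
  )
}

#' Collapse PCR duplicates on barcode, UMI and insertion position
#'
#' Records are grouped by (barcode, contig, strand, 5' position), where the
#' 5' position is `pos` for forward-strand reads and
#' `pos + alignedLength - 1` for reverse-strand reads — the genuine Tn5
#' insertion site. Within a group, reads sharing a UMI collapse to one
#' representative carrying the collapsed read multiplicity.
#'
#' With `umiMerge = "directional"` (the default), UMIs within the group are
#' additionally merged across single-base differences using the directional
#' network rule: UMI `a` absorbs UMI `b` when they differ at exactly one base
#' and `count(a) >= 2 * count(b) - 1`, expanding transitively from
#' higher-count UMIs. This removes apparent molecules created by PCR or
#' sequencing errors in the UMI. `umiMerge = "exact"` keeps every distinct
#' UMI separate.
#'
#' Determinism: cluster seeds are taken in order of decreasing count with
#' lexicographically smaller UMI winning ties; the representative record per
#' collapsed set is the one with the smallest (pos, readName); output is
#' sorted by (barcode, contig, strand, 5' position, UMI).
#'
#' @param records Annotated alignment data.frame (every record must carry
#'   `barcode` and `umi`; a missing annotation is a hard error).
#' @param umiMerge `"directional"` or `"exact"`.
#' @return Alignment data.frame with one row per retained molecule and an
#'   integer `count` column (collapsed multiplicity). Sum of `count` equals
#'   `nrow(records)`.
#' @export
deduplicateAlignments <- function(records, umiMerge = c("directional", "exact")) {
  umiMerge <- match.arg(umiMerge)
  cl <- attr(records, "contigLengths")
  if (nrow(records) == 0L) {
    out <- records
    out$count <- integer(0)
    return(out)
  }
  if (anyNA(records$barcode) || anyNA(records$umi)) {
    stop("deduplication requires every record to carry barcode and umi annotations")
  }
  if (is.null(records$count)) records$count <- 1L
  dt <- data.table::as.data.table(records)
  dt[, fivePrime := ifelse(strand == "+", pos, pos + alignedLength - 1L)]
  dt[, grp := .GRP, by = .(barcode, contig, strand, fivePrime)]

  # per (group, umi): total multiplicity and representative row index in dt
  perUmi <- dt[, .(count = sum(count),
                   rep = .I[order(pos, readName)[1L]]), by = .(grp, umi)]

  if (umiMerge == "directional") {
    heads <- perUmi[, mergeDirectional(umi, count), by = grp]
    perUmi <- heads[perUmi, on = c("grp", "umi")]
  } else {
    perUmi[, umiHead := umi]
  }
  # representative record of a collapsed set: smallest (pos, readName); each
  # per-UMI rep is already minimal within its UMI, so minimize over reps
  collapsed <- perUmi[, {
    k <- order(dt$pos[rep], dt$readName[rep])[1L]
    list(count = sum(count), rep = rep[k])
  }, by = .(grp, umiHead)]

  out <- dt[collapsed$rep]
  out[, count := collapsed$count]
  out[, umi := collapsed$umiHead]
  setorder(out, barcode, contig, strand, fivePrime, umi)
  out[, c("fivePrime", "grp") := NULL]
  out <- as.data.frame(out)
  attr(out, "contigLengths") <- cl
  out
}

# Directional UMI-network clustering within one dedup group.
# Returns a data.table(umi, umiHead) mapping each UMI to its cluster head.
mergeDirectional <- function(umis, counts) {
  n <- length(umis)
  if (n == 1L) return(data.table::data.table(umi = umis, umiHead = umis))
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  adj <- hamming1Matrix(umis)
  head <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(head[i])) next
    head[i] <- umis[i]
    frontier <- i
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        cand <- which(is.na(head) & adj[u, ] & counts[u] >= 2L * counts - 1L)
        if (length(cand) > 0L) {
          head[cand] <- umis[i]
          nxt <- c(nxt, cand)
        }
      }
      frontier <- nxt
    }
  }
  data.table::data.table(umi = umis, umiHead = head)
}

# symmetric logical matrix: TRUE where two UMIs differ at exactly one base
hamming1Matrix <- function(umis) {
  n <- length(umis)
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (j in seq_len(ncol(chars))) {
    d <- d + outer(chars[, j], chars[, j], "!=")
  }
  d == 1L
}
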