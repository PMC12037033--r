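#' Fragment file input/output
#'
#' Deduplicated accessibility fragments are the pipeline's central currency.
#' On disk they follow the de-facto fragments-file standard: tab-separated,
#' five columns (`contig`, `start`, `end`, `barcode`, `count`), no header,
#' 0-based half-open coordinates, sorted by (contig, start, end, barcode).
#' In memory they are a `GRanges` (1-based closed, as usual for Bioconductor)
#' with metadata columns `barcode` and `count`; the conversion is
#' `start0 = start - 1`, `end_exclusive = end`, so round-trips are exact.
#'
#' `writeFragments()` refuses unsorted input: sortedness is its precondition,
#' not its job. Use [sortFragments()] first.
#'
#' @param path Path to a fragments TSV.
#' @return `readFragments()` returns a `GRanges` with `barcode` and `count`
#'   metadata columns; `writeFragments()` returns `path` invisibly.
#' @name fragments-io
NULL

#' @rdname fragments-io
#' @export
readFragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "start", "end", "barcode", "count"),
                          colClasses = list(character = c(1L, 4L)))
  if (nrow(dt) == 0L) {
    return(GRanges(character(), IRanges(), barcode = character(), count = integer()))
  }
  if (any(dt$start >= dt$end)) {
    stop("fragment with start >= end at row ", which(dt$start >= dt$end)[1L])
  }
  gr <- GRanges(dt$contig, IRanges(start = dt$start + 1L, end = dt$end),
                barcode = dt$barcode, count = as.integer(dt$count))
  if (any(mcols(gr)$count < 1L)) stop("fragment count must be >= 1")
  gr
}

#' @param fragments A fragment `GRanges` (metadata columns `barcode`, `count`).
#' @rdname fragments-io
#' @export
writeFragments <- function(fragments, path) {
  checkFragments(fragments)
  if (!isSortedFragments(fragments)) {
    stop("fragments must be sorted by (contig, start, end, barcode) before writing; ",
         "see sortFragments()")
  }
  dt <- data.table::data.table(
    contig = as.character(seqnames(fragments)),
    start = start(fragments) - 1L,
    end = end(fragments),
    barcode = mcols(fragments)$barcode,
    count = mcols(fragments)$count
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname fragments-io
#' @export
sortFragments <- function(fragments) {
  checkFragments(fragments)
  o <- order(match(as.character(seqnames(fragments)),
                   GenomeInfoDb::seqlevels(fragments)),
             start(fragments), end(fragments), mcols(fragments)$barcode,
             method = "radix")
  fragments[o]
}

isSortedFragments <- function(fragments) {
  if (length(fragments) < 2L) return(TRUE)
  o <- order(match(as.character(seqnames(fragments)),
                   GenomeInfoDb::seqlevels(fragments)),
             start(fragments), end(fragments), mcols(fragments)$barcode,
             method = "radix")
  identical(o, seq_along(fragments))
}

checkFragments <- function(fragments) {
  if (!is(fragments, "GRanges")) stop("fragments must be a GRanges")
  md <- mcols(fragments)
  if (is.null(md$barcode) || is.null(md$count)) {
    stop("fragments need 'barcode' and 'count' metadata columns")
  }
  invisible(TRUE)
}

#' Read a tissue-position spot layout
#'
#' Parses the slide layout CSV (`barcode`, `in_tissue`, `array_row`,
#' `array_col`, `pixel x`, `pixel y`). Spot barcodes must be unique and
#' each (row, col) position must be used at most once.
#'
#' @param path Path to a tissue-position CSV (with header).
#' @return A data.frame with columns `barcode`, `in_tissue` (logical),
#'   `array_row`, `array_col`, `pixel_x`, `pixel_y`.
#' @export
readSpotLayout <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("tissue-position file needs 6 columns: ", path)
  names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pixel_x", "pixel_y")
  if (anyDuplicated(tab$barcode)) {
    stop("duplicate spot barcode in layout: ",
         tab$barcode[duplicated(tab$barcode)][1L])
  }
  if (anyDuplicated(tab[, c("array_row", "array_col")])) {
    stop("duplicate (array_row, array_col) position in layout")
  }
  if (!all(tab$in_tissue %in% c(0L, 1L))) stop("in_tissue must be 0 or 1")
  tab$in_tissue <- tab$in_tissue == 1L
  tab
}

#' Write a tissue-position spot layout
#'
#' @param layout Layout data.frame (see [readSpotLayout()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpotLayout <- function(layout, path) {
  out <- layout
  out$in_tissue <- as.integer(out$in_tissue)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED blacklist into a normalized interval set
#'
#' Reads the first three columns of a BED file (0-based half-open) and merges
#' overlapping or bookended intervals, the canonical exclusion-set form used
#' to drop mapping-artifact regions.
#'
#' @param path Path to a BED file (3+ columns, no header).
#' @return A reduced (sorted, non-overlapping) `GRanges`. Empty file gives an
#'   empty `GRanges`.
#' @export
readBlacklist <- function(path) {
  if (file.size(path) == 0L) return(GRanges())
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  bad <- tab[[2L]] >= tab[[3L]]
  if (any(bad)) {
    stop("BED interval with start >= end at row ", which(bad)[1L], " of ", path)
  }
  reduce(GRanges(tab[[1L]], IRanges(start = tab[[2L]] + 1L, end = tab[[3L]])))
}

#' Read gene or TSS annotations from BED-like TSV
#'
#' Expects columns contig, start (0-based), end (exclusive), name, strand.
#'
#' @param path Path to the annotation file (no header).
#' @return A `GRanges` with a `name` metadata column.
#' @export
readGeneBed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) stop("gene BED needs 5 columns (contig,start,end,name,strand)")
  if (any(tab[[2L]] >= tab[[3L]])) stop("gene interval with start >= end")
  GRanges(tab[[1L]], IRanges(start = tab[[2L]] + 1L, end = tab[[3L]]),
          strand = tab[[5L]], name = tab[[4L]])
}

#' Serialize / load a sparse spot-by-feature matrix
#'
#' Writes the assay as MatrixMarket triplet text plus sidecar TSVs for row
#' (feature) and column (barcode) names, a plain-text trio any downstream
#' tool can read.
#'
#' @param se A `SummarizedExperiment` with one sparse assay.
#' @param prefix Output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.features.tsv`, `<prefix>.barcodes.tsv`.
#' @return `writeSparseMatrix()` returns the prefix invisibly;
#'   `readSparseMatrix()` returns a list with `matrix` (dgCMatrix with
#'   dimnames), ready to rebuild a `SummarizedExperiment`.
#' @name sparse-io
#' @export
writeSparseMatrix <- function(se, prefix) {
  m <- SummarizedExperiment::assay(se)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(se), paste0(prefix, ".features.tsv"))
  writeLines(colnames(se), paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' @rdname sparse-io
#' @export
readSparseMatrix <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  rn <- readLines(paste0(prefix, ".features.tsv"))
  cn <- readLines(paste0(prefix, ".barcodes.tsv"))
  dimnames(m) <- list(rn, cn)
  list(matrix = m)
}
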