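#' Read a SAM-format alignment stream
#'
#' Parses SAM text into a data.frame of single-end alignment records, the
#' package's alignment currency. Coordinates are converted to 0-based
#' (`pos` is the leftmost mapped reference base). Spot barcodes and UMIs are
#' taken from `CB:Z:` / `UB:Z:` tags when present.
#'
#' @param path Path to a SAM-format text file. A header with `@SQ` lines
#'   naming every contig is required.
#' @param requireMapped Drop unmapped, secondary and supplementary records
#'   when `TRUE` (the default). When `FALSE` they are retained (unmapped
#'   records keep `pos = NA`), which is what barcode-table construction needs.
#' @param keepSeq Retain the SEQ and QUAL fields (needed for mitochondrial
#'   allele counting). Default `FALSE` to keep memory down.
#'
#' @return A data.frame with columns `readName`, `contig`, `pos` (0-based),
#'   `strand` (`"+"`/`"-"`), `alignedLength` (reference bases consumed),
#'   `mapped`, `barcode`, `umi` (NA when the tag is absent), and, with
#'   `keepSeq = TRUE`, `cigar`, `seq`, `qual`. The header's contig lengths are
#'   attached as `attr(x, "contigLengths")`.
#'
#' A record naming a contig absent from the header, or a line with fewer than
#' the 11 mandatory SAM fields, is a hard error naming the offending line.
#'
#' @seealso [writeSam()], [buildReadBarcodeTable()], [attachBarcodes()]
#' @export
readAlignments <- function(path, requireMapped = TRUE, keepSeq = FALSE) {
  lines <- readLines(path)
  isHdr <- startsWith(lines, "@")
  if (any(!isHdr & seq_along(lines) < match(FALSE, isHdr))) stop("header must precede records")
  hdr <- lines[isHdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stop("SAM header contains no @SQ lines: ", path)
  sqFields <- strsplit(sq, "\t", fixed = TRUE)
  getTag <- function(fields, tag) {
    hit <- fields[startsWith(fields, paste0(tag, ":"))]
    if (length(hit) == 0L) stop("@SQ line missing ", tag, " field")
    sub(paste0("^", tag, ":"), "", hit[1L])
  }
  contigLengths <- setNames(
    vapply(sqFields, function(f) as.numeric(getTag(f, "LN")), numeric(1)),
    vapply(sqFields, function(f) getTag(f, "SN"), character(1))
  )

  recLines <- lines[!isHdr]
  recLineNo <- which(!isHdr)
  if (length(recLines) == 0L) {
    out <- emptyAlignments(keepSeq)
    attr(out, "contigLengths") <- contigLengths
    return(out)
  }

  fields <- data.table::tstrsplit(recLines, "\t", fixed = TRUE)
  short <- if (length(fields) < 11L) rep(TRUE, length(recLines)) else
    is.na(fields[[11L]])
  if (any(short)) {
    nf <- lengths(strsplit(recLines[short], "\t", fixed = TRUE))
    stop("malformed SAM record (", min(nf), " of 11 mandatory fields) at line ",
         recLineNo[short][which.min(nf)], " of ", path)
  }

  flag <- as.integer(fields[[2L]])
  if (anyNA(flag)) {
    stop("malformed FLAG field at line ", recLineNo[which(is.na(flag))[1L]],
         " of ", path)
  }
  rname <- fields[[3L]]
  unmapped <- bitwAnd(flag, 4L) > 0L | rname == "*"
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L

  badContig <- !unmapped & !(rname %in% names(contigLengths))
  if (any(badContig)) {
    i <- which(badContig)[1L]
    stop("record on contig '", rname[i], "' absent from header at line ",
         recLineNo[i], " of ", path)
  }

  cigar <- fields[[6L]]
  alnLen <- rep(NA_integer_, length(flag))
  hasCigar <- !unmapped & cigar != "*"
  if (any(hasCigar)) {
    alnLen[hasCigar] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[hasCigar])
  }

  # CB/UB tags live in optional columns 12+
  barcode <- rep(NA_character_, length(flag))
  umi <- rep(NA_character_, length(flag))
  if (length(fields) > 11L) {
    for (j in 12:length(fields)) {
      col <- fields[[j]]
      cb <- !is.na(col) & startsWith(col, "CB:Z:")
      if (any(cb)) barcode[cb] <- substring(col[cb], 6L)
      ub <- !is.na(col) & startsWith(col, "UB:Z:")
      if (any(ub)) umi[ub] <- substring(col[ub], 6L)
    }
  }

  out <- data.frame(
    readName = fields[[1L]],
    contig = ifelse(unmapped, NA_character_, rname),
    pos = ifelse(unmapped, NA_integer_, as.integer(fields[[4L]]) - 1L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    alignedLength = alnLen,
    mapped = !unmapped,
    barcode = barcode,
    umi = umi,
    stringsAsFactors = FALSE
  )
  if (keepSeq) {
    out$cigar <- cigar
    out$seq <- fields[[10L]]
    out$qual <- fields[[11L]]
  }
  if (requireMapped) out <- out[!unmapped & !secondary, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contigLengths") <- contigLengths
  out
}

emptyAlignments <- function(keepSeq = FALSE) {
  out <- data.frame(
    readName = character(), contig = character(), pos = integer(),
    strand = character(), alignedLength = integer(), mapped = logical(),
    barcode = character(), umi = character(), stringsAsFactors = FALSE
  )
  if (keepSeq) {
    out$cigar <- character(); out$seq <- character(); out$qual <- character()
  }
  out
}

#' Write alignment records as SAM text
#'
#' Inverse of [readAlignments()] for records produced by this package or its
#' simulator. Barcode/UMI annotations are emitted as `CB:Z:`/`UB:Z:` tags and
#' a `cn:i:` tag carries collapsed duplicate multiplicity when a `count`
#' column is present.
#'
#' @param records Alignment data.frame as returned by [readAlignments()].
#' @param path Output file path.
#' @param contigLengths Named vector of contig lengths for the `@SQ` header;
#'   defaults to `attr(records, "contigLengths")`.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, path, contigLengths = attr(records, "contigLengths")) {
  if (is.null(contigLengths)) stop("contigLengths required to write a SAM header")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigLengths),
                   as.integer(contigLengths)))
  n <- nrow(records)
  if (n == 0L) { writeLines(hdr, path); return(invisible(path)) }
  flag <- ifelse(records$mapped, 0L, 4L) + ifelse(records$strand == "-", 16L, 0L)
  cig <- if (!is.null(records$cigar)) records$cigar else
    ifelse(records$mapped, paste0(records$alignedLength, "M"), "*")
  seqF <- if (!is.null(records$seq)) records$seq else rep("*", n)
  qualF <- if (!is.null(records$qual)) records$qual else rep("*", n)
  body <- paste(records$readName, flag,
                ifelse(records$mapped, records$contig, "*"),
                ifelse(records$mapped, records$pos + 1L, 0L),
                ifelse(records$mapped, 60L, 0L), cig, "*", 0L, 0L,
                seqF, qualF, sep = "\t")
  tag <- !is.na(records$barcode) & !is.na(records$umi)
  body[tag] <- paste0(body[tag], "\tCB:Z:", records$barcode[tag],
                      "\tUB:Z:", records$umi[tag])
  if (!is.null(records$count)) {
    body <- paste0(body, "\tcn:i:", records$count)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(body, con)
  invisible(path)
}

#' Read a FASTA-index-style contig length table
#'
#' Parses the first two columns (contig name, length) of a `.fai` text index.
#'
#' @param path Path to a `.fai`-style tab-separated file.
#' @return Named numeric vector of contig lengths.
#' @export
readFai <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("fai index needs at least 2 columns: ", path)
  if (anyDuplicated(tab[[1L]])) stop("duplicate contig in fai index: ", path)
  setNames(as.numeric(tab[[2L]]), tab[[1L]])
}

#' Contig lengths of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named numeric vector of sequence lengths.
#' @export
contigLengths <- function(genome) {
  setNames(as.numeric(Biostrings::width(genome)), names(genome))
}
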