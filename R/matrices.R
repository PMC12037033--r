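#' Build the spot-by-tile insertion matrix
#'
#' Bins insertion sites into fixed-width genomic tiles (default 5 kb, the
#' tile size used in place of a peak matrix for spatial ATAC). Each fragment
#' contributes one insertion per counted end (see [insertionSites()]); the
#' last tile of each contig may be short. Tiles are rows, spots are columns,
#' following the usual feature-by-sample convention.
#'
#' @param fragments Fragment `GRanges`.
#' @param contigLengths Named vector of contig lengths covering every
#'   fragment contig. A fragment extending beyond its contig is a hard error.
#' @param tileWidth Tile width in bp (default 5000).
#' @param countMode Passed to [insertionSites()].
#' @return A `RangedSummarizedExperiment` with assay `"insertions"`
#'   (`dgCMatrix`, tile x barcode) and tile coordinates as `rowRanges`.
#' @export
buildTileMatrix <- function(fragments, contigLengths, tileWidth = 5000L,
                            countMode = "both") {
  ctgs <- as.character(seqnames(fragments))
  missing <- setdiff(unique(ctgs), names(contigLengths))
  if (length(missing) > 0L) {
    stop("contig lengths missing for: ", paste(missing, collapse = ", "))
  }
  beyond <- end(fragments) > contigLengths[ctgs]
  if (any(beyond)) {
    stop("fragment beyond contig length on ", ctgs[which(beyond)[1L]])
  }

  nTiles <- setNames(pmax(1L, as.integer(ceiling(contigLengths / tileWidth))),
                     names(contigLengths))
  tileStarts <- unlist(lapply(names(contigLengths), function(cn) {
    seq.int(0L, by = tileWidth, length.out = nTiles[[cn]])
  }))
  tileContig <- rep(names(contigLengths), nTiles)
  tileEnds <- pmin(tileStarts + tileWidth, contigLengths[tileContig])
  tiles <- GRanges(tileContig, IRanges(start = tileStarts + 1L, end = tileEnds))
  tileOffset <- setNames(cumsum(c(0L, head(nTiles, -1L))), names(contigLengths))

  barcodes <- sort(unique(mcols(fragments)$barcode))
  ins <- insertionSites(fragments, countMode)
  if (nrow(ins) > 0L) {
    tileIdx <- tileOffset[ins$contig] + (ins$pos - 1L) %/% tileWidth + 1L
    bcIdx <- match(ins$barcode, barcodes)
    m <- Matrix::sparseMatrix(i = tileIdx, j = bcIdx, x = 1,
                              dims = c(length(tiles), length(barcodes)))
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(tiles), max(1L, length(barcodes))))
    if (length(barcodes) == 0L) barcodes <- character(1L)[0]
    m <- m[, seq_along(barcodes), drop = FALSE]
  }
  rownames(m) <- paste0(tileContig, ":", tileStarts, "-", tileEnds)
  colnames(m) <- barcodes
  SummarizedExperiment(
    assays = list(insertions = methods::as(m, "CsparseMatrix")),
    rowRanges = setNames(tiles, rownames(m))
  )
}

#' Accessibility gene scores from insertion counts
#'
#' Scores each gene per spot as the number of insertions falling in the gene
#' body plus a promoter window 5' of the TSS (strand-aware; default 2 kb
#' upstream). Deliberately a transparent counting model — no distance decay —
#' documented as such. Insertions under overlapping genes are credited to
#' every overlapping gene.
#'
#' @param fragments Fragment `GRanges`.
#' @param genes Gene `GRanges` with a `name` metadata column and strand.
#' @param promoterUpstream Bases upstream of the TSS to include (default
#'   2000).
#' @param countMode Passed to [insertionSites()].
#' @return A `RangedSummarizedExperiment` with assay `"score"` (gene x
#'   barcode sparse matrix).
#' @export
geneScore <- function(fragments, genes, promoterUpstream = 2000L,
                      countMode = "both") {
  if (is.null(mcols(genes)$name)) stop("genes need a 'name' metadata column")
  fwd <- as.character(strand(genes)) != "-"
  extStart <- ifelse(fwd, pmax(1L, start(genes) - promoterUpstream), start(genes))
  extEnd <- ifelse(fwd, end(genes), end(genes) + promoterUpstream)
  ext <- GRanges(seqnames(genes), IRanges(extStart, extEnd))

  barcodes <- sort(unique(mcols(fragments)$barcode))
  ins <- insertionSites(fragments, countMode)
  insGr <- GRanges(ins$contig, IRanges(ins$pos, width = 1L))
  hits <- findOverlaps(insGr, ext, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    m <- Matrix::sparseMatrix(
      i = subjectHits(hits),
      j = match(ins$barcode[queryHits(hits)], barcodes),
      x = 1,
      dims = c(length(genes), length(barcodes))
    )
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(genes), length(barcodes)))
  }
  rownames(m) <- mcols(genes)$name
  colnames(m) <- barcodes
  SummarizedExperiment(
    assays = list(score = methods::as(m, "CsparseMatrix")),
    rowRanges = setNames(granges(genes), mcols(genes)$name)
  )
}

#' Accessibility / expression concordance across clusters
#'
#' Mirrors the cross-modality concordance analysis: per gene, every pair of
#' clusters is compared in each modality with a rank-sum test (normal
#' approximation) and a log2 fold change of cluster means (pseudocount 1, on
#' per-spot library-size-normalized values, counts per 10,000). A gene
#' passes when any cluster pair reaches `p <= pMax` and `|log2FC| >= lfcMin`
#' in either modality; for reporting, the Pearson correlation of per-cluster
#' means between the two modalities is attached per gene.
#'
#' @param geneScores,geneExpression `SummarizedExperiment`s (gene x barcode)
#'   or plain matrices with dimnames; shared genes and barcodes are used.
#' @param clusters Named vector (names = barcodes) of cluster labels; at
#'   least 2 clusters among the shared barcodes required.
#' @param lfcMin Minimum |log2 fold change| (default 1).
#' @param pMax Maximum rank-sum p-value (default 0.05).
#' @return A data.frame, one row per shared gene: `gene`, `pass`,
#'   `correlation` (per-cluster-mean Pearson r between modalities),
#'   `min_p_score`, `max_abs_lfc_score`, `min_p_expr`, `max_abs_lfc_expr`.
#' @export
concordanceAnalysis <- function(geneScores, geneExpression, clusters,
                                lfcMin = 1, pMax = 0.05) {
  a <- asGeneMatrix(geneScores)
  e <- asGeneMatrix(geneExpression)
  genes <- intersect(rownames(a), rownames(e))
  bcs <- intersect(intersect(colnames(a), colnames(e)), names(clusters))
  if (length(genes) == 0L || length(bcs) == 0L) {
    stop("no shared genes/barcodes between modalities")
  }
  cl <- as.character(clusters[bcs])
  labs <- sort(unique(cl))
  if (length(labs) < 2L) stop("need at least 2 clusters")
  a <- normalizeCp10k(a[genes, bcs, drop = FALSE])
  e <- normalizeCp10k(e[genes, bcs, drop = FALSE])

  pairStats <- function(m) {
    minP <- rep(1, length(genes)); maxL <- rep(0, length(genes))
    pass <- rep(FALSE, length(genes))
    for (i in seq_len(length(labs) - 1L)) for (j in (i + 1L):length(labs)) {
      g1 <- cl == labs[i]; g2 <- cl == labs[j]
      m1 <- Matrix::rowMeans(m[, g1, drop = FALSE])
      m2 <- Matrix::rowMeans(m[, g2, drop = FALSE])
      lfc <- log2((m1 + 1) / (m2 + 1))
      p <- rankSumP(m[, g1, drop = FALSE], m[, g2, drop = FALSE])
      pass <- pass | (p <= pMax & abs(lfc) >= lfcMin)
      minP <- pmin(minP, p); maxL <- pmax(maxL, abs(lfc))
    }
    list(pass = pass, minP = minP, maxL = maxL)
  }
  sa <- pairStats(a)
  se <- pairStats(e)

  meansBy <- function(m) {
    vapply(labs, function(l) Matrix::rowMeans(m[, cl == l, drop = FALSE]),
           numeric(length(genes)))
  }
  ma <- meansBy(a); me <- meansBy(e)
  corr <- vapply(seq_along(genes), function(g) {
    va <- ma[g, ]; ve <- me[g, ]
    if (stats::sd(va) == 0 || stats::sd(ve) == 0) NA_real_ else cor(va, ve)
  }, numeric(1))

  data.frame(
    gene = genes,
    pass = sa$pass | se$pass,
    correlation = corr,
    min_p_score = sa$minP, max_abs_lfc_score = sa$maxL,
    min_p_expr = se$minP, max_abs_lfc_expr = se$maxL,
    stringsAsFactors = FALSE
  )
}

asGeneMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("gene matrices need gene rownames and barcode colnames")
  }
  x
}

normalizeCp10k <- function(m) {
  libSize <- Matrix::colSums(m)
  libSize[libSize == 0] <- 1
  methods::as(m %*% Matrix::Diagonal(x = 1e4 / libSize), "CsparseMatrix")
}

# Vectorized two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie correction and continuity correction), one test per row.
rankSumP <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  m <- cbind(as.matrix(m1), as.matrix(m2))
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    r <- rank(x)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  pmin(1, p)
}
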