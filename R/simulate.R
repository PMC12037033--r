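#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulateSpatialAtac()].
#' Defaults describe a modest but realistic spatially barcoded ATAC library:
#' 16-nt spot barcodes and 12-nt UMIs, 75-bp single-end reads (read 2 after
#' trimming; read 1 holds barcode and UMI), a PCR duplicate rate of 0.5 and
#' a small UMI error rate. Genome, amplicon and mitochondrial components are
#' fully configurable so each downstream module can be driven at the scale
#' its tests need.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param nSpots Number of spots in the layout.
#' @param genome Data.frame with columns `contig`, `length`, `gc` (target GC
#'   fraction per contig). Default: 5 contigs of 2 Mb with GC 0.38-0.52.
#' @param readsPerSpot Nuclear reads emitted per spot (duplicates included).
#' @param readLength Aligned read length in bp (default 75).
#' @param duplicateRate Probability that a read re-emits an existing molecule
#'   of its spot rather than creating a new one (default 0.5).
#' @param umiErrorRate Probability that a duplicate read's UMI acquires one
#'   substituted base (default 0.01).
#' @param barcodeDropout Fraction of reads whose barcode/UMI tags are absent
#'   from the barcode-resolved stream (default 0).
#' @param inTissueFraction Fraction of spots flagged in-tissue (default 1).
#' @param amplicon Optional `list(contig, start, end, trueCn,
#'   affectedFraction)`; 0-based half-open interval. In affected spots, read
#'   density inside the amplicon is `trueCn / 2` times the diploid density.
#' @param mito Optional `list(contigLength, coveragePerSpot, variants)`;
#'   `variants` is a data.frame with `position` (1-based), `alt`,
#'   `heteroplasmy`, `strandBias` (0.5 = balanced, 1 = alternate allele only
#'   on the forward strand; fully biased artifacts should use heteroplasmy
#'   at most 0.5 so the marginal allele frequency is preserved). Optional
#'   keys `coverageDispersion` (lognormal sdlog of per-spot mtDNA abundance,
#'   default 0.3) and `hetConcentration` (beta concentration of per-spot
#'   heteroplasmy around the clone mean, default 20) control between-spot
#'   variability.
#' @param barcodeLength,umiLength Tag lengths (defaults 16 and 12).
#' @return A validated config list of class `spatacSimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nSpots = 50L,
                      genome = data.frame(
                        contig = paste0("chr", 1:5),
                        length = rep(2e6, 5),
                        gc = seq(0.38, 0.52, length.out = 5)),
                      readsPerSpot = 400L,
                      readLength = 75L,
                      duplicateRate = 0.5,
                      umiErrorRate = 0.01,
                      barcodeDropout = 0,
                      inTissueFraction = 1,
                      amplicon = NULL,
                      mito = NULL,
                      barcodeLength = 16L,
                      umiLength = 12L) {
  stopifnot(
    duplicateRate >= 0, duplicateRate < 1,
    umiErrorRate >= 0, umiErrorRate < 1,
    barcodeDropout >= 0, barcodeDropout <= 1,
    all(c("contig", "length", "gc") %in% names(genome)),
    nSpots >= 1, readsPerSpot >= 1, readLength >= 1
  )
  if (!is.null(amplicon)) {
    stopifnot(all(c("contig", "start", "end", "trueCn", "affectedFraction")
                  %in% names(amplicon)),
              amplicon$trueCn >= 2)
    g <- genome[genome$contig == amplicon$contig, ]
    if (nrow(g) != 1L || amplicon$start < 0 || amplicon$end > g$length ||
        amplicon$start >= amplicon$end) {
      stop("amplicon outside the simulated genome")
    }
  }
  if (!is.null(mito)) {
    stopifnot(all(c("contigLength", "coveragePerSpot", "variants")
                  %in% names(mito)))
    v <- mito$variants
    stopifnot(all(c("position", "alt", "heteroplasmy", "strandBias")
                  %in% names(v)),
              all(v$position >= 1), all(v$position <= mito$contigLength),
              all(v$heteroplasmy > 0), all(v$heteroplasmy <= 1),
              all(v$strandBias >= 0), all(v$strandBias <= 1))
  }
  structure(list(
    seed = as.integer(seed), nSpots = as.integer(nSpots), genome = genome,
    readsPerSpot = as.integer(readsPerSpot),
    readLength = as.integer(readLength),
    duplicateRate = duplicateRate, umiErrorRate = umiErrorRate,
    barcodeDropout = barcodeDropout, inTissueFraction = inTissueFraction,
    amplicon = amplicon, mito = mito,
    barcodeLength = as.integer(barcodeLength),
    umiLength = as.integer(umiLength)
  ), class = "spatacSimConfig")
}

randSeqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

randContig <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Simulate a spatially barcoded ATAC experiment with ground truth
#'
#' Generates, deterministically for a fixed seed: a random genome (plus an
#' optional mitochondrial-like contig), a spot layout, and two alignment
#' streams over the same reads — a barcode-resolved stream carrying
#' corrected barcode/UMI tags and a plain genome stream without them.
#' Nuclear reads are drawn uniformly outside the amplicon; in affected
#' spots, density inside the amplicon is scaled by `trueCn / 2`. PCR
#' duplicates re-emit an existing molecule of the same spot under a fresh
#' read name, optionally with a single-base UMI error. Mitochondrial reads
#' carry real sequences with variant alleles injected per-strand according
#' to each variant's heteroplasmy and strand bias. Ground truth (read to
#' molecule map, molecule intervals, per-variant per-spot allele counts) is
#' returned alongside.
#'
#' @param config A [simConfig()] object.
#' @return A list of class `spatacSim`: `config`, `genome` (`DNAStringSet`),
#'   `layout`, `barcodeAlignments`, `genomeAlignments` (alignment
#'   data.frames as from [readAlignments()]), and `truth` (list with `reads`,
#'   `molecules`, `mitoVariants`, `affectedSpots`, `ampliconDensityRatio`).
#' @seealso [writeSimulation()] to materialize all external file formats.
#' @export
simulateSpatialAtac <- function(config = simConfig()) {
  stopifnot(inherits(config, "spatacSimConfig"))
  set.seed(config$seed)
  gdef <- config$genome
  seqs <- vapply(seq_len(nrow(gdef)),
                 function(i) randContig(gdef$length[i], gdef$gc[i]),
                 character(1))
  names(seqs) <- gdef$contig
  hasMito <- !is.null(config$mito)
  if (hasMito) {
    mitoSeq <- randContig(config$mito$contigLength, 0.45)
    # the reference base at a variant site must differ from the alternate
    v <- config$mito$variants
    for (k in seq_len(nrow(v))) {
      if (substring(mitoSeq, v$position[k], v$position[k]) == v$alt[k]) {
        repl <- setdiff(c("A", "C", "G", "T"), v$alt[k])[1L]
        substring(mitoSeq, v$position[k], v$position[k]) <- repl
      }
    }
    seqs <- c(seqs, chrM = mitoSeq)
  }
  genome <- DNAStringSet(seqs)

  # spot layout on a near-square array
  ncol <- ceiling(sqrt(config$nSpots))
  barcodes <- character(0)
  while (length(barcodes) < config$nSpots) {
    barcodes <- unique(c(barcodes,
                         randSeqs(config$nSpots + 8L, config$barcodeLength)))
  }
  barcodes <- barcodes[seq_len(config$nSpots)]
  layout <- data.frame(
    barcode = barcodes,
    in_tissue = seq_len(config$nSpots) <=
      round(config$inTissueFraction * config$nSpots),
    array_row = (seq_len(config$nSpots) - 1L) %/% ncol,
    array_col = (seq_len(config$nSpots) - 1L) %% ncol,
    pixel_x = round(runif(config$nSpots, 0, 2000), 1),
    pixel_y = round(runif(config$nSpots, 0, 2000), 1),
    stringsAsFactors = FALSE
  )

  amp <- config$amplicon
  affectedSpots <- character(0)
  if (!is.null(amp) && amp$affectedFraction > 0) {
    affectedSpots <- sample(barcodes,
                            round(amp$affectedFraction * config$nSpots))
  }

  mol <- simulateMolecules(config, layout, affectedSpots)
  reads <- simulateReadsFromMolecules(config, mol)

  mitoOut <- NULL
  if (hasMito) {
    mitoOut <- simulateMitoReads(config, barcodes, genome[["chrM"]],
                                 startId = max(mol$moleculeId) + 1L,
                                 startRead = nrow(reads) + 1L)
    mol <- rbind(mol, mitoOut$molecules)
    reads <- rbind(reads, mitoOut$reads)
  }

  cl <- contigLengths(genome)
  mkRecords <- function(withTags, withSeq) {
    out <- data.frame(
      readName = reads$readName, contig = reads$contig, pos = reads$pos,
      strand = reads$strand, alignedLength = reads$alignedLength,
      mapped = TRUE,
      barcode = if (withTags) reads$barcodeTag else NA_character_,
      umi = if (withTags) reads$umiTag else NA_character_,
      stringsAsFactors = FALSE
    )
    if (withSeq) {
      out$cigar <- paste0(reads$alignedLength, "M")
      out$seq <- reads$seq
      out$qual <- reads$qual
    }
    attr(out, "contigLengths") <- cl
    out
  }
  barcodeAlignments <- mkRecords(withTags = TRUE, withSeq = FALSE)
  if (config$barcodeDropout > 0) {
    drop <- runif(nrow(reads)) < config$barcodeDropout
    barcodeAlignments$barcode[drop] <- NA_character_
    barcodeAlignments$umi[drop] <- NA_character_
  }
  genomeAlignments <- mkRecords(withTags = FALSE, withSeq = TRUE)

  pooled <- if (is.null(amp)) 1 else
    amp$affectedFraction * amp$trueCn / 2 + (1 - amp$affectedFraction)

  structure(list(
    config = config,
    genome = genome,
    layout = layout,
    barcodeAlignments = barcodeAlignments,
    genomeAlignments = genomeAlignments,
    truth = list(
      reads = reads[, c("readName", "barcode", "umi", "moleculeId")],
      molecules = mol,
      mitoVariants = if (hasMito) mitoOut$variantTruth else NULL,
      affectedSpots = affectedSpots,
      ampliconDensityRatio = pooled
    )
  ), class = "spatacSim")
}

# one molecule per non-duplicate read; amplicon-aware position draw
simulateMolecules <- function(config, layout, affectedSpots) {
  gdef <- config$genome
  rl <- config$readLength
  # usable start space per contig (reads must fit)
  usable <- pmax(0, gdef$length - rl)
  amp <- config$amplicon

  nReads <- config$readsPerSpot
  isDup <- matrix(runif(nReads * config$nSpots) < config$duplicateRate,
                  nrow = nReads)
  isDup[1L, ] <- FALSE
  nMolPerSpot <- Matrix::colSums(!isDup)

  spotBc <- rep(layout$barcode, nMolPerSpot)
  nMol <- length(spotBc)
  affected <- spotBc %in% affectedSpots

  contig <- character(nMol); pos <- integer(nMol)
  if (is.null(amp)) {
    w <- usable / sum(usable)
    ctgIdx <- sample.int(nrow(gdef), nMol, replace = TRUE, prob = w)
    contig <- gdef$contig[ctgIdx]
    pos <- as.integer(floor(runif(nMol) * usable[ctgIdx]))
  } else {
    ampLen <- amp$end - amp$start
    outLen <- sum(usable) - ampLen
    boost <- amp$trueCn / 2
    pIn <- ifelse(affected,
                  ampLen * boost / (outLen + ampLen * boost),
                  ampLen / (outLen + ampLen))
    inAmp <- runif(nMol) < pIn
    nIn <- sum(inAmp)
    pos[inAmp] <- as.integer(amp$start + floor(runif(nIn) * (ampLen - rl)))
    contig[inAmp] <- amp$contig
    # outside: draw uniformly over non-amplicon start space
    segs <- data.frame(contig = gdef$contig, from = 0, to = usable)
    ai <- match(amp$contig, segs$contig)
    segs <- rbind(
      segs[-ai, ],
      data.frame(contig = amp$contig, from = 0, to = max(0, amp$start - rl)),
      data.frame(contig = amp$contig, from = amp$end,
                 to = usable[ai])
    )
    segs <- segs[segs$to > segs$from, ]
    segLen <- segs$to - segs$from
    nOut <- sum(!inAmp)
    si <- sample.int(nrow(segs), nOut, replace = TRUE, prob = segLen)
    pos[!inAmp] <- as.integer(segs$from[si] + floor(runif(nOut) * segLen[si]))
    contig[!inAmp] <- segs$contig[si]
  }

  data.frame(
    moleculeId = seq_len(nMol),
    barcode = spotBc,
    umi = randSeqs(nMol, config$umiLength),
    contig = contig,
    pos = pos,
    strand = sample(c("+", "-"), nMol, replace = TRUE),
    alignedLength = rl,
    isMito = FALSE,
    stringsAsFactors = FALSE
  )
}

# emit reads: every molecule once, plus duplicates re-emitting a random
# molecule of the same spot, possibly with a one-base UMI error
simulateReadsFromMolecules <- function(config, mol) {
  nDupTotal <- config$nSpots * config$readsPerSpot - nrow(mol)
  molIdxBySpot <- split(seq_len(nrow(mol)), mol$barcode)
  nMolBySpot <- lengths(molIdxBySpot)
  nDupBySpot <- config$readsPerSpot - nMolBySpot
  dupIdx <- unlist(lapply(names(molIdxBySpot), function(b) {
    k <- nDupBySpot[[b]]
    if (k <= 0L) return(integer(0))
    sample(molIdxBySpot[[b]], k, replace = TRUE)
  }), use.names = FALSE)

  src <- c(seq_len(nrow(mol)), dupIdx)
  umiTag <- mol$umi[src]
  isDupRead <- c(rep(FALSE, nrow(mol)), rep(TRUE, length(dupIdx)))
  if (config$umiErrorRate > 0 && length(dupIdx) > 0L) {
    err <- isDupRead & runif(length(src)) < config$umiErrorRate
    if (any(err)) umiTag[err] <- vapply(umiTag[err], mutateOneBase, character(1))
  }
  ord <- sample.int(length(src))  # shuffle read order
  src <- src[ord]; umiTag <- umiTag[ord]
  data.frame(
    readName = sprintf("read%08d", seq_along(src)),
    barcode = mol$barcode[src],
    umi = mol$umi[src],
    barcodeTag = mol$barcode[src],
    umiTag = umiTag,
    moleculeId = mol$moleculeId[src],
    contig = mol$contig[src],
    pos = mol$pos[src],
    strand = mol$strand[src],
    alignedLength = mol$alignedLength[src],
    seq = "*",
    qual = "*",
    stringsAsFactors = FALSE
  )
}

mutateOneBase <- function(s) {
  i <- sample.int(nchar(s), 1L)
  old <- substring(s, i, i)
  substring(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  s
}

# Mitochondrial reads with injected variant alleles; unique molecules.
# Spots differ in mtDNA abundance (lognormal coverage factor) and in
# per-spot heteroplasmy (beta-dispersed around the clone mean): the
# between-spot variance is what makes forward and reverse support of a
# genuine variant co-vary across spots.
simulateMitoReads <- function(config, barcodes, mitoRef, startId, startRead) {
  m <- config$mito
  covDisp <- m$coverageDispersion %||% 0.3
  hetConc <- m$hetConcentration %||% 20
  rl <- config$readLength
  mitoLen <- length(mitoRef)
  nSpots <- length(barcodes)
  covFactor <- stats::rlnorm(nSpots, -covDisp^2 / 2, covDisp)
  nPerSpot <- pmax(1L, round(m$coveragePerSpot * covFactor * mitoLen / rl))
  n <- sum(nPerSpot)
  bc <- rep(barcodes, nPerSpot)
  spotIdx <- rep(seq_len(nSpots), nPerSpot)
  pos <- as.integer(floor(runif(n) * (mitoLen - rl)))
  strandF <- runif(n) < 0.5
  refChars <- strsplit(as.character(mitoRef), "")[[1L]]

  seqMat <- matrix("", nrow = n, ncol = rl)
  for (j in seq_len(rl)) seqMat[, j] <- refChars[pos + j]

  v <- m$variants
  variantTruth <- vector("list", nrow(v))
  for (k in seq_len(nrow(v))) {
    vp <- v$position[k]
    h <- v$heteroplasmy[k]
    hSpot <- if (h >= 1) rep(1, nSpots) else
      stats::rbeta(nSpots, h * hetConc, (1 - h) * hetConc)
    covers <- vp > pos & vp <= pos + rl
    hRead <- hSpot[spotIdx[covers]]
    pAlt <- ifelse(strandF[covers],
                   pmin(1, 2 * hRead * v$strandBias[k]),
                   pmin(1, 2 * hRead * (1 - v$strandBias[k])))
    isAlt <- runif(sum(covers)) < pAlt
    col <- vp - pos[covers]
    rows <- which(covers)
    seqMat[cbind(rows[isAlt], col[isAlt])] <- v$alt[k]
    tt <- data.table::data.table(barcode = bc[covers], alt = isAlt)
    tt <- tt[, .(altCount = sum(alt), coverage = .N), by = barcode]
    tt[, position := vp]
    tt[, c("altBase", "trueHet") := list(v$alt[k], hSpot[match(barcode, barcodes)])]
    variantTruth[[k]] <- tt
  }
  seqStr <- apply(seqMat, 1L, paste, collapse = "")

  mol <- data.frame(
    moleculeId = startId + seq_len(n) - 1L,
    barcode = bc,
    umi = randSeqs(n, config$umiLength),
    contig = "chrM",
    pos = pos,
    strand = ifelse(strandF, "+", "-"),
    alignedLength = rl,
    isMito = TRUE,
    stringsAsFactors = FALSE
  )
  reads <- data.frame(
    readName = sprintf("read%08d", startRead + seq_len(n) - 1L),
    barcode = bc, umi = mol$umi, barcodeTag = bc, umiTag = mol$umi,
    moleculeId = mol$moleculeId, contig = "chrM", pos = pos,
    strand = mol$strand, alignedLength = rl,
    seq = seqStr, qual = strrep("I", rl),
    stringsAsFactors = FALSE
  )
  list(molecules = mol, reads = reads,
       variantTruth = as.data.frame(data.table::rbindlist(variantTruth)))
}

#' @export
print.spatacSim <- function(x, ...) {
  cat("spatacSim:", nrow(x$layout), "spots,",
      nrow(x$genomeAlignments), "reads,",
      nrow(x$truth$molecules), "truth molecules,",
      length(x$genome), "contigs\n")
  invisible(x)
}

#' Write a simulation to its external file formats
#'
#' Materializes everything a from-files pipeline run needs: the
#' barcode-resolved and genome alignment streams as SAM text, the spot
#' layout CSV, the genome FASTA with a `.fai`-style length index, and the
#' truth tables as TSV.
#'
#' @param sim A `spatacSim` from [simulateSpatialAtac()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    barcode_sam = file.path(dir, "barcode.sam"),
    genome_sam = file.path(dir, "genome.sam"),
    layout = file.path(dir, "layout.csv"),
    fasta = file.path(dir, "genome.fa"),
    fai = file.path(dir, "genome.fa.fai"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    truth_molecules = file.path(dir, "truth_molecules.tsv")
  )
  writeSam(sim$barcodeAlignments, paths[["barcode_sam"]])
  writeSam(sim$genomeAlignments, paths[["genome_sam"]])
  writeSpotLayout(sim$layout, paths[["layout"]])
  writeXStringSet(sim$genome, paths[["fasta"]])
  cl <- contigLengths(sim$genome)
  writeLines(sprintf("%s\t%d\t0\t0\t0", names(cl), as.integer(cl)),
             paths[["fai"]])
  data.table::fwrite(sim$truth$reads, paths[["truth_reads"]], sep = "\t")
  data.table::fwrite(sim$truth$molecules, paths[["truth_molecules"]],
                     sep = "\t")
  if (!is.null(sim$truth$mitoVariants)) {
    paths[["truth_mito"]] <- file.path(dir, "truth_mito.tsv")
    data.table::fwrite(sim$truth$mitoVariants, paths[["truth_mito"]],
                       sep = "\t")
  }
  paths
}

#' Simulate fragments with a controlled TSS insertion profile
#'
#' Draws width-1 fragments whose insertion positions around a set of TSS
#' follow a piecewise-uniform profile: weight `enrichment` within
#' `+/- enrichWidth` of a TSS, weight 1 elsewhere in the `+/- window`
#' profile. Used to calibrate [tssEnrichment()]: `enrichment = 1` is a flat
#' profile (score ~1); `enrichment = E` scores ~E.
#'
#' @param tss TSS `GRanges` (width 1, stranded).
#' @param nInsertions Total insertions to draw (each fragment contributes
#'   its two ends under `countMode = "both"`).
#' @param enrichment Fold enrichment at the center (default 1).
#' @param enrichWidth Half-width in bp of the enriched center (default 50).
#' @param window Profile half-width (default 2000), matching the scorer.
#' @param barcode Spot barcode assigned to the fragments.
#' @return A fragment `GRanges`.
#' @export
simulateTssFragments <- function(tss, nInsertions, enrichment = 1,
                                 enrichWidth = 50L, window = 2000L,
                                 barcode = "SPOT") {
  offsets <- -window:window
  w <- ifelse(abs(offsets) <= enrichWidth, enrichment, 1)
  nFrag <- ceiling(nInsertions / 2)
  ti <- sample.int(length(tss), nFrag, replace = TRUE)
  rel <- sample(offsets, nFrag, replace = TRUE, prob = w / sum(w))
  flip <- as.character(strand(tss))[ti] == "-"
  rel[flip] <- -rel[flip]
  p <- pmax(1L, start(tss)[ti] + rel)
  # width-2 fragments: the two counted ends are adjacent distinct positions
  GRanges(as.character(seqnames(tss))[ti], IRanges(p, width = 2L),
          strand = "+", barcode = barcode, count = 1L)
}

#' Simulate paired accessibility / expression matrices with known DE genes
#'
#' Generates gene-by-spot count matrices for two modalities over clustered
#' spots. A chosen subset of genes is concordantly differential: its counts
#' are multiplied by `effect` in one cluster in both modalities. All other
#' genes share one mean everywhere. Baseline counts are Poisson.
#'
#' @param nGenes Total genes (default 200).
#' @param nDE Number of concordant differential genes (default 50).
#' @param nClusters Number of clusters (default 3).
#' @param spotsPerCluster Spots per cluster (default 40).
#' @param baseline Poisson mean for non-differential counts (default 5).
#' @param effect Fold change applied to DE genes in their up cluster
#'   (default 4, i.e. log2 FC = 2).
#' @return A list: `geneScores`, `geneExpression` (matrices with dimnames),
#'   `clusters` (named vector), `trueDE` (character vector of gene names).
#' @export
simulateConcordanceData <- function(nGenes = 200L, nDE = 50L, nClusters = 3L,
                                    spotsPerCluster = 40L, baseline = 5,
                                    effect = 4) {
  genes <- sprintf("gene%03d", seq_len(nGenes))
  nSpots <- nClusters * spotsPerCluster
  bcs <- randSeqs(nSpots, 16L)
  clusters <- setNames(rep(paste0("C", seq_len(nClusters)),
                           each = spotsPerCluster), bcs)
  deGenes <- genes[seq_len(nDE)]
  upCluster <- rep(paste0("C", seq_len(nClusters)), length.out = nDE)

  drawModality <- function() {
    lambda <- matrix(baseline, nrow = nGenes, ncol = nSpots,
                     dimnames = list(genes, bcs))
    for (k in seq_len(nDE)) {
      lambda[deGenes[k], clusters == upCluster[k]] <- baseline * effect
    }
    matrix(rpois(nGenes * nSpots, lambda), nrow = nGenes,
           dimnames = dimnames(lambda))
  }
  list(geneScores = drawModality(), geneExpression = drawModality(),
       clusters = clusters, trueDE = deGenes)
}
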