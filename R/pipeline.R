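#' Default pipeline configuration
#'
#' Flat key-value configuration for [runPipeline()]. Defaults equal the
#' analysis parameters used throughout the package: 5-kb tiles, 3-Mb/1-Mb
#' copy-number windows with 200 GC-matched backgrounds, strand-correlation
#' pass threshold 0.25, Tn5 shifts (+4, -5). Paths with `NULL` defaults are
#' required (`barcode_sam`, `genome_sam`, `layout`, `out_dir`) or optional
#' stage switches (`fasta` + `blacklist` enable copy number; `mito_ref`
#' enables mitochondrial calling).
#'
#' @param ... Overrides for any config key.
#' @return Named list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    barcode_sam = NULL, genome_sam = NULL, layout = NULL, out_dir = NULL,
    fasta = NULL, blacklist = NULL, mito_ref = NULL,
    tile_width = 5000, cn_window = 3e6, cn_step = 1e6, cn_n_match = 200,
    strand_corr_min = 0.25, min_barcodes = 5,
    tn5_shift_plus = 4, tn5_shift_minus = -5,
    umi_merge = "directional", mito_contig = "chrM",
    keep_off_tissue = FALSE, count_mode = "both", seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg
}

logKV <- function(stage, ...) {
  kv <- list(...)
  message(paste0("stage=", stage, " ",
                 paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
}

#' Run the full processing pipeline
#'
#' Orchestrates transfer, deduplication, fragment construction and the
#' matrix / copy-number / mitochondrial stages in dependency order, logging
#' per-stage record counts as `key=value` lines to standard error and
#' writing a JSON manifest (package version, parameters, per-stage counts,
#' output checksums) alongside the outputs. Any stage failure aborts with an
#' error naming the stage.
#'
#' @param config A [pipelineConfig()] list, or a path to a flat JSON file of
#'   the same keys.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- do.call(pipelineConfig,
                                              jsonlite::read_json(config))
  for (key in c("barcode_sam", "genome_sam", "layout", "out_dir")) {
    if (is.null(config[[key]])) stop("stage 'config': missing key '", key, "'")
  }
  for (key in c("barcode_sam", "genome_sam", "layout", "fasta", "blacklist",
                "mito_ref")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("stage '", sub("_.*", "", key), "': input file not found for '",
           key, "': ", p)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  layout <- stage("layout", readSpotLayout(config$layout))
  barcodeAln <- stage("transfer",
                      readAlignments(config$barcode_sam, requireMapped = FALSE))
  tbl <- stage("transfer", buildReadBarcodeTable(barcodeAln))
  genomeAln <- stage("transfer",
                     readAlignments(config$genome_sam, keepSeq = TRUE))
  attached <- stage("transfer", attachBarcodes(genomeAln, tbl))
  counts$transfer <- c(tbl$summary, attached$summary)
  logKV("transfer", n_table = tbl$summary[["n_assigned"]],
        n_annotated = attached$summary[["n_annotated"]],
        n_dropped = attached$summary[["n_dropped_no_table_entry"]])

  dedup <- stage("dedup",
                 deduplicateAlignments(attached$records,
                                       umiMerge = config$umi_merge))
  counts$dedup <- c(n_in = nrow(attached$records), n_molecules = nrow(dedup),
                    n_reads_out = sum(dedup$count))
  logKV("dedup", n_in = nrow(attached$records), n_molecules = nrow(dedup))

  built <- stage("fragments", buildFragmentsFile(
    dedup, layout, keepOffTissue = config$keep_off_tissue,
    tn5Shift = c(config$tn5_shift_plus, config$tn5_shift_minus),
    mitoContig = config$mito_contig))
  fragPath <- file.path(config$out_dir, "fragments.tsv")
  qcPath <- file.path(config$out_dir, "qc.csv")
  stage("fragments", writeFragments(built$fragments, fragPath))
  stage("fragments", write.csv(built$qc, qcPath, row.names = FALSE))
  counts$fragments <- built$summary
  logKV("fragments", n_fragments = length(built$fragments),
        n_reads_kept = built$summary[["n_reads_kept"]])

  cl <- attr(genomeAln, "contigLengths")
  tiles <- stage("tiles", buildTileMatrix(built$fragments, cl,
                                          tileWidth = config$tile_width,
                                          countMode = config$count_mode))
  stage("tiles", writeSparseMatrix(tiles, file.path(config$out_dir, "tiles")))
  counts$tiles <- c(n_tiles = nrow(tiles),
                    total_insertions = sum(SummarizedExperiment::assay(tiles)))
  logKV("tiles", n_tiles = nrow(tiles),
        total_insertions = counts$tiles[["total_insertions"]])

  if (!is.null(config$fasta)) {
    genome <- stage("cn", readDNAStringSet(config$fasta))
    names(genome) <- sub("\\s.*", "", names(genome))
    blk <- if (is.null(config$blacklist)) GRanges() else
      stage("cn", readBlacklist(config$blacklist))
    windows <- stage("cn", makeGenomeWindows(
      genome[setdiff(names(genome), config$mito_contig)],
      width = config$cn_window, step = config$cn_step, blacklist = blk))
    windows <- stage("cn", windowCn(windows, built$fragments,
                                    nMatch = config$cn_n_match,
                                    countMode = config$count_mode))
    cnPath <- file.path(config$out_dir, "window_cn.tsv")
    stage("cn", write.table(
      data.frame(contig = as.character(seqnames(windows)),
                 start = start(windows) - 1L, end = end(windows),
                 gc_fraction = mcols(windows)$gc_fraction,
                 insertions_per_bp = mcols(windows)$insertions_per_bp,
                 log2fc = mcols(windows)$log2fc, cn = mcols(windows)$cn),
      cnPath, sep = "\t", row.names = FALSE, quote = FALSE))
    counts$cn <- c(n_windows = length(windows))
    logKV("cn", n_windows = length(windows),
          median_cn = round(median(mcols(windows)$cn, na.rm = TRUE), 3))
  }

  if (!is.null(config$mito_ref)) {
    mitoRef <- stage("mito", readDNAStringSet(config$mito_ref))
    mitoRecords <- dedup[dedup$contig == config$mito_contig, , drop = FALSE]
    ac <- stage("mito", countAlleles(mitoRecords, mitoRef,
                                     contig = config$mito_contig))
    variants <- stage("mito", callMitoVariants(
      ac, strandCorrMin = config$strand_corr_min,
      minBarcodes = config$min_barcodes))
    varPath <- file.path(config$out_dir, "mito_variants.tsv")
    stage("mito", write.table(variants, varPath, sep = "\t",
                              row.names = FALSE, quote = FALSE))
    counts$mito <- c(n_candidates = nrow(variants),
                     n_pass = sum(variants$pass))
    logKV("mito", n_candidates = nrow(variants), n_pass = sum(variants$pass))
  }

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "spatac",
    version = as.character(utils::packageVersion("spatac")),
    parameters = config[!vapply(config, is.null, logical(1))],
    stage_counts = lapply(counts, as.list),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(p) list(md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
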