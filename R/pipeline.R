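# Pipeline configuration and the end-to-end driver tying the stages
# together: simulate -> annotate -> clonotype -> diversity -> rescue ->
# phenotype, each toggleable, with a machine-readable JSON summary and a
# run log.

#' Default pipeline configuration
#'
#' Every parameter has a documented default equal to the package's
#' design decisions; see the vignette. The configuration round-trips
#' losslessly through YAML ([readPipelineConfig()]).
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, annotate = TRUE, clonotype = TRUE,
                  diversity = TRUE, rescue = FALSE, phenotype = FALSE),
    paths = list(reference = NULL, contigs = NULL, out_dir = "tcr_out",
                 expression = NULL, cell_metadata = NULL),
    simulation = list(n_cells = 500L, clonality_profile = "polyclonal"),
    annotation = list(score_floor = 40),
    diversity = list(n_target = 1850L, n_perm = 100L, paired_only = FALSE),
    rescue = list(segments = character(), junction_window = 12L,
                  shared_fraction = 0.9),
    phenotype = list(threshold = 0.01, panels = c("activation", "exhaustion")))
}

#' Read (or validate) a pipeline configuration
#'
#' @param config a YAML file path or a configuration list; missing
#'   entries are filled from [defaultPipelineConfig()].
#' @return complete configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  utils::modifyList(defaultPipelineConfig(config$seed %||% 1L), config)
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages against a configuration, writing
#' annotation, clonotype, diversity, rescue and phenotype outputs plus a
#' machine-readable `summary.json` and a `run.log` (seed, package
#' version, parameter echo) into the output directory. A stage failure
#' raises an error naming the stage.
#'
#' @param config YAML path or configuration list; see
#'   [readPipelineConfig()].
#' @param outDir overrides `paths$out_dir`.
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- readPipelineConfig(config)
  outDir <- outDir %||% cfg$paths$out_dir
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE)) {
    stop("cannot create output directory: ", outDir)
  }
  logLines <- c(paste("scTCRdog", as.character(utils::packageVersion("scTCRdog"))),
                paste("seed:", cfg$seed),
                paste("config:", jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                  null = "null", force = TRUE)))
  runStage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(NULL)
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()
  summary <- list(seed = cfg$seed)

  refset <- if (is.null(cfg$paths$reference)) {
    syntheticReference()
  } else {
    annotateAnchors(readSegmentFasta(cfg$paths$reference))
  }
  results$reference <- refset

  results$sim <- runStage("simulate", cfg$stages$simulate, function() {
    simCfg <- do.call(simulationConfig,
                      c(list(seed = cfg$seed), cfg$simulation))
    sim <- simulateRepertoire(refset, simCfg)
    exportSimulation(sim, file.path(outDir, "simulation"))
    sim
  })

  contigs <- if (!is.null(results$sim)) {
    simContigs(results$sim)
  } else if (!is.null(cfg$paths$contigs)) {
    seqs <- Biostrings::readDNAStringSet(cfg$paths$contigs)
    normalizeContigInput(seqs)
  } else {
    NULL
  }

  results$annotations <- runStage("annotate", cfg$stages$annotate, function() {
    if (is.null(contigs)) stop("no contig input (enable simulate or set paths$contigs)")
    ann <- annotateContigs(contigs, refset,
                           scoreFloor = cfg$annotation$score_floor)
    writeContigCsv(ann, file.path(outDir, "contig_annotations.csv"))
    ann2 <- ann
    ann2$umi_count <- contigs$umi_count %||% NA_integer_
    writeAirr(ann2, file.path(outDir, "airr.tsv"))
    ann
  })

  results$clonotypes <- runStage("clonotype", cfg$stages$clonotype, function() {
    if (is.null(results$annotations)) stop("clonotype stage requires annotations")
    cl <- buildClonotypes(results$annotations)
    writeClonotypesCsv(cl, file.path(outDir, "clonotypes.csv"))
    summary$pairing <<- as.list(pairingSummary(cl))
    met <- summaryMetrics(results$annotations, cl,
                          umiCounts = contigs$umi_count %||% NULL)
    summary$metrics <<- met
    cl
  })

  results$diversity <- runStage("diversity", cfg$stages$diversity, function() {
    cl <- results$clonotypes
    if (is.null(cl)) stop("diversity stage requires clonotypes")
    cellMap <- attr(cl, "cells")
    ds <- downsampleDiversity(cellMap$clonotype_id,
                              nTarget = cfg$diversity$n_target,
                              nPerm = cfg$diversity$n_perm,
                              seed = cfg$seed)
    div <- clonotypeDiversity(cl, pairedOnly = cfg$diversity$paired_only)
    bins <- clonotypeBinProportions(cl)
    summary$diversity <<- c(div, list(bin_fractions = as.list(bins),
                                      downsampled = list(
                                        inverse_simpson = ds$inverse_simpson,
                                        bin_fractions = as.list(ds$bin_fractions))))
    list(full = div, bins = bins, downsampled = ds)
  })

  results$rescue <- runStage("rescue", cfg$stages$rescue, function() {
    if (is.null(results$sim)) stop("rescue stage requires a simulated repertoire")
    segs <- cfg$rescue$segments
    if (!length(segs)) {
      segs <- simTruth(results$sim)$rescue$segment
    }
    if (!length(segs)) return(NULL)
    usage <- segmentUsage(results$annotations, refset)
    assessments <- do.call(rbind, lapply(segs, function(s) {
      assessDefects(refset, s, segmentConsensus(results$sim, s),
                    junctionWindow = cfg$rescue$junction_window,
                    sharedFraction = cfg$rescue$shared_fraction)
    }))
    rec <- proposeReannotation(assessments, usage)
    utils::write.csv(assessments, file.path(outDir, "defect_assessments.csv"),
                     row.names = FALSE)
    utils::write.csv(rec, file.path(outDir, "reannotation_proposals.csv"),
                     row.names = FALSE)
    summary$rescue <<- list(assessments = assessments, proposals = rec)
    list(assessments = assessments, proposals = rec)
  })

  results$phenotype <- runStage("phenotype", cfg$stages$phenotype, function() {
    if (is.null(cfg$paths$expression)) {
      stop("phenotype stage requires paths$expression")
    }
    expr <- readExpressionTable(cfg$paths$expression)
    meta <- utils::read.delim(cfg$paths$cell_metadata, stringsAsFactors = FALSE)
    common <- intersect(colnames(expr), meta$barcode)
    meta <- meta[match(common, meta$barcode), , drop = FALSE]
    expr <- expr[, common, drop = FALSE]
    expanded <- labelExpanded(stats::setNames(meta$clonotype_id, meta$barcode),
                              threshold = cfg$phenotype$threshold)
    res <- testMarkers(expr, expanded, panels = cfg$phenotype$panels)
    utils::write.csv(res, file.path(outDir, "marker_tests.csv"),
                     row.names = FALSE)
    summary$phenotype <<- res
    res
  })

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(results)
}

#' Read a gene-by-cell expression table
#'
#' Dense TSV (first column gene names, remaining columns cells) or
#' MatrixMarket `.mtx` with `genes.tsv`/`barcodes.tsv` sidecars next to
#' it.
#'
#' @param path file path.
#' @return numeric matrix, genes x cells.
#' @export
readExpressionTable <- function(path) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("reading MTX requires the Matrix package")
    }
    m <- as.matrix(Matrix::readMM(path))
    dirn <- dirname(path)
    genes <- utils::read.delim(file.path(dirn, "genes.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.delim(file.path(dirn, "barcodes.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    dimnames(m) <- list(genes, cells)
    m
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
}
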