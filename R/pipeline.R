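#' @importFrom yaml read_yaml write_yaml
#' @importFrom jsonlite write_json
NULL

# full config schema with defaults; NULL = no default, optional
.configDefaults <- function() {
  list(
    seed = 1L,
    library = NULL,
    counts = NULL,
    fastq = NULL,
    gmt = NULL,
    design = list(ko = c("KO1", "KO2"), control = c("C1", "C2")),
    simulate = list(
      n_genes = 513L, clones_per_gene = c(4L, 10L), n_nontargeting = 100L,
      abundance_mu = 0, abundance_sigma = 1, depth = 5e6, dispersion = 0.05,
      sl_genes = character(), n_sl_genes = 0L, fold_depletion = 10,
      penetrance = 0.8, enr_genes = character(), fold_enrichment = 5,
      error_rate = 0.01, read_length = 21L, barcode_length = 21L,
      depth_mode = "random", write_fastq = FALSE),
    count = list(max_mismatch = 0L, offset = 0L, try_revcomp = FALSE),
    hitcall = list(pseudocount = 1, normalization = "cpm",
                   fold_threshold = 5, min_depleted = 2L, min_fivefold = 1L,
                   include_controls = TRUE, min_count = 10,
                   threshold_z = -1.5),
    enrichment = list(alpha = 0.01, edge_threshold = 0.25)
  )
}

# reject unknown keys, fill defaults (one level of nesting)
.resolveConfig <- function(config) {
  def <- .configDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  nested <- c("design", "simulate", "count", "hitcall", "enrichment")
  for (blk in intersect(nested, names(config))) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad))
        stop("unknown config key(s) in '", blk, "': ",
             paste(bad, collapse = ", "))
    }
  }
  res <- def
  for (k in names(config)) {
    if (k %in% nested && !is.null(config[[k]])) {
      for (k2 in names(config[[k]])) res[[k]][[k2]] <- config[[k]][[k2]]
    } else if (!is.null(config[[k]])) {
      res[[k]] <- config[[k]]
    }
  }
  # the simulate block only applies when no real inputs are given
  res$run_simulate <- is.null(res$library) && is.null(res$counts) &&
    is.null(res$fastq) || "simulate" %in% names(config)
  res
}

#' Read and validate a pipeline configuration
#'
#' YAML key-value configuration covering every tunable of every stage.
#' Unknown keys are rejected; defaults are filled in, and the fully
#' resolved configuration is written next to the outputs by
#' [runPipeline()] so a run is auditable and repeatable.
#'
#' @param path YAML config path.
#' @return the resolved configuration list.
#' @export
readPipelineConfig <- function(path) {
  .resolveConfig(yaml::read_yaml(path))
}

#' Run the full screen analysis pipeline
#'
#' Executes, in order: synthetic screen generation (when no real inputs are
#' configured), barcode counting (when FASTQ input is present), ratio-based
#' hit calling with z-scores and ranked reports, and gene-set
#' over-representation with enrichment-map export (when a GMT is
#' configured). Every stage logs its parameters and tallies (excluded
#' clones, unassigned reads) to `pipeline.log`; all outputs are plain
#' TSV/JSON so each stage can be re-run independently. Re-running with the
#' same configuration and seed reproduces byte-identical outputs.
#'
#' Output files: `resolved_config.yaml`, `library.tsv`, `truth.tsv` (when
#' simulated), `counts.tsv`, `shrna_stats.tsv`, `gene_calls.tsv`,
#' `enriched_genes.tsv`, `summary.json`, and with a GMT `enrichment.tsv`,
#' `em_nodes.tsv`, `em_edges.tsv`. On stage failure, partial outputs are
#' kept alongside a `PIPELINE_FAILED` marker naming the stage.
#'
#' @param config path to a YAML config, or a config list.
#' @param outdir output directory, created if needed.
#' @param seed optional integer overriding the config seed.
#' @param verbose echo log lines as messages (default FALSE).
#' @return invisibly, a list with the key tables (`counts`, `stats`,
#'   `geneCalls`, `enrichment`, `summary`) and the resolved config.
#' @export
runPipeline <- function(config, outdir, seed = NULL, verbose = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else .resolveConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
    invisible(NULL)
  }
  flush_log <- function()
    writeLines(log_lines, file.path(outdir, "pipeline.log"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("[", name, "] FAILED: ", conditionMessage(e))
      flush_log()
      writeLines(paste0("failed at stage: ", name),
                 file.path(outdir, "PIPELINE_FAILED"))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  res_cfg <- cfg
  res_cfg$run_simulate <- NULL
  yaml::write_yaml(res_cfg, file.path(outdir, "resolved_config.yaml"))
  log("[config] seed = ", cfg$seed)

  lib <- NULL; cm <- NULL; truth <- NULL
  if (cfg$run_simulate) {
    stage("simulate", {
      sp <- cfg$simulate
      sl <- toupper(as.character(sp$sl_genes))
      if (length(sl) == 0L && sp$n_sl_genes > 0L) {
        set.seed(.childSeed(cfg$seed, 5L))
        sl <- sample(sprintf("KIN%04d", seq_len(sp$n_genes)),
                     sp$n_sl_genes)
      }
      params <- SimulationParams(
        nGenes = sp$n_genes, clonesPerGene = unlist(sp$clones_per_gene),
        nNontargeting = sp$n_nontargeting,
        abundanceMu = sp$abundance_mu, abundanceSigma = sp$abundance_sigma,
        depth = sp$depth, dispersion = sp$dispersion,
        slGenes = sl, foldDepletion = sp$fold_depletion,
        penetrance = sp$penetrance,
        enrGenes = toupper(as.character(sp$enr_genes)),
        foldEnrichment = sp$fold_enrichment,
        errorRate = sp$error_rate, readLength = sp$read_length,
        barcodeLength = sp$barcode_length, depthMode = sp$depth_mode,
        seed = cfg$seed)
      lib <- simulateLibrary(params)
      sim <- simulateCounts(lib, params)
      truth <- sim$truth
      writeLibrary(lib, file.path(outdir, "library.tsv"))
      utils::write.table(truth, file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log("[simulate] ", length(lib), " clones, ",
          librarySummary(lib)$n_genes, " genes, ", length(sl), " SL genes")
      if (isTRUE(sp$write_fastq)) {
        paths <- simulateFastq(sim$counts, lib, params,
                               file.path(outdir, "fastq"))
        cfg$fastq <- as.list(paths)
        log("[simulate] FASTQ written for ",
            length(paths), " samples")
      } else {
        cm <- sim$counts
      }
    })
  } else {
    stage("input", {
      if (is.null(cfg$library))
        stop("a library annotation is required with real inputs")
      lib <- readLibrary(cfg$library)
      log("[input] library: ", length(lib), " clones")
      if (!is.null(cfg$counts)) {
        cm <- readCounts(cfg$counts, lib)
        log("[input] counts: ", ncol(cm), " samples")
      }
    })
  }

  if (is.null(cm)) {
    stage("count", {
      if (is.null(cfg$fastq)) stop("no counts or FASTQ input available")
      fq <- unlist(cfg$fastq)
      cm <- countReads(fq, lib,
                        maxMismatch = cfg$count$max_mismatch,
                        offset = cfg$count$offset,
                        tryRevComp = cfg$count$try_revcomp)
      ua <- unassignedCounts(cm)
      log("[count] assigned = ", sum(SummarizedExperiment::assay(cm)),
          ", no_match = ", sum(ua$no_match),
          ", ambiguous = ", sum(ua$ambiguous))
    })
  }
  stage("count", writeCounts(cm, file.path(outdir, "counts.tsv")))

  stats <- NULL; calls <- NULL; summ <- NULL
  stage("call", {
    design <- ScreenDesign(ko = unlist(cfg$design$ko),
                           control = unlist(cfg$design$control))
    hc <- cfg$hitcall
    stats <- computeRatios(cm, design, pseudocount = hc$pseudocount,
                            normalization = hc$normalization,
                            minCount = hc$min_count)
    stats <- flagFivefold(stats, foldThreshold = hc$fold_threshold)
    stats <- computeZscores(stats,
                             includeControls = hc$include_controls)
    calls <- callGenes(stats, minDepleted = hc$min_depleted,
                        minFivefold = hc$min_fivefold)
    summ <- screenReport(stats, calls, thresholdZ = hc$threshold_z,
                          outdir = outdir)
    log("[call] ", summ$n_candidates, " candidate gene(s); ",
        summ$n_low_abundance, " low-abundance clone(s); ",
        summ$n_excluded_zero_control, " excluded zero-control clone(s)")
  })

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    stage("enrich", {
      gsc <- readGmt(cfg$gmt)
      hits <- calls$gene[calls$candidate]
      universe <- setdiff(unique(targetGenes(lib)), NONTARGETING)
      enr <- enrich(hits, universe, gsc, alpha = cfg$enrichment$alpha)
      utils::write.table(.roundNum(as.data.frame(enr)),
                         file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      exportNetwork(enr, outdir,
                    edgeThreshold = cfg$enrichment$edge_threshold)
      log("[enrich] ", sum(enr$significant_p), " set(s) at p < ",
          cfg$enrichment$alpha)
    })
  }
  flush_log()
  invisible(list(counts = cm, stats = stats, geneCalls = calls,
                 enrichment = enr, truth = truth, summary = summ,
                 config = res_cfg))
}
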