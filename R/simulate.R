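#' Construct simulation parameters for a synthetic pooled screen
#'
#' Defaults emulate a kinome-scale MISSION-style screen: 513 target genes
#' with 4-10 hairpins each plus 100 nontargeting controls, log-normal
#' relative clone abundance (the one-integration-per-cell regime of a
#' low-MOI transduction), negative-binomial sequencing noise, and a
#' two-genotype (knockout vs control) by two-replicate sample layout.
#' Synthetic-lethal truth genes have each hairpin rendered effective with
#' probability `penetrance`; effective hairpins are depleted
#' `foldDepletion`-fold in the knockout samples only.
#'
#' @param nGenes number of targeted genes (default 513).
#' @param clonesPerGene inclusive range of clones per gene, drawn uniformly
#'   (default `c(4, 10)`).
#' @param nNontargeting number of nontargeting control clones (default 100).
#' @param abundanceMu,abundanceSigma log-normal parameters of relative clone
#'   abundance (defaults 0 and 1).
#' @param depth expected reads per sample (default 5e6; tests use much less).
#' @param dispersion NB overdispersion phi, variance `m + phi m^2`
#'   (default 0.05; 0 gives Poisson noise).
#' @param slGenes character vector of synthetic-lethal truth genes; must be
#'   a subset of the simulated gene universe (default none).
#' @param foldDepletion multiplicative count reduction in knockout samples
#'   for effective clones of `slGenes` (default 10).
#' @param penetrance probability each clone of a truth gene is effective
#'   (default 0.8).
#' @param enrGenes,foldEnrichment optional enriched truth genes and their
#'   fold increase (defaults none / 5).
#' @param errorRate per-base substitution probability in emitted FASTQ reads
#'   (default 0.01).
#' @param readLength emitted read length, `>= barcodeLength`
#'   (default = `barcodeLength`).
#' @param barcodeLength barcode length in nt (default 21).
#' @param depthMode `"random"` (default; per-sample totals vary) or
#'   `"exact"` (multinomial at exactly `depth` reads per sample, used for
#'   conservation tests).
#' @param seed master seed; identical parameters and seed give bit-identical
#'   libraries, counts and FASTQ.
#' @return a validated [SimulationParams-class] object.
#' @examples
#' p <- SimulationParams(nGenes = 20, depth = 1e4, seed = 1)
#' lib <- simulateLibrary(p)
#' librarySummary(lib)$n_genes
#' @export
SimulationParams <- function(nGenes = 513, clonesPerGene = c(4, 10),
                             nNontargeting = 100,
                             abundanceMu = 0, abundanceSigma = 1,
                             depth = 5e6, dispersion = 0.05,
                             slGenes = character(), foldDepletion = 10,
                             penetrance = 0.8,
                             enrGenes = character(), foldEnrichment = 5,
                             errorRate = 0.01, readLength = barcodeLength,
                             barcodeLength = 21,
                             depthMode = "random", seed = 1) {
  new("SimulationParams",
      nGenes = as.integer(nGenes),
      clonesPerGene = as.integer(clonesPerGene),
      nNontargeting = as.integer(nNontargeting),
      abundanceMu = as.numeric(abundanceMu),
      abundanceSigma = as.numeric(abundanceSigma),
      depth = as.numeric(depth), dispersion = as.numeric(dispersion),
      slGenes = toupper(as.character(slGenes)),
      foldDepletion = as.numeric(foldDepletion),
      penetrance = as.numeric(penetrance),
      enrGenes = toupper(as.character(enrGenes)),
      foldEnrichment = as.numeric(foldEnrichment),
      errorRate = as.numeric(errorRate),
      readLength = as.integer(readLength),
      barcodeLength = as.integer(barcodeLength),
      depthMode = depthMode, seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nGenes, "genes x",
      paste(object@clonesPerGene, collapse = "-"), "clones/gene +",
      object@nNontargeting, "controls\n")
  cat("  depth:", format(object@depth, big.mark = ","),
      sprintf("(%s), phi = %g", object@depthMode, object@dispersion), "\n")
  cat("  truth: ", length(object@slGenes), " SL genes (fold ",
      object@foldDepletion, ", penetrance ", object@penetrance, "), ",
      length(object@enrGenes), " enriched\n", sep = "")
  cat("  seed:", object@seed, "\n")
})

# deterministic per-stage seed derived from the master seed
.childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage) %% 2147483647)
}

# n distinct random barcodes of length L
.randomBarcodes <- function(n, L) {
  if (n > 4^L / 2)
    stop("barcode space too small: cannot draw ", n,
         " distinct barcodes of length ", L)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * L, replace = TRUE),
                nrow = k)
    apply(m, 1L, paste, collapse = "")
  }
  bc <- unique(draw(n))
  while (length(bc) < n)
    bc <- unique(c(bc, draw(n - length(bc))))
  bc[seq_len(n)]
}

#' Simulate an shRNA library annotation
#'
#' Generates `nGenes` genes named `KIN0001...`, each with a uniform draw of
#' clones from the configured range, plus nontargeting controls; every clone
#' receives a distinct random barcode of the configured length.
#'
#' @param params a [SimulationParams-class].
#' @return an [ShRNALibrary-class]; deterministic under `params@seed`.
#' @export
simulateLibrary <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(.childSeed(params@seed, 1L))
  genes <- sprintf("KIN%04d", seq_len(params@nGenes))
  cpg_range <- seq(params@clonesPerGene[1L], params@clonesPerGene[2L])
  cpg <- if (params@nGenes == 0L) integer()
  else if (length(cpg_range) == 1L) rep(cpg_range, params@nGenes)
  else sample(cpg_range, params@nGenes, replace = TRUE)
  gene <- c(rep(genes, cpg), rep(NONTARGETING, params@nNontargeting))
  clone_id <- c(
    unlist(lapply(seq_along(genes),
                  function(i) sprintf("%s_sh%02d", genes[i], seq_len(cpg[i]))),
           use.names = FALSE),
    sprintf("NTC_sh%03d", seq_len(params@nNontargeting)))
  if (length(clone_id) == 0L)
    stop("simulated library would be empty; increase nGenes or nNontargeting")
  bc <- .randomBarcodes(length(clone_id), params@barcodeLength)
  ShRNALibrary(clone_id, gene, bc)
}

#' Simulate screen counts with ground-truth labels
#'
#' Each clone gets a relative abundance from the log-normal prior; expected
#' counts are `depth x abundance`, multiplied by `1/foldDepletion` in the
#' knockout samples for effective clones of synthetic-lethal genes (and by
#' `foldEnrichment` for effective clones of enriched genes). Counts are
#' drawn per sample from a negative binomial with variance `m + phi m^2`
#' (Poisson when `phi = 0`), or from a multinomial at exactly `depth` reads
#' when `depthMode = "exact"`. Samples are named `KO1, KO2, C1, C2`.
#'
#' Effectiveness is Bernoulli(`penetrance`) per clone, resampled so every
#' truth gene keeps at least one effective clone.
#'
#' @param lib an [ShRNALibrary-class].
#' @param params a [SimulationParams-class]; `slGenes` and `enrGenes` must
#'   be genes of `lib`.
#' @return a list with `counts` (a [ScreenCounts-class]) and `truth`
#'   (data.frame: `clone_id`, `gene`, `class` in
#'   neutral/synthetic_lethal/enriched, and logical `effective`).
#' @export
simulateCounts <- function(lib, params) {
  stopifnot(is(lib, "ShRNALibrary"), is(params, "SimulationParams"))
  validObject(params)
  if (params@depth <= 0) stop("depth must be > 0")
  genes <- unique(targetGenes(lib))
  miss <- setdiff(c(params@slGenes, params@enrGenes), genes)
  if (length(miss))
    stop("truth gene(s) not in library: ", paste(miss, collapse = ", "))
  if (params@penetrance == 0 &&
      (length(params@slGenes) || length(params@enrGenes)))
    stop("penetrance = 0 cannot give every truth gene an effective clone")
  set.seed(.childSeed(params@seed, 2L))

  n <- length(lib)
  gene <- targetGenes(lib)
  cls <- rep("neutral", n)
  cls[gene %in% params@slGenes] <- "synthetic_lethal"
  cls[gene %in% params@enrGenes] <- "enriched"

  effective <- rep(FALSE, n)
  idx <- which(cls != "neutral")
  if (length(idx)) {
    effective[idx] <- runif(length(idx)) < params@penetrance
    # every truth gene must keep >= 1 effective clone
    for (g in unique(gene[idx])) {
      gi <- which(gene == g)
      while (!any(effective[gi]))
        effective[gi] <- runif(length(gi)) < params@penetrance
    }
  }

  ab <- if (params@abundanceSigma == 0) rep(exp(params@abundanceMu), n)
        else rlnorm(n, params@abundanceMu, params@abundanceSigma)
  p <- ab / sum(ab)
  effect <- rep(1, n)
  effect[effective & cls == "synthetic_lethal"] <- 1 / params@foldDepletion
  effect[effective & cls == "enriched"] <- params@foldEnrichment

  samples <- c("KO1", "KO2", "C1", "C2")
  is_ko <- c(TRUE, TRUE, FALSE, FALSE)
  m <- matrix(0L, n, 4L, dimnames = list(cloneIds(lib), samples))
  for (j in seq_along(samples)) {
    mu <- params@depth * p * (if (is_ko[j]) effect else 1)
    m[, j] <- if (params@depthMode == "exact")
      as.integer(rmultinom(1L, size = as.integer(params@depth),
                           prob = mu / sum(mu)))
    else if (params@dispersion == 0) rpois(n, mu)
    else rnbinom(n, mu = mu, size = 1 / params@dispersion)
  }
  truth <- data.frame(clone_id = cloneIds(lib), gene = gene,
                      class = cls, effective = effective,
                      stringsAsFactors = FALSE)
  list(counts = ScreenCounts(m, gene = gene), truth = truth)
}

# inject iid per-base substitution errors into equal-length reads
.injectErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  chars <- strsplit(paste(reads, collapse = ""), "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # substitute with one of the three other bases, uniformly
    chars[hit] <- bases[(match(chars[hit], bases) - 1L +
                         sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  s <- paste(chars, collapse = "")
  substring(s, seq(1L, nchar(s), by = L), seq(L, nchar(s), by = L))
}

#' Emit per-sample FASTQ files for a simulated screen
#'
#' Sample `s` emits exactly `sum(counts[, s])` reads. Each read carries its
#' clone's barcode at offset 0, padded to `readLength` with `A` stuffer
#' bases; every base is then substituted independently with probability
#' `errorRate`. Records are 4-line Sanger FASTQ with constant quality `I`
#' (Phred+33 score 40), so output is bit-reproducible under the seed.
#'
#' @param counts a [ScreenCounts-class] (e.g. from [simulateCounts()]).
#' @param lib the matching [ShRNALibrary-class].
#' @param params a [SimulationParams-class] (`errorRate`, `readLength`,
#'   `seed`).
#' @param outdir output directory, created if needed.
#' @return named character vector of FASTQ paths, one per sample.
#' @export
simulateFastq <- function(counts, lib, params, outdir) {
  stopifnot(is(counts, "ScreenCounts"), is(lib, "ShRNALibrary"),
            is(params, "SimulationParams"))
  if (params@readLength < barcodeLength(lib))
    stop("readLength (", params@readLength, ") < barcode length (",
         barcodeLength(lib), ")")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(counts, "counts")
  m <- m[cloneIds(lib), , drop = FALSE]
  stuffer <- strrep("A", params@readLength - barcodeLength(lib))
  template <- paste0(as.character(cloneSequences(lib)), stuffer)
  paths <- character(0)
  for (j in seq_len(ncol(m))) {
    sample_id <- colnames(m)[j]
    set.seed(.childSeed(params@seed, 10L + j))
    reads <- .injectErrors(rep(template, m[, j]), params@errorRate)
    ids <- if (length(reads) == 0L) character()
    else paste0(sample_id, ":", rep(cloneIds(lib), m[, j]), ":",
                seq_along(reads))
    path <- file.path(outdir, paste0(sample_id, ".fastq"))
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- ids
    qual <- Biostrings::BStringSet(rep(strrep("I", params@readLength),
                                       length(x)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
    paths[sample_id] <- path
  }
  paths
}
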