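#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet width subseq reverseComplement
#' @importFrom stats rnbinom rpois rlnorm rbinom runif rmultinom sd phyper
#'   p.adjust setNames
#' @importFrom utils read.delim write.table combn
NULL

#' Reserved gene token for nontargeting control hairpins
#'
#' Clones annotated with this gene symbol are treated as neutral controls:
#' they are excluded from the gene universe used for candidate calling and
#' enrichment, but retained for counting and (by default) for z-score
#' standardization.
#'
#' @export
NONTARGETING <- "NONTARGETING"

#' ShRNALibrary: annotation of a pooled shRNA library
#'
#' Holds the clone-to-gene map of a pooled short-hairpin library together
#' with each clone's barcode (hairpin) sequence as a
#' [Biostrings::DNAStringSet]. All barcodes share one declared length.
#' Control hairpins carry the reserved gene symbol [NONTARGETING].
#'
#' @slot cloneId character, unique clone identifiers (library order).
#' @slot gene character, upper-cased target gene symbol per clone.
#' @slot sequences [Biostrings::DNAStringSet] of barcode sequences, named by
#'   clone id, all of width `barcodeLength`.
#' @slot barcodeLength integer(1), barcode length in nucleotides.
#'
#' @seealso [ShRNALibrary()] (constructor), [readLibrary()],
#'   [librarySummary()]
#' @exportClass ShRNALibrary
setClass("ShRNALibrary",
  slots = c(
    cloneId = "character",
    gene = "character",
    sequences = "DNAStringSet",
    barcodeLength = "integer"
  )
)

setValidity("ShRNALibrary", function(object) {
  n <- length(object@cloneId)
  msg <- character()
  if (length(object@gene) != n || length(object@sequences) != n)
    msg <- c(msg, "cloneId, gene and sequences must have equal length")
  if (n == 0L)
    msg <- c(msg, "library must contain at least one clone")
  dup <- object@cloneId[duplicated(object@cloneId)]
  if (length(dup))
    msg <- c(msg, paste0("duplicate clone_id: ",
                         paste(unique(dup), collapse = ", ")))
  if (length(object@barcodeLength) != 1L || is.na(object@barcodeLength))
    msg <- c(msg, "barcodeLength must be a single integer")
  if (n > 0L && length(msg) == 0L) {
    w <- Biostrings::width(object@sequences)
    if (any(w != object@barcodeLength))
      msg <- c(msg, sprintf(
        "ragged sequence lengths: expected %d nt, found %s",
        object@barcodeLength,
        paste(unique(w[w != object@barcodeLength]), collapse = ", ")))
    bad <- grep("^[ACGT]+$", as.character(object@sequences), invert = TRUE)
    if (length(bad))
      msg <- c(msg, paste0("non-ACGT character in sequence at row(s): ",
                           paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ScreenCounts: clone-by-sample read counts from a pooled screen
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `"counts"` assay
#' holds the nonnegative integer read count ("raw copy number") of each
#' library clone in each sequenced sample. Row metadata carries the target
#' gene; column metadata carries the per-sample unassigned-read tallies
#' (`no_match`, `ambiguous`) so that, per sample,
#' assigned + no_match + ambiguous equals the reads processed.
#'
#' @seealso [ScreenCounts()] (constructor), [countReads()], [readCounts()]
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
  if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("no_match", "ambiguous")) {
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
    else if (any(cd[[col]] < 0))
      msg <- c(msg, sprintf("colData '%s' must be nonnegative", col))
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "rownames (clone ids) are required")
  if (length(msg)) msg else TRUE
})

#' ScreenDesign: sample roles in a two-genotype, two-replicate screen
#'
#' Names the two knockout-genotype replicate samples (the screen's samples
#' #1 and #2) and the two control-genotype replicates (#3 and #4). The four
#' cross-replicate ratios are formed knockout/control: 1/3, 1/4, 2/3, 2/4.
#'
#' @slot koSamples character(2), knockout replicate sample ids.
#' @slot controlSamples character(2), control replicate sample ids.
#'
#' @seealso [ScreenDesign()] (constructor), [computeRatios()]
#' @exportClass ScreenDesign
setClass("ScreenDesign",
  slots = c(koSamples = "character", controlSamples = "character")
)

setValidity("ScreenDesign", function(object) {
  ids <- c(object@koSamples, object@controlSamples)
  msg <- character()
  if (length(object@koSamples) != 2L || length(object@controlSamples) != 2L)
    msg <- c(msg, "exactly two knockout and two control samples are required")
  if (anyDuplicated(ids))
    msg <- c(msg, "sample ids must be distinct")
  if (any(is.na(ids)) || any(!nzchar(ids)))
    msg <- c(msg, "sample ids must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' SimulationParams: generative model settings for a synthetic screen
#'
#' Parameters of the synthetic pooled dropout screen: library shape
#' (genes, clones per gene, nontargeting controls), a log-normal prior on
#' relative clone abundance, sequencing depth, negative-binomial
#' overdispersion (variance `m + phi * m^2`), the designated
#' synthetic-lethal (and optionally enriched) truth genes with their fold
#' effects and per-clone penetrance, FASTQ emission settings, and the master
#' seed from which all stage seeds derive.
#'
#' @slot nGenes integer(1), number of targeted genes.
#' @slot clonesPerGene integer(2), inclusive range of clones per gene.
#' @slot nNontargeting integer(1), number of nontargeting control clones.
#' @slot abundanceMu,abundanceSigma numeric(1), log-normal parameters of
#'   relative clone abundance.
#' @slot depth numeric(1), expected reads per sample.
#' @slot dispersion numeric(1), NB overdispersion phi >= 0 (0 = Poisson).
#' @slot slGenes character, synthetic-lethal truth genes.
#' @slot foldDepletion numeric(1) > 1, count reduction in knockout samples
#'   for effective clones of synthetic-lethal genes.
#' @slot penetrance numeric(1) in (0, 1], probability a clone of a
#'   non-neutral gene is effective.
#' @slot enrGenes character, enriched truth genes (optional).
#' @slot foldEnrichment numeric(1) > 1, count increase for effective clones
#'   of enriched genes.
#' @slot errorRate numeric(1), per-base substitution rate for FASTQ reads.
#' @slot readLength integer(1), emitted read length (>= barcodeLength).
#' @slot barcodeLength integer(1), barcode length in nucleotides.
#' @slot depthMode `"random"` (per-sample total is a sum of NB draws) or
#'   `"exact"` (multinomial at exactly `depth` reads).
#' @slot seed integer(1), master seed.
#'
#' @seealso [SimulationParams()] (constructor), [simulateLibrary()],
#'   [simulateCounts()], [simulateFastq()]
#' @exportClass SimulationParams
setClass("SimulationParams",
  slots = c(
    nGenes = "integer", clonesPerGene = "integer", nNontargeting = "integer",
    abundanceMu = "numeric", abundanceSigma = "numeric",
    depth = "numeric", dispersion = "numeric",
    slGenes = "character", foldDepletion = "numeric", penetrance = "numeric",
    enrGenes = "character", foldEnrichment = "numeric",
    errorRate = "numeric", readLength = "integer", barcodeLength = "integer",
    depthMode = "character", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (length(object@clonesPerGene) != 2L ||
      any(object@clonesPerGene < 1L) ||
      object@clonesPerGene[1L] > object@clonesPerGene[2L])
    msg <- c(msg, "clonesPerGene must be an increasing pair of integers >= 1")
  if (object@nNontargeting < 0L) msg <- c(msg, "nNontargeting must be >= 0")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion (phi) must be >= 0")
  if (object@foldDepletion <= 1) msg <- c(msg, "foldDepletion must be > 1")
  if (object@foldEnrichment <= 1) msg <- c(msg, "foldEnrichment must be > 1")
  if (object@penetrance < 0 || object@penetrance > 1)
    msg <- c(msg, "penetrance must be in [0, 1]")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (object@readLength < object@barcodeLength)
    msg <- c(msg, "readLength must be >= barcodeLength")
  if (!object@depthMode %in% c("random", "exact"))
    msg <- c(msg, "depthMode must be 'random' or 'exact'")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene sets loaded from a GMT file
#'
#' A list of gene-symbol sets (upper-cased, deduplicated) keyed by unique
#' set names, as used for hypergeometric over-representation analysis.
#'
#' @slot sets named list of character vectors; no set is empty.
#' @slot source character(1), provenance tag (e.g. the GMT path).
#'
#' @seealso [readGmt()], [enrich()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(sets = "list", source = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (length(object@sets) && (is.null(nm) || any(!nzchar(nm))))
    msg <- c(msg, "all sets must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, paste0("duplicate set name: ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (length(msg)) msg else TRUE
})
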