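#' @rdname ShRNALibrary-class
#' @param x,object a `ShRNALibrary`
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname ShRNALibrary-class
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname ShRNALibrary-class
#' @export
setGeneric("cloneSequences", function(x) standardGeneric("cloneSequences"))

#' @rdname ShRNALibrary-class
#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @rdname ShRNALibrary-class
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))

#' @rdname librarySummary
#' @export
setGeneric("librarySummary", function(x) standardGeneric("librarySummary"))

#' @rdname ScreenCounts-class
#' @param x a `ScreenCounts`
#' @export
setGeneric("unassignedCounts",
           function(x) standardGeneric("unassignedCounts"))

#' @rdname ScreenDesign-class
#' @export
setGeneric("koSamples", function(x) standardGeneric("koSamples"))

#' @rdname ScreenDesign-class
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname GeneSetCollection-class
#' @param x a `GeneSetCollection`
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
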