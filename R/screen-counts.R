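#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, clones x samples, with clone ids as
#'   rownames and sample ids as colnames.
#' @param gene optional character vector of target genes (one per clone),
#'   stored in `rowData`.
#' @param unassigned optional data.frame with columns `no_match` and
#'   `ambiguous`, one row per sample; defaults to zero tallies.
#' @return a [ScreenCounts-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), nrow = 5,
#'             dimnames = list(paste0("sh", 1:5), c("KO1","KO2","C1","C2")))
#' ScreenCounts(m, gene = c("G1","G1","G2","G2","NONTARGETING"))
#' @export
ScreenCounts <- function(counts, gene = NULL, unassigned = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(unassigned))
    unassigned <- data.frame(no_match = rep(0L, ncol(counts)),
                             ambiguous = rep(0L, ncol(counts)))
  cd <- S4Vectors::DataFrame(unassigned, row.names = colnames(counts))
  rd <- if (is.null(gene)) S4Vectors::DataFrame(row.names = rownames(counts))
        else S4Vectors::DataFrame(gene = gene, row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  new("ScreenCounts", se)
}

#' @describeIn ScreenCounts-class per-sample tallies of reads that matched
#'   no barcode (`no_match`) or tied between clones (`ambiguous`).
#' @export
setMethod("unassignedCounts", "ScreenCounts", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(no_match = cd$no_match, ambiguous = cd$ambiguous,
             row.names = rownames(cd))
})

setMethod("show", "ScreenCounts", function(object) {
  cat("ScreenCounts:", nrow(object), "clones x", ncol(object), "samples\n")
  cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
  ua <- unassignedCounts(object)
  if (any(ua > 0))
    cat("  unassigned reads: no_match =", sum(ua$no_match),
        ", ambiguous =", sum(ua$ambiguous), "\n")
})

#' Read or write a clone count matrix as TSV
#'
#' The TSV has a `clone_id` column followed by one integer column per
#' sample. On read, cells are checked to be nonnegative integers (errors
#' report the offending row and column) and, when a library is supplied,
#' clone ids must match it exactly; rows are returned in library order.
#'
#' @param path TSV path.
#' @param lib optional [ShRNALibrary-class] to validate and order against.
#' @return [readCounts()] returns a [ScreenCounts-class];
#'   [writeCounts()] returns `path` invisibly.
#' @export
readCounts <- function(path, lib = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "clone_id")
    stop("counts TSV must start with a 'clone_id' column")
  if (ncol(df) < 2L) stop("counts TSV has no sample columns")
  ids <- as.character(df$clone_id)
  m <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf(
        "invalid count '%s' at (row %d, column '%s'): counts must be %s",
        m[bad[1L], j], bad[1L], colnames(m)[j], "nonnegative integers"))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  gene <- NULL
  if (!is.null(lib)) {
    stray <- setdiff(ids, cloneIds(lib))
    if (length(stray))
      stop("clone id(s) not in library: ", paste(stray, collapse = ", "))
    missing <- setdiff(cloneIds(lib), ids)
    if (length(missing))
      stop("clone id(s) missing from counts: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    m <- m[cloneIds(lib), , drop = FALSE]
    gene <- targetGenes(lib)
  }
  ScreenCounts(m, gene = gene)
}

#' @param cm a [ScreenCounts-class].
#' @rdname readCounts
#' @export
writeCounts <- function(cm, path) {
  stopifnot(is(cm, "ScreenCounts"))
  m <- SummarizedExperiment::assay(cm, "counts")
  df <- data.frame(clone_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
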