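#' Construct an ShRNALibrary from clone annotation vectors
#'
#' Gene symbols are normalized by trimming whitespace and upper-casing; no
#' alias resolution is attempted, so the gene universe is exactly what the
#' annotation declares. Clones whose gene equals [NONTARGETING] are control
#' hairpins. Duplicate barcode sequences across different clone ids are
#' permitted (real vendor libraries contain them) but flagged with a
#' warning; the ambiguity is resolved at counting time, where a read
#' matching several clones equally well is tallied as ambiguous.
#'
#' @param clone_id character, unique clone identifiers.
#' @param gene character, target gene symbol per clone (or [NONTARGETING]).
#' @param sequence character or [Biostrings::DNAStringSet], barcode per
#'   clone; all must share one length.
#' @return a validated [ShRNALibrary-class] object.
#' @examples
#' lib <- ShRNALibrary(
#'   clone_id = c("sh1", "sh2", "sh3"),
#'   gene = c("GENEA", "GENEA", "NONTARGETING"),
#'   sequence = c("ACGTACGTACGTACGTACGTA",
#'                "TGCATGCATGCATGCATGCAT",
#'                "GGGTTTAAACCCGGGTTTAAA"))
#' librarySummary(lib)
#' @export
ShRNALibrary <- function(clone_id, gene, sequence) {
  clone_id <- as.character(clone_id)
  gene <- toupper(trimws(as.character(gene)))
  if (is.character(sequence)) {
    sequence <- toupper(trimws(sequence))
    bad <- grep("^[ACGT]+$", sequence, invert = TRUE)
    if (length(bad))
      stop("non-ACGT character in sequence at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  names(sequence) <- clone_id
  L <- unique(Biostrings::width(sequence))
  if (length(L) != 1L)
    stop("ragged sequence lengths: ", paste(L, collapse = ", "),
         " (all barcodes must share one length)")
  dupseq <- as.character(sequence)[duplicated(as.character(sequence))]
  if (length(dupseq))
    warning(length(unique(dupseq)),
            " barcode sequence(s) shared by multiple clones; reads matching",
            " them will be counted as ambiguous")
  new("ShRNALibrary", cloneId = clone_id, gene = gene,
      sequences = sequence, barcodeLength = as.integer(L))
}

#' @rdname ShRNALibrary-class
#' @export
setMethod("cloneIds", "ShRNALibrary", function(x) x@cloneId)

#' @rdname ShRNALibrary-class
#' @export
setMethod("targetGenes", "ShRNALibrary", function(x) x@gene)

#' @rdname ShRNALibrary-class
#' @export
setMethod("cloneSequences", "ShRNALibrary", function(x) x@sequences)

#' @rdname ShRNALibrary-class
#' @export
setMethod("barcodeLength", "ShRNALibrary", function(x) x@barcodeLength)

#' @rdname ShRNALibrary-class
#' @export
setMethod("length", "ShRNALibrary", function(x) length(x@cloneId))

#' @describeIn ShRNALibrary-class gene-to-clone-ids map; every clone appears
#'   under exactly one gene key, controls under `NONTARGETING`.
#' @export
setMethod("geneIndex", "ShRNALibrary", function(x) {
  split(x@cloneId, x@gene)
})

setMethod("show", "ShRNALibrary", function(object) {
  s <- librarySummary(object)
  cat("ShRNALibrary with", s$n_clones, "clones targeting",
      s$n_genes, "genes\n")
  cat("  barcode length:", object@barcodeLength, "nt\n")
  cat("  nontargeting controls:", s$n_controls, "\n")
  if (s$n_genes > 0L)
    cat("  clones per gene:", min(s$clones_per_gene), "-",
        max(s$clones_per_gene), "\n")
})

#' Summarize the shape of an shRNA library
#'
#' @param x an [ShRNALibrary-class].
#' @return a list with `n_clones`, `n_genes` (excluding nontargeting
#'   controls), `clones_per_gene` (named integer vector over target genes),
#'   and `n_controls`.
#' @rdname librarySummary
#' @export
setMethod("librarySummary", "ShRNALibrary", function(x) {
  ctrl <- x@gene == NONTARGETING
  cpg <- table(x@gene[!ctrl])
  list(
    n_clones = length(x@cloneId),
    n_genes = length(cpg),
    clones_per_gene = setNames(as.integer(cpg), names(cpg)),
    n_controls = sum(ctrl)
  )
})

#' Read an shRNA library annotation from TSV
#'
#' Expects a tab-separated file with header columns `clone_id`, `gene`,
#' `sequence` (UTF-8; LF or CRLF line endings). Row order is preserved;
#' gene symbols are upper-cased.
#'
#' @param path path to the annotation TSV.
#' @return a validated [ShRNALibrary-class].
#' @seealso [writeLibrary()], [writeLibraryFasta()]
#' @export
readLibrary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("clone_id", "gene", "sequence")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("library TSV is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    stop("library TSV contains no data rows")
  dup <- df$clone_id[duplicated(df$clone_id)]
  if (length(dup))
    stop("duplicate clone_id: ", paste(unique(dup), collapse = ", "))
  ShRNALibrary(df$clone_id, df$gene, df$sequence)
}

#' Write an shRNA library annotation to TSV
#'
#' Writes `clone_id<TAB>gene<TAB>sequence` with a header; reading the file
#' back with [readLibrary()] reproduces the library field-for-field.
#'
#' @param lib an [ShRNALibrary-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLibrary <- function(lib, path) {
  stopifnot(is(lib, "ShRNALibrary"))
  validObject(lib)
  df <- data.frame(clone_id = cloneIds(lib), gene = targetGenes(lib),
                   sequence = as.character(cloneSequences(lib)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export library barcodes as FASTA
#'
#' Record id is the clone id and the description is the target gene, so
#' standard sequence tools can carry the annotation along.
#'
#' @inheritParams writeLibrary
#' @return the path, invisibly.
#' @export
writeLibraryFasta <- function(lib, path) {
  stopifnot(is(lib, "ShRNALibrary"))
  seqs <- cloneSequences(lib)
  names(seqs) <- paste(cloneIds(lib), targetGenes(lib))
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}
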