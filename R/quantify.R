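#' Count reads per clone by barcode matching
#'
#' Assigns each FASTQ read to the unique library clone whose barcode has
#' minimal Hamming distance, at most `maxMismatch`, to the read's barcode
#' window (`offset + 1 .. offset + barcodeLength`). Reads tying between
#' clones at the minimal distance are tallied as `ambiguous`; reads with no
#' barcode within `maxMismatch` (or shorter than the window) as `no_match`,
#' so per sample assigned + no_match + ambiguous equals the reads processed.
#'
#' Exact matches are resolved through a hashed lookup; only imperfect reads
#' fall back to a full Hamming scan, which does not change the semantics:
#' results equal a brute-force all-pairs scan. Base qualities are ignored.
#'
#' @param fastqFiles named character vector, sample id -> FASTQ path (plain
#'   or gzip).
#' @param lib an [ShRNALibrary-class].
#' @param maxMismatch maximum Hamming distance accepted (default 0,
#'   exact-match counting).
#' @param offset 0-based position of the barcode within the read
#'   (default 0).
#' @param tryRevComp also match the reverse complement of the window; a
#'   read whose two strands match different clones is ambiguous
#'   (default FALSE).
#' @return a [ScreenCounts-class] in library clone order.
#' @examples
#' \dontrun{
#' cm <- countReads(c(KO1 = "ko1.fastq.gz", KO2 = "ko2.fastq.gz",
#'                    C1 = "c1.fastq.gz", C2 = "c2.fastq.gz"), lib)
#' }
#' @export
countReads <- function(fastqFiles, lib, maxMismatch = 0L, offset = 0L,
                       tryRevComp = FALSE) {
  stopifnot(is(lib, "ShRNALibrary"), maxMismatch >= 0L, offset >= 0L)
  if (is.null(names(fastqFiles)) || any(!nzchar(names(fastqFiles))))
    stop("fastqFiles must be a named vector: sample_id = path")
  bc <- as.character(cloneSequences(lib))
  L <- barcodeLength(lib)
  n <- length(lib)
  samples <- names(fastqFiles)
  m <- matrix(0L, n, length(samples),
              dimnames = list(cloneIds(lib), samples))
  no_match <- ambiguous <- setNames(integer(length(samples)), samples)

  for (s in samples) {
    reads <- tryCatch(
      Biostrings::readDNAStringSet(fastqFiles[[s]], format = "fastq"),
      error = function(e) stop("malformed FASTQ in sample '", s, "' (",
                               fastqFiles[[s]], "): ", conditionMessage(e)))
    short <- Biostrings::width(reads) < offset + L
    if (any(short)) {
      warning(sum(short), " read(s) shorter than the barcode window in ",
              "sample '", s, "'; counted as no_match")
      no_match[s] <- no_match[s] + sum(short)
      reads <- reads[!short]
    }
    if (length(reads) == 0L) next
    win <- as.character(Biostrings::subseq(reads, offset + 1L, offset + L))
    asn <- .assignWindows(win, bc, maxMismatch)
    if (tryRevComp) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win)))
      asn2 <- .assignWindows(rc, bc, maxMismatch)
      asn <- .combineStrands(asn, asn2)
    }
    hit <- asn > 0L
    m[, s] <- m[, s] + tabulate(asn[hit], nbins = n)
    ambiguous[s] <- ambiguous[s] + sum(asn == -1L)
    no_match[s] <- no_match[s] + sum(asn == 0L)
  }
  ScreenCounts(m, gene = targetGenes(lib),
               unassigned = data.frame(no_match = as.integer(no_match),
                                       ambiguous = as.integer(ambiguous)))
}

# assign barcode windows to clone indices: >0 clone index, 0 no_match,
# -1 ambiguous (tie at the minimal distance)
.assignWindows <- function(win, bc, maxMismatch) {
  dup_bc <- unique(bc[duplicated(bc)])
  asn <- match(win, bc)            # exact matches, hashed
  asn[!is.na(asn) & bc[asn] %in% dup_bc] <- -1L  # exact tie between clones
  miss <- which(is.na(asn))
  asn[is.na(asn)] <- 0L
  if (maxMismatch > 0L && length(miss)) {
    uw <- unique(win[miss])
    scan <- hamming_scan(uw, bc, as.integer(maxMismatch))
    res <- ifelse(is.na(scan[, 1L]), 0L,
                  ifelse(scan[, 3L] > 1L, -1L, scan[, 1L]))
    asn[miss] <- res[match(win[miss], uw)]
  }
  asn
}

# forward/reverse assignments -> single call per read
.combineStrands <- function(f, r) {
  out <- f
  out[f == 0L] <- r[f == 0L]                       # only reverse matched
  both <- f > 0L & r > 0L & f != r                 # strands disagree
  out[both] <- -1L
  out[f == -1L | r == -1L] <- -1L                  # any strand ambiguous
  out
}
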