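# write a minimal 4-line-record FASTQ for constructed reads
write_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(seq_along(reads), function(i)
    c(paste0("@r", i), reads[i], "+",
      strrep("I", nchar(reads[i])))))
  writeLines(lines, path)
  path
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

test_that("error-free FASTQ inverts to the simulated count matrix", {
  p <- SimulationParams(nGenes = 15, nNontargeting = 5, depth = 8000,
                        errorRate = 0, seed = 21)
  lib <- simulateLibrary(p)
  sim <- simulateCounts(lib, p)
  fq <- simulateFastq(sim$counts, lib, p, tempfile())
  cm <- countReads(fq, lib, maxMismatch = 0)
  expect_identical(SummarizedExperiment::assay(cm, "counts"),
                   SummarizedExperiment::assay(sim$counts, "counts"))
  ua <- unassignedCounts(cm)
  expect_true(all(ua$no_match == 0) && all(ua$ambiguous == 0))
})

test_that("mismatch tolerance and ties follow the minimal-distance rule", {
  lib <- make_fixture_library()
  bc <- as.character(cloneSequences(lib))
  # one substitution away from clone sh1, >=2 from all others
  read1 <- mutate_at(bc[1], 5, setdiff(c("A","C","G","T"),
                                       substr(bc[1], 5, 5))[1])
  d <- unname(naive_hamming_assign(read1, bc, 21))
  expect_identical(d, 1L)  # fixture sanity: nearest is sh1
  fqs <- c(S1 = write_fastq(read1))
  cm0 <- countReads(fqs, lib, maxMismatch = 0)
  expect_identical(sum(SummarizedExperiment::assay(cm0)), 0L)
  expect_identical(unassignedCounts(cm0)$no_match, 1L)
  cm1 <- countReads(fqs, lib, maxMismatch = 1)
  expect_identical(SummarizedExperiment::assay(cm1)["sh1", "S1"], 1L)

  # read equidistant (distance 1) from two clones -> ambiguous
  libAB <- ShRNALibrary(c("A", "B"), c("G1", "G2"),
                        c(paste0("A", strrep("C", 20)),
                          paste0("G", strrep("C", 20))))
  readT <- paste0("T", strrep("C", 20))
  cmT <- countReads(c(S1 = write_fastq(readT)), libAB, maxMismatch = 1)
  expect_identical(sum(SummarizedExperiment::assay(cmT)), 0L)
  expect_identical(unassignedCounts(cmT)$ambiguous, 1L)
})

test_that("reads matching a duplicated barcode are ambiguous", {
  libdup <- suppressWarnings(
    ShRNALibrary(c("a", "b", "c"), c("G1", "G2", "G3"),
                 c(strrep("ACG", 7), strrep("ACG", 7), strrep("T", 21))))
  fqs <- c(S1 = write_fastq(c(strrep("ACG", 7), strrep("T", 21))))
  cm <- countReads(fqs, libdup, maxMismatch = 0)
  expect_identical(unassignedCounts(cm)$ambiguous, 1L)
  expect_identical(SummarizedExperiment::assay(cm)["c", "S1"], 1L)
})

test_that("assignments equal the brute-force Hamming oracle", {
  set.seed(31)
  p <- SimulationParams(nGenes = 12, nNontargeting = 4, depth = 600,
                        errorRate = 0.05, seed = 31)
  lib <- simulateLibrary(p)
  sim <- simulateCounts(lib, p)
  fq <- simulateFastq(sim$counts, lib, p, tempfile())
  bc <- as.character(cloneSequences(lib))
  for (mm in c(0L, 1L, 2L)) {
    cm <- countReads(fq, lib, maxMismatch = mm)
    for (s in names(fq)) {
      reads <- as.character(
        Biostrings::readDNAStringSet(fq[[s]], format = "fastq"))
      oracle <- naive_hamming_assign(reads, bc, mm)
      counts_oracle <- tabulate(oracle[oracle > 0], nbins = length(bc))
      expect_identical(unname(SummarizedExperiment::assay(cm)[, s]),
                       counts_oracle)
      expect_identical(unassignedCounts(cm)[s, "ambiguous"],
                       sum(oracle == -1L))
      expect_identical(unassignedCounts(cm)[s, "no_match"],
                       sum(oracle == 0L))
    }
  }
})

test_that("raising maxMismatch never decreases a clone count", {
  p <- SimulationParams(nGenes = 10, nNontargeting = 0, depth = 2000,
                        errorRate = 0.05, seed = 32)
  lib <- simulateLibrary(p)
  sim <- simulateCounts(lib, p)
  fq <- simulateFastq(sim$counts, lib, p, tempfile())
  prev <- NULL
  for (mm in 0:3) {
    m <- SummarizedExperiment::assay(countReads(fq, lib, maxMismatch = mm))
    if (!is.null(prev)) expect_true(all(m >= prev))
    prev <- m
  }
})

test_that("read conservation holds per sample", {
  p <- SimulationParams(nGenes = 10, nNontargeting = 5, depth = 3000,
                        errorRate = 0.03, seed = 33)
  lib <- simulateLibrary(p)
  sim <- simulateCounts(lib, p)
  fq <- simulateFastq(sim$counts, lib, p, tempfile())
  cm <- countReads(fq, lib, maxMismatch = 1)
  ua <- unassignedCounts(cm)
  total_in <- colSums(SummarizedExperiment::assay(sim$counts))
  total_out <- colSums(SummarizedExperiment::assay(cm)) +
    ua$no_match + ua$ambiguous
  expect_identical(unname(total_out), unname(total_in))
})

test_that("short reads are tallied as no_match with a warning", {
  lib <- make_fixture_library()
  bc <- as.character(cloneSequences(lib))
  fqs <- c(S1 = write_fastq(c(bc[1], substr(bc[2], 1, 10))))
  expect_warning(cm <- countReads(fqs, lib), "shorter")
  expect_identical(unassignedCounts(cm)$no_match, 1L)
  expect_identical(SummarizedExperiment::assay(cm)["sh1", "S1"], 1L)
})

test_that("reverse-complement matching resolves strand, flags conflicts", {
  lib <- make_fixture_library()
  bc <- as.character(cloneSequences(lib))
  rc1 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(bc[1])))
  fqs <- c(S1 = write_fastq(rc1))
  cm_fwd <- countReads(fqs, lib, maxMismatch = 0)
  expect_identical(sum(SummarizedExperiment::assay(cm_fwd)), 0L)
  cm_rc <- countReads(fqs, lib, maxMismatch = 0, tryRevComp = TRUE)
  expect_identical(SummarizedExperiment::assay(cm_rc)["sh1", "S1"], 1L)
})

test_that("counts TSV round-trips and rejects bad cells and stray clones", {
  lib <- make_fixture_library()
  set.seed(1)
  m <- matrix(rpois(32, 40), 8, 4,
              dimnames = list(cloneIds(lib), c("KO1", "KO2", "C1", "C2")))
  cm <- ScreenCounts(m, gene = targetGenes(lib))
  p <- tempfile(fileext = ".tsv")
  writeCounts(cm, p)
  cm2 <- readCounts(p, lib)
  expect_identical(SummarizedExperiment::assay(cm2),
                   SummarizedExperiment::assay(cm))

  bad <- readLines(p)
  bad[3] <- sub("^(\\S+\t)\\d+", "\\1-3", bad[3])
  pb <- tempfile(); writeLines(bad, pb)
  expect_error(readCounts(pb, lib), "row 2.*KO1|KO1.*row 2")

  stray <- readLines(p)
  stray[2] <- sub("^\\S+", "shX", stray[2])
  ps <- tempfile(); writeLines(stray, ps)
  expect_error(readCounts(ps, lib), "shX")
})
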