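# Independent reference implementations used as oracles. Written as plain
# loops over the stated rules, deliberately naive and separate from the
# package's code paths.

# Naive re-evaluation of the screen rules on a raw counts matrix with
# columns KO1, KO2, C1, C2. Returns per-clone flags and per-gene candidacy.
naive_hitcall <- function(m, gene, pseudocount = 1,
                          normalization = "raw", fold = 5,
                          min_depleted = 2, min_fivefold = 1) {
  stopifnot(ncol(m) == 4L)
  x <- m
  if (normalization == "cpm")
    for (j in 1:4) x[, j] <- m[, j] / sum(m[, j]) * 1e6
  n <- nrow(m)
  fivefold <- character(n)
  depleted <- logical(n)
  for (i in seq_len(n)) {
    rs <- c(
      (x[i, 1] + pseudocount) / (x[i, 3] + pseudocount),
      (x[i, 1] + pseudocount) / (x[i, 4] + pseudocount),
      (x[i, 2] + pseudocount) / (x[i, 3] + pseudocount),
      (x[i, 2] + pseudocount) / (x[i, 4] + pseudocount))
    fivefold[i] <- if (all(rs <= 1 / fold)) "depleted"
      else if (all(rs >= fold)) "enriched" else "none"
    depleted[i] <- all(rs < 1)
  }
  genes <- sort(unique(gene[gene != "NONTARGETING"]))
  candidate <- logical(length(genes))
  names(candidate) <- genes
  for (g in genes) {
    gi <- which(gene == g)
    candidate[g] <- sum(depleted[gi]) >= min_depleted &&
      sum(fivefold[gi] == "depleted") >= min_fivefold
  }
  list(fivefold = fivefold, depleted_all4 = depleted,
       candidate = candidate)
}

# Brute-force all-pairs Hamming assignment: >0 clone index, 0 no match,
# -1 tie at the minimal distance.
naive_hamming_assign <- function(reads, barcodes, max_mismatch) {
  bchars <- strsplit(barcodes, "")
  vapply(strsplit(reads, ""), function(rc) {
    d <- vapply(bchars, function(bc) sum(bc != rc), integer(1))
    dmin <- min(d)
    if (dmin > max_mismatch) return(0L)
    hits <- which(d == dmin)
    if (length(hits) > 1L) -1L else unname(hits)
  }, integer(1))
}

# Hypergeometric upper tail by exhaustive enumeration of all size-n draws
# from a universe of N items of which the first K are "in the set".
hyper_enum <- function(k, K, n, N) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Hypergeometric upper tail as an explicit combinatorial sum (independent
# of stats::phyper); exact for moderate N.
hyper_sum <- function(k, K, n, N) {
  j <- seq(k, min(n, K))
  if (k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# 8-clone fixture: two genes with four hairpins each
make_fixture_library <- function() {
  ids <- sprintf("sh%d", 1:8)
  genes <- rep(c("G1", "G2"), each = 4)
  set.seed(42)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
    character(1))
  ShRNALibrary(ids, genes, seqs)
}

write_fixture_tsv <- function(lib, path = tempfile(fileext = ".tsv")) {
  writeLibrary(lib, path)
  path
}

# small ScreenCounts with given 4-column layout
make_counts <- function(m, gene = NULL) {
  colnames(m) <- c("KO1", "KO2", "C1", "C2")
  if (is.null(rownames(m))) rownames(m) <- sprintf("sh%d", seq_len(nrow(m)))
  ScreenCounts(m, gene = gene)
}

default_design <- function() ScreenDesign(c("KO1", "KO2"), c("C1", "C2"))
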