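#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols. Symbols are upper-cased and deduplicated
#' within a set; a line with fewer than three fields or a duplicated set
#' name is a hard error.
#'
#' @param path GMT path.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1L), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate set name: ", paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f) {
    g <- unique(toupper(trimws(f[-(1:2)])))
    g[nzchar(g)]
  })
  names(sets) <- nm
  new("GeneSetCollection", sets = sets, source = path)
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets",
      if (length(object@source)) paste0("(", object@source, ")"), "\n")
  if (length(object@sets))
    cat("  set sizes:", min(lengths(object@sets)), "-",
        max(lengths(object@sets)), "genes\n")
})

#' Hypergeometric upper-tail probability of a gene-set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` hit genes
#' from a universe of `N` of which `K` belong to the set. Vectorized;
#' argument bounds (`max(0, n + K - N) <= k <= min(n, K)`) are enforced.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n number of hits within the universe.
#' @param N universe size.
#' @return upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeomUpper(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 0) ||
      any(K > N) || any(n > N) ||
      any(k > pmin(n, K)) || any(k < pmax(0, n + K - N)))
    stop("hypergeometric bounds violated: need max(0, n+K-N) <= k <= ",
         "min(n, K) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of hits in gene sets
#'
#' Tests each gene set for over-representation of the hit genes within the
#' screened universe (by default the library's target genes — the screen
#' only interrogated those, so a genome-wide background would inflate
#' significance). Reports the unadjusted p-value with a flag at
#' `p < alpha` (the convention used for screen enrichment maps) alongside
#' Benjamini-Hochberg q-values with a flag at `q < alpha`.
#'
#' @param hits character vector of hit gene symbols; genes outside the
#'   universe are dropped with a warning.
#' @param universe character vector of background gene symbols.
#' @param gsc a [GeneSetCollection-class].
#' @param alpha significance threshold applied to both flags
#'   (default 0.01).
#' @return a [S4Vectors::DataFrame] sorted by p: `set`, `N`, `K`, `n`,
#'   `k`, `p`, `q`, `significant_p`, `significant_q`, `overlap`
#'   (comma-separated gene list). Only sets overlapping the universe are
#'   tested.
#' @export
enrich <- function(hits, universe, gsc, alpha = 0.01) {
  stopifnot(is(gsc, "GeneSetCollection"))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe")
  hits <- unique(toupper(hits))
  out <- setdiff(hits, universe)
  if (length(out)) {
    warning(length(out), " hit gene(s) outside the universe dropped: ",
            paste(utils::head(out, 5L), collapse = ", "))
    hits <- intersect(hits, universe)
  }
  N <- length(universe)
  n <- length(hits)
  sets <- lapply(geneSets(gsc), intersect, universe)
  keep <- lengths(sets) >= 1L
  sets <- sets[keep]
  K <- lengths(sets)
  overlap <- lapply(sets, intersect, hits)
  k <- lengths(overlap)
  p <- hypergeomUpper(k, K, n, N)
  q <- stats::p.adjust(p, method = "BH")
  res <- S4Vectors::DataFrame(
    set = names(sets), N = N, K = as.integer(K), n = n, k = as.integer(k),
    p = p, q = q,
    significant_p = p < alpha, significant_q = q < alpha,
    overlap = vapply(overlap, function(g)
      paste(sort(g), collapse = ","), character(1L)))
  res <- res[order(res$p, res$set), , drop = FALSE]
  S4Vectors::metadata(res) <- list(alpha = alpha, n_hits = n, universe = N)
  res
}

#' Export an enrichment map as node and edge tables
#'
#' Nodes are the tested gene sets; edges connect sets whose overlap gene
#' lists have Jaccard similarity at or above `edgeThreshold`. The TSVs load
#' directly into standard network viewers.
#'
#' @param results output of [enrich()].
#' @param outdir output directory for `em_nodes.tsv` and `em_edges.tsv`;
#'   `NULL` to skip writing.
#' @param edgeThreshold minimum Jaccard similarity for an edge
#'   (default 0.25).
#' @param significantOnly restrict nodes to sets with `significant_p`
#'   (default FALSE).
#' @return a list with data.frames `nodes` (`set`, `K`, `k`, `p`, `q`) and
#'   `edges` (`set_i`, `set_j`, `jaccard`), invisibly when writing.
#' @export
exportNetwork <- function(results, outdir = NULL, edgeThreshold = 0.25,
                          significantOnly = FALSE) {
  df <- as.data.frame(results)
  if (significantOnly) df <- df[df$significant_p, , drop = FALSE]
  nodes <- df[, c("set", "K", "k", "p", "q")]
  ov <- lapply(strsplit(df$overlap, ",", fixed = TRUE),
               function(g) g[nzchar(g)])
  names(ov) <- df$set
  edges <- data.frame(set_i = character(), set_j = character(),
                      jaccard = numeric())
  if (nrow(df) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(df)), 2L)
    jac <- apply(pairs, 2L, function(ij) {
      a <- ov[[ij[1L]]]; b <- ov[[ij[2L]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    keep <- jac >= edgeThreshold & jac > 0
    edges <- data.frame(set_i = df$set[pairs[1L, keep]],
                        set_j = df$set[pairs[2L, keep]],
                        jaccard = jac[keep])
  }
  out <- list(nodes = nodes, edges = edges)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(.roundNum(nodes),
                       file.path(outdir, "em_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(.roundNum(edges),
                       file.path(outdir, "em_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
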