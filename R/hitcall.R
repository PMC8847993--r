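#' Construct a ScreenDesign
#'
#' @param ko character(2), knockout-genotype replicate sample ids (the
#'   screen's samples #1 and #2).
#' @param control character(2), control-genotype replicate sample ids
#'   (samples #3 and #4).
#' @return a validated [ScreenDesign-class].
#' @examples
#' ScreenDesign(ko = c("KO1", "KO2"), control = c("C1", "C2"))
#' @export
ScreenDesign <- function(ko, control) {
  new("ScreenDesign", koSamples = as.character(ko),
      controlSamples = as.character(control))
}

#' @rdname ScreenDesign-class
#' @param x a `ScreenDesign`
#' @export
setMethod("koSamples", "ScreenDesign", function(x) x@koSamples)

#' @rdname ScreenDesign-class
#' @export
setMethod("controlSamples", "ScreenDesign", function(x) x@controlSamples)

setMethod("show", "ScreenDesign", function(object) {
  cat("ScreenDesign: knockout =", paste(object@koSamples, collapse = ", "),
      "| control =", paste(object@controlSamples, collapse = ", "), "\n")
})

#' Per-clone cross-replicate copy-number ratios
#'
#' For each clone, computes the four knockout/control ratios between the two
#' knockout replicates (#1, #2) and the two control replicates (#3, #4):
#' r13, r14, r23, r24, each `(n_ko + pseudocount) / (n_ctrl + pseudocount)`
#' on raw or depth-normalized (counts-per-million) counts, plus the mean of
#' their log2 values. A ratio below 1 means fewer copies in the knockout —
#' the direction of candidate synthetic lethality.
#'
#' With `pseudocount = 0`, clones with a zero count in either control
#' replicate have undefined ratios; they are excluded (NA ratios, flagged
#' `excluded_zero_control`) with a message reporting the tally.
#'
#' Clones whose four raw counts are all below `minCount` are flagged
#' `low_abundance`; their ratios are unstable and they are left out of
#' z-score standardization (see [computeZscores()]) while remaining in all
#' tables.
#'
#' @param cm a [ScreenCounts-class].
#' @param design a [ScreenDesign-class]; all four samples must be columns
#'   of `cm`.
#' @param pseudocount nonnegative constant added to numerator and
#'   denominator (default 1).
#' @param normalization `"cpm"` (default; per-sample counts per million, so
#'   replicate depth differences cancel) or `"raw"` (ratios of raw copy
#'   numbers).
#' @param minCount low-abundance threshold on raw counts (default 10).
#' @return a [S4Vectors::DataFrame] with one row per clone: `clone_id`,
#'   `gene`, `r13`, `r14`, `r23`, `r24`, `mean_log2_ratio`,
#'   `low_abundance`, `excluded_zero_control`. Parameters are recorded in
#'   `metadata()`.
#' @export
computeRatios <- function(cm, design, pseudocount = 1,
                          normalization = c("cpm", "raw"), minCount = 10) {
  stopifnot(is(cm, "ScreenCounts"), is(design, "ScreenDesign"),
            pseudocount >= 0)
  normalization <- match.arg(normalization)
  validObject(design)
  ids <- c(koSamples(design), controlSamples(design))
  miss <- setdiff(ids, colnames(cm))
  if (length(miss))
    stop("design sample(s) not in counts: ", paste(miss, collapse = ", "))
  raw <- SummarizedExperiment::assay(cm, "counts")[, ids, drop = FALSE]
  zero_col <- colSums(raw) == 0
  if (any(zero_col) && normalization == "cpm")
    stop("sample(s) with all-zero counts: ",
         paste(ids[zero_col], collapse = ", "),
         " (depth normalization impossible; suspect input)")
  m <- if (normalization == "cpm")
    t(t(raw) / colSums(raw)) * 1e6 else raw
  pc <- pseudocount

  excluded <- rep(FALSE, nrow(raw))
  if (pc == 0) {
    excluded <- raw[, 3L] == 0 | raw[, 4L] == 0
    if (any(excluded))
      message(sum(excluded), " clone(s) with a zero control count excluded",
              " from ratios (pseudocount = 0)")
  }
  r <- unname(cbind(
    (m[, 1L] + pc) / (m[, 3L] + pc),
    (m[, 1L] + pc) / (m[, 4L] + pc),
    (m[, 2L] + pc) / (m[, 3L] + pc),
    (m[, 2L] + pc) / (m[, 4L] + pc)))
  colnames(r) <- c("r13", "r14", "r23", "r24")
  r[excluded, ] <- NA_real_
  mlr <- rowMeans(log2(r))

  gene <- SummarizedExperiment::rowData(cm)$gene
  if (is.null(gene)) gene <- rep(NA_character_, nrow(raw))
  out <- S4Vectors::DataFrame(
    clone_id = rownames(raw), gene = gene,
    r13 = as.vector(r[, "r13"]), r14 = as.vector(r[, "r14"]),
    r23 = as.vector(r[, "r23"]), r24 = as.vector(r[, "r24"]),
    mean_log2_ratio = mlr,
    low_abundance = rowSums(raw < minCount) == 4L,
    excluded_zero_control = excluded,
    row.names = rownames(raw))
  S4Vectors::metadata(out) <- list(
    design = list(ko = koSamples(design), control = controlSamples(design)),
    pseudocount = pc, normalization = normalization, min_count = minCount)
  out
}

#' Flag five-fold dropout and depletion across all four comparisons
#'
#' A clone is `fivefold = "depleted"` when all four ratios are at most
#' `1/foldThreshold`, `"enriched"` when all four are at least
#' `foldThreshold`, otherwise `"none"`. Independently, `depleted_all4` is
#' TRUE when all four ratios are below 1 (the synthetic-lethality
#' direction). Clones with NA ratios get `"none"` / FALSE.
#'
#' @param stats output of [computeRatios()].
#' @param foldThreshold fold-change threshold > 1 (default 5).
#' @return `stats` with `fivefold` and `depleted_all4` columns added.
#' @export
flagFivefold <- function(stats, foldThreshold = 5) {
  stopifnot(foldThreshold > 1)
  r <- as.matrix(as.data.frame(stats[, c("r13", "r14", "r23", "r24")]))
  ok <- rowSums(is.na(r)) == 0L
  dep5 <- ok & rowSums(r <= 1 / foldThreshold) == 4L
  enr5 <- ok & rowSums(r >= foldThreshold) == 4L
  stats$fivefold <- ifelse(dep5, "depleted",
                           ifelse(enr5, "enriched", "none"))
  stats$depleted_all4 <- ok & rowSums(r < 1) == 4L
  S4Vectors::metadata(stats)$fold_threshold <- foldThreshold
  stats
}

#' Aggregate clone flags into gene-level candidate calls
#'
#' A gene is a synthetic-lethality candidate when at least `minDepleted` of
#' its clones are depleted in all four comparisons and at least
#' `minFivefold` of those show the five-fold dropout. Nontargeting controls
#' are excluded from the gene table. Genes with the mirror-image enrichment
#' pattern are tallied separately (`n_enriched`, `n_fivefold_enriched`) and
#' never mixed into the candidate flag.
#'
#' @param stats output of [flagFivefold()] (and optionally
#'   [computeZscores()], in which case `best_z` is the gene's minimum
#'   clone z-score).
#' @param minDepleted minimum clones with all four ratios below 1
#'   (default 2).
#' @param minFivefold minimum clones with the five-fold dropout flag
#'   (default 1).
#' @return a [S4Vectors::DataFrame], one row per gene: `gene`, `n_clones`,
#'   `n_depleted`, `n_fivefold_depleted`, `n_enriched`,
#'   `n_fivefold_enriched`, `candidate`, `best_z`.
#' @export
callGenes <- function(stats, minDepleted = 2L, minFivefold = 1L) {
  if (!"fivefold" %in% colnames(stats))
    stop("run flagFivefold() before callGenes()")
  keep <- !is.na(stats$gene) & stats$gene != NONTARGETING
  st <- stats[keep, , drop = FALSE]
  g <- factor(st$gene, levels = sort(unique(st$gene)))
  r <- as.matrix(as.data.frame(st[, c("r13", "r14", "r23", "r24")]))
  enr_all4 <- rowSums(is.na(r)) == 0L & rowSums(r > 1) == 4L
  tab <- S4Vectors::DataFrame(
    gene = levels(g),
    n_clones = as.integer(table(g)),
    n_depleted = as.integer(tapply(st$depleted_all4, g, sum)),
    n_fivefold_depleted =
      as.integer(tapply(st$fivefold == "depleted", g, sum)),
    n_enriched = as.integer(tapply(enr_all4, g, sum)),
    n_fivefold_enriched =
      as.integer(tapply(st$fivefold == "enriched", g, sum)))
  tab$candidate <- tab$n_depleted >= minDepleted &
    tab$n_fivefold_depleted >= minFivefold
  tab$best_z <- if ("z" %in% colnames(st))
    as.numeric(tapply(st$z, g, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)))
  else NA_real_
  S4Vectors::metadata(tab) <- c(S4Vectors::metadata(stats),
                                list(min_depleted = minDepleted,
                                     min_fivefold = minFivefold))
  tab
}

#' Per-clone z-scores of the mean log2 knockout/control ratio
#'
#' Standardizes each clone's `mean_log2_ratio` against the mean and sample
#' standard deviation of the standardization set: all clones with finite
#' ratios that pass the low-abundance filter (nontargeting controls
#' included by default, since they estimate the null spread). Over that
#' set the resulting scores have mean 0 and standard deviation 1 exactly.
#' Clones outside the set (low-abundance or excluded) still receive a score
#' on the same scale when their ratio is finite, and are identifiable via
#' their flags.
#'
#' @param stats output of [computeRatios()] (or later stages).
#' @param includeControls keep nontargeting controls in the
#'   standardization set (default TRUE).
#' @return `stats` with a `z` column added.
#' @export
computeZscores <- function(stats, includeControls = TRUE) {
  x <- stats$mean_log2_ratio
  set <- is.finite(x) & !stats$low_abundance & !stats$excluded_zero_control
  if (!includeControls) set <- set & stats$gene != NONTARGETING
  if (sum(set) < 2L)
    stop("fewer than two clones in the z standardization set")
  mu <- mean(x[set])
  s <- stats::sd(x[set])
  if (s == 0)
    stop("zero variance in mean log2 ratios: degenerate screen")
  stats$z <- ifelse(is.finite(x), (x - mu) / s, NA_real_)
  S4Vectors::metadata(stats)$z_convention <- list(
    statistic = "mean_log2_ratio", sd = "sample",
    include_controls = includeControls, mean = mu, sd_value = s)
  stats
}

#' Write ranked screen reports
#'
#' Writes `shrna_stats.tsv` (per-clone table), `gene_calls.tsv` (per-gene
#' table ranked by ascending best z-score, ties broken alphabetically by
#' gene symbol, NA last), `enriched_genes.tsv` (genes with five-fold
#' enriched clones, kept apart from the dropout candidates), and
#' `summary.json` with headline tallies: candidate genes, clones below the
#' z threshold, excluded and low-abundance clones.
#'
#' @param stats per-clone table after [computeZscores()].
#' @param geneCalls per-gene table from [callGenes()].
#' @param thresholdZ clone z-score threshold counted in the summary
#'   (default -1.5, the scale on which screen hits cluster).
#' @param outdir output directory, created if needed.
#' @return the summary list, invisibly.
#' @export
screenReport <- function(stats, geneCalls, thresholdZ = -1.5, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sdf <- as.data.frame(stats)
  gdf <- as.data.frame(geneCalls)
  ord <- order(is.na(gdf$best_z), gdf$best_z, gdf$gene)
  gdf <- gdf[ord, , drop = FALSE]
  utils::write.table(.roundNum(sdf), file.path(outdir, "shrna_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.roundNum(gdf), file.path(outdir, "gene_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- gdf[gdf$n_fivefold_enriched >= 1L, , drop = FALSE]
  utils::write.table(.roundNum(enr),
                     file.path(outdir, "enriched_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_clones = nrow(sdf),
    n_genes = length(unique(sdf$gene[sdf$gene != NONTARGETING])),
    n_candidates = sum(gdf$candidate),
    candidates = gdf$gene[gdf$candidate],
    n_clones_z_below_threshold =
      if ("z" %in% colnames(sdf))
        sum(sdf$z < thresholdZ, na.rm = TRUE) else NA,
    threshold_z = thresholdZ,
    n_low_abundance = sum(sdf$low_abundance),
    n_excluded_zero_control = sum(sdf$excluded_zero_control),
    n_enriched_genes = nrow(enr),
    params = S4Vectors::metadata(geneCalls))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

# round numeric columns for stable, readable TSV output
.roundNum <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.finite(v), signif(v, digits), v))
  df
}
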