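test_that("cross-replicate ratios match direct arithmetic", {
  # symmetric counts: all ratios 1
  cm <- make_counts(matrix(c(50, 50, 50, 50), 1), gene = "G1")
  st <- computeRatios(cm, default_design(), pseudocount = 0,
                      normalization = "raw")
  expect_equal(unlist(as.data.frame(st[, c("r13","r14","r23","r24")])),
               c(r13 = 1, r14 = 1, r23 = 1, r24 = 1), ignore_attr = TRUE)
  expect_equal(st$mean_log2_ratio, 0)

  # (KO1,KO2,C1,C2) = (10,8,100,80), raw, no pseudocount
  cm <- make_counts(matrix(c(10, 8, 100, 80), 1), gene = "G1")
  st <- computeRatios(cm, default_design(), pseudocount = 0,
                      normalization = "raw")
  expect_equal(st$r13, 0.100)
  expect_equal(st$r14, 0.125)
  expect_equal(st$r23, 0.080)
  expect_equal(st$r24, 0.100)
  expect_equal(st$mean_log2_ratio,
               mean(log2(c(0.1, 0.125, 0.08, 0.1))), tolerance = 1e-12)
  expect_equal(st$mean_log2_ratio, -3.3219, tolerance = 1e-4)

  # zero knockout counts with pseudocount 1
  cm <- make_counts(matrix(c(0, 0, 40, 60), 1), gene = "G1")
  st <- computeRatios(cm, default_design(), pseudocount = 1,
                      normalization = "raw")
  expect_equal(st$r13, 1 / 41)
  expect_equal(st$r14, 1 / 61)
  expect_equal(st$r23, st$r13)
  expect_equal(st$r24, st$r14)
})

test_that("pseudocount 0 excludes zero-control clones with a tally", {
  m <- matrix(c(5, 5, 0, 9,
                7, 6, 8, 9), 2, 4, byrow = TRUE)
  cm <- make_counts(m, gene = c("G1", "G2"))
  expect_message(
    st <- computeRatios(cm, default_design(), pseudocount = 0,
                        normalization = "raw"),
    "1 clone")
  expect_true(st$excluded_zero_control[1])
  expect_true(all(is.na(unlist(
    as.data.frame(st[1, c("r13","r14","r23","r24")])))))
  expect_false(st$excluded_zero_control[2])
})

test_that("an all-zero sample column is rejected", {
  m <- matrix(c(1, 0, 2, 3), 1)
  cm <- make_counts(m, gene = "G1")
  expect_error(computeRatios(cm, default_design(), normalization = "cpm"),
               "all-zero")
})

test_that("cpm ratios are invariant to per-sample scaling", {
  set.seed(7)
  m <- matrix(rpois(400, 80), 100, 4)
  cm1 <- make_counts(m, gene = rep(sprintf("G%d", 1:25), each = 4))
  m2 <- m; m2[, 1] <- m[, 1] * 7L  # inflate KO1 depth 7x
  cm2 <- make_counts(m2, gene = rep(sprintf("G%d", 1:25), each = 4))
  s1 <- computeRatios(cm1, default_design(), pseudocount = 1)
  s2 <- computeRatios(cm2, default_design(), pseudocount = 1)
  expect_equal(s1$r13, s2$r13, tolerance = 1e-12)
  expect_equal(s1$mean_log2_ratio, s2$mean_log2_ratio, tolerance = 1e-12)
  # raw-mode ratios scale with the column
  r1 <- computeRatios(cm1, default_design(), pseudocount = 0,
                      normalization = "raw")
  r2 <- computeRatios(cm2, default_design(), pseudocount = 0,
                      normalization = "raw")
  expect_equal(r2$r13, r1$r13 * 7, tolerance = 1e-12)
})

test_that("five-fold and depletion flags follow the all-four rule", {
  mk <- function(rs) {
    st <- S4Vectors::DataFrame(clone_id = "c", gene = "G",
                               r13 = rs[1], r14 = rs[2],
                               r23 = rs[3], r24 = rs[4],
                               mean_log2_ratio = mean(log2(rs)),
                               low_abundance = FALSE,
                               excluded_zero_control = FALSE)
    flagFivefold(st)
  }
  f <- mk(c(0.19, 0.18, 0.15, 0.20))
  expect_identical(f$fivefold, "depleted")
  expect_true(f$depleted_all4)
  # boundary: one ratio just above 1/5
  f <- mk(c(0.19, 0.18, 0.15, 0.21))
  expect_identical(f$fivefold, "none")
  expect_true(f$depleted_all4)
  f <- mk(c(1, 1, 1, 1))
  expect_identical(f$fivefold, "none")
  expect_false(f$depleted_all4)
  f <- mk(c(6, 7, 5, 9))
  expect_identical(f$fivefold, "enriched")
  expect_false(f$depleted_all4)
})

test_that("raising the fold threshold never adds five-fold flags", {
  set.seed(13)
  m <- matrix(rpois(200 * 4, 30), 200, 4)
  cm <- make_counts(m, gene = rep(sprintf("G%d", 1:50), each = 4))
  st <- computeRatios(cm, default_design())
  prev <- Inf
  for (fold in c(2, 5, 10)) {
    n <- sum(flagFivefold(st, fold)$fivefold != "none")
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("gene candidacy needs >=2 depleted clones incl >=1 five-fold", {
  mk_gene <- function(dep, five) {
    n <- length(dep)
    r <- ifelse(five, 0.1, ifelse(dep, 0.5, 1.5))
    S4Vectors::DataFrame(clone_id = sprintf("c%d", seq_len(n)),
                         gene = "G1",
                         r13 = r, r14 = r, r23 = r, r24 = r,
                         mean_log2_ratio = log2(r),
                         low_abundance = FALSE,
                         excluded_zero_control = FALSE)
  }
  call1 <- function(dep, five)
    callGenes(flagFivefold(mk_gene(dep, five)))
  # two depleted, one of them five-fold -> candidate
  g <- call1(c(TRUE, TRUE, FALSE, FALSE, FALSE),
             c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(g$candidate)
  expect_identical(g$n_depleted, 2L)
  expect_identical(g$n_fivefold_depleted, 1L)
  # only one depleted clone -> no candidate
  expect_false(call1(c(TRUE, FALSE, FALSE, FALSE),
                     c(TRUE, FALSE, FALSE, FALSE))$candidate)
  # three depleted but none five-fold -> no candidate
  expect_false(call1(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE))$candidate)
})

test_that("controls are excluded from gene calls, kept in z-scores", {
  set.seed(17)
  m <- matrix(rpois(40 * 4, 50), 40, 4)
  gene <- c(rep(sprintf("G%d", 1:8), each = 4), rep("NONTARGETING", 8))
  cm <- make_counts(m, gene = gene)
  st <- computeZscores(flagFivefold(computeRatios(cm, default_design())))
  calls <- callGenes(st)
  expect_false("NONTARGETING" %in% calls$gene)
  expect_identical(nrow(calls), 8L)
  expect_false(any(is.na(st$z)))
})

test_that("z-scores standardize to exactly mean 0 and sd 1", {
  set.seed(19)
  m <- matrix(rpois(800, 60), 200, 4)
  cm <- make_counts(m, gene = rep(sprintf("G%d", 1:50), each = 4))
  st <- computeZscores(computeRatios(cm, default_design()))
  set <- is.finite(st$mean_log2_ratio) & !st$low_abundance
  expect_equal(mean(st$z[set]), 0, tolerance = 1e-12)
  expect_equal(sd(st$z[set]), 1, tolerance = 1e-12)
  # clone at the set mean gets z = 0
  mu <- mean(st$mean_log2_ratio[set])
  i <- which.min(abs(st$mean_log2_ratio - mu))
  expect_equal(st$z[i], (st$mean_log2_ratio[i] - mu) /
                 sd(st$mean_log2_ratio[set]), tolerance = 1e-12)
})

test_that("the worked z case {-2,0,0,2} gives z(-2) = -2/1.633", {
  st <- S4Vectors::DataFrame(
    clone_id = sprintf("c%d", 1:4), gene = sprintf("G%d", 1:4),
    r13 = 1, r14 = 1, r23 = 1, r24 = 1,
    mean_log2_ratio = c(-2, 0, 0, 2),
    low_abundance = FALSE, excluded_zero_control = FALSE)
  st <- computeZscores(st)
  expect_equal(st$z[1], -2 / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(st$z[1], -1.2247, tolerance = 1e-4)
})

test_that("degenerate screens are rejected by the z-score stage", {
  st <- S4Vectors::DataFrame(
    clone_id = c("a", "b"), gene = c("G1", "G2"),
    r13 = 1, r14 = 1, r23 = 1, r24 = 1,
    mean_log2_ratio = c(0, 0),
    low_abundance = FALSE, excluded_zero_control = FALSE)
  expect_error(computeZscores(st), "variance|degenerate")
  st$low_abundance <- c(TRUE, TRUE)
  expect_error(computeZscores(st), "fewer than two")
})

test_that("low-abundance clones are flagged and left out of the z set", {
  m <- rbind(c(2, 3, 4, 5),            # all four below 10
             matrix(rpois(396, 50), 99, 4))
  cm <- make_counts(m, gene = rep(sprintf("G%d", 1:25), each = 4))
  st <- computeRatios(cm, default_design(), normalization = "raw")
  expect_true(st$low_abundance[1])
  st <- computeZscores(st)
  set <- !st$low_abundance
  expect_equal(mean(st$z[set]), 0, tolerance = 1e-12)
  # the flagged clone still gets a score on the same scale
  expect_true(is.finite(st$z[1]))
})

test_that("reports rank by best z with stable alphabetical ties", {
  st <- S4Vectors::DataFrame(
    clone_id = sprintf("c%d", 1:6),
    gene = rep(c("GB", "GA", "GC"), each = 2),
    r13 = 0.1, r14 = 0.1, r23 = 0.1, r24 = 0.1,
    mean_log2_ratio = c(-2, -2, -2, -2, -1, -1),
    low_abundance = FALSE, excluded_zero_control = FALSE)
  st <- computeZscores(flagFivefold(st))
  calls <- callGenes(st)
  out1 <- tempfile(); out2 <- tempfile()
  screenReport(st, calls, outdir = out1)
  screenReport(st, calls, outdir = out2)
  g1 <- read.delim(file.path(out1, "gene_calls.tsv"))
  # GA and GB tie at the minimal z and order alphabetically
  expect_identical(g1$gene, c("GA", "GB", "GC"))
  expect_identical(readLines(file.path(out1, "gene_calls.tsv")),
                   readLines(file.path(out2, "gene_calls.tsv")))
})

test_that("an empty candidate set still writes valid tables", {
  set.seed(23)
  m <- matrix(rpois(160, 100), 40, 4)
  cm <- make_counts(m, gene = rep(sprintf("G%d", 1:10), each = 4))
  st <- computeZscores(flagFivefold(computeRatios(cm, default_design())))
  calls <- callGenes(st)
  out <- tempfile()
  s <- screenReport(st, calls, outdir = out)
  expect_identical(s$n_candidates, 0L)
  g <- read.delim(file.path(out, "gene_calls.tsv"))
  expect_identical(nrow(g), 10L)
  e <- read.delim(file.path(out, "enriched_genes.tsv"))
  expect_identical(colnames(e), colnames(g))
})
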