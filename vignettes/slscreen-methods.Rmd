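---
title: "Models and methods behind slscreen"
author: "slscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slscreen)
```

# The screening problem

A pooled shRNA dropout screen infects a cell population with a library of
thousands of short-hairpin constructs — here a kinome-scale library of
roughly 5000 hairpins covering ~513 kinase genes at 4–10 hairpins per
gene, plus nontargeting controls — at low multiplicity of infection, so
that each cell carries about one integrated hairpin. After selection and
outgrowth, the abundance of every clone is read out by sequencing its
integrated hairpin, which doubles as a barcode. Clones whose knockdown
kills or slows the cells drop out of the population.

Run in two isogenic genotypes — a knockout (for example *FANCA*-deficient
patient fibroblasts) and its corrected control, two replicates each — the
screen turns into a synthetic-lethality filter: genes whose hairpins
deplete in the knockout but not the control are candidate partners whose
loss is tolerated alone but lethal in combination with the deficiency.

`slscreen` implements the complete analysis for this design: barcode
counting from FASTQ, cross-replicate ratio statistics with a five-fold
dropout rule, gene-level candidate aggregation, per-hairpin z-scores,
and gene-set over-representation — together with a generative simulator
with ground-truth labels so that every claim about the pipeline can be
benchmarked quantitatively.

# Hit-calling model

## Cross-replicate ratios

With knockout replicates #1 and #2 and control replicates #3 and #4,
each clone's four copy-number ratios are

$$r_{ij} = \frac{n_i + c}{n_j + c}, \qquad (i, j) \in \{1,2\} \times \{3,4\}$$

computed on raw counts or, by default, counts-per-million. A ratio below
1 means fewer copies in the knockout — the synthetic-lethality
direction. The per-clone summary statistic is the mean of the four
$\log_2 r_{ij}$.

Two conventions are deliberate choices the procedure itself leaves open:

* **Normalization (`cpm` default, `raw` available).** Replicate
  sequencing depths differ in practice; ratios of raw counts then mix
  depth with biology. Counts-per-million removes that artifact and is
  exactly invariant to rescaling any one sample. The `raw` mode keeps
  fidelity to analyses performed directly on raw copy numbers; both are
  tested.
* **Pseudocount (default 1, applied to numerator and denominator).**
  Zero counts are certain in a dropout screen. With `pseudocount = 0`
  the package instead excludes clones with a zero control count,
  reporting the tally, because their ratios are undefined. The all-zero
  sample-column check is enforced in `cpm` mode, where depth
  normalization is impossible; `raw` mode leaves degenerate toy inputs
  usable.

## Five-fold rule and gene aggregation

A clone shows *five-fold dropout* when **all four** ratios are at most
$1/5$ (and the mirror image, all four at least 5, flags enrichment; the
threshold is tunable). Independently, a clone is *depleted* when all
four ratios are below 1. A gene becomes a candidate when

* at least 2 of its hairpins are depleted in all four comparisons, and
* at least 1 of those shows the five-fold dropout.

The "five-fold" requirement inside the gene rule is read as the same
all-four-comparisons criterion used for clone significance; the two
sentences of the procedure are otherwise inconsistent. Boundary
conventions are inclusive ($\le 1/5$) for the fold rule and strict
($< 1$) for depletion, and both are pinned by tests against a naive
re-implementation of the rules. Genes with the enrichment pattern are
reported in a separate table and never mixed into dropout candidates,
since the screen's question is depletion. Nontargeting controls are
excluded from the gene universe.

## z-scores

Each clone's mean log2 ratio $x_i$ is standardized,

$$z_i = \frac{x_i - \bar{x}}{s_x},$$

with $\bar{x}$ and the sample standard deviation $s_x$ taken over the
*standardization set*: all clones with finite ratios that pass the
low-abundance filter, nontargeting controls included by default. The
statistic ("deviation of the hairpin's frequency in the knockout from
its corrected counterpart") admits several formalizations — population
vs sample deviation, ratio vs log-ratio scale, with or without
controls. This package fixes one declared convention: log2 scale
(symmetric in depletion/enrichment), sample standard deviation,
controls in (they estimate the null spread without assuming most genes
are inert). The convention is recorded in the result's metadata; over
the standardization set the scores have mean 0 and standard deviation 1
exactly. Effective hairpins of true synthetic-lethal genes land far
below $-1.5$ on this scale, matching the empirical observation that
screen hits cluster below that value.

**Low-abundance filter.** Clones whose four raw counts are all below 10
have ratio estimates dominated by shot noise and the pseudocount; they
are flagged, kept in every table, but left out of the standardization
set so that a handful of near-zero clones cannot inflate $s_x$. The
threshold is configurable and reported.

# The synthetic screen generator

The simulator is first-class, tested code; it defines the conditions
under which the pipeline's operating characteristics are measured.

* **Library**: 513 genes, clones per gene uniform on 4–10, 100
  nontargeting controls, distinct random barcodes of 21 nt (the scale
  and shape of a commercial kinome library).
* **Abundance**: relative clone abundance is log-normal
  ($\mu = 0$, $\sigma = 1$), a standard model for the wide,
  right-skewed clone representation that low-MOI transduction and
  outgrowth produce.
* **Counts**: expected count = depth × relative abundance, times
  $1/\text{foldDepletion}$ (default 10) in knockout samples for
  effective hairpins of designated synthetic-lethal genes (and times
  `foldEnrichment` for enriched truth genes). Sampling is negative
  binomial via the Gamma–Poisson mixture with variance
  $m + \phi m^2$, $\phi = 0.05$ by default — the standard
  overdispersion model for pooled-screen counts; $\phi = 0$ degenerates
  to Poisson. An `exact` depth mode draws a multinomial at exactly
  `depth` reads for conservation tests; the default leaves per-sample
  totals random, as in real data.
* **Penetrance**: each hairpin of a truth gene is effective with
  probability 0.8, resampled so every truth gene keeps at least one
  effective hairpin; this mirrors the reality that not all hairpins
  against a true hit knock the gene down well, and it exercises the
  ≥2-concordant-hairpins gene rule. A penetrance of 0 with designated
  truth genes is rejected, since the guarantee is then unsatisfiable.
* **FASTQ**: reads carry the barcode at offset 0, padded with `A` to
  the read length, with iid per-base substitution errors (default
  1%), 4-line records, constant Phred+33 quality `I`. One master seed
  derives deterministic per-stage child seeds, so identical parameters
  and seed give bit-identical libraries, counts and FASTQ.

Sequencing depth defaults to 5×10⁶ expected reads per sample; no depth
or count distribution is published for the original screen, so this and
the abundance prior are conventional choices, not fits. The benchmark
and test presets use 2×10⁵ reads over ~2600 clones (mean ≈ 77
reads/clone), which preserves the regime where zero counts and
low-abundance clones actually occur.

**What the simulator does not emulate**: PCR amplification bias,
transduction stochastics beyond the abundance prior, hairpin-specific
off-target toxicity, quality-score degradation, or correlated
replicates. Passing benchmarks therefore demonstrate that the
implementation applies the stated rules correctly and that the rules
behave well under idealized overdispersed noise — not that the original
screen's specific gene list would be reproduced, which would require
the deposited raw data and the vendor's proprietary clone annotation.

# Barcode counting

Each read's barcode window (declared offset, library barcode length) is
assigned to the clone with the minimal Hamming distance, accepted up to
`maxMismatch` (default 0: exact matching, the usual vendor behavior;
tolerance is opt-in). Ties at the minimal distance — including exact
matches to a barcode shared by several clones — are counted as
*ambiguous*, never split or assigned arbitrarily; reads beyond the
threshold or shorter than the window count as *no match*. Per sample,
assigned + ambiguous + no match equals reads processed, an invariant
the tests enforce. Exact matches resolve through a hashed lookup and
only imperfect reads fall back to a compiled scan; the contract is
fixed by a brute-force all-pairs oracle in the test suite, so the
acceleration cannot change semantics. Base qualities are ignored:
Hamming tolerance already absorbs sequencing error, and no quality
model is warranted. Reverse-complement matching is available behind a
flag, with cross-strand disagreements counted ambiguous.

# Over-representation analysis

Candidate genes are tested for enrichment in user-supplied GMT gene
sets with the hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. The universe
defaults to the library's target genes: the screen only interrogated
those, and a genome-wide background would overstate significance.
Sets are intersected with the universe before testing; hits outside the
universe are dropped with a warning. Both the unadjusted $p < \alpha$
flag (the convention screen enrichment maps are usually drawn at,
$\alpha = 0.01$) and Benjamini–Hochberg $q < \alpha$ are reported so
the difference is visible rather than silent. The enrichment-map
export writes node and edge tables (edges = Jaccard similarity of
overlap gene lists ≥ 0.25) loadable by standard network viewers; no
live pathway-database queries are made, keeping runs reproducible and
offline.

# Numerical and degenerate-input conventions

* Ratios are positive whenever the pseudocount is; with
  `pseudocount = 0` a zero knockout count yields ratio 0 and
  $-\infty$ log ratios, which are excluded from z standardization.
* A screen with zero variance in mean log2 ratios, or fewer than two
  clones in the standardization set, is rejected rather than scored.
* Gene tables order by ascending best (minimum) clone z-score with
  alphabetical tie-breaks, so output files are byte-stable across runs.
* Barcode generation fails loudly if the requested clone count exceeds
  half the 4^L barcode space rather than looping indefinitely.
* All randomness flows from one integer seed; stage-specific child
  seeds are derived arithmetically below 2³¹.

# Benchmarks computed by the package

`scripts/acceptance.R` (see the README) regenerates the operating
characteristics from scratch at the benchmark scale of ten simulated
screens of 500 genes × 5 clones + 100 controls at depth 2×10⁵,
$\phi = 0.05$: the null gene-candidate rate with no truth genes; gene
sensitivity and precision with 25 designated synthetic-lethal genes at
10-fold depletion and penetrance 0.8; the fraction of effective
hairpins with $z < -1.5$; exact FASTQ→counts inversion and the
mismatch-1 assigned-read fraction against its binomial closed form
$0.99^{21} + 21 \cdot 0.01 \cdot 0.99^{20} \approx 0.981$; and the
hypergeometric tail against an explicit combinatorial sum on the full
grid up to $N = 20$. The same checks run in the test suite at the same
sizes. These scales keep the whole benchmark under a minute while
leaving each Monte-Carlo estimate enough events (≈1000 effective
hairpins, ≈2×10⁵ reads) for tight intervals.

# Known limitations

* The gene rule is a hard threshold chain, not a ranking model: no
  replicate-variance moderation, no MAGeCK/BAGEL-style aggregation.
  That is intentional — the package implements and audits this specific
  published-style procedure rather than replacing it.
* The z-score convention is declared, not canonical; other choices
  shift hit z-values by a scale factor.
* Counting assumes a fixed barcode offset; no adapter trimming or
  indel-tolerant alignment is performed.
* Gene symbols are normalized only by case; alias resolution is out of
  scope and would silently change the gene universe.

# Session info

```{r}
sessionInfo()
```
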