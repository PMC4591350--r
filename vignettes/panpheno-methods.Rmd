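---
title: "Methods: comparative genome post-processing and PM kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genome post-processing and PM kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpheno)
```

`panpheno` implements two independent analysis tracks for comparing
bacterial strains: a genomics track that post-processes pairwise local
whole-genome alignments, and a phenomics track that analyses OmniLog
Phenotype Microarray (PM) kinetic curves. This vignette documents the
models, the tunable parameters and the design decisions, so that a
reader can judge what the package's results do and do not show.

## The genomics track

### Coverage, similarity, unique regions

All interval work uses 0-based half-open coordinates internally (the
simplest convention for interval algebra); report output is converted
to the 1-based inclusive convention biologists read. The primitive is
the *merged coverage union*: the set of reference bases covered by at
least one filtered alignment segment. Because a multiply-aligned base
counts once, genomic repeats cannot inflate any downstream score.

Three statistics derive from it:

* **Similarity score.** For genomes $i, j$, the percent of genome
  $i$'s bases (chromosome and plasmids pooled) covered by the merged
  union of $i$-vs-$j$ segments. The matrix is asymmetric because the
  denominators differ — a small genome can share 81% of itself with a
  large one that shares only 52% back.
* **Unique regions.** The per-replicon complement of the union of
  coverage against *all* other genomes in the comparison set.
  Two thresholds deliberately differ: segments are pre-filtered at
  **at least 300 bp**, while complement intervals are kept only when
  **strictly longer than 300 bp**. Both are configurable
  (`min_len`, `min_unique_len`).
* **Uniqueness report.** ORF statistics over the unique set. A CDS
  counts as "in" a unique region when at least 50% of its length
  overlaps the set; this membership rule is our choice, as no
  operational definition is standard, and it is exposed as
  `min_overlap`. Hypothetical proteins are recognized by
  case-insensitive substring match on the product string.

Correctness of the interval algebra is established by *oracle
equivalence*: on replicons up to 100 kb the union, complement and
length computations are tested to agree exactly with a per-base
boolean-array implementation, and coverage plus complement always
conserves the replicon length before the uniqueness filter.

### The built-in anchor aligner

`anchor_align()` is a deliberately simple desk-scale aligner so the
synthetic genomes need no external tool: exact k-mer matches (default
`k = 15`, both strands, `N` never matches) are chained greedily along
diagonals with query gaps up to `max_gap = 100` bp, and chains spanning
at least `min_chain = 300` bp are emitted as gapless segments. For two
independent random 10-kb sequences the expected number of spurious
15-mer collisions is $2 \cdot (10^4)^2 / 4^{15} \approx 0.19$, so at
this scale emitted segments reflect genuinely shared sequence. The
aligner does no gapped extension and no substitution scoring; it is not
a substitute for a production aligner on real genomes, and parity with
any external tool is not promised. Chain edges can extend past a
planted block boundary by up to $k-1$ bp when flanking bases coincide
by chance; recovery tests therefore use a Jaccard criterion rather
than exact boundary equality.

### Order conservation

"Matched regions that keep the same order" is not operationally
defined in the comparative-genomics literature with one meaning, so two
criteria are provided. The default, `strict_rank`, ranks segments by
(replicon order, start) on each side and counts rank fixed points; this
is consistent with the very small conserved fractions (0.30%–5.18%)
observed between rearranged bacterial genomes. The alternative `lis`
counts the longest subsequence whose target ranks increase with query
rank, an upper bound on any order-preserving matching
(`strict_rank <= lis <= total` always). Percentages are rounded
half-up to two decimals, matching report-table formatting.

### Pan-genome partition and pathway completeness

CDS proteins from all genomes are clustered by single linkage over
pairs with global identity $\ge$ 50% covering $\ge$ 50% of the shorter
sequence (Needleman–Wunsch, BLOSUM62, after a shared-4-mer prefilter).
The thresholds follow common pan-genome practice and are configurable;
since no specific clustering method is canonical, published core-genome
counts are treated as reference values, not exact targets. Cluster ids
are deterministic (lexicographically smallest `genome:cds` member), so
results are invariant to input order. The Venn partition assigns each
cluster to the cell named by the set of genomes represented among its
members; cells always sum to the cluster count, and a multi-copy gene
family still occupies one cell.

Pathway completeness takes user-supplied pathway definitions
(`pathway_id -> set of EC codes`) and a genome's annotated EC set, and
reports the fraction of pathways with all enzymes present and the
fraction missing at most one (the latter includes the former, so it is
never smaller). No pathway database is fetched; the definitions file is
an input.

## The phenomics track

### Models

Three sigmoid growth models share the interpretable parameters
$A$ (plateau rise above baseline), $\mu$ (maximum slope, units/h),
$\lambda$ (lag, h) and $y_0$ (baseline):

$$\text{logistic: } y(t) = y_0 + \frac{A}{1 + \exp\!\big(\tfrac{4\mu}{A}(\lambda - t) + 2\big)}$$

$$\text{Gompertz: } y(t) = y_0 + A \exp\!\Big(-\exp\!\big(\tfrac{\mu e}{A}(\lambda - t) + 1\big)\Big)$$

$$\text{Richards: } y(t) = y_0 + A \Big(1 + \nu e^{1+\nu} \exp\!\big(\tfrac{\mu}{A}(1+\nu)^{1+1/\nu}(\lambda - t)\big)\Big)^{-1/\nu}$$

At $\nu = 1$ the Richards form reduces *exactly* to the logistic, which
has two consequences: the default $\nu = 1$ is a sensible neutral
starting value for fitting, and model-selection ties between logistic
and Richards on logistic-shaped data are real, not numerical noise.
`best_fit()` therefore treats RSS values within a small relative
tolerance as tied and resolves ties toward fewer parameters, then the
fixed order logistic, Gompertz, Richards. Model-recovery tests generate
Richards curves with $\nu = 2$ so the three shapes are genuinely
distinguishable.

### The nine curve parameters

Each curve is summarized by nine values: baseline $y_0$ (mean of the
first 3 points), signal minimum, maximum, span, average height, lag
$\lambda$, maximum slope $\mu$, plateau (mean of the last 8 points) and
AUC. This fixed set is this package's declared definition of the
nine-parameter summary; phenomics tools differ in which nine they use,
so the set is documented rather than assumed. $\mu$ is the maximum
first difference of the 5-point moving-average-smoothed signal;
$\lambda$ comes from the classical tangent construction at the point of
maximum slope, clamped to the observation window, with
$\lambda = t_{\max}$ when $\mu = 0$.

**Activity is the AUC of the baseline-subtracted signal (clamped below
at zero), never a fitted-model quantity.** PM curves at 72 h are often
not fully developed, where model-estimated parameters become unstable;
the direct area is the more robust activity measure, and the sigmoid
fits are kept as diagnostics only.

A caveat the tests encode: for slow curves (small $\mu/A$, short
$\lambda$) the signal is already rising at $t = 0$, so the measured
baseline absorbs part of the rise and the area deviates from the
closed-form oracle by a few percent. Recovery is therefore asserted on
the *median* relative error (< 3% over 200 curves with noise up to 5%
of $A$), not per curve.

### Replicates, categories, heat maps

Replicate areas are averaged; a record is flagged inconsistent (never
dropped) when the relative spread $(\max-\min)/\text{mean}$ exceeds
0.25 — our operationalization of "checked for consistency", exposed as
`consistency_tol`. Four activity levels (low, lower-middle,
upper-middle, high) are assigned per plate at fractions 0.25/0.50/0.75
of the plate maximum; published per-plate thresholds are never printed,
so this fraction-of-max rule is an interpretation and the cutpoints are
configurable. Heat-map values are min–max normalized per plate, with
constant plates mapping to zero.

### The activity-difference statistic

For two strains over a shared substrate list,
$\Delta A = A_{\text{strain2}} - A_{\text{strain1}}$ per substrate,
with mean $\mu_A$ and sample standard deviation $\sigma_A$ ($n-1$
denominator). The default call rule is the literal zero-centred band:
strain-1-specific iff $\Delta A < -\sigma_A$, strain-2-specific iff
$\Delta A > +\sigma_A$, else shared. Because the plotted band lines sit
at $\mu_A$ and $\mu_A \pm \sigma_A$, a mean-centred mode is also
provided; the two readings disagree whenever $\mu_A \neq 0$, and the
choice is exposed as `centering`. The statistic is antisymmetric under
strain swap and invariant to rescaling all activities.

Note that $\sigma_A$ is computed over *all* substrates including the
specific ones, so a plate where many substrates differ inflates the
band and hides moderate effects; the statistic is designed for the
regime where most substrates behave similarly.

## The synthetic-data generators

`simulate_genome_set()` plants shared blocks (verbatim copies,
optionally permuted and reverse-complemented per genome) and unique
blocks into i.i.d. uniform random DNA. Uniform random background is
sufficient for anchor uniqueness at $k \ge 15$; it does not emulate GC
bias, repeats, or indel divergence, so passing recovery tests show the
interval pipeline is correct, not that the anchor aligner would handle
diverged real genomes. Blocks are placed first-fit with random gaps; a
plan whose blocks exactly tile the replicon gets zero gaps, which is
how the recovery fixtures make "complement of shared" coincide with
the planted unique truth.

`simulate_cds_annotation()` places non-overlapping CDSs by rejection
sampling (keep coding occupancy below roughly 0.5), with a stated
hypothetical-protein fraction and category weights.

`simulate_pm_curve()` adds Gaussian noise to a sigmoid evaluated on the
OmniLog grid (15-min reads over 72 h, 289 points) and clips at zero.
Gaussian additive noise is an assumption — no noise model for OmniLog
signals is published. `simulate_pm_plate()` labels a substrate's true
specificity by the strain with the strictly larger noiseless
baseline-subtracted AUC when the relative difference
$|a_1 - a_2| / \bar a$ exceeds 50% — a margin chosen well clear of the
noise-induced $\sigma_A$ band so that recovery tests are unambiguous
(the denominator choice, the mean, is ours).

## Numerical choices and problem sizes

* Seeding: every generator takes an explicit seed and restores the
  caller's RNG state; identical inputs and seed give byte-identical
  outputs, including written files.
* Fitting: Levenberg–Marquardt (`minpack.lm::nlsLM`), initialized from
  the nine-parameter summary, bounded at $A, \mu, \lambda \ge 0$ and
  $\nu \in [0.05, 20]$; non-convergence is reported as
  `converged = FALSE` with an infinite-RSS sentinel, never an error.
* Rounding: report percentages round half-up to two decimals.
* Degenerate inputs: constant curves give $\mu = 0$, lag at the window
  end and zero activity; empty segment sets give empty region sets;
  an all-zero plate is all-"low"; $\sigma_A = 0$ makes every substrate
  shared.
* Test problem sizes were chosen for thorough-but-fast runs: six
  30-kb genomes with 4–6-kb planted blocks for recovery, 100-kb
  replicons for interval oracles, 200 curves for area recovery, and
  12-substrate plates for specificity recovery.

## Limitations

* The anchor aligner requires exact k-mer matches: it is for synthetic
  or near-identical sequences, not diverged real genomes; published
  full-genome similarity values additionally depend on the external
  aligner's (unstated) parameters and are treated as reference values.
* Protein clustering is single linkage, which can chain distantly
  related families through intermediates at permissive thresholds.
* The per-plate activity categories and the choice of zero- versus
  mean-centred specificity bands are interpretations of under-specified
  published procedures; both are parameterized rather than hidden.
* `category_summary()` assumes at most one category per CDS;
  multi-category annotation schemes must be flattened first.
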