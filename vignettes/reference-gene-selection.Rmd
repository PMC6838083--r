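---
title: "Selecting RT-qPCR reference genes by equivalence tests and maximal cliques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting RT-qPCR reference genes by equivalence tests and maximal cliques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliqueref)
```

## The problem

RT-qPCR starts from a fixed amount of total RNA, so the measured
quantities are compositional: if one transcript goes up, every other
transcript's share must go down. No statistical procedure can therefore
decide, from Cq values alone, whether a *single* gene's expression is
unchanged between two groups — only ratios between genes are
interpretable. Yet normalisation requires reference genes whose
expression is stable across the studied conditions.

The way out used here is relative: for every pair of candidate genes the
within-sample difference of quantification cycles,

$$ d_s = \mathrm{Cq}_s(a) - \mathrm{Cq}_s(b), $$

is the log2 ratio of their expressions (Cq is a log2-scale quantity at
100% amplification efficiency). If the between-group change of this
ratio is provably negligible, the two genes experience the same
expression change. A large set of mutually "co-stable" genes is then
very unlikely to consist of genes that all changed by exactly the same
amount, and is taken as the reference set. This is external, biological
reasoning — the compositional data themselves cannot exclude a common
shift of the whole set.

## The equivalence test

"Provably negligible" is formalised as a two one-sided t-test (TOST).
With groups 1 and 2 of sizes $n_1, n_2$, the estimate is
$\hat\theta = \bar d^{(2)} - \bar d^{(1)}$, its standard error comes
from the pooled within-group variance (Gaussian Cq, equal variances,
$\nu = n_1 + n_2 - 2$ degrees of freedom), and the hypotheses

$$ H_{0}^{-}: \theta \le -\Delta
   \qquad H_{0}^{+}: \theta \ge +\Delta $$

are each tested one-sided; the TOST p-value is the larger of the two.
Rejection at level $\alpha$ is *exactly* equivalent to the
$(1-2\alpha)$ confidence interval falling inside the equivalence region
$[-\Delta, +\Delta]$; the test suite verifies this duality numerically
on a random grid. Two degenerate cases are fixed by convention: with
zero pooled variance the p-value is 0 if $|\hat\theta| < \Delta$ and 1
otherwise.

The half-width $\Delta$ is the analyst's definition of "no relevant
change", in cycles. The default $\Delta = 0.5$ corresponds to a
$2^{0.5} \approx 1.414$-fold change. Values below the analytical
replicate noise (about 0.1 cycles) are unrealistic: no pair can be
proven that similar.

Pairs are tested on complete pairs of samples — a sample missing either
gene (failed triplicate) is excluded from that pair only. Pairs with
fewer than two usable samples in a group are *untestable*: they are
flagged distinctly and can never contribute a graph edge, which is
deliberately different from "tested and not significant". Only
two-group designs are supported; the statistic is not defined here for
more groups, and the package refuses them rather than improvising.

## Graph, cliques and the selected set

Every gene is a node; an edge joins two genes when their TOST p-value
is strictly below the cutoff. The reference set is read off the graph:

* all inclusion-maximal cliques are enumerated (pivoting
  Bron–Kerbosch; singletons count for isolated genes);
* among them, the maximum-cardinality cliques are intersected. A single
  maximum clique is taken whole; several maximum cliques keep only
  their common genes.

Two flags qualify the answer. The selection is *unreliable* when the
maximum clique has fewer than `min_reliable_clique` genes (default 4):
single edges, and even triangles, arise too easily by chance at the
permissive per-test cutoffs this method runs at, whereas an $N$-clique
requires all $N(N-1)/2$ edges jointly. It is *ambiguous* when several
maximum cliques share no gene; the method gives no principled
tie-break, so the package reports the situation instead of inventing
one. Profiling the selection over a $\Delta$ grid (`delta_profile()`)
annotates each gene with the smallest $\Delta$ at which it enters the
selected set — a partial stability ranking.

## Calibrating the cutoff

The per-test cutoff is *not* a conventional 0.05: it is chosen so that,
under a null where no clique of truly equivalent genes exists, a clique
of more than two nodes appears with probability at most `target_fwer`
(default 0.05). Because a $\ge 3$-clique exists iff the graph contains
a triangle, the simulation only needs triangle detection.

The null model is a "fence": gene $g$ receives a group-2 shift of
$g\,\Delta$, so each adjacent pair sits exactly on the equivalence
boundary — the least favourable configuration for false edges — and no
pair is truly equivalent. Per-cell noise is iid Gaussian with SD
`residual_sd / sqrt(2)`, making within-group pairwise differences have
SD `residual_sd`; the data-informed default pools that SD over all
pairs of the user's matrix (`estimate_residual_sd()`). The calibration
search is a bisection over a 0.001-resolution cutoff grid in which all
cutoffs are evaluated against the *same* simulated p-values (common
random numbers), so the search is monotone and, at fixed seed,
bit-reproducible.

Two properties of this design are worth stating openly. First, the
published operating point for a 30-gene panel (cutoff 0.3) is a
consistency anchor, not a reproducible constant: the calibrated value
depends on the null generator and on `residual_sd`, and the original
simulation design is not fully specified. Second, under the fence null
the calibrated cutoff *decreases* as the number of candidate genes
grows (measured here: 0.386, 0.262, 0.178, 0.158 for 5, 10, 20, 30
genes at `residual_sd` 1.0, groups of 14 and 26), simply because more
pairs offer more chances for spurious triangles. Claims that the
threshold rises with panel size must therefore rest on a different null
model; with the fence null they do not hold.

## Triplicate quality control

Replicate-level input passes two rules, in a fixed order, before
analysis:

1. *Failure*: a triplicate with any replicate undetected or detected
   after `max_cq` (default 32) cycles is failed and yields a missing
   cell. Flagging precedes outlier removal, so a late replicate is
   never "rescued" by being dropped.
2. *Single-outlier elimination*: in a non-failed triplicate whose
   replicate SD (n−1 denominator) exceeds `sd_threshold` (default 0.5
   cycles), the single value farthest from the triplicate mean is
   eliminated, once, never iterated; ties go to the larger replicate
   index, keeping the rule deterministic and order-independent. The
   remaining values are averaged.

The single-elimination rule cannot repair a triplicate containing two
coincident outliers — there it removes the lone good replicate and the
average inherits the outlier shift. This is faithful to the rule as
stated; it is visible in the synthetic experiments as the dominant
failure mode of exact recovery when the outlier rate is set well above
realistic levels.

## geNorm and NormFinder

Both comparison rankers are reimplemented here, treating Cq directly as
log2 expression. geNorm's $M_j$ is the mean over partners $k$ of the
across-sample SD of $d = \mathrm{Cq}_j - \mathrm{Cq}_k$; the largest-M
gene is removed stepwise (ties: alphabetically last) until two remain,
which are jointly best and cannot be ordered further. Pairwise SDs use
complete pairs of samples; a strict mode refuses missing data.

NormFinder is implemented in its two-group, model-based form. Each
sample is centred on its mean Cq across the $k$ genes, absorbing the
compositional loading; per gene and group the intra-group variance is
recovered from the centred residual variance $v$ with the correction
$\hat\sigma^2 = \frac{k}{k-2}\left(v - \bar v/(k-1)\right)$ (floored at
0), the inter-group bias is shrunk towards zero by
$\hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2/n_g)$ where $\hat\gamma^2$
is the between-gene dispersion of the biases minus their sampling
variance, and the stability value averages $|{\rm shrunk~bias}| +
\sqrt{\rm posterior~variance}$ over the two groups; lower is more
stable. The original publication's text was not at hand, so these
estimators were re-derived from the published random-effects model; the
test suite pins them against an independent straight-loop transcription
of the same formulas. NormFinder requires a complete matrix — the
command line front-end drops genes with missing cells before ranking —
and at least three samples per group.

A structural caveat explains part of the disagreement one should expect
between the two rankers and the clique selection: per-sample centring
spreads any single gene's true group bias across *all* genes' bias
estimates ($-1/k$ each), so a panel with one strongly shifted gene
makes every other gene look slightly biased to NormFinder.

## The synthetic data generator

`generate_cq()` draws
$\mathrm{Cq}_{sgr} = \mu_g + \beta_g\,[s \in \mathrm{group}\,2] +
\ell_s + b_{sg} + \varepsilon_{sgr}$: per-gene baselines (default
spread over 14–30 cycles), group effects, a per-sample loading shift
$\ell_s$ common to all genes (invisible, by construction, to every
pairwise statistic — asserted numerically in the tests), per-gene
inter-individual noise $b$, and per-replicate analytical noise
$\varepsilon$. Outliers (+`outlier_magnitude` cycles on single
replicates) and failures (one replicate undetected or pushed past 32
cycles) are injected explicitly; everything drawn is kept in a truth
record so tests never re-derive ground truth. A fixed seed gives
bit-identical output.

Default scales are anchored to what a well-run human panel shows:
analytical SD 0.1 cycles; inter-individual SD between about 0.3 (very
stable genes) and 2 (unusable ones); loading SD 0.5; outliers touching
roughly 1% of triplicates (rate 0.003 per replicate), magnitude +5;
failures in about 1% of triplicates plus whatever drifts past the
32-cycle limit at high baselines. The planted-truth invariant — all
planted genes share one effect, all other effects pairwise differ by
more than `delta_design` — forces the non-planted effects onto a wide
grid (up to several cycles in the 30-gene preset). Real candidate
panels do not show 100-fold shifts; the grid is a stylised device that
makes ground truth unambiguous, not a portrait of real effect sizes.
Consequently, passing recovery tests demonstrate correct behaviour
under the model's assumptions (Gaussian noise, two groups, exchangeable
samples), not robustness to, e.g., heavy-tailed biology or
amplification-efficiency differences, which the generator does not
emulate.

In the recovery experiments the planted genes' inter-individual SD is
set to 0.25 cycles, the bottom of the observed range: the method can
only certify equivalence of genes whose variability is small relative
to $\Delta$ at the available sample sizes, and genes with SD around
0.4 already cost noticeable power at $n = (14, 26)$ — visible in the
30-gene preset, where the exact-recovery rate sits well below the
6-of-15 scenario's.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: calibrations use
1 000–2 000 simulated null datasets (Monte-Carlo SE on a 0.05
probability: about 0.005), the family-wise check uses 2 000 fresh
datasets, recovery uses 200 independent datasets, and clique
enumeration is cross-checked against exhaustive subset search on
graphs of up to 12 nodes. Reports always carry the Monte-Carlo SE next
to an achieved error rate, so "≤ 0.05" statements are interpretable.
Edge inclusion is strict (`p < cutoff`); clique lists are ordered by
size then alphabetically, and all output files are written
deterministically so identical configurations produce byte-identical
reports.

## A worked run

```{r example, eval = FALSE}
spec <- paper_like_preset(seed = 1)       # 30 genes, groups of 14 and 26
synth <- generate_cq(spec)
m <- average_triplicates(synth$table)     # QC: failures, outlier rule

pairs <- all_pairs(m, delta = 0.5)        # 435 TOSTs
cal <- calibrate_cutoff(calibration_spec(
  n_genes = 30, group_sizes = c(14, 26), delta = 0.5,
  residual_sd = estimate_residual_sd(m), n_sim = 2000, seed = 1))
sel <- select_reference_genes(build_graph(pairs, cal$cutoff))
sel
compare_selections(sel, list(genorm_rank(m), normfinder_rank(
  cq_matrix(m$cq[, colSums(is.na(m$cq)) == 0], m$groups))))
```

The same pipeline is available from a shell via the `cliqueref`
executable under the package's `exec/` directory
(`cliqueref select --input data.csv --delta 0.5 --cutoff calibrate`).

## Known limitations

* Two groups only; no paired or repeated-measures designs.
* Gaussian equal-variance TOST only; a non-parametric equivalence test
  could be substituted wherever a p-value per pair is produced, but
  none ships.
* Amplification efficiency is taken as 100%; Cq differences are used as
  log2 ratios without efficiency correction.
* The calibration's fence null is one least-favourable configuration,
  not the only conceivable null; calibrated cutoffs are comparable only
  within a fixed null model and `residual_sd`.
* An empty intersection of maximum cliques is reported as ambiguous;
  the method defines no fallback.
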