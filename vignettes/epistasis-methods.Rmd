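---
title: "Measuring fitness and expression epistasis in double mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fitness and expression epistasis in double mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmepi)
```

# The problem

When two beneficial mutations are combined in one genome, the double
mutant's phenotype rarely equals the naive combination of the single
mutants' effects. `dmepi` quantifies that deviation — epistasis — at two
levels for bacterial evolution experiments of the *E. coli* rho + rpoB
type: competitive fitness measured by colony-count competition assays, and
genome-wide gene expression measured by RNA-seq. Around those two
estimators it provides the full supporting pipeline: growth-curve fitting,
a minimal differential-expression (DE) test for synthetic data, a
classifier of evolutionary expression change, a signed weighted
coexpression-network stage, comparisons against protein–protein interaction
(PPI) networks, and simulators that generate every input with known ground
truth.

# Fitness epistasis under a multiplicative null

A competition assay mixes the focal genotype 1:1 with a reference strain,
lets the culture expand $D$-fold (default $D = 100$, one serial-transfer
cycle), and plates before and after. The relative fitness is the ratio of
realized Malthusian parameters,

$$w_r = \frac{\ln(D\,N^f_{mut}/N^i_{mut})}{\ln(D\,N^f_{anc}/N^i_{anc})},$$

implemented in `relative_fitness()`. Counts of zero are hard errors: a
plate that cannot be counted is not data. Replicates are pooled by
`summarize_fitness()`, which reports the mean $\bar w_r$, the variance of
that mean ($s^2/n$), a one-sample t-test against neutrality
($\bar w_r = 1$) and Bonferroni-adjusted p-values across the family of
genotype × temperature tests. Technical replicates are pooled by default;
`average_bio = TRUE` collapses them within biological replicates first —
the appropriate choice when biological replicates differ detectably
(`replicate_anova()` checks exactly that).

For a double mutant $xy$ with constituent singles $x$ and $y$, the
multiplicative null expects $\bar w_{xy} = \bar w_x \bar w_y$, and the
epistatic deviation is

$$\varepsilon = \bar w_{xy} - \bar w_x \bar w_y.$$

Because the null prediction is a product of two independent estimates, its
variance follows the exact product-variance identity (for independent $X$,
$Y$):

$$\mathrm{Var}(XY) = (\mathrm{Var}X + (EX)^2)(\mathrm{Var}Y + (EY)^2)
  - (EX)^2 (EY)^2,$$

and $\mathrm{Var}(\varepsilon) = \mathrm{Var}(\bar w_{xy}) +
\mathrm{Var}(\bar w_x \bar w_y)$. The independence assumption can only
understate the variance if it fails; no covariance term is added. The
per-pair test statistic is $t = \varepsilon/\sqrt{\mathrm{Var}\varepsilon}$
with $df = n_{xy} - 1$ (the double mutant's replicate count minus one; the
`df` argument exposes alternatives). When $\mathrm{Var}(\varepsilon) = 0$
with $\varepsilon \ne 0$ — possible only with degenerate inputs — the
p-value is reported as 0 with a degeneracy flag rather than NaN, and an
$\varepsilon$ within machine noise of zero is treated as exactly zero.

`pooled_epistasis()` averages $\varepsilon$ across double mutants at one
temperature (one-sample t, 95% CI half-width), and `epistasis_anova()`
tests whether epistasis varies across environments — the G × G × E
question. `diminishing_returns()` regresses the fitness effect of the
foreground mutation, defined as the ratio $\bar w_{xy}/\bar w_x$ (a
relative gain; the difference is available via `effect = "difference"`),
on the background fitness $\bar w_x$: a negative slope is the signature of
diminishing returns. The ratio definition was chosen because fitness here
is itself a ratio of growth rates, so "the effect of adding the mutation"
is naturally multiplicative; both definitions give the same sign of the
slope on these data scales.

# Growth curves

`fit_growth()` identifies the linear component of the exponential phase by
scanning all windows of at least five consecutive points of
log-transformed density and keeping the window with the highest $R^2$
among positive slopes (ties resolved toward the earliest, then longest,
window). The slope is $\mu_{max}$ (per hour). The final yield defaults to
the maximum observed density; the last point of the fitted window is
available instead. Two-sample comparisons use Welch's t-test — the paper
trail for such assays rarely supports equal variances, and Welch is the
safer default.

# Expression epistasis under an additive log-scale model

Expression changes enter as log2 fold changes versus the common stressed
ancestor, so the additive (Fisher) null on the log scale corresponds to
the multiplicative null on the raw scale:

$$\varepsilon_{exp} = GE_{xy} - (GE_x + GE_y).$$

`expression_epistasis()` computes $\varepsilon_{exp}$ per gene, then a
genome-wide Z-score per double mutant (each gene's score standardized
against all genes of that double mutant — one score per gene per double
mutant, which is why a replicate-based per-gene SD is not used). Two
significance tiers mirror the two filtering stringencies used in this
study design:

* **tier A** — DE ($q < 0.001$) in at least one of the three
  mutant-versus-ancestor contrasts (rho single, rpoB single, double);
* **tier B** — $q < 0.001$ *and* $|$log2FC$| > 2$ in at least one of those
  contrasts, *plus* $|Z| > 2$.

All thresholds are arguments. Sign balance among flagged genes is tested
with an exact two-sided binomial test (`sign_balance()`); distribution
shape uses Pearson moments with population ($n$) divisors
(`epistasis_moments()`: skewness $m_3/m_2^{3/2}$, kurtosis $m_4/m_2^2$, so
a normal distribution sits at 3). Gene sets (heat-shock, stress-response,
Rho-terminated lists; plain or GMT files via `read_gene_set()`) are
summarized by `geneset_summary()`: sign binomial, rank-sum location test
in-set versus out-of-set (exact for small universes, normal approximation
with tie correction otherwise), a two-sided F-test of score variances, and
the tier-A DE fraction.

# Evolutionary change classification

`classify_expression()` places each gene into one of five directions of
change from three contrasts (ancestor stressed vs. unstressed; mutant vs.
stressed ancestor; mutant vs. unstressed ancestor), at $q < 0.001$:
*restored* (mutant moves significantly against the ancestral stress
response), *reinforced* (with it), *novel* (no ancestral response but the
mutant differs from the ancestor at both temperatures), *unrestored*
(ancestral response present, mutant indistinguishable from the stressed
ancestor), and *unclassified* for every remaining pattern. The fifth
category exists because the four published definitions are not exhaustive;
leaving the remainder implicit would make the partition depend on
evaluation order. A significant contrast with an exactly zero fold change
is pathological input and is left unclassified with a warning. The
classifier does not require direction agreement between the two mutant
contrasts for *novel* calls, and *restored* is not subdivided into partial
versus full restoration (no magnitude criterion is defined for it).

# The coexpression-network stage

Expression is transformed as $\log_2(\text{normalized} + 1)$.
Variance-stabilizing transforms differ in detail, but every downstream
statistic here is correlation- or rank-based, and the planted-structure
recovery results are insensitive to the choice; the simple log transform
keeps the stage self-contained. The signed adjacency is

$$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^\beta,$$

with Pearson correlation and default $\beta = 16$ (the value appropriate
for signed networks of this size; `pick_soft_threshold()` scans candidate
powers for the smallest one reaching a signed scale-free fit $R^2 \ge
0.8$ over 10 connectivity bins, falling back to the configured default
when every fit is degenerate). Topological overlap is

$$TOM_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}},$$

modules come from average-linkage clustering of $1 - TOM$, and clusters
below 30 genes (configurable) are left unassigned ("grey"). Modules are
named by size rank in the conventional color order, so "turquoise" is
always the largest.

**Choice of the static cut.** A cut at a fixed fraction (e.g. 0.995) of
the maximum merge height is unreliable with average linkage: the joins
between unrelated branches spread over the top several percent of the
height range, so a cut pinned within half a percent of the maximum merges
unrelated modules on a substantial fraction of simulated datasets. The
default is therefore an automatic cut placed in the widest gap of the
upper quarter of the merge-height distribution — between the within-module
merge regime and the between-branch joins — with a minimum gap width of
0.01 below which the tree is treated as one module. A numeric
`cut_height` restores the fixed-fraction behavior.

Module eigengenes are first principal components of the standardized
member expression, oriented to correlate positively with their members on
average and scaled to unit variance. Module membership (kME) is the
correlation of each gene with each eigengene, with the correlation t-test
p-value at $n - 2$ degrees of freedom. Hub genes require all three of:
intramodular connectivity at or above the module's 90th percentile
(linear-interpolation quantile; modules under 10 genes take their single
best-connected gene), kME strictly above 0.9, and membership $p < 0.01$.
The strict inequality at 0.9 is deliberate — a gene exactly at the
boundary is not a hub. Eigengene–trait correlations
(`module_trait_association()`) attach per-sample traits such as the
genotype's relative fitness at a given temperature.

# Network comparisons

PPI edge lists arrive as files (gene_a, gene_b, confidence; the 0–1000
integer dialect is auto-detected and divided by 1000). Degrees count
distinct partners at or above the confidence cutoff (default 0.9, the
highest-confidence tier); genes of the expression universe absent from the
retained edges count as degree 0 by default, since "interactions per gene"
is defined over the genome, with `include_missing = FALSE` available.
`compare_connectivity()` contrasts connectivity (coexpression `k_total` or
PPI degree) between epistatic and non-epistatic genes by rank-sum test;
`hub_enrichment()` is a two-sided Fisher exact test; `map_gene_ids()`
routes external gene names through an alias table and never silently drops
an unmapped name.

# What the simulators emulate — and what they do not

The generators reproduce the study design so every estimator can be tested
against known truth:

* `simulate_competition()` — Poisson plating noise on all four colony
  counts around the deterministic Malthusian expectations implied by a
  true $w$; default 10 assays per genotype × temperature (the study scale:
  243 double-mutant assays over 24 genotype × temperature groups) and a
  mean plating count of 30 colonies. Noise on counts, not Gaussian noise
  on $w$, because plating statistics are the actual measurement process.
* `simulate_counts()` — negative-binomial counts (variance
  $\mu + \alpha\mu^2$, default $\alpha = 0.02$, the scale observed between
  clonal bacterial replicates; baseline means log-normal around 500, a
  typical bulk sequencing depth) over the 29-library layout: ancestor at
  both temperatures, six singles and six doubles at the stressed
  temperature, ~2 replicates each. Planted effects: an ancestral stress
  response in 20% of genes (|log2FC| = 3), single-mutant responses in 10%
  (|log2FC| = 3, predominantly opposing the stress response), and 100
  planted epistatic genes per double mutant at $|\varepsilon_{exp}| = 2$
  with alternating sign; double-mutant fold changes are additive in the
  singles' plus the planted deviation. Planted epistatic genes are strong
  responders in their rho single, as the real strongly epistatic genes
  (flagellar, heat-shock, ribosomal) are.
* `simulate_coexpression()` — latent-factor blocks with designated
  highest-loading hub genes.
* `simulate_ppi()` — a configuration-model graph repaired to a simple
  graph by double-edge swaps, with confidences placed around the cutoff.
* `simulate_gene_set()` — weighted sampling with configurable enrichment
  odds.

Every generator draws from a named substream derived from one seed, so
adding a generator to a pipeline does not shift the randomness of the
others, and equal seeds give byte-identical output.

What passing these tests does *not* show: the simulators use independent
genes given the planted structure (no correlated dispersion, no GC or
length biases, no read-level error), Poisson plating with no
between-biological-replicate variance component, and symmetric planted
effects. Recovery rates on real data with correlated noise and asymmetric
effect distributions will be lower than on these simulations, and exact
published gene counts (DEG totals, module sizes) depend on the deposited
read data and are not reproduction targets.

# The internal DE test

The paper-grade DE engine for real data is an external tool; its tables
are ingested with `ingest_de_table()` (schema-checked, duplicate- and
type-validated). So that the whole pipeline also runs end-to-end on
synthetic data, `simple_de()` provides a per-gene Welch t-test on
$\log_2(\text{normalized} + 1)$ with Benjamini–Hochberg adjustment across
the genes of the contrast. It is deliberately minimal: no dispersion
shrinkage, no GLM offsets. At two replicates per group it has little
power at $q < 0.001$ — matching the intuition that the study's depth of
DE calling needs a dedicated engine — and the simulation-based tier
recovery tests therefore run at four replicates per group.
Normalization is the median-of-ratios method (`size_factors()`),
cross-checked in the test suite against an independently coded formula
and against the reference implementation.

# Numerical choices and degenerate inputs

* Counts of zero in assays: errors, never imputed.
* Constant pooled epistasis values: $t = 0$, $p = 1$ with a degeneracy
  flag, not NaN.
* Genes with zero counts across a contrast are dropped with a logged
  count; zero-variance genes are removed before network construction.
* BH is the q-value procedure; $q \in [0,1]$ always, monotone after
  sorting.
* Quantiles use R's default linear interpolation (type 7).
* Wilcoxon tests switch from exact enumeration to the tie-corrected
  normal approximation above a 50-gene universe.
* All statistics run through base R (`t.test`, `aov`/`lm`,
  `wilcox.test`, `fisher.test`, `binom.test`, `var.test`, `p.adjust`,
  `hclust`, `prcomp`); the epistasis estimators, the TOM stage and the
  simulators are the package's own.

# Problem sizes used in the checks

The shipped test-suite and the acceptance script run at sizes chosen to
exercise every code path at full statistical resolution: 2,000-gene count
simulations with four replicates per group for tier recovery, 100 seeds ×
4 planted effect sizes for fitness-epistasis recovery (10 assays each),
20 seeds of 200-gene five-block expression for module recovery, $10^6$
Monte-Carlo draws × 20 parameter pairs for the product-variance identity,
and brute-force TOM verification up to 12 nodes. These are the package's
reference conditions; all are arguments and scale up directly.

# Known limitations

* Per-pair fitness-epistasis variances depend on the chosen variance
  convention (variance of the mean, propagated exactly); published
  per-pair tables mixing conventions will not match numerically, though
  pooled statistics computed from printed $\varepsilon$ values do.
* The additive expression model is only as good as the shared reference:
  all three fold changes must be against the same ancestor condition.
* The network stage computes dense gene × gene matrices; it is meant for
  bacterial-genome scale (thousands of genes), not for >20k-gene
  transcriptomes.
* GO enrichment, read mapping and counting, and live database retrieval
  are out of scope by design; the package consumes their outputs as files.
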