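# dmepi

Epistasis analysis for engineered double mutants, built around the
*Escherichia coli* rho + rpoB system: pairs of beneficial mutations in the
transcription terminator Rho and the RNA-polymerase β-subunit, combined in
one ancestral background and assayed for competitive fitness and
genome-wide gene expression under thermal stress. The package is for
experimental-evolution groups who have competition-assay colony counts,
growth curves, RNA-seq count matrices (or externally produced
differential-expression tables), gene sets and protein–protein interaction
edge lists, and want the complete interaction analysis from those raw
tables.

## The models

**Fitness epistasis (multiplicative null).** Relative fitness from a
competition assay is the Malthusian-parameter ratio
*w*<sub>r</sub> = ln(*D·N<sup>f</sup><sub>mut</sub>/N<sup>i</sup><sub>mut</sub>*) /
ln(*D·N<sup>f</sup><sub>anc</sub>/N<sup>i</sup><sub>anc</sub>*) with
*D* the per-cycle fold expansion (default 100). For a double mutant *xy*,

&nbsp;&nbsp;&nbsp;&nbsp;ε = w̄<sub>xy</sub> − w̄<sub>x</sub>·w̄<sub>y</sub>,

with the variance of the product of independent estimates taken exactly,
Var(XY) = (Var X + (EX)²)(Var Y + (EY)²) − (EX)²(EY)², and
Var(ε) = Var(w̄<sub>xy</sub>) + Var(w̄<sub>x</sub>w̄<sub>y</sub>);
t = ε/√Var(ε) with df = n<sub>xy</sub> − 1. Pooled tests, a
cross-environment ANOVA (G × G × E) and the diminishing-returns regression
(fitness effect of the foreground mutation against background fitness)
complete the stage.

**Expression epistasis (additive log-scale null).** With per-gene log2
fold changes against the common stressed ancestor,

&nbsp;&nbsp;&nbsp;&nbsp;ε<sub>exp</sub> = GE<sub>xy</sub> − (GE<sub>x</sub> + GE<sub>y</sub>),

standardized genome-wide per double mutant (Z-score), with two
significance tiers (q < 0.001 in any mutant contrast; and additionally
|log2FC| > 2 plus |Z| > 2), exact binomial sign-balance tests, Pearson
moments, and gene-set summaries (Wilcoxon, F-test, DE fraction).

Downstream, each gene's expression shift is classified as
restored/unrestored/reinforced/novel/unclassified from three contrasts,
and a signed weighted coexpression network (adjacency
((1+cor)/2)<sup>β</sup>, β = 16, topological overlap, average-linkage
modules, eigengenes, kME, intramodular connectivity, hub genes at the top
connectivity decile with kME > 0.9 and p < 0.01) links epistasis to
connectivity, alongside PPI-degree comparisons and hub-enrichment tests.
Synthetic-data generators emulate the full study design — 29 RNA-seq
libraries, six doubles, three assay temperatures, ten assays per genotype
— with known ground truth for every stage.

## Worked example

The shipped per-pair epistasis table (eight rho + rpoB double mutants at
three temperatures) reproduces the pooled statistics directly:

```r
library(dmepi)
tab <- example_epistasis_estimates()
pooled_epistasis(tab$epsilon[tab$temperature == 42.2])
#> $mean_epsilon   -0.133725
#> $ci95_halfwidth  0.09033763
#> $t_stat         -3.500172
#> $df              7
#> $p               0.009989
epistasis_anova(tab$epsilon, tab$temperature)
#> $f 8.586672   $df1 2   $df2 21   $p 0.001882871
```

Mean epistasis at 42.2 °C is −0.134 ± 0.090 (95% CI): double mutants are
on average 13% less fit than the multiplicative expectation, and the
deviation differs across temperatures (F₂,₂₁ = 8.59, p = 0.0019).

A fully synthetic end-to-end run with known truth (planted fitness
epistasis −0.15 at 42.2 °C, 50 planted expression-epistatic genes per
double mutant among 500 genes):

```r
b <- simulate_bundle(n_genes = 500, replicates = 4, n_epistatic = 50, seed = 42)
res <- run_pipeline(b, min_module_size = 15)
res$fitness$epistasis[res$fitness$epistasis$temperature == 42.2,
                      c("double_id", "epsilon", "var_epsilon", "p")]
#>           double_id epsilon var_epsilon       p
#>   rhoA43T_rpoBI572F -0.1618     0.00224 0.00761
#>  rhoT231A_rpoBI572F -0.0164     0.00201 0.72331
#>   rhoI15N_rpoBI572F -0.0850     0.00205 0.09348
#>   rhoA43T_rpoBI572L -0.2060     0.00287 0.00392
#>  rhoT231A_rpoBI572L -0.1942     0.00270 0.00463
#>   rhoI15N_rpoBI572L -0.1341     0.00331 0.04458
```

The pooled estimate at 42.2 °C is −0.133 ± 0.075 (t₅ = −4.53,
p = 0.0062) around the planted −0.15. The same run flags 9–22 tier-B
epistatic genes per double mutant, recovers the planted coexpression
blocks (13 modules, 41 hub genes at β = 16), and finds epistatic genes
more connected than non-epistatic ones (mean k 7.06 vs 4.57, Wilcoxon
p = 4 × 10⁻⁸) — the connectivity contrast this analysis is designed to
expose.

`pipeline_report(res, "report.json")` writes the machine-readable summary
(per-pair ε table, pooled statistics, ANOVA, tier counts, sign tests,
module table, connectivity comparisons) with the seed and a configuration
hash.

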