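# mirmodules

Discovery, scoring, annotation and visualization of **miRNA–mRNA functional
modules** from matched expression data integrated with predicted-target
evidence.

MicroRNAs repress mRNAs post-transcriptionally, and single-interaction
analyses miss the modular character of that regulation: groups of miRNAs
jointly influencing groups of functionally related mRNAs. mirmodules is for
researchers with matched miRNA and mRNA expression profiles (e.g. a tumour
panel profiled on both platforms) plus a table of predicted target sites, who
want to recover that modular structure without supervision.

## Method

1. **Association matrix.** The full Spearman correlation matrix *C* between
   every miRNA *m* and mRNA *n* is reconciled with the predicted-target
   matrix *T* into an association matrix *Â*: cells with *c<sub>mn</sub> < 0*
   and a predicted site are kept (direct evidence), *c<sub>mn</sub> > 0*
   without a site are kept (indirect evidence), and the two conflicting
   combinations are set to 0. No magnitude threshold is applied.
2. **Bicluster search.** A module candidate is a submatrix *I × J* of *Â*
   scored by its mean value (an ideal direct module scores −1). Fixed-size
   seeds are found by simulated annealing (Metropolis acceptance, geometric
   cooling, deterministic greedy polish) and expanded deterministically:
   miRNAs by most-negative mean association (up to 10), then mRNAs best-first
   into a direct (negative) or indirect (positive) arm up to 250 combined.
3. **Cooperativity.** For each miRNA family or genomic cluster (miRNAs within
   10 kb or sharing a host gene), every targeted mRNA gets its targeting
   count *k* and the most-inverse member correlation; Spearman's ρ of the
   per-level medians against *k* measures cooperativity, with an empirical
   p-value from 100 random same-size groupings.
4. **Annotation.** Modules are labelled by hypergeometric over-representation
   *P(X ≥ n)* of gene categories (universe = the matrix's mRNAs) and miRNA
   classes; a permuted-label rerun provides the by-chance baseline, and
   validated-pair density quantifies agreement with known interactions.
5. **Module map.** Between-module similarity uses the overlap metric
   *|L₁ ∩ L₂| / max(|L₁|, |L₂|)*, whose complement is a true metric; classical
   MDS projects miRNA-side similarity onto X and mRNA-side similarity onto Y,
   with bubble radius proportional to the top category's enriched fraction.

A synthetic-data generator with planted module and cooperativity structure
(`generate_dataset()`) makes the whole pipeline testable without downloads.

## Worked example

```r
library(mirmodules)

sim   <- generate_dataset(n_mirnas = 100, n_mrnas = 600, n_samples = 40,
                          module_specs = replicate(3, planted_module_spec(),
                                                   simplify = FALSE),
                          rng_seed = 7)
corr  <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
assoc <- integrate_associations(corr, sim$targets)
assoc
#> <mirna_assoc> 100 miRNAs x 600 mRNAs, 30262 non-zero associations (50.4%)

mods <- discover_modules(assoc, search_config(n_modules = 3,
                                              admission_margin = 0.2,
                                              rng_seed = 11)) |>
  label_modules(sim$annotation, gene_universe = colnames(assoc))
glance(mods)
#> # A tibble: 3 × 5
#>   module n_mirnas n_direct n_indirect  score
#>    <int>    <int>    <int>      <int>  <dbl>
#> 1      1        6       20         63 -0.937
#> 2      2        6       20         67 -0.923
#> 3      3        6       20         56 -0.870
```

Each discovered module contains exactly one planted miRNA set (6 miRNAs) and
its 20 direct targets; the score is the mean association of the direct arm,
so −0.94 means near-perfect inverse expression backed by predicted sites. The
indirect arms hold positively correlated mRNAs (the 10 planted ones plus
background genes that co-vary with the module's latent activity by chance).
Annotation then recovers the planted categories:

```r
mods$annotation[, c("module", "label", "n", "S", "p_value")]
#>   module label                   n     S  p_value
#> 1      1 planted_category_03    26    83 1.81e-20
#> 2      2 planted_category_02    24    87 1.09e-16
#> 3      3 planted_category_01    26    76 1.21e-21
autoplot(layout_modules(mods))   # the bubble-plot module map
```

Cooperativity on a planted additive grouping (five miRNAs whose joint
targeting deepens repression by −0.1 in correlation per additional member):

```r
sim2 <- generate_dataset(n_mirnas = 60, n_mrnas = 700, n_samples = 40,
                         module_specs = list(),
                         coop_specs = list(coop_spec(n_members = 5,
                                                     n_targets = 500)),
                         rng_seed = 101)
corr2 <- compute_correlations(sim2$mirna_expr, sim2$mrna_expr)
cooperativity_pvalue(corr2, sim2$targets, sim2$truth$coop[[1]]$members,
                     name = "coop_01", kind = "genomic_cluster",
                     n_perm = 100, rng_seed = 2)
#> <cooperativity_result> coop_01 (genomic_cluster, n = 5): rho = -1.00, P = 0.02
```

The per-level medians fall from −0.05 (one targeting member) to −0.41 (all
five), a perfectly monotone trend (ρ = −1) that only about 2 of 101 random
same-size groupings match.

`run_pipeline()` chains all stages and writes TSV/JSON artifacts plus a run
manifest; `inst/scripts/mirmod.R` exposes the same stages as shell
subcommands (`simulate`, `integrate`, `bicluster`, `cooperativity`, `enrich`,
`run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic benchmark from the given seed, runs the
full pipeline on it from scratch — integration, module discovery, enrichment
labelling, the permuted-label baseline, cooperativity and validated-pair
density — logs the headline numbers, and writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/mirna-module-discovery.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices and limitations.
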