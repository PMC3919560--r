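---
title: "Discovering miRNA-mRNA functional modules from integrated expression and target-prediction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA-mRNA functional modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmodules)
```

## The model

MicroRNAs repress mRNAs post-transcriptionally through seed-region binding in
the 3' UTR, and our understanding of this layer of regulation increasingly
centres on *modules*: sets of miRNAs that jointly regulate sets of
functionally related mRNAs. mirmodules represents the evidence for such
modules as a weighted bipartite graph between a miRNA set $M$ and an mRNA set
$N$. A module has two arms:

* a **direct arm** — mRNAs inversely correlated with the module's miRNAs and
  carrying predicted target sites (a biclique in the graph), the signature of
  direct repression;
* an **indirect arm** — mRNAs positively correlated with the miRNAs and
  lacking sites, modelling coordinated downstream upregulation, which often
  carries most of the phenotypic signal used to annotate the module.

The model assumes only that miRNA-mRNA interaction requires sequence-specific
binding and that binding produces inverse expression. Everything else is left
to the data.

## From expression to the association matrix

Given matched miRNA and mRNA profiles over the same samples,
`compute_correlations()` builds the full Spearman rank-correlation matrix
$C$ (miRNAs in rows, mRNAs in columns; average ranks for ties; at least three
matched samples, configurable). `integrate_associations()` then reconciles
$C$ with a binary predicted-target matrix $T$ to produce the association
matrix $\hat A$:

| correlation | predicted site | kept as |
|---|---|---|
| $c < 0$ | yes | $c$ (direct evidence) |
| $c < 0$ | no  | $0$ (conflict) |
| $c > 0$ | no  | $c$ (indirect evidence) |
| $c > 0$ | yes | $0$ (conflict) |

Zero or missing correlations map to 0. No magnitude threshold is applied at
this stage; conflict-zeroing alone sparsifies the matrix substantially
(roughly half the cells in a random background) and smooths the search
landscape, because a cell can no longer reward the objective unless both
evidence types agree. Missing expression values are handled pairwise-complete
per cell with a minimum of 3 shared samples; cells below the minimum, or with
a zero-variance feature, are flagged missing and become 0 in $\hat A$.

## Bicluster search

A candidate module is a submatrix $I \times J$ of $\hat A$, scored by
`score_submatrix()` as the arithmetic mean of its entries — an ideal direct
module scores $-1$. Because module size is roughly known (on average, an mRNA
is targeted by ~10 miRNAs and a miRNA targets a few hundred mRNAs), the
search fixes the submatrix area and minimises the mean.

`sa_seed_search()` minimises this objective over fixed-size seeds (default
5 miRNAs x 20 mRNAs) with simulated annealing: a move replaces one randomly
chosen row or column (50/50) with a random outside one, and is accepted by
the Metropolis criterion. The schedule is geometric (cooling 0.95, 200 moves
per temperature, stop at $10^{-3}$), with the initial temperature calibrated
from 200 probe moves so that about 80% of early uphill moves are accepted.
After cooling, a deterministic best-improvement polish swaps rows/columns
until the seed is a strict local optimum; on small matrices this makes a
best-of-20-restart search hit the exhaustive-search optimum in effectively
every instance (the acceptance suite requires 95 of 100).

`expand_seed()` grows the seed deterministically: miRNAs are added by most
negative mean association to the direct arm (up to 10, the published column
threshold), then mRNAs are admitted best-first into whichever arm their sign
supports — most negative mean for the direct arm, most positive for the
indirect arm — until the combined arms reach 250 (the published row
threshold, shared across arms; the source is ambiguous on whether the
indirect arm counts against it, and sharing is this package's choice).
Candidates with the wrong sign are never admitted. `admission_margin` sets a
magnitude floor: the default 0 mirrors the unthresholded published
integration, but on noisy data an unthresholded expansion will spend the
250-column budget on near-zero background columns, so the planted-data
benchmarks in this package run with a floor of 0.2. Ties break
lexicographically, making expansion fully deterministic.

`discover_modules()` repeats seed search + expansion for `n_modules` rounds
(the published analyses retrieved 100). Between rounds, the default
`"seed-exclusion"` mask treats the cells of previously returned seeds as +1
(the worst value) during later *seed* searches, while expansion may still
reuse them — so modules can overlap, as the visualization assumes. One known
trade-off: a very wide planted structure (hundreds of columns) loses only
the seed's 100 cells per round and can be rediscovered repeatedly before
weaker structure is found; the alternative `"value-damping"` policy (halve
used cells) erodes such attractors faster. Results are ordered by ascending
score and are bitwise reproducible given `rng_seed` (the annealing kernel
draws from R's RNG).

## Cooperativity within miRNA families and genomic clusters

If members of a miRNA family or genomic cluster cooperate, mRNAs targeted by
more members should show stronger inverse expression.
`build_genomic_clusters()` groups miRNAs by single-linkage when loci on the
same chromosome are within 10 kb (gap between intervals) or share a host
gene. For a grouping of size $N$, `target_count_profile()` assigns each
targeted mRNA its targeting count $k \in 1..N$ and the *maximum inverse
correlation* over targeting members, read as the minimum signed correlation —
one rule applied even when all candidates are positive.
`cooperativity_trend()` takes the median per level and computes Spearman's
$\rho$ of medians against $k$; fewer than three populated levels (or all-tied
medians) yields an undefined $\rho$, which is reported but never tested.

`cooperativity_pvalue()` assesses significance against 100 random groupings
of the same size (the published design), with the add-one estimator
$p = (1 + \#\{\rho_{null} \le \rho_{obs}\})/(1 + n_{perm})$, so the most
extreme outcome at 100 permutations is $1/101$, printed "< 0.01" in the
published style. Two statistical properties matter when reading these
p-values:

* **Null pool.** By default the null excludes the tested grouping's own
  members (other groupings stay in the pool). Sampling the tested members
  back into the "null" contaminates it with the alternative: at five members
  among sixty miRNAs, roughly one null draw in twenty contains two or more
  true members and reproduces the real trend, inflating the null tail by
  about as much as the entire nominal significance level.
* **Granularity and conservatism.** The statistic is a rank correlation over
  a handful of medians, so its null distribution has large discrete atoms —
  a random grouping with three populated levels is perfectly monotone with
  probability about 1/6 — and the min-aggregation itself biases medians
  downwards with $k$. The permutation p-value absorbs both effects (that is
  its purpose) but is therefore conservative: individual p-values have a
  practical floor around 0.02-0.1 that no strength of signal can beat, and
  under a true null the p distribution is super-uniform, not uniform. The
  calibration test asserts the spec's rate form — among null groups with a
  defined trend, $P(p \le 0.05) = 0.05 \pm 0.03$ — which holds at biological
  target densities.

## Annotation, baseline and evaluation

`hypergeom_enrich()` computes the upper-tail hypergeometric probability
$P(X \ge n)$ for each annotation term, with the universe defaulting to the
mRNAs of the association matrix (not the genome), and no multiple-testing
correction by default — matching the published tables — with an optional
Benjamini-Hochberg flag. `label_modules()` annotates every module with its
most enriched gene category over the combined arms (indirect members
included; the published modules are annotated on all their mRNAs), the
enriched fraction $n/S$, the top-10 term list, and the most over-represented
miRNA family/cluster.

`permuted_baseline()` estimates what those p-values look like by chance.
Permuting the row and column *labels* of $\hat A$ is an isomorphism — the
discovered biclusters and their scores are identical by construction, and
only the correspondence to annotation is destroyed — which is precisely the
null needed for the enrichment comparison (Mann-Whitney on $-\log_{10} p$,
one-sided; the comparison test is unnamed in the source and this is the
package's choice). A second mode shuffles entries within rows, which does
destroy bicluster structure; that is the right null when comparing module
*scores* against chance, and the test suite uses it for exactly that.

`validated_pair_density()` counts experimentally validated miRNA-mRNA pairs
falling inside modules and reports their density over the distinct matrix
cells covered by any module (cells in overlapping modules count once), plus
the fold change against a baseline run.

## The module map

The bubble-plot visualization needs a between-module similarity that is fair
to modules of different sizes. `overlap()` uses
$s(L_1, L_2) = |L_1 \cap L_2| / \max(|L_1|, |L_2|)$: the printed form of the
metric is unreadable in the source material, but the text rules out the
min-denominator form (it inflates nested small modules) and requires that
$1 - s$ obey the triangle inequality, which the max form satisfies (and the
test suite verifies exhaustively on all triples). A union (Jaccard)
denominator is available as an option.

`similarity_matrices()` builds one similarity matrix from miRNA overlap and
one from combined-arm mRNA overlap. `classical_mds()` double-centers the
squared distances $d = 1 - s$, eigen-decomposes, truncates negative
eigenvalues to zero, and returns one coordinate per side (the published plot
projects miRNA similarity on X and mRNA similarity on Y), with each
dimension reflected so its largest-magnitude coordinate is positive — making
layouts deterministic and order-invariant. `layout_modules()` sizes each
bubble linearly in the enriched fraction of its top category, assigns a
(perimeter, area) colour pair — ten base colours encode up to 100 categories,
extras sharing an "other" pair with a warning — and z-orders larger modules
behind smaller ones. `autoplot()` renders the map; `export_module_graph()`
writes a module's bipartite graph (GraphML / edge-list TSV) with
sign-specific magnitude thresholds standing in for the interactive viewer's
correlation sliders.

## The synthetic world

`generate_dataset()` is first-class, tested code, not a fixture. Each planted
module draws a latent per-sample activity $z$; member miRNAs follow
$z + \varepsilon$, direct mRNAs $-\beta z + \varepsilon$, indirect mRNAs
$+\beta z + \varepsilon$ with Gaussian noise (default sd 0.1 against a
unit-variance activity); background features are independent noise. A
linear-Gaussian construction was chosen because its Spearman correlations
are analytically predictable from the Pearson ones, which keeps the oracle
tests closed-form. Predicted-target flags cover planted direct pairs minus a
10% false-negative rate plus 2% background false positives (echoing the
known unreliability of target prediction); indirect pairs never carry sites.
Planted categories coincide with module arms at 80% purity; validated pairs
are planted inside modules at ten times the background rate. Cooperative
groupings share one activity and scale each target so its expected
correlation with members is $k \times$ effect (default $-0.1$) — purely
additive cooperativity.

The default benchmark (200 miRNAs x 2000 mRNAs x 40 samples, five modules)
is a deliberate desk-scale analogue of a matched tumour panel (the original
analyses used 42 tumours with ~200 profiled miRNAs and ~13000 mRNAs). What
the generator does *not* emulate: array normalization artefacts, batch
effects, heavy-tailed per-mRNA targeting propensities, correlated target
sites within seed families, and overlapping planted modules. A green
recovery test therefore establishes that the search and integration machinery
recover well-separated linear-Gaussian structure at realistic noise — not
that every real-data module is trustworthy.

## Numerical and design choices

* Matrix orientation is miRNAs x mRNAs; the published "column threshold of
  10" (miRNAs) and "row threshold of 250" (mRNAs) map to `max_mirnas` and
  `max_mrnas`.
* The objective is the plain arithmetic mean (the printed formula is not
  recoverable from the source text; the prose states "low mean correlation"
  at fixed area). Any further normalisation is unknown and not applied.
* Seed size 5 x 20 is this package's default (unstated in the source):
  half the miRNA cap and a small fraction of the mRNA cap. All schedule
  parameters are exposed in `search_config()`.
* Exact zeros in $C$ carry no directional evidence and integrate to 0
  regardless of the target flag.
* Identifiers are matched case-sensitively after whitespace trimming;
  duplicates are an error, never silently averaged.
* Cooperativity uses raw correlations restricted to predicted-target pairs
  (the conflict-zeroed matrix can be passed instead; the source is ambiguous).
* Genomic clusters are named after their lexicographically first member;
  gaps are measured between interval boundaries and strand is ignored.
* `n_modules` independent rounds are run (whether the published 100 modules
  were 100 rounds or a top-100 selection is unstated).
* Degenerate inputs: an all-identical similarity matrix yields all-zero MDS
  coordinates; thresholds that exclude every edge export an empty-edge graph
  with a warning; modules with no annotated members are labelled
  "unannotated" and drawn at a minimal radius.

## A short run

```{r example, eval = FALSE}
sim <- generate_dataset(n_mirnas = 100, n_mrnas = 600, n_samples = 40,
                        module_specs = replicate(3, planted_module_spec(),
                                                 simplify = FALSE),
                        rng_seed = 7)
corr  <- compute_correlations(sim$mirna_expr, sim$mrna_expr)
assoc <- integrate_associations(corr, sim$targets)
mods  <- discover_modules(assoc, search_config(n_modules = 3,
                                               admission_margin = 0.2,
                                               rng_seed = 11)) |>
  label_modules(sim$annotation, gene_universe = colnames(assoc))
glance(mods)
autoplot(layout_modules(mods))
```

## Limitations

The search is stochastic between runs unless seeded; overlapping or very
wide structures can be rediscovered under the default mask policy; the
cooperativity p-value is conservative by construction (see above); GO terms
are treated as flat sets with no ancestor propagation; and no module merging
or pruning is performed — both are left to downstream judgement, as in the
original method.
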