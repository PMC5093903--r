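---
title: "Spatio-temporal differential expression in sorted epithelial populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal differential expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatempo)
```

## The analysis problem

The package analyses bulk RNA-seq time courses in which two FACS-sorted cell
populations — here the luminal (Lin^-^CD24^+^CD29^lo^) and basal
(Lin^-^CD24^+^CD29^hi^) lineages of the mouse mammary epithelium — are
profiled at eight postnatal time points: nulliparous week 10 (W10),
pregnancy days 3.5 and 14.5 (P3.5, P14.5), lactation days 3 and 10 (L3,
L10), involution day 2 and week 4 (Id2, Iw4), and the parous gland at four
months (M4). The design has 16 population-by-time conditions with three
biological replicates each, except a single missing replicate at L10, for
47 samples. Developmentally related time points are additionally pooled
into *stages*: lactogenesis = {P14.5, L3, L10}, lact-invo = {L3, L10, Id2},
lacto-invo = {P14.5, L3, L10, Id2}, plus non-pregnant {W10, M4} and
pregnancy {P3.5, P14.5}.

Two orthogonal axes of differential expression (DE) are distinguished:

* **spatial** — between the two populations at the same time point, and
* **temporal** — between two time points within one population.

On top of these, genes are classified as *luminal-specific* (up in luminal
at one or more time points, never up in basal), *basal-specific*
(symmetric), or *switching* (up in different populations at different time
points), with an *always-specific* flag when the direction is called at
every time point. Finally, *time-point-specific* and *stage-specific* genes
are those significant, with a consistent direction, in **every** pairwise
comparison of their target against the remaining time points (or against
each time point outside the stage).

## The inference procedure

`st_fit()` runs the full procedure and returns a classed object:

1. **Normalisation.** Counts per million: $\mathrm{CPM}_{gs} =
   10^6\, c_{gs} / \sum_g c_{gs}$, with the library size taken over all
   genes *before* filtering so CPM does not depend on the filter threshold.
   Tests operate on $\log_2(\mathrm{CPM} + 1)$; the pseudocount of 1 makes
   a CPM of zero map to zero and bounds fold changes of lowly expressed
   genes.
2. **Expression filter.** Genes with CPM $\ge$ 1 in at least 2 samples form
   the analysis universe. The thresholds are conventional defaults and are
   configurable; the universe size is data-dependent by construction.
3. **Omnibus ANOVA filter.** Per gene, a one-way ANOVA of log2 CPM across
   the 16 conditions, Benjamini–Hochberg (BH) adjusted across genes; genes
   with FDR < 0.01 are carried forward. This is the "DE in at least one
   population at at least one time point" gate.
4. **Spatial and temporal calls.** Per-comparison tests (below) with one BH
   family across all gene × time-point tests (spatial) and one across all
   gene × pair × population tests (temporal; 28 unordered pairs per
   population). A call requires FDR < 0.01 **and** a fold change of at
   least 2, computed as $\log_2\frac{\bar{x}_A + 1}{\bar{x}_B + 1}$ on
   group-mean CPM — pseudocounted so it is defined at zero and
   antisymmetric in the groups. The inclusive threshold
   ($|\mathrm{log_2FC}| \ge 1$) is used.
5. **Specificity targets.** For each population and each target (a time
   point, or a stage pooled into one group), the target is compared against
   every non-member time point, with one BH family per target across its
   gene × comparison grid; a gene enters the target's set only if every
   comparison is called with the same sign.
6. **Accounting.** All headline counts and percentages (share of ANOVA-DE
   genes, spatial/temporal shares, their intersection and
   inclusion–exclusion union, the specificity partition, always-specific
   shares, and per-population unique time-point/stage DE gene counts) are
   emitted by `accounting_report()` at one-decimal rounding.

### The per-comparison test

The two-group test is configurable (`test =`):

* `"anova"` (default) — a contrast t-test on the two group means using the
  per-gene residual mean square of the one-way condition model,
  $t = (\bar{x}_1 - \bar{x}_2) / \sqrt{\mathrm{MSE}\,(1/n_1 + 1/n_2)}$
  with $df = n - k$ (31 in the full design). No information is shared
  across genes, so this is an ordinary linear-model contrast, not
  empirical-Bayes moderation.
* `"welch"` — Welch's unequal-variance two-sample t on the two groups only.
* `"pooled"` — the pooled-variance two-sample t.

The default deserves a justification, because it was a genuinely open
design choice. With three replicates per group, a two-sample t has at most
4 (pooled) and often barely 2 (Welch) degrees of freedom, and its
attainable two-sided p-value decays only polynomially in $t$: surviving a
BH family of ~10^4 tests at FDR < 0.01 requires $p \lesssim 10^{-4.5}$,
i.e. $|t| \gtrsim 23$ at $df = 4$ — out of reach for most genes at
realistic counting noise *regardless of the biological effect size*. The
all-pairwise specificity definition, which demands seven simultaneous
calls, is then empty in practice. The condition-model contrast uses the
same within-group variability, estimated across all 16 conditions
(homoscedasticity on the log scale being the usual working assumption),
and its 31 residual degrees of freedom make the procedure's power
commensurate with its definitions. It is also the natural reading of
"ANOVA linear modeling" as the analysis framework: the omnibus filter and
the pairwise contrasts come from the same per-gene model.

### Degenerate inputs and numerical choices

* A gene with zero total variance gets $p = 1$ (trivially non-DE); zero
  within-group variance with non-zero between-group variance gets $p = 0$.
* Conditions with fewer than two replicates are dropped from testing with
  a warning rather than aborting.
* BH adjustment delegates to `stats::p.adjust`; `NA` entries (skipped
  comparisons) pass through untouched.
* PCA signs are fixed by flipping each loading vector so its
  largest-magnitude entry is positive, making outputs reproducible across
  platforms.
* Percentages are rounded to one decimal at the reporting boundary only.

## Quality control

`run_pca()` performs PCA on centred (unscaled — the convention for
log-expression) log2 CPM with samples as observations and reports
per-component explained-variance fractions. `associate_covariates()` tests
each covariate against each leading component — one-way ANOVA F for
categorical covariates, a regression F for numeric ones — distinguishing
biological covariates (population, time point, stage) from technical ones
(batch, lane, RNA amplification batch, sorting time). Covariates with a
single level are reported as not testable (`NA`), distinct from $p = 1$.
`detect_outliers()` flags samples whose median pairwise Pearson correlation
with the other samples falls below a threshold (default 0.8); a
constant-expression sample, whose correlation is undefined, is flagged as
degenerate. Outlier exclusion is an explicit, separate step
(`remove_outliers = TRUE`) that rewrites the sample list before testing.
Only the correlation rule is operationalised; the PCA is reported alongside
for visual confirmation, since no threshold for "sample–sample variability
in the PCA" can be stated precisely.

## Enrichment

`hypergeom_test()` computes the inclusive upper tail
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(N, K, n)$, for the
overlap $k$ between a query set ($n$ in the universe) and a reference set
($K$ in the universe); the inclusive tail is the standard
over-representation convention and the exclusive tail would be
anti-conservative. The universe defaults to the post-filter expression
universe, which is what the reported percentages are framed against; genes
outside it are dropped (and counted) before testing. `enrichment_matrix()`
runs all query × reference pairs, adjusts the grid as one BH family, and
flags significance at raw p < 0.01 to mirror the conventional heatmap
display, with the FDR column alongside for principled use. Cross-species
comparisons go through a user-supplied two-column ortholog table
(`map_orthologs()`); there are no online lookups.

## The synthetic-data generator

`simulate_dataset()` exists so that every downstream stage is testable with
planted ground truth. It emulates:

* the 47-sample design (three replicates per condition, two for basal L10 —
  the published design loses exactly one replicate at L10, and which
  population lost it is not recorded; the package fixes basal),
* negative-binomial counts, $\mathrm{Var} = \mu + \alpha\mu^2$ with
  constant dispersion $\alpha = 0.1$ (a typical bulk RNA-seq magnitude;
  constant across genes to keep recovery rates interpretable),
* a log-normal baseline (log2 CPM $\sim N(5, 2)$, a realistic dynamic
  range),
* log-uniform library sizes in 0.5–2 × 10^6 (so CPM normalisation is
  actually exercised),
* round-robin technical covariates (batch, lane, amplification batch,
  sorting time) with an optional additive batch effect (log2 magnitude
  configurable, default 0) applied to a random 20% of genes — applied to a
  gene subset because a whole-sample multiplicative shift would be removed
  exactly by CPM normalisation,
* five planted archetypes: null, population-specific, time-point-specific,
  stage-specific, and switching (up in luminal at one time point and in
  basal at a disjoint one).

Two generator design choices matter for calibration:

* **Mixture.** 10% effect genes in total (2.5% per effect archetype),
  the conventional DE fraction in benchmarking simulators. Planting much
  more mass makes condition library compositions diverge, which moves
  "null" genes off-null after CPM scaling — an artefact of the generator,
  not of the inference.
* **Mass-bounded planting.** An effect gene keeps its *baseline* level in
  its target conditions and sits `log2_effect` (default 4) lower everywhere
  else. The target-vs-rest contrast is identical to an up-shift, but each
  gene's contribution to any library is bounded by its baseline, so a
  heavy-tailed baseline draw cannot distort the composition. This is also
  what sorted-population marker genes look like in practice. True
  per-condition means are renormalised to the CPM scale and stored, so
  empirical mean CPM converges to the stored truth.

What the generator does *not* emulate: gene length and GC bias, isoform
structure, correlated genes/modules, sample-specific dispersion, batch
effects with structure beyond a single additive shift, or compositional
extremes such as the casein-dominated libraries of a lactating gland.
Passing recovery tests therefore demonstrates the correctness and
calibration of the inference machinery under its own assumptions — not
that the pipeline is robust to everything real data can do.

## Problem sizes and seeds

The bundled tests and the acceptance script run the generator at 2,000
genes × 47 samples (hundreds of milliseconds per fit), use fixed seeds
throughout, estimate the empirical FDR as the mean false-discovery
proportion over five simulation replicates (FDR is an expectation; a
single run's proportion among a few hundred discoveries is too noisy to
assert against), and check mean-CPM fidelity at 200 replicates per
condition with an explicit sampling allowance. Determinism is contractual:
the same configuration and seed reproduce byte-identical outputs, and the
simulator restores the caller's RNG state.

## Known limitations

* The per-gene condition model assumes homoscedasticity across conditions
  on the log scale; strongly mean-dependent noise at very low counts
  violates this, which is why very lowly expressed planted genes are the
  ones recovery misses.
* CPM is the only normalisation offered (by design); datasets with strong
  compositional differences between conditions need TMM-like scaling
  upstream of this package.
* The published study's gene-level results (exact DE lists, PCA p-values,
  universe size 17,606) depend on its deposited data and unstated
  preprocessing and are not reproduced here; the accounting arithmetic,
  the procedure definitions, and the statistical behaviour of every stage
  are.
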