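---
title: "Screening expression profiles for synthetic-lethal partners of p53"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening expression profiles for synthetic-lethal partners of p53}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(synlethscreen)
library(dplyr)
```

## The screening model

Wild-type p53 arrests the cell cycle or triggers apoptosis partly by
repressing transcription of proliferation genes. When a tumor acquires a
*functional* TP53 mutation — one assumed to abrogate p53 function — that
repression is lost, and p53's repression targets rise in expression. Genes
both *over-expressed in functional-p53-mutant samples* and *druggable*
(kinase-encoding) are plausible candidates for synthetic lethality with
p53: inhibiting them should preferentially harm the cells that have come to
depend on their elevated activity.

The package's pipeline operationalizes this as four stages, each a plain
function over tibbles.

### 1. Mutation-functionality classification

Missense, nonsense (stop-codon) and frameshift TP53 mutations count as
functional p53 mutations; silent changes — synonymous mutations and
mutations in noncoding DNA — do not, and are grouped with wild-type.
`assign_labels()` gives class `c1` to every sample carrying at least one
functional record and `c2` to the rest. Two choices here were genuinely
open:

* **Multiple records per sample.** Functionality is defined per mutation,
  so a sample with both a silent and a missense record is `c1`
  ("any-functional" rule): a single function-abrogating allele is what the
  mutant class is meant to capture. The alternative — requiring *all*
  records functional — would place compound-heterozygous samples in the
  wild-type-like class, which contradicts the class's meaning.
* **Samples present only with non-TP53 records.** Treated as TP53
  wild-type (`c2`), with a warning, since the table simply carries no TP53
  information for them.

Labels are a function of the mutation table alone; expression never feeds
back into them.

### 2. Per-gene class comparison

For each gene, `run_class_comparison()` computes a two-sample t statistic
between `c1` and `c2`, its two-sided parametric p, a label-permutation p,
and a Benjamini–Hochberg q-value.

**Variance model.** The default is the classical pooled-variance t (the
two-class specialization of the one-way F: with two groups, $F = t^2$
exactly, which the test suite asserts to $10^{-10}$). Welch's form is
available via `variance_mode = "welch"` for strongly heteroscedastic data.
The pooled default matches the classical class-comparison setting where
the same residual variance is assumed in both classes.

**Permutation p.** The permutation p-value of a gene is the proportion of
class-label permutations whose test p-value is *at least as small as* the
observed one — comparing on p rather than |t| keeps t-tested and F-tested
genes on one scale. Two numerical details:

* *Smoothing.* A raw Monte-Carlo proportion can be 0, which is both
  impossible (the true permutation p is positive) and useless for ranking.
  Monte-Carlo mode therefore reports
  $(1 + \#\{p_{perm} \le p_{obs}\})/(1 + B)$, whose smallest value with
  $B = 10{,}000$ draws is $1/10001 \approx 10^{-4}$. Exhaustive mode
  enumerates every distinct label assignment once (the observed assignment
  included, so p > 0 with no smoothing needed); `mode = "auto"` switches
  to enumeration whenever the assignment space is no larger than the
  requested number of draws.
* *Ties.* "At least as small" is a `<=` comparison with an absolute slack
  of $10^{-12}$: the mirrored assignment reproduces the observed p only up
  to the last floating-point ulp, and must count.

Permutations are drawn with replacement from the assignment space
(standard Monte-Carlo practice; exhaustive mode covers small spaces
exactly). The whole run is deterministic given `perm_scheme()`'s seed —
same seed, bit-identical p-values.

**Missing values.** Analysis is complete-case per gene; a gene needs at
least 2 values in each class to be testable, and untestable genes are
excluded (with a warning) from the run and from the FDR universe. Genes
sharing a missingness pattern share permutation draws, which lets the
engine process each pattern as one vectorized matrix product; per-gene
group sizes are fixed across permutations because labels are permuted
within the gene's observed samples.

**FDR.** q-values are Benjamini–Hochberg over the parametric p-values of
all testable genes of the run — the q reported alongside a gene answers
"what FDR would declaring this gene significant imply", while selection
itself defaults to the unadjusted 0.05 test (below). The `universe`
argument restricts both testing and the FDR universe to a gene subset
(e.g. the kinome): since BH depends on the number of tests, a
kinome-restricted run yields sharply lower q-values at the same p.

### 3. Candidate selection and consensus

`select_candidates()` keeps genes with selected p ≤ α, direction
`up_in_c1`, and membership in the kinase list. The default selection p is
the **parametric** p at α = 0.05 — a deliberately loose threshold: kinase
genes are a small minority of the genome, and a genome-wide-stringent cut
would empty the kinome intersection in small panels. The permutation p and
the q-value are available as alternative selection criteria via `p_type`.

Gene matching is exact and case-sensitive on the base symbol; no alias
resolution is attempted (alias maps are a data dependency with their own
versioning problems — callers should harmonize symbols upstream).
Multi-probe arrays are handled by `read_expression(probe_mode = "suffix")`,
which disambiguates duplicate symbols as `GENE#1`, `GENE#2`; the screen
maps a probe back to its base symbol and a gene is a candidate if *any*
probe passes.

`consensus_candidates()` counts, per gene, the datasets where it was
selected, and filters at `min_datasets = 2`: recurrence in two independent
datasets is the guard against single-platform artifacts. A gene untestable
in a dataset simply cannot vote there; the unfiltered union is kept as an
attribute (and via `tidy()`).

### 4. Drug-sensitivity comparison

For compounds whose annotated targets intersect the candidate set,
`compare_compound()` tests the one-sided alternative that mean
−log(GI50) z-score is *higher* in `c1` lines. Orientation matters: lower
GI50 means higher sensitivity, so higher z is higher sensitivity and the
alternative is "functional-p53-mutant lines are more sensitive" — the
direction synthetic lethality predicts. Compound p-values are reported
raw, without multiple-testing adjustment: the compound panel is small and
the comparison is explicitly exploratory, limited in power by the size of
the mutant class. Compound names match after case-folding and
whitespace-stripping only.

## The synthetic-data generator

`simulate_bundle()` generates the complete input set from one seed. Its
defaults are the study conditions the rest of the package is calibrated
under:

| parameter | default | meaning |
|---|---|---|
| `n_samples`, `n_mutant` | 60, 41 | NCI-60-like panel: 41 functional-mutant / 19 other |
| `n_genes`, `n_kinases` | 1000, 100 | kinome a 10% minority of the measured genes |
| `n_planted`, `effect_size` | 10, 1.5 | planted up-in-`c1` kinase genes, shift in noise-SD units |
| `sigma` | 1 | residual SD of log expression |
| `missing_rate` | 0.02 | fraction of cells missing |
| `n_datasets` | 3 | datasets sharing planted genes, independently drawn |
| `n_compounds`, `n_target_compounds` | 30, 8 | drug panel; compounds mapped to planted genes |
| `drug_effect` | 1 | z-score shift of target compounds in `c1` lines |
| `silent_rate` | 0.3 | fraction of `c2` samples given a silent-class record |

The 41/19 split mirrors the classic NCI-60 TP53 annotation; 1000 genes
with a 100-gene kinome keeps the kinome-minority structure at a size where
a full permutation run takes seconds, and an effect of 1.5 SD with a 41/19
split gives per-gene power high enough that the *consensus* step, not the
per-gene test, is what is being exercised. Baseline expression is uniform
on 4–12 log units per gene — purely cosmetic heterogeneity. Values are
rounded to 6 decimals so written bundles are byte-stable.

What the generator deliberately does **not** emulate: gene–gene
correlation (expression is independent Gaussian given the class), platform
effects between the datasets of a bundle, realistic mutation spectra, or
the marginal distributions of any real panel. Consequences: passing tests
demonstrate the pipeline's *operating characteristics under its own
assumptions* — calibrated type-I error, recovery of planted signal,
correct directionality — not performance on real arrays, where correlated
genes make the number of false positives more variable than binomial and
where batch effects can masquerade as class differences. Silent-class
records are placed only in `c2` samples by construction, so the
"non-functional plus wild-type" grouping is exercised on every run.

## Numerical and interface choices

* **Centred sums-of-squares.** The permutation engine centres each gene
  before computing $SS_{within} = S_2 - n_1\bar{x}_1^2 - n_2\bar{x}_2^2$,
  avoiding catastrophic cancellation when means dwarf variances; negative
  round-off residues are clamped at 0. Reported class means are restored
  to the original log scale.
* **Degenerate genes.** Both classes constant and equal: t = 0, p = 1 (and
  permutation p = 1, since every assignment ties). Constant but unequal:
  |t| = ∞, p = 0.
* **Determinism on disk.** `write_results_table()` applies a documented
  sort per table type (gene results: permutation p, then parametric p,
  then symbol); `read_results_table()` re-parses numbers with R's
  correctly-rounded parser so write→read→write is byte-identical.
* **Missing-value dialect.** Empty cell, `NA` and `NaN` parse as missing
  in every tabular reader; any other non-numeric cell is an error naming
  the row and column. Duplicate gene rows are rejected unless probe mode
  is requested; duplicate sample ids are always an error.
* **Statistical acceptance checks with many simultaneous bounds** (e.g.
  200 genes each compared to an exhaustive reference at 3 binomial SEs)
  use a family-wise 4.5-SE ceiling plus a ≥97.5% bulk-within-3-SE
  requirement: two hundred simultaneous 99.7% events fail as a family
  almost half the time, so a per-gene-only bound would reject a correct
  implementation by design.

## Problem sizes used by the test and acceptance runs

The suite exercises: exhaustive-vs-Monte-Carlo agreement on 200 genes with
class sizes ≤ (5, 5) at 10,000 draws; type-I calibration on one null
1000-gene 41/19 bundle with full 10,000-draw permutation p-values;
BH-against-definition on 1000 random p-vectors; F = t² across a full
dataset; consensus recovery and false-discovery proportion over 20
replicate 3-dataset bundles at the generator defaults; and drug-rank
separation plus label-shuffled nulls over 20 replicates. These sizes make
the binomial error bars small relative to the effects being verified while
keeping a full run in minutes on one core.

## Known limitations

* Candidate status is association, not synthetic lethality: elevated
  expression in mutant samples can arise from co-mutation, lineage, or
  batch structure. The screen is a pre-filter for RNAi or inhibitor
  validation, nothing more.
* No alias/ortholog resolution; symbol harmonization is the caller's job.
* The univariate tests ignore covariates (tissue of origin, batch); panels
  with strong structure need upstream adjustment.
* BH control is proven under independence/PRDS; correlated genes leave the
  q-values approximate.
* GI50 comparisons assume pre-computed, normalized z-scores on a shared
  cell-line panel; no dose-response fitting is done.

## A complete run

```{r pipeline, eval = FALSE}
bundle <- simulate_bundle(sim_config(seed = 2024))
labels <- assign_labels(bundle$mutations, expr_samples(bundle$expression[[1]]))

sets <- lapply(bundle$expression, function(e) {
  select_candidates(run_class_comparison(e, labels, scheme = NULL),
                    bundle$kinases)
})
consensus <- consensus_candidates(sets, min_datasets = 2)
drugs <- screen_compounds(bundle$drug_matrix, bundle$target_map,
                          consensus$gene, labels)

autoplot(run_class_comparison(bundle$expression[[1]], labels,
                              perm_scheme(10000, seed = 2025)))
autoplot(consensus)
autoplot(drugs)
```
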