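# synlethscreen

Expression-profile pre-screening of druggable synthetic-lethal partners of
p53.

## The problem

TP53 is mutated in over half of human cancers, but mutant p53 itself is not
druggable. A gene that is *synthetic lethal* to p53 — tolerable to lose on
its own, lethal to lose in a p53-mutant cell — is an indirect drug target
selective for tumor cells. Genome- or kinome-wide RNAi screens find such
partners directly but are costly; an expression-based pre-screen narrows
the candidate list first.

The screen rests on a simple observation: wild-type p53 transcriptionally
represses many proliferation and cell-cycle genes, so tumors that have
*lost* p53 function tend to over-express them. `synlethscreen` implements
the full pre-screen for users with summarized log-expression matrices and
TP53 mutation annotations (cell-line panels or tumor cohorts):

1. **Classification** — samples carrying a *functional* TP53 mutation
   (missense, nonsense, frameshift: changes assumed to abrogate p53
   function) form class `c1`; silent/synonymous/noncoding changes and
   wild-type form class `c2`.
2. **Class comparison** — per gene, a two-sample t statistic (pooled by
   default, Welch optional; the equivalent one-way F for multi-probe
   workflows), its two-sided parametric p, a label-permutation p (default
   10,000 permutations: the proportion of permuted labelings whose test p
   is at least as small as the observed one), and a Benjamini–Hochberg
   q-value over all testable genes.
3. **Candidate screen** — keep genes with p ≤ α (default 0.05), higher
   mean expression in `c1`, and membership in a supplied kinase list (the
   druggable kinome); candidates recurring in ≥ 2 independent datasets
   form the consensus list.
4. **Drug sensitivity** — for compounds whose annotated targets intersect
   the candidates, compare normalized −log(GI50) z-scores (higher z =
   higher sensitivity) between `c1` and `c2` cell lines with a one-sided t
   test of the alternative "mutant lines are more sensitive".

A seeded generator (`simulate_bundle()`) produces complete synthetic input
bundles — expression datasets with planted up-regulated kinase genes, a
matching mutation table, kinome list, drug matrix and compound→target map —
so the whole pipeline is testable and calibratable without any downloads.

## Worked example

```r
library(synlethscreen)
library(dplyr)

bundle <- simulate_bundle(sim_config(seed = 2024))   # 3 datasets, 41/19 split
labels <- assign_labels(bundle$mutations, expr_samples(bundle$expression[[1]]))

results <- run_class_comparison(bundle$expression[[1]], labels,
                                perm_scheme(10000, seed = 2025))
glance(results)
#> # A tibble: 1 × 8
#>   dataset  n_genes n_untestable alpha n_sig_parametric n_sig_permutation n_sig_q
#>   <chr>      <int>        <int> <dbl>            <int>             <int>   <int>
#> 1 sim_dat…    1000            0  0.05               60                61      11

head(arrange(tidy(results), permutation_p) |> select(-n1, -n2), 5)
#> # A tibble: 5 × 8
#>   gene   mean1 mean2 statistic parametric_p permutation_p   q_value direction
#>   <chr>  <dbl> <dbl>     <dbl>        <dbl>         <dbl>     <dbl> <chr>
#> 1 G00131 10.3   8.84      6.05 0.000000128      0.0001000 0.0000427 up_in_c1
#> 2 G00189 12.0  10.7       4.89 0.00000889       0.0001000 0.00148   up_in_c1
#> 3 G00212 12.7  11.3       5.22 0.00000269       0.0001000 0.000673  up_in_c1
#> 4 G00329  5.79  4.48      4.43 0.0000440        0.0001000 0.00550   up_in_c1
#> 5 G00427 10.9   8.91      6.34 0.0000000398     0.0001000 0.0000199 up_in_c1
```

`mean1`/`mean2` are class means of log expression; `permutation_p` bottoms
out at 1/10001 (add-one smoothing, so a permutation p is never 0). The
candidate screen and cross-dataset consensus:

```r
sets <- lapply(bundle$expression, function(e)
  select_candidates(run_class_comparison(e, labels, scheme = NULL),
                    bundle$kinases))
consensus <- consensus_candidates(sets, min_datasets = 2)
glance(consensus)
#> # A tibble: 1 × 4
#>   n_input_datasets min_datasets n_union_genes n_consensus_genes
#>              <int>        <int>         <int>             <int>
#> 1                3            2            15                10

mean(bundle$truth$planted_genes %in% consensus$gene)
#> [1] 1
```

All 10 planted kinase genes are recovered; the 5 extra union genes fell
short of the two-dataset threshold. Finally the drug-sensitivity
comparison for compounds targeting the consensus genes:

```r
drugs <- screen_compounds(bundle$drug_matrix, bundle$target_map,
                          consensus$gene, labels)
head(drugs |> select(-n1, -n2, -statistic), 5)
#> # A tibble: 5 × 6
#>   compound mean_c1 mean_c2 one_sided_p concordant targets
#>   <chr>      <dbl>   <dbl>       <dbl> <lgl>      <chr>
#> 1 D007       0.980 -0.461  0.000000366 TRUE       G00131,G00427,G00596
#> 2 D011       1.09  -0.0443 0.000000765 TRUE       G00131,G00189,G00209
#> 3 D017       1.21  -0.129  0.00000966  TRUE       G00596
#> 4 D022       1.34   0.237  0.0000438   TRUE       G00212,G00596
#> 5 D005       0.993 -0.140  0.0000796   TRUE       G00427,G00596
```

`concordant = TRUE` marks compounds with higher mean sensitivity in the
functional-p53-mutant lines — the direction a synthetic-lethal target
predicts. `autoplot()` methods draw a volcano plot of a comparison, a bar
chart of consensus counts, and a class-mean segment plot of a compound
screen.

Real data enter through `read_expression()` (plain TSV or `#1.2` GCT-like,
with `probe_mode = "suffix"` for multi-probe arrays), `read_mutations()`,
`read_gene_list()`, `read_drug_matrix()` and `read_target_map()`; results
leave through `write_results_table()`, which writes deterministic,
round-trippable TSVs.

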