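# peaclass

Classification-based pathway enrichment analysis (PEA) with analytic
confusion-matrix P-values.

## The problem

Classical enrichment methods (ORA, GSEA-style functional class scoring) test
whether a predefined gene set behaves differently between two sample groups,
but their rigid statistical models degrade on large, noisy, multi-center
expression datasets with low signal-to-noise ratios. `peaclass` takes the
classification view instead: **if a pathway is differentially expressed, a
classifier trained only on that pathway's genes should separate the two
groups better than chance.** Any binary classifier can be plugged in; the
package ships a permutation-invariant point-cloud neural network designed
for gene expression alongside logistic-regression and linear-SVM baselines.

## The statistic

Significance is read directly off the classifier's cross-validated 2×2
confusion matrix (a11 = class-1 hits, a12 = class-1 errors, a21 = class-2
errors, a22 = class-2 hits), with no permutation testing. With n1 = a11 +
a12, n2 = a21 + a22, N = n1 + n2, and empirical class priors p1 = n1/N,
p2 = n2/N, a "random guesser" assigns class 1 with probability p1
independently per sample, so its class-1 error count is Binomial(n1, 1 −
p1). The per-class P-values are the inclusive lower binomial tails

    P1 = P[Bin(n1, 1 − p1) ≤ a12],   P2 = P[Bin(n2, 1 − p2) ≤ a21]

— the probability that random guessing makes no more errors than the model
did — and the combined pathway P-value is

    P = 1 − (1 − P1)(1 − P2),

the probability that a random model matches or beats the classifier on at
least one class. P is small only when the classifier beats chance on *both*
classes, which makes the statistic conservative under the null (see the
methods vignette). The held-out confusion matrix comes from stratified
5-fold cross-validation with out-of-fold pooling, so training-set optimism
never inflates significance.

The package also contains the validation machinery: a block
compound-symmetric multivariate-normal expression simulator (within-pathway
correlation 0.8, between-pathway 0.05, mean shifts of `sigma * sqrt(SNR)`
in selected sets), a betweenness-centrality stimulation injector for
real-like data, and a replicated Type-I-error / power harness with
cross-constrained threshold calibration.

## Worked example

```r
library(peaclass)
library(dplyr)

cfg <- simulation_config(n_genes = 1000, n_sets = 10, genes_per_set = 100,
                         n_de_sets = 2, snr = 0.5, n_per_group = 100,
                         seed = 42)
sim <- simulate_dataset(cfg)
sim$truth
#> simulation truth: 2 differential sets (set01, set05), shift 0.7071

res <- run_pea(sim$expression, sim$gene_sets,
               classifier_spec("gpnet"), split_scheme(k = 5), seed = 42)
res |>
  mutate(is_de = pathway %in% sim$truth$de_sets) |>
  select(pathway, n_genes, accuracy, pvalue_combined, is_de)
#> # A tibble: 10 × 5
#>    pathway n_genes accuracy pvalue_combined is_de
#>    <chr>     <int>    <dbl>           <dbl> <lgl>
#>  1 set01       100    0.92            0     TRUE
#>  2 set02       100    0.5             0.809 FALSE
#>  3 set03       100    0.54            0.512 FALSE
#>  4 set04       100    0.49            0.906 FALSE
#>  5 set05       100    0.95            0     TRUE
#>  6 set06       100    0.545           0.382 FALSE
#>  7 set07       100    0.525           0.591 FALSE
#>  8 set08       100    0.42            0.998 FALSE
#>  9 set09       100    0.53            0.522 FALSE
#> 10 set10       100    0.455           0.979 FALSE
```

Both truly shifted pathways classify at ≥ 92% held-out accuracy and get
combined P-values at machine zero; every null pathway stays near
coin-flip accuracy with a large P-value. The statistic alone:

```r
combined_pvalue(confusion_matrix(40, 10, 15, 35))
#> confusion-matrix P-value
#>   P1 = 1.19307e-05  P2 = 0.00330022  combined = 0.00331212
#>   accuracy = 0.7500  (p1 = 0.5000, p2 = 0.5000)
```

`autoplot(res)` draws the P-value histogram;
`plot_error_power(type_i_and_power(records, by = c("n", "snr", "method")))`
draws Type-I/power curves from a [`replicate_experiment()`] run. A thin
command-line interface (`inst/cli/peaclass`) exposes `simulate`,
`stimulate`, `run`, `evaluate` and `pvalue` subcommands over the same
functions and logs every resolved configuration and seed next to its
outputs.

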