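# comodnet

Condition-annotated gene co-expression networks via Gaussian mixture
models.

## The problem

Gene co-expression networks (GCNs) connect transcripts whose expression
correlates across samples. Built from a *mixed-condition* compendium —
e.g. RNA-seq from several tumor subtypes pooled together — plain
correlation is unreliable: a gene pair expressed in two separated modes
(one per condition) yields a strong Pearson/Spearman coefficient driven by
the gap between the modes, not by co-regulation within either
(*co-modality*). `comodnet` is for researchers who want to build GCNs
from such heterogeneous compendia and know, for every edge, *which
samples* — hence which condition — produced it.

## The method

For each transcript pair, the complete observations
$x_i \in \mathbb{R}^2$ are decomposed with a bivariate Gaussian mixture

$$f(x_i \mid \theta) = \sum_{k=1}^K p_k\, h(x_i \mid \mu_k, \Sigma_k),$$

fit by EM (seeded random initialization) with $K$ chosen by the
integrated completed likelihood,
$\mathrm{ICL} = \mathrm{BIC} + 2\,\mathrm{ENT}$, which favours
well-separated components. Correlation (Spearman by default) is computed
*per cluster*, for clusters of ≥ 30 samples (a Fisher-z power bound at
α = 0.05, β = 0.2, effect 0.5) whose expression spans ≥ 0.1 log2 units.
Every edge carries a digit-coded **sample string** (one digit per sample:
`1` in-cluster, `0` out, `9` missing, `6`/`8` outlier-removed) — the
edge's condition annotation. The network threshold is found by random
matrix theory (first τ where the thresholded matrix's eigenvalue spacings
turn Poisson); overlapping modules come from link communities cut at
maximum partition density; modules are tested for clinical and functional
enrichment (Fisher's exact test) and networks evaluated by neighbor-voting
AUROC.

## Worked example

Simulate a small two-condition compendium with one 5-gene module active
only in condition A, run the pipeline, and ask which condition the
recovered module belongs to:

```r
library(comodnet)

cfg <- synth_config(
  conditions = c(A = 40L, B = 40L),
  modules = list(list(gene_count = 5L, active_conditions = "A",
                      r = 0.9, mean_shift = 3)),
  background_genes = 10L, missing_rate = 0.02, seed = 3)
sim <- generate_gem(cfg)

run <- run_pipeline(sim$gem, pairwise_config(seed = 9), tau = 0.8,
                    samples = sim$samples, log2 = FALSE, quantile = FALSE)
run$network
#> Co-expression network: 9 edges over 5 transcripts (|rho| >= 0.8)
#> # A tibble: 9 × 7
#>   gene_a   gene_b   cluster_index   rho method   num_samples sample_string
#> 1 MOD1_G01 MOD1_G02             2 0.889 spearman          35 11111111011191111…
#> 2 MOD1_G01 MOD1_G03             1 0.905 spearman          37 11111111011191111…
#> ...
```

Nine of the ten planted pairs are recovered, and most edges are backed by
30–40 samples — condition A's cluster only. (Two edges ride a ~78-sample
cluster spanning both conditions: at 40 samples per condition the mixture
occasionally fails to split the modes, which is exactly the small-N
behaviour the 30-sample power bound warns about.)

```r
score_recovery(run$network, sim$truth, sim$samples)
#> # A tibble: 1 × 5
#>   n_edges n_true_pairs precision recall purity
#> 1       9           10         1    0.9  0.847

library(dplyr)
run$enrichment |> filter(attribute == "condition") |> arrange(p) |> head(2)
#>   module_id attribute category     a     b     c     d        p p_bonferroni
#> 1 M0001     condition A           25     0    15    40 1.11e-10     2.21e-10
#> 2 M0001     condition B            0    25    40    15 1   e+ 0     1   e+ 0
```

The single detected module's sample set (samples present in ≥ 95% of its
edges) is 25 samples, all from condition A: Fisher's exact test calls the
planted condition at p ≈ 1e-10 while condition B shows nothing. `autoplot()`
on the network draws the sample-composition heatmap; `tidy()`/`glance()`
methods summarise every result type.

A thin command-line front end wraps the same functions
(`exec/comodnet`; subcommands `simulate`, `preprocess`, `similarity`,
`threshold`, `extract`, `heatmap`, `modules`, `enrich`, `evaluate`,
`run-all`), with `--chunk A:B` pair-index windows for embarrassingly
parallel similarity runs.

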