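# dawn

Screen-and-clean detection of disease risk genes by combining gene-level
rare-variant association scores with a gene co-expression network.

## What it does

Rare-variant association tests (e.g. TADA P values from exome studies of
autism trios) pinpoint only the few strongest risk genes; most true risk
genes carry weak marginal signal. `dawn` implements the DAWN algorithm:
risk genes cluster inside a brain co-expression network, so "hot spots" of
moderate signal are jointly informative.

**Screen.** Genes are organised into WGCNA-style co-expression modules
(soft powers 1 and 6, two developmental periods — four network
*representations*), tightly correlated genes collapse into multi-gene
nodes (scored by their minimum P value), and nodes are connected at
average |r| > 0.7. A hidden Markov random field with Ising prior

    P(I) ∝ exp( b Σᵢ Iᵢ + c Σ₍ᵢⱼ₎∈E Iᵢ Iⱼ ),   Zᵢ | Iᵢ ~ N(0,1) or N(μ, σ²)

is fitted over the node graph (ICM + pseudo-likelihood, with
marginal-mixture emissions and a Monte-Carlo-EM refinement of b, c); nodes
with posterior risk probability ≥ 0.5 are screened in (**nASD** genes).

**Clean.** A stratified two-component Gaussian-mixture local FDR (null
fixed at N(0,1); every screened multi-gene node with > 10 genes is its own
stratum) yields tail-averaged q-values; genes with q ≤ 0.05, minimised
over the four representations and passing a signal-removal robustness
filter (validation score ≥ 0.9), are the final **rASD** calls.

The package also ships the validation machinery: network scores
(Sᵢ = Σⱼ |r_ij| z_j with hard thresholds), a mutability-matched
connectivity permutation test, exact hypergeometric/Fisher enrichment
statistics with the conditional-MLE odds ratio, a de novo mutation
occupancy extrapolation, signal-dilution permutation experiments, and a
block-factor synthetic data generator so the whole pipeline is testable
without any external data.

## Worked example

```r
library(dawn)
sc  <- synth_scenario(seed = 1)            # two periods, 1000 genes, 50 planted risk genes
res <- run_dawn(sc$expression, sc$scores, dawn_config(seed = 1))
print(res)
#> dawn_result: 4 representations, 146 nASD genes, 40 rASD genes
#>   p35_pow1: c = 5.534, mu = 1.180, 39 nASD nodes
#>   p35_pow6: c = 2.408, mu = 1.656, 40 nASD nodes
#>   p46_pow1: c = 0.991, mu = 0.968, 17 nASD nodes
#>   p46_pow6: c = 0.476, mu = 1.919, 16 nASD nodes

head(res$gene_table[order(res$gene_table$q_min), ], 5)
#>      gene  p_value    z dnlof nASD network_score    q_min rASD
#> 162 G0162 9.64e-08 5.21     0 TRUE          61.6 5.38e-06 TRUE
#> 174 G0174 1.93e-07 5.08     0 TRUE          64.5 7.09e-06 TRUE
#> 159 G0159 2.47e-05 4.06     0 TRUE          62.2 1.38e-04 TRUE
#> 167 G0167 5.54e-08 5.31     0 TRUE          57.7 1.48e-04 TRUE
#> 7   G0007 3.21e-06 4.51     0 TRUE          61.1 2.18e-04 TRUE

sum(res$rasd_genes %in% sc$risk_genes)     # 39 of the 40 calls are planted risk genes
#> [1] 39
```

Reading the output: `c > 0` in every representation means association
signal is clustered on the network (the screening model's premise);
screening admits 146 genes, and cleaning refines them to 40 calls at
q ≤ 0.05, of which 39 are truly planted — a realised false discovery
proportion of 2.5% at the nominal 5% threshold.

Enrichment statistics used for validation against resequencing
experiments:

```r
hypergeom_tail(N = 44, K = 10, n = 8, k = 6)   # 0.000688
fisher_exact_test(matrix(c(2, 0, 1, 25), 2, byrow = TRUE))
#> $p_value 0.00794;  $odds_ratio Inf
fisher_exact_test(matrix(c(4, 4, 1, 7), 2, byrow = TRUE))
#> $p_value 0.141;    $odds_ratio 6.157   (conditional MLE, not 4*7/(4*1) = 7)
```

## Command line

```sh
Rscript inst/cli/dawn.R simulate --out data/ --seed 1
Rscript inst/cli/dawn.R run --expr data/expression_p35.tsv,data/expression_p46.tsv \
    --scores data/gene_scores.tsv --out results/ --seed 1
Rscript inst/cli/dawn.R stats hypergeom 44 10 8 6
Rscript inst/cli/dawn.R stats fisher 4 4 1 7
```

Inputs are plain TSV: an expression matrix (first column gene symbol,
header of replicate labels) per period, and a gene score table with
columns `gene`, `tada_p`, `dnlof`.

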