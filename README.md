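# pertnet

Perturbed-subnetwork and hub-network analysis for case/control expression
data on protein–protein interaction (PPI) networks.

## The problem

Diseases rarely dys-regulate isolated genes; they perturb connected regions
of the interactome. Given (i) an undirected PPI network, (ii) a genes ×
samples expression matrix with a two-group (case/control) design, and
optionally (iii) gene-set collections (GMT) and per-sample severity scores,
`pertnet` finds the *maximal-scoring connected subnetwork* — the "active
module" of coordinated differential expression — and characterizes its hub
genes across conditions. It is aimed at systems-biology analysts who want a
self-contained, scriptable, fully seeded version of this workflow, testable
end-to-end on synthetic data with known ground truth.

## The model

1. **Differential expression.** Per gene, an empirical-Bayes moderated
   t-statistic: the pooled variance `s²_g` is shrunk toward a prior,
   `s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d)`, with `(d₀, s₀²)` estimated by
   matching moments of `log s²` to a scaled-F model; p-values use
   `d + d₀` degrees of freedom.
2. **Node scores.** The p-value distribution is decomposed as a
   beta-uniform mixture (BUM), `f(x) = λ + (1−λ)·a·x^(a−1)`: uniform noise
   of weight λ plus `Beta(a,1)` signal. With
   `π = λ + (1−λ)a` (the noise upper bound), the threshold
   `τ(FDR) = ((π − FDR·λ)/(FDR·(1−λ)))^(1/(a−1))` controls the FDR of
   positively scored genes, and each gene scores
   `s(x) = (a−1)(ln x − ln τ)` — positive below τ, negative above. The FDR
   is chosen by scanning a grid so that ≈10% of network nodes score
   positively.
3. **Subnetwork search.** The maximal-scoring subgraph is found exactly by
   enumeration on small graphs, and on real-size graphs by an MST-based
   heuristic (contract positive components into meta-nodes, transfer
   negative-node penalties to edge weights, take the minimum spanning tree,
   collect negative connectors on meta-node paths, and return the
   highest-scoring path of a second MST, pruning negative leaves).
4. **Hubs and downstream.** Genes at or above the 90% within-subnetwork
   degree quantile are hubs; hubs across conditions form a hub network
   (edges present in ≥1 condition's subnetwork). Its perturbation in any
   dataset is the mean |moderated t| with a permutation p-value; overlap of
   subnetworks uses a one-sided Fisher test; gene-set over-representation
   uses the hypergeometric tail (significant when overlap > 5 and
   p < 0.01); severity coupling uses Pearson correlation at p ≤ 0.05.

## Worked example

A 500-gene scale-free interactome with a planted 20-gene module shifted by
2 SD in 10 case vs 10 control samples:

```r
library(pertnet)
g   <- simulate_network(500, 2, seed = 42)
mod <- plant_module(g, 20, seed = 42)
sim <- simulate_expression(g, mod, n_case = 10, n_control = 10,
                           effect = 2, seed = 43)
res <- perturbed_subnetwork(sim$matrix, g)
res$fit
#> beta-uniform mixture fit: lam = 0.9189, a = 0.1362 (n = 500, loglik = 108.26)
#>   upper bound on noise proportion pi = 0.9300
res$subnetwork
#> subnetwork: 27 nodes, 28 edges, total score 172.6431
perturbation_test(res$subnetwork$nodes, res$de, n_perm = 1000, seed = 1)
#> hub-network perturbation: mean |t| = 3.957 over 27 genes, p = 0.000999
#>   permutation null: 0.953 +/- 0.183
```

The fitted mixture says ~92% of genes are noise (λ̂ = 0.92); the scan picks
the FDR whose threshold leaves 10% of nodes positive; the recovered
27-node module contains all 20 planted genes (recall 1.0, precision 0.74,
F1 0.85); its mean |t| of 3.96 sits far outside the permutation null
(0.95 ± 0.18), p ≈ 0.001 at 1000 permutations.

The same pipeline is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","pertnet.R",package="pertnet"))') \
    simulate --out demo --n 500 --module-size 20 --seed 42
```

with subcommands `simulate`, `de`, `fit-bum`, `score`, `search`, `hubs`,
`perturb`, `enrich`, `correlate`, `run-all` (exit codes: 0 ok, 2 config,
3 data, 4 numerical).

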