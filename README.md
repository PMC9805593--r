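# meomi

Undirected gene regulatory network (GRN) inference from steady-state
expression data, for researchers benchmarking information-theoretic
network methods on DREAM-style matrices or their own compendia.

Mutual information finds nonlinear gene–gene association but cannot
separate direct regulation from association routed through other genes.
This package implements a three-stage correction pipeline:

1. **Mixed-entropy mutual information.** Each gene is discretized into
   equal-width bins and entropies are estimated by a James–Stein /
   Bayes hybrid: the shrinkage intensity
   λ̂ = (1 − Σθ̂²) / ((n−1)·Σ(θ̂ₖ − 1/K)²) is mapped to an equivalent
   Dirichlet pseudocount a = nλ̂/(K(1−λ̂)), and the entropy is the exact
   posterior expectation H = ψ(N+1) − Σ (ñₖ/N)·ψ(ñₖ+1) with
   ñₖ = nₖ + a, N = n + Ka. MI is I(X;Y) = H(X) + H(Y) − H(X,Y).
2. **CLR standardization.** Each gene's MI profile is z-scored against
   its own background; pair scores Z_ij = √(Z_i² + Z_j²) thresholded at
   λ₀ give the initial network.
3. **Multi-order CMI2 pruning.** For orders 1..`order_set`, every edge is
   tested against the maximal conditional mutual inclusive information
   CMI2(X;Y|S) = I(X;Y|S) + ½·E_z KL(θ(Y|z)‖q_{X→Y}(Y|z))
   + ½·E_z KL(θ(X|z)‖q_{Y→X}(X|z)) over conditioning subsets S of its
   common neighbours (Gaussian closed forms; the interference
   conditional q integrates θ(y|x,z) against the marginal of x). The
   edge is deleted when that maximum falls below a dynamically scaled
   threshold α·C(Order_Max, order).

A linear-Gaussian structural-equation simulator (with exact analytic
covariances), a gold-standard evaluator (TPR/FPR/PPV/ACC/F1/MCC,
AUPR/AUROC) and a command-line interface round out the toolkit.

## Worked example

```r
library(meomi)
net  <- generate_topology(50, "scale_free", param = 1, seed = 101)
expr <- simulate_expression(net, n_samples = 100, seed = 102)
fit  <- meomi(expr, bins = 5, order_set = 2, lambda0 = 1e-6, alpha = 0.01)
fit
#> Mixed-entropy CLR/CMI2 network
#>   50 genes, 100 samples; bins = 5, order_set = 2, lambda0 = 1e-06, alpha = 0.01
#>   edges: 228 surviving of 592 initial (364 pruned)
head(fit$edges, 5)
#>   gene_a gene_b    score rank
#> 1    G11    G37 8.032213    1
#> 2     G8    G15 7.405267    2
#> 3    G41    G50 7.404113    3
#> 4     G4    G34 7.365410    4
#> 5    G23    G27 7.116134    5
evaluate_network(fit, network_gold(net))
#> Network evaluation
#>   TP 37  FP 191  TN 985  FN 12
#>   TPR 0.7551  FPR 0.1624  PPV 0.1623  ACC 0.8343
#>   F1 0.2671  MCC 0.2984  AUPR 0.6587  AUROC 0.8533
```

The CLR threshold λ₀ = 1e-6 admits 592 candidate edges; two pruning
passes delete 364 of them, trading a little recall (TPR 0.76) for a
doubled precision relative to the unpruned network. The score column is
the CLR likelihood score of each surviving edge, which also drives the
AUPR/AUROC ranking. `summary(fit)` breaks deletions down by
conditioning order, and `fit$trace` records, for every evaluated edge,
its common-neighbour count, subset count, threshold, maximal CMI2 and
decision.

The same pipeline from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "meomi.R", package = "meomi"))')
Rscript $cli simulate --model scale_free --genes 50 --samples 100 --seed 7 --out run
Rscript $cli infer --expression run_expression.tsv --lambda0 1e-6 --alpha 0.01 --out run
Rscript $cli eval --edges run_edges.txt --gold run_gold.tsv --out run
```

Input is a tab-separated samples × genes matrix with a header of gene
identifiers (`--transpose` for genes × samples with a gene-id column);
gold standards are 3-column edge lists (`gene TAB gene TAB 0/1`).

## Documentation

The methods vignette (`vignettes/network-inference-methods.Rmd`) derives
the estimators, explains the interference conditional behind CMI2, the
dynamic threshold schedule, the numerical safeguards (ridge repair,
clipping) and what the linear-Gaussian simulator does and does not
emulate.
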