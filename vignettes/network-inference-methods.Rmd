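---
title: "Mixed-entropy network inference: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-entropy network inference: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meomi)
```

## The problem

Given a steady-state expression matrix (samples × genes), we want the
undirected skeleton of the gene regulatory network. Pairwise mutual
information (MI) detects nonlinear association without a parametric model,
but it cannot tell direct regulation from association mediated by other
genes, so raw MI networks carry many false positives. This package layers
three corrections on top of the MI matrix:

1. a **mixed entropy estimator** that keeps MI estimates stable at the
   small sample sizes typical of expression compendia;
2. **CLR (context likelihood of relatedness)** standardization, which
   removes per-gene background (promiscuous hubs, batch-driven inflation);
3. **multi-order pruning by conditional mutual inclusive information
   (CMI2)**, which removes edges explainable by common neighbours while
   avoiding plain conditional MI's tendency to underestimate direct links
   that share strong conditioners.

## The mixed entropy estimator

Each gene is discretized into `bins` equal-width cells (top cell
right-closed; a constant gene puts all mass in one cell and has zero
entropy). For cell counts $n_k$, $n = \sum_k n_k$, support size $K$:

* The ML estimate $\hat\theta_k = n_k/n$ is unbiased but high-variance,
  and empty cells bias the plug-in entropy downwards.
* James–Stein shrinkage pulls $\hat\theta$ towards the uniform target
  $t_k = 1/K$ with the risk-minimizing intensity
  $$\hat\lambda = \frac{1 - \sum_k \hat\theta_k^2}
                       {(n-1)\sum_k(\hat\theta_k - t_k)^2},$$
  clipped to $[0,1]$.
* The shrinkage intensity is converted to an equivalent symmetric
  Dirichlet pseudocount through the identity
  $\theta^{Dir}_k = (n_k + a)/(n + Ka) \equiv \theta^{JS}_k$, which gives
  $a = n\hat\lambda / (K(1-\hat\lambda))$.
* The entropy is then the exact posterior expectation under
  Dirichlet$(n_k + a)$:
  $$\hat H = \psi(N + 1) - \sum_k \frac{\tilde n_k}{N}\,\psi(\tilde n_k + 1),
  \qquad \tilde n_k = n_k + a,\; N = n + Ka,$$
  with $\psi$ the digamma function; this is evaluated in nats.

The posterior-expected-entropy form is used because it is the estimator
the $\beta$-moment derivation ($\partial E[\theta_j^\beta]/\partial\beta$
at $\beta = 1$) actually yields, and it is validated in the test suite
against Monte-Carlo sampling from the Dirichlet posterior rather than
against any printed formula. Likewise the $\lambda \to a$ bridge is the
unique form under which the Dirichlet posterior mean reproduces the
shrunken probabilities termwise; the suite checks that identity to 1e-12
on a thousand random count vectors.

Two boundary conventions matter. When $\hat\theta = t$ exactly the
shrinkage denominator vanishes; we return $\lambda = 1$ (full shrink is a
no-op there), whose $a = \infty$ limit is resolved as the uniform entropy
$\ln K$. And $K$ always means the *declared* support — `bins` for
marginals, `bins`² for joint tables — so the uniform target does not
drift with the data. A consequence worth knowing: the identity
$I(X,X) = H(X)$ holds exactly only in the `support = "occupied"`
sensitivity mode, because under declared support the joint table shrinks
on $K^2$ cells while the marginal shrinks on $K$. The default keeps the
fixed-support rationale; the tests pin both behaviours.

MI is assembled as $I = H(X) + H(Y) - H(X,Y)$, each term by the mixed
estimator on its own support (the joint re-derives its own $\lambda$).
Because the three estimators shrink independently the difference can be
marginally negative; it is clipped at 0.

## CLR scores

For gene $i$, the MI values to all other genes form its empirical
background with mean $\mu_i$ and population standard deviation
$\sigma_i$. The pair score is
$$Z_{ij} = \sqrt{\max\!\left(0,\tfrac{I_{ij}-\mu_i}{\sigma_i}\right)^2 +
                 \max\!\left(0,\tfrac{I_{ij}-\mu_j}{\sigma_j}\right)^2}.$$
$\sigma_i = 0$ (flat background) contributes a zero component. The
square-root combination is the CLR convention; `combine = "sumsq"`
preserves the plain sum of squares, which has the same ranking but a
different scale — relevant only because the initial threshold
$\lambda_0$ is applied to $Z$ values, not ranks. Population rather than
sample SD is the default (the background is treated as an empirical
distribution, not a sample from a larger one); both are exposed.

## CMI2 and the interference conditional

For jointly Gaussian $(X, Y, Z)$ the conditional MI is the determinant
closed form
$$I(X;Y\mid Z) = \tfrac12 \ln
  \frac{|\Sigma_{XZ}|\,|\Sigma_{YZ}|}{|\Sigma_Z|\,|\Sigma_{XYZ}|}.$$
CMI2 augments it with two interference (interventional) terms:
$$\mathrm{CMI2}(X;Y\mid Z) = I(X;Y\mid Z)
 + \tfrac12\,E_z\,D_{KL}\!\big(\theta(Y\mid z)\,\|\,q_{X\to Y}(Y\mid z)\big)
 + \tfrac12\,E_z\,D_{KL}\!\big(\theta(X\mid z)\,\|\,q_{Y\to X}(X\mid z)\big),$$
where the interference conditional integrates the observational
conditional against the *marginal* of the intervened variable:
$q_{X\to Y}(y\mid z) = \int \theta(y\mid x, z)\,\theta(x)\,dx$. Using the
marginal (rather than $\theta(x\mid z)$, under which the construction
collapses to the ordinary conditional and CMI2 degenerates to plain CMI)
is what gives the two directed divergences their "causal intensity"
asymmetry; the equality
$D_{KL}(\theta \| \theta_{X\to Y}) = I(X;Y|Z) + D_{KL}(\text{conditionals})$
holds exactly under this reading, and the total is their symmetric
average. `cmi2_mode = "plain"` provides the degenerate reading for
comparison.

With Gaussian working distributions every term is closed-form: the two
conditionals of $Y$ given $z$ are Gaussians whose means are linear in
$z$, so the $z$-expectation of their KL divergence reduces to a
log-variance ratio plus a quadratic form in the regression-coefficient
difference. The test suite verifies the closed form against direct grid
quadrature of the defining KL integrals (trapezoid grids over ±6 SD,
inner 1-D quadrature for the interference conditional) to 1e-3 on random
2–4 dimensional systems — the definition, not a formula, is the oracle.

Numerical choices: covariances are symmetrized, and any matrix failing a
Cholesky or reciprocal-condition test (rcond < 1e-10) is ridge-repaired
by adding $10^{-8}\,\mathrm{tr}(\Sigma)/d$ to the diagonal, with a
`meomi_ridge_repair` warning so runs can log repairs; tiny negative
log-determinant ratios are clipped at 0; everything is in nats.

## The pruning loop

The initial network keeps pairs with $Z_{ij} > \lambda_0$ (strict). For
each conditioning order $1, \dots,$ `order_set`, edges are visited in
ascending lexicographic order. For edge $(i, j)$ with `Order_Max` common
neighbours, the maximum CMI2 over all $m = \binom{Order\_Max}{order}$
conditioning subsets is compared with a dynamically scaled threshold;
the edge dies when the maximum falls below it. Deletions take effect
immediately (asynchronous update, the literal reading of sequential
per-edge processing); a `sync` mode decides every edge against the
pass-start adjacency because visit-order dependence is a known artefact
of path-consistency algorithms. Common neighbourhoods are re-derived
fresh at every pass, so an edge whose neighbourhood shrinks is
re-evaluated at later orders.

The threshold schedule is the genuinely open design point: the
combination count $m$ should raise the bar (more candidate explanations
of an edge mean more chances for a spurious maximum), but no functional
form is fixed by the method's description. The default is the most
literal monotone reading, $\lambda_{order} = \alpha\,m$, with `constant`
and `log_m` alternatives in the configuration. $\alpha$ defaults to
$\lambda_0$, keeping a single tuning parameter.

The final score of a surviving edge is its $Z_{ij}$; pruned pairs score
0. Ranking metrics need a full ordering, and the CLR score is the
quantity the initial network was built from; the trace additionally
records the last maximal CMI2 for every evaluated edge for users who
prefer it.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bins` | 5 | discretization cells per gene; 5 is robust for 50–1000 samples |
| `order_set` | 2 | cap on conditioning order; 2–3 is the practical range, cost grows as $\binom{Order\_Max}{order}$ |
| `lambda0` | 1e-3 | initial CLR threshold; useful range 1e-6–1e-2, smaller for smaller gene sets (1e-6 for ≤ a few hundred genes) |
| `alpha` | `lambda0` | base CMI2 threshold before dynamic scaling |
| `threshold_mode` | `linear_m` | how the threshold grows with the subset count |
| `update` | `async` | in-pass deletion semantics |

## The synthetic generator

`generate_topology()` + `simulate_expression()` produce linear-Gaussian
structural-equation data on acyclic topologies (canonical 3-gene motifs,
Erdős–Rényi, preferential-attachment scale-free; edges oriented low →
high index; coefficients uniform on ±[0.5, 1.5]; unit noise SD). The
coefficient floor of 0.5 exists so that recovery tests measure the
method, not near-null edges. `analytic_covariance()` returns the exact
population covariance $(I-W)^{-\top} D (I-W)^{-1}$, which makes the
Gaussian CMI/CMI2 oracles *exact* for this family — the reason a
linear-Gaussian generator was chosen over ODE-kinetics simulators.

What this generator does *not* emulate: nonlinear regulation,
saturation, measurement noise models, perturbation designs, and
non-Gaussian marginals. Passing the recovery tests therefore shows the
pipeline is correct under its own working assumptions, not that it will
attain the same accuracy on real compendia.

A deliberate caveat the fixtures document rather than hide: for a
collider (1 → 2 ← 3) the tails are marginally independent but become
dependent when conditioned on the common child, so common-neighbour
conditioning can in principle retain the 1–3 pair; the synthetic tests
record this behaviour instead of asserting a "correct" outcome.

## Problem sizes used by the tests

The suite favours exact, small oracles: thousand-case identity checks,
20-case Monte-Carlo and quadrature comparisons, 5–6-gene brute-force
pruning equivalence, 20-seed motif recovery at 1000 samples, and a
10-seed 50-gene scale-free end-to-end recovery at 100 samples with
`lambda0 = alpha = 1e-6` — the configuration recommended for gene sets
of that size. The motif fixtures use `alpha = 0.02` at $n = 1000$: an
order of magnitude above the conditional-independence sampling floor
(roughly $d/2n \approx 0.002$ nats) and below the weakest direct-edge
signal the ±[0.5, 1.5] coefficient range can produce (≈ 0.03 nats).

## Known limitations

* The network is undirected; the asymmetric directed intensities are
  computed internally but not used for orientation.
* Above a few hundred genes the order-2 pass dominates runtime; the
  per-edge subset count is unbounded by default (a warning fires past
  10,000 combinations per edge).
* Gold standards are compared by exact identifier match;
  no synonym resolution is attempted.
* Equal-width binning is the only discretization; quantile or adaptive
  schemes are out of scope.
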