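---
title: "Gene-pair biomarkers by sum-to-zero constrained L1 regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair biomarkers by sum-to-zero constrained L1 regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairzero)
```

## The problem

Ratios of gene expression levels make unusually robust biomarkers. A ratio
$x_j / x_k$ is unchanged when a sample's measurements are rescaled by
library size or sequencing depth, and it is exactly what a qPCR delta-Ct
measurement of two genes reports, with each gene acting as the other's
internal control. The catch is combinatorial: with $p$ candidate genes
there are $q = p(p-1)/2$ candidate ratios, so a regression of a continuous
outcome $Y$ on all log-ratios,

$$Y = \sum_{j<k} \alpha_{jk} \log(x_j/x_k) + \varepsilon,$$

carries $O(p^2)$ parameters and is severely non-identifiable: adding any
constant along a cycle of indices leaves the fitted function untouched.

`pairzero` works in the equivalent gene-level parameterization. Writing
$\beta_j = \sum_{k \ne j} \alpha_{jk}$ (with the antisymmetric convention
$\alpha_{kj} = -\alpha_{jk}$), the same regression function is

$$Y = \sum_{j=1}^p \beta_j \log x_j + \varepsilon,
\qquad \sum_{j=1}^p \beta_j = 0,$$

with only $p$ parameters and one linear constraint. The constraint is what
preserves the biomarker property: a per-sample rescaling of raw expression
adds a constant to every $\log x_j$, and a sum-to-zero $\beta$ annihilates
constants.

## From genes back to pairs: peeling

Fitting the constrained model gives $\hat\beta$; reporting biomarkers
requires pairs. Among the infinitely many $\alpha$ consistent with a given
$\beta$, the package selects a minimum-L1 representative with a peeling
recursion (`peel()`): repeatedly take the most positive and most negative
remaining coefficients (lowest index on ties), assign the smaller magnitude
as a pair weight, subtract it from both, and stop when everything is zero.
Each step zeroes at least one coordinate, so at most $p$ steps and $p-1$
pairs result, and the attained norm is exactly
$\|\hat\alpha\|_1 = \|\hat\beta\|_1/2$, which is the minimum possible
(every index-sharing product $\alpha_{ij}\alpha_{jk}$ comes out
non-positive, and this condition characterizes minimizers —
`is_min_l1_pairs()`). The minimizer is unique precisely when the pairs form
a star around one hub gene (`is_unique_min_l1()`); otherwise different tie
orders may return different pair sets of identical norm. Support sizes obey
$B \le 2A$, plus $2\sqrt{A} \le B$ for minimum-L1 representations and
$B = A + 1$ for stars, where $A$ and $B$ count nonzero pair and gene
coefficients (`pair_support_summary()`).

A worked step: if the working vector is $(1.5, -0.5)$, the step pairs genes
1 and 2 with weight $\min(1.5, 0.5) = 0.5$ and leaves $(1, 0)$:

```{r peel-step}
peel_step(c(1.5, -0.5))
```

## The solver

The estimator is the constrained lasso
$$\min_\beta \tfrac12 \|y - X\beta\|_2^2 + \lambda \|\beta\|_1
\quad \text{s.t.} \quad \textstyle\sum_j \beta_j = 0,$$
solved by ADMM on the split form ($x$ the primal coefficients, $z$ the
thresholded copy): a quadratic x-update from a cached Cholesky
factorization, a soft-threshold z-update, and a scaled dual update, with
joint absolute/relative stopping on the primal and dual residual norms.
Two factorization branches are used depending on shape — the $m \times m$
normal-equations form when samples outnumber coefficients, otherwise the
matrix inversion lemma on the (rows × rows) Gram matrix — and they agree to
solver precision. Coordinate descent is not an option here: the constraint
couples all coordinates, which is exactly what breaks the separability that
coordinate methods rely on, while ADMM handles the coupling in a single
linear solve per iteration and converges for any penalty parameter
$\rho > 0$.

Numerical choices that matter:

* **Penalty parameter $\rho$.** The optimum does not depend on it, but
  iteration counts do. The default scales it with the problem,
  $\rho = \max(\lambda,\ \overline{\mathrm{diag}}(X^TX))$, which keeps the
  threshold $\lambda/\rho$ and the quadratic curvature on comparable
  scales; on wide penalty grids this is up to ~50× faster than a fixed
  $\rho = 1$, which remains available through `admm_control(rho = )`.
  When $\rho$ changes along a path the factorization is redone and the
  scaled duals rescaled, so warm starts carry over exactly.
* **Tolerances.** Defaults are `eps_abs = 1e-6`, `eps_rel = 1e-4`
  (residual-norm stopping); the convergence benchmark tightens both to
  `1e-10`. Non-convergence within `max_iter` (default $10^5$) is always
  reported, never silently accepted.
* **Solution of record.** At convergence the primal iterate violates the
  constraint only at tolerance level, but even that residual leaks into
  objective comparisons; the reported `coefficients` spread the residual
  over the constrained coordinates so $\sum_j \hat\beta_j = 0$ holds
  exactly and peeling's precondition is met. The thresholded `z` iterate
  (exactly sparse) defines supports and entry order.
* **Paths.** `solve_path()` runs a decreasing geometric grid from
  $\lambda_{\max} = \|X^Ty\|_\infty$ (all-zero solution) with warm starts;
  the benchmark protocol uses 100 points from $10^4$ to $10^{-2}$.
* **Intercept.** Off by default (the simulation models are mean-zero); the
  expression pipeline turns it on as an unpenalized, unconstrained first
  column. Predictors are not standardized by default.

An independent check accompanies the solver: `reference_solution()` is a
finite active-set method on the KKT system (with a tiny escalating ridge as
an anti-cycling fallback on rank-deficient supports), sharing no machinery
with the ADMM iteration. Tests require the ADMM objective to match it to
$10^{-6}$ on random problems and to $10^{-8}$ under the convergence
benchmark protocol.

## What the generators emulate — and what they do not

`generate_dataset()` draws log expressions i.i.d. from $N(0, V)$ with the
autoregressive correlation $V_{ij} = 0.5^{|i-j|}$, and responses from the
gene-level model with i.i.d. Gaussian noise. Three built-in sparse pair
structures (on the first four genes) cover the qualitatively distinct
cases: a non-minimal representation, a minimal-but-not-unique one, and a
unique star. `generate_dense_beta_dataset()` draws a dense $N(0,1)$
coefficient vector centered to sum to zero — the convergence-benchmark
condition. `apply_sample_shifts()` and `apply_random_scaling()` emulate
normalization artifacts: per-sample shifts on the log scale and positive
per-gene/per-sample factors on the raw scale (log-normal(0,1); any positive
law probes the same invariance).

These generators produce Gaussian, stationary, moderately correlated log
expression. Real RNA-Seq has heavier tails, zeros, gene-specific dispersion
and block-structured correlation; passing the simulated benchmarks
therefore demonstrates correctness of the estimator and its invariances,
not performance guarantees on any particular dataset. Study conditions are
fixed by the protocol: training sizes $(p, n, \sigma) \in
\{(20, 50, 0.5), (100, 25, 0.2)\}$ with 20 replicates, 1000-point tuning
and validation sets, $N(0,1)$ sample shifts applied to validation
predictors only (the shifts model expression normalization, so the response
is untouched).

In the difficult $p \gg n$ regime the 20-replicate summaries are
heavy-tailed: occasionally (a few percent of draws) an $n = 25$ training
sample admits a sparse fit with near-zero training error that generalizes
poorly, inflating a cell mean far beyond its typical value. This is a
property of the estimator under those conditions, not of the optimizer —
on such draws the fitted solutions still match the reference optimum at
every penalty on the grid.

## The screening pipeline

For expression applications, `filter_low_expression()` drops genes with
mean normalized expression strictly below 10; `pearson_screen()` correlates
each gene's log expression with the log response, converts $r$ to a
two-sided p-value by the $t$ transform with $n-2$ degrees of freedom, and
retains genes with Benjamini–Hochberg adjusted values at or below 0.01.
Zeros are an error unless a pseudocount is supplied (default 1 when
enabled); constant genes are untestable and excluded with a recorded
reason. Two-sided tests are used — the screen is symmetric in the direction
of association.

`fit_pipeline()` then log-transforms, centers each sample's log expression
(the centered log-ratio transform — model-equivalent under the sum-to-zero
constraint), fits the constrained path with an intercept, peels every
solution, and reports genes in entry order (first grid point whose
coefficient magnitude exceeds `1e-10`). The centering is what makes the
*entire* pipeline — including the data-driven $\lambda_{\max}$ and hence
the grid itself — invariant to per-sample rescaling; without it, the grid
endpoints would shift with the normalization even though each fixed-λ
solution would not. Per-gene rescaling is absorbed by the intercept, and
the Pearson screen ignores it too (a per-gene constant on the log scale
does not move a correlation). Per-sample rescaling, by contrast, does
perturb the screen's correlations; only the constrained fit downstream is
immune to it.

```{r pipeline, eval = TRUE}
st <- simulation_setting(3, p = 12, n = 60, sigma = 0.5)
d <- generate_dataset(st, 60, seed = 42)
expr <- t(exp(d$log_expr))
rownames(expr) <- paste0("g", 1:12)
fit <- fit_pipeline(expr, exp(d$response), nlambda = 40)
head(fit$entry, 4)
as.data.frame(fit$pairs[[40]])[1:3, ]
```

## Benchmarks and problem sizes

`benchmark_convergence()` reproduces the solver-accuracy protocol: dense
centered coefficients, $\lambda = 1$, solver precision $10^{-10}$, success
iff the constraint holds to $10^{-8}$ and the solution and objective are
within $10^{-8}$ of the reference optimum; sizes up to
$(p, n) = (200, 1000)$ over 20 replicates. `benchmark_accuracy()`
reproduces the estimation protocol above against two baselines fitted by
the same solver without the constraint: `lasso1` on the $q$ pair columns
(scored against the true pair coefficients) and `lasso2` on the $p$ log
columns (scored against the true gene coefficients). Baseline predictions
on large tuning/validation sets are computed through the collapsed
gene-level coefficients, which is the same linear map without materializing
thousand-row pair designs. Relative error is
$\|\tilde\gamma - \gamma^0\|_2 / \|\gamma^0\|_2$ on each method's own
coefficient scale; the false identification rate keeps only the
$|\Gamma^0|$ largest-magnitude estimates (ties to the lowest index) and
counts the missed fraction of the true support. $R^2$ is
$1 - \mathrm{MSE}/\mathrm{var}(y)$ with the population variance, so
predicting the mean scores exactly zero. Wall-clock times are recorded for
information only.

The unit suite exercises the same machinery at reduced sizes (oracle
cross-checks at $p \le 20$, LP cross-checks of peeling at $p \le 6$,
property loops of 200–1000 draws); the full protocol sizes run in the
acceptance suite.

## Known limitations

* The minimum-L1 pair representation is a modeling choice; minimum-L0
  representations are combinatorially hard and not attempted.
* The screen's p-values assume approximate normality of log expression;
  for heavy-tailed data a rank-based screen would be more defensible.
* No generalized-linear-model variant (binary outcomes) is provided.
* Inexact/parallel ADMM variants and non-convex penalties are out of
  scope; the solver is exact ADMM with dense factorizations, suitable for
  the screened problem sizes (hundreds to a few thousand genes), not for
  genome-wide fits without pre-screening.
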