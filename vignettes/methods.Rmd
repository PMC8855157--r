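---
title: "Deconvolving bulk RNA-seq with an entropic optimal transport loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving bulk RNA-seq with an entropic optimal transport loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otdeconv)
```

## The model

A bulk RNA-seq sample measures the average transcriptome of a mixed cell
population. Given an annotated single-cell reference, the composition of the
mixture can be estimated: normalise the bulk expression vector to a
probability histogram $y \in \Sigma_n$ over $n$ genes, build a signature
matrix $C \in \mathbb{R}^{n \times k}$ whose columns are the per-cell-type
mean expression profiles (each itself a histogram), and find mixing
proportions $p \in \Sigma_k$ such that $Cp \approx y$.

Where square-loss methods (NNLS and its weighted relatives) compare $y$ and
$Cp$ gene by gene, this package measures their discrepancy with a
Wasserstein (optimal transport) distance

$$W(y, q)_M = \min_{T \in U(y, q)} \langle M, T \rangle,$$

where $U(y,q)$ is the set of couplings with marginals $y$ and $q$, and the
ground cost $M_{ij}$ prices moving expression mass from gene $i$ to gene
$j$. Because $M$ is built from gene co-expression in the reference cells,
residual mass landing on a tightly co-expressed neighbour of the right gene
is cheap, while mass on an unrelated gene is expensive: the loss exploits
gene-space structure that element-wise losses cannot see.

Exact transport is a linear program, intractable at thousands of genes, so
the loss is the entropic-regularised distance

$$W_\gamma(y, q)_M = \min_{T \in U(y, q)} \langle M, T \rangle - \gamma h(T),
\qquad h(T) = -\sum_{ij} T_{ij} \log T_{ij},$$

solved by Sinkhorn scaling. The deconvolution objective for one sample is

$$\min_{p \in \Sigma_k} \; W_\gamma(y, Cp)_M + \rho \, E(p), \qquad
E(p) = \sum_i p_i \log p_i,$$

with defaults $\gamma = \rho = 0.001$ on a ground cost rescaled to maximum
entry 1.

### The sign of the entropy term

With $E(p) = \langle p, \log p \rangle$ (negative entropy), adding
$+\rho E(p)$ acts as a smooth barrier: its gradient $\log p + 1$ diverges as
any $p_i \to 0$, which keeps iterates strictly inside the simplex — the role
this term plays in the Wasserstein dictionary-learning literature the
formulation follows. Subtracting the term instead rewards sparse
proportions. The barrier form is the default (`barrier_sign = "barrier"`);
the subtracting variant is available as `"sparsity"`. At
$\rho = 0.001$ the two differ negligibly away from the boundary, but the
barrier form is the one under which the optimisation theory holds, so it is
the default.

## Ground costs

Four metrics over genes are supported, all computed from the reference
cells' expression matrix (rows = genes):

* **euclidean** — $\lVert x_i - x_j \rVert_2$ across cells;
* **cosine** — $1 - \cos(x_i, x_j)$;
* **correlation** — $1 - \mathrm{cor}(x_i, x_j)$ (Pearson; note this ranges
  to 2 for anti-correlated genes);
* **dissTOM** — one minus the topological overlap of the soft-thresholded
  co-expression network: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, and
  $$d_{ij} = 1 - \frac{\sum_{u \neq i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$
  with connectivity $k_i = \sum_{u \neq i} a_{iu}$.

dissTOM is the recommended default: topological overlap looks at shared
network neighbourhoods rather than single pairwise correlations and is the
more robust measure of gene interconnection. The soft-threshold power
defaults to $\beta = 6$, the customary unsigned-network choice; it is
configurable, and no automatic scale-free-fit selection of $\beta$ is
attempted. Two connectivity conventions for the overlap exist in the
literature; the one above (connectivity excludes only the gene itself) is
pinned by a regression test on a 3-gene fully connected fixture, for which
$d_{ij} = 0$. The variant that also removes the partner gene from the
connectivity is available (`convention = "strict"`) but can leave $[0,1]$
and is not used by default.

All costs are rescaled to maximum entry 1 by default so that a given
$\gamma$ means the same amount of entropic smoothing for every metric;
raw-scale mode is retained (`rescale = FALSE`).

## Numerical choices

**Sinkhorn.** The scaling iteration runs in C++ in the ordinary domain,
absorbing the scaling vectors into the dual potentials whenever they leave
$[10^{-100}, 10^{100}]$ (with a full log-domain `logsumexp` step as the
recovery path when the kernel underflows entirely). Cold solves run a short
geometric $\varepsilon$-scaling schedule from $0.05 \cdot \max M$ down to
the target $\gamma$, because at $\gamma = 10^{-3}$ the plain iteration's
linear rate is far too slow to move the potentials any macroscopic
distance; warm-started solves first try the target $\gamma$ directly and
fall back to the schedule only when that short pass misses. Convergence is
declared at a maximum marginal violation below `tol` ($10^{-7}$ by
default); hitting `max_iter` is flagged with a warning, never silent. On
adversarial small instances the linear rate can still require $10^5$-plus
iterations to reach $10^{-7}$ — iterations are cheap there, so oracle
comparisons simply use a large budget.

**Gradient and objective inside the outer loop.** The gradient of
$W_\gamma(y, \cdot)$ is the centred dual potential of the second marginal.
The outer solver evaluates the objective through the *dual* value
$f^\top y + g^\top q - \gamma(\sum T - 1)$ rather than the primal plan
value: the dual estimate is second-order accurate in the remaining
potential error and exactly consistent with the gradient it returns, so the
line search cannot stall on truncation noise of a capped inner solve. For
this reason the inner Sinkhorn budget inside the deconvolution is modest
(300 iterations and marginal tolerance $10^{-5}$ at $n = 200$ genes), both
scaled as $\propto 1/n^2$ so that every inner solve costs roughly constant
work — small problems are solved essentially exactly. The user-facing
`sinkhorn_wasserstein()` reports the primal regularised value (with the
transport part $\langle M, T\rangle$ also exposed) and keeps the
5000-iteration, $10^{-7}$ defaults.

**Outer optimisation.** Proportions are updated by exponentiated gradient
(mirror descent on the simplex): $p \leftarrow p \odot e^{-\eta g}$,
renormalised, where $g = C^\top \nabla_q W_\gamma(y, Cp) + \rho(\log p + 1)$.
The step $\eta$ is backtracked (halved up to 30 times) whenever the
objective would increase, and grown by 1.5× after accepted steps, so the
accepted objective trace is non-increasing. Iteration starts at the uniform
vector (a seeded jittered start is available for multi-start use) and stops
when the relative objective change drops below $10^{-6}$ or after 2000
outer iterations. $Cp$ is renormalised, and both histograms are
$\varepsilon$-smoothed ($10^{-9}$, renormalised), before every transport
call; the smoothing keeps dual potentials finite at zero counts.

**Warm starts.** Inner solves reuse the previous iteration's *raw* dual
potentials. Centred potentials must not be used for warm starting: centring
each potential separately destroys the dual gauge $f_i + g_j \approx
M_{ij} + \gamma \log T_{ij}$ and overflows the kernel, which the core also
guards against by renormalising the gauge on entry.

**Degenerate inputs.** Zero histogram entries are supported natively (zero
plan rows/columns, $-\infty$ potentials excluded from centring). Duplicate
signature columns make the split between them unidentifiable; the total
mass of the duplicated pair is still recovered, and the barrier term
governs the (near-even) split. Zero-variance genes get correlation treated
as 0 — cost 1 against everything — with a warning. Ties in the
rarest-cell-type removal order break lexicographically; degenerate ties in
the ensemble weight program resolve toward the most uniform optimum.

## Quality control and data handling

The reference QC applies, in order: (1) drop all-zero and zero-variance
genes; (2) drop cells whose library size deviates from the mean by more
than 3 median absolute deviations — both the deviation and the MAD itself
are centred at the *mean* library size, which is what makes the rule behave
sensibly when most libraries are identical (a median-centred MAD would be 0
and remove every cell); (3) keep genes with a count above 1 in at least 5%
of remaining cells (closed bound); (4) keep cell types with at least 50
remaining cells. Re-running QC on its own output is a fixed point on
well-behaved data. The library-size filter pools cells by default; a
per-individual switch exists because multi-donor data can have
donor-specific depth.

Duplicate gene ids in input files are collapsed by summation (counts are
conserved). Gene alignment between bulk and reference defaults to all
shared genes; a top-variable-N option (variance of `log1p` reference
expression, N = 500 by default) is provided for tractability on large gene
sets.

Signatures average raw counts within cell type and then renormalise; a
variant that normalises each cell first is exposed
(`cell_normalize = TRUE`) since either reading of "averaging the cell
expressions" is defensible, but raw-count averaging is the default because
it weighs cells by their actual molecule counts.

## The ensemble across individuals

With references from $R$ individuals, each individual's reference is used
for an independent deconvolution (with a ground cost computed from that
individual's own cells), giving $\hat P^{(r)}$ and fitted bulk
$\hat Y^{(r)} = C^{(r)} \hat P^{(r)}$. Because the true proportions are
unknown, the combination weights are fitted in expression space:

$$\min_w \; \lVert Y - \textstyle\sum_r w_r \hat Y^{(r)} \rVert^2
\quad \text{s.t.} \quad \textstyle\sum_r w_r = 1, \; w_r \ge 0,$$

pooling all bulk samples into one quadratic program. With $R$ small the
program is solved exactly by enumerating support subsets and solving each
equality-constrained KKT system. The weights read as the similarity of
each reference individual to the individual behind the bulk samples;
combined proportions are the weighted sum on the union cell-type set
(absent types contribute zero) with columns renormalised — the
renormalisation is this package's choice to keep the simplex invariant,
as type-set mismatches between individuals have no canonical treatment.

Missing cell types in a reference can alternatively be imputed before
solving: the missing column is the mean of the other individuals' columns
for that type.

## The synthetic generator and the pseudo-bulk protocol

`generate_synthetic_truth()` emulates a small multi-donor single-cell
experiment: log-normal per-type expression programs over genes (sdlog 1.5,
giving the heavy-tailed expression ranges typical of transcript counts), a
log-normal per-individual multiplicative gene effect (sdlog 0.3 by default
— a moderate batch/individual shift), per-cell multinomial counts at depth
2000 (droplet-scale), and Dirichlet(1) mixing proportions for optional
paired bulks. Defaults: 200 genes, 5 types, 3 individuals, 100 cells per
type per individual.

What it does *not* emulate: zero inflation or other dropout structure
beyond multinomial sampling, cell-type-specific batch effects (the
individual effect is shared across types), within-type expression
heterogeneity or continuous cell states, gene length and GC bias between
bulk and single-cell protocols, or doublets and ambient RNA. Passing the
recovery tests therefore shows correctness of the optimisation and the
protocol plumbing under a well-specified generative model, not performance
on tissue data with protocol-specific distortions.

The pseudo-bulk benchmark follows the standard protocol: per individual
and cell type, cells are split 50/50 into reference and testing halves
(reference takes the odd cell); each pseudo-bulk replicate samples 60% of
a testing pool uniformly without replacement (the floor of $0.6N$ cells,
replicate $r$ seeded as `seed` + $r$) and sums counts per gene. The
recorded truth is the *realised* composition of the sampled cells, not the
pool composition, because the realised draw is what the mixture actually
contains. Protocol defaults are 200 replicates; the workflow driver runs
20 in quick mode. Accuracy metrics are the pooled RMSE
$\sqrt{\tfrac{1}{km}\sum_{ij}(P_{ij}-\hat P_{ij})^2}$ and the Pearson
correlation of the flattened matrices (a per-sample-mean variant exists;
flattening is the default reading of correlating $P$ with $\hat P$).

## Problem sizes used by the test-suite and acceptance script

The shipped checks run, on one CPU, with: 100 random transport instances
at up to 10 bins against the LP oracle; 50 finite-difference gradient
instances at 4–8 bins; the recovery scenario at 200 genes, 5 types, 20
mixtures (noise-free and multinomial at depth $10^5$); a 3-individual
ensemble scenario with 20 pseudo-bulk replicates for the self-reference
check; the missing-type experiment at removal levels 1–3 over 10 mixtures;
and the $\gamma \in \{10^{-4}, 10^{-3}, 10^{-2}, 5\cdot10^{-2}\} \times
\rho \in \{10^{-4}, 10^{-3}, 10^{-2}\}$ robustness grid on the recovery
instance. These sizes keep the full suite in the minutes range while still
exercising every code path at gene-scale dimensionality.

## Known limitations

* Runtime grows as $n^2$ per Sinkhorn iteration; tens of thousands of
  genes are impractical without the top-variable gene selection.
* At $\gamma$ far below $10^{-3}$ the inner solves lean on the
  $\varepsilon$-scaling schedule and capped iteration budgets; marginal
  violations of order $10^{-5}$ can remain at gene-scale sizes and are
  reported in the diagnostics rather than eliminated.
* The ensemble weights are fitted on bulk expression, not on proportions;
  when all references fit the bulk equally well the weights are weakly
  identified (the exact QP then prefers the most uniform optimum).
* Joint estimation of signatures and proportions (NMF-style) is out of
  scope, as is any cell-type-specific expression output.
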