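---
title: "Heritable cell states from lineage trees: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritable cell states from lineage trees: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clonal cell populations are phenotypically heterogeneous, and part of that
heterogeneity is heritable: a cell's division timing and its propensity to
die resemble its mother's more than a random cell's. Time-lapse tracking
gives us binary genealogical trees — each node a cell, each edge a
mother-daughter link — annotated with per-cell phenotypes: whether the cell
divided or died at the end of each cell-cycle phase (G1, then S/G2; or a
single whole-lifetime record), and how long each phase lasted. `lineagehmm`
models such data with a hidden Markov model whose index set is the lineage
tree rather than a chain, so that a cell's unobserved phenotypic *state* is
inherited stochastically from its mother.

## Model

Each cell $n$ carries a hidden state $z_n \in \{1,\dots,K\}$. Root cells
draw their state from an initial distribution $\pi$; every daughter draws
hers from row $z_{mother}$ of a $K \times K$ row-stochastic transition
matrix $T$. Both daughters draw independently, and the two daughters of a
mother are exchangeable — there is no birth-order semantics anywhere.

Conditioned on its state, a cell emits independent observations per phase:

* a Bernoulli fate — probability $p$ of progressing (entering S phase, or
  dividing) rather than dying;
* a gamma-distributed duration in hours, with shape $k$ and scale
  $\theta$.

Independence across components means the emission log-likelihood of a cell
is a sum over whichever components were observed; a missing component
contributes nothing, and a cell that is a placeholder for the unseen
progeny of a dead cell ("unobserved") contributes exactly $\log 1 = 0$ in
every state.

When one experiment contains several treatment conditions (e.g. four drug
concentrations), $\pi$ and $T$ are shared across all conditions, the
Bernoulli and gamma-scale parameters are per-condition, and the gamma
*shape* of each state/phase is shared across conditions: inspection of
phase-length distributions motivates treatments rescaling a state's
durations without changing their form. Optionally the scales are
constrained non-decreasing along the dose order (a dose can slow a state
down, not speed it up); fates are never constrained.

## Censorship

Durations are only partially observed at the boundaries of an experiment:
a phase that is still running when the recording stops (or was already
running when it started) yields only a lower bound on the true duration.
Both cases are treated as right-censorship of the observed in-window span:
censored durations enter the likelihood through the gamma survival
function $S(t) = 1 - F(t)$ instead of the density, and the fate of a cell
clipped by the end of the window is missing (its end was never seen). This
is what removes the systematic downward bias that a naive fit of clipped
durations shows — the package's tests verify that the censored estimator
restores the true mean where the naive fit underestimates it.

## State inference

Inference on the tree uses the scaled upward-downward recursions for
hidden Markov trees (after Durand and colleagues' normalizing-factor
scheme). The *marginal state distribution* (MSD) propagates $\pi$ through
$T$ from the root down, giving each cell's prior state distribution. The
upward pass runs leaf-to-root, producing for each cell the conditional
state probability $\beta_n$ of its subtree and a per-cell normalizing
factor $NF(n)$; the tree log-likelihood telescopes into
$\sum_n \log NF(n)$. The downward pass turns these into smoothed
posteriors $\gamma_n(k) = P(z_n = k \mid \text{whole tree})$. A
max-product version of the upward pass (tree Viterbi, run in log space)
returns the jointly most probable state assignment; ties break toward the
lowest state index for determinism.

Numerical choices:

* emission log-likelihood rows are exponentiated after subtracting their
  row maximum, and the shift is absorbed into $\log NF$ — the recursions
  therefore operate on well-scaled linear-domain quantities and survive
  lineages of hundreds of cells without underflow;
* marginal state probabilities are clamped at $10^{-323}$ before division
  so states made unreachable by a sparse $T$ cannot poison the recursion;
* all three passes are verified against exhaustive $K^N$ enumeration on
  hundreds of random trees ($N \le 7$, $K \le 3$) at $10^{-8}$ relative
  tolerance.

## Fitting

Parameters are fit by Baum-Welch expectation-maximization:

* **E-step** — upward/downward recursions per lineage give $\gamma$ and the
  pairwise transition posteriors $\xi$ for every mother-daughter pair.
* **M-step** — $\pi$ is the mean posterior over root cells; $T$ is the
  row-normalized sum of $\xi$ over all pairs in all conditions; Bernoulli
  parameters are posterior-weighted sample means; gamma parameters come
  from the censorship-corrected weighted MLE with the shared-shape
  (optionally scale-ordered) structure described above.

The gamma M-step solves the weighted uncensored problem exactly (profile
score equation in the shape, solved by bisection) and otherwise maximizes
the censored likelihood over $(\log k, \log \theta)$ with L-BFGS-B inside
the bounds $k \in [0.01, 100]$, $\theta \in [0.01, 10^4]$. The ordered
multi-condition fit parameterizes scales as a base plus positive
increments so the ordering holds exactly; because a log-increment started
at zero has a vanishing gradient, initial increments are floored at 5% of
the mean scale and the result is polished with a short Nelder-Mead run.
The objective is convex in practice and the tests probe local optimality
with random feasible perturbations. Bernoulli estimates are clipped to
$[10^{-6}, 1-10^{-6}]$ before logs; estimation weights below $10^{-10}$
are dropped.

EM is initialized by drawing each cell's soft state assignment from a flat
Dirichlet (concentration 1) — the first M-step runs on those random
responsibilities. One additional deterministic restart assigns cells
softly to $K$ quantile bins of their first observed duration
(held-out/masked cells stay uniform): when states differ strongly in
duration, purely random responsibilities can leave every restart at the
symmetric fixed point where all states fit the pooled distribution, and
the ranked start escapes it; the highest-likelihood fit across all
restarts is kept either way. Defaults: convergence when the relative
log-likelihood improvement falls below $10^{-6}$, at most 200 iterations,
3 Dirichlet restarts plus the ranked one. The per-iteration
log-likelihood is non-decreasing (verified to $10^{-8}$ slack across
seeded runs). A state that loses all posterior mass keeps its previous
parameters, and an empty transition row resets to uniform with a warning,
so that sweeps over generous $K$ complete rather than abort.

## Choosing the number of states

**BIC.** $\mathrm{BIC} = \mathrm{dof}\,\ln(n) - 2\,\ell$, with $n$ the
number of observed (non-masked) cells and the degrees of freedom

$$\mathrm{dof}(K) = (K-1) + K(K-1) + K\,n_{phases}\,(1 + 2\,n_{conditions}).$$

Per state and phase this counts one shared shape plus one Bernoulli and
one scale per condition. The source descriptions of the parameter count
can be read two ways ("2 free parameters per condition" vs. 2 per phase
per condition); we fix the per-phase reading, which is the one consistent
with phase-specific emissions, and the model-selection tests confirm that
best-$K$ conclusions are insensitive to the alternative (the count only
shifts every candidate's penalty by a $K$-proportional term of the same
order). Reports normalize BIC so the sweep minimum is zero; the best $K$
is the smallest minimizer.

**Cross-validation.** 20% of observed cells, stratified by condition, are
masked: their emission likelihood is set to 1 in every state, so they
contribute weight exactly zero to every M-step sum while their posteriors
are still inferred through their relatives. After convergence the masked
cells' actual observations are scored by the log of the posterior-mixed
likelihood, $\sum_{masked} \log \sum_k \gamma_n(k)\,P(x_n \mid z_n = k)$.
We score the mixture rather than the arithmetic posterior average of
log-likelihoods because the latter is dominated by small posterior mass on
badly matching states and empirically degrades monotonically with $K$,
whereas the mixture is the predictive density of the held-out observation
under the inferred assignment. One mask is drawn per population and reused
across the whole $K$ sweep, pairing the comparisons. The selected $K$ is
the smallest one whose held-out log-likelihood is within 1% (relative to
the maximum's magnitude) of the sweep maximum — a plateau rule. Freezing
$T$ at $1/K$ ("no-inheritance" baseline) quantifies how much of the
held-out likelihood comes from lineage structure.

## Synthetic lineages

The generator draws a state tree (root from $\pi$, daughters from $T$) to
a generation cap, samples emissions per cell from its state, then applies
the experiment window: cells born after the end of the window become
unobserved placeholders; a cell whose phase straddles the end keeps the
in-window span as a censored duration and loses that phase's fate; a cell
that dies makes its entire progeny unobserved. Subtrees lying entirely
below an unobserved cell are dropped while the first unobserved boundary
cells remain, so trees stay strictly binary and the likelihood is
unchanged (dropped cells would contribute $\log 1 = 0$ rows). Breadth
(number of founding lineages) and depth (window length / generation cap)
are controlled independently. Identical seeds give bit-identical
populations.

The emission parameter tables behind `preset()` are synthetic stand-ins
(see `inst/extdata/preset-emissions-synthetic.json`), chosen once to
emulate the regime the benchmarks describe: AU565-like cells under
low-dose lapatinib, 1–5 generations inside a 96 h window, later states
cycling slower and dying more. Gamma shapes of 20–25 (duration CV of
~20%) keep phase lengths realistically noisy while leaving neighbouring
states distinguishable. The two-state benchmark uses the printed
$T = [[0.9, 0.1], [0.1, 0.9]]$ with $\pi$ its stationary distribution
$[0.5, 0.5]$; the five-state benchmark uses the printed $5 \times 5$
transition matrix and initial probabilities (normalized — the printed
vector sums to 0.98) with a 96 h window.

What the generator deliberately does **not** emulate: sibling-correlated
emissions beyond shared state, mother-daughter duration correlations
within a state, start-of-experiment censorship (synthetic roots are born
at $t = 0$), motility or spatial effects, and state processes that change
over time. Passing the synthetic benchmarks therefore demonstrates
correct inference under the model's own assumptions, not robustness to
their violation in real recordings.

## Benchmarks and problem sizes

The packaged experiments run at desk scale, with sizes chosen to finish in
minutes while preserving the qualitative regime:

* **Two-state recovery** (censored, phase-specific, 15 lineages ≈ 100–300
  observed cells, 20 trials): adjusted Rand index of Viterbi states
  against the generating states, transition-matrix summed squared error,
  and Euclidean error of $\pi$, all after exact best-permutation
  alignment of the interchangeable labels.
* **BIC sweep** (true $K = 1..4$, complete 5-generation trees, breadth
  grown with $K$ from 12 to 40 lineages ≈ 300–650 observed cells,
  candidates 1–5, 10 trials each): the sweep recovers the true state
  count. The larger breadth at $K = 4$ matters: at ~370 cells the best
  attainable 4-state likelihood gain falls below the BIC penalty of the
  13 extra parameters, so state-count recovery there is data-limited
  rather than estimator-limited. Window censorship is omitted here; combined with
  per-state death it removes most of the information that distinguishes
  slow states, and state-count recovery is then limited by the data, not
  the estimator (the censored regime is exercised by the two-state
  benchmark and cross-validation keeps the masking machinery honest).
* **Cross-validation** (true $K = 2..5$, breadth grown with $K$ up to 80
  lineages): the held-out curve plateaus at the true $K$, and the
  no-inheritance baseline scores strictly lower on heritable data.
* **Separation sweep**: two states identical except state 1's G1 scale
  (swept over 4–20 h at shared shape 16, i.e. from coincident
  distributions to ~5 SD apart), so the Wasserstein distance (for gammas
  with shared shape, the absolute difference of means
  $|k_1\theta_1 - k_2\theta_2|$) grows from 0. The *fitted* tree HMM is
  compared against the *true-parameter* lineage-free boundary
  classifier: it matches or beats it at every grid point (assessed as a
  one-sided paired comparison at two standard errors of the 20-trial
  mean) and is decisively better in the overlapping mid-range. At zero
  separation the states are unidentifiable in principle, both methods
  sit at chance, and only sampling noise separates their means — which
  is why the point-wise assertion is statistical, not strict.

The lineage-free baseline places the decision boundary where the two
shared-shape gamma densities intersect,
$x = k \ln(\theta_2/\theta_1) / (1/\theta_1 - 1/\theta_2)$, falling back
to the mean $k\theta$ when the scales coincide; exact ties go to the
smaller-scale state.

## Limitations

* Emissions are restricted to Bernoulli fates and gamma durations;
  correlated or multivariate emissions are out of scope.
* The state space is discrete and fixed over the experiment; gradual
  drift within a state is absorbed into the duration noise.
* The ordered-scale constraint encodes a monotone dose effect; responses
  that reverse direction across doses would be mis-specified.
* Experimental initial cells (alive before recording starts) are handled
  as right-censored like end-of-window cells; if their fates are
  systematically unusual this single-mechanism treatment is approximate.
* EM finds local optima; restarts mitigate but do not guarantee the
  global maximum, and with many states on small populations some
  restarts collapse adjacent states (the restart with the best likelihood
  is kept).
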