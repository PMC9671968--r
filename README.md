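# lineagehmm

Heritable phenotypic heterogeneity from single-cell lineage trees, via a
tree-structured hidden Markov model (tHMM).

Time-lapse tracking of dividing cells yields binary genealogical trees in
which each cell carries phenotypic observations: its fate at the end of
each cell-cycle phase (progressed/divided vs. died) and the phase
durations in hours (G1 and S/G2, or one whole-lifetime record). Distinct
heritable cell states — drug-resistant vs. sensitive subpopulations, for
instance — show up as clusters of related cells with similar phenotypes.
`lineagehmm` infers those hidden states: each cell has a discrete state
$z_n \in \{1,\dots,K\}$ drawn from its mother's via a $K \times K$
transition matrix $T$ (roots from the initial distribution $\pi$), and
conditioned on the state, a cell emits independent Bernoulli fates and
gamma-distributed durations, $x_n \mid z_n = k \sim
\mathrm{Bern}(p_k) \times \Gamma(\text{shape } k_k, \text{scale }
\theta_k)$ per phase.

The package provides:

* exact state inference on trees — scaled upward/downward recursions
  (marginal state distribution, $\beta$/NF pass, smoothed posteriors
  $\gamma$) and tree Viterbi decoding;
* Baum-Welch fitting with censorship-corrected emission estimation:
  durations clipped by the experiment window enter through the gamma
  survival function, shapes are shared across treatment conditions, and
  scales can be constrained non-decreasing along a dose order;
* model selection — BIC sweeps and masked-cell cross-validation with a
  no-inheritance (uniform transition) baseline;
* a branching-process generator of synthetic lineage populations with
  death propagation and 96 h experiment-window censorship, plus the
  printed benchmark transition structures (emission preset tables are
  synthetic stand-ins; see `inst/extdata/preset-emissions-synthetic.json`);
* benchmarking utilities: adjusted Rand state-assignment accuracy,
  permutation-aligned transition/initial-probability errors, gamma
  Wasserstein distances, and the analytic lineage-free baseline
  classifier.

Lineage data are exchanged as flat CSV (one row per cell: `lineage_id,
cell_id, parent_id, condition, fate_g1, dur_g1, cens_g1, fate_g2, dur_g2,
cens_g2, observed[, true_state]`); see `?read_population_csv`.

## Worked example

Simulate a censored two-state population from the benchmark preset
($T = [[0.9, 0.1], [0.1, 0.9]]$, $\pi = [0.5, 0.5]$), fit a 2-state
model, and score the recovery:

```r
library(lineagehmm)
cfg <- preset("two_state_phase", n_initial_lineages = 10, seed = 1)
pop <- generate_population(cfg)
pop
#> <lineage_population> 10 lineage(s), 182 cells (150 observed), schema phase_specific
#>   conditions: control

fit <- baum_welch(pop, K = 2, seed = 1)
fit
#> <thmm_fit> K = 2 | loglik = -633.283 | 14 iteration(s) (converged)
#> pi: 0.5 0.5
round(fit$structure$T, 3)
#>       [,1]  [,2]
#> [1,] 0.898 0.102
#> [2,] 0.117 0.883

truth <- unlist(lapply(pop$lineages, function(tr) tr$obs$true_state[tr$obs$observed]))
pred  <- unlist(lapply(seq_along(pop$lineages),
                       function(li) fit$viterbi_states[[li]][pop$lineages[[li]]$obs$observed]))
rand_index(truth, pred)
#> [1] 1
```

The fitted transition matrix sits within ~0.02 of the generating one, the
initial probabilities are recovered exactly, and the Viterbi decoding
labels every observed cell correctly (adjusted Rand index 1). A BIC sweep
picks the true state count:

```r
sweep_states(pop, 1:3, seed = 1, n_restarts = 2, tol = 1e-5, max_iter = 60)
#>  K    loglik dof      bic normalized_bic
#>  1 -779.8280   6 1589.720       247.9920
#>  2 -633.2842  15 1341.728         0.0000
#>  3 -628.5015  26 1387.279        45.5516
#> best_k: 2
```

A thin command-line front end over the same functions lives at
`inst/cli/thmm.R` (`simulate`, `fit`, `select`, `crossval`, `benchmark`
subcommands, each driven by a small JSON config).

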