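# Shared synthetic study configurations.

# Two-state benchmark: T = [[0.9, 0.1], [0.1, 0.9]], pi its stationary
# distribution, phase-specific preset emissions, 96 h window censorship.
two_state_population <- function(n_lineages = 15, seed = 1) {
  cfg <- preset("two_state_phase", n_initial_lineages = n_lineages,
                seed = seed, censor = TRUE, max_generations = 5)
  generate_population(cfg)
}

# k-state population built as in the cross-validation experiments: the
# first k states of the five-state table, T = normalize(I + 0.1),
# uniform initial probabilities, complete (window-free) 5-generation trees.
k_state_population <- function(k, n_lineages, seed) {
  em5 <- lineagehmm:::preset_emission_table("five_state_phase")
  em <- emission_model(em5$params[seq_len(k)], em5$schema)
  Tm <- diag(k) + 0.1
  Tm <- Tm / rowSums(Tm)
  st <- transition_structure(rep(1 / k, k), Tm)
  cfg <- generator_config(st, em, n_initial_lineages = n_lineages,
                          max_generations = 5, censor = FALSE, seed = seed)
  generate_population(cfg)
}

# observed-cell true and predicted state vectors for a fit
observed_truth <- function(pop) {
  unlist(lapply(pop$lineages, function(tr) tr$obs$true_state[tr$obs$observed]))
}
observed_viterbi <- function(pop, fit) {
  unlist(lapply(seq_along(pop$lineages), function(li) {
    fit$viterbi_states[[li]][pop$lineages[[li]]$obs$observed]
  }))
}

# small fixed lineage used across I/O tests: 7 cells, one death, one
# censored leaf, one unobserved placeholder pair
fixture_records <- function() {
  data.frame(
    cell_id = 0:6,
    parent_id = c(NA, 0, 0, 1, 1, 2, 2),
    fate_g1 = c(1, 1, 0, 1, NA, NA, NA),
    dur_g1 = c(10.25, 8.5, 12.125, 9, 14.5, NA, NA),
    cens_g1 = c(0, 0, 0, 0, 1, NA, NA),
    fate_g2 = c(1, 1, NA, 1, NA, NA, NA),
    dur_g2 = c(20.5, 17, NA, 15.75, NA, NA, NA),
    cens_g2 = c(0, 0, NA, 0, NA, NA, NA),
    observed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    true_state = c(1, 1, 2, 1, 2, NA, NA)
  )
}
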