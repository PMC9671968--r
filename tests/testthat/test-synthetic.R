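test_that("identity transitions propagate the root state everywhere", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  st <- transition_structure(c(0.5, 0.5), diag(2))
  cfg <- generator_config(st, em, n_initial_lineages = 1,
                          max_generations = 5, censor = FALSE, seed = 71)
  tr <- generate_state_tree(cfg)
  expect_equal(length(unique(tr$obs$true_state)), 1L)
})

test_that("a death-free generation-capped lineage at 5 generations has 31 cells", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  for (k in 1:2) em$params[[k]]$bern[] <- 1   # no deaths
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  cfg <- generator_config(st, em, n_initial_lineages = 1,
                          max_generations = 5, censor = FALSE, seed = 72)
  pop <- generate_population(cfg)
  expect_equal(n_cells(pop$lineages[[1]]), 31L)
  expect_true(all(pop$lineages[[1]]$obs$observed))
})

test_that("sampled daughter states follow the transition matrix", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  Tm <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  st <- transition_structure(c(0.5, 0.5), Tm)
  cfg <- generator_config(st, em, n_initial_lineages = 60,
                          max_generations = 11, censor = FALSE)
  set.seed(73)
  pairs <- do.call(rbind, lapply(seq_len(60), function(i) {
    tr <- generate_state_tree(cfg)
    nonroot <- which(!is.na(tr$parent))
    cbind(tr$obs$true_state[tr$parent[nonroot]], tr$obs$true_state[nonroot])
  }))
  expect_gte(nrow(pairs), 1e5)
  for (i in 1:2) {
    n_i <- sum(pairs[, 1] == i)
    phat <- mean(pairs[pairs[, 1] == i, 2] == 1)
    se <- sqrt(Tm[i, 1] * (1 - Tm[i, 1]) / n_i)
    expect_lt(abs(phat - Tm[i, 1]), 3 * se)
  }
})

test_that("sampled durations match their state's gamma moments", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  st <- transition_structure(c(1, 0), diag(2))   # all cells state 1
  for (k in 1:2) em$params[[k]]$bern[] <- 1
  cfg <- generator_config(st, em, n_initial_lineages = 30,
                          max_generations = 12, censor = FALSE)
  set.seed(74)
  durs <- unlist(lapply(seq_len(30), function(i) {
    tr <- attach_emissions(generate_state_tree(cfg), em, 1L)
    tr$obs$dur_g1
  }))
  expect_gte(length(durs), 1e5)
  k <- em$params[[1]]$shape[1]; th <- em$params[[1]]$scale[1, 1]
  se <- sqrt(k * th^2 / length(durs))
  expect_lt(abs(mean(durs) - k * th), 3 * se)
})

test_that("death at the root leaves every descendant unobserved", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  for (k in 1:2) em$params[[k]]$bern[] <- 0   # guaranteed death in G1
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  cfg <- generator_config(st, em, n_initial_lineages = 1,
                          max_generations = 4, censor = FALSE, seed = 75)
  tr <- attach_emissions(generate_state_tree(cfg), em, 1L)
  expect_true(tr$obs$observed[1])
  expect_false(any(tr$obs$observed[-1]))
  expect_true(is.na(tr$obs$dur_g2[1]))   # died in G1: no S/G2 observation
  expect_equal(tr$obs$fate_g1[1], 0)
})

test_that("time censorship clips exactly the durations crossing the window", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  cfg <- generator_config(st, em, n_initial_lineages = 1,
                          max_generations = 6, censor = FALSE, seed = 76)
  for (trial in 1:5) {
    cfg$seed <- 76 + trial
    full <- attach_emissions(generate_state_tree(cfg), em, 1L)
    Texp <- 40
    cens <- apply_time_censorship(full, Texp, 2L)
    expect_equal(apply_time_censorship(full, Inf, 2L), full)
    bt <- lineagehmm:::birth_times(full, 2L)
    for (i in seq_len(n_cells(full))) {
      if (!full$obs$observed[i]) next
      if (is.na(bt[i])) next
      g1_cross <- bt[i] < Texp & bt[i] + full$obs$dur_g1[i] > Texp
      if (!is.na(g1_cross) && g1_cross) {
        expect_equal(cens$obs$cens_g1[i], 1L)
        expect_equal(cens$obs$dur_g1[i], Texp - bt[i])
        expect_true(is.na(cens$obs$fate_g1[i]))
      }
      if (bt[i] >= Texp) expect_false(cens$obs$observed[i])
      # every censored flag corresponds to a true crossing
      if (!is.na(cens$obs$cens_g1[i]) && cens$obs$cens_g1[i] == 1L) {
        expect_true(bt[i] + full$obs$dur_g1[i] > Texp)
      }
    }
  }
})

test_that("generation is reproducible and trees stay binary after pruning", {
  cfg <- preset("two_state_phase", n_initial_lineages = 5, seed = 77)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  for (tr in a$lineages) {
    has_d <- !is.na(tr$daughters[, 1])
    expect_true(all(is.na(tr$daughters[!has_d, 2])))
    expect_true(all(!is.na(tr$daughters[has_d, 2])))
    # unobserved boundary cells are leaves
    expect_true(all(is.na(tr$daughters[!tr$obs$observed, 1])))
  }
})

test_that("presets carry the printed transition structures", {
  for (nm in c("two_state_phase", "two_state_lifetime", "five_state_phase")) {
    cfg <- preset(nm, n_initial_lineages = 1)
    expect_equal(rowSums(cfg$structure$T), rep(1, cfg$structure$K))
    expect_equal(sum(cfg$structure$pi), 1, tolerance = 1e-12)
  }
  two <- preset("two_state_phase", n_initial_lineages = 1)
  expect_equal(two$structure$pi, c(0.5, 0.5), tolerance = 1e-12)
  five <- preset("five_state_phase", n_initial_lineages = 1)
  expect_equal(five$experiment_time, 96)
  drift <- as.numeric(five$structure$pi %*% five$structure$T)
  expect_true(all(abs(drift - five$structure$pi) < 0.01))
  expect_error(preset("nonexistent"))
})

test_that("stationary distributions satisfy pi T = pi and detect reducibility", {
  Tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(stationary_distribution(Tm), c(0.5, 0.5), tolerance = 1e-12)
  set.seed(78)
  Ts <- matrix(rgamma(9, 1), 3); Ts <- (Ts + t(Ts)) / 2
  Ts <- Ts / rowSums(Ts)   # symmetric up to row scaling
  p <- stationary_distribution(Ts)
  expect_equal(as.numeric(p %*% Ts), p, tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "reducible")
})
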