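test_that("marginal state distribution propagates pi through T", {
  tr <- build_lineage(data.frame(cell_id = 0:2, parent_id = c(NA, 0, 0)))
  st <- transition_structure(c(0.3, 0.7),
                             matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE))
  MSD <- compute_MSD(tr, st)
  expect_equal(MSD[1, ], c(0.3, 0.7))
  expect_equal(MSD[2, ], as.numeric(c(0.3, 0.7) %*% st$T))
  expect_equal(rowSums(MSD), rep(1, 3))

  st1 <- transition_structure(1, matrix(1))
  expect_equal(compute_MSD(tr, st1), matrix(1, 3, 1))
})

test_that("single-cell upward recursion matches the closed form", {
  tr <- build_lineage(data.frame(cell_id = 0, parent_id = NA))
  st <- transition_structure(c(0.5, 0.5), matrix(0.5, 2, 2))
  a <- 0.12; b <- 0.48
  logEL <- matrix(log(c(a, b)), 1)
  up <- upward_recursion(tr, logEL, compute_MSD(tr, st), st)
  expect_equal(up$beta[1, ], c(a, b) / (a + b))
  expect_equal(log(up$NF[1]) + up$shift[1], log(0.5 * (a + b)))
  expect_equal(log_likelihood(up), log(0.5 * (a + b)))
})

test_that("uniform emissions leave beta equal to the prior MSD", {
  set.seed(5)
  tr <- build_lineage(random_tree_records(7))
  st <- random_structure(3)
  MSD <- compute_MSD(tr, st)
  logEL <- matrix(0, n_cells(tr), 3)
  up <- upward_recursion(tr, logEL, MSD, st)
  expect_equal(up$beta, MSD, tolerance = 1e-12)
})

test_that("recursions and Viterbi agree with exhaustive enumeration", {
  set.seed(99)
  for (rep_i in 1:40) {
    K <- sample(1:3, 1)
    tr <- build_lineage(random_tree_records(7))
    st <- random_structure(K)
    logEL <- random_logEL(n_cells(tr), K)
    MSD <- compute_MSD(tr, st)
    up <- upward_recursion(tr, logEL, MSD, st)
    oracle <- brute_force_tree(tr, logEL, st)

    expect_equal(log_likelihood(up), oracle$loglik, tolerance = 1e-8)
    g <- downward_recursion(tr, up, MSD, st)
    expect_equal(g, oracle$gamma, tolerance = 1e-8)
    expect_equal(rowSums(g), rep(1, n_cells(tr)), tolerance = 1e-10)

    vit <- viterbi(tr, logEL, st)
    joint <- function(z) {
      lp <- log(st$pi[z[1]]) + sum(logEL[cbind(seq_along(z), z)])
      for (i in seq_along(z)[-1]) lp <- lp + log(st$T[z[tr$parent[i]], z[i]])
      lp
    }
    expect_equal(joint(vit$states), oracle$viterbi_logp, tolerance = 1e-8)
  }
})

test_that("posterior additivity: population log-likelihood sums per-lineage values", {
  pop <- two_state_population(n_lineages = 2, seed = 31)
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  es_both <- e_step(pop, st, em)
  singles <- vapply(1:2, function(i) {
    sub <- lineage_population(pop$lineages[i], pop$schema, pop$conditions)
    e_step(sub, st, em)$loglik
  }, 0)
  expect_equal(es_both$loglik, sum(singles), tolerance = 1e-10)
})

test_that("relabeling states permutes posteriors identically", {
  set.seed(17)
  tr <- build_lineage(random_tree_records(7))
  K <- 3
  st <- random_structure(K)
  logEL <- random_logEL(n_cells(tr), K, p_unobserved = 0)
  perm <- c(3, 1, 2)
  st_p <- transition_structure(st$pi[perm], st$T[perm, perm])
  MSD <- compute_MSD(tr, st)
  MSD_p <- compute_MSD(tr, st_p)
  g <- downward_recursion(tr, upward_recursion(tr, logEL, MSD, st), MSD, st)
  g_p <- downward_recursion(tr, upward_recursion(tr, logEL[, perm], MSD_p, st_p),
                            MSD_p, st_p)
  expect_equal(g_p, g[, perm], tolerance = 1e-12)
})

test_that("scaled recursions stay finite on deep lineages", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  for (k in 1:2) em$params[[k]]$bern[] <- 1   # keep the full 127-cell tree
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE))
  cfg <- generator_config(st, em, n_initial_lineages = 1,
                          max_generations = 7, censor = FALSE, seed = 8)
  pop <- generate_population(cfg)
  expect_gte(n_cells(pop$lineages[[1]]), 100)
  logEL <- compute_EL(pop, em)[[1]]
  MSD <- compute_MSD(pop$lineages[[1]], st)
  up <- upward_recursion(pop$lineages[[1]], logEL, MSD, st)
  expect_true(all(up$NF > 1e-300 & up$NF < 1e300))
  g <- downward_recursion(pop$lineages[[1]], up, MSD, st)
  expect_equal(rowSums(g), rep(1, n_cells(pop$lineages[[1]])),
               tolerance = 1e-10)
})

test_that("Viterbi decodes trivially for K = 1 and separable emissions", {
  tr <- build_lineage(data.frame(cell_id = 0:2, parent_id = c(NA, 0, 0)))
  st1 <- transition_structure(1, matrix(1))
  expect_equal(viterbi(tr, matrix(log(0.3), 3, 1), st1)$states, rep(1L, 3))

  # near-delta emissions recover the generated states exactly
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  em$params[[1]]$scale[, 1] <- em$params[[1]]$scale[, 1] / 10  # widen gap
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  cfg <- generator_config(st, em, n_initial_lineages = 3,
                          max_generations = 4, censor = FALSE, seed = 23)
  pop <- generate_population(cfg)
  logEL <- compute_EL(pop, em)
  for (li in seq_along(pop$lineages)) {
    trl <- pop$lineages[[li]]
    states <- viterbi(trl, logEL[[li]], st)$states
    obs <- trl$obs$observed
    expect_equal(states[obs], trl$obs$true_state[obs])
  }
})
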