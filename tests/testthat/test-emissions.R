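make_params <- function(bern = c(0.9, 0.8), shape = c(7, 14),
                        scale = c(4, 2)) {
  state_emission_params(bern = bern, shape = shape, scale = scale)
}

test_that("observation likelihood handles missing, unobserved and censored slots", {
  p <- make_params()
  unob <- list(observed = FALSE, fate_g1 = NA, dur_g1 = NA, cens_g1 = NA,
               fate_g2 = NA, dur_g2 = NA, cens_g2 = NA)
  expect_identical(observation_loglik(unob, p), 0)

  sure <- make_params(bern = c(1, 1))
  fate_only <- list(observed = TRUE, fate_g1 = 1, dur_g1 = NA, cens_g1 = NA,
                    fate_g2 = NA, dur_g2 = NA, cens_g2 = NA)
  expect_equal(observation_loglik(fate_only, sure), 0, tolerance = 1e-5)

  # exponential special case: censored survival is -t / theta
  expo <- make_params(bern = c(0.5, 0.5), shape = c(1, 1), scale = c(3, 3))
  censored <- list(observed = TRUE, fate_g1 = NA, dur_g1 = 7.5, cens_g1 = 1,
                   fate_g2 = NA, dur_g2 = NA, cens_g2 = NA)
  expect_equal(observation_loglik(censored, expo), -7.5 / 3, tolerance = 1e-12)

  neg <- list(observed = TRUE, fate_g1 = NA, dur_g1 = -2, cens_g1 = 0,
              fate_g2 = NA, dur_g2 = NA, cens_g2 = NA)
  expect_error(observation_loglik(neg, p), "negative duration")

  # independence: components add in log space
  both <- list(observed = TRUE, fate_g1 = 1, dur_g1 = 5, cens_g1 = 0,
               fate_g2 = 0, dur_g2 = NA, cens_g2 = NA)
  expect_equal(observation_loglik(both, p),
               log(0.9) + dgamma(5, 7, scale = 4, log = TRUE) + log(1 - 0.8),
               tolerance = 1e-9)
})

test_that("the duration component is a normalized density", {
  p <- make_params()
  grid <- seq(0.001, 400, by = 0.01)
  one_cell <- function(t) {
    observation_loglik(list(observed = TRUE, fate_g1 = NA, dur_g1 = t,
                            cens_g1 = 0, fate_g2 = NA, dur_g2 = NA,
                            cens_g2 = NA), p)
  }
  dens <- vapply(grid, function(t) exp(one_cell(t)), 0)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 1e-3)
})

test_that("compute_EL matches per-cell likelihood calls and zeroes unobserved rows", {
  pop <- two_state_population(n_lineages = 3, seed = 21)
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  EL <- compute_EL(pop, em)
  tr <- pop$lineages[[1]]
  for (i in seq_len(n_cells(tr))) {
    for (k in 1:2) {
      expect_equal(EL[[1]][i, k],
                   observation_loglik(tr$obs[i, ], em$params[[k]], 1L),
                   tolerance = 1e-12)
    }
    if (!tr$obs$observed[i]) expect_identical(EL[[1]][i, ], c(0, 0))
  }
  # K = 1 gives a single column
  em1 <- emission_model(em$params[1], em$schema)
  expect_equal(ncol(compute_EL(pop, em1)[[1]]), 1L)
})

test_that("weighted Bernoulli estimation is the weighted mean", {
  expect_equal(fit_bernoulli_weighted(c(1, 1, 1), c(1, 1, 1)), 1.0)
  expect_equal(fit_bernoulli_weighted(c(1, 0), c(1, 1)), 0.5)
  expect_equal(fit_bernoulli_weighted(c(1, 0), c(1, 3)), 0.25)
  expect_error(fit_bernoulli_weighted(c(1, 0), c(0, 0)), "weights")
})

test_that("censored gamma MLE recovers simulation truth and matches the uncensored oracle", {
  set.seed(42)
  x <- rgamma(50000, shape = 7, scale = 4)
  f <- fit_gamma_censored(x)
  expect_lt(abs(f["shape"] - 7) / 7, 0.05)
  expect_lt(abs(f["scale"] - 4) / 4, 0.05)

  # no censored flags: equals the independent uncensored MLE (fitdistrplus)
  set.seed(43)
  y <- rgamma(400, shape = 3, scale = 5)
  ours <- fit_gamma_censored(y, censor_flags = rep(0, 400))
  oracle <- fitdistrplus::fitdist(y, "gamma", method = "mle")
  expect_equal(unname(ours["shape"]), unname(oracle$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(unname(ours["scale"]), 1 / unname(oracle$estimate["rate"]),
               tolerance = 1e-3)

  expect_error(fit_gamma_censored(c(3, 4), censor_flags = c(1, 1)),
               "unidentifiable")
})

test_that("censorship correction removes the downward bias of the naive fit", {
  set.seed(7)
  x <- rgamma(3000, shape = 7, scale = 4)
  bound <- 25   # heavy right-censorship (~mean)
  cens <- x > bound
  xc <- pmin(x, bound)
  corrected <- fit_gamma_censored(xc, cens)
  naive <- fit_gamma_censored(xc, rep(FALSE, length(xc)))
  expect_gt(corrected["shape"] * corrected["scale"],
            naive["shape"] * naive["scale"])
  # corrected mean is close to the true mean of 28
  expect_lt(abs(corrected["shape"] * corrected["scale"] - 28) / 28, 0.1)
})

test_that("shared-shape fit reduces to the single-condition fit and obeys ordering", {
  set.seed(11)
  x <- rgamma(500, shape = 5, scale = 3)
  cens <- x > 20
  x <- pmin(x, 20)
  single <- fit_gamma_censored(x, cens)
  shared <- fit_gamma_shared_shape(list(list(durations = x, censor_flags = cens)))
  expect_equal(shared$shape, unname(single["shape"]), tolerance = 1e-4)
  expect_equal(shared$scales, unname(single["scale"]), tolerance = 1e-4)

  # four conditions drawn from one gamma: scales agree and satisfy ordering
  set.seed(12)
  groups <- lapply(1:4, function(i) list(durations = rgamma(800, 6, scale = 2)))
  fit <- fit_gamma_shared_shape(groups, ordered = TRUE)
  expect_true(all(diff(fit$scales) >= 0))
  expect_lt(max(fit$scales) - min(fit$scales), 0.35)
  expect_lt(abs(fit$shape - 6) / 6, 0.15)

  # ordering holds even when the data pull the other way
  set.seed(13)
  rev_groups <- list(list(durations = rgamma(400, 6, scale = 3)),
                     list(durations = rgamma(400, 6, scale = 2)))
  rev_fit <- fit_gamma_shared_shape(rev_groups, ordered = TRUE)
  expect_true(all(diff(rev_fit$scales) >= -1e-9))
})

test_that("constrained fit is locally optimal against random feasible probes", {
  set.seed(14)
  groups <- lapply(c(2, 2.8), function(s) {
    x <- rgamma(300, 5, scale = s)
    list(durations = pmin(x, 18), censor_flags = x > 18)
  })
  fit <- fit_gamma_shared_shape(groups, ordered = TRUE)
  pooled <- function(shape, scales) {
    sum(vapply(1:2, function(ci) {
      lineagehmm:::gamma_cens_loglik(shape, scales[ci], groups[[ci]]$durations,
                                     as.logical(groups[[ci]]$censor_flags),
                                     rep(1, 300))
    }, 0))
  }
  at_fit <- pooled(fit$shape, fit$scales)
  for (probe in 1:20) {
    shape <- fit$shape * exp(runif(1, -0.3, 0.3))
    scales <- sort(fit$scales * exp(runif(2, -0.3, 0.3)))
    expect_lte(pooled(shape, scales), at_fit + 1e-6)
  }
})

test_that("emission parameters serialize to a state/phase-keyed JSON document", {
  em <- lineagehmm:::preset_emission_table("two_state_phase")
  doc <- jsonlite::fromJSON(write_emissions_json(em), simplifyVector = FALSE)
  expect_named(doc, c("state_1", "state_2"))
  expect_equal(doc$state_1[[1]]$shape, em$params[[1]]$shape[1])
  expect_equal(unlist(doc$state_2[[2]]$scale), em$params[[2]]$scale[2, 1])
})
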