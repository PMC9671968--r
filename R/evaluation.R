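#' Adjusted Rand index between two state labelings
#'
#' Chance-corrected agreement between the true and predicted partitions of
#' the observed cells; invariant to label permutation, 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param true_states,predicted_states Equal-length label vectors.
#' @return Scalar adjusted Rand index.
#' @export
rand_index <- function(true_states, predicted_states) {
  if (length(true_states) != length(predicted_states)) {
    stop("label vectors differ in length")
  }
  mclust::adjustedRandIndex(true_states, predicted_states)
}

#' Wasserstein distance between two gamma distributions
#'
#' The analytic first-Wasserstein distance between the two duration
#' distributions reduces to the absolute difference of their means
#' `|shape_a * scale_a - shape_b * scale_b|`.
#'
#' @param params_a,params_b Numeric `c(shape, scale)` pairs.
#' @return Nonnegative distance (hours).
#' @export
wasserstein_gamma <- function(params_a, params_b) {
  abs(params_a[1] * params_a[2] - params_b[1] * params_b[2])
}

# all permutations of 1..K (K! rows)
permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(K - 1L)
  out <- do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, matrix(c(seq_len(K)[-i])[sub], nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Align predicted states to true states
#'
#' Exact search over the K! state permutations for the one maximizing
#' label agreement with the truth (states are interchangeable, so all
#' parameter-error metrics are computed after this relabeling).
#'
#' @param true_states,predicted_states Label vectors in `1..K`.
#' @param K Number of states.
#' @return Integer permutation `p` such that `p[predicted]` best matches
#'   the truth.
#' @export
align_states <- function(true_states, predicted_states,
                         K = max(true_states, predicted_states)) {
  perms <- permutations(K)
  agree <- apply(perms, 1, function(p) {
    sum(p[predicted_states] == true_states)
  })
  perms[which.max(agree), ]
}

#' Squared-error distance between transition matrices
#'
#' Sum of squared element-wise differences (squared Frobenius norm) after
#' optimal state relabeling: either the supplied permutation or, by
#' default, the permutation minimizing the error.
#'
#' @param T_true,T_est K x K matrices.
#' @param perm Optional permutation aligning estimated to true states
#'   (e.g. from [align_states()]).
#' @return Nonnegative scalar.
#' @export
transition_error <- function(T_true, T_est, perm = NULL) {
  if (!all(dim(T_true) == dim(T_est))) stop("matrix shapes differ")
  K <- nrow(T_true)
  err <- function(p) sum((T_true - T_est[order(p), order(p), drop = FALSE])^2)
  if (!is.null(perm)) return(err(perm))
  min(apply(permutations(K), 1, err))
}

#' Euclidean error between initial-probability vectors
#'
#' @param pi_true,pi_est Length-K probability vectors.
#' @param perm Optional state alignment permutation.
#' @return Euclidean distance, after optimal relabeling if `perm` is NULL.
#' @export
pi_error <- function(pi_true, pi_est, perm = NULL) {
  if (length(pi_true) != length(pi_est)) stop("vector lengths differ")
  err <- function(p) sqrt(sum((pi_true - pi_est[order(p)])^2))
  if (!is.null(perm)) return(err(perm))
  min(apply(permutations(length(pi_true)), 1, err))
}

#' Optimal lineage-free classification boundary between two gamma states
#'
#' With a shared shape `k`, the two gamma densities intersect at
#' `x = k * log(theta_2 / theta_1) / (1 / theta_1 - 1 / theta_2)`; when
#' the scales coincide the distribution mean `k * theta` is used.
#'
#' @param shape Shared gamma shape.
#' @param scale_1,scale_2 Gamma scales of states 1 and 2.
#' @return Duration threshold (hours).
#' @export
baseline_threshold <- function(shape, scale_1, scale_2) {
  if (scale_1 == scale_2) return(shape * scale_1)
  shape * log(scale_2 / scale_1) / (1 / scale_1 - 1 / scale_2)
}

#' Classify durations with the lineage-free optimal boundary
#'
#' Labels each duration by which side of [baseline_threshold()] it falls
#' on: durations strictly below the threshold get the smaller-scale state,
#' durations at or above it the larger-scale state. A duration exactly at
#' the threshold breaks the tie toward the smaller-scale state.
#'
#' @param durations Numeric durations.
#' @param shape Shared gamma shape.
#' @param scales Length-2 vector of gamma scales (state order).
#' @return Integer labels in `{1, 2}` matching the order of `scales`.
#' @export
baseline_classify <- function(durations, shape, scales) {
  stopifnot(length(scales) == 2)
  thr <- baseline_threshold(shape, scales[1], scales[2])
  small <- which.min(scales)           # ties -> state 1
  big <- if (small == 1L) 2L else 1L
  ifelse(durations <= thr, small, big)
}

#' Generator configuration for the emission-separation sweep
#'
#' Two states identical in every respect except the first-phase (G1)
#' gamma scale of state 1, which sweeps upward from the fixed state-2
#' value: at the first grid point the states coincide and no classifier
#' can beat chance; as the scale grows, so does the Wasserstein distance
#' between the states. The shared G1 shape lets the analytic lineage-free
#' boundary ([baseline_threshold()]) apply.
#'
#' @param scale1 State-1 G1 gamma scale (state 2 stays at 4).
#' @param n_initial_lineages Breadth.
#' @param seed Seed stored in the config.
#' @return A [generator_config()] (complete 4-generation trees).
#' @export
separation_sweep_config <- function(scale1, n_initial_lineages = 15L,
                                    seed = NULL) {
  base <- list(bern = c(0.99, 0.95), shape = c(16, 25), scale = c(4, 0.8))
  s1 <- state_emission_params(base$bern, base$shape, c(scale1, 0.8))
  s2 <- state_emission_params(base$bern, base$shape, base$scale)
  st <- transition_structure(c(0.5, 0.5),
                             matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  generator_config(st, emission_model(list(s1, s2),
                                      obs_schema("phase_specific")),
                   n_initial_lineages = n_initial_lineages,
                   max_generations = 4L, censor = FALSE, seed = seed)
}

#' Run the synthetic benchmark harness
#'
#' For each grid row and trial: generate a population from the named
#' preset (optionally overriding the state-1 G1 scale for the
#' emission-separation sweep), fit the model with [baum_welch()], and
#' score state-assignment accuracy (adjusted Rand of Viterbi vs true
#' states over observed cells), transition and initial-probability errors
#' after optimal state alignment, the mean per-state Wasserstein distance
#' between fitted and true duration distributions, and (for two-state
#' shared-shape sweeps) the lineage-free baseline accuracy on first-phase
#' durations.
#'
#' @param config_grid Data frame with columns `preset`, `n_lineages`, and
#'   optionally `scale1` (state-1 first-phase gamma scale override),
#'   `censor`, `max_generations`.
#' @param n_trials Trials per grid row.
#' @param seed Base seed; trial `t` of row `r` uses `seed + 1000 r + t`.
#' @param ... Passed to [baum_welch()] (e.g. `n_restarts`, `tol`).
#' @return Data frame, one row per grid row x trial.
#' @export
run_benchmark <- function(config_grid, n_trials = 20L, seed = 1L, ...) {
  out <- list()
  for (r in seq_len(nrow(config_grid))) {
    row <- config_grid[r, , drop = FALSE]
    for (trial in seq_len(n_trials)) {
      trial_seed <- seed + 1000L * r + trial
      if (row$preset == "separation_sweep") {
        cfg <- separation_sweep_config(row$scale1,
                                       n_initial_lineages = row$n_lineages,
                                       seed = trial_seed)
      } else {
        cfg <- preset(row$preset,
                      n_initial_lineages = row$n_lineages,
                      seed = trial_seed,
                      censor = if ("censor" %in% names(row)) row$censor else TRUE,
                      max_generations = if ("max_generations" %in% names(row))
                        row$max_generations else 5L)
        if ("scale1" %in% names(row) && !is.na(row$scale1)) {
          cfg$emissions$params[[1]]$scale[1, 1] <- row$scale1
        }
      }
      pop <- generate_population(cfg)
      out[[length(out) + 1L]] <-
        score_fit(pop, cfg, trial_seed = trial_seed, ...)
    }
  }
  do.call(rbind, out)
}

# fit one generated population and score it against the generator truth
score_fit <- function(pop, cfg, trial_seed, ...) {
  K <- cfg$structure$K
  fit <- baum_welch(pop, K, seed = trial_seed, ...)
  truth <- unlist(lapply(pop$lineages, function(tr) {
    tr$obs$true_state[tr$obs$observed]
  }))
  pred <- unlist(lapply(seq_along(pop$lineages), function(li) {
    fit$viterbi_states[[li]][pop$lineages[[li]]$obs$observed]
  }))
  perm <- align_states(truth, pred, K = K)
  wass <- mean(vapply(seq_len(K), function(k) {
    kt <- cfg$emissions$params[[k]]
    ke <- fit$emissions$params[[order(perm)[k]]]
    mean(vapply(seq_along(kt$shape), function(ph) {
      wasserstein_gamma(c(kt$shape[ph], kt$scale[ph, 1]),
                        c(ke$shape[ph], ke$scale[ph, 1]))
    }, 0))
  }, 0))
  baseline_acc <- NA_real_
  if (K == 2L &&
      cfg$emissions$params[[1]]$shape[1] == cfg$emissions$params[[2]]$shape[1]) {
    durs <- unlist(lapply(pop$lineages, function(tr) {
      tr$obs$dur_g1[tr$obs$observed]
    }))
    keep <- !is.na(durs)
    bl <- baseline_classify(durs[keep],
                            cfg$emissions$params[[1]]$shape[1],
                            c(cfg$emissions$params[[1]]$scale[1, 1],
                              cfg$emissions$params[[2]]$scale[1, 1]))
    baseline_acc <- rand_index(truth[keep], bl)
  }
  data.frame(
    trial_seed = trial_seed,
    n_lineages = length(pop$lineages),
    n_cells = n_cells(pop, observed_only = TRUE),
    accuracy = rand_index(truth, pred),
    transition_error = transition_error(cfg$structure$T, fit$structure$T,
                                        perm = perm),
    pi_error = pi_error(cfg$structure$pi, fit$structure$pi, perm = perm),
    wasserstein = wass,
    baseline_accuracy = baseline_acc
  )
}
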