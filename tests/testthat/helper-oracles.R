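# Independent brute-force oracle: enumerate all K^N hidden-state
# assignments of a small tree and compute the joint probability of each
# directly from pi, T and the emission log-likelihoods. Used to verify the
# scaled recursions, posteriors and Viterbi decoding.

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

brute_force_tree <- function(tree, logEL, structure) {
  n <- n_cells(tree)
  K <- structure$K
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logp <- apply(grid, 1, function(z) {
    lp <- log(structure$pi[z[1]]) + sum(logEL[cbind(seq_len(n), z)])
    if (n > 1) {
      for (i in 2:n) lp <- lp + log(structure$T[z[tree$parent[i]], z[i]])
    }
    lp
  })
  loglik <- log_sum_exp(logp)
  gamma <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      sel <- grid[, i] == k
      gamma[i, k] <- if (any(sel)) exp(log_sum_exp(logp[sel]) - loglik) else 0
    }
  }
  list(loglik = loglik, gamma = gamma,
       viterbi = as.integer(grid[which.max(logp), ]),
       viterbi_logp = max(logp))
}

# random binary tree with at most n_max cells (1, 3, 5, or 7)
random_tree_records <- function(n_max) {
  ids <- 0L
  parent <- NA_integer_
  repeat {
    leaves_now <- setdiff(ids, parent)
    if (length(ids) + 2 > n_max) break
    if (length(ids) > 1 && stats::runif(1) < 0.3) break
    mom <- sample(leaves_now, 1)
    ids <- c(ids, max(ids) + 1:2)
    parent <- c(parent, mom, mom)
  }
  data.frame(cell_id = ids, parent_id = parent)
}

random_structure <- function(K) {
  pi <- stats::rgamma(K, 1); pi <- pi / sum(pi)
  Tm <- matrix(stats::rgamma(K * K, 1), K)
  transition_structure(pi, Tm / rowSums(Tm))
}

# random emission log-likelihood matrix; a fraction of rows are all-zero,
# mimicking unobserved placeholder cells
random_logEL <- function(n, K, p_unobserved = 0.15) {
  m <- matrix(log(stats::runif(n * K, 0.05, 1)), n, K)
  unob <- stats::runif(n) < p_unobserved
  m[unob, ] <- 0
  m
}
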