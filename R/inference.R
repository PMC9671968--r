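#' Initial and transition probabilities of the hidden-state chain
#'
#' @param pi Length-K initial probability vector (sums to 1).
#' @param T_mat K x K row-stochastic transition matrix; entry (i, j) is the
#'   probability that a daughter is in state j given the mother in state i.
#' @return A `transition_structure`.
#' @export
transition_structure <- function(pi, T_mat) {
  pi <- as.numeric(pi)
  T_mat <- as.matrix(T_mat)
  K <- length(pi)
  if (!all(dim(T_mat) == c(K, K))) stop("T must be K x K with K = length(pi)")
  if (any(pi < 0) || any(T_mat < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(abs(rowSums(T_mat) - 1) > 1e-8)) stop("rows of T must sum to 1")
  structure(list(pi = pi, T = T_mat, K = K), class = "transition_structure")
}

#' @export
print.transition_structure <- function(x, ...) {
  cat(sprintf("<transition_structure> K = %d\n", x$K))
  cat("pi:", signif(x$pi, 4), "\n")
  print(signif(x$T, 4))
  invisible(x)
}

MSD_EPS <- 1e-323  # clamp before dividing by marginal state probabilities

# 0-based link vectors for the compiled recursions (-1 = none)
tree_links <- function(tree) {
  parent <- tree$parent
  parent[is.na(parent)] <- 0L
  d <- tree$daughters
  d[is.na(d)] <- 0L
  list(parent = as.integer(parent - 1L), daughters = d - 1L)
}

#' Marginal state distribution down a lineage tree
#'
#' Prior probability of each state for each cell, before seeing any
#' observation: the root row is `pi` and every daughter row is its mother's
#' row times `T`.
#'
#' @param tree A `lineage_tree` (breadth-first ordered).
#' @param structure A [transition_structure()].
#' @return `n_cells x K` matrix with rows summing to 1.
#' @export
compute_MSD <- function(tree, structure) {
  lk <- tree_links(tree)
  cpp_msd(lk$parent, structure$pi, structure$T)
}

#' Scaled upward (leaf-to-root) recursion
#'
#' Computes the conditional state probabilities `beta`, the per-cell
#' normalizing factors `NF`, and the parent-daughter linking vectors
#' `beta_pc` by recursing from the leaves to the root. Emission
#' log-likelihoods are exponentiated after subtracting a per-cell row
#' maximum; that shift is returned and absorbed into the log-likelihood, so
#' the scaled recursion never under- or overflows on realistic lineages.
#'
#' @param tree A `lineage_tree`.
#' @param logEL `n x K` emission log-likelihood matrix (see [compute_EL()]).
#' @param MSD `n x K` marginal state distribution (see [compute_MSD()]).
#' @param structure A [transition_structure()].
#' @return List with `beta` (n x K), `NF` (length n, scaled), `beta_pc`
#'   (n x K; row n is the linking vector between cell n and its mother,
#'   NA for the root) and `shift` (length n log-scaling offsets).
#' @export
upward_recursion <- function(tree, logEL, MSD, structure) {
  lk <- tree_links(tree)
  cpp_upward(lk$parent, lk$daughters, logEL, MSD, structure$T)
}

#' Observed-data log-likelihood from the upward recursion
#'
#' The tree likelihood telescopes into the product of per-cell normalizing
#' factors, so the log-likelihood is the sum of `log NF` (plus the scaling
#' shifts) over all cells; for a population, per-lineage values add.
#'
#' @param upward One result of [upward_recursion()], or a list of them.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(upward) {
  if (!is.null(upward$NF)) upward <- list(upward)
  sum(vapply(upward, function(u) sum(log(u$NF) + u$shift), 0))
}

#' Downward (root-to-leaf) recursion: smoothed posteriors
#'
#' Turns the upward quantities into the posterior state probability of
#' every cell given the entire tree's observations: the root posterior is
#' its `beta` row, and each daughter row combines its `beta` with the
#' mother's posterior through the transition matrix.
#'
#' @inheritParams upward_recursion
#' @param upward Result of [upward_recursion()] for the same tree.
#' @return `n x K` matrix `gamma`; rows sum to 1.
#' @export
downward_recursion <- function(tree, upward, MSD, structure) {
  lk <- tree_links(tree)
  cpp_downward(lk$parent, upward$beta, upward$beta_pc, MSD, structure$T)
}

#' Most likely joint state assignment on a lineage tree (Viterbi)
#'
#' Dynamic program from the leaves to the root in log space: for each cell
#' and state, the best log-probability of the subtree below it; the root
#' then adds `log pi` and the optimal states are read back down the tree.
#' Ties break toward the lowest state index.
#'
#' @inheritParams upward_recursion
#' @return List with `states` (length-n integer vector in `1..K`) and
#'   `delta` (`n x K` log-domain score matrix).
#' @export
viterbi <- function(tree, logEL, structure) {
  lk <- tree_links(tree)
  cpp_viterbi(lk$parent, lk$daughters, logEL, structure$pi, structure$T)
}
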