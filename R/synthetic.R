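#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `T` for eigenvalue 1, normalized to sum to 1: the
#' state mix a population settles into under pure inheritance, used as the
#' initial probability vector of the benchmark presets.
#'
#' @param T_mat Row-stochastic K x K matrix; must be irreducible (unique
#'   stationary distribution).
#' @return Length-K probability vector `p` with `p %*% T_mat = p`.
#' @export
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
stationary_distribution <- function(T_mat) {
  T_mat <- as.matrix(T_mat)
  if (any(abs(rowSums(T_mat) - 1) > 1e-8)) stop("T must be row-stochastic")
  e <- eigen(t(T_mat))
  ones <- which(abs(e$values - 1) < 1e-9)
  if (length(ones) != 1) {
    stop("transition matrix is reducible: stationary distribution not unique")
  }
  v <- Re(e$vectors[, ones])
  v <- v / sum(v)
  if (any(v < -1e-12)) stop("transition matrix is reducible or periodic")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Configuration for the synthetic lineage generator
#'
#' @param structure A [transition_structure()] (true `pi` and `T`).
#' @param emissions An [emission_model()] (true per-state phenotypes).
#' @param n_initial_lineages Number of founding cells, i.e. lineage trees
#'   (breadth).
#' @param experiment_time Observation window in hours (depth), or `NULL`.
#' @param max_generations Hard generation cap; defaults to 10 when only
#'   `experiment_time` is given. At least one of the two must be set.
#' @param censor Apply the experiment-window censorship to the generated
#'   observations?
#' @param seed Integer seed; identical seeds give bit-identical
#'   populations.
#' @return A `generator_config`.
#' @export
generator_config <- function(structure, emissions, n_initial_lineages = 10L,
                             experiment_time = NULL, max_generations = NULL,
                             censor = !is.null(experiment_time),
                             seed = NULL) {
  if (is.null(experiment_time) && is.null(max_generations)) {
    stop("set at least one of experiment_time / max_generations")
  }
  if (is.null(max_generations)) max_generations <- 10L
  if (structure$K != emissions$n_states) {
    stop("structure and emissions disagree on the number of states")
  }
  structure(list(structure = structure, emissions = emissions,
                 n_initial_lineages = as.integer(n_initial_lineages),
                 experiment_time = experiment_time,
                 max_generations = as.integer(max_generations),
                 censor = censor, seed = seed),
            class = "generator_config")
}

# full binary tree in heap order: cell i has parent floor(i/2)
heap_tree_skeleton <- function(g) {
  n <- 2L^g - 1L
  idx <- seq_len(n)
  parent <- ifelse(idx == 1L, NA_integer_, idx %/% 2L)
  daughters <- cbind(ifelse(2L * idx <= n, 2L * idx, NA_integer_),
                     ifelse(2L * idx + 1L <= n, 2L * idx + 1L, NA_integer_))
  generation <- floor(log2(idx)) + 1L
  list(n = n, parent = as.integer(parent), daughters = daughters,
       generation = as.integer(generation))
}

#' Sample a hidden-state tree
#'
#' Seeds a root state from `pi`, then expands a full binary tree to
#' `max_generations`, sampling each daughter's state independently from the
#' mother's row of `T`. Observations are left empty; see
#' [attach_emissions()].
#'
#' @param config A [generator_config()].
#' @param lineage_id Label for the new tree.
#' @param condition Condition label.
#' @return A `lineage_tree` with `true_state` set and all observations
#'   missing.
#' @export
generate_state_tree <- function(config, lineage_id = "lineage-1",
                                condition = "control") {
  if (!is.null(config$seed)) set.seed(config$seed)
  sk <- heap_tree_skeleton(config$max_generations)
  K <- config$structure$K
  st <- integer(sk$n)
  st[1] <- sample.int(K, 1, prob = config$structure$pi)
  if (sk$n > 1) {
    for (i in 2:sk$n) {
      st[i] <- sample.int(K, 1, prob = config$structure$T[st[sk$parent[i]], ])
    }
  }
  obs <- normalize_obs(data.frame(row.names = seq_len(sk$n)), sk$n)
  obs$true_state <- st
  new_lineage_tree(cell_id = as.character(seq_len(sk$n) - 1L),
                   parent = sk$parent, daughters = sk$daughters,
                   generation = sk$generation, obs = obs,
                   condition = condition, lineage_id = lineage_id)
}

#' Sample observations onto a state tree
#'
#' Draws each cell's fate(s) from the Bernoulli and duration(s) from the
#' gamma distribution of its true state. A cell that dies at the end of a
#' phase has no later-phase observation, and its entire progeny is marked
#' unobserved (all fields missing).
#'
#' @param tree A `lineage_tree` with `true_state` set.
#' @param emissions An [emission_model()].
#' @param condition Condition index into the emission parameter columns.
#' @param seed Optional seed.
#' @return The tree with observations filled in.
#' @export
attach_emissions <- function(tree, emissions, condition = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_cells(tree)
  st <- tree$obs$true_state
  if (anyNA(st)) stop("tree has cells without true_state; generate states first")
  obs <- tree$obs
  n_phases <- emissions$schema$n_phases
  dead <- rep(FALSE, n)      # cell's subtree below it is unobservable
  unobserved <- rep(FALSE, n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (!is.na(p) && dead[p]) {
      unobserved[i] <- TRUE
      dead[i] <- TRUE
      next
    }
    par <- emissions$params[[st[i]]]
    died <- FALSE
    for (ph in seq_len(n_phases)) {
      suf <- if (ph == 1L) "g1" else "g2"
      dur <- stats::rgamma(1, shape = par$shape[ph],
                           scale = par$scale[ph, condition])
      fate <- stats::rbinom(1, 1, par$bern[ph, condition])
      obs[[paste0("dur_", suf)]][i] <- dur
      obs[[paste0("cens_", suf)]][i] <- 0L
      obs[[paste0("fate_", suf)]][i] <- fate
      if (fate == 0) { died <- TRUE; break }   # no later-phase observation
    }
    dead[i] <- died
  }
  obs$observed <- !unobserved
  for (cc in setdiff(OBS_COLS, c("observed", "true_state"))) {
    obs[[cc]][unobserved] <- NA
  }
  tree$obs <- obs
  tree
}

# cumulative birth time of each cell (hours since experiment start);
# NA below dead/unobserved cells
birth_times <- function(tree, n_phases) {
  n <- n_cells(tree)
  bt <- rep(NA_real_, n)
  bt[1] <- 0
  life <- tree$obs$dur_g1
  if (n_phases == 2L) life <- life + tree$obs$dur_g2
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (!is.na(p) && !is.na(bt[p]) && !is.na(life[p])) bt[i] <- bt[p] + life[p]
  }
  bt
}

#' Clip a lineage to a finite experiment window
#'
#' Cells born at or after `experiment_time` become unobserved placeholders;
#' a cell whose phase straddles the end of the window keeps the in-window
#' span as a right-censored duration, loses the (unseen) fate of that
#' phase and any later phase, and its progeny becomes unobserved.
#'
#' @param tree A `lineage_tree` with observations attached.
#' @param experiment_time Window length in hours (`Inf` leaves the tree
#'   unchanged).
#' @param n_phases Number of phases in the observation schema.
#' @return The censored tree.
#' @export
apply_time_censorship <- function(tree, experiment_time, n_phases = 2L) {
  if (!is.finite(experiment_time)) return(tree)
  n <- n_cells(tree)
  bt <- birth_times(tree, n_phases)
  obs <- tree$obs
  newly_unobs <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!obs$observed[i]) next
    if (is.na(bt[i])) next
    if (bt[i] >= experiment_time) {
      newly_unobs[i] <- TRUE
      next
    }
    t_end <- bt[i] + obs$dur_g1[i]
    if (!is.na(obs$dur_g1[i]) && t_end > experiment_time) {
      obs$dur_g1[i] <- experiment_time - bt[i]
      obs$cens_g1[i] <- 1L
      obs$fate_g1[i] <- NA_real_
      if (n_phases == 2L) {
        obs$dur_g2[i] <- NA_real_; obs$cens_g2[i] <- NA_integer_
        obs$fate_g2[i] <- NA_real_
      }
    } else if (n_phases == 2L && !is.na(obs$dur_g2[i]) &&
               t_end + obs$dur_g2[i] > experiment_time) {
      obs$dur_g2[i] <- experiment_time - t_end
      obs$cens_g2[i] <- 1L
      obs$fate_g2[i] <- NA_real_
    }
  }
  # unobservability propagates down the tree
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (!is.na(p)) {
      if (newly_unobs[p]) newly_unobs[i] <- TRUE
      # a parent censored mid-phase never produced in-window daughters
      if (obs$observed[p] &&
          ((!is.na(obs$cens_g1[p]) && obs$cens_g1[p] == 1L) ||
           (n_phases == 2L && !is.na(obs$cens_g2[p]) && obs$cens_g2[p] == 1L))) {
        newly_unobs[i] <- TRUE
      }
    }
  }
  for (cc in setdiff(OBS_COLS, c("observed", "true_state"))) {
    obs[[cc]][newly_unobs] <- NA
  }
  obs$observed <- obs$observed & !newly_unobs
  tree$obs <- obs
  tree
}

# drop cells whose parent is already unobserved; the first unobserved
# boundary cells stay, so every remaining cell has 0 or 2 daughters and
# the likelihood is unchanged (dropped rows contribute log 1 = 0)
prune_unobserved_tails <- function(tree) {
  n <- n_cells(tree)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (!is.na(p) && (!tree$obs$observed[p] || !keep[p])) keep[i] <- FALSE
  }
  if (all(keep)) return(tree)
  idx <- which(keep)
  newpos <- rep(NA_integer_, n); newpos[idx] <- seq_along(idx)
  parent <- ifelse(is.na(tree$parent[idx]), NA_integer_,
                   newpos[tree$parent[idx]])
  daughters <- matrix(NA_integer_, length(idx), 2)
  for (j in seq_along(idx)) {
    d <- tree$daughters[idx[j], ]
    if (!is.na(d[1]) && keep[d[1]]) {
      daughters[j, ] <- c(newpos[d[1]], newpos[d[2]])
    }
  }
  obs <- tree$obs[idx, , drop = FALSE]
  rownames(obs) <- NULL
  new_lineage_tree(tree$cell_id[idx], as.integer(parent), daughters,
                   tree$generation[idx], obs, tree$condition, tree$lineage_id)
}

#' Generate a synthetic lineage population
#'
#' Draws `n_initial_lineages` independent trees: hidden states from the
#' transition structure, observations from the per-state emissions, then
#' (if configured) experiment-window censorship. Subtrees lying entirely
#' below an unobserved cell are dropped; the first unobserved boundary
#' cells remain as placeholders, so trees stay binary.
#'
#' @param config A [generator_config()].
#' @param condition Condition label for every lineage.
#' @param condition_index Column of the emission parameters to draw from.
#' @param lineage_prefix Prefix for lineage ids.
#' @return A `lineage_population` with `true_state` set on every cell.
#' @export
generate_population <- function(config, condition = "control",
                                condition_index = 1L,
                                lineage_prefix = "sim") {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL   # one stream for the whole population
  lineages <- lapply(seq_len(config$n_initial_lineages), function(i) {
    tr <- generate_state_tree(cfg_noseed,
                              lineage_id = sprintf("%s-%03d", lineage_prefix, i),
                              condition = condition)
    tr <- attach_emissions(tr, config$emissions, condition = condition_index)
    if (config$censor && !is.null(config$experiment_time)) {
      tr <- apply_time_censorship(tr, config$experiment_time,
                                  config$emissions$schema$n_phases)
    }
    prune_unobserved_tails(tr)
  })
  lineage_population(lineages, config$emissions$schema,
                     conditions = condition)
}

#' Benchmark generator presets
#'
#' Printed benchmark parameter sets: the two-state presets use
#' `T = [[0.9, 0.1], [0.1, 0.9]]` with `pi` its stationary distribution
#' `[0.5, 0.5]`; the five-state preset uses the printed 5 x 5 transition
#' matrix and initial probabilities with a 96 h experiment window and up to
#' 5 generations. Emission parameter tables are synthetic stand-ins shipped
#' in `inst/extdata/preset-emissions-synthetic.json` (see that file's
#' comment), chosen to emulate lapatinib-treated AU565-like phenotypes.
#'
#' @param name One of `"two_state_lifetime"`, `"two_state_phase"`,
#'   `"five_state_phase"`.
#' @param n_initial_lineages Breadth of the generated population.
#' @param seed Seed stored in the config.
#' @param censor Apply the 96 h window? Defaults to `TRUE`.
#' @param max_generations Generation cap (default 5).
#' @return A [generator_config()].
#' @export
preset <- function(name = c("two_state_phase", "two_state_lifetime",
                            "five_state_phase"),
                   n_initial_lineages = 10L, seed = NULL, censor = TRUE,
                   max_generations = 5L) {
  name <- match.arg(name)
  tbl <- preset_emission_table(name)
  if (name == "five_state_phase") {
    T_mat <- matrix(c(0.60, 0.10, 0.10, 0.10, 0.10,
                      0.05, 0.80, 0.05, 0.05, 0.05,
                      0.01, 0.10, 0.70, 0.09, 0.10,
                      0.10, 0.10, 0.05, 0.70, 0.05,
                      0.10, 0.10, 0.05, 0.05, 0.70),
                    5, 5, byrow = TRUE)
    # the printed initial probabilities sum to 0.98 (rounding); normalize
    pi <- c(0.13, 0.33, 0.16, 0.18, 0.18)
    pi <- pi / sum(pi)
  } else {
    T_mat <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
    pi <- stationary_distribution(T_mat)
  }
  generator_config(
    structure = transition_structure(pi, T_mat),
    emissions = tbl,
    n_initial_lineages = n_initial_lineages,
    experiment_time = if (censor) 96 else NULL,
    max_generations = max_generations,
    censor = censor,
    seed = seed
  )
}

# load a preset emission table (single condition) from package data
preset_emission_table <- function(name) {
  path <- system.file("extdata", "preset-emissions-synthetic.json",
                      package = "lineagehmm")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entry <- doc[[name]]
  if (is.null(entry)) stop("unknown preset: ", name)
  schema <- obs_schema(entry$schema)
  params <- lapply(entry$states, function(s) {
    state_emission_params(bern = matrix(unlist(s$bern), ncol = 1),
                          shape = unlist(s$shape),
                          scale = matrix(unlist(s$scale), ncol = 1))
  })
  emission_model(params, schema)
}
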