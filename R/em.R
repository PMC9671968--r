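#' Initial-probability M-step estimate
#'
#' Maximum-likelihood estimate of `pi`: the mean posterior state
#' distribution over root cells.
#'
#' @param root_posteriors `n_roots x K` matrix of root posterior rows.
#' @return Length-K probability vector summing to 1.
#' @export
estimate_pi <- function(root_posteriors) {
  rp <- rbind(root_posteriors)
  if (nrow(rp) < 1) stop("at least one root posterior is required")
  p <- colMeans(rp)
  p / sum(p)
}

#' Transition-matrix M-step estimate
#'
#' Prevalence of each mother-to-daughter transition across all lineage
#' trees: summed joint posterior transition weights `xi`, row-normalized.
#' A state with no posterior mass among mothers gets a uniform row (with a
#' warning) so that model sweeps over generous K complete.
#'
#' @param xi List (per lineage) of `K x K x n` arrays of pairwise posterior
#'   transition weights; slice `[, , i]` belongs to the pair (mother of
#'   cell i, cell i) and is NA for roots. See [e_step()].
#' @param gamma List of posterior matrices from the same E-step (used only
#'   for dimensions; the row sums of `xi` already carry the denominators).
#' @return K x K row-stochastic matrix.
#' @export
estimate_T <- function(xi, gamma = NULL) {
  if (is.array(xi)) xi <- list(xi)
  K <- dim(xi[[1]])[1]
  num <- matrix(0, K, K)
  for (x in xi) {
    n <- dim(x)[3]
    for (i in seq_len(n)) {
      sl <- x[, , i]
      if (!anyNA(sl)) num <- num + sl
    }
  }
  den <- rowSums(num)
  empty <- den <= 0
  if (any(empty)) {
    warning(sprintf("state(s) %s have no transition mass; row(s) reset to uniform",
                    paste(which(empty), collapse = ", ")), call. = FALSE)
    num[empty, ] <- 1 / K
    den[empty] <- 1
  }
  num / den
}

# zero out masked rows of per-lineage log-EL matrices
apply_mask <- function(logEL, mask) {
  if (is.null(mask)) return(logEL)
  for (li in seq_along(logEL)) {
    m <- mask[[li]]
    if (any(m)) logEL[[li]][m, ] <- 0
  }
  logEL
}

#' Expectation step over a population
#'
#' Runs the upward and downward recursions on every lineage, producing the
#' per-cell posterior state matrix `gamma`, the pairwise transition
#' posteriors `xi` and the observed-data log-likelihood at the current
#' parameters. Masked cells (cross-validation) have their emission
#' likelihood set to 1 for every state, so their states are inferred purely
#' from relatives.
#'
#' @param population A `lineage_population`.
#' @param structure A [transition_structure()].
#' @param emissions An [emission_model()].
#' @param mask Optional list of per-lineage logical vectors marking masked
#'   cells.
#' @return List with `gamma` (list of `n x K` matrices), `xi` (list of
#'   `K x K x n` arrays, NA slice for roots), and `loglik`.
#' @export
e_step <- function(population, structure, emissions, mask = NULL) {
  logEL <- apply_mask(compute_EL(population, emissions), mask)
  K <- structure$K
  gamma <- vector("list", length(population$lineages))
  xi <- vector("list", length(population$lineages))
  ll <- 0
  for (li in seq_along(population$lineages)) {
    tr <- population$lineages[[li]]
    lk <- tree_links(tr)
    MSD <- cpp_msd(lk$parent, structure$pi, structure$T)
    up <- cpp_upward(lk$parent, lk$daughters, logEL[[li]], MSD, structure$T)
    g <- cpp_downward(lk$parent, up$beta, up$beta_pc, MSD, structure$T)
    gamma[[li]] <- g
    xi[[li]] <- cpp_xi(lk$parent, g, up$beta, up$beta_pc, MSD, structure$T)
    ll <- ll + sum(log(up$NF) + up$shift)
  }
  list(gamma = gamma, xi = xi, loglik = ll)
}

# pooled per-cell observations and condition indices for the M-step,
# computed once per fit
pool_observations <- function(population) {
  list(obs = do.call(rbind, lapply(population$lineages, `[[`, "obs")),
       ci = unlist(lapply(population$lineages, function(tr) {
         rep(match(tr$condition, population$conditions), n_cells(tr))
       })))
}

# default fallback parameters for a state that lost all its posterior mass
fallback_params <- function(schema, n_cond) {
  state_emission_params(bern = matrix(0.5, schema$n_phases, n_cond),
                        shape = rep(2, schema$n_phases),
                        scale = matrix(10, schema$n_phases, n_cond))
}

#' Maximization step
#'
#' Re-estimates `pi` (mean root posterior), `T` (pooled transition
#' prevalence across all conditions) and the emission parameters: fate
#' probabilities as weighted means per condition, durations by the
#' censorship-corrected gamma fit with one shape per state/phase shared
#' across conditions (and optionally non-decreasing scales along the
#' condition order). Masked cells enter every sum with weight exactly 0.
#'
#' @param population A `lineage_population`.
#' @param gamma,xi E-step outputs (see [e_step()]).
#' @param ordered Enforce non-decreasing gamma scales along the condition
#'   order?
#' @param mask Optional masked-cell list (see [e_step()]).
#' @param fixed_T Optional matrix; when given, the transition matrix is
#'   frozen at this value (used by the no-inheritance baseline).
#' @param prev Optional previous [emission_model()] used as warm start and
#'   as fallback for states with no posterior mass.
#' @param pooled Optional precomputed observation pool (internal cache).
#' @return List with `structure` and `emissions`.
#' @export
m_step <- function(population, gamma, xi, ordered = FALSE, mask = NULL,
                   fixed_T = NULL, prev = NULL, pooled = NULL) {
  schema <- population$schema
  K <- ncol(gamma[[1]])
  conds <- population$conditions
  C <- length(conds)

  g_eff <- gamma
  xi_eff <- xi
  if (!is.null(mask)) {
    for (li in seq_along(g_eff)) {
      m <- mask[[li]]
      if (any(m)) {
        g_eff[[li]][m, ] <- 0
        tr <- population$lineages[[li]]
        for (i in which(m)) {
          xi_eff[[li]][, , i] <- NA_real_            # pair (parent, masked i)
          ds <- tr$daughters[i, ]
          for (d in ds[!is.na(ds)]) xi_eff[[li]][, , d] <- NA_real_
        }
      }
    }
  }

  root_rows <- matrix(vapply(g_eff, function(g) g[1, ], numeric(K)),
                      ncol = K, byrow = TRUE)
  keep_roots <- rowSums(root_rows) > 0
  pi_hat <- estimate_pi(root_rows[keep_roots, , drop = FALSE])
  T_hat <- if (is.null(fixed_T)) estimate_T(xi_eff) else fixed_T
  structure_hat <- transition_structure(pi_hat, T_hat)

  if (is.null(pooled)) pooled <- pool_observations(population)
  obs_all <- pooled$obs
  ci_all <- pooled$ci
  W <- do.call(rbind, g_eff)                       # total cells x K
  usable <- obs_all$observed
  if (!is.null(mask)) usable <- usable & !unlist(mask)

  params <- vector("list", K)
  for (k in seq_len(K)) {
    w <- W[, k]
    bern <- matrix(NA_real_, schema$n_phases, C)
    shape <- numeric(schema$n_phases)
    scale <- matrix(NA_real_, schema$n_phases, C)
    ok <- TRUE
    for (ph in seq_len(schema$n_phases)) {
      suf <- if (ph == 1L) "g1" else "g2"
      fate <- obs_all[[paste0("fate_", suf)]]
      dur <- obs_all[[paste0("dur_", suf)]]
      cens <- obs_all[[paste0("cens_", suf)]]
      for (cc in seq_len(C)) {
        sel <- usable & ci_all == cc & !is.na(fate)
        bern[ph, cc] <- tryCatch(
          fit_bernoulli_weighted(fate[sel], w[sel]),
          error = function(e) NA_real_)
      }
      groups <- lapply(seq_len(C), function(cc) {
        sel <- usable & ci_all == cc & !is.na(dur)
        list(durations = dur[sel],
             censor_flags = !is.na(cens[sel]) & cens[sel] == 1L,
             weights = w[sel])
      })
      init <- if (!is.null(prev)) {
        list(shape = prev$params[[k]]$shape[ph],
             scales = prev$params[[k]]$scale[ph, ])
      }
      fit <- tryCatch(fit_gamma_shared_shape(groups, ordered = ordered,
                                             init = init),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(bern[ph, ])) { ok <- FALSE; break }
      shape[ph] <- fit$shape
      scale[ph, ] <- fit$scales
    }
    params[[k]] <- if (ok) {
      state_emission_params(pmin(pmax(bern, 0), 1), shape, scale)
    } else if (!is.null(prev)) {
      warning(sprintf("state %d has no estimable emissions; keeping previous parameters", k),
              call. = FALSE)
      prev$params[[k]]
    } else {
      warning(sprintf("state %d has no estimable emissions; using fallback parameters", k),
              call. = FALSE)
      fallback_params(schema, C)
    }
  }
  list(structure = structure_hat,
       emissions = emission_model(params, schema))
}

# flat Dirichlet (concentration 1) soft state assignments per cell
dirichlet_init <- function(population, K) {
  lapply(population$lineages, function(tr) {
    n <- n_cells(tr)
    g <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    g / rowSums(g)
  })
}

# deterministic duration-ranked soft assignment: cells split into K
# quantile bins of their first observed duration. Complements the random
# Dirichlet restarts: when states differ strongly in duration, random
# responsibilities can leave every restart at the symmetric fixed point
# (all states fitting the pooled distribution), which this start escapes.
ranked_init <- function(population, K, mask = NULL) {
  durs <- unlist(lapply(population$lineages, function(tr) {
    d <- tr$obs$dur_g1
    ifelse(is.na(d), tr$obs$dur_g2, d)
  }))
  if (!is.null(mask)) durs[unlist(mask)] <- NA  # held-out cells stay unseen
  if (all(is.na(durs))) return(NULL)
  qs <- stats::quantile(durs, probs = seq(0, 1, length.out = K + 1),
                        na.rm = TRUE)
  qs[1] <- -Inf; qs[K + 1] <- Inf
  bin_all <- cut(durs, qs, labels = FALSE)
  offset <- 0L
  lapply(population$lineages, function(tr) {
    n <- n_cells(tr)
    bins <- bin_all[offset + seq_len(n)]
    offset <<- offset + n
    g <- matrix(0.1 / max(K - 1, 1), n, K)
    hit <- !is.na(bins)
    g[hit, ] <- 0.1 / max(K - 1, 1)
    g[cbind(which(hit), bins[hit])] <- 0.9
    g[!hit, ] <- 1 / K
    if (K == 1) g[] <- 1
    g / rowSums(g)
  })
}

init_xi_from_gamma <- function(population, gamma) {
  K <- ncol(gamma[[1]])
  lapply(seq_along(gamma), function(li) {
    tr <- population$lineages[[li]]
    n <- n_cells(tr)
    x <- array(NA_real_, c(K, K, n))
    if (n > 1) {
      for (i in 2:n) {
        x[, , i] <- outer(gamma[[li]][tr$parent[i], ], gamma[[li]][i, ])
      }
    }
    x
  })
}

#' Fit the lineage tree HMM by Baum-Welch expectation-maximization
#'
#' Alternates the tree E-step ([e_step()]) and M-step ([m_step()]) from a
#' random per-cell Dirichlet soft assignment until the relative
#' log-likelihood improvement falls below `tol` or `max_iter` is reached.
#' `pi` and `T` are shared across all conditions; emissions are
#' condition-specific with shared gamma shapes. Among `n_restarts`
#' independent initializations the highest-likelihood fit is returned.
#'
#' @param population A `lineage_population`.
#' @param K Number of hidden states (>= 1).
#' @param seed Integer seed for the Dirichlet initializations.
#' @param tol Relative log-likelihood convergence threshold.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Independent random initializations.
#' @param ordered Enforce dose-ordered gamma scales (multi-condition fits).
#' @param mask Optional list of per-lineage logical vectors; masked cells
#'   contribute likelihood 1 everywhere and weight 0 to every M-step sum.
#' @param uniform_T Freeze the transition matrix at `1/K` (no-inheritance
#'   baseline).
#' @return A `thmm_fit`: `structure`, `emissions`, `gamma` (per-lineage
#'   posteriors), `viterbi_states` (per-lineage, 1-based), `loglik`,
#'   `loglik_trace`, `n_iterations`, `converged`.
#' @export
baum_welch <- function(population, K, seed = NULL, tol = 1e-6,
                       max_iter = 200L, n_restarts = 3L, ordered = FALSE,
                       mask = NULL, uniform_T = FALSE) {
  stopifnot(K >= 1, length(population$lineages) >= 1)
  fixed_T <- if (uniform_T) matrix(1 / K, K, K) else NULL
  pooled <- pool_observations(population)
  ranked <- if (K > 1) ranked_init(population, K, mask)
  best <- NULL
  for (r in seq_len(n_restarts + !is.null(ranked))) {
    if (!is.null(seed)) set.seed(seed + r - 1L)
    g0 <- if (r > n_restarts) ranked else dirichlet_init(population, K)
    x0 <- init_xi_from_gamma(population, g0)
    ms <- m_step(population, g0, x0, ordered = ordered, mask = mask,
                 fixed_T = fixed_T, pooled = pooled)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    es <- NULL
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      es <- e_step(population, ms$structure, ms$emissions, mask = mask)
      trace <- c(trace, es$loglik)
      if (is.finite(ll_prev) &&
          abs(es$loglik - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- es$loglik
      ms <- m_step(population, es$gamma, es$xi, ordered = ordered,
                   mask = mask, fixed_T = fixed_T, prev = ms$emissions,
                   pooled = pooled)
    }
    cand <- list(structure = ms$structure, emissions = ms$emissions,
                 gamma = es$gamma, loglik = es$loglik, loglik_trace = trace,
                 n_iterations = it, converged = converged)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  logEL <- apply_mask(compute_EL(population, best$emissions), mask)
  best$viterbi_states <- lapply(seq_along(population$lineages), function(li) {
    viterbi(population$lineages[[li]], logEL[[li]], best$structure)$states
  })
  best$K <- K
  class(best) <- "thmm_fit"
  best
}

#' @export
print.thmm_fit <- function(x, ...) {
  cat(sprintf("<thmm_fit> K = %d | loglik = %.3f | %d iteration(s)%s\n",
              x$K, x$loglik, x$n_iterations,
              if (x$converged) " (converged)" else ""))
  cat("pi:", signif(x$structure$pi, 4), "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the transition structure, emission parameters, log-likelihood and
#' per-cell Viterbi states (keyed by lineage and cell id).
#'
#' @param fit A `thmm_fit`.
#' @param population The population the fit was computed on.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @export
write_fit_json <- function(fit, population, path = NULL) {
  states <- lapply(seq_along(population$lineages), function(li) {
    tr <- population$lineages[[li]]
    stats::setNames(as.list(fit$viterbi_states[[li]]), tr$cell_id)
  })
  names(states) <- vapply(population$lineages, `[[`, "", "lineage_id")
  doc <- list(
    K = fit$K,
    pi = fit$structure$pi,
    T = fit$structure$T,
    emissions = jsonlite::fromJSON(write_emissions_json(fit$emissions),
                                   simplifyVector = TRUE),
    loglik = fit$loglik,
    converged = fit$converged,
    viterbi_states = states
  )
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
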