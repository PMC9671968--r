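#' Independent parameter count of a K-state lineage HMM
#'
#' `(K - 1)` free initial probabilities, `K (K - 1)` free transition
#' entries (rows sum to 1), and per state and phase one shared gamma shape
#' plus, per condition, one Bernoulli and one gamma scale parameter.
#'
#' @param K Number of hidden states.
#' @param schema An [obs_schema()].
#' @param n_conditions Number of treatment conditions fit jointly.
#' @return Integer degrees of freedom.
#' @export
#' @examples
#' degrees_of_freedom(2, obs_schema("phase_specific"), 4)  # 39
degrees_of_freedom <- function(K, schema, n_conditions = 1L) {
  stopifnot(K >= 1)
  as.integer((K - 1) + K * (K - 1) +
               K * schema$n_phases * (1 + 2 * n_conditions))
}

#' Bayesian information criterion
#'
#' @param loglik Observed-data log-likelihood of the fit.
#' @param dof Degrees of freedom (see [degrees_of_freedom()]).
#' @param n_cells Number of observed (non-masked) cells.
#' @return `dof * log(n_cells) - 2 * loglik`; lower is better.
#' @export
bic <- function(loglik, dof, n_cells) {
  dof * log(n_cells) - 2 * loglik
}

#' Sweep the number of hidden states and rank by BIC
#'
#' Fits the model for each candidate K with [baum_welch()] and reports
#' log-likelihood, degrees of freedom, BIC and BIC normalized so its
#' minimum is zero. `best_k` is the (smallest, on ties) K attaining the
#' minimum BIC.
#'
#' @param population A `lineage_population`.
#' @param k_range Integer vector of candidate state counts.
#' @param seed Seed forwarded to each fit.
#' @param ... Further arguments passed to [baum_welch()] (e.g. `tol`,
#'   `max_iter`, `n_restarts`, `ordered`).
#' @return A `selection_report`: data frame with columns `K`, `loglik`,
#'   `dof`, `bic`, `normalized_bic`, plus attribute `best_k`.
#' @export
sweep_states <- function(population, k_range, seed = NULL, ...) {
  stopifnot(length(k_range) >= 1)
  n_obs <- n_cells(population, observed_only = TRUE)
  C <- length(population$conditions)
  rows <- lapply(k_range, function(K) {
    fit <- baum_welch(population, K, seed = seed, ...)
    dof <- degrees_of_freedom(K, population$schema, C)
    data.frame(K = K, loglik = fit$loglik, dof = dof,
               bic = bic(fit$loglik, dof, n_obs))
  })
  rep_df <- do.call(rbind, rows)
  rep_df$normalized_bic <- rep_df$bic - min(rep_df$bic)
  attr(rep_df, "best_k") <- rep_df$K[which.min(rep_df$bic)]
  class(rep_df) <- c("selection_report", "data.frame")
  rep_df
}

#' @export
print.selection_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("best_k:", attr(x, "best_k"), "\n")
  invisible(x)
}

#' Write a state-number selection report
#'
#' @param report A `selection_report` from [sweep_states()].
#' @param path Output path; `.json` writes JSON, anything else a tidy CSV.
#' @export
write_selection_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(table = as.data.frame(report),
                              best_k = attr(report, "best_k")),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

# stratified-by-condition mask over observed cells
draw_mask <- function(population, mask_fraction) {
  conds <- vapply(population$lineages, `[[`, "", "condition")
  mask <- lapply(population$lineages, function(tr) rep(FALSE, n_cells(tr)))
  for (cond in unique(conds)) {
    lis <- which(conds == cond)
    pool <- do.call(rbind, lapply(lis, function(li) {
      obs <- population$lineages[[li]]$obs$observed
      if (!any(obs)) return(NULL)
      cbind(li, which(obs))
    }))
    if (is.null(pool)) next
    n_mask <- round(mask_fraction * nrow(pool))
    if (n_mask >= nrow(pool)) {
      stop("mask_fraction would mask every observed cell of condition ", cond)
    }
    if (n_mask > 0) {
      pick <- pool[sample.int(nrow(pool), n_mask), , drop = FALSE]
      for (r in seq_len(nrow(pick))) {
        mask[[pick[r, 1]]][pick[r, 2]] <- TRUE
      }
    }
  }
  mask
}

#' Held-out log-likelihood by relative-informed masking
#'
#' Randomly masks a fraction of observed cells in each condition, fits the
#' model on the remaining cells (masked cells keep likelihood 1 for every
#' state, so their posteriors are inferred purely from relatives), and then
#' scores the masked cells' actual observations under their inferred
#' posterior state weights. With `uniform_T = TRUE` the transition matrix
#' is frozen at `1/K` (no-inheritance baseline).
#'
#' @param population A `lineage_population`.
#' @param K Number of hidden states.
#' @param mask_fraction Fraction of observed cells to hold out per
#'   condition (default 0.2).
#' @param seed Seed for the mask draw and the fit.
#' @param uniform_T Freeze transitions at `1/K`?
#' @param mask Optional precomputed mask (list of per-lineage logical
#'   vectors), e.g. to score several candidate K on the same held-out
#'   split; overrides `mask_fraction`.
#' @param ... Further arguments to [baum_welch()].
#' @return Scalar held-out log-likelihood, with attributes `fit` and
#'   `mask`.
#' @export
crossvalidate <- function(population, K, mask_fraction = 0.2, seed = NULL,
                          uniform_T = FALSE, mask = NULL, ...) {
  stopifnot(mask_fraction >= 0, mask_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) {
    mask <- if (mask_fraction == 0) {
      lapply(population$lineages, function(tr) rep(FALSE, n_cells(tr)))
    } else {
      draw_mask(population, mask_fraction)
    }
  }
  fit <- baum_welch(population, K, seed = seed, mask = mask,
                    uniform_T = uniform_T, ...)
  logEL_full <- compute_EL(population, fit$emissions)  # unmasked likelihoods
  held <- 0
  for (li in seq_along(population$lineages)) {
    m <- mask[[li]]
    if (any(m)) {
      # log of the posterior-mixture likelihood of each masked cell:
      # log sum_k gamma_n(k) P(x_n | z_n = k), summed over masked cells
      g <- fit$gamma[[li]][m, , drop = FALSE]
      ll <- logEL_full[[li]][m, , drop = FALSE]
      shift <- apply(ll, 1, max)
      held <- held + sum(log(rowSums(g * exp(ll - shift))) + shift)
    }
  }
  attr(held, "fit") <- fit
  attr(held, "mask") <- mask
  held
}

#' Held-out log-likelihood across candidate state counts
#'
#' Draws one stratified 20% mask and scores every candidate K on that same
#' held-out split (pairing the comparisons), as in state-number selection
#' by cross-validation.
#'
#' @inheritParams crossvalidate
#' @param k_values Candidate state counts.
#' @return Named numeric vector of held-out log-likelihoods (one per K),
#'   with the mask as attribute.
#' @export
crossvalidate_sweep <- function(population, k_values, mask_fraction = 0.2,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mask <- draw_mask(population, mask_fraction)
  out <- vapply(k_values, function(K) {
    as.numeric(crossvalidate(population, K, seed = seed, mask = mask, ...))
  }, 0)
  names(out) <- k_values
  attr(out, "mask") <- mask
  out
}

#' Smallest K at which a criterion curve plateaus
#'
#' Plateau rule used for cross-validation state-number selection: the
#' smallest K whose held-out log-likelihood is within `tol` (relative, of
#' the maximum's magnitude) of the maximum over the sweep.
#'
#' @param k_values Candidate state counts.
#' @param values Held-out log-likelihood per K.
#' @param tol Relative closeness to the maximum (default 0.01).
#' @return The selected K.
#' @export
select_k_plateau <- function(k_values, values, tol = 0.01) {
  stopifnot(length(k_values) == length(values))
  best <- max(values)
  ok <- values >= best - tol * abs(best)
  k_values[which(ok)[1]]
}
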