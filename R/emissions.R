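#' Per-state emission parameters
#'
#' Each hidden state emits, per cell-cycle phase, a Bernoulli fate outcome
#' (progression/division vs death) and a gamma-distributed duration in
#' hours. The gamma shape is shared across treatment conditions within a
#' state (phenotype distributions keep their form, treatments rescale
#' them); the Bernoulli probability and the gamma scale are
#' condition-specific.
#'
#' @param bern `n_phases x n_conditions` matrix (or vector, recycled) of
#'   progression probabilities in `[0, 1]`.
#' @param shape Length-`n_phases` vector of gamma shapes `k > 0`.
#' @param scale `n_phases x n_conditions` matrix (or vector) of gamma
#'   scales `theta > 0` (hours).
#' @return A `state_emission_params` object.
#' @export
state_emission_params <- function(bern, shape, scale) {
  shape <- as.numeric(shape)
  n_phases <- length(shape)
  bern <- matrix(as.numeric(bern), nrow = n_phases)
  scale <- matrix(as.numeric(scale), nrow = n_phases)
  if (ncol(bern) != ncol(scale)) {
    stop("bern and scale must cover the same number of conditions")
  }
  if (any(bern < 0 | bern > 1)) stop("bern probabilities must lie in [0, 1]")
  if (any(shape <= 0) || any(scale <= 0)) stop("shape and scale must be > 0")
  structure(list(bern = bern, shape = shape, scale = scale),
            class = "state_emission_params")
}

#' Emission model over K states
#'
#' @param params List of `K` [state_emission_params()] objects (one per
#'   hidden state), all with the same phase and condition counts.
#' @param schema An [obs_schema()]; `n_phases` must match the parameters.
#' @return An `emission_model` with fields `schema`, `params`, `n_states`,
#'   `n_conditions`.
#' @export
emission_model <- function(params, schema = obs_schema("phase_specific")) {
  stopifnot(length(params) >= 1)
  for (p in params) {
    if (!inherits(p, "state_emission_params")) {
      stop("params must be state_emission_params objects")
    }
    if (length(p$shape) != schema$n_phases) {
      stop("parameter phase count does not match schema")
    }
  }
  ncond <- ncol(params[[1]]$bern)
  if (!all(vapply(params, function(p) ncol(p$bern), 0L) == ncond)) {
    stop("all states must cover the same conditions")
  }
  structure(list(schema = schema, params = params,
                 n_states = length(params), n_conditions = ncond),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf("<emission_model> %d state(s), %d condition(s), schema %s\n",
              x$n_states, x$n_conditions, x$schema$mode))
  invisible(x)
}

BERN_EPS <- 1e-6   # Bernoulli clip before logs
W_EPS <- 1e-10     # weights below this are dropped from estimation sums

#' Log-likelihood of one cell's observation under one state
#'
#' Observation components are independent given the state: observed fates
#' contribute a Bernoulli log-pmf, uncensored durations a gamma log-density,
#' right-censored durations a gamma log-survival (the observed span is a
#' lower bound on the true phase length). Missing components contribute 0,
#' and unobserved placeholder cells return exactly 0 (likelihood 1).
#'
#' @param obs One-row data frame (or list) with fields `fate_g1, dur_g1,
#'   cens_g1, fate_g2, dur_g2, cens_g2, observed`.
#' @param params A [state_emission_params()].
#' @param condition Condition index (column of the parameter matrices).
#' @return Scalar log-probability.
#' @export
observation_loglik <- function(obs, params, condition = 1L) {
  n_phases <- length(params$shape)
  if (!is.null(obs$observed) && !isTRUE(obs$observed[1])) return(0)
  ll <- 0
  for (ph in seq_len(n_phases)) {
    suf <- if (ph == 1L) "g1" else "g2"
    fate <- obs[[paste0("fate_", suf)]][1]
    dur <- obs[[paste0("dur_", suf)]][1]
    cens <- obs[[paste0("cens_", suf)]][1]
    if (!is.na(fate)) {
      p <- min(max(params$bern[ph, condition], BERN_EPS), 1 - BERN_EPS)
      ll <- ll + if (fate == 1) log(p) else log1p(-p)
    }
    if (!is.na(dur)) {
      if (dur < 0) stop("negative duration", call. = FALSE)
      k <- params$shape[ph]; th <- params$scale[ph, condition]
      ll <- ll + if (!is.na(cens) && cens == 1L) {
        stats::pgamma(dur, shape = k, scale = th, lower.tail = FALSE,
                      log.p = TRUE)
      } else {
        stats::dgamma(dur, shape = k, scale = th, log = TRUE)
      }
    }
  }
  ll
}

# vectorized per-lineage emission log-likelihood matrix (n cells x K)
lineage_logEL <- function(tree, model, cond_idx) {
  n <- n_cells(tree)
  K <- model$n_states
  out <- matrix(0, n, K)
  obs <- tree$obs
  live <- obs$observed
  for (ph in seq_len(model$schema$n_phases)) {
    suf <- if (ph == 1L) "g1" else "g2"
    fate <- obs[[paste0("fate_", suf)]]
    dur <- obs[[paste0("dur_", suf)]]
    cens <- obs[[paste0("cens_", suf)]]
    if (any(!is.na(dur) & dur < 0)) stop("negative duration", call. = FALSE)
    for (k in seq_len(K)) {
      p <- model$params[[k]]
      pb <- min(max(p$bern[ph, cond_idx], BERN_EPS), 1 - BERN_EPS)
      sel <- live & !is.na(fate)
      out[sel, k] <- out[sel, k] +
        ifelse(fate[sel] == 1, log(pb), log1p(-pb))
      shp <- p$shape[ph]; th <- p$scale[ph, cond_idx]
      sel <- live & !is.na(dur) & (is.na(cens) | cens == 0L)
      out[sel, k] <- out[sel, k] +
        stats::dgamma(dur[sel], shape = shp, scale = th, log = TRUE)
      sel <- live & !is.na(dur) & !is.na(cens) & cens == 1L
      out[sel, k] <- out[sel, k] +
        stats::pgamma(dur[sel], shape = shp, scale = th,
                      lower.tail = FALSE, log.p = TRUE)
    }
  }
  out
}

#' Emission log-likelihood matrices for a population
#'
#' @param population A `lineage_population`.
#' @param model An [emission_model()] sharing the population's schema.
#' @return A list (one `n_cells x K` matrix per lineage, in population
#'   order) of log-likelihoods; rows of unobserved cells are all zero.
#' @export
compute_EL <- function(population, model) {
  if (population$schema$mode != model$schema$mode) {
    stop("population and emission model use different observation schemas")
  }
  lapply(population$lineages, function(tr) {
    ci <- match(tr$condition, population$conditions)
    if (is.na(ci) || ci > model$n_conditions) {
      stop("condition ", tr$condition, " not covered by the emission model")
    }
    lineage_logEL(tr, model, ci)
  })
}

#' Weighted Bernoulli estimate
#'
#' State-assignment-weighted sample mean of binary outcomes, the M-step
#' estimator for fate probabilities.
#'
#' @param outcomes Binary vector (0/1), missing values excluded by caller.
#' @param weights Nonnegative weights, same length.
#' @return Probability in `[0, 1]`.
#' @export
fit_bernoulli_weighted <- function(outcomes, weights) {
  stopifnot(length(outcomes) == length(weights))
  keep <- weights > W_EPS
  if (!any(keep) || sum(weights[keep]) <= 0) {
    stop("all weights are zero; Bernoulli parameter not estimable",
         call. = FALSE)
  }
  p <- sum(weights[keep] * outcomes[keep]) / sum(weights[keep])
  min(max(p, 0), 1)
}

# weighted censored gamma log-likelihood; durations/censor/weights vectors
gamma_cens_loglik <- function(shape, scale, dur, cens, w) {
  unc <- !cens
  ll <- 0
  if (any(unc)) {
    ll <- ll + sum(w[unc] * stats::dgamma(dur[unc], shape = shape,
                                          scale = scale, log = TRUE))
  }
  if (any(cens)) {
    ll <- ll + sum(w[cens] * stats::pgamma(dur[cens], shape = shape,
                                           scale = scale,
                                           lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

SHAPE_LO <- 0.01; SHAPE_HI <- 100
SCALE_LO <- 0.01; SCALE_HI <- 1e4

# weighted uncensored gamma MLE: profile out scale, solve the shape score
# equation log(k) - digamma(k) = log(mean) - mean(log) by uniroot
gamma_mle_uncensored <- function(dur, w) {
  sw <- sum(w)
  mbar <- sum(w * dur) / sw
  lbar <- sum(w * log(dur)) / sw
  s <- log(mbar) - lbar
  if (s <= 0) return(c(shape = SHAPE_HI, scale = max(mbar / SHAPE_HI, SCALE_LO)))
  f <- function(k) log(k) - digamma(k) - s
  lo <- SHAPE_LO; hi <- SHAPE_HI
  if (f(lo) < 0) return(c(shape = lo, scale = min(max(mbar / lo, SCALE_LO), SCALE_HI)))
  if (f(hi) > 0) return(c(shape = hi, scale = min(max(mbar / hi, SCALE_LO), SCALE_HI)))
  k <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  c(shape = k, scale = min(max(mbar / k, SCALE_LO), SCALE_HI))
}

#' Censorship-corrected weighted gamma fit
#'
#' Maximum-likelihood gamma parameters where uncensored durations enter
#' through the density and right-censored durations through the survival
#' function, each weighted by state assignment. Without censored
#' observations this reduces to the weighted gamma MLE (solved from the
#' profile score equation); with censoring the 2-parameter likelihood is
#' maximized numerically in log-parameter space.
#'
#' @param durations Positive durations (hours).
#' @param censor_flags Logical or 0/1; `TRUE`/1 marks right-censored
#'   observations.
#' @param weights Nonnegative weights (default 1).
#' @param init Optional `c(shape, scale)` warm start.
#' @return Named vector `c(shape, scale)`.
#' @export
fit_gamma_censored <- function(durations, censor_flags = NULL, weights = NULL,
                               init = NULL) {
  dur <- as.numeric(durations)
  n <- length(dur)
  cens <- if (is.null(censor_flags)) rep(FALSE, n) else as.logical(censor_flags)
  cens[is.na(cens)] <- FALSE
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  keep <- !is.na(dur) & w > W_EPS
  dur <- pmax(dur[keep], 1e-9); cens <- cens[keep]; w <- w[keep]
  if (!length(dur) || !any(!cens)) {
    stop("gamma parameters unidentifiable: no uncensored observation with positive weight",
         call. = FALSE)
  }
  if (!any(cens)) return(gamma_mle_uncensored(dur, w))
  start <- if (!is.null(init)) init else gamma_mle_uncensored(dur[!cens], w[!cens])
  nll <- function(par) {
    -gamma_cens_loglik(exp(par[1]), exp(par[2]), dur, cens, w)
  }
  fit <- stats::optim(log(pmin(pmax(start, c(SHAPE_LO, SCALE_LO)),
                               c(SHAPE_HI, SCALE_HI))),
                      nll, method = "L-BFGS-B",
                      lower = log(c(SHAPE_LO, SCALE_LO)),
                      upper = log(c(SHAPE_HI, SCALE_HI)),
                      control = list(factr = 1e4))
  c(shape = unname(exp(fit$par[1])), scale = unname(exp(fit$par[2])))
}

#' Shared-shape (optionally scale-ordered) gamma fit across conditions
#'
#' Fits one gamma shape common to all treatment conditions and a scale per
#' condition, maximizing the pooled censorship-corrected weighted
#' log-likelihood. With `ordered = TRUE` the scales are constrained to be
#' non-decreasing along the condition order (higher doses slow a state down,
#' never speed it up); the constraint is enforced exactly through an
#' increment parameterization `theta_c = theta_1 + sum(increments)`.
#'
#' @param groups List with one element per condition, each a list with
#'   `durations`, `censor_flags`, `weights`.
#' @param ordered Enforce non-decreasing scales along the condition order?
#' @param init Optional list `list(shape =, scales =)` warm start.
#' @return List with `shape` (scalar) and `scales` (one per condition).
#' @export
fit_gamma_shared_shape <- function(groups, ordered = FALSE, init = NULL) {
  C <- length(groups)
  gs <- lapply(groups, function(g) {
    dur <- as.numeric(g$durations)
    cens <- if (is.null(g$censor_flags)) rep(FALSE, length(dur)) else
      as.logical(g$censor_flags)
    cens[is.na(cens)] <- FALSE
    w <- if (is.null(g$weights)) rep(1, length(dur)) else as.numeric(g$weights)
    keep <- !is.na(dur) & w > W_EPS
    list(dur = pmax(dur[keep], 1e-9), cens = cens[keep], w = w[keep])
  })
  for (g in gs) {
    if (!length(g$dur) || !any(!g$cens)) {
      stop("gamma parameters unidentifiable in at least one condition group",
           call. = FALSE)
    }
  }
  if (C == 1L) {
    f <- fit_gamma_censored(gs[[1]]$dur, gs[[1]]$cens, gs[[1]]$w,
                            init = if (!is.null(init)) c(init$shape, init$scales))
    return(list(shape = unname(f["shape"]), scales = unname(f["scale"])))
  }
  if (is.null(init)) {
    singles <- lapply(gs, function(g) {
      fit_gamma_censored(g$dur, g$cens, g$w)
    })
    init <- list(shape = mean(vapply(singles, `[[`, 0, "shape")),
                 scales = vapply(singles, `[[`, 0, "scale"))
  }
  sc0 <- pmin(pmax(init$scales, SCALE_LO), SCALE_HI)
  if (ordered) sc0 <- cummax(sc0)  # feasible start
  # par = (log shape, log theta_1, log increments...) if ordered,
  # else (log shape, log thetas)
  to_scales <- function(par) {
    if (ordered) cumsum(c(exp(par[2]), exp(par[-(1:2)]))) else exp(par[-1])
  }
  par0 <- if (ordered) {
    # floor the initial increments: a log-increment started too close to
    # zero has a vanishing gradient and never moves
    c(log(init$shape), log(sc0[1]),
      log(pmax(diff(sc0), 0.05 * mean(sc0))))
  } else c(log(init$shape), log(sc0))
  nll <- function(par) {
    k <- exp(par[1]); sc <- to_scales(par)
    if (any(!is.finite(sc)) || any(sc > SCALE_HI * 10) ||
        k < SHAPE_LO / 2 || k > SHAPE_HI * 2 || any(sc < SCALE_LO / 2)) {
      return(1e12)
    }
    -sum(vapply(seq_len(C), function(ci) {
      gamma_cens_loglik(k, sc[ci], gs[[ci]]$dur, gs[[ci]]$cens, gs[[ci]]$w)
    }, 0))
  }
  lower <- c(log(SHAPE_LO), rep(log(1e-8), length(par0) - 1))
  lower[2] <- log(SCALE_LO)
  upper <- c(log(SHAPE_HI), rep(log(SCALE_HI), length(par0) - 1))
  fit <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e4, maxit = 500))
  # Nelder-Mead polish from the better of start and L-BFGS-B result; the
  # increment parameterization can leave L-BFGS-B short near the ordering
  # boundary
  best0 <- if (fit$value <= nll(par0)) fit$par else par0
  pol <- stats::optim(best0, nll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  par_best <- if (pol$value < fit$value) pol$par else fit$par
  sc <- to_scales(par_best)
  list(shape = exp(par_best[1]), scales = pmin(pmax(sc, SCALE_LO), SCALE_HI))
}

#' Serialize emission parameters to JSON
#'
#' Writes a document keyed `state -> phase -> {bern, shape, scale}` with
#' per-condition lists for `bern` and `scale`.
#'
#' @param model An [emission_model()].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @export
write_emissions_json <- function(model, path = NULL) {
  doc <- lapply(seq_len(model$n_states), function(k) {
    p <- model$params[[k]]
    lapply(seq_len(model$schema$n_phases), function(ph) {
      list(bern = as.numeric(p$bern[ph, ]), shape = p$shape[ph],
           scale = as.numeric(p$scale[ph, ]))
    })
  })
  names(doc) <- paste0("state_", seq_len(model$n_states))
  if (is.null(path)) {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
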