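#' Build the transition dataset of an occupancy series
#'
#' Enumerates consecutive pairs of *observed* survey years and keeps, under
#' the default `drop_gaps` policy, only pairs one survey interval apart —
#' pairs spanning an unsurveyed year (e.g. a missing census) are dropped so
#' all models are compared on identical one-year transitions. Within a
#' retained pair only patches observed at both endpoints contribute.
#'
#' @param series an [occupancy_series()].
#' @param gap_policy currently only `"drop_gaps"`.
#' @return An object of class `transition_dataset`: a list with `pairs`
#'   (each a list `year_t`, `year_u`, `from`, `to`, `patch_idx`, `gap`) and
#'   `n_transitions`, the total count of patch-level transitions.
#' @export
build_transitions <- function(series, gap_policy = c("drop_gaps")) {
  gap_policy <- match.arg(gap_policy)
  obs <- observed_years(series)
  if (length(obs) < 2) stop("need >= 2 observed years to build transitions")
  pairs <- list()
  n <- 0L
  for (p in seq_len(length(obs) - 1)) {
    yt <- obs[p]; yu <- obs[p + 1]
    gap <- (yu - yt) > 1L
    if (gap) next  # drop_gaps
    from <- series$states[, as.character(yt)]
    to <- series$states[, as.character(yu)]
    keep <- which(!is.na(from) & !is.na(to))
    if (length(keep) == 0) next
    pairs[[length(pairs) + 1L]] <- list(year_t = yt, year_u = yu,
                                        from = from[keep], to = to[keep],
                                        patch_idx = keep, gap = gap)
    n <- n + length(keep)
  }
  # pooled transition counts: sufficient statistics when colonization and
  # extinction probabilities are constant across patches and years (PRM)
  cnt <- c(n00 = 0L, n01 = 0L, n10 = 0L, n11 = 0L)
  for (pair in pairs) {
    cnt["n00"] <- cnt[["n00"]] + sum(pair$from == 0 & pair$to == 0)
    cnt["n01"] <- cnt[["n01"]] + sum(pair$from == 0 & pair$to == 1)
    cnt["n10"] <- cnt[["n10"]] + sum(pair$from == 1 & pair$to == 0)
    cnt["n11"] <- cnt[["n11"]] + sum(pair$from == 1 & pair$to == 1)
  }
  structure(list(pairs = pairs, n_transitions = n, counts = cnt),
            class = "transition_dataset")
}

#' @export
print.transition_dataset <- function(x, ...) {
  cat(sprintf("<transition_dataset> %d year pairs, %d patch transitions\n",
              length(x$pairs), x$n_transitions))
  invisible(x)
}

PROB_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Log-likelihood of a transition dataset under a patch occupancy model
#'
#' The occupancy process is a Markov chain: conditional on the year-t
#' state, patches transition independently, an empty patch colonizing with
#' probability `C_i(t)` and an occupied one going extinct with probability
#' `E_i(t)`. The log-likelihood sums, over retained year pairs and patches,
#' `log C_i(t)` for 0->1, `log(1 - C_i(t))` for 0->0, `log E_i(t)` for
#' 1->0 and `log(1 - E_i(t))` for 1->1, with `C_i(t)` constant (PRM) or
#' connectivity-driven from the year-t state (LM), and `E_i(t)` from the
#' (possibly rescue-modified) extinction function. Probabilities are
#' clamped to `[1e-12, 1 - 1e-12]` so logs stay finite.
#'
#' @param spec a [model_spec()].
#' @param params a [spom_params()] valid for `spec`.
#' @param data a [build_transitions()] dataset.
#' @param network the [patch_network()] the series was observed on
#'   (required for the LM family).
#' @param base_extinction passed to [extinction_prob()].
#' @return The log-likelihood (a finite scalar).
#' @export
transition_loglik <- function(spec, params, data, network = NULL,
                              base_extinction = "eq5") {
  check_params(spec, params)
  if (!all(is.finite(params))) stop("parameters must be finite")
  if (spec$family == "LM" && is.null(network))
    stop("the Levins model requires the patch network")

  if (spec$family == "PRM") {
    # constant probabilities: the pooled transition counts are sufficient
    Cit <- colonization_prob(spec, params)
    Eit <- extinction_prob(spec, params, Cit, base_extinction = base_extinction)
    Cit <- clamp_prob(Cit); Eit <- clamp_prob(Eit)
    cnt <- data$counts
    return(cnt[["n01"]] * log(Cit) + cnt[["n00"]] * log1p(-Cit) +
           cnt[["n10"]] * log(Eit) + cnt[["n11"]] * log1p(-Eit))
  }

  # LM family: one kernel matrix and one matrix product per evaluation,
  # shared across year pairs; probability formulas inlined over whole
  # matrices (identical to colonization_prob()/extinction_prob(), which
  # the test suite cross-checks against a brute-force oracle)
  K <- exp(-params[["alpha"]] * network$dist)
  diag(K) <- 0
  np <- n_patches(network)
  P <- length(data$pairs)
  Fmat <- matrix(0, np, P)
  for (p in seq_len(P)) Fmat[data$pairs[[p]]$patch_idx, p] <- data$pairs[[p]]$from
  Smat <- K %*% Fmat
  Cmat <- -expm1(-params[["y"]] * Smat)
  R <- if (spec$rescue) params[["R"]] else 1
  Emat <- if (!spec$rescue && base_extinction == "constant")
    matrix(params[["E"]], np, P) else params[["E"]] * (1 - Cmat)^R
  Cmat <- clamp_prob(Cmat); Emat <- clamp_prob(Emat)
  ll <- 0
  for (p in seq_len(P)) {
    pair <- data$pairs[[p]]
    Cit <- Cmat[pair$patch_idx, p]
    Eit <- Emat[pair$patch_idx, p]
    empty <- pair$from == 0
    ll <- ll +
      sum(log(Cit[empty & pair$to == 1])) +
      sum(log1p(-Cit[empty & pair$to == 0])) +
      sum(log(Eit[!empty & pair$to == 0])) +
      sum(log1p(-Eit[!empty & pair$to == 1]))
  }
  ll
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`; the correction requires
#' `n > k + 1` and vanishes as `n` grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (here: patch-level transition count).
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop(sprintf("AICc undefined for n = %d, k = %d (need n > k + 1)", n, k))
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# parameter transforms: unconstrained optimizer scale <-> natural scale
to_unconstrained <- function(p, names) {
  vapply(names, function(nm)
    if (nm %in% c("C", "E")) stats::qlogis(p[[nm]]) else log(p[[nm]]), numeric(1))
}

from_unconstrained <- function(theta, names) {
  # plogis/exp guarantee the parameter ranges, so skip spom_params()
  # validation (extreme thetas can hit probability 0/1 exactly in floating
  # point; the likelihood clamp handles those)
  p <- ifelse(names %in% c("C", "E"), stats::plogis(theta), exp(theta))
  names(p) <- names
  structure(p, class = "spom_params")
}

# Deterministic multistart grid on the transformed scale; at most
# `n_starts` rows, picked at evenly spaced indices of the full grid.
start_grid <- function(spec, n_starts) {
  vals <- list(C = stats::qlogis(c(0.1, 0.5)), E = stats::qlogis(c(0.1, 0.5)),
               alpha = log(c(1 / 5, 1 / 50)), y = log(c(0.1, 2)),
               R = log(c(0.5, 2)))
  grid <- as.matrix(expand.grid(vals[param_names(spec)]))
  if (nrow(grid) > n_starts)
    grid <- grid[round(seq(1, nrow(grid), length.out = n_starts)), , drop = FALSE]
  grid
}

#' Optimizer settings for model fitting
#'
#' Derivative-free Nelder-Mead search from a deterministic grid of starting
#' points spread over the transformed parameter box (logit scale for the
#' probabilities C and E, log scale for alpha, y and R). Multiple starts
#' guard against the multimodality the LM likelihood can show in
#' (alpha, y).
#'
#' @param n_starts number of deterministic starts (default 8).
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 8L, reltol = 1e-8, maxit = 500L) {
  structure(list(n_starts = as.integer(n_starts), reltol = reltol,
                 maxit = as.integer(maxit)), class = "fit_control")
}

#' Maximum-likelihood fit of one model to a transition dataset
#'
#' Maximizes [transition_loglik()] over the model's parameters on
#' transformed scales, from multiple deterministic starting points, and
#' returns the MLE with its log-likelihood and AICc. A fit whose best
#' transformed parameter sits at an extreme value (|theta| > 12, i.e. a
#' probability within ~6e-6 of 0/1 or a rate outside [e-12, e12]) is
#' flagged `boundary = TRUE` (likely non-identifiable data, e.g. a series
#' with no colonization events).
#'
#' @param spec a [model_spec()].
#' @param data a [build_transitions()] dataset with
#'   `n_transitions >= k + 2`.
#' @param network the [patch_network()] (required for LM).
#' @param control a [fit_control()].
#' @param base_extinction passed to [transition_loglik()].
#' @return An object of class `fit_result`: `spec`, `mle`, `loglik`, `k`,
#'   `n`, `aicc`, `converged`, `boundary`, `n_restarts_used`.
#' @export
fit_model <- function(spec, data, network = NULL, control = fit_control(),
                      base_extinction = "eq5") {
  nm <- param_names(spec)
  if (data$n_transitions < spec$k + 2)
    stop(sprintf("too few transitions (%d) to fit %s (k = %d)",
                 data$n_transitions, spec$label, spec$k))
  negll <- function(theta) {
    p <- from_unconstrained(theta, nm)
    -transition_loglik(spec, p, data, network, base_extinction = base_extinction)
  }
  starts <- start_grid(spec, control$n_starts)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], negll, method = "Nelder-Mead",
                   control = list(reltol = control$reltol, maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  mle <- from_unconstrained(best$par, nm)
  structure(
    list(spec = spec, mle = mle, loglik = -best$value, k = spec$k,
         n = data$n_transitions,
         aicc = aicc(-best$value, spec$k, data$n_transitions),
         converged = any_conv, boundary = any(abs(best$par) > 12),
         n_restarts_used = nrow(starts)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: logL = %.3f, AICc = %.3f (k = %d, n = %d)%s\n",
              x$spec$label, x$loglik, x$aicc, x$k, x$n,
              if (x$boundary) " [boundary]" else ""))
  print(round(unclass(x$mle), 5))
  invisible(x)
}

MODEL_LABELS <- c("LM", "PRM", "LM+R", "PRM+R")

all_model_specs <- function() {
  specs <- list(model_spec("LM"), model_spec("PRM"),
                model_spec("LM", rescue = TRUE), model_spec("PRM", rescue = TRUE))
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

#' Four-way AICc model selection for one street-species metapopulation
#'
#' Fits LM, PRM, LM+R and PRM+R to the series and picks the model with the
#' smallest AICc. Exact ties (|delta AICc| < 1e-9, which arise because the
#' rescue models nest the base models) are broken toward the model with
#' fewer parameters, then lexicographically by label.
#'
#' @param series an [occupancy_series()] with at least one presence record.
#' @param network the matching [patch_network()].
#' @param control a [fit_control()].
#' @param species optional species label carried into the result.
#' @param base_extinction passed to the fits.
#' @return An object of class `selection_result`: `street`, `species`,
#'   `fits` (named list of four [fit_model()] results), `aicc_table`
#'   (label, k, loglik, aicc, delta_aicc), `best`.
#' @export
select_model <- function(series, network, control = fit_control(),
                         species = NA_character_, base_extinction = "eq5") {
  if (sum(series$states, na.rm = TRUE) == 0)
    stop(sprintf("series '%s' has no presence records: nothing to fit",
                 series$network_ref))
  data <- build_transitions(series)
  fits <- lapply(all_model_specs(), function(sp)
    tryCatch(fit_model(sp, data, network, control, base_extinction),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no model could be fitted")
  if (!all(ok))
    warning(sprintf("model(s) %s failed to fit; selecting among the rest",
                    paste(names(fits)[!ok], collapse = ", ")))
  fits <- fits[ok]
  if (any(!vapply(fits, `[[`, logical(1), "converged")))
    warning("some fits did not converge; selection proceeds over all attempts")
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, `[[`, integer(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    row.names = NULL
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tied <- which(tab$delta_aicc < 1e-9)
  best <- tied[order(tab$k[tied], tab$model[tied])][1]
  structure(
    list(street = series$network_ref, species = species, fits = fits,
         aicc_table = tab, best = tab$model[best]),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> street '%s'%s: best = %s\n", x$street,
              if (is.na(x$species)) "" else sprintf(", species '%s'", x$species),
              x$best))
  print(transform(x$aicc_table, loglik = round(loglik, 3),
                  aicc = round(aicc, 3), delta_aicc = round(delta_aicc, 3)))
  invisible(x)
}

#' Run model selection for every series of a synthetic study
#'
#' @param study a [generate_study()] result.
#' @param control a [fit_control()].
#' @param verbose print one line per completed pair?
#' @return A list of [select_model()] results, one per street-species pair,
#'   named `street|species`.
#' @export
select_all <- function(study, control = fit_control(), verbose = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  out <- list()
  for (key in names(study$series)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sel <- select_model(study$series[[key]], study$networks[[parts[1]]],
                        control = control, species = parts[2])
    out[[key]] <- sel
    if (verbose) message(sprintf("%s -> %s", key, sel$best))
  }
  out
}
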