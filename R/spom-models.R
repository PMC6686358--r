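#' Spatial patch network of one street
#'
#' A `patch_network` holds the planar layout of the habitat patches (tree
#' bases) of a single street: patch identifiers, projected coordinates in
#' meters, and the pairwise Euclidean distance matrix `d_ij` that feeds the
#' dispersal kernel. Coordinates are assumed already projected; no geodesy
#' is performed.
#'
#' @param patch_ids character or integer vector of unique patch labels.
#' @param x,y numeric coordinates in meters, same length as `patch_ids`.
#' @param street_id single street label.
#' @return An object of class `patch_network` with fields `street_id`,
#'   `patch_ids`, `coords` (n x 2 matrix) and `dist` (n x n symmetric
#'   matrix, zero diagonal).
#' @examples
#' net <- patch_network(1:3, x = c(0, 10, 20), y = c(0, 0, 0), street_id = "A")
#' net$dist
#' @export
patch_network <- function(patch_ids, x, y, street_id = "street") {
  patch_ids <- as.character(patch_ids)
  if (anyDuplicated(patch_ids)) stop("duplicate patch_ids")
  if (length(x) != length(patch_ids) || length(y) != length(patch_ids))
    stop("coordinates must match patch_ids in length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  coords <- cbind(x_m = as.numeric(x), y_m = as.numeric(y))
  rownames(coords) <- patch_ids
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(patch_ids, patch_ids)
  structure(
    list(street_id = as.character(street_id)[1], patch_ids = patch_ids,
         coords = coords, dist = d),
    class = "patch_network"
  )
}

#' @export
print.patch_network <- function(x, ...) {
  cat(sprintf("<patch_network> street '%s': %d patches, extent %.1f m\n",
              x$street_id, length(x$patch_ids), max(x$dist)))
  invisible(x)
}

n_patches <- function(network) length(network$patch_ids)

#' Binary occupancy time series for one street
#'
#' Presence/absence of one species in every patch of one street across the
#' survey years. Entries are 0 (absent), 1 (present) or `NA` (unobserved,
#' e.g. a year skipped by the survey). Years are calendar labels, possibly
#' non-contiguous, so survey gaps are detectable from the data.
#'
#' @param states numeric matrix, patches x years, entries in \{0, 1, NA\}.
#' @param years integer vector of calendar-year labels, one per column.
#' @param network_ref street label the series belongs to.
#' @param patch_ids optional patch labels (defaults to rownames of `states`).
#' @return An object of class `occupancy_series`.
#' @export
occupancy_series <- function(states, years, network_ref = "street",
                             patch_ids = rownames(states)) {
  states <- as.matrix(states)
  years <- as.integer(years)
  if (length(years) != ncol(states))
    stop("length(years) must equal ncol(states)")
  if (length(years) < 2) stop("an occupancy series needs >= 2 survey years")
  if (anyDuplicated(years)) stop("duplicate year labels")
  if (is.unsorted(years)) stop("years must be increasing")
  bad <- !(is.na(states) | states == 0 | states == 1)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid occupancy value %s at patch %d, year %d (must be 0, 1 or NA)",
                 format(states[bad][1]), idx[1], years[idx[2]]))
  }
  if (is.null(patch_ids)) patch_ids <- as.character(seq_len(nrow(states)))
  dimnames(states) <- list(as.character(patch_ids), years)
  structure(
    list(network_ref = as.character(network_ref)[1], years = years,
         states = states),
    class = "occupancy_series"
  )
}

#' @export
print.occupancy_series <- function(x, ...) {
  obs <- observed_years(x)
  cat(sprintf("<occupancy_series> street '%s': %d patches, years %d-%d (%d surveyed)\n",
              x$network_ref, nrow(x$states), min(x$years), max(x$years), length(obs)))
  invisible(x)
}

observed_years <- function(series) {
  series$years[colSums(!is.na(series$states)) > 0]
}

#' Specify one of the four patch occupancy models
#'
#' The model family is either `"LM"` (Levins: colonization driven by
#' connectivity to occupied patches within the street) or `"PRM"`
#' (propagule rain: constant colonization from an external source), each
#' optionally extended with a rescue effect on extinction. Parameter counts
#' are PRM: 2 (C, E); LM: 3 (alpha, y, E); a rescue effect adds R.
#'
#' @param family `"LM"` or `"PRM"`.
#' @param rescue logical; add the rescue-effect parameter R?
#' @return An object of class `model_spec` with fields `family`, `rescue`,
#'   `label` (one of "LM", "PRM", "LM+R", "PRM+R") and `k` (parameter count).
#' @examples
#' model_spec("PRM")            # 2 parameters
#' model_spec("LM", rescue = TRUE)  # 4 parameters
#' @export
model_spec <- function(family = c("LM", "PRM"), rescue = FALSE) {
  family <- match.arg(family)
  stopifnot(is.logical(rescue), length(rescue) == 1L, !is.na(rescue))
  k <- if (family == "PRM") 2L else 3L
  if (rescue) k <- k + 1L
  structure(
    list(family = family, rescue = rescue,
         label = paste0(family, if (rescue) "+R" else ""), k = k),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d parameters: %s)\n", x$label, x$k,
              paste(param_names(x), collapse = ", ")))
  invisible(x)
}

#' @rdname model_spec
#' @param spec a `model_spec`.
#' @return `param_names()` returns the names of the free parameters of `spec`.
#' @export
param_names <- function(spec) {
  nm <- if (spec$family == "PRM") c("C", "E") else c("alpha", "y", "E")
  if (spec$rescue) nm <- c(nm, "R")
  nm
}

#' Parameter vector for a patch occupancy model
#'
#' Bundles and validates the parameters of one model: `C`, the yearly
#' colonization probability (PRM only); `E`, the intrinsic yearly extinction
#' probability; `alpha`, the inverse mean dispersal distance in 1/m (LM
#' only; `1/alpha` is the mean dispersal distance); `y`, the dimensionless
#' colonization scaling of the street (LM only); and `R >= 0`, the rescue
#' strength (rescue models only).
#'
#' @param C,E,alpha,y,R numeric scalars; supply those required by the model.
#' @return A named numeric vector of class `spom_params`.
#' @examples
#' spom_params(C = 0.3, E = 0.2)                  # PRM
#' spom_params(alpha = 0.1, y = 1, E = 0.2, R = 2)  # LM+R
#' @export
spom_params <- function(C = NULL, E = NULL, alpha = NULL, y = NULL, R = NULL) {
  p <- c(C = C, E = E, alpha = alpha, y = y, R = R)
  if (!all(is.finite(p))) stop("parameters must be finite numbers")
  chk <- function(name, ok, msg) {
    if (name %in% names(p) && !ok(p[[name]]))
      stop(sprintf("parameter %s %s (got %g)", name, msg, p[[name]]))
  }
  # closed interval: boundary rates (e.g. E = 0, no extinction) are valid
  # simulation settings; fitted values stay interior via the logit transform
  chk("C", function(v) v >= 0 && v <= 1, "must lie in [0, 1]")
  chk("E", function(v) v >= 0 && v <= 1, "must lie in [0, 1]")
  chk("alpha", function(v) v > 0, "must be > 0")
  chk("y", function(v) v > 0, "must be > 0")
  chk("R", function(v) v >= 0, "must be >= 0")
  structure(p, class = "spom_params")
}

check_params <- function(spec, params) {
  need <- param_names(spec)
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("model %s requires parameter(s): %s", spec$label,
                 paste(missing, collapse = ", ")))
  invisible(params)
}

#' Negative-exponential dispersal kernel
#'
#' `exp(-alpha * d)`: the probability weight with which a patch at distance
#' `d` meters contributes propagules. `1/alpha` is the mean dispersal
#' distance; at `alpha = 0` the kernel degenerates to the constant 1.
#'
#' @param d distance(s) in meters, `>= 0`; vectorized.
#' @param alpha inverse mean dispersal distance (1/m), `>= 0`.
#' @return Numeric in (0, 1], same length as `d`.
#' @examples
#' dispersal_kernel(100, 0.01)  # exp(-1)
#' @export
dispersal_kernel <- function(d, alpha) {
  if (any(d < 0)) stop("distance d must be >= 0")
  if (length(alpha) != 1L || alpha < 0) stop("alpha must be a scalar >= 0")
  exp(-alpha * d)
}

#' Connectivity of a patch to the occupied part of the street
#'
#' `S_i = sum_{j != i} O_j * exp(-alpha * d_ij)`: the occupancy-weighted sum
#' of distance-discounted contributions from every other patch. The focal
#' patch never contributes to itself, and an all-empty street has
#' connectivity 0 everywhere.
#'
#' @param occupancy 0/1 vector over patches (fully observed; `NA` is an error).
#' @param network a [patch_network()].
#' @param alpha inverse mean dispersal distance (1/m).
#' @param i focal patch index (or vector of indices; default all patches).
#' @return Numeric vector `S_i >= 0`, one value per requested index.
#' @export
connectivity <- function(occupancy, network, alpha, i = seq_len(n_patches(network))) {
  np <- n_patches(network)
  if (length(occupancy) != np)
    stop("occupancy length must equal the number of patches")
  if (anyNA(occupancy))
    stop("connectivity requires a fully observed occupancy state (no NA)")
  if (!all(occupancy %in% c(0, 1))) stop("occupancy entries must be 0 or 1")
  if (any(i < 1 | i > np)) stop("patch index out of range")
  K <- dispersal_kernel(network$dist[i, , drop = FALSE], alpha)
  # zero out the self-term (diagonal of the full matrix)
  K[cbind(seq_along(i), i)] <- 0
  as.numeric(K %*% occupancy)
}

#' Per-patch colonization probability
#'
#' Under the propagule rain model colonization is the constant `C`,
#' independent of within-street occupancy (external seed source). Under the
#' Levins model it is `1 - exp(-y * S_i)`, an increasing saturating function
#' of the connectivity `S_i`.
#'
#' @param spec a [model_spec()].
#' @param params a [spom_params()] valid for `spec`.
#' @param S_i connectivity value(s); required for the LM family, ignored for PRM.
#' @return Probability in `[0, 1)`, vectorized over `S_i`.
#' @export
colonization_prob <- function(spec, params, S_i = NULL) {
  check_params(spec, params)
  if (spec$family == "PRM") {
    n <- if (is.null(S_i)) 1L else length(S_i)
    return(rep(unname(params[["C"]]), n))
  }
  if (is.null(S_i)) stop("the Levins model requires connectivity S_i")
  if (any(S_i < 0)) stop("connectivity must be >= 0")
  -expm1(-params[["y"]] * S_i)
}

#' Per-patch extinction probability
#'
#' A single formula covers all four models: `E * (1 - C_it)^R`, where `C_it`
#' is the patch's colonization probability that year. Base models fix
#' `R = 1` (extinction is the intrinsic rate `E` times the probability the
#' patch was not colonized); rescue models free `R >= 0`, so `R = 1`
#' recovers the base model exactly and larger `R` means stronger rescue.
#' With `base_extinction = "constant"` the base models instead use the
#' fixed rate `E` alone.
#'
#' @param spec a [model_spec()].
#' @param params a [spom_params()] valid for `spec`.
#' @param C_it colonization probability(ies) in `[0, 1]`.
#' @param base_extinction for non-rescue models, `"eq5"` (default; the
#'   `E * (1 - C)` form) or `"constant"` (plain `E`).
#' @return Probability in `[0, E]`, vectorized over `C_it`.
#' @export
extinction_prob <- function(spec, params, C_it,
                            base_extinction = c("eq5", "constant")) {
  base_extinction <- match.arg(base_extinction)
  check_params(spec, params)
  if (any(C_it < 0 | C_it > 1)) stop("C_it must lie in [0, 1]")
  E <- params[["E"]]
  if (spec$rescue) {
    R <- params[["R"]]
    if (R < 0) stop("rescue strength R must be >= 0")
    E * (1 - C_it)^R
  } else if (base_extinction == "eq5") {
    E * (1 - C_it)
  } else {
    rep(E, length(C_it))
  }
}
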