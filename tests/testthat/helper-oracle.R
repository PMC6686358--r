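# Independent brute-force oracles, deliberately sharing no code with the
# package internals: explicit loops, no matrix algebra, no shared helpers.

# Log-likelihood of an occupancy matrix under one of the four models,
# looping over observed consecutive year pairs and patches.
oracle_loglik <- function(family, rescue, params, states, years, dmat,
                          base_extinction = "eq5") {
  eps <- 1e-12
  obs <- which(colSums(!is.na(states)) > 0)
  ll <- 0
  for (p in seq_along(obs)[-1]) {
    tcol <- obs[p - 1]; ucol <- obs[p]
    if (years[ucol] - years[tcol] != 1) next
    for (i in seq_len(nrow(states))) {
      from <- states[i, tcol]; to <- states[i, ucol]
      if (is.na(from) || is.na(to)) next
      if (family == "LM") {
        S <- 0
        for (j in seq_len(nrow(states))) {
          if (j != i && !is.na(states[j, tcol]) && states[j, tcol] == 1)
            S <- S + exp(-params$alpha * dmat[i, j])
        }
        C <- 1 - exp(-params$y * S)
      } else {
        C <- params$C
      }
      if (rescue) {
        E <- params$E * (1 - C)^params$R
      } else if (base_extinction == "constant") {
        E <- params$E
      } else {
        E <- params$E * (1 - C)
      }
      C <- min(max(C, eps), 1 - eps)
      E <- min(max(E, eps), 1 - eps)
      ll <- ll + if (from == 0 && to == 1) log(C)
            else if (from == 0) log(1 - C)
            else if (to == 0) log(E)
            else log(1 - E)
    }
  }
  ll
}

# Exhaustive grid search MLE for the PRM (C, E) likelihood, counting
# transitions by explicit loops.
oracle_prm_grid <- function(states, years, resolution = 0.001) {
  obs <- which(colSums(!is.na(states)) > 0)
  n01 <- n00 <- n10 <- n11 <- 0
  for (p in seq_along(obs)[-1]) {
    tcol <- obs[p - 1]; ucol <- obs[p]
    if (years[ucol] - years[tcol] != 1) next
    for (i in seq_len(nrow(states))) {
      from <- states[i, tcol]; to <- states[i, ucol]
      if (is.na(from) || is.na(to)) next
      if (from == 0 && to == 1) n01 <- n01 + 1
      else if (from == 0) n00 <- n00 + 1
      else if (to == 0) n10 <- n10 + 1
      else n11 <- n11 + 1
    }
  }
  g <- seq(resolution, 1 - resolution, by = resolution)
  grid <- expand.grid(C = g, E = g)
  Eeff <- grid$E * (1 - grid$C)
  ll <- n01 * log(grid$C) + n00 * log(1 - grid$C) +
        n10 * log(Eeff) + n11 * log(1 - Eeff)
  grid[which.max(ll), ]
}

# Random small fitting instance: a jittered linear street and an occupancy
# matrix drawn per-cell at random (not from any model), possibly with one
# unsurveyed year.
random_instance <- function(seed) {
  set.seed(seed)
  np <- sample(3:8, 1)
  ny <- sample(3:6, 1)
  net <- generate_network(np, spacing = sample(5:15, 1), jitter = 2,
                          seed = seed + 1000, street_id = paste0("rnd", seed))
  states <- matrix(rbinom(np * ny, 1, runif(1, 0.2, 0.8)), np, ny)
  years <- 2000L + seq_len(ny)
  if (ny >= 4 && runif(1) < 0.5) states[, sample(2:(ny - 1), 1)] <- NA
  list(net = net, series = occupancy_series(states, years,
                                            network_ref = net$street_id,
                                            patch_ids = net$patch_ids))
}

random_params <- function(spec, seed) {
  set.seed(seed)
  vals <- list(C = runif(1, 0.05, 0.9), E = runif(1, 0.05, 0.9),
               alpha = runif(1, 0.01, 0.5), y = runif(1, 0.1, 3),
               R = runif(1, 0.2, 3))
  do.call(spom_params, vals[param_names(spec)])
}
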