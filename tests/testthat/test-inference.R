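make_series <- function(states, years = NULL, net = NULL) {
  if (is.null(years)) years <- 2008L + seq_len(ncol(states))
  occupancy_series(states, years)
}

test_that("build_transitions enumerates one-year pairs and drops gap pairs", {
  states <- matrix(rbinom(100 * 7, 1, 0.5), 100, 7)
  states[, 5] <- NA  # 2013 unsurveyed
  td <- build_transitions(make_series(states, 2009:2015))
  expect_length(td$pairs, 4)
  expect_equal(vapply(td$pairs, `[[`, integer(1), "year_t"), c(2009L, 2010L, 2011L, 2014L))
  expect_equal(td$n_transitions, 400)
  expect_true(all(!vapply(td$pairs, `[[`, logical(1), "gap")))
  # counts are consistent with n_transitions
  expect_equal(sum(td$counts), 400)

  two <- build_transitions(make_series(matrix(rbinom(62, 1, 0.5), 31, 2)))
  expect_equal(two$n_transitions, 31)
  full <- build_transitions(make_series(matrix(rbinom(20 * 7, 1, 0.5), 20, 7)))
  expect_equal(full$n_transitions, 6 * 20)

  allna <- matrix(NA_real_, 5, 3); allna[, 1] <- 1
  expect_error(build_transitions(make_series(allna)), ">= 2 observed years")
})

test_that("aicc applies the small-sample correction", {
  expect_equal(aicc(-5, 2, 10), 10 + 4 + 12 / 7)
  expect_equal(aicc(0, 3, 5), 6 + 24)
  expect_equal(aicc(-5, 2, 1e7), 14, tolerance = 1e-5)  # approaches plain AIC
  expect_error(aicc(-5, 2, 3), "undefined")
})

test_that("PRM transition likelihood matches hand-computed single terms", {
  net <- patch_network("p1", x = 0, y = 0)
  prm <- model_spec("PRM")
  colonize <- build_transitions(occupancy_series(matrix(c(0, 1), 1, 2), 2009:2010))
  expect_equal(transition_loglik(prm, spom_params(C = 0.3, E = 0.5), colonize, net),
               log(0.3))
  persist <- build_transitions(occupancy_series(matrix(c(1, 1), 1, 2), 2009:2010))
  # survival prob is 1 - E(1 - C) = 0.65
  expect_equal(transition_loglik(prm, spom_params(C = 0.3, E = 0.5), persist, net),
               log(0.65))
})

test_that("transition likelihood equals the brute-force oracle on random instances", {
  specs <- list(model_spec("LM"), model_spec("PRM"),
                model_spec("LM", rescue = TRUE), model_spec("PRM", rescue = TRUE))
  n_checked <- 0
  for (seed in 1:24) {
    inst <- random_instance(seed)
    td <- build_transitions(inst$series)
    if (td$n_transitions == 0) next
    spec <- specs[[(seed %% 4) + 1]]
    params <- random_params(spec, seed + 500)
    for (mode in c("eq5", "constant")) {
      got <- transition_loglik(spec, params, td, inst$net, base_extinction = mode)
      want <- oracle_loglik(spec$family, spec$rescue, as.list(params),
                            inst$series$states, inst$series$years,
                            inst$net$dist, base_extinction = mode)
      expect_equal(got, want, tolerance = 1e-10)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("rescue fits nest the base fits in maximized likelihood", {
  net <- generate_network(40, spacing = 8, jitter = 1, seed = 21)
  sim <- simulate_series(net, model_spec("LM"),
                         spom_params(alpha = 0.1, y = 1, E = 0.25),
                         initial = rbinom(40, 1, 0.4), n_steps = 6, seed = 22)
  td <- build_transitions(sim)
  tol <- 1e-6  # optimizer tolerance, not a model property
  expect_gte(fit_model(model_spec("LM", rescue = TRUE), td, net)$loglik,
             fit_model(model_spec("LM"), td, net)$loglik - tol)
  expect_gte(fit_model(model_spec("PRM", rescue = TRUE), td, net)$loglik,
             fit_model(model_spec("PRM"), td, net)$loglik - tol)
})

test_that("the PRM MLE matches an exhaustive grid-search oracle", {
  net <- generate_network(150, spacing = 8, jitter = 1, seed = 31)
  sim <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0.2),
                         initial = rbinom(150, 1, 0.2), n_steps = 6, seed = 32)
  td <- build_transitions(sim)
  fit <- fit_model(model_spec("PRM"), td, net)
  ref <- oracle_prm_grid(sim$states, sim$years, resolution = 0.001)
  expect_lt(abs(fit$mle[["C"]] - ref$C), 2e-3)
  expect_lt(abs(fit$mle[["E"]] - ref$E), 2e-3)
  # and both land near the truth
  expect_lt(abs(fit$mle[["C"]] - 0.3), 0.05)
  expect_lt(abs(fit$mle[["E"]] - 0.2), 0.05)
  expect_true(fit$converged)
  expect_false(fit$boundary)
})

test_that("an informationless series drives C to the boundary and is flagged", {
  empty <- occupancy_series(matrix(0, 20, 4), 2009:2012)
  td <- build_transitions(empty)
  fit <- fit_model(model_spec("PRM"), td)
  expect_lt(fit$mle[["C"]], 1e-4)
  expect_true(fit$boundary)
})

test_that("the LM fit dominates the generating parameters in likelihood", {
  net <- generate_network(150, spacing = 8, jitter = 1, seed = 41)
  truth <- spom_params(alpha = 0.1, y = 1, E = 0.2)
  sim <- simulate_series(net, model_spec("LM"), truth,
                         initial = rbinom(150, 1, 0.3), n_steps = 6, seed = 42)
  td <- build_transitions(sim)
  fit <- fit_model(model_spec("LM"), td, net)
  expect_gte(fit$loglik, transition_loglik(model_spec("LM"), truth, td, net))
})

test_that("select_model picks the smallest AICc and breaks ties toward parsimony", {
  net <- generate_network(60, spacing = 8, jitter = 1, seed = 51)
  sim <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.4, E = 0.3),
                         initial = rbinom(60, 1, 0.3), n_steps = 6, seed = 52)
  sel <- select_model(sim, net, species = "sp")
  expect_setequal(sel$aicc_table$model, c("LM", "PRM", "LM+R", "PRM+R"))
  expect_equal(min(sel$aicc_table$delta_aicc), 0)
  expect_equal(sel$aicc_table$aicc[sel$aicc_table$model == sel$best],
               min(sel$aicc_table$aicc))
  allabs <- occupancy_series(matrix(0, 10, 3), 2009:2011)
  expect_error(select_model(allabs, generate_network(10, 8, seed = 1)),
               "no presence")
})

test_that("AICc ordering ignores patches unobserved in every year", {
  net <- generate_network(30, spacing = 8, jitter = 1, seed = 61)
  sim <- simulate_series(net, model_spec("LM"),
                         spom_params(alpha = 0.1, y = 1, E = 0.2),
                         initial = rbinom(30, 1, 0.4), n_steps = 5, seed = 62)
  sel <- select_model(sim, net, species = "sp")
  # augment with 5 never-observed patches (and matching network rows)
  aug_states <- rbind(sim$states, matrix(NA_real_, 5, ncol(sim$states)))
  aug_net <- patch_network(c(net$patch_ids, paste0("ghost", 1:5)),
                           x = c(net$coords[, 1], seq(500, 540, by = 10)),
                           y = c(net$coords[, 2], rep(0, 5)),
                           street_id = net$street_id)
  aug <- occupancy_series(aug_states, sim$years, network_ref = sim$network_ref,
                          patch_ids = aug_net$patch_ids)
  sel2 <- select_model(aug, aug_net, species = "sp")
  expect_equal(sel2$aicc_table$aicc, sel$aicc_table$aicc, tolerance = 1e-6)
  expect_equal(sel2$best, sel$best)
})
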