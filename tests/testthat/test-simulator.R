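test_that("generate_network lays patches on a line with the requested spacing", {
  net <- generate_network(3, spacing = 10, jitter = 0)
  expect_equal(net$dist[1, 2], 10)
  expect_equal(net$dist[1, 3], 20)
  expect_equal(generate_network(2, spacing = 5, jitter = 0)$dist[1, 2], 5)
  # jitter bound: nearest-neighbor distances stay in spacing +/- 2*jitter
  net2 <- generate_network(50, spacing = 8, jitter = 1, seed = 7)
  nn <- diff(sort(net2$coords[, 1]))
  expect_true(all(nn >= 6 & nn <= 10))
  # determinism
  expect_identical(generate_network(20, 8, jitter = 1, seed = 3)$coords,
                   generate_network(20, 8, jitter = 1, seed = 3)$coords)
  expect_error(generate_network(1, 8), "at least 2")
  expect_error(generate_network(5, 0), "spacing")
})

test_that("street-to-green-space distance is the smallest mean patch distance", {
  one <- patch_network("p", x = 0, y = 0)
  res <- street_distance_to_green_spaces(one, list(green_space("near", 30, 40),
                                                   green_space("far", 60, 80)))
  expect_equal(res$distance_m, 50)
  expect_equal(res$nearest, "near")
  two <- patch_network(1:2, x = c(0, 0), y = c(0, 20))
  expect_equal(street_distance_to_green_spaces(two, green_space("g", 0, 10))$distance_m, 10)
  three <- patch_network(1:3, x = c(0, 10, 20), y = c(0, 0, 0))
  expect_equal(street_distance_to_green_spaces(three, green_space("g", 0, 0))$distance_m, 10)
  expect_error(street_distance_to_green_spaces(three, list()), "at least one")
})

test_that("simulate_series follows the synchronous Markov chain rules", {
  net <- generate_network(30, spacing = 8, seed = 1)
  # absorbing empty state: certain extinction, no colonization
  dead <- simulate_series(net, model_spec("PRM"), spom_params(C = 0, E = 1),
                          initial = rep(1, 30), n_steps = 4, seed = 2)
  expect_equal(unname(dead$states[, -1]), matrix(0, 30, 4))
  # E = 0: occupancy is monotone non-decreasing patch-wise
  grow <- simulate_series(net, model_spec("LM"),
                          spom_params(alpha = 0.1, y = 1, E = 0),
                          initial = rep(c(1, 0), 15), n_steps = 5, seed = 3)
  expect_true(all(apply(grow$states, 1, function(r) all(diff(r) >= 0))))
  # determinism given a seed
  a <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0.2),
                       initial = rep(0, 30), n_steps = 6, seed = 11)
  b <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0.2),
                       initial = rep(0, 30), n_steps = 6, seed = 11)
  expect_identical(a$states, b$states)
  expect_error(simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0.2),
                               initial = rep(NA, 30), n_steps = 1), "NA")
})

test_that("one PRM step from empty colonizes a binomial fraction close to C", {
  net <- generate_network(1000, spacing = 8, seed = 5)
  sim <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.3, E = 0),
                         initial = rep(0, 1000), n_steps = 1, seed = 8)
  frac <- mean(sim$states[, 2])
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("LM cannot colonize an empty street (no external source)", {
  net <- generate_network(25, spacing = 8, seed = 2)
  sim <- simulate_series(net, model_spec("LM"),
                         spom_params(alpha = 0.1, y = 2, E = 0.2),
                         initial = rep(0, 25), n_steps = 10, seed = 4)
  expect_equal(sum(sim$states), 0)
})

test_that("apply_missing_years blanks columns but keeps the labels", {
  net <- generate_network(10, spacing = 8, seed = 1)
  sim <- simulate_series(net, model_spec("PRM"), spom_params(C = 0.4, E = 0.2),
                         initial = rep(0, 10), n_steps = 6, seed = 6,
                         start_year = 2009)
  gap <- apply_missing_years(sim, 2013)
  expect_true(all(is.na(gap$states[, "2013"])))
  expect_equal(gap$years, 2009:2015)
  expect_identical(apply_missing_years(sim, integer(0))$states, sim$states)
  expect_error(apply_missing_years(sim, 1999), "unknown year")
  # the transition builder sees the gap: 4 one-year pairs remain
  td <- build_transitions(gap)
  expect_equal(td$n_transitions, 4 * 10)
  # blanking the first year: transitions start at the first observed year
  first <- apply_missing_years(sim, 2009)
  expect_equal(build_transitions(first)$n_transitions, 5 * 10)
})

test_that("generate_study assembles the full design reproducibly", {
  small <- study_config(
    streets = data.frame(name = c("S1", "S2"), n_patches = c(10L, 12L),
                         patch_spacing_m = 8, green_space_distance_m = c(50, 120),
                         nearest_green_space = "park"),
    species = default_species()[c(1, 5), ],
    years = 2009:2012, missing_years = integer(0), rng_seed = 42L)
  st <- generate_study(small)
  expect_length(st$series, 4)
  expect_named(st$networks, c("S1", "S2"))
  expect_equal(nrow(st$street_covariates), 2)
  # bitwise-identical rerun
  st2 <- generate_study(small)
  expect_identical(lapply(st$series, `[[`, "states"),
                   lapply(st2$series, `[[`, "states"))
  # every pair has at least one presence record (prevalent-species design)
  expect_true(all(vapply(st$series, function(s) sum(s$states, na.rm = TRUE), 0) > 0))
  # adding a species does not perturb the existing series (substream hashing)
  plus <- small
  plus$species <- default_species()[c(1, 5, 9), ]
  st3 <- generate_study(plus)
  expect_identical(st$series[[1]]$states, st3$series[[1]]$states)

  # a 2-year study yields exactly one transition per patch
  tiny <- study_config(
    streets = data.frame(name = "S1", n_patches = 8L, patch_spacing_m = 8,
                         green_space_distance_m = 10, nearest_green_space = "park"),
    species = default_species()[7, ], years = 2009:2010,
    missing_years = integer(0), rng_seed = 1L)
  expect_equal(build_transitions(generate_study(tiny)$series[[1]])$n_transitions, 8)

  expect_error(study_config(streets = data.frame(
    name = c("A", "A"), n_patches = c(5L, 5L), patch_spacing_m = 8,
    green_space_distance_m = 1, nearest_green_space = "x")), "duplicate")
})

test_that("the default configuration reproduces the published study design", {
  cfg <- study_config(rng_seed = 7L)
  expect_equal(nrow(cfg$streets), 15)
  expect_equal(nrow(cfg$species), 15)
  expect_equal(sum(cfg$streets$n_patches), 1324)
  expect_equal(range(cfg$streets$n_patches), c(31, 186))
  expect_equal(cfg$years, 2009:2015)
  expect_equal(cfg$missing_years, 2013L)
  st <- generate_study(cfg)
  expect_length(st$series, 225)
  expect_true(all(vapply(st$series, function(s) all(is.na(s$states[, "2013"])), TRUE)))
})
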